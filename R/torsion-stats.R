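# First-order torsional (Gibbs) entropy with undersampling correction, and
# pairwise mutual information of torsion-angle distributions.
#
# Entropies are discrete histogram entropies in nats, reported in units of
# the Boltzmann constant k_B. The undersampling (finite-N) correction is
# Miller-Madow: + (M_occ - 1) / (2N) per histogram, applied to marginal and
# joint terms alike; it is switchable because the exact correction used in
# earlier torsional-entropy work is not uniquely pinned down.

#' Bin an angular sample
#'
#' @param angles numeric vector of angles in degrees in `[-180, 180)`;
#'   `NA` values (undefined dihedrals) are dropped.
#' @param bins number of equal-width bins `M` over the full circle
#'   (default 30, i.e. 12-degree bins).
#' @return object of class `angular_histogram` with elements `counts`, `p`,
#'   `bins`, `occupied`, `n`.
#' @export
angular_histogram <- function(angles, bins = 30) {
  angles <- angles[!is.na(angles)]
  if (!length(angles)) stopf("empty angular sample")
  if (any(angles < -180 | angles >= 180)) stopf("angles outside [-180, 180)")
  idx <- pmin(floor((angles + 180) / (360 / bins)) + 1L, bins)
  counts <- tabulate(idx, bins)
  structure(list(counts = counts, p = counts / sum(counts), bins = bins,
                 occupied = sum(counts > 0), n = length(angles)),
            class = "angular_histogram")
}

# Plug-in entropy of a count vector plus the Miller-Madow correction term.
entropy_from_counts <- function(counts, correction = "miller-madow") {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  s_raw <- max(0, -sum(p * log(p)))  # clamp the -0 of a single-bin sample
  corr <- if (correction == "miller-madow") (sum(counts > 0) - 1) / (2 * n) else 0
  list(raw = s_raw, correction = corr, corrected = s_raw + corr)
}

#' First-order torsional entropy
#'
#' Gibbs entropy `S_raw = -sum p_k log p_k` of the binned angular
#' distribution plus the undersampling correction, in k_B units (nats).
#'
#' @param series a [torsion_series()] or a bare numeric vector of angles in
#'   degrees.
#' @param bins histogram bin count `M` (default 30).
#' @param correction `"miller-madow"` (default) or `"none"`.
#' @return object of class `entropy_result`: `S_raw`, `S`, `correction`,
#'   `bins`, `occupied`, `n`.
#' @export
torsion_entropy <- function(series, bins = 30, correction = "miller-madow") {
  angles <- if (inherits(series, "torsion_series")) series$angles else series
  h <- angular_histogram(angles, bins)
  if (h$n < bins)
    warning(sprintf("only %d samples for %d bins; entropy will be noisy",
                    h$n, bins))
  e <- entropy_from_counts(h$counts, correction)
  structure(list(S_raw = e$raw, S = e$corrected, correction = e$correction,
                 bins = bins, occupied = h$occupied, n = h$n),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<entropy_result> S = %.4f k_B (raw %.4f + correction %.4g), M=%d, N=%d\n",
              x$S, x$S_raw, x$correction, x$bins, x$n))
  invisible(x)
}

#' Mutual information between two torsion series
#'
#' `MI = S(a) + S(b) - S(a, b)` with all three entropies estimated by the
#' same histogram estimator (joint on an `M x M` grid) and the undersampling
#' correction applied to each term. Negative estimates are clamped to zero;
#' the raw (unclamped) value is kept alongside.
#'
#' @param a,b [torsion_series()] objects or numeric angle vectors (degrees)
#'   of equal length.
#' @param bins marginal bin count `M`.
#' @param correction `"miller-madow"` or `"none"`.
#' @return list with `mi` (clamped, nats), `mi_raw`, `S_a`, `S_b`, `S_joint`.
#' @export
mutual_information <- function(a, b, bins = 30, correction = "miller-madow") {
  av <- if (inherits(a, "torsion_series")) a$angles else a
  bv <- if (inherits(b, "torsion_series")) b$angles else b
  if (length(av) != length(bv)) stopf("series lengths differ (%d vs %d)",
                                      length(av), length(bv))
  ok <- !is.na(av) & !is.na(bv)
  av <- av[ok]; bv <- bv[ok]
  if (!length(av)) stopf("no jointly defined frames")
  w <- 360 / bins
  ia <- pmin(floor((av + 180) / w) + 1L, bins)
  ib <- pmin(floor((bv + 180) / w) + 1L, bins)
  ca <- tabulate(ia, bins)
  cb <- tabulate(ib, bins)
  cj <- tabulate((ia - 1L) * bins + ib, bins * bins)
  ea <- entropy_from_counts(ca, correction)
  eb <- entropy_from_counts(cb, correction)
  ej <- entropy_from_counts(cj, correction)
  mi_raw <- ea$corrected + eb$corrected - ej$corrected
  list(mi = max(0, mi_raw), mi_raw = mi_raw,
       S_a = ea$corrected, S_b = eb$corrected, S_joint = ej$corrected)
}

#' Extract torsion-angle series from a trajectory ensemble
#'
#' Computes backbone phi/psi (and side-chain chi1 where the atoms exist)
#' for every protein residue, per frame, using the standard signed-dihedral
#' formula. Terminal residues lacking phi or psi are skipped; frames with a
#' collinear atom triplet yield `NA` and are excluded from histograms
#' downstream.
#'
#' @param top a [topology()].
#' @param ens a [trajectory_ensemble()] (already windowed by the caller).
#' @param which `"both"` (default), `"backbone"`, or `"sidechain"`.
#' @return named list of [torsion_series()] (`"R<res>:phi"` etc.).
#' @export
extract_torsions <- function(top, ens, which = c("both", "backbone",
                                                 "sidechain")) {
  which <- match.arg(which)
  coords <- pool_frames(ens)
  run_lengths <- vapply(ens$runs, function(r) dim(r)[1], integer(1))
  a <- top$atoms
  prot <- top$residues[!top$residues$is_ligand, ]
  idx_of <- function(res, nm) {
    i <- a$atom_index[a$resid == res & a$name == nm]
    if (length(i) == 1) i else NA_integer_
  }
  chi1_tip <- c("CG", "CG1", "OG", "OG1", "SG", "CD")  # first match wins
  out <- list()
  add <- function(res, nm, quad) {
    if (anyNA(quad)) return(invisible(NULL))
    ang <- dihedral_angle(coords[, quad[1], ], coords[, quad[2], ],
                          coords[, quad[3], ], coords[, quad[4], ])
    out[[sprintf("R%d:%s", res, nm)]] <<-
      torsion_series(res, nm, ang, run_lengths)
  }
  resids <- prot$resid
  for (k in seq_along(resids)) {
    r <- resids[k]
    if (which != "sidechain") {
      prev_ok <- k > 1 && resids[k - 1] == r - 1
      next_ok <- k < length(resids) && resids[k + 1] == r + 1
      if (prev_ok)
        add(r, "phi", c(idx_of(r - 1, "C"), idx_of(r, "N"),
                        idx_of(r, "CA"), idx_of(r, "C")))
      if (next_ok)
        add(r, "psi", c(idx_of(r, "N"), idx_of(r, "CA"),
                        idx_of(r, "C"), idx_of(r + 1, "N")))
    }
    if (which != "backbone") {
      cb <- idx_of(r, "CB")
      if (!is.na(cb)) {
        tip <- NA_integer_
        for (nm in chi1_tip) {
          tip <- idx_of(r, nm)
          if (!is.na(tip)) break
        }
        add(r, "chi1", c(idx_of(r, "N"), idx_of(r, "CA"), cb, tip))
      }
    }
  }
  out
}

#' Per-torsion entropy table
#'
#' @param series named list of [torsion_series()].
#' @inheritParams torsion_entropy
#' @return data.frame with columns `residue_id`, `torsion`, `S_raw`,
#'   `correction`, `S`, `n`.
#' @export
torsion_entropy_table <- function(series, bins = 30,
                                  correction = "miller-madow") {
  rows <- lapply(series, function(s) {
    e <- torsion_entropy(s, bins, correction)
    data.frame(residue_id = s$residue_id, torsion = s$torsion_name,
               S_raw = e$S_raw, correction = e$correction, S = e$S, n = e$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Total torsional entropy of a region
#'
#' Sums the corrected per-torsion entropies over all torsions of all
#' residues in the region, with per-loop subtotals when the region carries
#' loop definitions.
#'
#' @param entropy_table output of [torsion_entropy_table()].
#' @param region a [region_set()]; every region residue must have at least
#'   one torsion entry.
#' @return list with `total` (k_B) and `per_loop` (named numeric or `NULL`).
#' @export
region_entropy <- function(entropy_table, region) {
  stopifnot(inherits(region, "region_set"))
  miss <- setdiff(region$residues, entropy_table$residue_id)
  if (length(miss))
    stopf("region '%s' residues without torsion results: %s", region$name,
          paste(miss, collapse = ", "))
  sum_over <- function(ids)
    sum(entropy_table$S[entropy_table$residue_id %in% ids])
  per_loop <- NULL
  if (!is.null(region$loops))
    per_loop <- vapply(region$loops, sum_over, numeric(1))
  list(total = sum_over(region$residues), per_loop = per_loop)
}

#' Residue-pair mutual information matrix
#'
#' Residue-level MI is aggregated over all (torsion-of-i, torsion-of-j)
#' combinations; the default aggregation is the maximum, recording which
#' torsion pair attained it. The result is symmetric by construction.
#'
#' @param series named list of [torsion_series()].
#' @param pairs optional 2-column matrix / data.frame of residue-id pairs;
#'   default all residue pairs present in `series`.
#' @param bins histogram bin count.
#' @param aggregate `"max"` (default), `"sum"`, or `"mean"`.
#' @param correction passed to [mutual_information()].
#' @return object of class `mi_matrix`: long-form data.frame with columns
#'   `res_i`, `res_j`, `mi`, `torsion_i`, `torsion_j` (attaining pair; `NA`
#'   for sum/mean aggregation).
#' @export
mi_matrix <- function(series, pairs = NULL, bins = 30,
                      aggregate = c("max", "sum", "mean"),
                      correction = "miller-madow") {
  aggregate <- match.arg(aggregate)
  res_ids <- sort(unique(vapply(series, function(s) s$residue_id, integer(1))))
  by_res <- split(series, vapply(series, function(s) s$residue_id, integer(1)))
  if (is.null(pairs)) {
    if (length(res_ids) < 2) stopf("need at least two residues")
    pairs <- t(utils::combn(res_ids, 2))
  } else {
    pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
    bad <- !(pairs %in% res_ids)
    if (any(bad)) stopf("pair list references residues without torsions: %s",
                        paste(unique(pairs[bad]), collapse = ", "))
  }
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- min(pairs[k, ]); j <- max(pairs[k, ])
    si <- by_res[[as.character(i)]]
    sj <- by_res[[as.character(j)]]
    vals <- expand.grid(a = seq_along(si), b = seq_along(sj))
    mis <- mapply(function(ai, bi)
      mutual_information(si[[ai]], sj[[bi]], bins, correction)$mi,
      vals$a, vals$b)
    mi <- switch(aggregate, max = max(mis), sum = sum(mis), mean = mean(mis))
    best <- if (aggregate == "max") which.max(mis) else NA_integer_
    rows[[k]] <- data.frame(
      res_i = i, res_j = j, mi = mi,
      torsion_i = if (is.na(best)) NA_character_ else
        si[[vals$a[best]]]$torsion_name,
      torsion_j = if (is.na(best)) NA_character_ else
        sj[[vals$b[best]]]$torsion_name,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mi_matrix", "data.frame")
  out
}

#' Look up an MI value in an mi_matrix
#'
#' @param mi an [mi_matrix()].
#' @param i,j residue ids (order-free).
#' @return MI in nats, or `NA` if the pair is absent.
#' @export
mi_lookup <- function(mi, i, j) {
  a <- min(i, j); b <- max(i, j)
  hit <- mi$res_i == a & mi$res_j == b
  if (!any(hit)) NA_real_ else mi$mi[which(hit)[1]]
}
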