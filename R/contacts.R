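# Ligand-receptor contact detection and statistics.
#
# Two contact kinds are recognised, matching common MD practice:
#   hbond - heteroatom (N/O) pair within 3.5 A with a donor-H-acceptor
#           angle of at least 120 degrees;
#   vdw   - any ligand-carbon / residue-carbon pair within 4.0 A.
# A contact is "sustained" when present in strictly more than 40% of the
# analysis frames pooled over runs (occupancy exactly 0.40 is not
# sustained).

SUSTAINED_THRESHOLD <- 0.40

# Frame coordinates as an atoms x 3 matrix from a pooled array.
frame_coords <- function(coords, f) matrix(coords[f, , ], ncol = 3)

# Hydrogens bonded to a heavy atom: same residue, within 1.25 A.
attached_h <- function(top, frame, heavy_idx) {
  a <- top$atoms
  same_res <- a$atom_index[a$resid == a$resid[heavy_idx] & a$element == "H"]
  if (!length(same_res)) return(integer(0))
  d <- cross_dist(matrix(frame[heavy_idx, ], ncol = 3),
                  matrix(frame[same_res, ], ncol = 3))
  same_res[d[1, ] <= 1.25]
}

# Infer an ideal donor-H position from heavy-atom geometry: 1.0 A from the
# donor, directed away from the mean of its bonded heavy neighbours
# (within 1.8 A, same residue).
infer_h_position <- function(top, frame, donor_idx) {
  a <- top$atoms
  cand <- a$atom_index[a$resid == a$resid[donor_idx] & a$element != "H" &
                         a$atom_index != donor_idx]
  if (!length(cand)) stopf("cannot infer H: donor atom %d has no neighbours",
                           donor_idx)
  d <- cross_dist(matrix(frame[donor_idx, ], ncol = 3),
                  matrix(frame[cand, ], ncol = 3))
  nb <- cand[d[1, ] <= 1.8]
  if (!length(nb)) nb <- cand[which.min(d[1, ])]
  dir <- frame[donor_idx, ] - colMeans(matrix(frame[nb, ], ncol = 3))
  nrm <- sqrt(sum(dir^2))
  if (nrm < 1e-9) stopf("cannot infer H: degenerate neighbour geometry")
  frame[donor_idx, ] + dir / nrm
}

angle_deg <- function(a, b, c) {
  # angle at b (degrees)
  u <- a - b; v <- c - b
  rad2deg(acos(pmax(-1, pmin(1, sum(u * v) /
                               (sqrt(sum(u^2)) * sqrt(sum(v^2)))))))
}

#' Hydrogen-bond detection in one frame
#'
#' Tests every heteroatom (N, O) pair between two atom groups against the
#' geometric gate: heavy-atom distance `<= dist_cutoff` and donor-H-acceptor
#' angle `>= angle_cutoff` for at least one hydrogen on either heavy atom
#' (both donor directions are tried). If a candidate donor carries no
#' explicit hydrogen, an ideal H is inferred from heavy-atom geometry when
#' `infer_h = TRUE`, otherwise detection fails.
#'
#' @param top a [topology()].
#' @param frame `atoms x 3` coordinate matrix.
#' @param group_a,group_b atom index vectors (e.g. ligand vs one residue).
#' @param dist_cutoff heavy-atom N/O distance cutoff, A (default 3.5).
#' @param angle_cutoff donor-H-acceptor angle cutoff, degrees (default 120).
#' @param infer_h infer missing donor hydrogens from geometry.
#' @return data.frame of candidate pairs: `atom_a`, `atom_b`, `distance`,
#'   `angle` (best donor-H-acceptor angle, NA if distance gate fails),
#'   `contact`, `h_inferred`.
#' @export
detect_hbond_frame <- function(top, frame, group_a, group_b,
                               dist_cutoff = 3.5, angle_cutoff = 120,
                               infer_h = TRUE) {
  a <- top$atoms
  ha <- group_a[a$element[group_a] %in% c("N", "O")]
  hb <- group_b[a$element[group_b] %in% c("N", "O")]
  if (!length(ha) || !length(hb))
    return(data.frame(atom_a = integer(0), atom_b = integer(0),
                      distance = numeric(0), angle = numeric(0),
                      contact = logical(0), h_inferred = logical(0)))
  grid <- expand.grid(atom_a = ha, atom_b = hb)
  out <- data.frame(grid, distance = NA_real_, angle = NA_real_,
                    contact = FALSE, h_inferred = FALSE)
  for (k in seq_len(nrow(out))) {
    i <- out$atom_a[k]; j <- out$atom_b[k]
    dist <- sqrt(sum((frame[i, ] - frame[j, ])^2))
    out$distance[k] <- dist
    if (dist > dist_cutoff) next
    best <- -Inf; inferred <- FALSE
    h_i <- attached_h(top, frame, i)
    h_j <- attached_h(top, frame, j)
    if (!length(h_i) && !length(h_j)) {
      # no explicit hydrogen on either side: infer an ideal donor H (on
      # both candidates, taking the best geometry) or fail
      if (!infer_h)
        stopf("no hydrogen on atoms %d/%d and inference is disabled", i, j)
      inferred <- TRUE
      ok <- FALSE
      for (dir in list(c(i, j), c(j, i))) {
        hp <- tryCatch(infer_h_position(top, frame, dir[1]),
                       error = function(e) NULL)
        if (is.null(hp)) next
        ok <- TRUE
        best <- max(best, angle_deg(frame[dir[1], ], hp, frame[dir[2], ]))
      }
      if (!ok) stopf("cannot infer a donor hydrogen for atoms %d/%d", i, j)
    } else {
      for (h in h_i)
        best <- max(best, angle_deg(frame[i, ], frame[h, ], frame[j, ]))
      for (h in h_j)
        best <- max(best, angle_deg(frame[j, ], frame[h, ], frame[i, ]))
    }
    out$angle[k] <- best
    out$h_inferred[k] <- inferred
    out$contact[k] <- best >= angle_cutoff
  }
  out
}

#' Van der Waals contact detection in one frame
#'
#' A residue is in vdW contact with the ligand iff any ligand-carbon to
#' residue-carbon distance is `<=` the cutoff. Residues without carbon atoms
#' can never be in vdW contact.
#'
#' @inheritParams detect_hbond_frame
#' @param dist_cutoff C-C distance cutoff, A (default 4.0).
#' @return list with `contact` (logical) and `min_cc` (minimum C-C distance,
#'   `Inf` if either group has no carbons).
#' @export
detect_vdw_frame <- function(top, frame, group_a, group_b,
                             dist_cutoff = 4.0) {
  a <- top$atoms
  ca <- group_a[a$element[group_a] == "C"]
  cb <- group_b[a$element[group_b] == "C"]
  if (!length(ca) || !length(cb))
    return(list(contact = FALSE, min_cc = Inf))
  mind <- min(cross_dist(matrix(frame[ca, ], ncol = 3),
                         matrix(frame[cb, ], ncol = 3)))
  list(contact = mind <= dist_cutoff, min_cc = mind)
}

# Min distance between the contact-defining atom sets of a pair of groups.
contact_defining_distance <- function(top, frame, group_a, group_b, kind) {
  a <- top$atoms
  pick <- function(g) switch(kind,
    hbond = g[a$element[g] %in% c("N", "O")],
    vdw = g[a$element[g] == "C"],
    any = g[a$element[g] != "H"])
  ga <- pick(group_a); gb <- pick(group_b)
  if (!length(ga) || !length(gb)) return(Inf)
  min(cross_dist(matrix(frame[ga, ], ncol = 3),
                 matrix(frame[gb, ], ncol = 3)))
}

#' Ligand-residue contact occupancy
#'
#' Fraction of analysis frames (pooled over runs) in which the given
#' residue is in contact with the ligand, for one contact kind or for any.
#' When a residue touches the ligand through several atoms, all pairs count
#' toward the same residue-level contact (their occupancy is the fraction
#' of frames with at least one qualifying pair). The sustained flag follows
#' the strict rule: occupancy must exceed 0.40.
#'
#' @param top a [topology()].
#' @param ens a [trajectory_ensemble()] (already windowed).
#' @param residue receptor residue id.
#' @param kind `"hbond"`, `"vdw"`, or `"any"` (either kind counts).
#' @param ligand atom indices of the ligand; default all `is_ligand` atoms.
#' @param ... passed to the frame detectors (cutoffs, `infer_h`).
#' @return object of class `contact_record`: `residue_id`, `kind`,
#'   `occupancy`, `sustained`, `mean_distance_contact` (over in-contact
#'   frames, NA if never in contact), `mean_distance_all` (over all frames),
#'   `n_frames`.
#' @export
contact_occupancy <- function(top, ens, residue, kind = c("hbond", "vdw",
                                                          "any"),
                              ligand = NULL, ...) {
  kind <- match.arg(kind)
  if (!residue %in% top$residues$resid) stopf("unknown residue %s", residue)
  ligand <- ligand %||% atom_select(top, "ligand")
  if (!length(ligand)) stopf("topology has no ligand atoms")
  res_atoms <- top$atoms$atom_index[top$atoms$resid == residue]
  coords <- pool_frames(ens)
  nf <- dim(coords)[1]
  hit <- logical(nf)
  dists <- numeric(nf)
  for (f in seq_len(nf)) {
    fr <- frame_coords(coords, f)
    in_h <- in_v <- FALSE
    if (kind %in% c("hbond", "any"))
      in_h <- any(detect_hbond_frame(top, fr, ligand, res_atoms, ...)$contact)
    if (kind %in% c("vdw", "any"))
      in_v <- detect_vdw_frame(top, fr, ligand, res_atoms)$contact
    hit[f] <- in_h || in_v
    dists[f] <- contact_defining_distance(top, fr, ligand, res_atoms, kind)
  }
  occ <- mean(hit)
  structure(list(residue_id = residue, kind = kind, occupancy = occ,
                 sustained = occ > SUSTAINED_THRESHOLD,
                 mean_distance_contact = if (any(hit)) mean(dists[hit])
                                         else NA_real_,
                 mean_distance_all = mean(dists), n_frames = nf),
            class = "contact_record")
}

#' @export
print.contact_record <- function(x, ...) {
  cat(sprintf("<contact_record> residue %d %s: occupancy %.1f%%%s, mean dist %.2f A\n",
              x$residue_id, x$kind, 100 * x$occupancy,
              if (x$sustained) " (sustained)" else "",
              x$mean_distance_all))
  invisible(x)
}

#' Contact table for a set of residues
#'
#' Convenience wrapper producing the per-residue table (both kinds plus the
#' combined any-contact occupancy) reported by the pipeline.
#'
#' @inheritParams contact_occupancy
#' @param residues residue ids to test.
#' @return data.frame with one row per (residue, kind).
#' @export
contact_table <- function(top, ens, residues, ligand = NULL, ...) {
  rows <- list()
  for (r in residues) for (k in c("hbond", "vdw", "any")) {
    cr <- contact_occupancy(top, ens, r, k, ligand = ligand, ...)
    rows[[length(rows) + 1]] <- data.frame(
      residue_id = r, kind = k, occupancy = cr$occupancy,
      occupancy_pct = 100 * cr$occupancy, sustained = cr$sustained,
      mean_distance_contact = cr$mean_distance_contact,
      mean_distance_all = cr$mean_distance_all)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean ligand-residue contact distance
#'
#' Mean over analysis frames of the minimum distance between the
#' contact-defining atom sets (N/O pairs for hbond, C/C for vdw, heavy
#' atoms for `"any"`).
#'
#' @inheritParams contact_occupancy
#' @param kind atom-pair policy.
#' @return mean distance in Angstrom.
#' @export
mean_contact_distance <- function(top, ens, residue,
                                  kind = c("any", "hbond", "vdw"),
                                  ligand = NULL) {
  kind <- match.arg(kind)
  if (!residue %in% top$residues$resid) stopf("unknown residue %s", residue)
  ligand <- ligand %||% atom_select(top, "ligand")
  res_atoms <- top$atoms$atom_index[top$atoms$resid == residue]
  coords <- pool_frames(ens)
  nf <- dim(coords)[1]
  if (!nf) stopf("empty frame set")
  d <- vapply(seq_len(nf), function(f)
    contact_defining_distance(top, frame_coords(coords, f), ligand,
                              res_atoms, kind), numeric(1))
  mean(d)
}

#' Nonbonded parameter set
#'
#' Per-atom partial charges and Lennard-Jones parameters for the simple
#' interaction-energy model. Parameters are matched to atoms by index.
#'
#' @param charge per-atom partial charge, e.
#' @param sigma per-atom LJ sigma, A.
#' @param epsilon per-atom LJ epsilon `>= 0`, kcal/mol.
#' @param combining `"lorentz-berthelot"` (arithmetic sigma, geometric
#'   epsilon) or `"geometric"`.
#' @param coulomb_k Coulomb constant, kcal A / (mol e^2).
#' @return object of class `nonbonded_params`.
#' @export
nonbonded_params <- function(charge, sigma, epsilon,
                             combining = c("lorentz-berthelot", "geometric"),
                             coulomb_k = 332.0636) {
  combining <- match.arg(combining)
  if (any(epsilon < 0)) stopf("epsilon must be non-negative")
  n <- length(charge)
  if (length(sigma) != n || length(epsilon) != n)
    stopf("charge, sigma, epsilon must have equal length (one per atom)")
  structure(list(charge = charge, sigma = sigma, epsilon = epsilon,
                 combining = combining, coulomb_k = coulomb_k),
            class = "nonbonded_params")
}

#' Ligand-receptor nonbonded interaction energy
#'
#' Per frame, sums Coulomb and Lennard-Jones terms over all inter-group
#' atom pairs (no cutoff; intended for small toy systems):
#' `k q_i q_j / r + 4 eps_ij ((sig_ij/r)^12 - (sig_ij/r)^6)`, then averages
#' over the analysis frames.
#'
#' @param top a [topology()].
#' @param ens a [trajectory_ensemble()] (already windowed).
#' @param params a [nonbonded_params()] covering every atom in the topology.
#' @param group_a,group_b atom index vectors.
#' @return list with `mean`, `sd` (kcal/mol over frames), `per_frame`,
#'   and the mean `coulomb` and `vdw` components.
#' @export
interaction_energy <- function(top, ens, params, group_a, group_b) {
  stopifnot(inherits(params, "nonbonded_params"))
  na <- n_atoms(top)
  if (length(params$charge) != na)
    stopf("parameters cover %d atoms but topology has %d (missing: %s)",
          length(params$charge), na,
          paste(setdiff(seq_len(na), seq_along(params$charge)),
                collapse = ", "))
  qa <- params$charge[group_a]; qb <- params$charge[group_b]
  qq <- params$coulomb_k * outer(qa, qb)
  if (params$combining == "lorentz-berthelot") {
    sij <- outer(params$sigma[group_a], params$sigma[group_b], `+`) / 2
  } else {
    sij <- sqrt(outer(params$sigma[group_a], params$sigma[group_b]))
  }
  eij <- sqrt(outer(params$epsilon[group_a], params$epsilon[group_b]))
  coords <- pool_frames(ens)
  nf <- dim(coords)[1]
  etot <- ecoul <- evdw <- numeric(nf)
  for (f in seq_len(nf)) {
    fr <- frame_coords(coords, f)
    r <- cross_dist(matrix(fr[group_a, ], ncol = 3),
                    matrix(fr[group_b, ], ncol = 3))
    sr6 <- (sij / r)^6
    ecoul[f] <- sum(qq / r)
    evdw[f] <- sum(4 * eij * (sr6^2 - sr6))
    etot[f] <- ecoul[f] + evdw[f]
  }
  list(mean = mean(etot), sd = if (nf > 1) sd(etot) else 0,
       per_frame = etot, coulomb = mean(ecoul), vdw = mean(evdw))
}
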