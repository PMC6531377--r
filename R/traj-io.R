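# Topology and multi-run trajectory ensemble I/O.
#
# PDB parsing/writing is delegated to bio3d; the package wraps the result in
# a light topology container keyed by 1-based author residue numbering.
# Trajectories use a documented plain-text dialect (one header line with
# n_atoms and n_frames, then one "x y z" line per atom per frame, Angstrom),
# written at full double precision so disk round-trips are exact.

#' Construct a topology
#'
#' @param atoms data.frame with columns `atom_index` (unique, contiguous
#'   from 1), `name`, `element`, `resid` (author residue number), `resname`,
#'   `chain`, `is_ligand` (logical).
#' @param xyz optional reference coordinates, `n_atoms x 3` matrix (A).
#' @param bw optional named character vector of Ballesteros-Weinstein labels
#'   keyed by residue id.
#' @return object of class `topology`.
#' @export
topology <- function(atoms, xyz = NULL, bw = NULL) {
  need <- c("atom_index", "name", "element", "resid", "resname", "chain",
            "is_ligand")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("atoms is missing columns: %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$atom_index) ||
      !identical(sort(atoms$atom_index), seq_len(nrow(atoms))))
    stopf("atom indices must be unique and contiguous from 1")
  atoms <- atoms[order(atoms$atom_index), ]
  if (!is.null(xyz)) {
    xyz <- as.matrix(xyz)
    if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3)
      stopf("xyz must be an n_atoms x 3 matrix")
  }
  res <- unique(atoms[, c("chain", "resid", "resname", "is_ligand")])
  res <- res[order(res$chain, res$resid), ]
  if (anyDuplicated(res$resid))
    stopf("residue ids must be unique across chains in v1")
  structure(list(atoms = atoms, xyz = xyz, residues = res, bw = bw),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms, %d residues (%d ligand)\n",
              nrow(x$atoms), nrow(x$residues), sum(x$residues$is_ligand)))
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Select atom indices from a topology
#'
#' @param top a [topology()].
#' @param what `"calpha"`, `"heavy"`, `"ligand"`, `"receptor"`, `"all"`, or
#'   a character vector of atom names.
#' @param resid optional residue id filter.
#' @return integer vector of atom indices.
#' @export
atom_select <- function(top, what = "all", resid = NULL) {
  a <- top$atoms
  keep <- switch(what[1],
    all = rep(TRUE, nrow(a)),
    calpha = a$name == "CA" & !a$is_ligand,
    heavy = a$element != "H",
    ligand = a$is_ligand,
    receptor = !a$is_ligand,
    a$name %in% what)
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  a$atom_index[keep]
}

#' Read a PDB topology
#'
#' Parses ATOM/HETATM records via `bio3d::read.pdb`; HETATM residues are
#' flagged as ligand. Residues are ordered by (chain, residue number).
#' Duplicate atom serials and insertion codes are rejected (insertion codes
#' are unsupported in v1).
#'
#' @param path PDB file.
#' @return a [topology()] carrying the file's coordinates as `xyz`.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stopf("unparseable PDB %s: %s",
                                            path, conditionMessage(e)))
  at <- pdb$atom
  if (anyDuplicated(at$eleno)) stopf("duplicate atom serials in %s", path)
  ins <- !is.na(at$insert) & at$insert != ""
  if (any(ins)) stopf("insertion codes are unsupported (residues: %s)",
                      paste(unique(at$resno[ins]), collapse = ", "))
  ord <- order(at$chain, at$resno, at$eleno)
  at <- at[ord, ]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(gsub("[0-9']", "", at$elety), 1, 1)
  elem[is.na(elem) | elem == ""] <-
    substr(gsub("[0-9']", "", at$elety[is.na(elem) | elem == ""]), 1, 1)
  atoms <- data.frame(atom_index = seq_len(nrow(at)),
                      name = at$elety, element = toupper(trimws(elem)),
                      resid = at$resno, resname = at$resid,
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      is_ligand = at$type == "HETATM",
                      stringsAsFactors = FALSE)
  topology(atoms, xyz = cbind(at$x, at$y, at$z))
}

#' Write a topology as PDB
#'
#' @param top a [topology()]; must carry reference coordinates.
#' @param path output file.
#' @export
write_topology <- function(top, path) {
  if (is.null(top$xyz)) stopf("topology has no reference coordinates")
  a <- top$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(top$xyz)),
                   type = ifelse(a$is_ligand, "HETATM", "ATOM"),
                   resno = a$resid, resid = a$resname, eleno = a$atom_index,
                   elety = a$name, chain = a$chain,
                   elesy = a$element)
  invisible(path)
}

#' Construct a trajectory ensemble
#'
#' @param runs list of coordinate arrays, each `frames x atoms x 3` (A).
#' @return object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(runs) {
  if (!length(runs)) stopf("ensemble needs at least one run")
  na <- vapply(runs, function(r) dim(r)[2], integer(1))
  if (length(unique(na)) != 1) stopf("runs disagree on atom count")
  if (any(vapply(runs, function(r) dim(r)[1], integer(1)) < 1))
    stopf("empty run")
  structure(list(runs = runs), class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %d run(s), frames: %s, %d atoms\n",
              length(x$runs),
              paste(vapply(x$runs, function(r) dim(r)[1], integer(1)),
                    collapse = "/"),
              dim(x$runs[[1]])[2]))
  invisible(x)
}

#' Keep the trailing analysis window of each run
#'
#' Mirrors the convention of analysing only the last part of each replicate
#' simulation (default: the last half, e.g. the last 100 ns of 200 ns runs).
#' The window is applied per run, never across concatenated runs. The
#' retained length is `floor(fraction * frames)` taken from the run's tail.
#'
#' @param ens a [trajectory_ensemble()].
#' @param fraction fraction of each run to keep, `0 < fraction <= 1`.
#' @return a new [trajectory_ensemble()].
#' @export
select_analysis_frames <- function(ens, fraction = 0.5) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stopf("fraction must be in (0, 1]")
  runs <- lapply(ens$runs, function(r) {
    f <- dim(r)[1]
    keep <- floor(fraction * f)
    if (keep < 1) stopf("analysis window empty for a %d-frame run", f)
    r[(f - keep + 1):f, , , drop = FALSE]
  })
  trajectory_ensemble(runs)
}

# Pool the frames of all runs into one frames x atoms x 3 array.
pool_frames <- function(ens) {
  if (length(ens$runs) == 1) return(ens$runs[[1]])
  do.call(abind3, ens$runs)
}

abind3 <- function(...) {
  parts <- list(...)
  A <- dim(parts[[1]])[2]
  out <- array(0, dim = c(sum(vapply(parts, function(p) dim(p)[1], 1L)), A, 3))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Write one run in the plain-text trajectory dialect
#'
#' Format: header line `n_atoms n_frames`, then for each frame `n_atoms`
#' lines of whitespace-separated `x y z` (A). Values are written at full
#' double precision (17 significant digits) so that write/read round-trips
#' are numerically exact.
#'
#' @param run coordinate array `frames x atoms x 3`.
#' @param path output file.
#' @export
write_trajectory <- function(run, path) {
  d <- dim(run)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", d[2], d[1]), con)
  # flatten to (frames*atoms) x 3, frame-major
  m <- matrix(aperm(run, c(2, 1, 3)), d[1] * d[2], 3)
  writeLines(sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3]), con)
  invisible(path)
}

#' Read one run in the plain-text trajectory dialect
#'
#' @param path file written by [write_trajectory()].
#' @return coordinate array `frames x atoms x 3`.
#' @export
read_trajectory <- function(path) {
  hdr <- scan(path, what = integer(), n = 2, quiet = TRUE)
  if (length(hdr) != 2 || any(hdr < 1)) stopf("bad trajectory header in %s", path)
  na <- hdr[1]; nf <- hdr[2]
  vals <- scan(path, what = double(), skip = 1, quiet = TRUE)
  if (length(vals) != na * nf * 3)
    stopf("trajectory %s truncated: expected %d values, found %d",
          path, na * nf * 3, length(vals))
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  aperm(array(m, dim = c(na, nf, 3)), c(2, 1, 3))
}
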