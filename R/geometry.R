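# Flexibility maps, ligand spatial density, binding-site volume, and
# activation-state projections.

#' Bondi van der Waals radii (Angstrom)
#'
#' Default clash radii for the pocket-volume grid; any named numeric vector
#' keyed by element symbol may be substituted.
#' @export
bondi_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

#' Per-atom root-mean-square fluctuation
#'
#' Superposes every pooled analysis frame onto a reference by least squares
#' over the fit selection, then computes
#' `RMSF_i = sqrt(mean_f |x_i(f) - <x_i>|^2)` about the ensemble-average
#' structure. The reference is the ensemble average itself, obtained by a
#' two-pass fit (fit to the first frame, average, refit to the average).
#' For isotropic per-axis Gaussian jitter of amplitude sigma, the expected
#' RMSF is `sigma * sqrt(3)`.
#'
#' @param ens a [trajectory_ensemble()] (already windowed).
#' @param selection atom indices to report RMSF for.
#' @param fit_selection atom indices used for superposition; defaults to
#'   `selection`. Needs `>= 3` atoms.
#' @param superpose set `FALSE` to skip superposition (coordinates already
#'   in a common frame).
#' @return named numeric vector of RMSF (A) for `selection`.
#' @export
compute_rmsf <- function(ens, selection, fit_selection = selection,
                         superpose = TRUE) {
  if (!length(selection)) stopf("selection is empty")
  coords <- pool_frames(ens)
  nf <- dim(coords)[1]
  if (nf < 2) stopf("need at least two frames")
  if (superpose) {
    if (length(fit_selection) < 3)
      stopf("fit selection needs at least 3 atoms")
    ref <- frame_coords(coords, 1)
    for (f in seq_len(nf))
      coords[f, , ] <- superpose_frame(frame_coords(coords, f), ref,
                                       fit_selection)
    ref <- apply(coords, c(2, 3), mean)
    for (f in seq_len(nf))
      coords[f, , ] <- superpose_frame(frame_coords(coords, f), ref,
                                       fit_selection)
  }
  avg <- apply(coords[, selection, , drop = FALSE], c(2, 3), mean)
  avg <- matrix(avg, ncol = 3)
  dev2 <- matrix(0, nf, length(selection))
  for (k in 1:3)
    dev2 <- dev2 + sweep(matrix(coords[, selection, k],
                                ncol = length(selection)),
                         2, avg[, k])^2
  setNames(sqrt(colMeans(dev2)), selection)
}

#' Convert RMSF to a thermal B-factor
#'
#' `B = (8 pi^2 / 3) * RMSF^2`, in square Angstrom.
#'
#' @param rmsf RMSF value(s) in Angstrom, `>= 0`.
#' @return B-factor(s) in A^2.
#' @export
rmsf_to_bfactor <- function(rmsf) {
  if (any(rmsf < 0)) stopf("RMSF must be non-negative")
  (8 * pi^2 / 3) * rmsf^2
}

#' Write per-residue B-factors into a PDB B-factor column
#'
#' For rendering flexibility heat maps on the structure.
#'
#' @param top a [topology()] with reference coordinates.
#' @param bfactor named numeric vector keyed by residue id.
#' @param path output PDB.
#' @export
write_bfactor_pdb <- function(top, bfactor, path) {
  if (is.null(top$xyz)) stopf("topology has no reference coordinates")
  a <- top$atoms
  b <- bfactor[as.character(a$resid)]
  b[is.na(b)] <- 0
  bio3d::write.pdb(file = path, xyz = as.numeric(t(top$xyz)),
                   type = ifelse(a$is_ligand, "HETATM", "ATOM"),
                   resno = a$resid, resid = a$resname, eleno = a$atom_index,
                   elety = a$name, chain = a$chain, elesy = a$element,
                   b = round(b, 2))
  invisible(path)
}

#' Spatial distribution function of tracked atoms
#'
#' Superposes every frame onto the first frame's alignment selection, then
#' bins the tracked atom positions on a regular 3D grid. Events falling
#' outside the grid are tallied separately.
#'
#' @param ens a [trajectory_ensemble()] (already windowed).
#' @param tracked_atoms atom indices whose density is accumulated.
#' @param alignment_selection atom indices for superposition (`>= 3`); set
#'   `NULL` to skip alignment.
#' @param grid_spacing voxel edge, A.
#' @param pad grid padding beyond the tracked atoms' bounding box, A.
#' @return object of class `density_grid`: `origin`, `spacing`, `counts`
#'   (3D array), `n_frames`, `n_outside`.
#' @export
spatial_distribution <- function(ens, tracked_atoms, alignment_selection,
                                 grid_spacing = 1.0, pad = 2.0) {
  if (!length(tracked_atoms)) stopf("no tracked atoms")
  coords <- pool_frames(ens)
  nf <- dim(coords)[1]
  if (!is.null(alignment_selection)) {
    if (length(alignment_selection) < 3)
      stopf("degenerate alignment selection (need >= 3 atoms)")
    ref <- frame_coords(coords, 1)
    for (f in seq_len(nf))
      coords[f, , ] <- superpose_frame(frame_coords(coords, f), ref,
                                       alignment_selection)
  }
  pts <- matrix(coords[, tracked_atoms, ], ncol = 3)
  origin <- floor(apply(pts, 2, min)) - pad
  upper <- ceiling(apply(pts, 2, max)) + pad
  nvox <- pmax(1L, as.integer(ceiling((upper - origin) / grid_spacing)))
  idx <- sweep(pts, 2, origin)
  idx <- floor(idx / grid_spacing) + 1
  inside <- idx[, 1] >= 1 & idx[, 1] <= nvox[1] &
            idx[, 2] >= 1 & idx[, 2] <= nvox[2] &
            idx[, 3] >= 1 & idx[, 3] <= nvox[3]
  counts <- array(0L, dim = nvox)
  if (any(inside)) {
    lin <- (idx[inside, 3] - 1) * nvox[1] * nvox[2] +
      (idx[inside, 2] - 1) * nvox[1] + idx[inside, 1]
    tab <- tabulate(lin, prod(nvox))
    counts <- array(tab, dim = nvox)
  }
  structure(list(origin = origin, spacing = grid_spacing, counts = counts,
                 n_frames = nf, n_outside = sum(!inside)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %s voxels @ %.2f A, %d frames, %d outside\n",
              paste(dim(x$counts), collapse = "x"), x$spacing, x$n_frames,
              x$n_outside))
  invisible(x)
}

#' Write a density grid as plain text
#'
#' Header lines give origin, spacing and dimensions; the body lists one
#' `ix iy iz count` line per non-empty voxel.
#'
#' @param grid a [spatial_distribution()] result.
#' @param path output file.
#' @export
write_density_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# origin %.6f %.6f %.6f", grid$origin[1],
                       grid$origin[2], grid$origin[3]),
               sprintf("# spacing %.6f", grid$spacing),
               sprintf("# dims %d %d %d", dim(grid$counts)[1],
                       dim(grid$counts)[2], dim(grid$counts)[3]),
               sprintf("# frames %d outside %d", grid$n_frames,
                       grid$n_outside)), con)
  nz <- which(grid$counts > 0, arr.ind = TRUE)
  if (nrow(nz))
    writeLines(sprintf("%d %d %d %d", nz[, 1], nz[, 2], nz[, 3],
                       grid$counts[nz]), con)
  invisible(path)
}

#' Grid-based binding-site volume of one frame
#'
#' Fills a cubic box centred at the ligand centroid with grid points spaced
#' `spacing` apart, one per voxel, anchored at the box centre (so the centre
#' itself carries a grid point for even grids, mirroring POVME-style
#' centre-outward point construction). Every point within the van der Waals
#' radius of any receptor atom is deleted, and retained points not
#' 6-connected to the core region (a sphere at the box centre) are
#' optionally pruned. The volume is the retained-point count times the
#' voxel volume.
#'
#' @param top a [topology()].
#' @param frame `atoms x 3` coordinate matrix (A).
#' @param ligand ligand atom indices (excluded from the clash set); their
#'   centroid defines the box centre.
#' @param spacing grid resolution, A (default 1).
#' @param box box edge length, A (default 12).
#' @param core_radius core-region sphere radius, A (default 4).
#' @param radii named vdW radius table by element (default [bondi_radii]).
#' @param prune_core prune voxels unreachable from the core sphere.
#' @return object of class `volume_result`: `volume` (A^3), `retained`,
#'   `deleted`, `total_voxels`.
#' @export
pocket_volume <- function(top, frame, ligand, spacing = 1.0, box = 12.0,
                          core_radius = 4.0, radii = bondi_radii,
                          prune_core = TRUE) {
  if (spacing <= 0 || box <= 0) stopf("spacing and box must be positive")
  if (!length(ligand)) stopf("ligand selection is empty")
  centre <- colMeans(matrix(frame[ligand, ], ncol = 3))
  nside <- max(1L, round(box / spacing))
  ax <- centre[1] + spacing * (seq_len(nside) - 1 - floor(nside / 2))
  ay <- centre[2] + spacing * (seq_len(nside) - 1 - floor(nside / 2))
  az <- centre[3] + spacing * (seq_len(nside) - 1 - floor(nside / 2))
  keep <- array(TRUE, dim = c(nside, nside, nside))
  rec <- setdiff(seq_len(n_atoms(top)), ligand)
  maxr <- max(radii)
  for (at in rec) {
    p <- frame[at, ]
    r <- radii[[top$atoms$element[at]]] %||% 1.7
    if (any(p < centre - box / 2 - r) || any(p > centre + box / 2 + r)) next
    dx2 <- (ax - p[1])^2; dy2 <- (ay - p[2])^2; dz2 <- (az - p[3])^2
    clash <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
    keep <- keep & !clash
  }
  deleted <- sum(!keep)
  if (prune_core && any(keep)) {
    dx2 <- (ax - centre[1])^2; dy2 <- (ay - centre[2])^2
    dz2 <- (az - centre[3])^2
    core <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= core_radius^2
    seeds <- which(keep & core)
    reach <- array(FALSE, dim = dim(keep))
    if (length(seeds)) {
      reach[seeds] <- TRUE
      frontier <- seeds
      nvx <- dim(keep)
      while (length(frontier)) {
        arr <- arrayInd(frontier, nvx)
        nxt <- integer(0)
        for (d in 1:3) for (s in c(-1L, 1L)) {
          nb <- arr
          nb[, d] <- nb[, d] + s
          ok <- nb[, d] >= 1 & nb[, d] <= nvx[d]
          if (!any(ok)) next
          lin <- (nb[ok, 3] - 1) * nvx[1] * nvx[2] +
            (nb[ok, 2] - 1) * nvx[1] + nb[ok, 1]
          new <- lin[keep[lin] & !reach[lin]]
          reach[new] <- TRUE
          nxt <- c(nxt, new)
        }
        frontier <- unique(nxt)
      }
    }
    keep <- reach
  }
  retained <- sum(keep)
  structure(list(volume = retained * spacing^3, retained = retained,
                 deleted = deleted, total_voxels = nside^3,
                 spacing = spacing, box = box, core_radius = core_radius),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("<volume_result> %.1f A^3 (%d/%d voxels retained)\n",
              x$volume, x$retained, x$total_voxels))
  invisible(x)
}

#' Binding-site volume over an ensemble
#'
#' Applies [pocket_volume()] to every pooled analysis frame and reports the
#' per-frame series with its mean and SD (frames pooled over runs).
#'
#' @inheritParams pocket_volume
#' @param ens a [trajectory_ensemble()] (already windowed).
#' @param ... passed to [pocket_volume()].
#' @return list with `per_frame` (A^3), `mean`, `sd`.
#' @export
pocket_volume_series <- function(top, ens, ligand, ...) {
  coords <- pool_frames(ens)
  nf <- dim(coords)[1]
  v <- vapply(seq_len(nf), function(f)
    pocket_volume(top, frame_coords(coords, f), ligand, ...)$volume,
    numeric(1))
  list(per_frame = v, mean = mean(v), sd = if (nf > 1) sd(v) else 0)
}

#' Activation-state projection map
#'
#' Per-frame Calpha-Calpha distances for two residue pairs (canonically
#' TM3-TM6 and TM3-TM7), plus a 2D occupancy histogram over a regular grid.
#' Crystal-structure reference points may be attached as annotations.
#'
#' @param top a [topology()].
#' @param ens a [trajectory_ensemble()] (already windowed).
#' @param pairA,pairB length-2 residue-id vectors.
#' @param bin_width 2D histogram bin width, A (default 0.25).
#' @param markers optional data.frame with columns `label`, `dA`, `dB`.
#' @return object of class `state_projection`: `dA`, `dB` (per-frame, A),
#'   `breaksA`, `breaksB`, `map` (2D count matrix), `markers`.
#' @export
state_projection <- function(top, ens, pairA, pairB, bin_width = 0.25,
                             markers = NULL) {
  ca_of <- function(res) {
    i <- atom_select(top, "calpha", resid = res)
    if (length(i) != 1) stopf("residue %s has no (unique) Calpha", res)
    i
  }
  idx <- vapply(c(pairA, pairB), ca_of, integer(1))
  coords <- pool_frames(ens)
  dpair <- function(i, j) sqrt(rowSums((coords[, i, , drop = TRUE] -
                                        coords[, j, , drop = TRUE])^2))
  dA <- dpair(idx[1], idx[2])
  dB <- dpair(idx[3], idx[4])
  brk <- function(d) {
    lo <- floor(min(d) / bin_width) * bin_width
    hi <- ceiling(max(d) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    seq(lo, hi, by = bin_width)
  }
  bA <- brk(dA); bB <- brk(dB)
  ia <- pmin(findInterval(dA, bA, rightmost.closed = TRUE), length(bA) - 1)
  ib <- pmin(findInterval(dB, bB, rightmost.closed = TRUE), length(bB) - 1)
  map <- matrix(tabulate((ib - 1) * (length(bA) - 1) + ia,
                         (length(bA) - 1) * (length(bB) - 1)),
                length(bA) - 1, length(bB) - 1)
  structure(list(dA = dA, dB = dB, breaksA = bA, breaksB = bB, map = map,
                 markers = markers),
            class = "state_projection")
}

#' @export
print.state_projection <- function(x, ...) {
  cat(sprintf("<state_projection> %d frames; dA %.2f-%.2f A, dB %.2f-%.2f A\n",
              length(x$dA), min(x$dA), max(x$dA), min(x$dB), max(x$dB)))
  invisible(x)
}
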