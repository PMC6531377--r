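# Toy receptor/ligand trajectory generator.
#
# The fixture emulates the geometry of a helical-bundle receptor with a
# small ligand in a central pocket: helices are placed on a circle around
# the ligand, atoms fluctuate isotropically with prescribed per-axis sigma,
# and ligand-residue contacts are switched on/off frame-by-frame so that
# engineered occupancies are realised exactly by construction. No force
# field or integrator is involved; the fixture exists so that every
# downstream statistic has a known ground truth.

#' Specify a toy receptor/ligand system
#'
#' @param helix_count,residues_per_helix receptor layout; each residue
#'   carries backbone atoms N, CA, C, O.
#' @param ligand_atom_names ligand atom names; must include a primary-amine
#'   nitrogen (name starting `N`) and a hydroxyl oxygen (name starting `O`).
#'   A donor hydrogen `HN` is added automatically unless an `H*` name is
#'   supplied.
#' @param per_atom_sigma per-axis Gaussian fluctuation amplitude in Angstrom;
#'   scalar, or a vector over all atoms (receptor then ligand). The expected
#'   3D RMSF of an atom is `sigma * sqrt(3)`.
#' @param contact_schedule list of engineered ligand contacts, each a list
#'   with elements `residue`, `kind` (`"hbond"` or `"vdw"`),
#'   `occupancy` in `[0, 1]`, and optionally `d_in` (contact distance,
#'   default 2.9 A for hbond, 3.8 A for vdw) and `d_out` (out-of-contact
#'   distance, default 5.5 / 6.5 A).
#' @param n_runs,frames_per_run ensemble layout.
#' @param seed integer seed.
#' @return an object of class `toy_receptor_spec`.
#' @export
toy_receptor_spec <- function(helix_count = 4, residues_per_helix = 8,
                              ligand_atom_names = c("N1", "C1", "O1"),
                              per_atom_sigma = 0.2,
                              contact_schedule = list(),
                              n_runs = 5, frames_per_run = 200, seed = 1) {
  if (helix_count < 1 || residues_per_helix < 2)
    stopf("receptor must have at least one helix of two residues")
  if (!any(grepl("^N", ligand_atom_names)) ||
      !any(grepl("^O", ligand_atom_names)))
    stopf("ligand_atom_names must include an amine-like N and a hydroxyl-like O")
  if (any(per_atom_sigma < 0)) stopf("fluctuation amplitudes must be >= 0")
  n_res <- helix_count * residues_per_helix
  for (cs in contact_schedule) {
    if (!is.list(cs) || is.null(cs$residue) || is.null(cs$kind) ||
        is.null(cs$occupancy))
      stopf("contact_schedule entries need residue, kind, occupancy")
    if (!cs$kind %in% c("hbond", "vdw")) stopf("contact kind must be hbond or vdw")
    if (cs$occupancy < 0 || cs$occupancy > 1)
      stopf("schedule infeasible: occupancy %g outside [0, 1]", cs$occupancy)
    if (cs$residue < 1 || cs$residue > n_res)
      stopf("scheduled residue %d not in receptor", cs$residue)
  }
  if (!any(grepl("^H", ligand_atom_names)))
    ligand_atom_names <- c(ligand_atom_names, "HN")
  structure(list(helix_count = helix_count,
                 residues_per_helix = residues_per_helix,
                 ligand_atom_names = ligand_atom_names,
                 per_atom_sigma = per_atom_sigma,
                 contact_schedule = contact_schedule,
                 n_runs = n_runs, frames_per_run = frames_per_run,
                 seed = as.integer(seed)),
            class = "toy_receptor_spec")
}

# Base (mean) coordinates: receptor helices on a circle of radius 12 A
# around the ligand at the origin, ideal-helix CA trace, backbone atoms at
# fixed local offsets. Returns list(atoms = data.frame, xyz = matrix).
toy_base_geometry <- function(spec) {
  nres <- spec$helix_count * spec$residues_per_helix
  atoms <- NULL
  xyz <- NULL
  res <- 0
  for (h in seq_len(spec$helix_count)) {
    phi0 <- 2 * pi * (h - 1) / spec$helix_count
    cx <- 12 * cos(phi0); cy <- 12 * sin(phi0)
    for (k in seq_len(spec$residues_per_helix)) {
      res <- res + 1
      t <- deg2rad(100 * (k - 1))
      ca <- c(cx + 2.3 * cos(t), cy + 2.3 * sin(t), 1.5 * (k - 1))
      local <- rbind(N  = ca + c(-1.46, 0.00, -0.50),
                     CA = ca,
                     C  = ca + c(1.52, 0.00, 0.45),
                     O  = ca + c(1.90, 1.05, 1.10))
      atoms <- rbind(atoms, data.frame(
        name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
        resid = res, resname = "ALA", chain = "A", is_ligand = FALSE,
        stringsAsFactors = FALSE))
      xyz <- rbind(xyz, local)
    }
  }
  lig_names <- spec$ligand_atom_names
  lp <- matrix(0, length(lig_names), 3)
  nlig <- which(grepl("^N", lig_names))[1]
  hlig <- which(grepl("^H", lig_names))[1]
  slot <- 0
  for (i in seq_along(lig_names)) {
    if (i == nlig) { lp[i, ] <- c(0, 0, 0) }
    else if (i == hlig) { lp[i, ] <- c(1.0, 0, 0) }
    else { slot <- slot + 1; lp[i, ] <- c(-1.4 * slot, 0.6 * (slot %% 2), 0) }
  }
  atoms <- rbind(atoms, data.frame(
    name = lig_names, element = substr(lig_names, 1, 1),
    resid = nres + 1, resname = "LIG", chain = "L", is_ligand = TRUE,
    stringsAsFactors = FALSE))
  xyz <- rbind(xyz, lp)
  rownames(xyz) <- NULL
  atoms$atom_index <- seq_len(nrow(atoms))
  list(atoms = atoms, xyz = xyz)
}

# Deterministic contact-frame masks: the target occupancy is realised
# separately within the first and last half of each run (so a trailing-half
# analysis window sees the same occupancy), via a seeded permutation.
schedule_masks <- function(occupancy, n_runs, frames_per_run) {
  masks <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    half1 <- floor(frames_per_run / 2)
    half2 <- frames_per_run - half1
    m <- logical(frames_per_run)
    k1 <- floor(occupancy * half1 + 0.5)
    k2 <- floor(occupancy * half2 + 0.5)
    if (half1 > 0) m[sample.int(half1, k1)] <- TRUE
    m[half1 + sample.int(half2, k2)] <- TRUE
    masks[[r]] <- m
  }
  masks
}

#' Generate a toy receptor/ligand trajectory ensemble
#'
#' Builds the topology and a multi-run coordinate ensemble from a
#' [toy_receptor_spec()]. All atoms jitter isotropically about their base
#' positions with the prescribed per-axis sigma; atoms that define a
#' scheduled contact are pinned (no jitter) and are moved between an
#' in-contact and an out-of-contact position so that the target occupancy is
#' met within `1/frames_per_run` by construction, in every half-run window.
#' For `hbond` contacts the residue's backbone O is placed near the ligand
#' amine along a direction 30 degrees off the N-H bond (donor-H-acceptor
#' angle about 136 degrees); for `vdw` the residue's CA carbon approaches the
#' ligand carbon.
#'
#' @param spec a [toy_receptor_spec()].
#' @return list with elements `topology` ([topology()]), `ensemble`
#'   ([trajectory_ensemble()]), and `truth` (list of ground-truth values:
#'   per-atom expected RMSF, schedule realised occupancies).
#' @export
gen_toy_trajectory <- function(spec) {
  stopifnot(inherits(spec, "toy_receptor_spec"))
  set.seed(spec$seed)
  geo <- toy_base_geometry(spec)
  A <- nrow(geo$atoms)
  sig <- rep_len(spec$per_atom_sigma, A)
  lig_idx <- which(geo$atoms$is_ligand)
  n_atom <- lig_idx[grepl("^N", geo$atoms$name[lig_idx])][1]
  h_atom <- lig_idx[grepl("^H", geo$atoms$name[lig_idx])][1]
  c_atom <- lig_idx[grepl("^C", geo$atoms$name[lig_idx])][1]

  # Pre-compute pinned positions per scheduled contact.
  sched <- list()
  hb_seen <- 0
  n_hb <- sum(vapply(spec$contact_schedule, function(x) x$kind == "hbond", TRUE))
  for (cs in spec$contact_schedule) {
    rows <- which(geo$atoms$resid == cs$residue)
    if (cs$kind == "hbond") {
      hb_seen <- hb_seen + 1
      az <- 2 * pi * (hb_seen - 1) / max(1, n_hb)
      dir <- c(cos(pi / 6), sin(pi / 6) * cos(az), sin(pi / 6) * sin(az))
      atom <- rows[geo$atoms$name[rows] == "O"]
      base <- geo$xyz[n_atom, ]
      d_in <- cs$d_in %||% 2.9; d_out <- cs$d_out %||% 5.5
    } else {
      if (is.na(c_atom)) stopf("vdw schedule requires a ligand carbon")
      atom <- rows[geo$atoms$name[rows] == "CA"]
      dir <- geo$xyz[rows[2], ] - geo$xyz[c_atom, ]
      dir <- dir / sqrt(sum(dir^2))
      base <- geo$xyz[c_atom, ]
      d_in <- cs$d_in %||% 3.8; d_out <- cs$d_out %||% 6.5
    }
    sched[[length(sched) + 1]] <- list(
      residue = cs$residue, kind = cs$kind, atom = atom,
      pos_in = base + d_in * dir, pos_out = base + d_out * dir,
      masks = schedule_masks(cs$occupancy, spec$n_runs, spec$frames_per_run))
  }
  pinned <- c(vapply(sched, function(s) s$atom, integer(1)), h_atom, n_atom,
              c_atom)
  pinned <- unique(pinned[!is.na(pinned)])
  sig[pinned] <- 0

  runs <- vector("list", spec$n_runs)
  Fr <- spec$frames_per_run
  realised <- lapply(sched, function(s) numeric(0))
  for (r in seq_len(spec$n_runs)) {
    arr <- array(0, dim = c(Fr, A, 3))
    for (k in 1:3)
      arr[, , k] <- matrix(geo$xyz[, k], Fr, A, byrow = TRUE) +
        matrix(rnorm(Fr * A, sd = rep(sig, each = Fr)), Fr, A)
    for (si in seq_along(sched)) {
      s <- sched[[si]]
      m <- s$masks[[r]]
      for (k in 1:3)
        arr[, s$atom, k] <- ifelse(m, s$pos_in[k], s$pos_out[k])
      realised[[si]] <- c(realised[[si]], mean(m))
    }
    runs[[r]] <- arr
  }
  truth <- list(
    expected_rmsf = sig * sqrt(3),
    schedule = lapply(seq_along(sched), function(si) list(
      residue = sched[[si]]$residue, kind = sched[[si]]$kind,
      target = spec$contact_schedule[[si]]$occupancy,
      realised = mean(realised[[si]]))))
  list(topology = topology(geo$atoms, xyz = geo$xyz),
       ensemble = trajectory_ensemble(runs),
       truth = truth)
}

#' Write a toy fixture to disk
#'
#' Writes the topology as PDB, each run in the package's plain-text
#' trajectory dialect (`run1.traj`, ...), and a YAML metadata file carrying
#' the ground-truth values, so the fixture can be round-tripped through the
#' trajectory I/O layer.
#'
#' @param fix result of [gen_toy_trajectory()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toy_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_topology(fix$topology, file.path(dir, "topology.pdb"))
  for (r in seq_along(fix$ensemble$runs))
    write_trajectory(fix$ensemble$runs[[r]],
                     file.path(dir, sprintf("run%d.traj", r)))
  meta <- list(n_runs = length(fix$ensemble$runs),
               runs = sprintf("run%d.traj", seq_along(fix$ensemble$runs)),
               topology = "topology.pdb",
               truth = list(expected_rmsf = as.numeric(fix$truth$expected_rmsf),
                            schedule = fix$truth$schedule))
  yaml::write_yaml(meta, file.path(dir, "fixture.yml"))
  invisible(dir)
}

#' Read a toy fixture from disk
#'
#' @param dir directory written by [write_toy_fixture()].
#' @return list with `topology`, `ensemble`, `truth`.
#' @export
read_toy_fixture <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "fixture.yml"))
  top <- read_topology(file.path(dir, meta$topology))
  runs <- lapply(file.path(dir, meta$runs), read_trajectory)
  list(topology = top, ensemble = trajectory_ensemble(runs),
       truth = meta$truth)
}
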