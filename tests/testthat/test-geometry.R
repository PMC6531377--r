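# RMSF/B-factor, spatial density, pocket volume, state projections.

test_that("RMSF is zero for static trajectories and after rigid-body motion", {
  spec <- toy_receptor_spec(helix_count = 2, residues_per_helix = 6,
                            per_atom_sigma = 0, n_runs = 1,
                            frames_per_run = 10, seed = 1)
  fix <- gen_toy_trajectory(spec)
  ca <- atom_select(fix$topology, "calpha")
  expect_true(all(compute_rmsf(fix$ensemble, ca) < 1e-9))
  # rigid-body rotated/translated copies of one frame superpose to zero
  fr <- fix$ensemble$runs[[1]][1, , ]
  rot <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0,
                              0, 0, 1), 3, 3)
  frames <- lapply(1:8, function(f) fr %*% rot(0.3 * f) +
                     matrix(0.5 * f, nrow(fr), 3))
  r <- compute_rmsf(make_frames_ensemble(frames), ca)
  expect_lt(max(r), 1e-6)
  expect_error(compute_rmsf(fix$ensemble, integer(0)), "empty")
})

test_that("isotropic jitter yields RMSF = sigma * sqrt(3)", {
  spec <- toy_receptor_spec(helix_count = 4, residues_per_helix = 20,
                            per_atom_sigma = 0.5, n_runs = 1,
                            frames_per_run = 2000, seed = 3)
  fix <- gen_toy_trajectory(spec)
  ca <- atom_select(fix$topology, "calpha")
  r <- compute_rmsf(fix$ensemble, ca)
  expect_equal(mean(r), 0.5 * sqrt(3), tolerance = 0.05)
  # without superposition the match is exact up to sampling error
  r2 <- compute_rmsf(fix$ensemble, ca, superpose = FALSE)
  expect_equal(mean(r2), 0.5 * sqrt(3), tolerance = 0.02)
})

test_that("per-atom sigma levels reproduce the flexibility ranking exactly", {
  # >= 5 distinct, well-separated sigma levels across the Calphas;
  # the RMSF ranking must reproduce the prescribed ordering exactly
  spec <- toy_receptor_spec(helix_count = 1, residues_per_helix = 10,
                            per_atom_sigma = 0.1, n_runs = 1,
                            frames_per_run = 3000, seed = 4)
  fix <- gen_toy_trajectory(spec)
  na <- nrow(fix$topology$atoms)
  ca <- atom_select(fix$topology, "calpha")
  sig <- rep(0.1, na)
  sig[ca] <- seq(0.1, 1.0, length.out = length(ca))
  spec$per_atom_sigma <- sig
  fix <- gen_toy_trajectory(spec)
  r <- compute_rmsf(fix$ensemble, ca, superpose = FALSE)
  expect_equal(cor(r, sig[ca], method = "spearman"), 1)
})

test_that("B-factor conversion follows (8 pi^2 / 3) RMSF^2", {
  expect_equal(rmsf_to_bfactor(1.0), 8 * pi^2 / 3)
  expect_equal(rmsf_to_bfactor(1.0), 26.3189, tolerance = 1e-4)
  expect_equal(rmsf_to_bfactor(0), 0)
  expect_equal(rmsf_to_bfactor(2), 4 * rmsf_to_bfactor(1))
  expect_error(rmsf_to_bfactor(-0.1), "non-negative")
})

test_that("spatial distribution bins tracked atoms faithfully", {
  # static atom: one voxel holding every frame
  top <- make_test_topology(c("CA", "CA", "CA", "N1"), c("C", "C", "C", "N"),
                            c(1, 2, 3, 4),
                            rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0),
                                  c(1.2, 1.2, 1.2)),
                            is_ligand = c(FALSE, FALSE, FALSE, TRUE))
  ens <- make_static_ensemble(top$xyz, n_frames = 7)
  g <- spatial_distribution(ens, tracked_atoms = 4,
                            alignment_selection = 1:3)
  expect_equal(sum(g$counts), 7)
  expect_equal(max(g$counts), 7)
  expect_equal(g$n_outside, 0)
  # atom alternating between two voxels 50/50
  f1 <- top$xyz; f2 <- top$xyz; f2[4, ] <- f2[4, ] + c(5, 0, 0)
  ens2 <- make_frames_ensemble(rep(list(f1, f2), 5))
  g2 <- spatial_distribution(ens2, 4, 1:3)
  expect_equal(sort(g2$counts[g2$counts > 0]), c(5, 5))
  expect_error(spatial_distribution(ens, 4, alignment_selection = 1:2),
               "degenerate")
})

test_that("an isotropic 1 A cloud keeps >= 99% of density within 4 A", {
  set.seed(5)
  base <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(2, 2, 3))
  nf <- 4000
  frames <- lapply(seq_len(nf), function(f) {
    m <- base
    m[4, ] <- m[4, ] + rnorm(3, sd = 1)
    m
  })
  top <- make_test_topology(c("CA", "CA", "CA", "N1"), c("C", "C", "C", "N"),
                            1:4, base, is_ligand = c(FALSE, FALSE, FALSE,
                                                     TRUE))
  g <- spatial_distribution(make_frames_ensemble(frames), 4, 1:3, pad = 6)
  nz <- which(g$counts > 0, arr.ind = TRUE)
  centres <- sweep((nz - 0.5) * g$spacing, 2, g$origin, `+`)
  com <- colSums(centres * g$counts[nz]) / sum(g$counts[nz])
  d <- sqrt(rowSums(sweep(centres, 2, com)^2))
  frac <- sum(g$counts[nz][d <= 4]) / sum(g$counts)
  expect_gte(frac, 0.99)
})

test_that("pocket volume matches analytic values on engineered boxes", {
  lig_xyz <- rbind(c(0, 0, 0))
  # empty box: no receptor atoms -> full 12^3
  top_empty <- make_test_topology("N1", "N", 1, lig_xyz, is_ligand = TRUE)
  v <- pocket_volume(top_empty, lig_xyz, 1)
  expect_equal(v$volume, 1728)
  # halving the spacing leaves the empty-box volume unchanged
  v05 <- pocket_volume(top_empty, lig_xyz, 1, spacing = 0.5)
  expect_equal(v05$volume, 1728)
  # single receptor atom with 3 A clash radius at the centre: deleted
  # volume approximates the analytic sphere 4/3 pi 3^3 = 113.1
  top1 <- make_test_topology(c("N1", "X"), c("N", "C"), c(1, 2),
                             rbind(c(0, 0, 0), c(0, 0, 0)),
                             is_ligand = c(TRUE, FALSE))
  v1 <- pocket_volume(top1, top1$xyz, 1, radii = c(C = 3.0),
                      prune_core = FALSE)
  sphere <- 4 / 3 * pi * 27
  expect_lt(abs(v1$deleted * 1 - sphere) / sphere, 0.15)
  # grid refinement moves the deleted volume toward the analytic value
  v1f <- pocket_volume(top1, top1$xyz, 1, spacing = 0.5, radii = c(C = 3.0),
                       prune_core = FALSE)
  expect_lte(abs(v1f$deleted * 0.5^3 - sphere),
             abs(v1$deleted - sphere))
  # fully occluded box
  atoms <- expand.grid(x = seq(-5, 5, by = 2.5), y = seq(-5, 5, by = 2.5),
                       z = seq(-5, 5, by = 2.5))
  top_full <- make_test_topology(c("N1", rep("X", nrow(atoms))),
                                 c("N", rep("C", nrow(atoms))),
                                 c(1, rep(2, nrow(atoms))),
                                 rbind(c(0, 0, 0), as.matrix(atoms)),
                                 is_ligand = c(TRUE, rep(FALSE,
                                                         nrow(atoms))))
  vf <- pocket_volume(top_full, top_full$xyz, 1, radii = c(C = 3.0))
  expect_equal(vf$volume, 0)
  expect_error(pocket_volume(top_empty, lig_xyz, 1, spacing = -1),
               "positive")
})

test_that("pocket volume is monotone under receptor-atom addition", {
  set.seed(9)
  for (k in 1:20) {
    n0 <- sample(0:4, 1)
    pos <- matrix(runif((n0 + 2) * 3, -6, 6), ncol = 3)
    build <- function(n) {
      nm <- c("N1", rep("X", n))
      make_test_topology(nm, c("N", rep("C", n)), c(1, rep(2, n)),
                         rbind(c(0, 0, 0), pos[seq_len(n), , drop = FALSE]),
                         is_ligand = c(TRUE, rep(FALSE, n)))
    }
    lig_frame <- function(top) rbind(c(0, 0, 0),
                                     pos[seq_len(nrow(top$atoms) - 1), ,
                                         drop = FALSE])
    v_small <- pocket_volume(build(n0), lig_frame(build(n0)), 1)
    v_big <- pocket_volume(build(n0 + 1), lig_frame(build(n0 + 1)), 1)
    expect_lte(v_big$volume, v_small$volume)
  }
})

test_that("state projections recover engineered distance distributions", {
  # fixed geometry: a single occupied 2D bin
  xyz <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 9, 0))
  top <- make_test_topology(rep("CA", 3), rep("C", 3), 1:3, xyz)
  ens <- make_static_ensemble(xyz, n_frames = 6)
  pr <- state_projection(top, ens, c(1, 2), c(1, 3))
  expect_equal(sum(pr$map > 0), 1)
  expect_equal(sum(pr$map), 6)
  expect_equal(pr$dA, rep(8, 6))
  # two-state toggling: bimodal with masses matching the state fractions
  far <- xyz; far[2, 1] <- 13
  frames <- c(replicate(6, xyz, simplify = FALSE),
              replicate(2, far, simplify = FALSE))
  pr2 <- state_projection(top, make_frames_ensemble(frames), c(1, 2),
                          c(1, 3))
  expect_equal(sort(pr2$map[pr2$map > 0]), c(2, 6))
  # distances invariant under global rotation
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  ensR <- make_static_ensemble(xyz %*% R, n_frames = 6)
  prR <- state_projection(top, ensR, c(1, 2), c(1, 3))
  expect_equal(prR$dA, pr$dA)
  expect_error(state_projection(top, ens, c(1, 9), c(1, 3)), "Calpha")
})
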