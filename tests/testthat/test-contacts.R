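# Contact geometry gates, occupancy statistics, interaction energy.

test_that("the hydrogen-bond gate enforces 3.5 A and 120 degrees", {
  cases <- list(list(d = 2.9, ang = 165, expect = TRUE),
                list(d = 3.6, ang = 165, expect = FALSE),  # distance gate
                list(d = 3.2, ang = 110, expect = FALSE))  # angle gate
  for (cs in cases) {
    top <- hb_fixture(acceptor_at(cs$d, cs$ang))
    det <- detect_hbond_frame(top, top$xyz, atom_select(top, "ligand"),
                              atom_select(top, "receptor"))
    expect_equal(any(det$contact), cs$expect,
                 info = sprintf("d=%g ang=%g", cs$d, cs$ang))
    hit <- det[which.min(det$distance), ]
    expect_equal(hit$distance, cs$d, tolerance = 1e-6)
    if (cs$d <= 3.5) expect_equal(hit$angle, cs$ang, tolerance = 1e-4)
  }
})

test_that("hydrogen inference is geometric and can be disabled", {
  # strip the explicit H: N1 keeps a carbon neighbour so inference points
  # the H away from it, i.e. toward +x where the acceptor sits
  top <- make_test_topology(c("C2", "N1", "O"), c("C", "N", "O"),
                            c(1, 1, 2),
                            rbind(c(-1.4, 0, 0), c(0, 0, 0), c(2.9, 0, 0)),
                            is_ligand = c(TRUE, TRUE, FALSE))
  det <- detect_hbond_frame(top, top$xyz, atom_select(top, "ligand"),
                            atom_select(top, "receptor"), infer_h = TRUE)
  expect_true(any(det$contact))
  expect_true(any(det$h_inferred))
  expect_error(detect_hbond_frame(top, top$xyz, atom_select(top, "ligand"),
                                  atom_select(top, "receptor"),
                                  infer_h = FALSE), "inference is disabled")
})

test_that("the vdW gate is a strict 4 A carbon-carbon boundary", {
  mk <- function(d) make_test_topology(c("C1", "CA"), c("C", "C"), c(1, 2),
                                       rbind(c(0, 0, 0), c(d, 0, 0)),
                                       is_ligand = c(TRUE, FALSE))
  for (cs in list(c(3.99, TRUE), c(4.01, FALSE))) {
    top <- mk(cs[1])
    det <- detect_vdw_frame(top, top$xyz, 1, 2)
    expect_equal(det$contact, as.logical(cs[2]), info = cs[1])
  }
  # residue with no carbons can never be in vdW contact
  top <- make_test_topology(c("C1", "O"), c("C", "O"), c(1, 2),
                            rbind(c(0, 0, 0), c(0.5, 0, 0)),
                            is_ligand = c(TRUE, FALSE))
  expect_false(detect_vdw_frame(top, top$xyz, 1, 2)$contact)
})

test_that("contact detection is invariant to rigid-body transforms", {
  top <- hb_fixture(acceptor_at(2.9, 165))
  ang <- 0.7
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3)
  moved <- top$xyz %*% R + matrix(c(5, -3, 2), 3, 3, byrow = TRUE)
  d0 <- detect_hbond_frame(top, top$xyz, 1:2, 3)
  d1 <- detect_hbond_frame(top, moved, 1:2, 3)
  expect_equal(d1$contact, d0$contact)
  expect_equal(d1$distance, d0$distance, tolerance = 1e-9)
  # symmetric in group order
  d2 <- detect_hbond_frame(top, top$xyz, 3, 1:2)
  expect_equal(sort(d2$distance), sort(d0$distance))
  expect_equal(any(d2$contact), any(d0$contact))
})

test_that("occupancy follows the strict >40% sustained rule", {
  spec <- toy_receptor_spec(helix_count = 2, residues_per_helix = 5,
                            per_atom_sigma = 0.05, n_runs = 2,
                            frames_per_run = 200, seed = 6,
                            contact_schedule = list(
                              list(residue = 2, kind = "hbond",
                                   occupancy = 0.41),
                              list(residue = 7, kind = "vdw",
                                   occupancy = 0.39)))
  fix <- gen_toy_trajectory(spec)
  ens <- select_analysis_frames(fix$ensemble, 0.5)
  hb <- contact_occupancy(fix$topology, ens, 2, "hbond")
  vd <- contact_occupancy(fix$topology, ens, 7, "vdw")
  expect_equal(hb$occupancy, 0.41, tolerance = 1e-9)
  expect_true(hb$sustained)
  expect_equal(vd$occupancy, 0.39, tolerance = 1e-9)
  expect_false(vd$sustained)
  # occupancy exactly 0.40 is NOT sustained
  spec40 <- toy_receptor_spec(helix_count = 2, residues_per_helix = 5,
                              per_atom_sigma = 0.05, n_runs = 1,
                              frames_per_run = 200, seed = 7,
                              contact_schedule = list(
                                list(residue = 2, kind = "hbond",
                                     occupancy = 0.40)))
  fx <- gen_toy_trajectory(spec40)
  c40 <- contact_occupancy(fx$topology,
                           select_analysis_frames(fx$ensemble, 0.5),
                           2, "hbond")
  expect_equal(c40$occupancy, 0.40, tolerance = 1e-9)
  expect_false(c40$sustained)
  # unknown residue
  expect_error(contact_occupancy(fix$topology, ens, 999, "hbond"),
               "unknown residue")
})

test_that("zero-contact residues still report an all-frame mean distance", {
  spec <- toy_receptor_spec(helix_count = 1, residues_per_helix = 4,
                            per_atom_sigma = 0, n_runs = 1,
                            frames_per_run = 10, seed = 1)
  fix <- gen_toy_trajectory(spec)
  cr <- contact_occupancy(fix$topology, fix$ensemble, 3, "vdw")
  expect_equal(cr$occupancy, 0)
  expect_true(is.na(cr$mean_distance_contact))
  expect_true(is.finite(cr$mean_distance_all))
})

test_that("pooled occupancy equals the frame-weighted mean of per-run occupancies", {
  spec <- toy_receptor_spec(helix_count = 1, residues_per_helix = 4,
                            per_atom_sigma = 0.05, n_runs = 3,
                            frames_per_run = 100, seed = 12,
                            contact_schedule = list(
                              list(residue = 2, kind = "vdw",
                                   occupancy = 0.3)))
  fix <- gen_toy_trajectory(spec)
  pooled <- contact_occupancy(fix$topology, fix$ensemble, 2, "vdw")$occupancy
  per_run <- vapply(fix$ensemble$runs, function(r)
    contact_occupancy(fix$topology, trajectory_ensemble(list(r)), 2,
                      "vdw")$occupancy, numeric(1))
  nf <- vapply(fix$ensemble$runs, function(r) dim(r)[1], numeric(1))
  expect_equal(pooled, sum(per_run * nf) / sum(nf), tolerance = 1e-12)
})

test_that("mean contact distance reproduces constructed geometries", {
  top <- make_test_topology(c("C1", "CA"), c("C", "C"), c(1, 2),
                            rbind(c(0, 0, 0), c(3, 0, 0)),
                            is_ligand = c(TRUE, FALSE))
  ens <- make_static_ensemble(top$xyz, n_frames = 5)
  expect_equal(mean_contact_distance(top, ens, 2, "vdw"), 3.0)
  # two half-populated distances 2.8 / 3.2 average to 3.0
  f1 <- rbind(c(0, 0, 0), c(2.8, 0, 0))
  f2 <- rbind(c(0, 0, 0), c(3.2, 0, 0))
  ens2 <- make_frames_ensemble(list(f1, f2, f1, f2))
  expect_equal(mean_contact_distance(top, ens2, 2, "vdw"), 3.0)
  expect_error(mean_contact_distance(top, ens, 99), "unknown residue")
})

test_that("interaction energy matches hand-computed values and scaling laws", {
  top <- make_test_topology(c("Q1", "Q2"), c("C", "C"), c(1, 2),
                            rbind(c(0, 0, 0), c(3, 0, 0)),
                            is_ligand = c(TRUE, FALSE))
  ens <- make_static_ensemble(top$xyz, n_frames = 3)
  # two +1e charges at 3 A, LJ off: 332.0636 / 3 kcal/mol
  p <- nonbonded_params(charge = c(1, 1), sigma = c(1, 1),
                        epsilon = c(0, 0))
  e <- interaction_energy(top, ens, p, 1, 2)
  expect_equal(e$mean, 332.0636 / 3, tolerance = 1e-9)
  expect_equal(e$sd, 0)
  # r = sigma_ij with charges off: LJ term exactly 0
  p2 <- nonbonded_params(charge = c(0, 0), sigma = c(3, 3),
                         epsilon = c(0.2, 0.2))
  expect_equal(interaction_energy(top, ens, p2, 1, 2)$mean, 0,
               tolerance = 1e-12)
  # doubling all charges quadruples the Coulomb term
  p4 <- nonbonded_params(charge = c(2, 2), sigma = c(1, 1),
                         epsilon = c(0, 0))
  expect_equal(interaction_energy(top, ens, p4, 1, 2)$mean, 4 * e$mean,
               tolerance = 1e-12)
  # sign flip of one group negates the Coulomb term
  pm <- nonbonded_params(charge = c(-1, 1), sigma = c(1, 1),
                         epsilon = c(0, 0))
  expect_equal(interaction_energy(top, ens, pm, 1, 2)$coulomb, -e$coulomb)
  # translation / rotation invariance
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)
  moved <- make_static_ensemble(top$xyz %*% R +
                                  matrix(c(1, 2, 3), 2, 3, byrow = TRUE), 3)
  expect_equal(interaction_energy(top, moved, p, 1, 2)$mean, e$mean,
               tolerance = 1e-9)
  # incomplete parameters fail loudly
  expect_error(interaction_energy(top, ens,
                                  nonbonded_params(1, 1, 0), 1, 2),
               "parameters cover")
  expect_error(nonbonded_params(c(0, 0), c(1, 1), c(-0.1, 0)),
               "non-negative")
})
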