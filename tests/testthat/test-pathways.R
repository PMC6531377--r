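# MI-weighted residue graphs, max-MI pathways, pipelines.

test_that("graph construction enforces proximity, positive MI and cost convention", {
  # two residues placed far apart: no edge regardless of MI
  top <- make_test_topology(c("CA", "CA"), c("C", "C"), 1:2,
                            rbind(c(0, 0, 0), c(30, 0, 0)))
  ens <- make_static_ensemble(top$xyz)
  mi <- data.frame(res_i = 1, res_j = 2, mi = 5)
  class(mi) <- c("mi_matrix", "data.frame")
  expect_error(build_residue_graph(top, ens, mi), "empty graph")
  # close pair: edge kept, max-MI edge has cost 0
  top2 <- make_test_topology(rep("CA", 3), rep("C", 3), 1:3,
                             rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0)))
  ens2 <- make_static_ensemble(top2$xyz)
  mi2 <- data.frame(res_i = c(1, 2), res_j = c(2, 3), mi = c(0.8, 0.2))
  class(mi2) <- c("mi_matrix", "data.frame")
  g <- build_residue_graph(top2, ens2, mi2)
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$edges$cost[g$edges$mi == 0.8], 0)
  expect_equal(g$edges$cost[g$edges$mi == 0.2], -log(0.2 / 0.8))
  # occupancy gate: residue 1 drifts away from 2-3 in half the frames, so
  # edge (1,2) is within the cutoff in only 50% < 75% of frames
  shifted <- top2$xyz + rbind(c(20, 0, 0), c(0, 0, 0), c(0, 0, 0))
  frames <- c(replicate(5, top2$xyz, simplify = FALSE),
              replicate(5, shifted, simplify = FALSE))
  ens3 <- make_frames_ensemble(frames)
  g3 <- build_residue_graph(top2, ens3, mi2, proximity_occupancy = 0.75)
  expect_false(any(g3$edges$res_i == 1 & g3$edges$res_j == 2))
  expect_true(any(g3$edges$res_i == 2 & g3$edges$res_j == 3))
})

test_that("max_mi_path handles base cases and ties deterministically", {
  g1 <- residue_graph(data.frame(res_i = 1, res_j = 2, mi = 1))
  p <- max_mi_path(g1, 1, 2)
  expect_equal(p$residues, c(1, 2))
  # triangle: 1-3 direct cost 2.5 vs 1-2-3 cost 2
  g2 <- residue_graph(data.frame(res_i = c(1, 2, 1), res_j = c(2, 3, 3),
                                 mi = c(1, 1, 1),
                                 cost = c(1, 1, 2.5)))
  expect_equal(max_mi_path(g2, 1, 3)$residues, c(1, 2, 3))
  expect_equal(max_mi_path(g2, 1, 3)$total_cost, 2)
  # exact tie: both routes cost 2; lexicographically smaller path wins
  g3 <- residue_graph(data.frame(res_i = c(1, 2, 1, 4), res_j = c(2, 3, 4, 3),
                                 mi = rep(1, 4), cost = rep(1, 4)))
  expect_equal(max_mi_path(g3, 1, 3)$residues, c(1, 2, 3))
  # disconnected: explicit no-path result, not an exception
  g4 <- residue_graph(data.frame(res_i = c(1, 3), res_j = c(2, 4),
                                 mi = c(1, 1)))
  expect_false(max_mi_path(g4, 1, 4)$found)
  expect_error(max_mi_path(g4, 1, 99), "not in graph")
})

test_that("a proximity chain constrains the path to the chain", {
  # 5 residues in a line, 3.5 A apart: only consecutive pairs are proximal
  xyz <- cbind(seq(0, 14, by = 3.5), 0, 0)
  top <- make_test_topology(rep("CA", 5), rep("C", 5), 1:5, xyz)
  ens <- make_static_ensemble(xyz)
  mi <- expand.grid(res_i = 1:5, res_j = 1:5)
  mi <- mi[mi$res_i < mi$res_j, ]
  mi$mi <- 0.5
  class(mi) <- c("mi_matrix", "data.frame")
  g <- build_residue_graph(top, ens, mi, proximity_cutoff = 4)
  expect_equal(nrow(g$edges), 4)
  expect_equal(max_mi_path(g, 1, 5)$residues, 1:5)
})

test_that("max_mi_path equals exhaustive simple-path enumeration", {
  set.seed(202)
  for (k in 1:60) {
    g <- random_mi_graph(max_nodes = 10)
    s <- g$nodes[1]; t <- g$nodes[length(g$nodes)]
    p <- max_mi_path(g, s, t)
    b <- brute_force_min_cost(g, s, t)
    if (!p$found) expect_false(is.finite(b)) else
      expect_equal(p$total_cost, b, tolerance = 1e-9)
  }
})

test_that("max_mi_path agrees with an independent graph library", {
  set.seed(303)
  for (k in 1:20) {
    g <- random_mi_graph(max_nodes = 12)
    s <- g$nodes[1]; t <- g$nodes[length(g$nodes)]
    p <- max_mi_path(g, s, t)
    ig <- igraph::graph_from_data_frame(
      data.frame(from = g$edges$res_i, to = g$edges$res_j),
      directed = FALSE, vertices = data.frame(name = g$nodes))
    d <- igraph::distances(ig, v = as.character(s), to = as.character(t),
                           weights = g$edges$cost)[1, 1]
    if (p$found) expect_equal(p$total_cost, d, tolerance = 1e-9)
    else expect_false(is.finite(d))
  }
})

test_that("pathway enumeration honours the via region", {
  # corridor fixture: 1-2-3-4 and a branch 1-5-4; via = {2}
  g <- residue_graph(data.frame(res_i = c(1, 2, 3, 1, 5),
                                res_j = c(2, 3, 4, 5, 4),
                                mi = c(1, 1, 1, 1, 1),
                                cost = c(1, 1, 1, 0.4, 0.4)))
  pw <- enumerate_pathways(g, sources = 1, sinks = 4, via = 2)
  expect_length(pw$pathways, 0)        # optimum goes 1-5-4, avoiding via
  expect_equal(pw$absent$reason, "avoids via region")
  # via = all nodes reduces to all-pairs max-MI paths
  pw2 <- enumerate_pathways(g, sources = 1, sinks = 4, via = g$nodes)
  expect_length(pw2$pathways, 1)
  expect_equal(pw2$pathways[[1]]$residues, c(1, 5, 4))
  # isolated via residues: retained set empty
  pw3 <- enumerate_pathways(g, sources = 1, sinks = 4, via = 99)
  expect_length(pw3$pathways, 0)
  expect_error(enumerate_pathways(g, sources = integer(0), sinks = 4,
                                  via = 2))
})

test_that("pipelines are overlap components with correct strengths and hubs", {
  same <- replicate(4, make_pathway(c(1, 2, 3)), simplify = FALSE)
  p <- assemble_pipelines(same)
  expect_length(p, 1)
  expect_equal(p[[1]]$strength, 4)
  # two edge-disjoint families
  fam <- list(make_pathway(c(1, 2, 3)), make_pathway(c(1, 2, 4)),
              make_pathway(c(7, 8, 9)))
  p2 <- assemble_pipelines(fam)
  expect_length(p2, 2)
  expect_equal(vapply(p2, function(x) x$strength, integer(1)), c(2L, 1L))
  # strengths sum to the retained-pathway count
  expect_equal(sum(vapply(p2, function(x) x$strength, integer(1))),
               length(fam))
  # hub count of a residue on k of the member pathways is k (direct count)
  paths7 <- list(make_pathway(c(1, 2, 3)), make_pathway(c(1, 2, 4)),
                 make_pathway(c(2, 3, 4)), make_pathway(c(1, 2, 5)),
                 make_pathway(c(2, 5, 6)), make_pathway(c(1, 2, 6)),
                 make_pathway(c(2, 6, 3)))
  p3 <- assemble_pipelines(paths7)
  expect_length(p3, 1)
  hub <- p3[[1]]$hub_counts
  direct <- sum(vapply(paths7, function(pp) 2 %in% pp$residues, logical(1)))
  expect_equal(unname(hub["2"]), direct)
  direct5 <- sum(vapply(paths7, function(pp) 5 %in% pp$residues, logical(1)))
  expect_equal(unname(hub["5"]), direct5)
})

test_that("pipeline assembly is deterministic and strength-monotone", {
  set.seed(11)
  paths <- lapply(1:8, function(k) make_pathway(sample(1:6, 3)))
  a <- assemble_pipelines(paths)
  b <- assemble_pipelines(paths)
  expect_identical(a, b)
  # adding a pathway never decreases any pipeline's strength: every old
  # pipeline's members land in a single new pipeline of >= strength
  added <- c(paths, list(make_pathway(c(1, 2, 3))))
  a2 <- assemble_pipelines(added)
  for (old in a) {
    containing <- Filter(function(np) all(old$members %in% np$members), a2)
    expect_length(containing, 1)
    expect_gte(containing[[1]]$strength, old$strength)
  }
  expect_equal(sum(vapply(a2, function(x) x$strength, integer(1))),
               length(added))
})
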