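# Allosteric communication pathways on a mutual-information-weighted
# residue graph.
#
# Edges connect spatially proximal residue pairs (min heavy-atom distance
# within a cutoff in a sufficient fraction of analysis frames) with positive
# torsional MI. The multiplicative max-MI objective is mapped to an additive
# shortest-path problem through the cost transform -log(MI / MI_max), which
# is non-negative by construction; the search is Dijkstra with a
# deterministic lexicographic tie-break on the residue sequence. Pipelines
# are connected components of the pathway-overlap graph.

#' Per-frame minimum heavy-atom distances between residue pairs
#'
#' @param top a [topology()].
#' @param ens a [trajectory_ensemble()] (already windowed).
#' @param pairs 2-column matrix of residue-id pairs.
#' @param cutoff contact cutoff in Angstrom.
#' @return data.frame with `res_i`, `res_j`, `contact_fraction` (fraction of
#'   frames with min distance `<=` cutoff), `mean_min_dist` (A).
#' @export
residue_proximity <- function(top, ens, pairs, cutoff = 5.0) {
  coords <- pool_frames(ens)
  nf <- dim(coords)[1]
  heavy_of <- lapply(split(top$atoms, top$atoms$resid), function(df)
    df$atom_index[df$element != "H"])
  out <- data.frame(res_i = pmin(pairs[, 1], pairs[, 2]),
                    res_j = pmax(pairs[, 1], pairs[, 2]),
                    contact_fraction = NA_real_, mean_min_dist = NA_real_)
  for (k in seq_len(nrow(out))) {
    ai <- heavy_of[[as.character(out$res_i[k])]]
    aj <- heavy_of[[as.character(out$res_j[k])]]
    if (!length(ai) || !length(aj)) stopf("residue without heavy atoms")
    mind <- numeric(nf)
    for (f in seq_len(nf))
      mind[f] <- min(cross_dist(matrix(coords[f, ai, ], ncol = 3),
                                matrix(coords[f, aj, ], ncol = 3)))
    out$contact_fraction[k] <- mean(mind <= cutoff)
    out$mean_min_dist[k] <- mean(mind)
  }
  out
}

#' Construct a residue graph directly from edge data
#'
#' Low-level constructor used by [build_residue_graph()] and by tests that
#' engineer graphs explicitly. Costs are recomputed as
#' `-log(mi / max(mi))` unless supplied.
#'
#' @param edges data.frame with columns `res_i`, `res_j`, `mi` and
#'   optionally `cost`, `mean_min_dist`.
#' @return object of class `residue_graph`.
#' @export
residue_graph <- function(edges) {
  if (!nrow(edges)) stopf("empty graph: no edges satisfy the criteria")
  if (any(edges$mi <= 0)) stopf("edges require positive MI")
  i <- pmin(edges$res_i, edges$res_j)
  j <- pmax(edges$res_i, edges$res_j)
  edges$res_i <- i; edges$res_j <- j
  if (anyDuplicated(paste(i, j))) stopf("duplicate edges")
  if (is.null(edges$cost)) edges$cost <- -log(edges$mi / max(edges$mi))
  if (any(edges$cost < 0)) stopf("negative edge costs")
  nodes <- sort(unique(c(edges$res_i, edges$res_j)))
  structure(list(nodes = nodes, edges = edges), class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("<residue_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Build the MI-weighted residue graph
#'
#' Keeps edge (i, j) iff the residues' minimum heavy-atom distance is within
#' `proximity_cutoff` in at least `proximity_occupancy` of the analysis
#' frames and MI(i, j) > 0. Edge cost is `-log(MI / MI_max)` with `MI_max`
#' the maximum MI among kept edges, so the strongest edge has cost 0.
#'
#' @param top a [topology()].
#' @param ens a [trajectory_ensemble()] (already windowed).
#' @param mi an [mi_matrix()].
#' @param proximity_cutoff heavy-atom distance cutoff, A.
#' @param proximity_occupancy minimum fraction of frames within the cutoff.
#' @return a [residue_graph()].
#' @export
build_residue_graph <- function(top, ens, mi, proximity_cutoff = 5.0,
                                proximity_occupancy = 0.75) {
  cand <- mi[mi$mi > 0, , drop = FALSE]
  if (!nrow(cand))
    stopf("empty graph: no residue pair has positive MI")
  prox <- residue_proximity(top, ens, cbind(cand$res_i, cand$res_j),
                            cutoff = proximity_cutoff)
  keep <- prox$contact_fraction >= proximity_occupancy
  if (!any(keep))
    stopf(paste0("empty graph: no pair is within %.1f A in >= %.0f%% of ",
                 "frames (closest mean min distance %.2f A)"),
          proximity_cutoff, 100 * proximity_occupancy,
          min(prox$mean_min_dist))
  edges <- data.frame(res_i = cand$res_i[keep], res_j = cand$res_j[keep],
                      mi = cand$mi[keep],
                      mean_min_dist = prox$mean_min_dist[keep])
  residue_graph(edges)
}

# Adjacency list: for each node, matrix of (neighbour, cost, mi).
graph_adjacency <- function(g) {
  adj <- setNames(vector("list", length(g$nodes)), g$nodes)
  for (k in seq_len(nrow(g$edges))) {
    e <- g$edges[k, ]
    adj[[as.character(e$res_i)]] <-
      rbind(adj[[as.character(e$res_i)]], c(e$res_j, e$cost, e$mi))
    adj[[as.character(e$res_j)]] <-
      rbind(adj[[as.character(e$res_j)]], c(e$res_i, e$cost, e$mi))
  }
  adj
}

# TRUE if integer vector a precedes b lexicographically.
lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (k in seq_len(n)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  length(a) < length(b)
}

#' Maximum-mutual-information pathway between two residues
#'
#' Minimum-total-cost simple path (equivalently, maximum sum of log MI)
#' found by Dijkstra's algorithm on the non-negative edge costs. Ties in
#' total cost are broken deterministically in favour of the
#' lexicographically smallest residue sequence.
#'
#' @param g a [residue_graph()].
#' @param source,sink residue ids present in the graph.
#' @return object of class `pathway`: `residues` (ordered ids), `total_mi`
#'   (sum of member-edge MI), `total_cost`, `found` (FALSE for a
#'   disconnected pair, in which case the other fields are empty/NA).
#' @export
max_mi_path <- function(g, source, sink) {
  if (!source %in% g$nodes || !sink %in% g$nodes)
    stopf("source/sink not in graph")
  adj <- graph_adjacency(g)
  nn <- length(g$nodes)
  key <- setNames(seq_len(nn), g$nodes)
  dist <- rep(Inf, nn)
  path <- vector("list", nn)
  done <- logical(nn)
  s <- key[[as.character(source)]]
  dist[s] <- 0
  path[[s]] <- source
  eps <- 1e-12
  repeat {
    open <- which(!done & is.finite(dist))
    if (!length(open)) break
    u <- open[which.min(dist[open])]
    cands <- open[dist[open] <= dist[u] + eps]
    if (length(cands) > 1) u <- cands[which.min(g$nodes[cands])]
    done[u] <- TRUE
    if (g$nodes[u] == sink) break
    nb <- adj[[as.character(g$nodes[u])]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- key[[as.character(nb[r, 1])]]
      if (done[v]) next
      alt <- dist[u] + nb[r, 2]
      cand_path <- c(path[[u]], g$nodes[v])
      if (alt < dist[v] - eps ||
          (alt <= dist[v] + eps && lex_less(cand_path, path[[v]]))) {
        dist[v] <- min(alt, dist[v])
        path[[v]] <- cand_path
      }
    }
  }
  t <- key[[as.character(sink)]]
  if (!is.finite(dist[t]))
    return(structure(list(residues = integer(0), total_mi = NA_real_,
                          total_cost = NA_real_, found = FALSE,
                          source = source, sink = sink),
                     class = "pathway"))
  p <- path[[t]]
  mi_sum <- 0
  for (k in seq_len(length(p) - 1)) {
    e <- g$edges[(g$edges$res_i == min(p[k], p[k + 1]) &
                  g$edges$res_j == max(p[k], p[k + 1])), ]
    mi_sum <- mi_sum + e$mi[1]
  }
  structure(list(residues = p, total_mi = mi_sum, total_cost = dist[t],
                 found = TRUE, source = source, sink = sink),
            class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  if (!x$found)
    cat(sprintf("<pathway> %d -> %d: no path\n", x$source, x$sink))
  else
    cat(sprintf("<pathway> %s (cost %.4f, MI %.4f)\n",
                paste(x$residues, collapse = "-"), x$total_cost, x$total_mi))
  invisible(x)
}

#' Enumerate max-MI pathways between two regions
#'
#' Computes the max-MI pathway for every (source, sink) residue pair and
#' retains it only if it passes through at least one residue of `via`
#' (typically the agonist binding site). Pairs that are disconnected or
#' whose optimal path avoids `via` are recorded as absent, not errors.
#'
#' @param g a [residue_graph()].
#' @param sources,sinks,via [region_set()] objects (or bare id vectors);
#'   source/sink residues not present in the graph are skipped.
#' @return list with `pathways` (retained [max_mi_path()] results, each with
#'   `passes_binding_site = TRUE`) and `absent` (data.frame of source, sink,
#'   reason).
#' @export
enumerate_pathways <- function(g, sources, sinks, via) {
  ids <- function(x) if (inherits(x, "region_set")) x$residues else
    sort(unique(as.integer(x)))
  src <- intersect(ids(sources), g$nodes)
  snk <- intersect(ids(sinks), g$nodes)
  via_ids <- ids(via)
  if (!length(ids(sources)) || !length(ids(sinks)) || !length(via_ids))
    stopf("region sets must be nonempty")
  paths <- list()
  absent <- NULL
  for (s in src) for (t in snk) {
    if (s == t) next
    p <- max_mi_path(g, s, t)
    if (!p$found) {
      absent <- rbind(absent, data.frame(source = s, sink = t,
                                         reason = "disconnected"))
    } else if (!any(p$residues %in% via_ids)) {
      absent <- rbind(absent, data.frame(source = s, sink = t,
                                         reason = "avoids via region"))
    } else {
      p$passes_binding_site <- TRUE
      paths[[length(paths) + 1]] <- p
    }
  }
  list(pathways = paths, absent = absent)
}

path_edge_keys <- function(p) {
  r <- p$residues
  if (length(r) < 2) return(character(0))
  paste(pmin(r[-length(r)], r[-1]), pmax(r[-length(r)], r[-1]), sep = "-")
}

#' Assemble pathways into allosteric communication pipelines
#'
#' Pipelines are the connected components of the pathway-overlap graph, in
#' which two pathways are adjacent iff they share at least `overlap_min`
#' edges. A pipeline's strength is its number of member pathways; a
#' residue's hub count is the number of member pathways containing it.
#' Pipelines are sorted by decreasing strength, ties broken by the smallest
#' member residue id.
#'
#' @param paths list of found [max_mi_path()] results.
#' @param overlap_min minimum number of shared edges for overlap.
#' @return list of `pipeline` objects: `members` (pathway indices into
#'   `paths`), `strength`, `hub_counts` (named integer by residue),
#'   `edge_usage` (named integer by edge key `"i-j"`).
#' @export
assemble_pipelines <- function(paths, overlap_min = 1) {
  if (!length(paths)) stopf("no pathways to assemble")
  keys <- lapply(paths, path_edge_keys)
  np <- length(paths)
  adj <- matrix(FALSE, np, np)
  for (i in seq_len(np)) for (j in seq_len(np))
    if (i < j && sum(keys[[i]] %in% keys[[j]]) >= overlap_min)
      adj[i, j] <- adj[j, i] <- TRUE
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
  pipes <- lapply(sort(unique(comp)), function(cid) {
    members <- which(comp == cid)
    res_all <- unlist(lapply(paths[members], function(p) unique(p$residues)))
    hub <- sort(table(res_all), decreasing = TRUE)
    edge_all <- unlist(keys[members])
    usage <- sort(table(edge_all), decreasing = TRUE)
    structure(list(members = members, strength = length(members),
                   hub_counts = setNames(as.integer(hub), names(hub)),
                   edge_usage = setNames(as.integer(usage), names(usage))),
              class = "pipeline")
  })
  strength <- vapply(pipes, function(p) p$strength, integer(1))
  min_res <- vapply(pipes, function(p)
    min(as.integer(names(p$hub_counts))), numeric(1))
  pipes[order(-strength, min_res)]
}

#' @export
print.pipeline <- function(x, ...) {
  cat(sprintf("<pipeline> strength %d, %d residues, top hub %s (%d paths)\n",
              x$strength, length(x$hub_counts), names(x$hub_counts)[1],
              x$hub_counts[1]))
  invisible(x)
}

#' Export a residue graph as an edge list
#'
#' @param g a [residue_graph()].
#' @param path output TSV (`res_i`, `res_j`, `mi`, `cost`).
#' @export
write_graph_edgelist <- function(g, path) {
  write.table(g$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
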