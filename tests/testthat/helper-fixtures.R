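# Shared fixture builders and independent oracles used across test files.

# Minimal topology from parallel vectors; coordinates attached as xyz.
make_test_topology <- function(names, elements, resids, xyz,
                               is_ligand = NULL, resnames = NULL) {
  n <- length(names)
  if (is.null(is_ligand)) is_ligand <- rep(FALSE, n)
  if (is.null(resnames)) resnames <- ifelse(is_ligand, "LIG", "ALA")
  topology(data.frame(atom_index = seq_len(n), name = names,
                      element = elements, resid = resids,
                      resname = resnames, chain = "A",
                      is_ligand = is_ligand, stringsAsFactors = FALSE),
           xyz = xyz)
}

# Static ensemble: the same frame repeated n_frames times (optionally a list
# of per-frame coordinate matrices).
make_static_ensemble <- function(xyz, n_frames = 4) {
  arr <- array(0, dim = c(n_frames, nrow(xyz), 3))
  for (f in seq_len(n_frames)) arr[f, , ] <- xyz
  trajectory_ensemble(list(arr))
}

make_frames_ensemble <- function(frames) {
  arr <- array(0, dim = c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  trajectory_ensemble(list(arr))
}

# Exhaustive minimum-cost simple path by depth-first enumeration: the
# independent oracle for the shortest-path search. Returns Inf when the
# pair is disconnected.
brute_force_min_cost <- function(g, s, t) {
  adj <- list()
  for (k in seq_len(nrow(g$edges))) {
    e <- g$edges[k, ]
    adj[[as.character(e$res_i)]] <- rbind(adj[[as.character(e$res_i)]],
                                          c(e$res_j, e$cost))
    adj[[as.character(e$res_j)]] <- rbind(adj[[as.character(e$res_j)]],
                                          c(e$res_i, e$cost))
  }
  best <- Inf
  dfs <- function(v, cost, vis) {
    if (v == t) { best <<- min(best, cost); return(invisible(NULL)) }
    nb <- adj[[as.character(v)]]
    if (is.null(nb)) return(invisible(NULL))
    for (r in seq_len(nrow(nb)))
      if (!(nb[r, 1] %in% vis)) dfs(nb[r, 1], cost + nb[r, 2],
                                    c(vis, nb[r, 1]))
  }
  dfs(s, 0, s)
  best
}

# Random connected-ish test graph with positive MI weights.
random_mi_graph <- function(max_nodes = 12, p = 0.4) {
  repeat {
    nn <- sample(4:max_nodes, 1)
    em <- which(upper.tri(matrix(0, nn, nn)) &
                  matrix(runif(nn * nn) < p, nn, nn), arr.ind = TRUE)
    if (nrow(em) >= 2) break
  }
  residue_graph(data.frame(res_i = em[, 1], res_j = em[, 2],
                           mi = runif(nrow(em), 0.01, 1)))
}

# Hand-buildable pathway stub for pipeline-assembly tests.
make_pathway <- function(residues) {
  structure(list(residues = residues, total_mi = 1,
                 total_cost = length(residues) - 1, found = TRUE,
                 source = residues[1], sink = residues[length(residues)]),
            class = "pathway")
}

# Small PDB text fixture written on the fly (three alanine-like residues,
# plus an optional HETATM ligand record).
write_mini_pdb <- function(path, with_ligand = FALSE, insert_code = NULL,
                           dup_serial = FALSE) {
  fmt <- "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  lines <- character(0)
  serial <- 0
  for (r in 1:3) {
    for (at in list(c("N", "N"), c("CA", "C"), c("C", "C"), c("O", "O"))) {
      serial <- serial + 1
      ins <- if (!is.null(insert_code) && r == 2) insert_code else ""
      sn <- if (dup_serial && serial == 2) 1 else serial
      lines <- c(lines, sprintf(fmt, "ATOM", sn, paste0(" ", at[1]), "",
                                "ALA", "A", r, ins,
                                r * 3.8 + serial * 0.1, 0.5 * serial, 0.0,
                                1.0, 0.0, at[2]))
    }
  }
  if (with_ligand) {
    serial <- serial + 1
    lines <- c(lines, sprintf(fmt, "HETATM", serial, " N1 ", "", "LIG",
                              "A", 9, "", 0.0, 5.0, 0.0, 1.0, 0.0, "N"))
  }
  writeLines(c(lines, "END"), path)
  path
}

# Two-residue hand geometry: a ligand amine N (with explicit H along +x)
# and a receptor backbone O placed at a chosen distance/angle.
hb_fixture <- function(o_pos) {
  make_test_topology(c("N1", "HN", "O"), c("N", "H", "O"),
                     c(1, 1, 2),
                     rbind(c(0, 0, 0), c(1, 0, 0), o_pos),
                     is_ligand = c(TRUE, TRUE, FALSE))
}

# Acceptor position with N-O distance d and donor-H-acceptor angle ang
# (degrees): O in the xz plane so that the angle at H (at (1,0,0), with the
# donor N at the origin) is exactly ang and |N - O| = d.
acceptor_at <- function(d, ang) {
  u <- c(cos(pi - ang * pi / 180), 0, sin(pi - ang * pi / 180))
  f <- function(r) sqrt(sum((c(1, 0, 0) + r * u)^2)) - d
  r <- uniroot(f, c(0.01, d + 2), tol = 1e-12)$root
  c(1, 0, 0) + r * u
}

# Histogram MI with Miller-Madow correction computed *independently* of the
# package (plain R, used to cross-check mutual_information on raw vectors).
reference_mi <- function(a_deg, b_deg, bins = 30) {
  w <- 360 / bins
  ia <- pmin(floor((a_deg + 180) / w) + 1, bins)
  ib <- pmin(floor((b_deg + 180) / w) + 1, bins)
  ent <- function(cnt) {
    n <- sum(cnt); p <- cnt[cnt > 0] / n
    -sum(p * log(p)) + (sum(cnt > 0) - 1) / (2 * n)
  }
  ent(tabulate(ia, bins)) + ent(tabulate(ib, bins)) -
    ent(tabulate((ia - 1) * bins + ib, bins * bins))
}
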