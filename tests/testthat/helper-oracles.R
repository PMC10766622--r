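# Independent oracles and fixture builders shared across test files.

# ---- brute-force optimal transport by vertex enumeration -------------------
# Every vertex of the transportation polytope is a basic solution supported
# on m + k - 1 cells whose bipartite incidence forms a spanning tree. For
# tiny supports we enumerate all bases, solve each by a linear system, keep
# the feasible ones and take the minimum objective. Basis structure depends
# only on the shape (m, k), so the inverses are precomputed per shape.
.ot_bases_cache <- new.env(parent = emptyenv())

ot_bases <- function(m, k) {
  key <- paste(m, k)
  if (!is.null(.ot_bases_cache[[key]])) return(.ot_bases_cache[[key]])
  cells <- expand.grid(i = seq_len(m), j = seq_len(k))
  nb <- m + k - 1L
  combos <- utils::combn(nrow(cells), nb)
  inv_list <- list()
  combo_list <- list()
  for (c_idx in seq_len(ncol(combos))) {
    sel <- combos[, c_idx]
    # constraint matrix: m row sums + k col sums, last col constraint dropped
    A <- matrix(0, nb, nb)
    for (q in seq_len(nb)) {
      i <- cells$i[sel[q]]; j <- cells$j[sel[q]]
      A[i, q] <- 1
      if (j < k) A[m + j, q] <- A[m + j, q] + 1
    }
    inv <- tryCatch(solve(A), error = function(e) NULL)
    if (!is.null(inv)) {
      inv_list[[length(inv_list) + 1L]] <- inv
      combo_list[[length(combo_list) + 1L]] <- sel
    }
  }
  res <- list(
    cells = cells,
    combos = do.call(rbind, combo_list),
    inv = do.call(rbind, inv_list) # stacked (n_bases * nb) x nb
  )
  .ot_bases_cache[[key]] <- res
  res
}

bf_wasserstein <- function(mu, nu, C) {
  m <- length(mu); k <- length(nu)
  if (m == 1L) return(sum(nu * C[1L, ]))
  if (k == 1L) return(sum(mu * C[, 1L]))
  B <- ot_bases(m, k)
  nb <- m + k - 1L
  b <- c(mu, nu[-k])
  V <- B$inv %*% b # stacked basic solutions
  Vm <- matrix(V, ncol = nb, byrow = TRUE)
  cvals <- matrix(C[cbind(B$cells$i[t(B$combos)], B$cells$j[t(B$combos)])],
                  ncol = nb, byrow = TRUE)
  feas <- rowSums(Vm < -1e-9) == 0L
  stopifnot(any(feas))
  min(rowSums(Vm * cvals)[feas])
}

# ---- small LP oracle via boot::simplex --------------------------------------
lp_wasserstein <- function(mu, nu, C) {
  m <- length(mu); k <- length(nu)
  rowA <- t(vapply(seq_len(m), function(i) {
    z <- matrix(0, m, k); z[i, ] <- 1; as.vector(z)
  }, numeric(m * k)))
  colA <- t(vapply(seq_len(k), function(j) {
    z <- matrix(0, m, k); z[, j] <- 1; as.vector(z)
  }, numeric(m * k)))
  A3 <- rbind(rowA, colA)[-(m + k), , drop = FALSE]
  b3 <- c(mu, nu)[-(m + k)]
  unname(boot::simplex(a = as.vector(C), A3 = A3, b3 = b3)$value)
}

# ---- literal weighted-hop distance by path enumeration ----------------------
# Evaluates the minimal accumulated edge weight over all simple paths.
bf_weighted_hop <- function(g, strengths, from, to) {
  w <- stats::setNames(1 / sqrt(strengths$strength),
                       curvnet:::edge_key(strengths$from, strengths$to))
  paths <- igraph::all_simple_paths(g, from, to)
  lens <- vapply(paths, function(p) {
    nm <- names(p)
    sum(w[curvnet:::edge_key(nm[-length(nm)], nm[-1L])])
  }, numeric(1))
  min(lens)
}

# ---- fixture builders --------------------------------------------------------
named_graph <- function(edges) {
  igraph::graph_from_edgelist(matrix(edges, ncol = 2L, byrow = TRUE),
                              directed = FALSE)
}

path_graph3 <- function() named_graph(c("A", "B", "B", "C"))

triangle_graph <- function() named_graph(c("A", "B", "B", "C", "A", "C"))

star_graph4 <- function() named_graph(c("H", "L1", "H", "L2", "H", "L3"))

# random connected simple graph with named nodes
rand_connected_graph <- function(n, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::count_components(g) == 1L) break
  }
  igraph::V(g)$name <- sprintf("V%02d", seq_len(n))
  g
}

# random strictly positive strengths on a graph
rand_strengths <- function(g, lo = 0.1, hi = 1) {
  s <- uniform_strengths(g)
  s$strength <- stats::runif(nrow(s), lo, hi)
  s$correlation <- s$strength
  s
}

unit_wnet <- function(g) weighted_hop_distances(g, uniform_strengths(g))

# ---- knockout oracle ---------------------------------------------------------
# Rebuilds the knocked-out weighted network from scratch through the public
# constructor and recomputes baseline curvature on it.
knockout_oracle <- function(g, strengths, gene, pair) {
  g2 <- igraph::delete_vertices(g, gene)
  comp <- igraph::components(g2)
  if (comp$membership[pair[1]] != comp$membership[pair[2]]) return(NA_real_)
  keep <- names(comp$membership)[comp$membership == comp$membership[pair[1]]]
  g2 <- igraph::induced_subgraph(g2, keep)
  el2 <- igraph::as_edgelist(g2)
  k2 <- curvnet:::edge_key(el2[, 1], el2[, 2])
  sk <- curvnet:::edge_key(strengths$from, strengths$to)
  s2 <- strengths[match(k2, sk), ]
  wn2 <- weighted_hop_distances(g2, s2)
  unname(baseline_curvature(wn2, matrix(pair, ncol = 2)))
}

# ---- shared expensive fixtures (computed once per test run) -----------------
.fixture_cache <- new.env(parent = emptyenv())

fig1_analysis <- function() {
  if (is.null(.fixture_cache$fig1)) {
    fx <- synth_fig1(seed = 7)
    traj <- dynamic_curvature(fx$wnet)
    scales <- critical_scales(traj)
    .fixture_cache$fig1 <- list(fx = fx, traj = traj, scales = scales)
  }
  .fixture_cache$fig1
}
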