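#' Per-edge critical scales of the dynamic curvature
#'
#' The critical scale of an edge is the first grid scale at which its dynamic
#' curvature reaches the critical value (default 0.75) — the scale by which
#' information has diffused through the edge's community. Edges that never
#' reach the critical value get the last grid scale and are flagged. The
#' network characteristic scale `tau_star`, used for bridge calling, is the
#' grid point at the median critical-scale index over edges that reached the
#' threshold.
#'
#' @param traj a `curvature_trajectory` spanning the full grid.
#' @param critical_value curvature threshold (default 0.75).
#' @return object of class `critical_scale_result`: `t_c` (named per-edge
#'   scale), `reached` (logical flags), `tau_star`, `tau_star_index`,
#'   `kappa_at_tau_star` (named per-edge curvature at the characteristic
#'   scale), `critical_value` and the `grid`.
#' @export
critical_scales <- function(traj, critical_value = 0.75) {
  grid <- traj$grid
  idx <- apply(traj$kappa >= critical_value, 1L, function(z) {
    k <- which(z)
    if (length(k)) k[1L] else NA_integer_
  })
  reached <- !is.na(idx)
  t_c <- ifelse(reached, grid[idx], grid[length(grid)])
  names(t_c) <- rownames(traj$kappa)
  if (!any(reached))
    stop("no edge reached the critical curvature; extend the scale grid")
  tau_star_index <- as.integer(round(stats::median(idx[reached])))
  structure(list(t_c = t_c, reached = reached,
                 t_c_index = ifelse(reached, idx, length(grid)),
                 tau_star = grid[tau_star_index],
                 tau_star_index = tau_star_index,
                 kappa_at_tau_star = traj$kappa[, tau_star_index],
                 critical_value = critical_value, grid = grid),
            class = "critical_scale_result")
}

#' Critical-curvature filter and bridge identification
#'
#' Bridges — inter-community edges with restricted information exchange — are
#' the edges whose dynamic curvature is negative at the network
#' characteristic scale. Removing them decomposes the network into its
#' functional communities.
#'
#' @param wnet a `weighted_network` (or plain gene network) whose edges match
#'   `scales`.
#' @param scales a `critical_scale_result`.
#' @return list with `graph` (the filtered network, possibly disconnected),
#'   `bridges` (two-column matrix of removed edges), and `membership` (named
#'   component labels of the filtered network).
#' @export
critical_filter <- function(wnet, scales) {
  g <- if (inherits(wnet, "weighted_network")) wnet$graph else wnet
  el <- igraph::as_edgelist(g)
  keys <- edge_key(el[, 1L], el[, 2L])
  kap <- scales$kappa_at_tau_star[keys]
  if (anyNA(kap)) stop("curvature at the characteristic scale missing for ",
                       "some edges")
  drop <- which(kap < 0)
  filtered <- igraph::delete_edges(g, drop)
  comp <- igraph::components(filtered)
  list(graph = filtered,
       bridges = el[drop, , drop = FALSE],
       membership = stats::setNames(comp$membership, igraph::V(g)$name))
}

#' Average critical curvature per edge
#'
#' Averages the dynamic curvature over the critical dynamic range
#' \eqn{[0, t_c]}: the discrete sum is evaluated as a trapezoidal integral
#' over the (log-spaced) grid divided by \eqn{t_c}, so the value does not
#' depend on grid density. Edges that never reach the critical value are
#' averaged over the full grid.
#'
#' @param traj a `curvature_trajectory`.
#' @param scales the matching `critical_scale_result`.
#' @return named numeric vector of average critical curvatures.
#' @export
average_critical_curvature <- function(traj, scales) {
  grid <- traj$grid
  keys <- rownames(traj$kappa)
  acc <- vapply(seq_along(keys), function(e) {
    m <- scales$t_c_index[e]
    x <- grid[seq_len(m)]
    y <- traj$kappa[e, seq_len(m)]
    sum(diff(x) * (y[-1L] + y[-m]) / 2) / x[m]
  }, numeric(1))
  stats::setNames(acc, keys)
}

#' Persistent component scores under curvature-ordered pruning
#'
#' Edges are pruned iteratively by average critical curvature: iteration 0
#' removes all edges with negative values, and each following iteration
#' removes the edge set carrying the next-smallest value (ties removed
#' together) until no edges remain. After every iteration, each node pair
#' still sharing a connected component scores one point in the persistence
#' matrix R — the longer two genes stay co-membered, the stronger their
#' functional association. The gene distance is `D = max(R) - R`.
#'
#' @param net gene network (igraph) or `weighted_network`.
#' @param acc named vector of average critical curvatures covering every
#'   edge (canonical edge keys).
#' @return object of class `persistence_matrices`: `R` (integer co-membership
#'   counts, diagonal = total iterations), `D` (gene distance matrix),
#'   `n_iterations`.
#' @export
persistence_scores <- function(net, acc) {
  g <- if (inherits(net, "weighted_network")) net$graph else net
  el <- igraph::as_edgelist(g)
  keys <- edge_key(el[, 1L], el[, 2L])
  vals <- acc[keys]
  if (anyNA(vals)) stop("average critical curvature missing for some edges")
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  R <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  active <- vals >= 0 # iteration 0: negative sweep
  count_comembership <- function(active_idx) {
    gg <- igraph::subgraph_from_edges(g, which(active_idx),
                                      delete.vertices = FALSE)
    mem <- igraph::components(gg)$membership
    same <- outer(mem, mem, "==")
    R <<- R + same
  }
  count_comembership(active)
  n_iter <- 1L
  while (any(active)) {
    nxt <- min(vals[active])
    active[vals <= nxt] <- FALSE
    count_comembership(active)
    n_iter <- n_iter + 1L
  }
  storage.mode(R) <- "integer"
  D <- max(R) - R
  structure(list(R = R, D = D, n_iterations = n_iter),
            class = "persistence_matrices")
}

#' Hierarchical clustering of genes by persistence distance
#'
#' Agglomerative clustering on the gene distance `D = max(R) - R` derived
#' from the persistent component scores ("hierarchical-acc"). `D` is a valid
#' dissimilarity (symmetric, nonnegative, zero diagonal) but need not satisfy
#' the triangle inequality.
#'
#' @param D gene distance matrix.
#' @param linkage agglomeration rule (default `"average"`).
#' @param n_clusters optional number of flat clusters.
#' @return list with `tree` (`hclust`) and `labels` (or `NULL`).
#' @export
hierarchical_acc <- function(D, linkage = c("average", "complete", "single"),
                             n_clusters = NULL) {
  linkage <- match.arg(linkage)
  if (max(abs(D - t(D))) > 0 || any(diag(D) != 0) || any(D < 0))
    stop("D must be symmetric and nonnegative with zero diagonal")
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  labels <- if (!is.null(n_clusters)) stats::cutree(hc, k = n_clusters)
  list(tree = hc, labels = labels)
}
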