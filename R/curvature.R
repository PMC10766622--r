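#' Nodal probability measures on a weighted network
#'
#' Builds the per-node probability measures used by the coarse curvature:
#' either the strength measure, which distributes mass over a node's
#' neighbors proportionally to interaction strengths,
#' \deqn{\mu_r(s) = \tilde w_{rs} / \sum_{q \in N_r} \tilde w_{rq},}
#' or the one-step walk measure, the corresponding row of the node-weighted
#' transition matrix (see [transition_matrix()]).
#'
#' @param wnet a `weighted_network`.
#' @param kind `"strength"` or `"walk"`.
#' @param node_weights named positive node weights, required for
#'   `kind = "walk"`.
#' @return matrix of class `nodal_measures`, one row per node, rows sum to 1;
#'   attribute `kind` records the construction.
#' @export
nodal_measures <- function(wnet, kind = c("strength", "walk"),
                           node_weights = NULL) {
  kind <- match.arg(kind)
  if (kind == "strength") {
    M <- strength_measures(wnet$graph, igraph::E(wnet$graph)$strength)
  } else {
    if (is.null(node_weights)) stop("walk measures require node weights")
    M <- transition_matrix(wnet$graph, node_weights)
  }
  structure(M, kind = kind, class = c("nodal_measures", "matrix"))
}

# strength-normalized neighbor measures from an edge-value vector aligned
# with the graph's edge order; also used for perturbed measures where the
# edge values are the perturbed attribute a_rs.
strength_measures <- function(g, edge_values) {
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  el <- igraph::as_edgelist(g, names = FALSE)
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1L]; j <- el[e, 2L]
    M[i, j] <- M[i, j] + edge_values[e]
    M[j, i] <- M[j, i] + edge_values[e]
  }
  rs <- rowSums(M)
  if (any(rs <= 0)) stop("node with no positive-strength neighbor")
  M / rs
}

#' Ollivier-Ricci curvature between node pairs
#'
#' Coarse discrete Ricci curvature on the metric-measure network:
#' \deqn{\kappa(i,j) = 1 - W_1(\mu_i, \mu_j) / d_{ij},}
#' comparing the transport cost between the nodes' neighborhood measures to
#' the distance between the nodes themselves. Unless another ground metric is
#' supplied, the weighted hop distance of the network is used both as the
#' transport ground metric and as the denominator.
#'
#' @param wnet a `weighted_network`.
#' @param measures a `nodal_measures` matrix over the network nodes.
#' @param pairs two-column character matrix (or vector of length 2) of node
#'   pairs; both nodes must be distinct.
#' @param D ground metric; defaults to `wnet$dist`. The same metric is used
#'   inside the Wasserstein distance and in the denominator.
#' @return named numeric vector of curvatures, names are canonical edge keys.
#' @export
ollivier_ricci <- function(wnet, measures, pairs, D = wnet$dist) {
  if (is.vector(pairs)) pairs <- matrix(pairs, ncol = 2L)
  kap <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    if (identical(i, j)) stop("curvature undefined for a node with itself")
    w1 <- wasserstein1(measures[i, ], measures[j, ], D, check = FALSE)
    kap[k] <- 1 - w1 / D[i, j]
  }
  names(kap) <- edge_key(pairs[, 1L], pairs[, 2L])
  kap
}

#' Heat-diffusion operator of a weighted network
#'
#' Builds the generator of the network diffusion used by the dynamic
#' curvature. Edges carry the affinity \eqn{A_{ij} = d_{max} - d_{ij}} (zero
#' off-edges), where \eqn{d} is the weighted hop distance and \eqn{d_{max}}
#' the largest distance over edges; the affinity of the longest edge, which
#' would otherwise vanish, is floored at `alpha_factor * d_max` so no edge is
#' diffusion-silent. The generator is the random-walk normalized Laplacian
#' \eqn{L = I - K^{-1} A} with \eqn{K_{ii} = \sum_j A_{ij}}. Because
#' \eqn{K^{-1}A} is similar to a symmetric matrix, the heat kernel
#' \eqn{\exp(-L\tau)} is evaluated through one symmetric eigendecomposition,
#' reused across all scales.
#'
#' @param wnet a `weighted_network`.
#' @param alpha_factor relative affinity floor (default `1e-6`).
#' @return object of class `diffusion_operator`: nodes, affinity `A`, degree
#'   vector `deg`, eigenvalues `lambda` (ascending) and eigenvectors `U` of
#'   the symmetrized generator, and `lambda2`, the spectral gap (smallest
#'   nonzero eigenvalue).
#' @export
diffusion_operator <- function(wnet, alpha_factor = 1e-6) {
  nodes <- wnet$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  el <- wn_edges(wnet)
  aff <- wnet$d_max - wnet$edge_dist
  floor_a <- alpha_factor * wnet$d_max
  aff <- pmax(aff, floor_a)
  A[cbind(el[, 1L], el[, 2L])] <- aff
  A[cbind(el[, 2L], el[, 1L])] <- aff
  deg <- rowSums(A)
  if (any(deg <= 0)) stop("isolated node in diffusion operator")
  dis <- 1 / sqrt(deg)
  Lsym <- diag(n) - (dis * A) * rep(dis, each = n) # K^-1/2 A K^-1/2
  Lsym <- (Lsym + t(Lsym)) / 2
  eig <- eigen(Lsym, symmetric = TRUE)
  ord <- order(eig$values)
  lambda <- pmax(eig$values[ord], 0)
  # the conserved mode is exactly zero analytically; clamp its numerical
  # estimate so it does not decay over very long diffusion horizons
  lambda[lambda < 1e-12 * max(lambda)] <- 0
  U <- eig$vectors[, ord, drop = FALSE]
  lambda2 <- lambda[lambda > 0][1L]
  if (!length(lambda2) || is.na(lambda2))
    stop("diffusion generator has no spectral gap (disconnected network?)")
  structure(list(nodes = nodes, A = A, deg = deg, lambda = lambda, U = U,
                 lambda2 = lambda2, alpha_factor = alpha_factor),
            class = "diffusion_operator")
}

#' Diffused Dirac measures at a given scale
#'
#' Evolves Dirac measures under the heat semigroup of the random-walk
#' Laplacian: \eqn{\eta_i(\tau)} is row i of \eqn{\exp(-L\tau)}. Mass
#' conservation is checked against a loose sanity bound, atoms below
#' `support_tol` are truncated, and each measure is renormalized, so
#' returned rows sum to 1.
#'
#' @param op a `diffusion_operator`.
#' @param tau diffusion scale, nonnegative.
#' @param seeds nodes whose measures are required (default all).
#' @param support_tol truncation threshold for negligible atoms
#'   (default `1e-8`).
#' @return matrix with one probability row per seed node.
#' @export
diffusion_measures <- function(op, tau, seeds = op$nodes,
                               support_tol = 1e-8) {
  if (tau < 0) stop("diffusion scale tau must be nonnegative")
  n <- length(op$nodes)
  si <- match(seeds, op$nodes)
  if (anyNA(si)) stop("unknown seed node(s)")
  if (tau == 0) {
    H <- matrix(0, length(si), n, dimnames = list(op$nodes[si], op$nodes))
    H[cbind(seq_along(si), si)] <- 1
    return(H)
  }
  dis <- 1 / sqrt(op$deg)
  # rows of exp(-L tau) = K^-1/2 U exp(-lambda tau) U' K^1/2
  left <- (dis[si] * op$U[si, , drop = FALSE]) *
    rep(exp(-op$lambda * tau), each = length(si))
  H <- left %*% t(op$U * rep(sqrt(op$deg), times = ncol(op$U)))
  dimnames(H) <- list(op$nodes[si], op$nodes)
  # exact mass conservation holds analytically; the numerical error of the
  # eigendecomposition route grows with the dynamic range of the degrees, so
  # the sanity bound is loose and rows are renormalized on return
  # a near-degenerate pair (0, lambda2) limits attainable eigen accuracy to
  # roughly the mixing angle eps/lambda2, hence a loose sanity bound here;
  # rows are renormalized below
  mass_err <- max(abs(rowSums(H) - 1))
  if (mass_err > 1e-7)
    stop("diffusion lost mass beyond tolerance: ", mass_err)
  H[H < support_tol] <- 0
  H / rowSums(H)
}

#' Logarithmic scale grid for the dynamic curvature
#'
#' Zero plus `n_points` logarithmically spaced scales spanning
#' `[1e-2 * c_lo / lambda2, t_max_factor / lambda2]`, where `lambda2` is the
#' generator's spectral gap; the upper end is far beyond the mixing time so
#' trajectories reach their limiting value.
#'
#' @param op a `diffusion_operator` (or a numeric `lambda2`).
#' @param n_points number of positive grid points (default 40).
#' @param c_lo multiplier on the lower end (default 1).
#' @param t_max_factor multiplier on the upper end (default 10).
#' @return increasing numeric vector starting at 0.
#' @export
scale_grid <- function(op, n_points = 40L, c_lo = 1, t_max_factor = 10) {
  lambda2 <- if (inherits(op, "diffusion_operator")) op$lambda2 else op
  c(0, exp(seq(log(1e-2 * c_lo / lambda2), log(t_max_factor / lambda2),
               length.out = n_points)))
}

#' Dynamic Ollivier-Ricci curvature over a scale grid
#'
#' Replaces the static neighborhood measures by heat-diffused Dirac measures
#' and tracks, per edge, the curvature
#' \deqn{\kappa_{ij}(\tau) = 1 - W_1(\eta_i(\tau), \eta_j(\tau)) / d_{ij}}
#' across scales. At \eqn{\tau = 0} the measures are independent Diracs and
#' the curvature is exactly 0; as the diffusions mix to the common stationary
#' distribution the curvature tends to 1. Intra-community edges turn positive
#' early, while bridges between communities stay flat or dip negative —
#' restricted information exchange.
#'
#' @param wnet a `weighted_network`.
#' @param grid scale grid starting at 0; default [scale_grid()] of the
#'   network's diffusion operator.
#' @param edges two-column character matrix of edges to monitor (default all
#'   edges).
#' @param n_grid grid size used when `grid` is `NULL`.
#' @param support_tol measure truncation threshold (see
#'   [diffusion_measures()]).
#' @param op optionally a precomputed `diffusion_operator`.
#' @return object of class `curvature_trajectory`: list with `edges`, `grid`,
#'   `kappa` (edges x scales matrix, rownames canonical edge keys), `d`
#'   (ground distances of the monitored edges), and `lambda2`.
#' @export
dynamic_curvature <- function(wnet, grid = NULL, edges = NULL, n_grid = 40L,
                              support_tol = 1e-8, op = NULL) {
  if (is.null(op)) op <- diffusion_operator(wnet)
  if (is.null(grid)) grid <- scale_grid(op, n_points = n_grid)
  if (grid[1L] != 0) stop("scale grid must start at 0")
  if (is.null(edges)) edges <- wn_edges(wnet)
  if (is.vector(edges)) edges <- matrix(edges, ncol = 2L)
  keys <- edge_key(edges[, 1L], edges[, 2L])
  D <- wnet$dist
  d_edge <- D[edges]
  kap <- matrix(NA_real_, nrow(edges), length(grid),
                dimnames = list(keys, NULL))
  for (t in seq_along(grid)) {
    H <- diffusion_measures(op, grid[t], support_tol = support_tol)
    for (e in seq_len(nrow(edges))) {
      w1 <- wasserstein1(H[edges[e, 1L], ], H[edges[e, 2L], ], D,
                         check = FALSE)
      kap[e, t] <- 1 - w1 / d_edge[e]
    }
  }
  structure(list(edges = edges, grid = grid, kappa = kap, d = d_edge,
                 lambda2 = op$lambda2),
            class = "curvature_trajectory")
}

#' @export
print.curvature_trajectory <- function(x, ...) {
  cat("dynamic curvature trajectories:", nrow(x$kappa), "edges,",
      length(x$grid), "scales in [0, ", format(max(x$grid), digits = 4),
      "]\n", sep = " ")
  invisible(x)
}

#' Plot dynamic curvature trajectories
#'
#' One line per monitored edge, scale on a log axis (the zero scale is
#' dropped from the display).
#'
#' @param x a `curvature_trajectory`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.curvature_trajectory <- function(x, ...) {
  pos <- x$grid > 0
  graphics::matplot(x$grid[pos], t(x$kappa[, pos, drop = FALSE]),
                    type = "l", lty = 1, log = "x",
                    xlab = expression(tau), ylab = expression(kappa(tau)),
                    ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
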