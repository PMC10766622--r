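#' Node weights from an expression profile
#'
#' Maps one sample's expression values onto the network nodes as random-walk
#' node weights. Values at or below zero (possible after regularized-log
#' normalization) are floored at a small positive constant so the walk stays
#' well defined.
#'
#' @param expr expression matrix (genes x samples) covering every node.
#' @param sample sample identifier (column) to extract.
#' @param net gene network whose nodes define the weight support.
#' @param floor positive lower bound applied to the weights (default `1e-6`).
#' @return named positive numeric vector over the network nodes.
#' @export
node_weights <- function(expr, sample, net, floor = 1e-6) {
  nodes <- igraph::V(net)$name
  if (!all(nodes %in% rownames(expr)))
    stop("expression matrix does not cover every network node")
  w <- expr[nodes, sample]
  pmax(w, floor)
}

#' Transition matrix of the node-weighted random walk
#'
#' For a walk at node i, the probability of stepping to a neighbor j is
#' proportional to j's node weight:
#' \deqn{P_{ij} = w_j / \sum_{k \in N_i} w_k} for \eqn{j \in N_i}, zero
#' otherwise. With uniform weights this is the simple random walk.
#'
#' @param net connected gene network (`igraph`).
#' @param w strictly positive node weights named by node.
#' @return row-stochastic matrix with node dimnames.
#' @export
transition_matrix <- function(net, w) {
  validate_gene_network(net)
  nodes <- igraph::V(net)$name
  w <- w[nodes]
  if (any(!is.finite(w)) || any(w <= 0))
    stop("node weights must be strictly positive on every node")
  A <- as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))
  P <- A * rep(w, each = length(w)) # P_ij = A_ij * w_j
  rs <- rowSums(P)
  if (any(rs <= 0)) stop("node with empty neighborhood")
  P <- P / rs
  dimnames(P) <- list(nodes, nodes)
  P
}

#' Stationary distribution of the node-weighted walk (closed form)
#'
#' The walk of [transition_matrix()] is reversible and its unique stationary
#' distribution has the closed form
#' \deqn{\pi_i = w_i \sum_{j \in N_i} w_j / K,} with K the normalizing
#' constant. The fixed-point residual \eqn{\lVert \pi P - \pi \rVert_\infty}
#' is verified to be below `1e-10`.
#'
#' @inheritParams transition_matrix
#' @return named probability vector with attribute `K_norm` (the
#'   normalization constant).
#' @export
stationary_distribution <- function(net, w) {
  validate_gene_network(net)
  nodes <- igraph::V(net)$name
  w <- w[nodes]
  if (any(!is.finite(w)) || any(w <= 0))
    stop("node weights must be strictly positive on every node")
  A <- as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))
  s <- w * as.numeric(A %*% w)
  K <- sum(s)
  pi <- s / K
  names(pi) <- nodes
  P <- transition_matrix(net, w)
  resid <- max(abs(as.numeric(pi %*% P) - pi))
  if (resid > 1e-10)
    stop("stationary fixed-point residual above tolerance: ", resid)
  attr(pi, "K_norm") <- K
  pi
}

#' All-pairs hop distances
#'
#' Unweighted shortest-path lengths between all node pairs; the ground metric
#' used for sample-level Wasserstein distances.
#'
#' @param net connected gene network.
#' @return symmetric integer matrix with zero diagonal.
#' @export
hop_distance_matrix <- function(net) {
  validate_gene_network(net, require_connected = FALSE)
  D <- igraph::distances(net, weights = NA)
  if (any(!is.finite(D))) stop("network is disconnected")
  storage.mode(D) <- "integer"
  D
}

#' Sample-pairwise Wasserstein distance matrix
#'
#' For each sample, expression values become node weights, the stationary
#' distribution of the node-weighted walk is computed in closed form, and
#' samples are compared by the Wasserstein-1 distance between their
#' stationary distributions under the hop-distance ground metric.
#'
#' @param expr expression matrix (genes x samples) covering every node of
#'   `net`; extra genes are ignored.
#' @param net connected gene network.
#' @param floor node-weight floor (see [node_weights()]).
#' @param method transport solver passed to [wasserstein1()].
#' @return symmetric nonnegative matrix with zero diagonal, sample dimnames.
#' @export
sample_distance_matrix <- function(expr, net, floor = 1e-6,
                                   method = "exact") {
  validate_gene_network(net)
  if (ncol(expr) < 2L) stop("need at least two samples")
  expr <- match_genes(expr, net, quiet = TRUE)
  D <- hop_distance_matrix(net)
  samples <- colnames(expr)
  pis <- vapply(samples, function(s) {
    as.numeric(stationary_distribution(net, node_weights(expr, s, net, floor)))
  }, numeric(igraph::vcount(net)))
  S <- length(samples)
  W <- matrix(0, S, S, dimnames = list(samples, samples))
  for (q in seq_len(S - 1L)) {
    for (r in seq(q + 1L, S)) {
      W[q, r] <- W[r, q] <- wasserstein1(pis[, q], pis[, r], D,
                                         method = method, check = FALSE)
    }
  }
  W
}

#' Hierarchical clustering of samples from a precomputed distance matrix
#'
#' Agglomerative clustering on the Wasserstein sample-distance matrix. The
#' result is deterministic given `W`.
#'
#' @param W symmetric sample-distance matrix.
#' @param n_clusters number of flat clusters to cut; the number of groups is
#'   a required analysis choice, no heuristic is applied.
#' @param linkage agglomeration rule; `"ward"` is accepted but warned about,
#'   since Ward linkage presumes squared-Euclidean input which a Wasserstein
#'   matrix is not.
#' @return list with `labels` (named integer vector) and `tree` (`hclust`).
#' @export
cluster_samples <- function(W, n_clusters,
                            linkage = c("average", "complete", "single", "ward")) {
  linkage <- match.arg(linkage)
  S <- nrow(W)
  if (n_clusters < 1L || n_clusters > S)
    stop("n_clusters must be between 1 and the number of samples")
  if (linkage == "ward") {
    warning("ward linkage is metrically improper on a non-Euclidean ",
            "Wasserstein distance matrix")
    linkage <- "ward.D2"
  }
  hc <- stats::hclust(stats::as.dist(W), method = linkage)
  labels <- stats::cutree(hc, k = n_clusters)
  list(labels = labels, tree = hc)
}

#' Export an hclust tree in Newick format
#'
#' @param tree an `hclust` object.
#' @param path output file.
#' @export
write_dendrogram_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
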