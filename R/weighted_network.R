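#' Outlier-desensitized Pearson correlation
#'
#' Pearson correlation is sensitive to single influential samples. This
#' routine greedily removes the sample whose leave-one-out exclusion changes
#' the correlation the most, as long as that change exceeds
#' `influence_threshold` and fewer than `max_removed` samples have been
#' removed, then returns the correlation on the remaining samples.
#'
#' @param x,y numeric vectors of equal length (>= 4 after any removal).
#' @param influence_threshold minimum leave-one-out change in r that triggers
#'   a removal (default 0.2); `Inf` disables removal entirely.
#' @param max_removed cap on removals (default 2).
#' @return list with `r` (signed correlation) and `removed` (indices of
#'   removed samples, possibly empty).
#' @export
desensitized_correlation <- function(x, y, influence_threshold = 0.2,
                                     max_removed = 2L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4L) stop("need at least 4 paired samples")
  keep <- seq_along(x)
  removed <- integer(0)
  repeat {
    xs <- x[keep]; ys <- y[keep]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
      stop("constant vector: correlation undefined")
    r_cur <- stats::cor(xs, ys)
    if (length(removed) >= max_removed || length(keep) - 1L < 4L) break
    infl <- vapply(seq_along(keep), function(k) {
      x2 <- xs[-k]; y2 <- ys[-k]
      if (stats::sd(x2) == 0 || stats::sd(y2) == 0) return(NA_real_)
      abs(stats::cor(x2, y2) - r_cur)
    }, numeric(1))
    if (all(is.na(infl))) break
    top <- which.max(infl)
    if (!is.finite(influence_threshold) || is.na(infl[top]) ||
        infl[top] <= influence_threshold) break
    removed <- c(removed, keep[top])
    keep <- keep[-top]
  }
  xs <- x[keep]; ys <- y[keep]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("constant vector: correlation undefined")
  list(r = stats::cor(xs, ys), removed = removed)
}

#' Per-edge interaction strengths from expression correlations
#'
#' For every network edge (i, j), the interaction strength is the absolute
#' (optionally desensitized) Pearson correlation of the two genes across the
#' cohort samples: \eqn{\tilde w_{ij} = |c_{ij}|}. Strengths of (numerically)
#' zero are floored at `floor` so the reciprocal edge weights stay finite.
#'
#' @param expr expression matrix (genes x samples) covering every node.
#' @param net connected gene network.
#' @param desensitize apply [desensitized_correlation()] per edge.
#' @param influence_threshold,max_removed passed to the desensitizer.
#' @param floor positive lower bound on strengths (default `1e-6`).
#' @return data frame of class `interaction_strengths` with columns `from`,
#'   `to`, `correlation` (signed), `strength` (in `[floor, 1]`), `n_removed`,
#'   and a list column `removed` of removed sample names; rows follow the
#'   edge order of `net`.
#' @export
interaction_strengths <- function(expr, net, desensitize = TRUE,
                                  influence_threshold = 0.2,
                                  max_removed = 2L, floor = 1e-6) {
  validate_gene_network(net)
  nodes <- igraph::V(net)$name
  missing <- setdiff(nodes, rownames(expr))
  if (length(missing) > 0L)
    stop("genes missing from the expression matrix: ",
         paste(missing, collapse = ", "))
  el <- igraph::as_edgelist(net)
  can_desensitize <- desensitize && ncol(expr) >= 5L
  res <- lapply(seq_len(nrow(el)), function(e) {
    x <- expr[el[e, 1L], ]; y <- expr[el[e, 2L], ]
    if (can_desensitize) {
      d <- desensitized_correlation(x, y, influence_threshold, max_removed)
      list(r = d$r, removed = colnames(expr)[d$removed])
    } else {
      if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("constant expression for edge ", el[e, 1L], "-", el[e, 2L])
      list(r = stats::cor(x, y), removed = character(0))
    }
  })
  r <- vapply(res, `[[`, numeric(1), "r")
  removed <- lapply(res, `[[`, "removed")
  out <- data.frame(from = el[, 1L], to = el[, 2L], correlation = r,
                    strength = pmax(abs(r), floor),
                    n_removed = lengths(removed), stringsAsFactors = FALSE)
  out$removed <- removed
  class(out) <- c("interaction_strengths", class(out))
  out
}

#' Uniform interaction strengths
#'
#' Assigns the same strength to every edge; used for idealized topologies
#' where the analysis should reflect structure alone.
#'
#' @param net gene network.
#' @param value common strength in (0, 1].
#' @return an `interaction_strengths` data frame.
#' @export
uniform_strengths <- function(net, value = 1) {
  validate_gene_network(net, require_connected = FALSE)
  if (value <= 0 || value > 1) stop("strength must lie in (0, 1]")
  el <- igraph::as_edgelist(net)
  out <- data.frame(from = el[, 1L], to = el[, 2L], correlation = value,
                    strength = value, n_removed = 0L,
                    stringsAsFactors = FALSE)
  out$removed <- replicate(nrow(el), character(0), simplify = FALSE)
  class(out) <- c("interaction_strengths", class(out))
  out
}

#' Weighted gene network with all-pairs weighted hop distances
#'
#' Maps interaction strengths to edge weights \eqn{w_{uv} = 1/\sqrt{\tilde
#' w_{uv}}}; a path's length is the sum of its edge weights and the weighted
#' hop distance \eqn{d^w_{ij}} is the minimum path length over all paths,
#' computed by Dijkstra's algorithm (identical to explicit path enumeration
#' because all edge weights are positive).
#'
#' @param net connected gene network.
#' @param strengths an `interaction_strengths` data frame covering every edge
#'   of `net` (row order need not match).
#' @return object of class `weighted_network`: list with `graph` (igraph with
#'   `strength` and `weight` edge attributes), `nodes`, `strengths` and
#'   `weights` (vectors in graph edge order, named by canonical edge key),
#'   `dist` (all-pairs weighted hop distance matrix) and `d_max` (largest
#'   distance over edges).
#' @export
weighted_hop_distances <- function(net, strengths) {
  validate_gene_network(net)
  el <- igraph::as_edgelist(net)
  keys <- edge_key(el[, 1L], el[, 2L])
  skeys <- edge_key(strengths$from, strengths$to)
  idx <- match(keys, skeys)
  if (anyNA(idx))
    stop("strengths missing for edges: ",
         paste(utils::head(keys[is.na(idx)], 5L), collapse = ", "))
  s <- strengths$strength[idx]
  if (any(!is.finite(s)) || any(s <= 0))
    stop("interaction strengths must be strictly positive")
  w <- 1 / sqrt(s)
  g <- net
  igraph::E(g)$strength <- s
  igraph::E(g)$weight <- w
  Dw <- igraph::distances(g, weights = w)
  if (any(!is.finite(Dw))) stop("weighted network is disconnected")
  nodes <- igraph::V(g)$name
  dimnames(Dw) <- list(nodes, nodes)
  d_edge <- Dw[cbind(el[, 1L], el[, 2L])]
  structure(list(graph = g, nodes = nodes,
                 strengths = stats::setNames(s, keys),
                 weights = stats::setNames(w, keys),
                 edge_dist = stats::setNames(d_edge, keys),
                 dist = Dw, d_max = max(d_edge)),
            class = "weighted_network")
}

#' Build a cohort-specific weighted network
#'
#' Convenience wrapper: optionally restricts the expression matrix to the
#' samples of one subtype, computes per-edge interaction strengths and the
#' weighted hop distances.
#'
#' @inheritParams interaction_strengths
#' @param labels optional named character vector of sample subtype labels.
#' @param subtype optional subtype whose samples form the cohort.
#' @param ... passed on to [interaction_strengths()].
#' @return a `weighted_network`.
#' @export
build_weighted_network <- function(expr, net, labels = NULL, subtype = NULL,
                                   ...) {
  if (!is.null(subtype)) {
    if (is.null(labels)) stop("subtype restriction requires labels")
    keep <- names(labels)[labels == subtype]
    keep <- intersect(colnames(expr), keep)
    if (length(keep) < 4L)
      stop("fewer than 4 samples for subtype ", subtype)
    expr <- expr[, keep, drop = FALSE]
  }
  strengths <- interaction_strengths(expr, net, ...)
  weighted_hop_distances(net, strengths)
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("weighted gene network:", length(x$nodes), "nodes,",
      length(x$weights), "edges\n")
  cat("  strength range: [", format(min(x$strengths), digits = 4), ", ",
      format(max(x$strengths), digits = 4), "]\n", sep = "")
  cat("  d_max (largest edge distance):", format(x$d_max, digits = 4), "\n")
  invisible(x)
}

# 2-column character matrix of the edges of a weighted network (graph order)
wn_edges <- function(wnet) {
  igraph::as_edgelist(wnet$graph)
}

#' Write and read a weighted network as GraphML
#'
#' Edge attributes `strength` and `weight` are preserved; distances are
#' recomputed on load.
#'
#' @param wnet a `weighted_network`.
#' @param path GraphML file path.
#' @export
write_weighted_network <- function(wnet, path) {
  igraph::write_graph(wnet$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_weighted_network
#' @export
read_weighted_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  igraph::V(g)$name <- toupper(trimws(igraph::V(g)$name))
  g <- igraph::as_undirected(g, mode = "each")
  if (is.null(igraph::E(g)$strength))
    stop("GraphML file lacks the 'strength' edge attribute")
  el <- igraph::as_edgelist(g)
  strengths <- data.frame(from = el[, 1L], to = el[, 2L],
                          correlation = igraph::E(g)$strength,
                          strength = igraph::E(g)$strength,
                          n_removed = 0L, stringsAsFactors = FALSE)
  base <- igraph::delete_edge_attr(g, "strength")
  if (!is.null(igraph::E(base)$weight))
    base <- igraph::delete_edge_attr(base, "weight")
  weighted_hop_distances(base, strengths)
}
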