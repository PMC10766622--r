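#' Baseline Ollivier-Ricci curvature of monitored gene pairs
#'
#' Curvature of [ollivier_ricci()] with strength-normalized nodal measures
#' and the weighted hop distance as ground metric — the reference value
#' against which perturbation and knockout effects are measured.
#'
#' @param wnet a `weighted_network`.
#' @param pairs two-column character matrix of monitored gene pairs.
#' @return named numeric vector of curvatures.
#' @export
baseline_curvature <- function(wnet, pairs) {
  mu <- nodal_measures(wnet, "strength")
  ollivier_ricci(wnet, mu, pairs)
}

#' Perturbation grid for an edge strength
#'
#' `n` uniformly spaced values from a negligible strength `epsilon` up to the
#' edge's current strength: \eqn{\hat c^{(\zeta)} = \epsilon + (\zeta - 1) h}
#' with step \eqn{h = (\tilde w_{ij} - \epsilon)/(N - 1)}. The last grid
#' point equals the unperturbed strength.
#'
#' @param w_tilde current interaction strength of the edge.
#' @param epsilon negligible strength (default `1e-6`).
#' @param n number of grid points (default 6).
#' @return strictly increasing numeric vector of length `n`.
#' @export
perturbation_grid <- function(w_tilde, epsilon = 1e-6, n = 6L) {
  if (w_tilde <= epsilon)
    stop("edge strength is already at or below epsilon; nothing to perturb")
  h <- (w_tilde - epsilon) / (n - 1L)
  grid <- epsilon + (seq_len(n) - 1L) * h
  grid[n] <- w_tilde
  grid
}

# rebuild a weighted network from modified strengths on the same topology
rebuild_weighted <- function(wnet, strengths_vec) {
  el <- wn_edges(wnet)
  s <- data.frame(from = el[, 1L], to = el[, 2L],
                  correlation = strengths_vec, strength = strengths_vec,
                  n_removed = 0L, stringsAsFactors = FALSE)
  s$removed <- replicate(nrow(el), character(0), simplify = FALSE)
  class(s) <- c("interaction_strengths", class(s))
  base <- wnet$graph
  base <- igraph::delete_edge_attr(base, "strength")
  base <- igraph::delete_edge_attr(base, "weight")
  weighted_hop_distances(base, s)
}

#' In-silico perturbation of a single edge
#'
#' Dampens the interaction strength of one edge toward zero along a
#' [perturbation_grid()] to simulate disrupted cooperation between its
#' endpoints. At each grid value the edge weight, the weighted hop distances
#' and the strength measures are rebuilt from scratch and the curvature of
#' every monitored pair is recomputed. The net effect is
#' \eqn{\Delta = \kappa(\hat c = \epsilon) - \kappa(\mathrm{baseline})}.
#' Edges whose removal disconnects the network (topological cut edges) are
#' excluded, mirroring their elimination from the reported rankings.
#'
#' @param wnet a `weighted_network`.
#' @param edge character vector of length 2, an existing edge.
#' @param pairs two-column character matrix of monitored gene pairs.
#' @param epsilon,n_grid perturbation grid parameters (defaults `1e-6`, 6).
#' @return list with `edge`, `excluded` flag (+ `reason`), and when not
#'   excluded: `grid`, `kappa` (pairs x grid matrix), `baseline`, and `delta`
#'   (named per pair).
#' @export
perturb_edge <- function(wnet, edge, pairs, epsilon = 1e-6, n_grid = 6L) {
  if (is.vector(pairs)) pairs <- matrix(pairs, ncol = 2L)
  key <- edge_key(edge[1L], edge[2L])
  if (!key %in% names(wnet$strengths)) stop("edge not in network: ", key)
  eid <- igraph::get_edge_ids(wnet$graph, edge)
  if (eid %in% igraph::bridges(wnet$graph)) {
    return(list(edge = edge, excluded = TRUE,
                reason = "disconnects the network when removed"))
  }
  grid <- perturbation_grid(wnet$strengths[[key]], epsilon, n_grid)
  base_kappa <- baseline_curvature(wnet, pairs)
  kap <- matrix(NA_real_, nrow(pairs), length(grid),
                dimnames = list(names(base_kappa), NULL))
  keys_all <- names(wnet$strengths)
  for (z in seq_along(grid)) {
    s2 <- wnet$strengths
    s2[[key]] <- grid[z]
    wn2 <- rebuild_weighted(wnet, s2[keys_all])
    mu2 <- nodal_measures(wn2, "strength")
    kap[, z] <- ollivier_ricci(wn2, mu2, pairs)
  }
  list(edge = edge, excluded = FALSE, grid = grid, kappa = kap,
       baseline = base_kappa, delta = kap[, 1L] - base_kappa)
}

#' In-silico knockout of a gene
#'
#' Removes the gene's node and all incident edges, rebuilds the weighted hop
#' distances and strength measures on the surviving subgraph, and recomputes
#' the curvature of every monitored pair. Pairs separated into different
#' components by the knockout are excluded (their ground distance would be
#' infinite).
#'
#' @param wnet a `weighted_network`.
#' @param gene node to remove; must not belong to any monitored pair.
#' @param pairs two-column character matrix of monitored gene pairs.
#' @return list with `gene`, per-pair `baseline`, `kappa_knockout`, `delta`
#'   (NA where excluded), `excluded` (logical per pair) and `reason`.
#' @export
knockout_gene <- function(wnet, gene, pairs) {
  if (is.vector(pairs)) pairs <- matrix(pairs, ncol = 2L)
  if (gene %in% pairs)
    stop("knocked-out gene belongs to a monitored pair: ", gene)
  if (!gene %in% wnet$nodes) stop("unknown gene: ", gene)
  base_kappa <- baseline_curvature(wnet, pairs)
  g2 <- igraph::delete_vertices(wnet$graph, gene)
  comp <- igraph::components(g2)
  # keep the component(s); distances on the full surviving subgraph
  el2 <- igraph::as_edgelist(g2)
  keys2 <- edge_key(el2[, 1L], el2[, 2L])
  pair_keys <- names(base_kappa)
  excluded <- logical(nrow(pairs))
  kap_ko <- rep(NA_real_, nrow(pairs))
  names(kap_ko) <- pair_keys
  same_comp <- comp$membership[pairs[, 1L]] == comp$membership[pairs[, 2L]]
  excluded[!same_comp] <- TRUE
  if (any(same_comp)) {
    # isolated survivors carry no measure; drop them before rebuilding
    iso <- igraph::V(g2)$name[igraph::degree(g2) == 0]
    if (length(iso)) g2 <- igraph::delete_vertices(g2, iso)
    w2 <- wnet$weights[keys2]
    Dw2 <- igraph::distances(g2, weights = w2)
    mu2 <- strength_measures(g2, wnet$strengths[keys2])
    for (k in which(same_comp)) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      w1 <- wasserstein1(mu2[i, ], mu2[j, ], Dw2, check = FALSE)
      kap_ko[k] <- 1 - w1 / Dw2[i, j]
    }
  }
  list(gene = gene, baseline = base_kappa, kappa_knockout = kap_ko,
       delta = kap_ko - base_kappa, excluded = excluded,
       reason = ifelse(excluded, "knockout separates the monitored pair", ""))
}

#' Perturbation effects for a set of edges
#'
#' Applies [perturb_edge()] across edges and assembles the intervention
#' effect table: one row per (edge, monitored pair) with baseline curvature,
#' endpoint curvature at the negligible strength, the net change Delta and
#' its sign class; excluded edges carry the exclusion reason.
#'
#' @param wnet a `weighted_network`.
#' @param pairs two-column character matrix of monitored pairs.
#' @param edges two-column matrix of edges to perturb (default: all edges).
#' @param epsilon,n_grid see [perturb_edge()].
#' @return data frame with columns `id`, `pair`, `kappa_baseline`,
#'   `kappa_endpoint`, `delta`, `sign_class`, `excluded`, `reason`.
#' @export
perturbation_effects <- function(wnet, pairs, edges = NULL,
                                 epsilon = 1e-6, n_grid = 6L) {
  if (is.null(edges)) edges <- wn_edges(wnet)
  if (is.vector(edges)) edges <- matrix(edges, ncol = 2L)
  if (is.vector(pairs)) pairs <- matrix(pairs, ncol = 2L)
  rows <- lapply(seq_len(nrow(edges)), function(e) {
    res <- perturb_edge(wnet, edges[e, ], pairs, epsilon, n_grid)
    id <- edge_key(edges[e, 1L], edges[e, 2L])
    if (res$excluded) {
      data.frame(id = id, pair = edge_key(pairs[, 1L], pairs[, 2L]),
                 kappa_baseline = NA_real_, kappa_endpoint = NA_real_,
                 delta = NA_real_, sign_class = NA_character_,
                 excluded = TRUE, reason = res$reason,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = id, pair = names(res$delta),
                 kappa_baseline = unname(res$baseline),
                 kappa_endpoint = unname(res$kappa[, 1L]),
                 delta = unname(res$delta),
                 sign_class = ifelse(res$delta > 0, "strengthening",
                                     "weakening"),
                 excluded = FALSE, reason = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("intervention_effects", class(out))
  out
}

#' Knockout effects for a set of genes
#'
#' Applies [knockout_gene()] across genes and assembles the intervention
#' effect table (see [perturbation_effects()]).
#'
#' @param wnet a `weighted_network`.
#' @param pairs two-column character matrix of monitored pairs.
#' @param genes genes to knock out; default all nodes not in any pair.
#' @return data frame as in [perturbation_effects()].
#' @export
knockout_effects <- function(wnet, pairs, genes = NULL) {
  if (is.vector(pairs)) pairs <- matrix(pairs, ncol = 2L)
  if (is.null(genes)) genes <- setdiff(wnet$nodes, as.vector(pairs))
  rows <- lapply(genes, function(g) {
    res <- knockout_gene(wnet, g, pairs)
    data.frame(id = g, pair = names(res$baseline),
               kappa_baseline = unname(res$baseline),
               kappa_endpoint = unname(res$kappa_knockout),
               delta = unname(res$delta),
               sign_class = ifelse(is.na(res$delta), NA_character_,
                                   ifelse(res$delta > 0, "strengthening",
                                          "weakening")),
               excluded = res$excluded, reason = res$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("intervention_effects", class(out))
  out
}

#' Filter and rank intervention effects
#'
#' Keeps rows whose net curvature change exceeds the reporting cutoff in
#' absolute value and sorts them by decreasing |Delta|; ties are ordered
#' stably by row identifier. Excluded rows are dropped.
#'
#' @param table an intervention effect table.
#' @param cutoff minimal |Delta| worth reporting (default `1e-5`).
#' @return the filtered, sorted table.
#' @export
rank_effects <- function(table, cutoff = 1e-5) {
  keep <- !table$excluded & !is.na(table$delta) & abs(table$delta) > cutoff
  out <- table[keep, , drop = FALSE]
  out <- out[order(-abs(out$delta), out$id, out$pair), , drop = FALSE]
  rownames(out) <- NULL
  out
}
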