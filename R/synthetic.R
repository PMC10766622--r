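#' Two-community stochastic block model with planted bridges
#'
#' Generates a connected simple graph with dense blocks and explicit bridge
#' edges between them — the idealized topology on which bridges show negative
#' dynamic curvature while intra-community edges turn positive. Nodes are
#' labelled `N00, N01, ...` in block order. Generation retries until the
#' graph is connected.
#'
#' @param block_sizes integer vector of community sizes (default `c(17, 18)`,
#'   a 35-node two-community network).
#' @param p_in within-block edge probability (default 0.6).
#' @param p_out between-block edge probability (default 0; communities are
#'   joined only by the planted bridges).
#' @param bridges two-column matrix of 1-based node indices forced as
#'   inter-block edges; default one bridge from the first node of block 1 to
#'   the last node of block 2.
#' @param seed RNG seed (restored afterwards); `NULL` uses the current
#'   stream.
#' @param max_retries connectivity retry budget.
#' @return object of class `sbm_fixture`: `graph` (igraph), `blocks` (named
#'   integer membership), `bridges` (two-column character matrix).
#' @export
make_sbm <- function(block_sizes = c(17L, 18L), p_in = 0.6, p_out = 0,
                     bridges = NULL, seed = NULL, max_retries = 100L) {
  if (p_in < p_out) stop("p_in must be at least p_out")
  n <- sum(block_sizes)
  nodes <- sprintf(paste0("N%0", max(2L, nchar(n - 1L)), "d"), 0:(n - 1L))
  blocks <- rep(seq_along(block_sizes), block_sizes)
  names(blocks) <- nodes
  if (is.null(bridges)) bridges <- matrix(c(1L, n), ncol = 2L)
  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      pairs <- utils::combn(n, 2L)
      same <- blocks[pairs[1L, ]] == blocks[pairs[2L, ]]
      p <- ifelse(same, p_in, p_out)
      take <- stats::rbinom(ncol(pairs), 1L, p) == 1L
      el <- t(pairs[, take, drop = FALSE])
      el <- rbind(el, bridges)
      g <- igraph::graph_from_edgelist(
        matrix(nodes[el], ncol = 2L), directed = FALSE)
      g <- igraph::simplify(g)
      missing <- setdiff(nodes, igraph::V(g)$name)
      if (length(missing)) g <- igraph::add_vertices(g, length(missing),
                                                     name = missing)
      if (igraph::count_components(g) == 1L) {
        g <- igraph::set_graph_attr(g, "provenance", "synthetic SBM")
        return(structure(
          list(graph = g, blocks = blocks,
               bridges = matrix(nodes[as.matrix(bridges)], ncol = 2L)),
          class = "sbm_fixture"))
      }
    }
    stop("failed to generate a connected SBM within the retry budget")
  })
}

#' Synthetic multi-subtype expression matrix on a community graph
#'
#' Emulates the statistical structure the pipeline assumes in real cohorts:
#' each subtype elevates the mean expression of one community, and genes
#' within a community share a latent factor so that their pairwise Pearson
#' correlations concentrate near `rho_in` (near `rho_out` across
#' communities). Subtype `t` elevates community `((t - 1) mod C) + 1` by
#' `effect * (1 + (t - 1) %/% C)`, so every subtype has a distinct mean
#' profile even with fewer communities than subtypes. Values are floored to
#' stay strictly positive.
#'
#' @param net gene network whose nodes are the genes.
#' @param blocks named community membership of the nodes.
#' @param n_subtypes number of planted subtypes (default 4).
#' @param samples_per_subtype samples per subtype (default 10).
#' @param base_mean baseline mean expression on the normalized-log scale
#'   (default 5).
#' @param effect mean elevation of a subtype's community (default 2).
#' @param rho_in,rho_out target within-/between-community gene correlations
#'   (defaults 0.9 and 0).
#' @param noise_sd marginal standard deviation of expression noise
#'   (default 0.5).
#' @param floor positivity floor (default `1e-6`).
#' @param seed RNG seed (restored afterwards).
#' @return list with `expr` (genes x samples matrix), `labels` (named subtype
#'   labels) and `subtypes` (label levels).
#' @export
make_expression <- function(net, blocks, n_subtypes = 4L,
                            samples_per_subtype = 10L, base_mean = 5,
                            effect = 2, rho_in = 0.9, rho_out = 0,
                            noise_sd = 0.5, floor = 1e-6, seed = NULL) {
  if (rho_in < rho_out || rho_in > 1 || rho_out < 0)
    stop("need 0 <= rho_out <= rho_in <= 1")
  nodes <- igraph::V(net)$name
  blocks <- blocks[nodes]
  comms <- sort(unique(blocks))
  C <- length(comms)
  S <- n_subtypes * samples_per_subtype
  samples <- sprintf("S%02d", seq_len(S))
  subtype_of <- rep(seq_len(n_subtypes), each = samples_per_subtype)
  labels <- stats::setNames(paste0("T", subtype_of), samples)
  with_seed(seed, {
    expr <- matrix(0, length(nodes), S, dimnames = list(nodes, samples))
    for (s in seq_len(S)) {
      t <- subtype_of[s]
      elevated <- comms[((t - 1L) %% C) + 1L]
      magnitude <- effect * (1 + (t - 1L) %/% C)
      m <- base_mean + ifelse(blocks == elevated, magnitude, 0)
      h <- stats::rnorm(1L)                       # shared global factor
      f <- stats::rnorm(C)                        # per-community factors
      eps <- stats::rnorm(length(nodes))
      z <- sqrt(rho_out) * h + sqrt(rho_in - rho_out) * f[match(blocks, comms)] +
        sqrt(1 - rho_in) * eps
      expr[, s] <- pmax(m + noise_sd * z, floor)
    }
    list(expr = expr, labels = labels,
         subtypes = paste0("T", seq_len(n_subtypes)))
  })
}

#' Synthetic fixture presets
#'
#' `synth_fig1()` returns the idealized two-community 35-node SBM (one
#' planted bridge, unit interaction strengths) as a ready-made
#' `weighted_network` together with the block structure — the canonical
#' fixture on which the bridge attains negative dynamic curvature.
#' `synth_subtypes()` returns a 60-node community-structured interactome
#' (one community per subtype) with a planted multi-subtype expression
#' matrix for end-to-end clustering tests.
#'
#' @param seed RNG seed.
#' @param n_subtypes,samples_per_subtype see [make_expression()].
#' @return `synth_fig1`: list with `sbm`, `wnet`. `synth_subtypes`: list
#'   with `sbm`, `expr`, `labels`.
#' @export
synth_fig1 <- function(seed = 7L) {
  sbm <- make_sbm(seed = seed)
  wnet <- weighted_hop_distances(sbm$graph, uniform_strengths(sbm$graph))
  list(sbm = sbm, wnet = wnet)
}

#' @rdname synth_fig1
#' @export
synth_subtypes <- function(seed = 7L, n_subtypes = 4L,
                           samples_per_subtype = 10L) {
  sbm <- make_sbm(block_sizes = rep(15L, n_subtypes), p_in = 0.3,
                  p_out = 0.02,
                  bridges = matrix(c(1L, n_subtypes * 15L), ncol = 2L),
                  seed = seed)
  ex <- make_expression(sbm$graph, sbm$blocks, n_subtypes = n_subtypes,
                        samples_per_subtype = samples_per_subtype,
                        seed = seed + 1L)
  list(sbm = sbm, expr = ex$expr, labels = ex$labels)
}
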