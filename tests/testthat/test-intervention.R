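test_that("baseline curvature with strength measures matches oracle values", {
  tri <- unit_wnet(triangle_graph())
  expect_equal(unname(baseline_curvature(tri, c("A", "B"))), 0.5)
  p <- unit_wnet(path_graph3())
  expect_equal(unname(baseline_curvature(p, c("A", "B"))), 0)
})

test_that("perturbation grids follow the uniform discretization", {
  g <- perturbation_grid(1.0, epsilon = 1e-6, n = 6)
  expect_equal(g, c(1e-6, 0.2000008, 0.4000006, 0.6000004, 0.8000002, 1.0),
               tolerance = 1e-9)
  expect_equal(g[1], 1e-6)
  expect_equal(g[6], 1.0)
  expect_true(all(diff(g) > 0))
  expect_error(perturbation_grid(1e-7), "nothing to perturb")
})

test_that("the unperturbed grid endpoint reproduces baseline curvature", {
  set.seed(80)
  g <- rand_connected_graph(10, 0.4)
  wnet <- weighted_hop_distances(g, rand_strengths(g, 0.3, 0.95))
  el <- igraph::as_edgelist(g)
  nodes <- igraph::V(g)$name
  for (rep in 1:5) {
    e <- el[sample(nrow(el), 1), ]
    pair <- sample(nodes, 2)
    base <- baseline_curvature(wnet, matrix(pair, ncol = 2))
    res <- perturb_edge(wnet, e, matrix(pair, ncol = 2))
    if (res$excluded) next
    expect_lt(abs(res$kappa[, ncol(res$kappa)] - base), 1e-12)
    expect_equal(unname(res$delta), unname(res$kappa[, 1] - base))
  }
})

test_that("cut edges are excluded exactly, matching brute-force bridge finding", {
  # barbell: two triangles joined by one cut edge
  g <- named_graph(c("A", "B", "B", "C", "A", "C",
                     "D", "E", "E", "F", "D", "F",
                     "C", "D"))
  wnet <- unit_wnet(g)
  pairs <- matrix(c("A", "B"), ncol = 2)
  eff <- perturbation_effects(wnet, pairs)
  # brute force: an edge is a cut edge iff its removal disconnects the graph
  el <- igraph::as_edgelist(g)
  brute <- vapply(seq_len(nrow(el)), function(e) {
    igraph::count_components(igraph::delete_edges(g, e)) > 1
  }, logical(1))
  brute_keys <- curvnet:::edge_key(el[brute, 1], el[brute, 2])
  expect_setequal(unique(eff$id[eff$excluded]), brute_keys)
  expect_match(unique(eff$reason[eff$excluded]), "disconnects")
})

test_that("perturbing a remote edge leaves the monitored pair unchanged;
           incident edges reproduce a from-scratch rebuild", {
  # two triangles sharing node C; perturb one triangle edge, monitor the other
  g <- named_graph(c("A", "B", "B", "C", "A", "C",
                     "C", "D", "C", "E", "D", "E"))
  set.seed(81)
  s <- rand_strengths(g, 0.4, 0.9)
  wnet <- weighted_hop_distances(g, s)
  pairs <- matrix(c("D", "E"), ncol = 2)
  res <- perturb_edge(wnet, c("A", "B"), pairs)
  expect_false(res$excluded)
  # oracle: rebuild the graph with the perturbed strength from scratch
  sk <- curvnet:::edge_key(s$from, s$to)
  s2 <- s
  s2$strength[sk == "A|B"] <- res$grid[1]
  wn2 <- weighted_hop_distances(g, s2)
  oracle <- baseline_curvature(wn2, pairs)
  expect_equal(unname(res$kappa[, 1]), unname(oracle), tolerance = 1e-12)
})

test_that("knockout effects match the from-scratch recomputation oracle", {
  set.seed(82)
  checked_zero <- 0
  for (rep in 1:30) {
    g <- rand_connected_graph(10, 0.35)
    s <- rand_strengths(g, 0.2, 0.95)
    wnet <- weighted_hop_distances(g, s)
    nodes <- igraph::V(g)$name
    pair <- sample(nodes, 2)
    gene <- sample(setdiff(nodes, pair), 1)
    res <- knockout_gene(wnet, gene, matrix(pair, ncol = 2))
    oracle <- knockout_oracle(g, s, gene, pair)
    if (res$excluded[1]) {
      expect_true(is.na(oracle))
      next
    }
    expect_equal(unname(res$kappa_knockout[1]), oracle, tolerance = 1e-10)
    # locality: if the removed node touches neither measure support nor any
    # realizing shortest path, the effect is exactly zero
    supp <- unique(c(pair,
                     names(igraph::neighbors(g, pair[1])),
                     names(igraph::neighbors(g, pair[2]))))
    if (!gene %in% supp) {
      g2 <- igraph::delete_vertices(g, gene)
      el2 <- igraph::as_edgelist(g2)
      w2 <- wnet$weights[curvnet:::edge_key(el2[, 1], el2[, 2])]
      D2 <- igraph::distances(g2, weights = w2)
      if (max(abs(D2[supp, supp] - wnet$dist[supp, supp])) == 0) {
        expect_identical(unname(res$delta[1]), 0)
        checked_zero <- checked_zero + 1
      }
    }
  }
  expect_gte(checked_zero, 3) # the locality branch must actually be exercised
})

test_that("knocking out a gene of a monitored pair is refused; separation excluded", {
  p <- unit_wnet(path_graph3())
  expect_error(knockout_gene(p, "A", matrix(c("A", "C"), ncol = 2)),
               "monitored pair")
  res <- knockout_gene(p, "B", matrix(c("A", "C"), ncol = 2))
  expect_true(res$excluded[1])
  expect_match(res$reason[1], "separates")
  expect_true(is.na(res$delta[1]))
})

test_that("effect tables filter by cutoff and sort by |delta| with stable ties", {
  tab <- data.frame(id = c("E1", "E2", "E3", "E4", "E5"),
                    pair = "A|B",
                    kappa_baseline = 0.5,
                    kappa_endpoint = 0.5 + c(0.2, -0.1, 1e-7, 0.1, NA),
                    delta = c(0.2, -0.1, 1e-7, 0.1, NA),
                    sign_class = c("strengthening", "weakening",
                                   "strengthening", "strengthening", NA),
                    excluded = c(FALSE, FALSE, FALSE, FALSE, TRUE),
                    reason = "")
  out <- rank_effects(tab, cutoff = 1e-5)
  expect_equal(out$id, c("E1", "E2", "E4")) # |0.2| > |-0.1| = |0.1| tie by id
  expect_equal(out$delta, c(0.2, -0.1, 0.1))
  out <- rank_effects(tab, cutoff = 1)
  expect_equal(nrow(out), 0)
})
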