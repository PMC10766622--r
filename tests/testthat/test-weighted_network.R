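test_that("perfect linear relations give r = 1 with nothing removed", {
  x <- 1:10
  y <- 2 * x + 1
  res <- desensitized_correlation(x, y)
  expect_equal(res$r, 1)
  expect_length(res$removed, 0)
})

test_that("an injected co-outlier is removed and shrinks |r|", {
  set.seed(50)
  x <- rnorm(50)
  y <- rnorm(50)
  x[50] <- 10
  y[50] <- 10
  r_plain <- cor(x, y)
  res <- desensitized_correlation(x, y)
  expect_equal(res$removed, 50L)
  expect_lt(abs(res$r), abs(r_plain))
  # leave-one-out oracle: first removal is the most influential sample
  infl <- vapply(1:50, function(k) abs(cor(x[-k], y[-k]) - r_plain),
                 numeric(1))
  expect_equal(res$removed[1], which.max(infl))
})

test_that("infinite influence threshold reduces to plain Pearson", {
  set.seed(51)
  x <- rnorm(20); y <- rnorm(20)
  res <- desensitized_correlation(x, y, influence_threshold = Inf)
  expect_equal(res$r, cor(x, y))
  expect_length(res$removed, 0)
  expect_error(desensitized_correlation(rep(1, 10), rnorm(10)), "constant")
  expect_error(desensitized_correlation(1:3, 2:4), "at least 4")
})

test_that("interaction strengths are absolute correlations per edge", {
  tri <- triangle_graph()
  set.seed(52)
  base <- rnorm(8)
  expr <- rbind(A = base, B = -base, C = rnorm(8))
  colnames(expr) <- paste0("S", 1:8)
  s <- interaction_strengths(expr, tri, desensitize = FALSE)
  keys <- curvnet:::edge_key(s$from, s$to)
  expect_equal(s$strength[keys == "A|B"], 1) # |-1| = 1
  # hand-recomputation for the other edges
  expect_equal(s$strength[keys == "A|C"], abs(cor(expr["A", ], expr["C", ])))
  expect_equal(s$strength[keys == "B|C"], abs(cor(expr["B", ], expr["C", ])))
  expect_true(all(s$strength >= 1e-6 & s$strength <= 1))
  expect_error(interaction_strengths(expr[1:2, ], tri), "missing")
})

test_that("independent genes give near-zero floored strengths", {
  e <- named_graph(c("A", "B"))
  set.seed(53)
  expr <- rbind(A = rnorm(2000), B = rnorm(2000))
  colnames(expr) <- paste0("S", 1:2000)
  s <- interaction_strengths(expr, e, desensitize = FALSE)
  expect_lt(s$strength[1], 0.1)
  expect_gte(s$strength[1], 1e-6)
})

test_that("edge weights are reciprocal root strengths and distances are shortest", {
  tri <- triangle_graph()
  s <- uniform_strengths(tri)
  keys <- curvnet:::edge_key(s$from, s$to)
  s$strength[keys == "A|C"] <- 0.25
  s$strength[keys %in% c("A|B", "B|C")] <- 1
  wnet <- weighted_hop_distances(tri, s)
  expect_equal(unname(wnet$weights["A|C"]), 2) # 1/sqrt(0.25)
  expect_equal(wnet$dist["A", "C"], 2) # direct edge ties the two-step path

  # unit strengths reduce to hop distances
  set.seed(54)
  g <- rand_connected_graph(10, 0.3)
  wnet <- unit_wnet(g)
  expect_equal(wnet$dist, hop_distance_matrix(g) * 1.0, tolerance = 1e-12)
})

test_that("Dijkstra equals literal path enumeration on small graphs", {
  set.seed(55)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    g <- rand_connected_graph(n, 0.5)
    s <- rand_strengths(g)
    wnet <- weighted_hop_distances(g, s)
    nodes <- igraph::V(g)$name
    pr <- sample(nodes, 2)
    expect_equal(wnet$dist[pr[1], pr[2]],
                 bf_weighted_hop(g, s, pr[1], pr[2]), tolerance = 1e-12)
  }
})

test_that("weighted distances are symmetric, triangle-valid and monotone in strength", {
  set.seed(56)
  g <- rand_connected_graph(9, 0.4)
  s <- rand_strengths(g)
  wnet <- weighted_hop_distances(g, s)
  D <- wnet$dist
  expect_equal(D, t(D), tolerance = 1e-12)
  n <- nrow(D)
  for (a in 1:n) for (b in 1:n) for (c in 1:n) {
    expect_lte(D[a, b], D[a, c] + D[c, b] + 1e-10)
  }
  # per-edge distance never exceeds the direct edge weight
  expect_true(all(wnet$edge_dist <= wnet$weights + 1e-12))
  # raising one strength never increases any distance
  s2 <- s
  pick <- sample(nrow(s2), 1)
  s2$strength[pick] <- min(1, s2$strength[pick] * 2)
  D2 <- weighted_hop_distances(g, s2)$dist
  expect_true(all(D2 <= D + 1e-12))
})

test_that("subtype cohorts select the labelled samples", {
  set.seed(57)
  g <- triangle_graph()
  expr <- matrix(rnorm(30), 3, 10,
                 dimnames = list(c("A", "B", "C"), paste0("S", 1:10)))
  labels <- stats::setNames(rep(c("EWS", "OST"), each = 5), paste0("S", 1:10))
  wn <- build_weighted_network(expr, g, labels = labels, subtype = "EWS",
                               desensitize = FALSE)
  ref <- interaction_strengths(expr[, 1:5], g, desensitize = FALSE)
  expect_equal(unname(wn$strengths[curvnet:::edge_key(ref$from, ref$to)]),
               ref$strength, tolerance = 1e-12)
  expect_error(build_weighted_network(expr, g, labels = labels,
                                      subtype = "RMS"),
               "fewer than 4")
})

test_that("weighted networks round-trip through GraphML", {
  set.seed(58)
  g <- rand_connected_graph(8, 0.45)
  wnet <- weighted_hop_distances(g, rand_strengths(g))
  f <- withr::local_tempfile(fileext = ".graphml")
  write_weighted_network(wnet, f)
  wnet2 <- read_weighted_network(f)
  expect_setequal(names(wnet2$strengths), names(wnet$strengths))
  expect_equal(wnet2$strengths[names(wnet$strengths)], wnet$strengths,
               tolerance = 1e-12)
  expect_equal(wnet2$dist[wnet$nodes, wnet$nodes], wnet$dist,
               tolerance = 1e-12)
})
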