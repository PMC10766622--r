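# hand-built trajectory object for rule-level tests
fake_traj <- function(kappa, grid, d = NULL) {
  structure(list(edges = do.call(rbind, strsplit(rownames(kappa), "\\|")),
                 grid = grid, kappa = kappa,
                 d = if (is.null(d)) rep(1, nrow(kappa)) else d,
                 lambda2 = 1),
            class = "curvature_trajectory")
}

test_that("critical scale is the first grid point reaching the threshold", {
  kap <- rbind("A|B" = c(0, 0.5, 0.8),
               "B|C" = c(0, 0.75, 0.9),
               "C|D" = c(0, 0.1, 0.2))
  traj <- fake_traj(kap, grid = c(0, 1, 2))
  sc <- critical_scales(traj, 0.75)
  expect_equal(unname(sc$t_c["A|B"]), 2) # first crossing at the last point
  expect_equal(unname(sc$t_c["B|C"]), 1) # boundary inclusive (>= rule)
  expect_equal(unname(sc$t_c["C|D"]), 2) # never reached -> T
  expect_identical(unname(sc$reached), c(TRUE, TRUE, FALSE))
})

test_that("average critical curvature integrates a linear ramp to half its peak", {
  # grid contains the crossing scale exactly, so t_c = 0.8 and the
  # trapezoid rule is exact on a linear ramp: mean over [0, t_c] is 0.375
  grid <- seq(0, 1, length.out = 101)
  tc <- 0.8
  kap <- rbind("A|B" = 0.75 * grid / tc)
  traj <- fake_traj(kap, grid)
  sc <- critical_scales(traj, 0.75)
  expect_equal(unname(sc$t_c["A|B"]), 0.8)
  acc <- average_critical_curvature(traj, sc)
  expect_equal(unname(acc["A|B"]), 0.375, tolerance = 1e-12)

  # sub-threshold constant trajectory (jump at 0): averages over the full
  # grid and tends to the constant as the grid refines
  kap_const <- c(0, rep(0.5, 200))
  grid2 <- c(0, exp(seq(log(1e-6), log(1), length.out = 200)))
  traj2 <- fake_traj(rbind("A|B" = kap_const, "B|C" = c(0, rep(0.9, 200))),
                     grid2)
  sc2 <- critical_scales(traj2, 0.75)
  acc2 <- average_critical_curvature(traj2, sc2)
  expect_equal(unname(acc2["A|B"]), 0.5, tolerance = 0.01)

  # an edge never reaching the threshold is averaged over the full grid
  kap3 <- rbind("A|B" = c(0, 0.75, 0.9), "B|C" = c(0, 0.2, 0.4))
  traj3 <- fake_traj(kap3, c(0, 1, 2))
  sc3 <- critical_scales(traj3, 0.75)
  acc3 <- average_critical_curvature(traj3, sc3)
  expect_equal(unname(acc3["B|C"]), (0.1 + 0.3) / 2)
})

test_that("critical filter removes negative edges at the characteristic scale", {
  fx <- fig1_analysis()
  filt <- critical_filter(fx$fx$wnet, fx$scales)
  bkey <- curvnet:::edge_key(fx$fx$sbm$bridges[1, 1], fx$fx$sbm$bridges[1, 2])
  found <- curvnet:::edge_key(filt$bridges[, 1], filt$bridges[, 2])
  expect_true(bkey %in% found)
  # the two components are exactly the planted blocks
  expect_equal(max(filt$membership), 2)
  blocks <- fx$fx$sbm$blocks[names(filt$membership)]
  expect_equal(length(unique(paste(filt$membership, blocks))), 2)
})

test_that("a graph with all-positive curvature passes the filter unchanged", {
  kap <- rbind("A|B" = c(0, 0.8, 0.9), "B|C" = c(0, 0.8, 0.9),
               "A|C" = c(0, 0.8, 0.9))
  traj <- fake_traj(kap, c(0, 1, 2))
  sc <- critical_scales(traj, 0.75)
  filt <- critical_filter(triangle_graph(), sc)
  expect_equal(nrow(filt$bridges), 0)
  expect_equal(max(filt$membership), 1)
  expect_equal(igraph::ecount(filt$graph), 3)
})

test_that("persistence scores follow the pruning schedule on two bridged triangles", {
  g <- named_graph(c("A", "B", "B", "C", "A", "C",
                     "D", "E", "E", "F", "D", "F",
                     "C", "D"))
  acc <- c("A|B" = 0.6, "B|C" = 0.6, "A|C" = 0.6,
           "D|E" = 0.4, "E|F" = 0.4, "D|F" = 0.4,
           "C|D" = -0.1)
  pers <- persistence_scores(g, acc)
  R <- pers$R
  # bridge removed in the initial sweep: cross-triangle pairs never co-member
  expect_equal(R["A", "E"], 0L)
  # triangle ABC survives two counted iterations (after sweep, after 0.4 batch)
  expect_equal(R["A", "B"], 2L)
  expect_equal(R["D", "E"], 1L)
  # distance transform
  expect_equal(pers$D, max(R) - R)
  expect_true(all(diag(pers$D) == 0))
})

test_that("persistence rules handle single edges and uniform values", {
  e <- named_graph(c("A", "B"))
  pers <- persistence_scores(e, c("A|B" = 0.3))
  expect_equal(pers$R["A", "B"], 1L)
  pers <- persistence_scores(e, c("A|B" = -0.3))
  expect_equal(pers$R["A", "B"], 0L)

  # uniform positive values: all removed in one batch, off-diagonal uniform
  tri <- triangle_graph()
  pers <- persistence_scores(tri, c("A|B" = 0.5, "B|C" = 0.5, "A|C" = 0.5))
  off <- pers$R[upper.tri(pers$R)]
  expect_true(all(off == off[1]))
})

test_that("pruning is a filtration: co-membership never resumes", {
  set.seed(70)
  for (rep in 1:5) {
    g <- rand_connected_graph(12, 0.3)
    el <- igraph::as_edgelist(g)
    acc <- stats::setNames(runif(nrow(el), -0.2, 1),
                           curvnet:::edge_key(el[, 1], el[, 2]))
    vals <- acc
    # replay the schedule, tracking co-membership iteration by iteration
    active <- vals >= 0
    prev_same <- NULL
    repeat {
      gg <- igraph::subgraph_from_edges(g, which(active),
                                        delete.vertices = FALSE)
      mem <- igraph::components(gg)$membership
      same <- outer(mem, mem, "==")
      if (!is.null(prev_same)) expect_true(all(same <= prev_same))
      prev_same <- same
      if (!any(active)) break
      nxt <- min(vals[active])
      active[vals <= nxt] <- FALSE
    }
  }
})

test_that("on the planted-bridge fixture the bridge has minimal acc", {
  fx <- fig1_analysis()
  acc <- average_critical_curvature(fx$traj, fx$scales)
  bkey <- curvnet:::edge_key(fx$fx$sbm$bridges[1, 1], fx$fx$sbm$bridges[1, 2])
  expect_equal(names(which.min(acc)), bkey)
})

test_that("hierarchical-acc clusters block-structured distances correctly", {
  fx <- fig1_analysis()
  acc <- average_critical_curvature(fx$traj, fx$scales)
  pers <- persistence_scores(fx$fx$wnet, acc)
  hac <- hierarchical_acc(pers$D, n_clusters = 2)
  blocks <- fx$fx$sbm$blocks[names(hac$labels)]
  expect_equal(length(unique(paste(hac$labels, blocks))), 2)

  # identical rows merge first at height zero
  D <- matrix(c(0, 0, 3, 0, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hac <- hierarchical_acc(D)
  expect_equal(hac$tree$height[1], 0)
  expect_setequal(hac$tree$labels[-hac$tree$merge[1, ]], c("a", "b"))
})
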