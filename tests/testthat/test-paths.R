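test_that("graph construction mirrors the weight-matrix structure", {
  W <- matrix(c(NA, 1, NA,
                1, NA, 2,
                NA, 2, NA), 3, 3,
              dimnames = list(c("A:1", "A:2", "A:3"), c("A:1", "A:2", "A:3")))
  g <- build_graph(wm_from_weights(W))
  expect_equal(igraph::vcount(g$graph), 3)
  expect_equal(igraph::ecount(g$graph), 2)

  empty <- wm_from_weights(matrix(NA_real_, 3, 3,
                                  dimnames = list(c("A:1", "A:2", "A:3"),
                                                  c("A:1", "A:2", "A:3"))))
  ge <- build_graph(empty)
  expect_equal(igraph::ecount(ge$graph), 0)
  p <- suppressMessages(shortest_path(ge, "A:1", "A:3"))
  expect_false(p$reachable)
  expect_true(is.na(p$length))

  expect_error(build_graph(wm_from_weights(W), list(S4 = c("A:1", "B:9"))),
               "absent")
})

test_that("hand-built shortest paths, degenerate and single-edge cases", {
  nm <- c("A:1", "A:2", "A:3", "A:4")
  W <- matrix(NA_real_, 4, 4, dimnames = list(nm, nm))
  W["A:1", "A:2"] <- W["A:2", "A:1"] <- 1
  W["A:2", "A:3"] <- W["A:3", "A:2"] <- 1
  W["A:1", "A:3"] <- W["A:3", "A:1"] <- 3
  W["A:3", "A:4"] <- W["A:4", "A:3"] <- 1
  g <- build_graph(wm_from_weights(W))
  p <- shortest_path(g, "A:1", "A:4")
  expect_equal(p$nodes, c("A:1", "A:2", "A:3", "A:4"))
  expect_equal(p$length, 3)
  # cross-check against exhaustive enumeration
  bf <- bf_region_shortest(W, 1, 4)
  expect_equal(p$length, bf$length)

  # single edge
  W2 <- matrix(NA_real_, 2, 2, dimnames = list(c("A:1", "A:2"), c("A:1", "A:2")))
  W2[1, 2] <- W2[2, 1] <- 2.5
  p2 <- shortest_path(build_graph(wm_from_weights(W2)), "A:1", "A:2")
  expect_equal(p2$nodes, c("A:1", "A:2"))
  expect_equal(p2$length, 2.5)

  # overlapping source/target: zero-length path at the shared node
  p3 <- shortest_path(g, c("A:1", "A:2"), c("A:2", "A:4"))
  expect_equal(p3$nodes, "A:2")
  expect_equal(p3$length, 0)
})

test_that("tie-break prefers fewer hops then lexicographic order", {
  nm <- c("A:1", "A:2", "A:3", "A:4")
  W <- matrix(NA_real_, 4, 4, dimnames = list(nm, nm))
  # two equal-length routes 1->4: direct edge (2) and 1-2-4 (1+1); also 1-3-4 (1+1)
  W["A:1", "A:4"] <- W["A:4", "A:1"] <- 2
  W["A:1", "A:2"] <- W["A:2", "A:1"] <- 1
  W["A:2", "A:4"] <- W["A:4", "A:2"] <- 1
  W["A:1", "A:3"] <- W["A:3", "A:1"] <- 1
  W["A:3", "A:4"] <- W["A:4", "A:3"] <- 1
  p <- shortest_path(build_graph(wm_from_weights(W)), "A:1", "A:4")
  expect_equal(p$length, 2)
  expect_equal(p$nodes, c("A:1", "A:4"))      # fewest hops wins
  W["A:1", "A:4"] <- W["A:4", "A:1"] <- NA    # now two 2-hop ties
  p2 <- shortest_path(build_graph(wm_from_weights(W)), "A:1", "A:4")
  expect_equal(p2$nodes, c("A:1", "A:2", "A:4"))  # lexicographic tie-break
})

test_that("Dijkstra equals brute force on random small graphs", {
  set.seed(99)
  for (rep_ in 1:30) {
    n <- sample(4:8, 1)
    W <- random_weight_matrix(n, p_edge = 0.5)
    if (all(is.na(W))) next
    g <- build_graph(wm_from_weights(W))
    s <- sample(n, 1); t <- sample(setdiff(seq_len(n), s), 1)
    bf <- bf_region_shortest(W, s, t)
    p <- suppressMessages(shortest_path(g, rownames(W)[s], rownames(W)[t]))
    if (!p$reachable) {
      expect_identical(bf$length, Inf)
    } else {
      expect_equal(p$length, bf$length, tolerance = 1e-9)
    }
  }
})

test_that("per-subunit d_min: symmetry across duplicated subunits, scaling", {
  nm <- c("A:1", "A:2", "A:3")
  W1 <- matrix(NA_real_, 3, 3, dimnames = list(nm, nm))
  W1["A:1", "A:2"] <- W1["A:2", "A:1"] <- 0.7
  W1["A:2", "A:3"] <- W1["A:3", "A:2"] <- 0.4
  # replicate the same subunit graph on four chains
  chains <- c("A", "B", "C", "D")
  big_nm <- as.vector(vapply(chains, function(ch) sub("A", ch, nm), character(3)))
  W <- matrix(NA_real_, 12, 12, dimnames = list(big_nm, big_nm))
  for (k in seq_along(chains)) {
    idx <- (k - 1) * 3 + 1:3
    W[idx, idx] <- W1
  }
  src <- residue_region("S4", paste0(chains, ":1"))
  tgt <- residue_region("SF", paste0(chains, ":3"))
  g <- build_graph(wm_from_weights(W), list(S4 = src, SF = tgt))
  d <- minimal_path_length(g, "S4", "SF")
  expect_equal(nrow(d), 4)
  expect_true(all(abs(d$d_min - 1.1) < 1e-12))

  # scaling all weights by k scales d_min by k, path unchanged
  gk <- build_graph(wm_from_weights(W * 3), list(S4 = src, SF = tgt))
  dk <- minimal_path_length(gk, "S4", "SF")
  expect_equal(dk$d_min, d$d_min * 3, tolerance = 1e-12)
  expect_equal(dk$path, d$path)

  # mean-over-pairs aggregation lies at or above the minimum
  dm <- minimal_path_length(g, "S4", "SF", aggregate = "mean")
  expect_true(all(dm$d_min >= d$d_min - 1e-12))
})

test_that("triangle property holds for region-to-region distances", {
  set.seed(123)
  for (rep_ in 1:15) {
    W <- random_weight_matrix(7, p_edge = 0.7)
    g <- build_graph(wm_from_weights(W))
    nm <- rownames(W)
    a <- nm[1]; b <- nm[3]; c_ <- nm[5]
    d_ab <- suppressMessages(shortest_path(g, a, b))
    d_bc <- suppressMessages(shortest_path(g, b, c_))
    d_ac <- suppressMessages(shortest_path(g, a, c_))
    if (d_ab$reachable && d_bc$reachable && d_ac$reachable) {
      expect_lte(d_ac$length, d_ab$length + d_bc$length + 1e-9)
    }
  }
})

test_that("betweenness: path graph, star hub, isolated node, brute force", {
  nm <- paste0("A:", 1:5)
  W <- matrix(NA_real_, 5, 5, dimnames = list(nm, nm))
  for (i in 1:4) W[i, i + 1] <- W[i + 1, i] <- 1
  g <- build_graph(wm_from_weights(W))
  bc <- betweenness_profile(g, normalized = FALSE)
  expect_equal(bc$bc, c(0, 3, 4, 3, 0))

  # star: normalized hub betweenness is exactly 1
  nms <- paste0("A:", 1:6)
  Ws <- matrix(NA_real_, 6, 6, dimnames = list(nms, nms))
  Ws[1, 2:6] <- Ws[2:6, 1] <- 1
  bs <- betweenness_profile(build_graph(wm_from_weights(Ws)))
  expect_equal(bs$bc_norm[1], 1)
  expect_true(all(bs$bc[-1] == 0))

  # isolated node
  Wi <- matrix(NA_real_, 3, 3, dimnames = list(paste0("A:", 1:3), paste0("A:", 1:3)))
  Wi[1, 2] <- Wi[2, 1] <- 1
  bi <- betweenness_profile(build_graph(wm_from_weights(Wi)))
  expect_equal(bi$bc[3], 0)

  # weighted brute force on random graphs
  set.seed(77)
  for (rep_ in 1:20) {
    n <- sample(4:8, 1)
    W <- random_weight_matrix(n, p_edge = 0.6)
    if (all(is.na(W))) next
    got <- betweenness_profile(build_graph(wm_from_weights(W)),
                               normalized = FALSE)$bc
    expect_equal(got, bf_betweenness(W), tolerance = 1e-9)
  }
})

test_that("path comparison: identity, single-edge perturbation, oracle", {
  set.seed(5)
  W <- random_weight_matrix(6, p_edge = 0.9)
  nm <- rownames(W)
  regs <- list(S4 = nm[1], SF = nm[6])
  wt <- build_graph(wm_from_weights(W), regs)
  mut_same <- build_graph(wm_from_weights(W), regs)
  cmp0 <- compare_paths(wt, mut_same, "S4", "SF")
  expect_equal(attr(cmp0, "delta_mean"), 0)

  # raise every edge on the optimal path: d_min cannot decrease
  p <- shortest_path(wt, "S4", "SF")
  W2 <- W
  for (k in seq_len(length(p$nodes) - 1)) {
    i <- p$nodes[k]; j <- p$nodes[k + 1]
    W2[i, j] <- W2[j, i] <- W2[i, j] + 1.5
  }
  mut <- build_graph(wm_from_weights(W2), regs)
  cmp <- compare_paths(wt, mut, "S4", "SF")
  expect_gt(attr(cmp, "delta_mean"), 0)
  # oracle equality for the mutant graph
  bf <- bf_region_shortest(W2, 1, 6)
  expect_equal(cmp$d_min_mut, bf$length, tolerance = 1e-9)
})

test_that("correlation arm matches the closed-form oracle", {
  xs <- c(1, 2, 3, 4, 5)
  r1 <- correlate_metric_vs_energy(xs, 2 * xs + 1)
  expect_equal(r1$r, 1)
  expect_equal(r1$slope, 2)
  expect_equal(r1$intercept, 1)
  expect_equal(r1$n, 5)
  expect_equal(correlate_metric_vs_energy(xs, -xs)$r, -1)

  hand_x <- c(0.12, 0.55, 0.31, 0.87, 0.44, 0.68, 0.95, 0.23)
  hand_y <- c(-2.1, -0.4, -1.6, 1.3, -1.0, 0.2, 1.9, -1.8)
  got <- correlate_metric_vs_energy(hand_x, hand_y)
  expect_equal(got$r, pearson_closed_form(hand_x, hand_y), tolerance = 1e-12)

  expect_error(correlate_metric_vs_energy(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(correlate_metric_vs_energy(1:2, 1:2), "at least 3")
})
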