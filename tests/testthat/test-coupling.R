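test_that("contact map: constant geometry, two-level mix, brute-force oracle", {
  d5 <- array(5, c(2, 2, 10)); for (f in 1:10) diag(d5[, , f]) <- 0
  cm <- compute_contact_map(d5, c = 7)
  expect_true(all(cm$C == 1))

  # half the frames at 5 A (inside), half at 10 A (kernel 1e-5)
  dmix <- array(5, c(2, 2, 10))
  dmix[1, 2, 6:10] <- dmix[2, 1, 6:10] <- 10
  for (f in 1:10) diag(dmix[, , f]) <- 0
  sig <- solve_kernel_width(7, 10, 1e-5)
  cm2 <- compute_contact_map(dmix, c = 7, sigma = sig)
  expect_equal(cm2$C[1, 2], (1 + 1e-5) / 2, tolerance = 1e-12)

  # oracle: frame-by-frame kernel average on random distances
  set.seed(8)
  n <- 5; nf <- 17
  darr <- array(runif(n * n * nf, 2, 14), c(n, n, nf))
  for (f in seq_len(nf)) {
    darr[, , f] <- (darr[, , f] + t(darr[, , f])) / 2
    diag(darr[, , f]) <- 0
  }
  cm3 <- compute_contact_map(darr, c = 7, sigma = sig)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    manual <- mean(vapply(seq_len(nf), function(f) {
      d <- darr[i, j, f]
      if (d <= 7) 1 else exp(-(d^2 - 49) / (2 * sig^2))
    }, numeric(1)))
    expect_equal(cm3$C[i, j], manual, tolerance = 1e-12)
  }
  expect_identical(cm3$C, t(cm3$C))
  expect_true(all(diag(cm3$C) == 1))
})

test_that("contact map from strided frames converges to the full-frame value", {
  s <- chain_plant_spec(n_residues = 12, chain_indices = 1:5, n_frames = 1024,
                        seed = 4)
  traj <- generate_chain_trajectory(s)
  full <- compute_contact_map(traj)$C
  err <- vapply(c(16, 4, 2), function(k) {
    max(abs(compute_contact_map(traj_stride(traj, k))$C - full))
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(err[2], err[1])
})

test_that("mutual information: identity, independence, perfect dependence", {
  set.seed(2)
  x <- rnorm(200)
  m_id <- estimate_mutual_information(cbind(a = x, b = x), n_bins = 10)
  expect_equal(m_id$M_norm[1, 2], 1, tolerance = 1e-12)
  expect_equal(diag(m_id$M_norm), c(a = 1, b = 1))

  # exactly uniform 2x2 joint counts: independent, M = 0
  di <- rep(c(0, 0, 1, 1), 25)
  dj <- rep(c(0, 1, 0, 1), 25)
  m_ind <- estimate_mutual_information(cbind(a = di, b = dj), n_bins = 2)
  expect_equal(m_ind$M[1, 2], 0, tolerance = 1e-12)
  expect_equal(m_ind$M_norm[1, 2], 0, tolerance = 1e-12)

  # counts {(0,0): 50, (1,1): 50}: M' = 1 in any base
  dp <- rep(c(0, 1), 50)
  for (base in c("e", "2")) {
    m_dep <- estimate_mutual_information(cbind(a = dp, b = dp), n_bins = 2,
                                         log_base = base)
    expect_equal(m_dep$M_norm[1, 2], 1, tolerance = 1e-12)
  }
  # constant series: zero entropy handled as M' = 0 with a warning
  expect_warning(
    m_c <- estimate_mutual_information(cbind(a = rep(1, 50), b = rnorm(50))),
    "constant"
  )
  expect_equal(m_c$M_norm[1, 2], 0)
})

test_that("MI of independent series shrinks as frames grow", {
  sizes <- c(500, 1500, 5000)
  med <- matrix(NA_real_, 20, 3)
  for (sd_ in 1:20) {
    set.seed(sd_)
    big <- matrix(rnorm(5000 * 8), 5000, 8,
                  dimnames = list(NULL, paste0("r", 1:8)))
    for (k in seq_along(sizes)) {
      mi <- estimate_mutual_information(big[seq_len(sizes[k]), ])
      med[sd_, k] <- median(mi$M_norm[upper.tri(mi$M_norm)])
    }
  }
  agg <- colMeans(med)
  expect_true(all(diff(agg) < 0))
  expect_gt(mean(med[, 1] > med[, 3]), 0.95)
})

test_that("weights combine contacts and MI with the -log rule", {
  C <- matrix(c(1, 1, 1, 1), 2, 2)
  Mn <- matrix(c(1, 1, 1, 1), 2, 2)
  w <- build_weight_matrix(C, Mn)
  expect_equal(w$W[1, 2], 0)

  C2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  M2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  w2 <- build_weight_matrix(C2, M2)
  expect_equal(w2$W[1, 2], -log(0.25), tolerance = 1e-12)
  expect_equal(round(w2$W[1, 2], 3), 1.386)
  # base 2 rescales the magnitude only
  w2b <- build_weight_matrix(C2, M2, log_base = "2")
  expect_equal(w2b$W[1, 2], -log2(0.25), tolerance = 1e-12)

  # floor rule drops the pair entirely
  C3 <- matrix(c(1, 1e-7, 1e-7, 1), 2, 2)
  M3 <- matrix(c(1, 1e-7, 1e-7, 1), 2, 2)
  w3 <- build_weight_matrix(C3, M3, floor_eps = 1e-12)
  expect_false(w3$edge_mask[1, 2])
  expect_true(is.na(w3$W[1, 2]))
  expect_equal(nrow(as_tibble(w3)), 0)

  expect_error(build_weight_matrix(-C2, M2), "non-negative")
  expect_error(build_weight_matrix(C2 * 3, M2), "exceed")
})

test_that("pipeline matrices are exactly symmetric with bounded entries", {
  s <- chain_plant_spec(n_residues = 15, chain_indices = 1:5, n_frames = 300,
                        seed = 13)
  traj <- superpose_frames(generate_chain_trajectory(s))
  cm <- compute_contact_map(traj)
  mi <- estimate_mutual_information(compute_displacements(traj))
  expect_identical(cm$C, t(cm$C))
  expect_identical(mi$M_norm, t(mi$M_norm))
  expect_true(all(cm$C >= 0 & cm$C <= 1))
  expect_true(all(mi$M_norm >= 0 & mi$M_norm <= 1))
  w <- build_weight_matrix(cm, mi)
  expect_true(all(w$W[w$edge_mask] >= 0))
})

test_that("block formula: hand-set blocks, periodic fixture, oracle equality", {
  # two blocks with weights 1 and 3: sqrt(1/(2*1) * ((1-2)^2 + (3-2)^2)) = 1
  expect_identical(block_sd(c(1, 3)), 1)
  expect_equal(block_sd(c(2, 2, 2, 2)), 0)
  expect_error(block_sd(3), "2 blocks")

  set.seed(31)
  for (i in 1:25) {
    w <- rnorm(sample(2:8, 1), mean = 2)
    expect_equal(block_sd(w), bf_block_sd(w), tolerance = 1e-12)
  }

  # periodic trajectory: identical blocks give sigma = 0 everywhere
  s <- chain_plant_spec(n_residues = 8, chain_indices = 1:3, n_frames = 100,
                        seed = 6)
  traj <- generate_chain_trajectory(s)
  per_ca <- traj$ca[rep(1:100, 3), , , drop = FALSE]
  per_sc <- traj$sc[rep(1:100, 3), , , drop = FALSE]
  per <- trajectory_ensemble(traj$residues, per_ca, per_sc)
  bs <- block_weight_std(per, block_length = 100)
  expect_equal(bs$n_blocks, 3)
  expect_lt(max(abs(bs$sigma_w[!is.na(bs$sigma_w)])), 1e-10)

  # block weights feed the printed formula verbatim
  s2 <- chain_plant_spec(n_residues = 8, chain_indices = 1:3, n_frames = 400,
                         seed = 7)
  t2 <- superpose_frames(generate_chain_trajectory(s2))
  bs2 <- block_weight_std(t2, block_length = 100)
  i <- 1; j <- 2
  expect_equal(bs2$sigma_w[i, j], bf_block_sd(bs2$block_weights[i, j, ]),
               tolerance = 1e-12)
  expect_error(block_weight_std(t2, block_length = 500), "longer")
})
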