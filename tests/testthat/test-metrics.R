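test_that("excitability is the mean absolute activity", {
  expect_identical(excitability(c(0, 0, 0)), 0)
  expect_identical(excitability(c(1, -1)), 1)
  expect_equal(excitability(c(0.2, -0.4, 0.6)), 0.4)
})

test_that("distance correlation hits its affine anchors", {
  x <- as.numeric(1:12)
  expect_equal(distance_correlation(x, x), 1, tolerance = 1e-12)
  expect_equal(signed_distance_correlation(x, x), 1, tolerance = 1e-12)
  expect_equal(distance_correlation(x, -3 * x), 1, tolerance = 1e-12)
  expect_equal(signed_distance_correlation(x, -3 * x), -1, tolerance = 1e-12)
  expect_error(distance_correlation(x, rep(1, 12)), "constant")
})

test_that("distance correlation of independent pairs is small", {
  small <- vapply(1:50, function(s) {
    xy <- hmgm:::with_seed(s, matrix(rnorm(2000), 1000, 2))
    distance_correlation(xy[, 1], xy[, 2]) < 0.1
  }, logical(1))
  expect_gte(mean(small), 0.95)
})

test_that("distance correlation is invariant to shift and positive scaling", {
  xy <- hmgm:::with_seed(3, matrix(rnorm(120), 60, 2))
  base <- distance_correlation(xy[, 1], xy[, 2])
  expect_equal(distance_correlation(3 * xy[, 1] + 7, xy[, 2]), base,
               tolerance = 1e-10)
  expect_equal(distance_correlation(xy[, 1], 0.2 * xy[, 2] - 5), base,
               tolerance = 1e-10)
})

test_that("pairwise state similarity is symmetric with unit diagonal", {
  gt <- make_ground_truth(4, 10, sink_mass = NULL, block_sizes = c(5, 5),
                          seed = 7, shuffle_blocks = TRUE)
  sg <- state_graphs(ground_truth_as_fitted(gt))
  dup <- sg
  dup[[2]] <- dup[[1]]
  M <- pairwise_state_similarity(dup, mode = "connectivity")
  expect_equal(M[1, 2], 1, tolerance = 1e-12)
  M2 <- pairwise_state_similarity(sg, mode = "activity")
  expect_equal(M2, t(M2))
  expect_equal(unname(diag(M2)), rep(1, 4))
})

test_that("states sharing a block layout are more similar than reshuffled ones", {
  # two states with identical block assignment vs two with shuffled blocks
  gt_same <- make_ground_truth(2, 12, sink_mass = NULL, block_sizes = c(6, 6),
                               seed = 8, shuffle_blocks = FALSE)
  gt_diff <- make_ground_truth(2, 12, sink_mass = NULL, block_sizes = c(6, 6),
                               seed = 9, shuffle_blocks = TRUE)
  sim_same <- pairwise_state_similarity(state_graphs(ground_truth_as_fitted(gt_same)),
                                        mode = "connectivity")[1, 2]
  sim_diff <- pairwise_state_similarity(state_graphs(ground_truth_as_fitted(gt_diff)),
                                        mode = "connectivity")[1, 2]
  expect_gt(sim_same - sim_diff, 0.2)
})

test_that("global efficiency matches hand-enumerated graphs", {
  expect_equal(global_efficiency(matrix(1, 4, 4) - diag(4)), 1)
  P3 <- matrix(0, 3, 3)
  P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1
  expect_equal(global_efficiency(P3), (1 + 0.5 + 1) / 3, tolerance = 1e-12)
  expect_identical(global_efficiency(matrix(0, 3, 3)), 0)
})

test_that("efficiency never increases when edges are removed", {
  W <- hmgm:::with_seed(11, {
    M <- matrix(runif(64, 0.2, 1), 8, 8)
    hmgm:::zero_diag((M + t(M)) / 2)
  })
  e_full <- global_efficiency(W)
  for (s in 1:5) {
    Wsub <- hmgm:::with_seed(s, {
      drop <- which(upper.tri(W), arr.ind = TRUE)
      kill <- drop[sample(nrow(drop), 10), , drop = FALSE]
      M <- W
      M[kill] <- 0
      M[kill[, 2:1, drop = FALSE]] <- 0
      M
    })
    expect_lte(global_efficiency(Wsub), e_full + 1e-12)
  }
})

test_that("permutation-normalized efficiency is exactly 1 for equal weights", {
  Wc <- 0.4 * (matrix(1, 6, 6) - diag(6))
  expect_equal(normalized_global_efficiency(Wc, n_permutations = 20, seed = 1), 1,
               tolerance = 1e-12)
})

test_that("a weight-shuffled random graph normalizes to about 1", {
  W <- hmgm:::with_seed(13, {
    M <- matrix(0, 10, 10)
    ut <- upper.tri(M)
    w <- runif(sum(ut))
    w[runif(sum(ut)) < 0.5] <- 0
    M[ut] <- sample(w)
    M + t(M)
  })
  e_obs <- global_efficiency(W)
  null_vals <- vapply(1:100, function(b) {
    Wp <- hmgm:::with_seed(500 + b, {
      M <- matrix(0, 10, 10)
      M[upper.tri(M)] <- sample(W[upper.tri(W)])
      M + t(M)
    })
    global_efficiency(Wp)
  }, numeric(1))
  se <- sd(null_vals)
  expect_lt(abs(e_obs - mean(null_vals)), 2 * se + 1e-12)
  expect_error(normalized_global_efficiency(matrix(0, 4, 4), 10, 1), "undefined")
})

test_that("robust local efficiency matches closed forms and a direct summation", {
  K4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(local_efficiency_robust(K4, 1), 1)
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_identical(local_efficiency_robust(star, 1), 0)
  expect_identical(local_efficiency_robust(star, 2), 0)  # degree 1
  W <- hmgm:::with_seed(17, {
    M <- matrix(runif(49, 0, 1), 7, 7)
    M[M < 0.3] <- 0
    hmgm:::zero_diag((M + t(M)) / 2)
  })
  for (v in 1:7) {
    expect_equal(local_efficiency_robust(W, v), brute_local_efficiency(W, v),
                 tolerance = 1e-12)
  }
})

test_that("degree centrality is the strength vector", {
  K4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(unname(degree_centrality(K4)), rep(3, 4))
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 2
  expect_equal(unname(degree_centrality(W)), c(2, 2, 0, 0))
  Wr <- hmgm:::with_seed(19, {
    M <- matrix(runif(36), 6, 6)
    hmgm:::zero_diag((M + t(M)) / 2)
  })
  expect_equal(degree_centrality(Wr), colSums(hmgm:::zero_diag(Wr)),
               tolerance = 1e-12)
})

test_that("single-layer consensus detects planted cliques and uniform graphs", {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
  out <- single_layer_modularity_partition(W, resolution_grid = 1,
                                           n_runs = 8, seed = 3)
  expect_equal(ami(out$labels, rep(c(1, 2), each = 4)), 1)
  expect_equal(out$Q, 0.5, tolerance = 1e-12)
  flat <- single_layer_modularity_partition(matrix(1, 6, 6) - diag(6),
                                            resolution_grid = c(0.8, 1),
                                            n_runs = 6, seed = 4)
  expect_identical(length(unique(flat$labels)), 1L)
})
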