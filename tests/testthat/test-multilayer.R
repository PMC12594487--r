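test_that("HMGM layers are absolute correlations with TP-derived coupling", {
  P <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  model <- structure(list(
    K = 2L, means = matrix(0, 3, 2), covariances = list(diag(3), diag(3)),
    transition_matrix = P, initial_distribution = stationary_distribution(P),
    loglik_trace = NA_real_, n_reinit = 0L, map = NULL, ridge = 0,
    roi_means = matrix(0, 3, 2),
    roi_covariances = list(diag(3),
                           matrix(c(1, -0.8, 0, -0.8, 1, 0, 0, 0, 1), 3, 3))),
    class = "fitted_state_model")
  h <- build_hmgm(model, coupling_scale = 1)
  expect_equal(h$A[[1]], matrix(0, 3, 3))            # identity cov: no edges
  expect_equal(h$A[[2]][1, 2], 0.8)                  # |corr|
  expect_equal(h$omega[1, 2], 0.3)                   # (0.1 + 0.5) / 2
  expect_equal(h$omega, t(h$omega))
  expect_equal(unname(diag(h$omega)), rep(0, 2))
  h2 <- rescale_coupling(h, 2)
  expect_equal(h2$omega[1, 2], 0.6)
})

test_that("a perfectly correlated ROI pair gets weight one", {
  S <- matrix(c(2, 2, 2, 2), 2, 2)  # rank-1, correlation 1
  model <- structure(list(
    K = 2L, means = matrix(0, 2, 2), covariances = list(diag(2), diag(2)),
    transition_matrix = matrix(0.5, 2, 2), initial_distribution = c(0.5, 0.5),
    loglik_trace = NA_real_, n_reinit = 0L, map = NULL, ridge = 0,
    roi_means = matrix(0, 2, 2), roi_covariances = list(S, diag(2))),
    class = "fitted_state_model")
  h <- build_hmgm(model)
  expect_equal(h$A[[1]][1, 2], 1)
})

test_that("single-layer modularity matches the Newman-Girvan closed form", {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
  h <- one_layer_hmgm(W)
  expect_equal(multilayer_modularity(h, rep(c(1, 2), each = 3), gamma = 1), 0.5,
               tolerance = 1e-12)
  expect_equal(multilayer_modularity(h, rep(1, 6), gamma = 1), 0,
               tolerance = 1e-12)
})

test_that("the modularity kernel agrees with a brute-force double loop", {
  for (s in 1:25) {
    D <- sample(2:5, 1)
    K <- sample(1:2, 1)
    hg <- random_toy_hmgm(D, K, seed = 1000 + s)
    labels <- hmgm:::with_seed(s, sample(1:3, D * K, replace = TRUE))
    gamma <- hmgm:::with_seed(200 + s, runif(1, 0.5, 1.5))
    expect_lt(abs(unname(multilayer_modularity(hg, labels, gamma)) -
                    brute_modularity(hg, labels, gamma)), 1e-12)
  }
})

test_that("generalized Louvain recovers a planted two-community bilayer", {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
  om <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  hg <- structure(list(A = list(W, W), omega_base = om, omega = om,
                       coupling_scale = 1, pi = c(0.5, 0.5), D = 6, K = 2L),
                  class = "hmgm")
  planted <- rep(rep(c(1, 2), each = 3), 2)
  for (s in 1:10) {
    p <- genlouvain_optimize(hg, gamma = 1, seed = s)
    expect_equal(ami(as.vector(p$labels), planted), 1)
  }
})

test_that("Louvain is deterministic per seed and never beats exhaustive search", {
  for (s in 1:8) {
    hg <- random_toy_hmgm(4, 2, seed = 300 + s)   # 8 node-layers
    p1 <- genlouvain_optimize(hg, gamma = 1, seed = s)
    p2 <- genlouvain_optimize(hg, gamma = 1, seed = s)
    expect_identical(p1$labels, p2$labels)
    opt <- exhaustive_modularity_optimum(hg, gamma = 1)
    expect_lte(p1$Q, opt + 1e-9)
  }
})

test_that("very large resolution isolates node-layers up to coupling", {
  hg <- random_toy_hmgm(5, 2, seed = 77)
  p <- genlouvain_optimize(hg, gamma = 1000, seed = 1)
  for (s in 1:2) {
    layer_labels <- p$labels[, s]
    expect_identical(length(unique(layer_labels)), 5L)  # no intralayer merges
  }
})

test_that("consensus terminates immediately when all runs agree", {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
  h <- one_layer_hmgm(W)
  cons <- consensus_communities(h, resolution_grid = 1, coupling_grid = 0,
                                n_runs = 8, seed = 2)
  expect_identical(cons$n_iterations, 1L)
  expect_true(cons$converged)
  expect_equal(ami(as.vector(cons$partition$labels), rep(c(1, 2), each = 3)), 1)
  C <- cons$coclassification
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 6))
  expect_true(all(C >= 0 & C <= 1))
})

test_that("consensus recovers planted spatiotemporal communities", {
  for (s in 1:5) {
    gt <- make_ground_truth(3, 12, sink_mass = 0.4, block_sizes = c(6, 6),
                            seed = child_seed(s, "cons"))
    h <- build_hmgm(ground_truth_as_fitted(gt))
    cons <- consensus_communities(h, n_runs = 10, seed = s)
    expect_gte(ami(as.vector(cons$partition$labels),
                   as.vector(gt$planted_labels)), 0.9)
  }
})

test_that("zero coupling reduces the multilayer result to per-layer consensus", {
  gt <- make_ground_truth(3, 10, sink_mass = NULL, block_sizes = c(5, 5), seed = 5)
  h <- build_hmgm(ground_truth_as_fitted(gt))
  cons <- consensus_communities(h, resolution_grid = c(0.9, 1, 1.1),
                                coupling_grid = 0, n_runs = 10, seed = 9)
  for (s in 1:3) {
    solo <- single_layer_modularity_partition(h$A[[s]],
                                              resolution_grid = c(0.9, 1, 1.1),
                                              n_runs = 10, seed = 9)
    expect_equal(ami(cons$partition$labels[, s], solo$labels), 1)
  }
})

test_that("consensus modularity does not fall below the mean run modularity", {
  gt <- make_ground_truth(3, 10, sink_mass = 0.4, block_sizes = c(5, 5), seed = 6)
  h <- build_hmgm(ground_truth_as_fitted(gt))
  gmid <- 1
  cons <- consensus_communities(h, resolution_grid = c(0.9, 1, 1.1),
                                coupling_grid = 1, n_runs = 10, seed = 10)
  run_q <- vapply(1:10, function(r) {
    genlouvain_optimize(h, gamma = gmid, seed = child_seed(10, paste0("q", r)))$Q
  }, numeric(1))
  q_cons <- multilayer_modularity(h, cons$partition, gamma = gmid)
  expect_gte(q_cons, mean(run_q) - 1e-9)
})

test_that("fractional membership is the stationary-weighted indicator sum", {
  labels <- cbind(c(1L, 1L, 2L), c(2L, 1L, 2L))
  part <- structure(list(labels = labels, Q = NA, gamma = 1,
                         coupling_scale = 1, seed = 1), class = "st_partition")
  F_mat <- fractional_membership(part, c(0.75, 0.25))
  expect_equal(unname(F_mat[1, ]), c(0.75, 0.25))
  expect_equal(unname(F_mat[2, ]), c(1, 0))     # same community in every state
  expect_equal(unname(rowSums(F_mat)), rep(1, 3), tolerance = 1e-12)
})

test_that("layer clustering uses pair Jaccard with Ward linkage", {
  labels <- cbind(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L))
  part <- structure(list(labels = labels, Q = NA, gamma = 1,
                         coupling_scale = 1, seed = 1), class = "st_partition")
  out <- cluster_layers(part, k_cut = 2)
  expect_equal(out$similarity[1, 2], 1)
  expect_equal(out$similarity[1, 3], 0)          # no co-clustered pair shared
  expect_identical(out$clusters[[1]], out$clusters[[2]])
  expect_false(out$clusters[[1]] == out$clusters[[3]])
  merge1 <- out$tree$merge[1, ]
  expect_setequal(abs(merge1), c(1, 2))
  reg <- cluster_regions(part, k_cut = 2)
  expect_equal(dim(reg$similarity), c(4L, 4L))
})

test_that("static planted communities give higher membership maxima than reshuffled ones", {
  gt_static <- make_ground_truth(4, 12, sink_mass = 0.4, block_sizes = c(6, 6),
                                 seed = 21, shuffle_blocks = FALSE)
  gt_shuffle <- make_ground_truth(4, 12, sink_mass = NULL, block_sizes = c(6, 6),
                                  seed = 22, shuffle_blocks = TRUE)
  f_static <- {
    h <- build_hmgm(ground_truth_as_fitted(gt_static))
    cons <- consensus_communities(h, n_runs = 10, seed = 23)
    fractional_membership(cons$partition, h$pi)
  }
  f_shuffle <- {
    h <- build_hmgm(ground_truth_as_fitted(gt_shuffle))
    cons <- consensus_communities(h, n_runs = 10, seed = 24)
    fractional_membership(cons$partition, h$pi)
  }
  expect_gt(mean(apply(f_static, 1, max)), mean(apply(f_shuffle, 1, max)))
})
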