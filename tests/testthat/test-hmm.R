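# Fit/decode checks run in the generator's native ROI space (no PCA) at small
# D so the oracle comparison is direct.

sim_reduced <- function(gt, N, T_len, seed, obs_noise = 0.2) {
  sc <- simulate_cohort(gt, N = N, T_len = T_len, seed = seed,
                        obs_noise = obs_noise)
  std <- standardize_concatenate(sc$cohort)
  list(data = std$data, boundaries = std$boundaries, std = std, sc = sc)
}

test_that("EM recovers a well-separated planted model", {
  gt <- make_ground_truth(3, 8, sink_mass = 0.4, block_sizes = c(4, 4),
                          separation = 4, seed = 21)
  sim <- sim_reduced(gt, N = 4, T_len = 200, seed = 22)
  m <- fit_hmm(sim$data, sim$boundaries, K = 3, n_restarts = 3, seed = 23,
               tol = 1e-6, max_iter = 200)
  # match states by mean distance (standardized truth vs fitted means)
  mu_z <- (gt$means - sim$std$center) / sim$std$scale
  cost <- outer(seq_len(3), seq_len(3), Vectorize(function(i, j) {
    sum((m$means[, i] - mu_z[, j])^2)
  }))
  perm <- match_states(cost)
  P_hat <- m$transition_matrix
  P_true <- gt$transition_matrix[perm, perm]
  expect_lt(max(abs(P_hat - P_true)), 0.05)
  cosines <- vapply(seq_len(3), function(i) {
    sum(m$means[, i] * mu_z[, perm[i]]) /
      sqrt(sum(m$means[, i]^2) * sum(mu_z[, perm[i]]^2))
  }, numeric(1))
  expect_gte(mean(cosines), 0.95)
})

test_that("fitting K = 2 to single-state data degenerates gracefully", {
  gt <- make_ground_truth(2, 6, sink_mass = NULL, block_sizes = c(3, 3), seed = 31)
  gt$transition_matrix <- diag(2)
  gt$initial_distribution <- c(1, 0)    # all data from state 1
  sim <- sim_reduced(gt, N = 3, T_len = 100, seed = 32)
  m <- fit_hmm(sim$data, sim$boundaries, K = 2, n_restarts = 2, seed = 33)
  dec <- decode_subjects(m, sim$data, sim$boundaries)
  occ <- colMeans(dec$fo)
  # either one state absorbs the data, or the two states are heavily
  # overlapping copies (Mahalanobis separation well below the >= 3 sd gap
  # that genuinely distinct states carry in this suite)
  dm <- m$means[, 1] - m$means[, 2]
  pooled <- (m$covariances[[1]] + m$covariances[[2]]) / 2
  maha <- sqrt(sum(dm * solve(pooled, dm)))
  expect_true(max(occ) >= 0.95 || maha < 2)
})

test_that("the log-likelihood trace is non-decreasing", {
  gt <- make_ground_truth(3, 6, sink_mass = 0.4, block_sizes = c(3, 3), seed = 41)
  sim <- sim_reduced(gt, N = 3, T_len = 120, seed = 42)
  m <- fit_hmm(sim$data, sim$boundaries, K = 3, n_restarts = 2, seed = 43)
  expect_true(all(diff(m$loglik_trace) > -1e-8 * pmax(1, abs(m$loglik_trace[-1]))))
})

test_that("near-deterministic emissions give exact paths and one-hot posteriors", {
  gt <- make_ground_truth(2, 6, sink_mass = NULL, block_sizes = c(3, 3),
                          separation = 12, seed = 51)
  sc <- simulate_cohort(gt, N = 2, T_len = 80, seed = 52, obs_noise = 0.01,
                        emission_scale = 0.01)
  std <- standardize_concatenate(sc$cohort)
  m <- fit_hmm(std$data, std$boundaries, K = 2, n_restarts = 2, seed = 53)
  dec <- decode_subjects(m, std$data, std$boundaries)
  # align fitted state 1/2 with truth via the first subject's majority match
  truth <- sc$state_paths[[1]]
  fit_path <- dec$viterbi[[1]]
  flip <- mean(fit_path == truth) < 0.5
  acc <- vapply(seq_along(dec$viterbi), function(i) {
    p <- dec$viterbi[[i]]
    if (flip) p <- 3L - p
    mean(p == sc$state_paths[[i]])
  }, numeric(1))
  expect_true(all(acc == 1))
  expect_gt(min(apply(dec$posteriors[[1]], 1, max)), 0.999)
})

test_that("with identical emissions the FO reduces to the stationary distribution", {
  P <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  pi0 <- stationary_distribution(P)
  model <- structure(list(
    K = 2L, means = matrix(0, 3, 2),
    covariances = list(diag(3), diag(3)),
    transition_matrix = P, initial_distribution = pi0,
    loglik_trace = NA_real_, n_reinit = 0L, map = NULL, ridge = 0),
    class = "fitted_state_model")
  X <- hmgm:::with_seed(61, matrix(rnorm(400 * 3), 400, 3))
  b <- data.frame(subject = "S01", start = 1L, end = 400L)
  dec <- decode_subjects(model, X, b)
  expect_equal(unname(dec$fo[1, ]), pi0, tolerance = 1e-8)
  expect_lt(max(abs(rowSums(dec$posteriors[[1]]) - 1)), 1e-10)
})

test_that("decoding respects subject boundaries", {
  gt <- make_ground_truth(3, 6, sink_mass = 0.4, block_sizes = c(3, 3), seed = 71)
  sim <- sim_reduced(gt, N = 2, T_len = 60, seed = 72)
  m <- fit_hmm(sim$data, sim$boundaries, K = 3, n_restarts = 2, seed = 73)
  dec_joint <- decode_subjects(m, sim$data, sim$boundaries)
  for (i in 1:2) {
    rows <- sim$boundaries$start[i]:sim$boundaries$end[i]
    b1 <- data.frame(subject = sim$boundaries$subject[i],
                     start = 1L, end = length(rows))
    dec_solo <- decode_subjects(m, sim$data[rows, , drop = FALSE], b1)
    expect_equal(dec_solo$posteriors[[1]], dec_joint$posteriors[[i]],
                 tolerance = 1e-12)
    expect_identical(dec_solo$viterbi[[1]], dec_joint$viterbi[[i]])
  }
})

test_that("transition recovery improves with recording length", {
  rmse <- function(T_len, seed) {
    gt <- make_ground_truth(3, 6, sink_mass = 0.4, block_sizes = c(3, 3),
                            separation = 4, seed = seed)
    sim <- sim_reduced(gt, N = 1, T_len = T_len, seed = seed + 500)
    m <- fit_hmm(sim$data, sim$boundaries, K = 3, n_restarts = 2,
                 seed = seed + 900)
    mu_z <- (gt$means - sim$std$center) / sim$std$scale
    cost <- outer(seq_len(3), seq_len(3), Vectorize(function(i, j) {
      sum((m$means[, i] - mu_z[, j])^2)
    }))
    perm <- match_states(cost)
    sqrt(mean((m$transition_matrix - gt$transition_matrix[perm, perm])^2))
  }
  seeds <- 1:10
  short <- vapply(seeds, function(s) rmse(200, s), numeric(1))
  long <- vapply(seeds, function(s) rmse(1000, s), numeric(1))
  expect_lte(mean(long), mean(short))
})

test_that("model size is chosen by maximum occupancy entropy with ties to smaller K", {
  expect_identical(choose_model_size(c(3, 4, 5), c(1.2, 1.5, 1.4)), 4L)
  expect_identical(choose_model_size(c(4, 6), c(1.3, 1.3)), 4L)
  expect_identical(choose_model_size(5, 0.7), 5L)
})

test_that("selection explores candidates and returns coherent diagnostics", {
  gt <- make_ground_truth(3, 6, sink_mass = NULL, block_sizes = c(3, 3),
                          separation = 4, seed = 81)
  sim <- sim_reduced(gt, N = 3, T_len = 100, seed = 82)
  cfg <- run_config(candidate_K_range = 2:4, n_restarts = 2, seed = 83)
  sel <- select_model_size(sim$data, sim$boundaries, config = cfg)
  expect_identical(sel$diagnostics$K, 2:4)
  expect_true(all(sel$diagnostics$occupancy_entropy >= 0))
  expect_true(sel$chosen_K %in% 2:4)
  expect_identical(sel$chosen_K,
                   choose_model_size(sel$diagnostics$K,
                                     sel$diagnostics$occupancy_entropy))
})

test_that("states below the subject-expression threshold are pruned", {
  # hand-built model and decode: state 3 visited by 2 of 13 subjects (15.4%)
  P <- rbind(c(0.6, 0.3, 0.1), c(0.3, 0.6, 0.1), c(0.2, 0.2, 0.6))
  model <- structure(list(
    K = 3L, means = matrix(c(-2, 0, 2), 1, 3),
    covariances = replicate(3, matrix(0.2), simplify = FALSE),
    transition_matrix = P, initial_distribution = rep(1 / 3, 3),
    loglik_trace = NA_real_, n_reinit = 0L, map = NULL, ridge = 1e-6),
    class = "fitted_state_model")
  paths <- c(replicate(11, rep(c(1L, 2L), 10), simplify = FALSE),
             replicate(2, rep(c(1L, 2L, 3L), length.out = 20), simplify = FALSE))
  data <- matrix(unlist(lapply(paths, function(p) model$means[1, p])), ncol = 1) +
    hmgm:::with_seed(91, rnorm(13 * 20, sd = 0.05))
  boundaries <- data.frame(subject = sprintf("S%02d", 1:13),
                           start = seq(1, by = 20, length.out = 13),
                           end = seq(20, by = 20, length.out = 13))
  dec <- decode_subjects(model, data, boundaries)
  visited3 <- vapply(dec$viterbi, function(p) any(p == 3L), logical(1))
  expect_identical(sum(visited3), 2L)
  pr <- prune_states(model, dec, pruning_fraction = 0.20,
                     data = data, boundaries = boundaries)
  expect_identical(pr$model$K, 2L)
  expect_identical(pr$kept, 1:2)
  expect_equal(unname(pr$model$transition_matrix[1, ]), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  expect_lt(max(abs(rowSums(pr$model$transition_matrix) - 1)), 1e-12)
  expect_identical(ncol(pr$decode$fo), 2L)
})

test_that("pruning leaves a fully expressed model unchanged", {
  gt <- make_ground_truth(2, 6, sink_mass = NULL, block_sizes = c(3, 3),
                          separation = 4, seed = 95)
  sim <- sim_reduced(gt, N = 4, T_len = 80, seed = 96)
  m <- fit_hmm(sim$data, sim$boundaries, K = 2, n_restarts = 2, seed = 97)
  dec <- decode_subjects(m, sim$data, sim$boundaries)
  pr <- prune_states(m, dec, 0.2, sim$data, sim$boundaries)
  expect_identical(pr$model$K, m$K)
  expect_identical(pr$model$transition_matrix, m$transition_matrix)
  expect_lt(max(abs(rowSums(pr$model$transition_matrix) - 1)), 1e-12)
})
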