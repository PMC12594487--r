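# Synthetic cohort generator. Emulates the statistical structure the analysis
# assumes: hidden Gaussian states over D ROIs, a planted dominant sink state
# for the anaesthesia-like condition, block (community) structured state
# covariances, and a structural connectome whose blocks can be aligned with,
# or shuffled against, the functional blocks.

stationary_eigen <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

# Constant-correlation block covariance: unit variances, `within` inside each
# block, `between` elsewhere. PSD by construction (min eigenvalue >= 1 - within).
block_covariance <- function(assignment, within, between) {
  D <- length(assignment)
  same <- outer(assignment, assignment, "==")
  C <- matrix(between, D, D)
  C[same] <- within
  diag(C) <- 1
  C
}

#' Plant a ground-truth hidden Markov model
#'
#' Builds the generative model the cohort simulator draws from: `K_true`
#' Gaussian states in ROI space with block-structured covariances (planted
#' spatiotemporal communities), well-separated means, and a row-stochastic
#' transition matrix. When `sink_mass` is given, the transition matrix is
#' constructed so that its exact stationary distribution places that mass on
#' the sink state: the sink row keeps a high self-transition (`sink_self`)
#' and every other row sends the incoming probability `a = (1 - sink_self) *
#' m / (1 - m)` to the sink, which balances the stationary flow exactly; the
#' construction is verified against the eigen-solution. Without `sink_mass`
#' the matrix is symmetric and the stationary distribution uniform.
#'
#' @param K_true Number of states (>= 2).
#' @param D Number of ROIs; must equal `sum(block_sizes)`.
#' @param sink_mass Target stationary probability of the sink state
#'   (0 < sink_mass < 1), or `NULL` for a uniform-stationary model.
#' @param block_sizes Integer sizes of the planted covariance blocks.
#' @param separation Scale of the state means (means are orthonormal
#'   directions times `separation`; emission standard deviations are 1, so
#'   `separation` is in sd units).
#' @param seed Integer seed.
#' @param within_cor,between_cor Within/between-block correlations of each
#'   state covariance (defaults 0.6 and 0.15, a 4x contrast).
#' @param sink_self Sink self-transition probability (default 0.9).
#' @param shuffle_blocks If `TRUE`, the ROI-to-block assignment is reshuffled
#'   independently in every state ("wake-like" reorganizing communities);
#'   if `FALSE` the planted communities are static across states
#'   ("anaesthesia-like").
#' @param sink_index Index of the sink state (default 1).
#' @return A `ground_truth_model`: means (D x K), covariances (list of
#'   D x D), transition matrix, initial (= stationary) distribution, planted
#'   community label for every (ROI, state), and sink metadata.
#' @export
make_ground_truth <- function(K_true, D, sink_mass = NULL, block_sizes,
                              separation = 3, seed = 1,
                              within_cor = 0.6, between_cor = 0.15,
                              sink_self = 0.9, shuffle_blocks = FALSE,
                              sink_index = 1L) {
  stopifnot(K_true >= 2, sum(block_sizes) == D, separation >= 0,
            within_cor > between_cor, between_cor >= 0)
  if (within_cor < 3 * between_cor) {
    stop("within-block correlation must be at least 3x the between-block value",
         call. = FALSE)
  }
  if (!is.null(sink_mass)) stopifnot(sink_mass > 0, sink_mass < 1)

  base_assign <- rep(seq_along(block_sizes), block_sizes)
  with_seed(seed, {
    # Means: scaled orthonormal directions, pairwise distance separation*sqrt(2).
    G <- matrix(rnorm(D * K_true), D, K_true)
    means <- qr.Q(qr(G))[, seq_len(K_true), drop = FALSE] * separation

    assignments <- lapply(seq_len(K_true), function(s) {
      if (shuffle_blocks) sample(base_assign) else base_assign
    })
    covariances <- lapply(assignments, block_covariance,
                          within = within_cor, between = between_cor)

    K <- K_true
    if (is.null(sink_mass)) {
      self <- 0.6
      P <- matrix((1 - self) / (K - 1), K, K)
      diag(P) <- self
    } else {
      m <- sink_mass
      a <- (1 - sink_self) * m / (1 - m)  # incoming mass balancing pi_sink = m
      if (a >= 1) {
        stop(sprintf("sink_mass %.3f infeasible for sink_self %.2f", m, sink_self),
             call. = FALSE)
      }
      nonsink_self <- min(0.3, 1 - a)
      spread <- 1 - a - nonsink_self
      P <- matrix(0, K, K)
      for (i in seq_len(K)) {
        if (i == sink_index) {
          P[i, ] <- (1 - sink_self) / (K - 1)
          P[i, i] <- sink_self
        } else {
          others <- setdiff(seq_len(K), c(i, sink_index))
          P[i, sink_index] <- a
          P[i, i] <- nonsink_self
          if (length(others)) P[i, others] <- spread / length(others)
          else P[i, i] <- P[i, i] + spread
        }
      }
    }
  })
  stopifnot(max(abs(rowSums(P) - 1)) < 1e-12)
  pi0 <- stationary_eigen(P)
  if (!is.null(sink_mass) && abs(pi0[sink_index] - sink_mass) > 0.02) {
    stop(sprintf("planted stationary mass %.4f misses target %.4f",
                 pi0[sink_index], sink_mass), call. = FALSE)
  }
  planted_labels <- do.call(cbind, assignments)  # D x K
  structure(list(
    K_true = as.integer(K_true), D = as.integer(D),
    means = means, covariances = covariances,
    transition_matrix = P, initial_distribution = pi0,
    planted_labels = planted_labels,
    block_sizes = as.integer(block_sizes),
    sink_index = if (is.null(sink_mass)) NULL else as.integer(sink_index),
    sink_mass = sink_mass,
    separation = separation, shuffle_blocks = shuffle_blocks,
    seed = as.integer(seed)), class = "ground_truth_model")
}

#' Sample hidden state paths from a Markov chain
#'
#' Vectorized across chains: `n` independent paths of length `T` from
#' `(initial_distribution, P)`.
#'
#' @param P Row-stochastic transition matrix.
#' @param initial Initial distribution.
#' @param n Number of chains.
#' @param T_len Path length.
#' @param seed Integer seed.
#' @return Integer matrix `n x T_len` of state indices.
#' @export
sample_state_paths <- function(P, initial, n, T_len, seed) {
  stopifnot(T_len >= 1, n >= 1)
  K <- nrow(P)
  CS <- t(apply(P, 1, cumsum))
  ci <- cumsum(initial)
  with_seed(seed, {
    s <- matrix(0L, n, T_len)
    s[, 1] <- findInterval(runif(n), ci) + 1L
    s[s[, 1] > K, 1] <- K  # guard numerical cumsum overflow
    if (T_len >= 2) {
      for (t in 2:T_len) {
        u <- runif(n)
        s[, t] <- as.integer(rowSums(u > CS[s[, t - 1], , drop = FALSE]) + 1L)
      }
    }
    s
  })
}

#' Simulate a synthetic multi-subject cohort
#'
#' Per subject, a hidden chain is sampled from the planted transition model
#' and emissions are drawn from the active state's Gaussian plus isotropic
#' observation noise.
#'
#' @param model A [make_ground_truth()] model.
#' @param N Number of subjects.
#' @param T_len Volumes per subject.
#' @param tr Sampling interval (seconds, default 3).
#' @param obs_noise Isotropic noise standard deviation added to emissions.
#' @param seed Integer seed.
#' @param condition Condition tag stored in the cohort.
#' @param emission_scale Multiplier on the state-covariance draw (default 1;
#'   0 gives noiseless emissions equal to the state mean plus `obs_noise`).
#' @return A `synthetic_cohort`: `$cohort` ([roi_cohort()]) and
#'   `$state_paths` (list of true state sequences per subject).
#' @export
simulate_cohort <- function(model, N, T_len, tr = 3, obs_noise = 0.5, seed = 1,
                            condition = "synthetic", emission_scale = 1) {
  stopifnot(inherits(model, "ground_truth_model"), N >= 1, T_len >= 1)
  D <- model$D
  paths <- sample_state_paths(model$transition_matrix, model$initial_distribution,
                              n = N, T_len = T_len,
                              seed = child_seed(seed, "paths"))
  chols <- lapply(model$covariances, chol)
  series <- vector("list", N)
  with_seed(child_seed(seed, "emissions"), {
    for (i in seq_len(N)) {
      X <- matrix(0, D, T_len)
      s <- paths[i, ]
      for (k in seq_len(model$K_true)) {
        idx <- which(s == k)
        if (!length(idx)) next
        Z <- matrix(rnorm(D * length(idx)), length(idx), D)
        X[, idx] <- emission_scale * t(Z %*% chols[[k]]) + model$means[, k]
      }
      if (obs_noise > 0) X <- X + obs_noise * matrix(rnorm(D * T_len), D, T_len)
      series[[i]] <- X
    }
  })
  names(series) <- sprintf("S%02d", seq_len(N))
  cohort <- roi_cohort(series, sprintf("ROI_%02d", seq_len(D)),
                       tr_seconds = tr, condition = condition)
  structure(list(cohort = cohort,
                 state_paths = setNames(lapply(seq_len(N), function(i) paths[i, ]),
                                        cohort$subjects),
                 model = model),
            class = "synthetic_cohort")
}

#' Generate a weighted structural connectome with planted blocks
#'
#' Weighted stochastic-block-model adjacency: within-block weights are drawn
#' from U(0.5, 1), between-block weights from `noise` * U(0, 0.5), then the
#' matrix is symmetrized with a zero diagonal. With `align_with` supplied,
#' the blocks coincide with the model's (static) covariance blocks.
#'
#' @param block_sizes Integer block sizes.
#' @param align_with Optional [make_ground_truth()] model whose base block
#'   assignment the connectome should share.
#' @param noise Between-block weight scale in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `adjacency` (D x D symmetric, zero diagonal) and
#'   `partition` (planted block label per ROI).
#' @export
make_structural_connectome <- function(block_sizes, align_with = NULL,
                                       noise = 0.1, seed = 1) {
  if (!is.null(align_with)) {
    assignment <- align_with$planted_labels[, 1]
    D <- align_with$D
  } else {
    assignment <- rep(seq_along(block_sizes), block_sizes)
    D <- sum(block_sizes)
  }
  stopifnot(length(assignment) == D)
  with_seed(seed, {
    same <- outer(assignment, assignment, "==")
    W <- matrix(0, D, D)
    ut <- upper.tri(W)
    n_ut <- sum(ut)
    w_in <- runif(n_ut, 0.5, 1)
    w_out <- noise * runif(n_ut, 0, 0.5)
    W[ut] <- ifelse(same[ut], w_in, w_out)
    W <- W + t(W)
  })
  rn <- sprintf("ROI_%02d", seq_len(D))
  dimnames(W) <- list(rn, rn)
  list(adjacency = W, partition = as.integer(assignment))
}
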