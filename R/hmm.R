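# Gaussian hidden Markov model fitting (Baum-Welch EM with restarts),
# decoding (forward-backward posteriors, Viterbi), model-size selection by
# maximum occupancy entropy, and pruning of weakly expressed states.
#
# All recursions run per subject segment, so no transition is ever counted
# across a subject boundary, and all likelihood arithmetic is scaled
# (Rabiner-style) so long recordings cannot underflow.

# Per-state Gaussian log densities for every row of X (T x d) -> T x K.
emission_logdens <- function(X, means, chols) {
  K <- ncol(means)
  d <- ncol(X)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    R <- chols[[k]]
    logdet <- 2 * sum(log(diag(R)))
    Y <- backsolve(R, t(X) - means[, k], transpose = TRUE)
    out[, k] <- -0.5 * (d * log(2 * pi) + logdet + colSums(Y^2))
  }
  out
}

# Scaled forward-backward on one segment. logB: T x K emission log densities.
forward_backward <- function(logB, P, pi0, want_xi = TRUE) {
  T_len <- nrow(logB)
  K <- ncol(logB)
  M <- apply(logB, 1, max)
  B <- exp(logB - M)
  alpha <- matrix(0, T_len, K)
  cvec <- numeric(T_len)
  a <- pi0 * B[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  if (T_len > 1) {
    for (t in 2:T_len) {
      a <- as.vector(alpha[t - 1, ] %*% P) * B[t, ]
      cvec[t] <- sum(a)
      alpha[t, ] <- a / cvec[t]
    }
  }
  beta <- matrix(0, T_len, K)
  beta[T_len, ] <- 1
  xi <- if (want_xi) matrix(0, K, K) else NULL
  if (T_len > 1) {
    for (t in (T_len - 1):1) {
      bb <- B[t + 1, ] * beta[t + 1, ]
      beta[t, ] <- as.vector(P %*% bb) / cvec[t + 1]
      if (want_xi) {
        xi <- xi + (alpha[t, ] %o% bb) * P / cvec[t + 1]
      }
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, xi = xi, loglik = sum(log(cvec)) + sum(M))
}

# Log-space Viterbi on one segment.
viterbi_path <- function(logB, P, pi0) {
  T_len <- nrow(logB)
  K <- ncol(logB)
  logP <- log(pmax(P, .Machine$double.xmin))
  delta <- log(pmax(pi0, .Machine$double.xmin)) + logB[1, ]
  psi <- matrix(0L, T_len, K)
  if (T_len > 1) {
    for (t in 2:T_len) {
      cand <- delta + logP                      # K x K: from i (row) to j (col)
      psi[t, ] <- max.col(t(cand), ties.method = "first")
      delta <- cand[cbind(psi[t, ], seq_len(K))] + logB[t, ]
    }
  }
  path <- integer(T_len)
  path[T_len] <- which.max(delta)
  if (T_len > 1) {
    for (t in (T_len - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  }
  path
}

segment_rows <- function(boundaries) {
  lapply(seq_len(nrow(boundaries)), function(i) boundaries$start[i]:boundaries$end[i])
}

init_hmm_params <- function(X, K, seed) {
  with_seed(seed, {
    km <- tryCatch(kmeans(X, centers = K, nstart = 3, iter.max = 50),
                   error = function(e) NULL)
    means <- if (is.null(km)) t(X[sample(nrow(X), K), , drop = FALSE]) else t(km$centers)
    means <- means + matrix(rnorm(length(means), sd = 0.01), nrow(means))
    S <- cov(X) + diag(1e-4, ncol(X))
    covariances <- replicate(K, S, simplify = FALSE)
    P <- matrix(0.2 / (K - 1), K, K)
    diag(P) <- 0.8
    list(means = means, covariances = covariances, P = P,
         pi0 = stationary_eigen(P))
  })
}

#' Fit a Gaussian hidden Markov model to a multi-subject concatenation
#'
#' Maximum-likelihood Baum-Welch EM with `n_restarts` seeded initializations
#' (k-means means, pooled covariance, sticky transitions); the restart with
#' the best final log likelihood is returned. Forward-backward recursions are
#' restarted at every subject boundary. Covariances carry a small diagonal
#' ridge so they stay positive definite at small T; a state whose total
#' responsibility mass collapses is reinitialized from a random observation
#' and the event is counted in `$n_reinit`.
#'
#' @param data Time x d reduced data matrix (concatenated subjects).
#' @param boundaries Subject boundary data frame from
#'   [standardize_concatenate()].
#' @param K Number of states (>= 2).
#' @param n_restarts EM restarts (default 5).
#' @param tol Convergence: stop when the log-likelihood gain of an iteration
#'   falls below `tol * max(1, |loglik|)`.
#' @param max_iter Maximum EM iterations per restart.
#' @param seed Integer seed (restart r uses `child_seed(seed, "restart<r>")`).
#' @param map Optional `reduction_map`; when given, per-state ROI-space means
#'   and covariances are attached via [project_state_to_roi()].
#' @param prior_strength Optional nonnegative pseudo-count added to every
#'   transition cell in the M-step (MAP shrinkage emulating a variational
#'   prior); default 0 = plain maximum likelihood.
#' @param ridge Diagonal covariance regularizer (default 1e-6).
#' @return A `fitted_state_model`: `K`, `means` (d x K), `covariances`,
#'   row-stochastic `transition_matrix`, `initial_distribution`,
#'   `loglik_trace` of the winning restart, and (if `map` given) `roi_means`
#'   (D x K) and `roi_covariances`.
#' @export
fit_hmm <- function(data, boundaries, K, n_restarts = 5, tol = 1e-4,
                    max_iter = 100, seed = 1, map = NULL, prior_strength = 0,
                    ridge = 1e-6) {
  stopifnot(K >= 2, nrow(data) >= 10 * K)
  segs <- segment_rows(boundaries)
  d <- ncol(data)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    par <- init_hmm_params(data, K, child_seed(seed, paste0("restart", r)))
    trace <- numeric(0)
    n_reinit <- 0L
    reinit_seed <- child_seed(seed, paste0("reinit", r))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      chols <- lapply(par$covariances, function(S) chol(S + diag(ridge, d)))
      logB <- emission_logdens(data, par$means, chols)
      Xi <- matrix(0, K, K)
      Gamma <- matrix(0, nrow(data), K)
      start_gamma <- matrix(0, length(segs), K)
      ll <- 0
      for (si in seq_along(segs)) {
        rows <- segs[[si]]
        fb <- forward_backward(logB[rows, , drop = FALSE], par$P, par$pi0)
        Gamma[rows, ] <- fb$gamma
        Xi <- Xi + fb$xi
        start_gamma[si, ] <- fb$gamma[1, ]
        ll <- ll + fb$loglik
      }
      trace <- c(trace, ll)
      # M-step; states whose responsibility mass collapses are reinitialized
      # from a random observation while the live states update as usual.
      Nk <- colSums(Gamma)
      dead <- which(Nk < 1)
      par$pi0 <- colMeans(start_gamma)
      par$pi0 <- par$pi0 / sum(par$pi0)
      Pnew <- Xi + prior_strength + 1e-10
      par$P <- Pnew / rowSums(Pnew)
      for (k in setdiff(seq_len(K), dead)) {
        par$means[, k] <- crossprod(Gamma[, k], data) / Nk[k]
        Xc <- sweep(data, 2, par$means[, k])
        S <- crossprod(Xc * Gamma[, k], Xc) / Nk[k]
        par$covariances[[k]] <- (S + t(S)) / 2 + diag(ridge, d)
      }
      if (length(dead)) {
        n_reinit <- n_reinit + length(dead)
        hmgm_log("reinitializing ", length(dead), " degenerate state(s)",
                 level = "warn")
        with_seed(reinit_seed + it, {
          for (k in dead) {
            par$means[, k] <- data[sample(nrow(data), 1), ] + rnorm(d, sd = 0.1)
            par$covariances[[k]] <- cov(data) + diag(1e-4, d)
          }
        })
        next
      }
      if (it > 1) {
        gain <- trace[it] - trace[it - 1]
        if (gain < tol * max(1, abs(trace[it]))) {
          converged <- TRUE
          break
        }
      }
    }
    if (!converged && n_reinit == 0L) {
      hmgm_log("EM did not converge in ", max_iter, " iterations; best iterate kept",
               level = "warn")
    }
    cand <- list(par = par, trace = trace, n_reinit = n_reinit)
    if (is.null(best) || tail(trace, 1) > tail(best$trace, 1)) best <- cand
  }
  par <- best$par
  model <- structure(list(
    K = as.integer(K), means = par$means, covariances = par$covariances,
    transition_matrix = par$P, initial_distribution = par$pi0,
    loglik_trace = best$trace, n_reinit = best$n_reinit,
    map = map, ridge = ridge), class = "fitted_state_model")
  if (!is.null(map)) model <- attach_roi_projection(model, map)
  model
}

# Project every state's parameters into ROI space through the reduction map.
attach_roi_projection <- function(model, map) {
  proj <- lapply(seq_len(model$K), function(k) {
    project_state_to_roi(model$means[, k], model$covariances[[k]], map)
  })
  model$map <- map
  model$roi_means <- vapply(proj, `[[`, numeric(length(map$center)), "mean")
  model$roi_covariances <- lapply(proj, `[[`, "covariance")
  model
}

#' @export
print.fitted_state_model <- function(x, ...) {
  cat(sprintf("<fitted_state_model> K=%d d=%d loglik=%.2f iters=%d\n",
              x$K, nrow(x$means), tail(x$loglik_trace, 1),
              length(x$loglik_trace)))
  invisible(x)
}

#' Decode per-subject state probabilities and best paths
#'
#' Forward-backward posteriors, Viterbi path, and fractional occupancy (FO,
#' the time-mean posterior) for every subject segment.
#'
#' @param model A `fitted_state_model`.
#' @param data Time x d matrix the model was (or could have been) fit on.
#' @param boundaries Subject boundary data frame.
#' @return A `decode_result`: `posteriors` (list of T_s x K matrices),
#'   `viterbi` (list of integer paths), `fo` (subjects x K matrix).
#' @export
decode_subjects <- function(model, data, boundaries) {
  if (ncol(data) != nrow(model$means)) {
    stop("data dimension does not match model", call. = FALSE)
  }
  d <- ncol(data)
  chols <- lapply(model$covariances, function(S) chol(S + diag(model$ridge, d)))
  logB <- emission_logdens(data, model$means, chols)
  segs <- segment_rows(boundaries)
  posteriors <- vector("list", length(segs))
  paths <- vector("list", length(segs))
  fo <- matrix(0, length(segs), model$K)
  for (si in seq_along(segs)) {
    rows <- segs[[si]]
    lb <- logB[rows, , drop = FALSE]
    fb <- forward_backward(lb, model$transition_matrix,
                           model$initial_distribution, want_xi = FALSE)
    posteriors[[si]] <- fb$gamma
    paths[[si]] <- viterbi_path(lb, model$transition_matrix,
                                model$initial_distribution)
    fo[si, ] <- colMeans(fb$gamma)
  }
  names(posteriors) <- names(paths) <- boundaries$subject
  rownames(fo) <- boundaries$subject
  structure(list(posteriors = posteriors, viterbi = paths, fo = fo),
            class = "decode_result")
}

#' Select the number of states by maximum occupancy entropy
#'
#' Fits every candidate K and computes the Shannon entropy of the group-mean
#' fractional occupancy; the chosen K maximizes this entropy, with ties
#' broken toward the smaller model.
#'
#' @param data,boundaries As for [fit_hmm()].
#' @param candidate_K_range Integer candidates (each >= 2).
#' @param config A [run_config()] providing restarts, tolerance and base seed.
#' @param map Optional reduction map passed to [fit_hmm()].
#' @return List: `chosen_K`, `diagnostics` (data frame of K, occupancy
#'   entropy in the configured base, final log likelihood), `models` and
#'   `decodes` (per candidate, named by K).
#' @export
select_model_size <- function(data, boundaries, candidate_K_range = NULL,
                              config = run_config(), map = NULL) {
  Ks <- if (is.null(candidate_K_range)) config$candidate_K_range else candidate_K_range
  stopifnot(length(Ks) >= 1, min(Ks) >= 2)
  models <- list()
  decodes <- list()
  ent <- numeric(length(Ks))
  ll <- numeric(length(Ks))
  for (i in seq_along(Ks)) {
    K <- Ks[i]
    m <- fit_hmm(data, boundaries, K,
                 n_restarts = config$n_restarts, tol = config$tol,
                 max_iter = config$max_iter,
                 seed = child_seed(config$seed, paste0("fitK", K)), map = map)
    dec <- decode_subjects(m, data, boundaries)
    mean_fo <- colMeans(dec$fo)
    ent[i] <- shannon_entropy(mean_fo, base = config$entropy_log_base)
    ll[i] <- tail(m$loglik_trace, 1)
    models[[as.character(K)]] <- m
    decodes[[as.character(K)]] <- dec
  }
  chosen <- choose_model_size(Ks, ent)
  list(chosen_K = as.integer(chosen),
       diagnostics = data.frame(K = Ks, occupancy_entropy = ent, loglik = ll),
       models = models, decodes = decodes)
}

#' Pick the model size maximizing occupancy entropy
#'
#' Argmax of the occupancy-entropy diagnostics with ties (within 1e-12)
#' broken toward the smaller model.
#'
#' @param Ks Candidate sizes.
#' @param entropies Occupancy entropy per candidate.
#' @return The chosen K.
#' @export
choose_model_size <- function(Ks, entropies) {
  stopifnot(length(Ks) == length(entropies))
  best <- max(entropies)
  as.integer(min(Ks[entropies >= best - 1e-12]))
}

#' Remove weakly expressed states and re-decode
#'
#' A state "appears" in a subject when that subject's Viterbi path visits it
#' at least once. States appearing in fewer than `pruning_fraction` of
#' subjects are deleted; the surviving transition rows (and the initial
#' distribution) are renormalized to sum to one, and decoding is recomputed
#' under the pruned model.
#'
#' @param model A `fitted_state_model`.
#' @param decode Its `decode_result` on `data`.
#' @param pruning_fraction Subject-fraction threshold in (0, 1); default 0.20.
#' @param data,boundaries The decoded data.
#' @return List: `model` (pruned), `decode` (recomputed), `kept` (indices of
#'   surviving states in the original model), `subject_fraction` (per original
#'   state, the fraction of subjects whose path visits it).
#' @export
prune_states <- function(model, decode, pruning_fraction = 0.20, data, boundaries) {
  stopifnot(pruning_fraction > 0, pruning_fraction < 1)
  K <- model$K
  visits <- vapply(seq_len(K), function(k) {
    mean(vapply(decode$viterbi, function(p) any(p == k), logical(1)))
  }, numeric(1))
  kept <- which(visits >= pruning_fraction)
  if (!length(kept)) stop("all states pruned; threshold too strict", call. = FALSE)
  if (length(kept) == K) {
    return(list(model = model, decode = decode, kept = kept,
                subject_fraction = visits))
  }
  P <- model$transition_matrix[kept, kept, drop = FALSE]
  P <- P / rowSums(P)
  pi0 <- model$initial_distribution[kept]
  pi0 <- pi0 / sum(pi0)
  pruned <- structure(list(
    K = length(kept), means = model$means[, kept, drop = FALSE],
    covariances = model$covariances[kept],
    transition_matrix = P, initial_distribution = pi0,
    loglik_trace = model$loglik_trace, n_reinit = model$n_reinit,
    map = model$map, ridge = model$ridge), class = "fitted_state_model")
  if (!is.null(model$map)) pruned <- attach_roi_projection(pruned, model$map)
  list(model = pruned,
       decode = decode_subjects(pruned, data, boundaries),
       kept = kept, subject_fraction = visits)
}
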