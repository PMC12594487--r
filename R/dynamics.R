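# Markov-chain and occupancy analytics: stationary (sink) centrality,
# strong-sink classification, switching rate, entropy (information) rate,
# normalized occupancy entropy, and subject clustering by fractional
# occupancy.

#' Stationary distribution of a row-stochastic matrix
#'
#' Computed as the Cesaro limit via power iteration on the time-averaged
#' (lazy) chain `(P + I) / 2`, starting from the uniform distribution. The
#' lazy chain has the same stationary vectors as `P` but is aperiodic, so
#' periodic inputs converge, and reducible inputs (which pruning can create)
#' still return a well-defined occupancy vector.
#'
#' @param P Square matrix with rows summing to 1 within 1e-8.
#' @param tol Iteration tolerance (default 1e-13 in the max norm).
#' @param max_iter Iteration cap.
#' @return Probability vector `pi` with `pi %*% P = pi` within 1e-10 for
#'   irreducible chains.
#' @export
stationary_distribution <- function(P, tol = 1e-13, max_iter = 1e6) {
  if (!is_square(P)) stop("P must be square", call. = FALSE)
  if (max(abs(rowSums(P) - 1)) > 1e-8 || any(P < -1e-12)) {
    stop("P rows must be nonnegative and sum to 1", call. = FALSE)
  }
  K <- nrow(P)
  if (K == 1) return(1)
  A <- (P + diag(K)) / 2
  x <- rep(1 / K, K)
  for (i in seq_len(max_iter)) {
    x_new <- as.vector(x %*% A)
    x_new <- x_new / sum(x_new)
    if (max(abs(x_new - x)) < tol) {
      x <- x_new
      break
    }
    x <- x_new
  }
  x
}

#' Classify strong sink states
#'
#' A state is a "strong" sink when its sink centrality (stationary
#' probability) is at least `threshold` (inclusive).
#'
#' @param pi Probability vector of sink centralities.
#' @param threshold Cutoff, default 0.05.
#' @return Integer indices of strong sinks.
#' @export
classify_strong_sinks <- function(pi, threshold = 0.05) {
  stopifnot(all(pi >= -1e-12), abs(sum(pi) - 1) < 1e-6)
  which(pi >= threshold)
}

#' State switching rate of a Viterbi path
#'
#' Number of state changes divided by the elapsed time spanned by the
#' transitions, `(T - 1) * tr_seconds`; in hertz, with ceiling `1 / TR`.
#'
#' @param viterbi_path Integer state sequence, length >= 2.
#' @param tr_seconds Sampling interval in seconds.
#' @return Switching rate in Hz.
#' @export
switching_rate <- function(viterbi_path, tr_seconds) {
  T_len <- length(viterbi_path)
  if (T_len < 2) stop("path must have at least 2 samples", call. = FALSE)
  stopifnot(tr_seconds > 0)
  sum(diff(viterbi_path) != 0) / ((T_len - 1) * tr_seconds)
}

#' Entropy (information) rate of a Markov chain
#'
#' `H = -sum_k pi_k sum_j P_kj log P_kj` with `0 log 0 = 0` and `pi` the
#' stationary distribution; a proxy for the temporal complexity of the state
#' process.
#'
#' @param P Row-stochastic transition matrix.
#' @param log_base 2 for bits (default) or `exp(1)` for nats.
#' @return Entropy rate (nonnegative, at most `log(K)`).
#' @export
entropy_rate <- function(P, log_base = 2) {
  pi <- stationary_distribution(P)
  row_h <- apply(P, 1, shannon_entropy, base = log_base)
  sum(pi * row_h)
}

#' Normalized occupancy entropy
#'
#' Shannon entropy of a fractional-occupancy vector divided by `log(K)`, so
#' the result lies in `[0, 1]`; defined as 0 for K = 1.
#'
#' @param fo Probability vector of length K.
#' @param K Number of states (defaults to `length(fo)`).
#' @return Normalized entropy in `[0, 1]`.
#' @export
occupancy_entropy <- function(fo, K = length(fo)) {
  stopifnot(abs(sum(fo) - 1) < 1e-6, all(fo >= -1e-12))
  if (K <= 1) return(0)
  shannon_entropy(fo, base = 2) / log2(K)
}

#' Hierarchically cluster subjects by fractional occupancy
#'
#' Distance between subjects is one minus the Pearson correlation of their FO
#' vectors; linkage is Ward's method.
#'
#' @param fo Subjects x states FO matrix (>= 2 subjects).
#' @param k_cut Number of flat clusters to cut (default 2).
#' @return List: `tree` (an `hclust` dendrogram), `clusters` (named integer
#'   vector of flat cluster labels).
#' @export
cluster_subjects_by_fo <- function(fo, k_cut = 2) {
  stopifnot(nrow(fo) >= 2)
  sds <- apply(fo, 1, sd)
  if (any(sds < .Machine$double.eps^0.5)) {
    bad <- rownames(fo)[which(sds < .Machine$double.eps^0.5)[1]]
    stop("constant FO vector for subject ", bad,
         "; correlation distance undefined", call. = FALSE)
  }
  d <- as.dist(1 - cor(t(fo)))
  tree <- hclust(d, method = "ward.D2")
  list(tree = tree, clusters = cutree(tree, k = min(k_cut, nrow(fo))))
}

#' Summarize the chain dynamics of a fitted, decoded model
#'
#' @param model A `fitted_state_model`.
#' @param decode Its `decode_result`.
#' @param tr_seconds Sampling interval.
#' @param config A [run_config()] (sink threshold, entropy base).
#' @return A `dynamics_summary`: stationary distribution, strong sinks,
#'   per-subject switching rates and normalized occupancy entropies, model
#'   entropy rate, and the subject FO dendrogram (when >= 2 subjects with
#'   non-constant FO).
#' @export
summarize_dynamics <- function(model, decode, tr_seconds, config = run_config()) {
  pi <- stationary_distribution(model$transition_matrix)
  sw <- vapply(decode$viterbi, switching_rate, numeric(1), tr_seconds = tr_seconds)
  occ <- apply(decode$fo, 1, occupancy_entropy, K = model$K)
  clus <- tryCatch(cluster_subjects_by_fo(decode$fo), error = function(e) NULL)
  structure(list(
    stationary_distribution = pi,
    strong_sinks = classify_strong_sinks(pi, config$strong_sink_threshold),
    switching_rate = sw,
    entropy_rate = entropy_rate(model$transition_matrix,
                                log_base = config$entropy_log_base),
    occupancy_entropy = occ,
    subject_clustering = clus), class = "dynamics_summary")
}
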