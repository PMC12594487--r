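# Structure-function comparison: partition similarity (AMI/ARI), edge-weight
# and centrality distance correlations, and the group-contrast machinery
# (permutation tests with the add-one estimator, rank tests).

#' Adjusted mutual information between two partitions
#'
#' Mutual information corrected for chance agreement by subtracting its
#' expectation under the hypergeometric (fixed-margins) model, normalized by
#' `max(H_a, H_b)`. AMI is 1 for identical partitions and has expectation 0
#' for independent ones; any partition scores 0 against the single-community
#' partition.
#'
#' @param a,b Label vectors over the same node set.
#' @return AMI in `[-1, 1]` (usually `[0, 1]`).
#' @export
ami <- function(a, b) {
  if (length(a) != length(b)) stop("partitions cover different node sets", call. = FALSE)
  n <- length(a)
  tab <- table(a, b)
  ai <- rowSums(tab)
  bj <- colSums(tab)
  mi <- 0
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      nij <- tab[i, j]
      if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (ai[i] * bj[j]))
    }
  }
  emi <- expected_mi(ai, bj, n)
  ha <- shannon_entropy(ai / n, base = exp(1))
  hb <- shannon_entropy(bj / n, base = exp(1))
  denom <- max(ha, hb) - emi
  if (abs(denom) < 1e-12) {
    # both partitions carry no information (single community each)
    return(if (identical(canonical_labels(a), canonical_labels(b))) 1 else 0)
  }
  unname((mi - emi) / denom)
}

# Expected mutual information under random partitions with fixed margins.
expected_mi <- function(ai, bj, n) {
  emi <- 0
  lgn <- lgamma(n + 1)
  for (i in seq_along(ai)) {
    a <- ai[i]
    for (j in seq_along(bj)) {
      b <- bj[j]
      lo <- max(1, a + b - n)
      hi <- min(a, b)
      if (hi < lo) next
      for (nij in lo:hi) {
        lp <- lgamma(a + 1) + lgamma(b + 1) + lgamma(n - a + 1) + lgamma(n - b + 1) -
          lgn - lgamma(nij + 1) - lgamma(a - nij + 1) - lgamma(b - nij + 1) -
          lgamma(n - a - b + nij + 1)
        emi <- emi + exp(lp) * (nij / n) * log(n * nij / (a * b))
      }
    }
  }
  emi
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Label vectors over the same node set.
#' @return ARI in `[-1, 1]`.
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stop("partitions cover different node sets", call. = FALSE)
  mclust::adjustedRandIndex(a, b)
}

#' Compare one state graph with the structural connectome
#'
#' Computes the Fig.-8-style per-state quantities: distance correlation of
#' the vectorized upper-triangle edge weights, AMI and ARI of the state's
#' consensus partition against the structural partition, and distance
#' correlations of the robust local-efficiency and degree-centrality
#' profiles.
#'
#' @param state A `state_graph`.
#' @param structure_weights Structural adjacency (same D and ROI order).
#' @param structure_partition Structural community labels.
#' @param state_partition Optional precomputed community labels of the state
#'   graph; if `NULL`, [single_layer_modularity_partition()] is run.
#' @param resolution_grid,n_runs,seed Consensus controls when the state
#'   partition is computed here.
#' @return One-row data frame: `state`, `edge_dcor`, `ami`, `ari`,
#'   `local_efficiency_dcor`, `degree_dcor`.
#' @export
compare_state_to_structure <- function(state, structure_weights,
                                       structure_partition,
                                       state_partition = NULL,
                                       resolution_grid = c(0.8, 0.9, 1.0, 1.1, 1.2),
                                       n_runs = 20, seed = 1) {
  W <- state$weights
  if (!all(dim(W) == dim(structure_weights))) {
    stop("state and structural graphs differ in size", call. = FALSE)
  }
  if (is.null(state_partition)) {
    state_partition <- single_layer_modularity_partition(
      W, resolution_grid = resolution_grid, n_runs = n_runs, seed = seed)$labels
  }
  # profiles of perfectly regular graphs can be constant, where distance
  # correlation is undefined; report NA for those entries
  safe_dcor <- function(x, y) {
    if (sd(x) < .Machine$double.eps^0.5 || sd(y) < .Machine$double.eps^0.5) {
      return(NA_real_)
    }
    distance_correlation(x, y)
  }
  data.frame(
    state = state$state,
    edge_dcor = safe_dcor(upper_tri_vec(W), upper_tri_vec(structure_weights)),
    ami = ami(state_partition, structure_partition),
    ari = ari(state_partition, structure_partition),
    local_efficiency_dcor = safe_dcor(local_efficiency_profile(W),
                                      local_efficiency_profile(structure_weights)),
    degree_dcor = safe_dcor(degree_centrality(W),
                            degree_centrality(structure_weights)))
}

#' Permutation test of association
#'
#' Permutes `y` and recomputes the statistic; the p-value uses the add-one
#' estimator `(1 + #extreme) / (1 + n_perm)`, which never returns zero.
#'
#' @param x,y Numeric vectors (statistic `"pearson"`) or label vectors
#'   (statistic `"ami"`) of equal length.
#' @param statistic `"pearson"` or `"ami"`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param sidedness `"two.sided"` (extremity in `|stat|`), `"greater"`, or
#'   `"less"`.
#' @return List: `statistic` (observed), `p_value`, `n_perm`, `sidedness`.
#' @export
permutation_test <- function(x, y, statistic = c("pearson", "ami"),
                             n_perm = 999, seed = 1,
                             sidedness = c("two.sided", "greater", "less")) {
  statistic <- match.arg(statistic)
  sidedness <- match.arg(sidedness)
  stopifnot(length(x) == length(y), n_perm >= 100)
  f <- switch(statistic,
              pearson = function(x, y) {
                if (sd(x) < .Machine$double.eps^0.5 ||
                    sd(y) < .Machine$double.eps^0.5) {
                  stop("Pearson statistic undefined for constant input",
                       call. = FALSE)
                }
                cor(x, y)
              },
              ami = ami)
  obs <- f(x, y)
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) f(x, sample(y)), numeric(1))
  })
  extreme <- switch(sidedness,
                    two.sided = abs(null_stats) >= abs(obs) - 1e-12,
                    greater = null_stats >= obs - 1e-12,
                    less = null_stats <= obs + 1e-12)
  list(statistic = obs, p_value = (1 + sum(extreme)) / (1 + n_perm),
       n_perm = n_perm, sidedness = sidedness)
}

#' Two-sided rank tests for group contrasts
#'
#' Mann-Whitney U for unpaired groups, Wilcoxon signed-rank for paired ones
#' (exact for small samples without ties, normal approximation with tie
#' correction otherwise, as implemented by [stats::wilcox.test()]).
#'
#' @param group_a,group_b Numeric vectors; equal lengths required when
#'   `paired`.
#' @param paired Use the signed-rank test.
#' @return List: `statistic`, `p_value`, `method`, `sidedness`.
#' @export
rank_tests <- function(group_a, group_b, paired = FALSE) {
  if (paired) {
    stopifnot(length(group_a) == length(group_b))
    if (all(abs(group_a - group_b) < .Machine$double.eps^0.5)) {
      stop("all paired differences are zero; signed-rank test undefined",
           call. = FALSE)
    }
  }
  ht <- suppressWarnings(wilcox.test(group_a, group_b, paired = paired,
                                     alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method, sidedness = "two.sided")
}
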