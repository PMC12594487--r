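# Per-state functional metrics and cross-state similarity: excitability,
# (signed) distance correlation, global efficiency with a permuted-weight
# null, robust local efficiency, single-layer modularity, degree centrality.

#' Per-state graphs of a fitted model
#'
#' For every state: the absolute ROI-space correlation matrix (zero
#' diagonal), the signed correlation matrix, and the ROI mean-activity
#' vector.
#'
#' @param model A `fitted_state_model` with ROI-space parameters.
#' @return List of `state_graph` objects (`weights`, `signed`, `activity`).
#' @export
state_graphs <- function(model) {
  if (is.null(model$roi_covariances)) {
    stop("model has no ROI-space covariances", call. = FALSE)
  }
  lapply(seq_len(model$K), function(k) {
    S <- model$roi_covariances[[k]]
    v <- diag(S)
    v[v < 1e-12] <- 1e-12
    C <- S / sqrt(v %o% v)
    C[C > 1] <- 1
    C[C < -1] <- -1
    structure(list(state = k,
                   weights = zero_diag(abs(C)),
                   signed = zero_diag(C),
                   activity = model$roi_means[, k]), class = "state_graph")
  })
}

#' Excitability of a state
#'
#' Mean absolute mean-activity over ROIs; high values mark excitable states,
#' values near zero quiescent ones.
#'
#' @param activity ROI mean-activity vector.
#' @return Nonnegative scalar.
#' @export
excitability <- function(activity) mean(abs(activity))

#' Sample distance correlation
#'
#' Szekely's distance correlation from doubly centered Euclidean distance
#' matrices; in `[0, 1]`, zero iff (in the population) the inputs are
#' independent, and sensitive to nonlinear dependence.
#'
#' @param x,y Numeric vectors of equal length >= 4; neither constant.
#' @return Distance correlation in `[0, 1]`.
#' @export
distance_correlation <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4)
  if (sd(x) < .Machine$double.eps^0.5 || sd(y) < .Machine$double.eps^0.5) {
    stop("distance correlation undefined for constant input", call. = FALSE)
  }
  A <- dcenter(abs(outer(x, x, "-")))
  B <- dcenter(abs(outer(y, y, "-")))
  dcov2 <- mean(A * B)
  dvx <- mean(A * A)
  dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(dcov2, 0)) / (dvx * dvy)^0.25
}

dcenter <- function(M) {
  rm_ <- rowMeans(M)
  M - rm_ - rep(rm_, each = nrow(M)) + mean(M)
}

#' Signed distance correlation
#'
#' Distance correlation multiplied by the sign of the Pearson correlation,
#' giving a dependence measure in `[-1, 1]` that keeps directionality.
#'
#' @inheritParams distance_correlation
#' @return Signed distance correlation in `[-1, 1]`.
#' @export
signed_distance_correlation <- function(x, y) {
  s <- sign(cor(x, y))
  if (s == 0) s <- 1
  s * distance_correlation(x, y)
}

#' Pairwise distance-correlation similarity between states
#'
#' Activity mode compares ROI mean-activity vectors; connectivity mode
#' compares the vectorized upper triangles of the weight matrices (absolute
#' correlations, or signed correlations with `signed = TRUE`). The diagonal
#' is 1.
#'
#' @param states List of `state_graph`s (>= 2).
#' @param mode `"activity"` or `"connectivity"`.
#' @param signed Use signed matrices / signed distance correlation.
#' @return Symmetric K x K similarity matrix with unit diagonal.
#' @export
pairwise_state_similarity <- function(states, mode = c("activity", "connectivity"),
                                      signed = FALSE) {
  mode <- match.arg(mode)
  K <- length(states)
  stopifnot(K >= 2)
  vecs <- lapply(states, function(st) {
    if (mode == "activity") st$activity
    else upper_tri_vec(if (signed) st$signed else st$weights)
  })
  f <- if (signed) signed_distance_correlation else distance_correlation
  M <- diag(1, K)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      M[i, j] <- M[j, i] <- f(vecs[[i]], vecs[[j]])
    }
  }
  M
}

weights_to_graph <- function(W) {
  assert_symmetric(W, tol = 1e-8, what = "weight matrix")
  if (any(W < 0)) stop("weights must be nonnegative", call. = FALSE)
  igraph::graph_from_adjacency_matrix(zero_diag(W), mode = "undirected",
                                      weighted = TRUE)
}

#' Weighted global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with
#' edge lengths `1 / weight` (absent edges unreachable, contributing 0).
#'
#' @param weights Symmetric nonnegative weight matrix.
#' @return Efficiency in `[0, max weight]`; 0 for an empty graph.
#' @export
global_efficiency <- function(weights) {
  g <- weights_to_graph(weights)
  if (igraph::ecount(g) == 0) return(0)
  dmat <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / dmat
  diag(inv) <- 0
  mean(inv[row(inv) != col(inv)])
}

#' Permutation-normalized global efficiency
#'
#' Divides the observed efficiency by the mean efficiency of graphs whose
#' off-diagonal upper-triangle weights are randomly permuted (then mirrored),
#' controlling for overall connectivity and weight-distribution differences
#' between states.
#'
#' @param weights Symmetric nonnegative weight matrix.
#' @param n_permutations Number of weight shuffles (default 100).
#' @param seed Integer seed.
#' @return Normalized efficiency (1 for any permutation-invariant graph).
#' @export
normalized_global_efficiency <- function(weights, n_permutations = 100, seed = 1) {
  e_obs <- global_efficiency(weights)
  ut <- upper.tri(weights)
  w <- weights[ut]
  null_vals <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      Wp <- matrix(0, nrow(weights), ncol(weights))
      Wp[ut] <- sample(w)
      global_efficiency(Wp + t(Wp))
    }, numeric(1))
  })
  e_null <- mean(null_vals)
  if (e_null == 0) {
    stop("null efficiency is zero (fully disconnected graph); ",
         "normalization undefined", call. = FALSE)
  }
  e_obs / e_null
}

#' Robust weighted local efficiency of one node
#'
#' Neighborhood efficiency with cube-root weighting: paths among the
#' neighbors of `node` are measured on the neighborhood subgraph with edge
#' lengths `(1/w)^(1/3)`, and each neighbor pair (j, h) contributes
#' `(w_ij * w_ih)^(1/3) / d_jh`, normalized by `k (k - 1)`. On 0/1 graphs
#' this reduces to the classic binary local efficiency; nodes of degree < 2
#' score 0.
#'
#' @param weights Symmetric nonnegative weight matrix.
#' @param node Node index.
#' @return Local efficiency of `node`.
#' @export
local_efficiency_robust <- function(weights, node) {
  assert_symmetric(weights, tol = 1e-8, what = "weight matrix")
  w_i <- zero_diag(weights)[node, ]
  nb <- which(w_i > 0)
  k <- length(nb)
  if (k < 2) return(0)
  sub <- weights[nb, nb, drop = FALSE]
  g <- weights_to_graph(sub)
  dmat <- if (igraph::ecount(g) > 0) {
    igraph::distances(g, weights = (1 / igraph::E(g)$weight)^(1 / 3))
  } else {
    matrix(Inf, k, k)
  }
  inv_d <- 1 / dmat
  diag(inv_d) <- 0
  ww <- (w_i[nb] %o% w_i[nb])^(1 / 3)
  sum(ww * inv_d) / (k * (k - 1))
}

#' Robust local efficiency of every node
#' @inheritParams local_efficiency_robust
#' @return Numeric vector over nodes.
#' @export
local_efficiency_profile <- function(weights) {
  vapply(seq_len(nrow(weights)), local_efficiency_robust,
         numeric(1), weights = weights)
}

#' Degree (strength) centrality
#'
#' Row sums of the weight matrix.
#'
#' @param weights Symmetric weight matrix.
#' @return Strength vector.
#' @export
degree_centrality <- function(weights) {
  assert_symmetric(weights, tol = 1e-8, what = "weight matrix")
  rowSums(zero_diag(weights))
}

#' Robust single-layer community detection
#'
#' Applies the same consensus machinery as the spatiotemporal detection to a
#' single graph (one layer, zero coupling) over a resolution grid.
#'
#' @param weights Symmetric nonnegative weight matrix.
#' @param resolution_grid Gamma values.
#' @param n_runs Louvain runs per gamma.
#' @param seed Integer seed.
#' @return List: `labels` (integer community per node), `Q` (Newman-Girvan
#'   modularity of the partition at gamma = 1), `consensus` (full consensus
#'   output).
#' @export
single_layer_modularity_partition <- function(weights,
                                              resolution_grid = c(0.8, 0.9, 1.0, 1.1, 1.2),
                                              n_runs = 20, seed = 1) {
  h <- structure(list(A = list(zero_diag(weights)),
                      omega_base = matrix(0, 1, 1), omega = matrix(0, 1, 1),
                      coupling_scale = 0, pi = 1,
                      D = nrow(weights), K = 1L), class = "hmgm")
  cons <- consensus_communities(h, resolution_grid = resolution_grid,
                                coupling_grid = 0, n_runs = n_runs, seed = seed)
  labels <- as.vector(cons$partition$labels)
  list(labels = labels,
       Q = multilayer_modularity(h, labels, gamma = 1),
       consensus = cons)
}
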