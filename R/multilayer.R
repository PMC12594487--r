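# The hidden Markov graph model (HMGM): a multilayer graph with one layer
# per brain state over the same D ROI nodes. Intralayer edges are absolute
# ROI-space state correlations; interlayer coupling between layers s and r is
# the symmetrized transition probability scaled by omega0. Spatiotemporal
# communities are found by maximizing a multilayer Newman-Girvan modularity
# (per-layer null, node-aligned coupling) with a generalized Louvain sweep,
# aggregated over a (gamma, omega0) grid by consensus clustering.

#' Build the hidden Markov graph model from a fitted state model
#'
#' @param model A `fitted_state_model` carrying ROI-space covariances (fit
#'   with a reduction map, or a ground-truth model converted via
#'   [ground_truth_as_fitted()]).
#' @param coupling_scale Interlayer coupling scale omega0 (default 1).
#' @return An `hmgm` object: `A` (list of K symmetric D x D intralayer
#'   weight matrices, entries in `[0, 1]`, zero diagonal), `omega_base`
#'   (symmetrized transition probabilities, zero diagonal), `omega`
#'   (`coupling_scale * omega_base`), and stationary weights `pi`.
#' @export
build_hmgm <- function(model, coupling_scale = 1) {
  if (is.null(model$roi_covariances)) {
    stop("model has no ROI-space covariances; fit with a reduction map",
         call. = FALSE)
  }
  A <- lapply(model$roi_covariances, function(S) {
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) stop("state covariance is not PSD", call. = FALSE)
    v <- diag(S)
    v[v < 1e-12] <- 1e-12
    C <- abs(S / sqrt(v %o% v))
    C[C > 1] <- 1
    zero_diag(C)
  })
  P <- model$transition_matrix
  omega_base <- zero_diag((P + t(P)) / 2)
  structure(list(A = A, omega_base = omega_base,
                 omega = coupling_scale * omega_base,
                 coupling_scale = coupling_scale,
                 pi = stationary_distribution(P),
                 D = nrow(A[[1]]), K = length(A)), class = "hmgm")
}

#' Rescale the interlayer coupling of an HMGM
#' @param hmgm An `hmgm`.
#' @param coupling_scale New omega0.
#' @return The rescaled `hmgm`.
#' @export
rescale_coupling <- function(hmgm, coupling_scale) {
  hmgm$omega <- coupling_scale * hmgm$omega_base
  hmgm$coupling_scale <- coupling_scale
  hmgm
}

#' Wrap a ground-truth generative model as a fitted state model
#'
#' Lets the community-detection stages run directly on planted parameters
#' (ROI-space means/covariances and the planted transition matrix), bypassing
#' estimation.
#'
#' @param gt A [make_ground_truth()] model.
#' @return A `fitted_state_model` with ROI-space parameters attached.
#' @export
ground_truth_as_fitted <- function(gt) {
  structure(list(
    K = gt$K_true, means = gt$means, covariances = gt$covariances,
    transition_matrix = gt$transition_matrix,
    initial_distribution = gt$initial_distribution,
    loglik_trace = NA_real_, n_reinit = 0L, map = NULL, ridge = 0,
    roi_means = gt$means, roi_covariances = gt$covariances),
    class = "fitted_state_model")
}

# Dense multilayer modularity matrix. Node-layer (i, s) -> row (s-1)*D + i.
# Returns B and the total weight 2*mu (intralayer weight plus coupling).
build_modularity_matrix <- function(hmgm, gamma) {
  D <- unname(hmgm$D)
  K <- unname(hmgm$K)
  n <- D * K
  B <- matrix(0, n, n)
  two_mu <- 0
  for (s in seq_len(K)) {
    A <- hmgm$A[[s]]
    two_m <- sum(A)
    rows <- (s - 1) * D + seq_len(D)
    if (two_m > 0) {
      k <- rowSums(A)
      B[rows, rows] <- A - gamma * (k %o% k) / two_m
    } else {
      hmgm_log("layer ", s, " has no intralayer weight; coupling terms only")
    }
    two_mu <- two_mu + two_m
  }
  idx <- diag(D) == 1
  for (s in seq_len(K)) {
    for (r in seq_len(K)) {
      if (s == r) next
      w <- hmgm$omega[s, r]
      if (w > 0) {
        rows <- (s - 1) * D + seq_len(D)
        cols <- (r - 1) * D + seq_len(D)
        B[rows, cols][idx] <- w
      }
      two_mu <- two_mu + D * w
    }
  }
  list(B = B, two_mu = two_mu)
}

#' Multilayer modularity of a spatiotemporal partition
#'
#' `Q = (1/2mu) * [ sum_s sum_ij (A_ijs - gamma k_is k_js / 2m_s)
#' delta(g_is, g_js) + sum_i sum_{s != r} omega_sr delta(g_is, g_ir) ]`,
#' the multilayer Newman-Girvan form with a uniform null per layer; `2mu` is
#' the total weight including couplings. Layers with no intralayer weight
#' contribute coupling terms only.
#'
#' @param hmgm An `hmgm`.
#' @param partition A `st_partition`, or a D x K label matrix, or a length
#'   D*K label vector in node-layer order.
#' @param gamma Resolution parameter (> 0).
#' @return Modularity value Q.
#' @export
multilayer_modularity <- function(hmgm, partition, gamma = 1) {
  labels <- partition_labels_vec(partition, hmgm$D, hmgm$K)
  bm <- build_modularity_matrix(hmgm, gamma)
  if (bm$two_mu == 0) return(0)  # weightless graph: Q defined as 0
  same <- outer(labels, labels, "==")
  unname(sum(bm$B[same]) / bm$two_mu)
}

partition_labels_vec <- function(partition, D, K) {
  labels <- if (inherits(partition, "st_partition")) partition$labels else partition
  if (is.matrix(labels)) labels <- as.vector(labels)
  if (length(labels) != D * K) {
    stop("partition does not cover the D*K node-layer set", call. = FALSE)
  }
  labels
}

# One Louvain local-move phase on a dense (modularity) matrix B.
# Nodes are visited in seeded-random order; each node moves to the community
# with the largest positive gain (ties to the lowest community id), repeating
# sweeps until no move improves. `init` gives starting labels.
louvain_local_moves <- function(B, init = seq_len(nrow(B))) {
  n <- nrow(B)
  comm <- as.integer(factor(init))
  C <- max(comm)
  S <- matrix(0, n, C)
  S[cbind(seq_len(n), comm)] <- 1
  G <- B %*% S                      # G[v, c] = sum of B[v, j] over j in c
  repeat {
    moved <- FALSE
    order_v <- sample.int(n)
    for (v in order_v) {
      c0 <- comm[v]
      base <- G[v, c0] - B[v, v]    # link mass to own community, minus self
      gains <- G[v, ] - base
      gains[c0] <- 0
      cbest <- which.max(gains)
      if (gains[cbest] > 1e-12 && cbest != c0) {
        comm[v] <- cbest
        G[, c0] <- G[, c0] - B[, v]
        G[, cbest] <- G[, cbest] + B[, v]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  as.integer(factor(comm))
}

# Full generalized Louvain on a dense modularity matrix: local moves,
# community aggregation, repeat; finished with one refinement pass at the
# original node level. Deterministic given the RNG state.
louvain_dense <- function(B) {
  n <- nrow(B)
  labels <- seq_len(n)
  Bcur <- B
  repeat {
    comm <- louvain_local_moves(Bcur)
    if (max(comm) == nrow(Bcur)) break      # nothing merged
    labels <- comm[labels]
    S <- matrix(0, nrow(Bcur), max(comm))
    S[cbind(seq_len(nrow(Bcur)), comm)] <- 1
    Bcur <- crossprod(S, Bcur %*% S)
    if (nrow(Bcur) == 1) break
  }
  # refinement at node level from the aggregated solution
  as.integer(factor(louvain_local_moves(B, init = labels)))
}

#' Optimize multilayer modularity by generalized Louvain
#'
#' Locally optimal: on return no single node-layer move increases Q.
#' Deterministic given `seed`.
#'
#' @param hmgm An `hmgm`.
#' @param gamma Resolution (> 0).
#' @param seed Integer seed controlling node sweep order.
#' @return An `st_partition`: `labels` (D x K matrix), `Q`, and the
#'   parameter provenance (gamma, coupling scale, seed).
#' @export
genlouvain_optimize <- function(hmgm, gamma = 1, seed = 1) {
  stopifnot(gamma > 0)
  bm <- build_modularity_matrix(hmgm, gamma)
  labels <- with_seed(seed, louvain_dense(bm$B))
  Q <- if (bm$two_mu == 0) 0 else {
    same <- outer(labels, labels, "==")
    unname(sum(bm$B[same]) / bm$two_mu)
  }
  new_st_partition(labels, hmgm, gamma = gamma, seed = seed, Q = Q)
}

new_st_partition <- function(labels, hmgm, gamma, seed, Q = NA_real_) {
  m <- matrix(as.integer(labels), hmgm$D, hmgm$K)
  rownames(m) <- sprintf("ROI_%02d", seq_len(hmgm$D))
  colnames(m) <- sprintf("state_%02d", seq_len(hmgm$K))
  structure(list(labels = m, Q = Q, gamma = gamma,
                 coupling_scale = hmgm$coupling_scale, seed = seed),
            class = "st_partition")
}

# Canonical form of a labeling (first-appearance relabeling) for equality
# checks that ignore label names.
canonical_labels <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

#' Consensus spatiotemporal communities over a parameter grid
#'
#' Runs [genlouvain_optimize()] for every (gamma, omega0) grid combination
#' and `n_runs` seeds, builds the co-classification frequency matrix over
#' node-layers, zeroes entries below the mean co-classification of a
#' label-permuted null (which, for uniformly permuted labels, equals the
#' run-averaged pair-agreement rate `sum_c n_c (n_c - 1) / (n (n - 1))`),
#' and re-clusters the thresholded matrix with single-layer Louvain until all
#' re-clustering runs agree.
#'
#' @param hmgm An `hmgm`.
#' @param resolution_grid Gamma values.
#' @param coupling_grid Omega0 values (may include 0).
#' @param n_runs Louvain runs per grid point.
#' @param seed Integer seed.
#' @param max_consensus_iter Consensus iteration cap (default 50; a warning
#'   is raised and the last iterate returned on non-convergence).
#' @return List: `partition` (consensus `st_partition`, with `Q` evaluated at
#'   the median grid point), `coclassification` (the pre-threshold D*K x D*K
#'   frequency matrix), `n_iterations`, `converged`.
#' @export
consensus_communities <- function(hmgm,
                                  resolution_grid = c(0.8, 0.9, 1.0, 1.1, 1.2),
                                  coupling_grid = c(0.5, 1.0, 2.0),
                                  n_runs = 20, seed = 1,
                                  max_consensus_iter = 50) {
  stopifnot(length(resolution_grid) >= 1, length(coupling_grid) >= 1)
  n <- hmgm$D * hmgm$K
  runs <- list()
  for (g in resolution_grid) {
    for (w in coupling_grid) {
      h <- rescale_coupling(hmgm, w)
      for (r in seq_len(n_runs)) {
        s <- child_seed(seed, sprintf("glv/%g/%g/%d", g, w, r))
        runs[[length(runs) + 1L]] <- genlouvain_optimize(h, gamma = g, seed = s)$labels
      }
    }
  }
  label_mat <- do.call(rbind, lapply(runs, as.vector))
  C0 <- coclassification_matrix(label_mat)
  labels <- NULL
  converged <- FALSE
  C <- C0
  for (iter in seq_len(max_consensus_iter)) {
    tau <- permuted_null_mean(label_mat)
    Cthr <- C
    Cthr[C < tau] <- 0
    diag(Cthr) <- 1
    reruns <- vapply(seq_len(n_runs), function(r) {
      s <- child_seed(seed, sprintf("consensus/%d/%d", iter, r))
      cluster_weight_matrix(Cthr, seed = s)
    }, integer(n))
    canon <- apply(reruns, 2, canonical_labels)
    if (all(canon == canon[, 1])) {
      labels <- canon[, 1]
      converged <- TRUE
      break
    }
    label_mat <- t(reruns)
    C <- coclassification_matrix(label_mat)
  }
  if (!converged) {
    warning("consensus did not stabilize in ", max_consensus_iter,
            " iterations; returning last iterate")
    labels <- canonical_labels(reruns[, 1])
    iter <- max_consensus_iter
  }
  g_mid <- median(resolution_grid)
  part <- new_st_partition(labels, rescale_coupling(hmgm, median(coupling_grid)),
                           gamma = g_mid, seed = seed)
  part$Q <- multilayer_modularity(rescale_coupling(hmgm, median(coupling_grid)),
                                  part, gamma = g_mid)
  list(partition = part, coclassification = C0,
       n_iterations = iter, converged = converged)
}

# Co-classification frequency matrix from a runs x nodes label matrix.
coclassification_matrix <- function(label_mat) {
  n <- ncol(label_mat)
  C <- matrix(0, n, n)
  for (r in seq_len(nrow(label_mat))) {
    C <- C + outer(label_mat[r, ], label_mat[r, ], "==")
  }
  C / nrow(label_mat)
}

# Mean off-diagonal co-classification under uniform label permutation: every
# permuted matrix has the same mean, the pair-agreement rate of the label
# multiset, so the null mean is available in closed form per run.
permuted_null_mean <- function(label_mat) {
  n <- ncol(label_mat)
  mean(apply(label_mat, 1, function(l) {
    nc <- table(l)
    sum(nc * (nc - 1)) / (n * (n - 1))
  }))
}

# Single-layer Newman-Girvan Louvain on a nonnegative weight matrix.
cluster_weight_matrix <- function(W, gamma = 1, seed = 1) {
  W <- zero_diag(W)
  two_m <- sum(W)
  if (two_m == 0) return(rep(1L, nrow(W)))
  k <- rowSums(W)
  B <- W - gamma * (k %o% k) / two_m
  with_seed(seed, louvain_dense(B))
}

#' Fractional community membership of every ROI
#'
#' `F[i, c] = sum_s pi_s * 1[g_is = c]`: the long-run proportion of time ROI
#' `i` is expected to spend in community `c`, weighting each layer by the
#' stationary probability of its state. Rows sum to 1.
#'
#' @param partition An `st_partition` (or D x K label matrix).
#' @param pi Stationary distribution over the K layers.
#' @return ROI x community matrix with rows summing to 1.
#' @export
fractional_membership <- function(partition, pi) {
  labels <- if (inherits(partition, "st_partition")) partition$labels else partition
  stopifnot(is.matrix(labels), ncol(labels) == length(pi))
  comms <- sort(unique(as.vector(labels)))
  F_mat <- vapply(comms, function(cc) {
    as.vector((labels == cc) %*% pi)
  }, numeric(nrow(labels)))
  F_mat <- matrix(F_mat, nrow = nrow(labels))
  dimnames(F_mat) <- list(rownames(labels), paste0("community_", comms))
  F_mat / sum(pi)
}

# Jaccard index of co-clustered pairs between two labelings of the same set.
pair_jaccard <- function(la, lb) {
  a <- outer(la, la, "==")[upper.tri(diag(length(la)))]
  b <- outer(lb, lb, "==")[upper.tri(diag(length(lb)))]
  un <- sum(a | b)
  if (un == 0) return(1)  # both all-singleton partitions: identical
  sum(a & b) / un
}

#' Hierarchically cluster layers (states) by community composition
#'
#' Pairwise layer similarity is the Jaccard index of co-clustered ROI pairs
#' between the two layers' induced partitions; distance is 1 - Jaccard with
#' Ward linkage.
#'
#' @param partition An `st_partition` with >= 2 layers.
#' @param k_cut Flat clusters to cut (default 2).
#' @return List: `similarity` (K x K Jaccard matrix), `tree` (`hclust`),
#'   `clusters`.
#' @export
cluster_layers <- function(partition, k_cut = 2) {
  labels <- partition$labels
  K <- ncol(labels)
  stopifnot(K >= 2)
  sim <- matrix(1, K, K, dimnames = list(colnames(labels), colnames(labels)))
  for (s in seq_len(K - 1)) {
    for (r in (s + 1):K) {
      sim[s, r] <- sim[r, s] <- pair_jaccard(labels[, s], labels[, r])
    }
  }
  tree <- hclust(as.dist(1 - sim), method = "ward.D2")
  list(similarity = sim, tree = tree, clusters = cutree(tree, k = min(k_cut, K)))
}

#' Hierarchically cluster regions by membership profile across states
#'
#' The transposed construction of [cluster_layers()]: each ROI induces a
#' partition of the states via its labels across layers; similarity is the
#' Jaccard index of co-clustered state pairs.
#'
#' @param partition An `st_partition` with >= 2 ROIs.
#' @param k_cut Flat clusters to cut (default 2).
#' @return List: `similarity`, `tree`, `clusters`.
#' @export
cluster_regions <- function(partition, k_cut = 2) {
  labels <- partition$labels
  D <- nrow(labels)
  stopifnot(D >= 2)
  sim <- matrix(1, D, D, dimnames = list(rownames(labels), rownames(labels)))
  for (i in seq_len(D - 1)) {
    for (j in (i + 1):D) {
      sim[i, j] <- sim[j, i] <- pair_jaccard(labels[i, ], labels[j, ])
    }
  }
  tree <- hclust(as.dist(1 - sim), method = "ward.D2")
  list(similarity = sim, tree = tree, clusters = cutree(tree, k = min(k_cut, D)))
}
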