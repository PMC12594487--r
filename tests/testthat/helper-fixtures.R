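# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (double loops, enumeration) so they cannot share a bug
# with the vectorized implementation.

toy_cohort <- function(n_subj = 2, d = 3, t_len = 10, seed = 1) {
  withr_seed <- function(s, e) hmgm:::with_seed(s, e)
  series <- withr_seed(seed, {
    lapply(seq_len(n_subj), function(i) matrix(rnorm(d * t_len), d, t_len))
  })
  names(series) <- sprintf("S%02d", seq_len(n_subj))
  roi_cohort(series, sprintf("R%d", seq_len(d)), tr_seconds = 3,
             condition = "toy")
}

# Single-layer hmgm wrapper around a weight matrix.
one_layer_hmgm <- function(W) {
  structure(list(A = list(hmgm:::zero_diag(W)),
                 omega_base = matrix(0, 1, 1), omega = matrix(0, 1, 1),
                 coupling_scale = 0, pi = 1, D = nrow(W), K = 1L),
            class = "hmgm")
}

# Small random HMGM: D nodes, K layers, weights in [0,1], random coupling.
random_toy_hmgm <- function(D, K, seed) {
  hmgm:::with_seed(seed, {
    A <- lapply(seq_len(K), function(s) {
      W <- matrix(0, D, D)
      ut <- upper.tri(W)
      w <- runif(sum(ut))
      w[runif(sum(ut)) < 0.4] <- 0      # some sparsity
      if (all(w == 0)) w[1] <- runif(1, 0.5, 1)  # keep the layer non-empty
      W[ut] <- w
      W + t(W)
    })
    P <- matrix(runif(K * K), K, K)
    P <- P / rowSums(P)
    om <- hmgm:::zero_diag((P + t(P)) / 2)
    structure(list(A = A, omega_base = om, omega = om, coupling_scale = 1,
                   pi = rep(1 / K, K), D = D, K = as.integer(K)),
              class = "hmgm")
  })
}

# Brute-force multilayer modularity: explicit double loops over the formula.
brute_modularity <- function(hg, labels, gamma) {
  D <- hg$D; K <- hg$K
  g <- matrix(labels, D, K)
  total <- 0
  two_mu <- 0
  for (s in seq_len(K)) {
    A <- hg$A[[s]]
    two_m <- sum(A)
    two_mu <- two_mu + two_m
    k <- rowSums(A)
    for (i in seq_len(D)) {
      for (j in seq_len(D)) {
        if (g[i, s] == g[j, s]) {
          null <- if (two_m > 0) gamma * k[i] * k[j] / two_m else 0
          total <- total + A[i, j] - null
        }
      }
    }
  }
  for (i in seq_len(D)) {
    for (s in seq_len(K)) {
      for (r in seq_len(K)) {
        if (s != r) {
          two_mu <- two_mu + hg$omega[s, r]
          if (g[i, s] == g[i, r]) total <- total + hg$omega[s, r]
        }
      }
    }
  }
  total / two_mu
}

# Enumerate all set partitions of n items as label vectors (restricted
# growth strings); n <= 10.
all_set_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    pos <- length(labels) + 1L
    if (pos > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible(NULL))
    }
    for (v in seq_len(next_max)) {
      recurse(c(labels, v), max(next_max, v + 1L))
    }
  }
  recurse(integer(0), 1L)
  out
}

# Exhaustive-search modularity optimum over all partitions of the node-layer
# set (small instances only).
exhaustive_modularity_optimum <- function(hg, gamma) {
  n <- hg$D * hg$K
  bm <- hmgm:::build_modularity_matrix(hg, gamma)
  best <- -Inf
  for (labels in all_set_partitions(n)) {
    same <- outer(labels, labels, "==")
    q <- sum(bm$B[same]) / bm$two_mu
    if (q > best) best <- q
  }
  best
}

# Naive weighted local efficiency by direct summation of the defining
# formula (cube-root lengths via Dijkstra on the neighborhood subgraph,
# done with igraph but independently of the package path).
brute_local_efficiency <- function(W, node) {
  nb <- which(W[node, ] > 0 & seq_len(ncol(W)) != node)
  k <- length(nb)
  if (k < 2) return(0)
  sub <- W[nb, nb, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                           weighted = TRUE)
  dmat <- if (igraph::ecount(g) > 0) {
    igraph::distances(g, weights = (1 / igraph::E(g)$weight)^(1 / 3))
  } else matrix(Inf, k, k)
  acc <- 0
  for (j in seq_len(k)) {
    for (h in seq_len(k)) {
      if (j != h && is.finite(dmat[j, h])) {
        acc <- acc + (W[node, nb[j]] * W[node, nb[h]])^(1 / 3) / dmat[j, h]
      }
    }
  }
  acc / (k * (k - 1))
}

# Concatenate a synthetic cohort in raw (unstandardized) units: time x D
# data plus subject boundaries; useful when fits should recover the
# generator's parameters on their native scale.
raw_concat <- function(sc) {
  X <- t(do.call(cbind, sc$cohort$series))
  lens <- vapply(sc$cohort$series, ncol, integer(1))
  ends <- cumsum(lens)
  list(data = X,
       boundaries = data.frame(subject = names(lens),
                               start = c(1L, head(ends, -1) + 1L), end = ends,
                               stringsAsFactors = FALSE))
}

# Match fitted states to generator states by squared mean distance.
match_to_truth <- function(model, gt_means) {
  K <- ncol(model$means)
  cost <- outer(seq_len(K), seq_len(ncol(gt_means)), Vectorize(function(i, j) {
    sum((model$means[, i] - gt_means[, j])^2)
  }))
  match_states(cost)
}

# Empirical one-step transition counts of a set of paths.
transition_counts <- function(paths, K) {
  counts <- matrix(0, K, K)
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    for (t in seq_len(length(p) - 1)) {
      counts[p[t], p[t + 1]] <- counts[p[t], p[t + 1]] + 1
    }
  }
  counts
}
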