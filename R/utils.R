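# Internal helpers: seed management, permutations, small numerics.

#' Derive a deterministic child seed for a pipeline stage
#'
#' Expands one global seed into stage-specific seeds so that each stage of the
#' pipeline is independently reproducible. The mapping is a simple polynomial
#' string hash of the stage label folded into the seed, reduced modulo
#' 2^31 - 1 so the result is always a valid 32-bit integer seed.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label (e.g. `"simulate/anaesthesia"`).
#' @return A single integer seed.
#' @export
#' @examples
#' child_seed(1, "simulate") != child_seed(1, "fit")
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647
  h <- abs(as.double(seed)) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

# All permutations of 1..n (n <= 9); used for exhaustive state matching.
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 9)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (pos in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, pos] <- n
    block[, -pos] <- sub
    out[[pos]] <- block
  }
  do.call(rbind, out)
}

#' Match fitted states to reference states by minimum total cost
#'
#' Exhaustive assignment over permutations (feasible for K <= 9 states, the
#' scale at which parameter-recovery checks run). `cost[i, j]` is the cost of
#' assigning fitted state `i` to reference state `j`.
#'
#' @param cost Square numeric cost matrix.
#' @return Integer vector `perm` with `perm[i]` the reference index assigned
#'   to fitted state `i`.
#' @export
match_states <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost))
  k <- nrow(cost)
  perms <- all_permutations(k)
  totals <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(k), p)]))
  perms[which.min(totals), ]
}

# Shannon entropy of a probability vector, 0 log 0 = 0.
shannon_entropy <- function(p, base = 2) {
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

# Symmetrize and zero the diagonal of a square matrix.
zero_diag <- function(m) {
  diag(m) <- 0
  m
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

# Stop unless matrix is symmetric within tol.
assert_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is_square(m)) stop(what, " must be square", call. = FALSE)
  dev <- max(abs(m - t(m)))
  if (dev > tol) {
    stop(sprintf("%s is asymmetric (max |m - t(m)| = %.3g > %.3g)", what, dev, tol),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Upper-triangle vectorization (no diagonal), fixed column-major order.
upper_tri_vec <- function(m) m[upper.tri(m)]

hmgm_log <- function(..., level = "info") {
  verbose <- getOption("hmgm.verbose", FALSE)
  if (isTRUE(verbose) || level %in% c("warn", "error")) {
    message(sprintf("[hmgm:%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}
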