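# Standardization, Horn parallel analysis, PCA reduction, and projection of
# fitted state parameters back to ROI space.

#' Standardize and concatenate a cohort
#'
#' Concatenates all subject recordings in time and z-scores every ROI channel
#' over the concatenation (not per subject), so each column of the result has
#' mean 0 and variance 1.
#'
#' @param cohort An [roi_cohort()].
#' @return List: `data` (total-time x D matrix), `boundaries` (data frame
#'   with `subject`, `start`, `end` row indices recovering each subject's
#'   segment), `center` and `scale` (per-ROI mean and sd of the raw
#'   concatenation).
#' @export
standardize_concatenate <- function(cohort) {
  stopifnot(inherits(cohort, "roi_cohort"))
  X <- do.call(cbind, cohort$series)       # D x total time
  lens <- vapply(cohort$series, ncol, integer(1))
  center <- rowMeans(X)
  scale <- apply(X, 1, sd)
  bad <- which(scale < .Machine$double.eps^0.5)
  if (length(bad)) {
    stop("zero-variance ROI: ", paste(cohort$roi_labels[bad], collapse = ", "),
         call. = FALSE)
  }
  Z <- t((X - center) / scale)             # time x D
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1) + 1L)
  colnames(Z) <- cohort$roi_labels
  list(data = Z,
       boundaries = data.frame(subject = cohort$subjects,
                               start = starts, end = ends,
                               stringsAsFactors = FALSE),
       center = center, scale = scale)
}

# Split a concatenated (time x p) matrix back into per-subject segments.
split_by_boundaries <- function(data, boundaries) {
  out <- lapply(seq_len(nrow(boundaries)), function(i) {
    data[boundaries$start[i]:boundaries$end[i], , drop = FALSE]
  })
  names(out) <- boundaries$subject
  out
}

#' Horn's parallel analysis for PCA dimension selection
#'
#' Retains the leading sample eigenvalues that exceed the given percentile of
#' eigenvalues obtained from null data in which every column is independently
#' permuted (marginals preserved). Counting stops at the first eigenvalue
#' that fails, and at least one dimension is always retained.
#'
#' @param data Time x variable matrix (columns are compared on the
#'   correlation scale, so prior standardization is immaterial).
#' @param n_null Number of permuted null datasets (>= 10).
#' @param percentile Null percentile to beat (default 0.95).
#' @param seed Integer seed.
#' @return Integer retained dimension `d`.
#' @export
horn_parallel_analysis <- function(data, n_null = 100, percentile = 0.95, seed = 1) {
  stopifnot(n_null >= 10, percentile > 0, percentile < 1)
  p <- ncol(data)
  ev <- eigen(cor(data), symmetric = TRUE, only.values = TRUE)$values
  null_ev <- with_seed(seed, {
    vapply(seq_len(n_null), function(b) {
      perm <- apply(data, 2, sample)
      eigen(cor(perm), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p))
  })
  thresh <- apply(null_ev, 1, quantile, probs = percentile, names = FALSE)
  keep <- ev > thresh
  d <- if (keep[1]) which.min(c(keep, FALSE)) - 1L else 0L
  max(1L, as.integer(d))
}

#' Reduce a standardized concatenation to d principal components
#'
#' Plain (unwhitened) PCA: the reduced series are the centered data times the
#' leading eigenvectors of the covariance, so components keep their
#' variances.
#'
#' @param data Time x D matrix (typically the output of
#'   [standardize_concatenate()]).
#' @param d Number of components, `1 <= d <= rank(data)`.
#' @param center,scale Optional per-ROI center/sd of the raw data to store in
#'   the map for de-standardization when projecting parameters back; default
#'   zeros and ones.
#' @return List: `reduced` (time x d), `map` (a `reduction_map` holding the
#'   D x d orthonormal `loadings`, the column means removed before rotation,
#'   `center`, `scale`, and per-component `explained_variance`).
#' @export
pca_reduce <- function(data, d, center = NULL, scale = NULL) {
  p <- ncol(data)
  stopifnot(d >= 1)
  mu <- colMeans(data)
  Xc <- sweep(data, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(p, nrow(data)))
  evals <- sv$d^2 / (nrow(data) - 1)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (d > rank) {
    stop(sprintf("d = %d exceeds the numerical rank %d of the data", d, rank),
         call. = FALSE)
  }
  W <- sv$v[, seq_len(d), drop = FALSE]
  map <- structure(list(
    loadings = W, pca_center = mu,
    center = if (is.null(center)) rep(0, p) else center,
    scale = if (is.null(scale)) rep(1, p) else scale,
    d = as.integer(d),
    explained_variance = evals[seq_len(d)]), class = "reduction_map")
  list(reduced = Xc %*% W, map = map)
}

#' Project reduced-space state parameters back to ROI space
#'
#' The state mean is rotated through the loadings and de-standardized by the
#' per-ROI scale; the covariance is congruence-transformed, which preserves
#' positive semi-definiteness.
#'
#' @param mean_d Length-d state mean in component space.
#' @param cov_d d x d symmetric PSD state covariance in component space.
#' @param map A `reduction_map` from [pca_reduce()].
#' @return List: `mean` (length D, in per-ROI sd units of the raw data) and
#'   `covariance` (D x D symmetric PSD).
#' @export
project_state_to_roi <- function(mean_d, cov_d, map) {
  W <- map$loadings
  if (length(mean_d) != ncol(W) || !all(dim(cov_d) == ncol(W))) {
    stop("state parameter dimension does not match the reduction map", call. = FALSE)
  }
  assert_symmetric(cov_d, tol = 1e-8, what = "cov_d")
  mean_roi <- map$scale * as.vector(W %*% mean_d)
  cov_roi <- (map$scale %o% map$scale) * (W %*% cov_d %*% t(W))
  cov_roi <- (cov_roi + t(cov_roi)) / 2
  list(mean = mean_roi, covariance = cov_roi)
}
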