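# File formats and run configuration. All matrices travel as headerless
# tab-separated text (row i = ROI i); model parameters and partitions as JSON.

#' Read a headerless tab-separated numeric matrix
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty matrix file: ", path, call. = FALSE)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    stop(sprintf("ragged rows in %s (line %d has %d fields, expected %d)",
                 path, which(ncols != ncols[1])[1], ncols[ncols != ncols[1]][1],
                 ncols[1]), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    line <- ((bad - 1) %/% ncols[1]) + 1
    stop(sprintf("non-numeric cell in %s at line %d", path, line), call. = FALSE)
  }
  matrix(vals, nrow = length(rows), ncol = ncols[1], byrow = TRUE)
}

#' Write a numeric matrix as headerless tab-separated text
#'
#' Values are written with 17 significant digits so a write-then-read round
#' trip reproduces the doubles bit for bit.
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m))
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Construct and validate an ROI cohort
#'
#' A cohort holds one ROI-by-time BOLD matrix per subject, the shared ROI
#' labels, the sampling interval (TR, seconds) and a condition tag.
#'
#' @param series Named list of numeric matrices, each D x T_subject (rows =
#'   ROIs, columns = volumes).
#' @param roi_labels Character vector of D region names.
#' @param tr_seconds Positive sampling interval in seconds.
#' @param condition Condition tag, e.g. `"wake"` or `"anaesthesia"`.
#' @return An object of class `roi_cohort`.
#' @export
roi_cohort <- function(series, roi_labels, tr_seconds, condition = "unknown") {
  stopifnot(is.list(series), length(series) >= 1)
  if (is.null(names(series)) || any(!nzchar(names(series)))) {
    names(series) <- sprintf("S%02d", seq_along(series))
  }
  d <- vapply(series, nrow, integer(1))
  if (length(unique(d)) != 1L) {
    bad <- names(series)[which(d != d[1])[1]]
    stop(sprintf("subject '%s' has %d ROIs; expected %d (dimensional consistency)",
                 bad, d[d != d[1]][1], d[1]), call. = FALSE)
  }
  D <- d[1]
  if (D < 2) stop("a cohort needs at least 2 ROIs", call. = FALSE)
  tt <- vapply(series, ncol, integer(1))
  if (any(tt < 2)) stop("every subject series needs at least 2 volumes", call. = FALSE)
  if (length(roi_labels) != D) {
    stop(sprintf("%d ROI labels for %d ROI rows", length(roi_labels), D), call. = FALSE)
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0) {
    stop("tr_seconds must be a positive scalar", call. = FALSE)
  }
  series <- lapply(series, function(m) {
    rownames(m) <- roi_labels
    m
  })
  structure(
    list(subjects = names(series), series = series,
         roi_labels = as.character(roi_labels),
         tr_seconds = as.numeric(tr_seconds), condition = as.character(condition)),
    class = "roi_cohort")
}

#' @export
print.roi_cohort <- function(x, ...) {
  cat(sprintf("<roi_cohort> condition=%s N=%d D=%d TR=%gs volumes=[%s]\n",
              x$condition, length(x$subjects), length(x$roi_labels), x$tr_seconds,
              paste(range(vapply(x$series, ncol, integer(1))), collapse = "-")))
  invisible(x)
}

#' Read an ROI cohort from per-subject matrix files
#'
#' @param paths Character vector of per-subject TSV paths (rows = ROIs in
#'   label order, columns = volumes).
#' @param roi_label_path Path to a text file with one ROI label per row.
#' @param tr Sampling interval in seconds.
#' @param condition Condition tag.
#' @return An [roi_cohort()].
#' @export
read_roi_cohort <- function(paths, roi_label_path, tr, condition = "unknown") {
  labels <- readLines(roi_label_path)
  labels <- labels[nzchar(labels)]
  series <- lapply(paths, read_matrix_tsv)
  names(series) <- sub("\\.[^.]*$", "", basename(paths))
  d <- vapply(series, nrow, integer(1))
  if (length(unique(d)) != 1L) {
    bad <- paths[which(d != d[1])[1]]
    stop(sprintf("file '%s' has %d rows; other files have %d", bad,
                 d[d != d[1]][1], d[1]), call. = FALSE)
  }
  roi_cohort(series, labels, tr_seconds = tr, condition = condition)
}

#' Write an ROI cohort to a directory of TSV files
#'
#' One `<subject>.tsv` per subject plus `roi_labels.txt` and a small
#' `cohort.json` with TR and condition; [read_cohort_dir()] inverts this
#' exactly.
#'
#' @param cohort An [roi_cohort()].
#' @param dir Output directory (created if needed).
#' @export
write_roi_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    write_matrix_tsv(cohort$series[[s]], file.path(dir, paste0(s, ".tsv")))
  }
  writeLines(cohort$roi_labels, file.path(dir, "roi_labels.txt"))
  jsonlite::write_json(
    list(subjects = cohort$subjects, tr_seconds = cohort$tr_seconds,
         condition = cohort$condition),
    file.path(dir, "cohort.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a cohort written by [write_roi_cohort()]
#' @param dir Directory written by [write_roi_cohort()].
#' @return An [roi_cohort()].
#' @export
read_cohort_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"), simplifyVector = TRUE)
  read_roi_cohort(file.path(dir, paste0(meta$subjects, ".tsv")),
                  file.path(dir, "roi_labels.txt"),
                  tr = meta$tr_seconds, condition = meta$condition)
}

#' Read a weighted structural connectome
#'
#' Loads a square, symmetric, nonnegative adjacency matrix; the diagonal is
#' zeroed on load. If the cohort's label order differs from the connectome
#' file's label order, rows and columns are permuted to match the cohort.
#'
#' @param path Path to the adjacency TSV.
#' @param roi_label_path Path to the connectome's own label file (one label
#'   per row, in the file's row order).
#' @param target_labels Optional character vector giving the ROI order of the
#'   analysis (usually `cohort$roi_labels`); the matrix is reordered to it.
#' @param tol Symmetry tolerance.
#' @return Symmetric nonnegative matrix with dimnames set to the labels.
#' @export
read_connectome <- function(path, roi_label_path, target_labels = NULL, tol = 1e-8) {
  m <- read_matrix_tsv(path)
  labels <- readLines(roi_label_path)
  labels <- labels[nzchar(labels)]
  if (!is_square(m)) stop("connectome must be square", call. = FALSE)
  if (length(labels) != nrow(m)) {
    stop("connectome label count does not match matrix dimension", call. = FALSE)
  }
  assert_symmetric(m, tol = tol, what = "connectome")
  if (any(m < 0)) stop("connectome has negative weights", call. = FALSE)
  m <- zero_diag((m + t(m)) / 2)
  dimnames(m) <- list(labels, labels)
  if (!is.null(target_labels)) {
    if (!setequal(labels, target_labels)) {
      stop("connectome labels do not match cohort ROI labels", call. = FALSE)
    }
    ord <- match(target_labels, labels)
    m <- m[ord, ord]
  }
  m
}

#' Serialize a fitted state model to JSON
#'
#' Writes every parameter (emission means and covariances, transition matrix,
#' initial distribution, projected ROI-space parameters when present) at full
#' precision, so [read_model_json()] reproduces the model exactly.
#'
#' @param model A `fitted_state_model`.
#' @param path Output JSON path.
#' @export
write_model_json <- function(model, path) {
  payload <- list(
    K = model$K, means = model$means,
    covariances = model$covariances,
    transition_matrix = model$transition_matrix,
    initial_distribution = model$initial_distribution,
    loglik_trace = model$loglik_trace,
    n_reinit = model$n_reinit, ridge = model$ridge,
    roi_means = model$roi_means,
    roi_covariances = model$roi_covariances)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a fitted state model written by [write_model_json()]
#' @param path JSON path.
#' @return A `fitted_state_model`.
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat_list <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.array(x) && length(dim(x)) == 3) {
      lapply(seq_len(dim(x)[1]), function(i) x[i, , ])
    } else {
      lapply(x, function(m) do.call(rbind, lapply(m, unlist)))
    }
  }
  structure(list(
    K = as.integer(p$K), means = p$means,
    covariances = as_mat_list(p$covariances),
    transition_matrix = p$transition_matrix,
    initial_distribution = p$initial_distribution,
    loglik_trace = p$loglik_trace,
    n_reinit = as.integer(p$n_reinit), map = NULL, ridge = p$ridge,
    roi_means = p$roi_means,
    roi_covariances = as_mat_list(p$roi_covariances)),
    class = "fitted_state_model")
}

#' Run configuration for the full analysis
#'
#' Collects the tunable parameters of every stage. Defaults follow the study
#' conventions: 20% subject-expression pruning, strong-sink threshold 0.05
#' (inclusive), entropies in bits.
#'
#' @param candidate_K_range Integer vector of candidate model sizes (min >= 2).
#' @param pruning_fraction States expressed in fewer than this fraction of
#'   subjects are removed (default 0.20).
#' @param strong_sink_threshold Stationary-probability cutoff for a "strong"
#'   sink state (default 0.05, inclusive).
#' @param entropy_log_base 2 (bits, default) or `exp(1)` (nats).
#' @param resolution_grid Positive modularity resolutions gamma.
#' @param coupling_grid Positive interlayer coupling scales omega0.
#' @param n_restarts EM restarts per fit.
#' @param n_permutations Permutations for nulls and permutation tests.
#' @param n_consensus_runs Louvain runs per (gamma, omega0) grid point.
#' @param tol,max_iter EM convergence controls.
#' @param seed Global seed; stages derive child seeds via [child_seed()].
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(candidate_K_range = 2:8,
                       pruning_fraction = 0.20,
                       strong_sink_threshold = 0.05,
                       entropy_log_base = 2,
                       resolution_grid = c(0.8, 0.9, 1.0, 1.1, 1.2),
                       coupling_grid = c(0.5, 1.0, 2.0),
                       n_restarts = 5,
                       n_permutations = 100,
                       n_consensus_runs = 20,
                       tol = 1e-4,
                       max_iter = 100,
                       seed = 1L) {
  stopifnot(length(candidate_K_range) >= 1, min(candidate_K_range) >= 2,
            pruning_fraction > 0, pruning_fraction < 1,
            strong_sink_threshold > 0,
            entropy_log_base > 1,
            length(resolution_grid) >= 1, all(resolution_grid > 0),
            length(coupling_grid) >= 1, all(coupling_grid >= 0),
            n_restarts >= 1, n_permutations >= 1, n_consensus_runs >= 1,
            tol > 0, max_iter >= 1)
  structure(list(
    candidate_K_range = as.integer(candidate_K_range),
    pruning_fraction = pruning_fraction,
    strong_sink_threshold = strong_sink_threshold,
    entropy_log_base = entropy_log_base,
    resolution_grid = resolution_grid,
    coupling_grid = coupling_grid,
    n_restarts = as.integer(n_restarts),
    n_permutations = as.integer(n_permutations),
    n_consensus_runs = as.integer(n_consensus_runs),
    tol = tol, max_iter = as.integer(max_iter),
    seed = as.integer(seed)), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; absent keys keep defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals)
}

#' Write a run manifest
#'
#' Records the configuration, seed, package version and stage child seeds of
#' a run, for provenance.
#'
#' @param config A `run_config`.
#' @param stages Character vector of stage labels that were run.
#' @param path Output JSON path.
#' @export
write_manifest <- function(config, stages, path) {
  jsonlite::write_json(list(
    package = "hmgm",
    version = as.character(utils::packageVersion("hmgm")),
    config = unclass(config),
    stage_seeds = setNames(
      lapply(stages, function(s) child_seed(config$seed, s)), stages)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
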