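# Shared plumbing for the numbered analysis scripts: argument parsing, the
# results layout, and the study configuration. Each script is a thin driver
# over the package; all computation lives in the hmgm package itself.

suppressPackageStartupMessages(library(hmgm))

RESULTS <- "results"
CONDITIONS <- c("anaesthesia", "wake")

get_seed <- function() {
  args <- commandArgs(trailingOnly = TRUE)
  i <- which(args == "--seed")
  if (length(i)) as.integer(args[i + 1]) else 1L
}

res_path <- function(...) {
  p <- file.path(RESULTS, ...)
  dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
  p
}

study_cfg <- function(seed) {
  cfg <- study_config()
  cfg$run$seed <- seed
  cfg
}

write_json17 <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
}

write_map_json <- function(map, path) {
  write_json17(unclass(map), path)
}

read_map_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(loadings = p$loadings, pca_center = p$pca_center,
                 center = p$center, scale = p$scale, d = as.integer(p$d),
                 explained_variance = p$explained_variance),
            class = "reduction_map")
}

write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
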