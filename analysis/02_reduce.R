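#!/usr/bin/env Rscript
# Stage 2 -- standardize, concatenate, and reduce each condition.
#
# Every ROI channel is z-scored over the concatenation of all subjects, the
# reduced dimension is selected by Horn parallel analysis (95th percentile of
# column-permuted nulls), and the concatenation is projected onto the leading
# principal components.

source(file.path("analysis", "00_common.R"))
seed <- get_seed()
cfg <- study_cfg(seed)

for (cond in CONDITIONS) {
  cohort <- read_cohort_dir(file.path(RESULTS, "simulate", cond))
  cond_seed <- child_seed(seed, paste0("condition/", cond))
  std <- standardize_concatenate(cohort)
  d <- horn_parallel_analysis(std$data, n_null = cfg$run$n_permutations,
                              seed = child_seed(cond_seed, "parallel"))
  red <- pca_reduce(std$data, d, center = std$center, scale = std$scale)
  write_matrix_tsv(red$reduced, res_path("reduce", cond, "reduced.tsv"))
  write_table_tsv(std$boundaries, res_path("reduce", cond, "boundaries.tsv"))
  write_map_json(red$map, res_path("reduce", cond, "map.json"))
  message(sprintf("[reduce] %s: retained d=%d of D=%d (top eigenvalue %.2f)",
                  cond, d, ncol(std$data), red$map$explained_variance[1]))
}
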