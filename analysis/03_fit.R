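#!/usr/bin/env Rscript
# Stage 3 -- fit Gaussian HMMs, select the model size, prune weak states.
#
# For each condition: every candidate K is fit by restarted Baum-Welch EM on
# the reduced concatenation (recursions restart at subject boundaries), the K
# maximizing the entropy of the group-mean fractional occupancy is kept, and
# states expressed in fewer than 20% of subjects (by Viterbi visits) are
# removed with transition rows restandardized.

source(file.path("analysis", "00_common.R"))
seed <- get_seed()
cfg <- study_cfg(seed)

for (cond in CONDITIONS) {
  data <- read_matrix_tsv(file.path(RESULTS, "reduce", cond, "reduced.tsv"))
  boundaries <- utils::read.delim(file.path(RESULTS, "reduce", cond, "boundaries.tsv"))
  map <- read_map_json(file.path(RESULTS, "reduce", cond, "map.json"))
  cond_seed <- child_seed(seed, paste0("condition/", cond))
  rc <- cfg$run
  rc$seed <- child_seed(cond_seed, "fit")
  sel <- select_model_size(data, boundaries, config = rc, map = map)
  model <- sel$models[[as.character(sel$chosen_K)]]
  decode <- sel$decodes[[as.character(sel$chosen_K)]]
  pr <- prune_states(model, decode, pruning_fraction = rc$pruning_fraction,
                     data = data, boundaries = boundaries)
  write_table_tsv(sel$diagnostics, res_path("fit", cond, "selection.tsv"))
  write_model_json(pr$model, res_path("fit", cond, "model.json"))
  write_matrix_tsv(pr$decode$fo, res_path("fit", cond, "fo.tsv"))
  write_matrix_tsv(do.call(rbind, pr$decode$viterbi),
                   res_path("fit", cond, "viterbi.tsv"))
  message(sprintf(
    "[fit] %s: chose K=%d by occupancy entropy (%.3f bits); %d state(s) pruned -> K=%d",
    cond, sel$chosen_K,
    max(sel$diagnostics$occupancy_entropy), model$K - pr$model$K, pr$model$K))
}
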