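#!/usr/bin/env Rscript
# Stage 1 -- simulate the synthetic study inputs.
#
# Generates the two-condition cohort at the recording scale of the study
# (N = 13 subjects, 63 ROIs, 200 volumes at TR = 3 s): an anaesthesia-like
# condition with a planted sink state (stationary mass 0.4) over static
# covariance blocks, a wake-like condition with more states, uniform
# stationary mass and reshuffled blocks, and a structural connectome whose
# blocks coincide with the anaesthesia-condition functional blocks.

source(file.path("analysis", "00_common.R"))
seed <- get_seed()
cfg <- study_cfg(seed)

inputs <- simulate_study(cfg, seed = seed)

for (cond in CONDITIONS) {
  sc <- inputs[[cond]]
  write_roi_cohort(sc$cohort, res_path("simulate", cond))
  paths <- do.call(rbind, sc$state_paths)
  write_matrix_tsv(paths, res_path("simulate", paste0(cond, "_true_paths.tsv")))
  gt <- sc$model
  write_json17(list(K_true = gt$K_true, sink_index = gt$sink_index,
                    sink_mass = gt$sink_mass,
                    transition_matrix = gt$transition_matrix,
                    stationary = gt$initial_distribution,
                    planted_labels = gt$planted_labels),
               res_path("simulate", paste0(cond, "_ground_truth.json")))
  message(sprintf("[simulate] %s: N=%d D=%d T=%d (true K=%d)", cond,
                  length(sc$cohort$subjects), length(sc$cohort$roi_labels),
                  ncol(sc$cohort$series[[1]]), gt$K_true))
}

write_matrix_tsv(inputs$structure$adjacency, res_path("simulate", "connectome.tsv"))
writeLines(rownames(inputs$structure$adjacency),
           res_path("simulate", "connectome_labels.txt"))
write_table_tsv(data.frame(roi = rownames(inputs$structure$adjacency),
                           block = inputs$structure$partition),
                res_path("simulate", "connectome_planted_blocks.tsv"))
write_manifest(cfg$run, c("gt/anaesthesia", "gt/wake", "cohort/anaesthesia",
                          "cohort/wake", "structure"),
               res_path("simulate", "manifest.json"))
message("[simulate] wrote ", RESULTS, "/simulate")
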