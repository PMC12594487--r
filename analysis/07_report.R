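#!/usr/bin/env Rscript
# Stage 7 -- gather the stage outputs into one report.
#
# Collects model sizes, sink centralities, complexity measures and
# structure-function similarities per condition, plus the condition-contrast
# rank tests, into results/report.json, and prints a short narrative.

source(file.path("analysis", "00_common.R"))
seed <- get_seed()

report <- list(seed = seed)
for (cond in CONDITIONS) {
  dyn <- jsonlite::read_json(file.path(RESULTS, "dynamics", paste0(cond, ".json")),
                             simplifyVector = TRUE)
  cmp <- utils::read.delim(file.path(RESULTS, "compare", paste0(cond, ".tsv")))
  sel <- utils::read.delim(file.path(RESULTS, "fit", cond, "selection.tsv"))
  model <- read_model_json(file.path(RESULTS, "fit", cond, "model.json"))
  frac <- read_matrix_tsv(file.path(RESULTS, "communities", cond,
                                    "fractional_membership.tsv"))
  report[[cond]] <- list(
    chosen_K = max(sel$K[sel$occupancy_entropy >= max(sel$occupancy_entropy) - 1e-12][1]),
    n_states_after_pruning = model$K,
    max_sink_centrality = max(dyn$stationary_distribution),
    n_strong_sinks = length(dyn$strong_sinks),
    entropy_rate_bits = dyn$entropy_rate_bits,
    mean_switching_rate_hz = mean(dyn$switching_rate_hz),
    mean_occupancy_entropy = mean(dyn$occupancy_entropy),
    mean_max_fractional_membership = mean(apply(frac, 1, max)),
    mean_ami_vs_structure = mean(cmp$ami),
    mean_edge_dcor_vs_structure = mean(cmp$edge_dcor))
}
report$contrasts <- jsonlite::read_json(file.path(RESULTS, "compare", "contrasts.json"),
                                        simplifyVector = TRUE)
jsonlite::write_json(report, res_path("report.json"), auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

an <- report$anaesthesia; wk <- report$wake
message(sprintf("states after pruning:      anaesthesia %d vs wake %d",
                an$n_states_after_pruning, wk$n_states_after_pruning))
message(sprintf("max sink centrality:       anaesthesia %.3f vs wake %.3f",
                an$max_sink_centrality, wk$max_sink_centrality))
message(sprintf("entropy rate (bits):       anaesthesia %.3f vs wake %.3f",
                an$entropy_rate_bits, wk$entropy_rate_bits))
message(sprintf("mean AMI vs structure:     anaesthesia %.3f vs wake %.3f (p=%.2g)",
                an$mean_ami_vs_structure, wk$mean_ami_vs_structure,
                report$contrasts$ami$p_value))
message(sprintf("mean edge dcor:            anaesthesia %.3f vs wake %.3f (p=%.2g)",
                an$mean_edge_dcor_vs_structure, wk$mean_edge_dcor_vs_structure,
                report$contrasts$edge_dcor$p_value))
message("wrote ", RESULTS, "/report.json")
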