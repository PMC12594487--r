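#!/usr/bin/env Rscript
# Stage 6 -- compare dynamic state graphs with the structural connectome.
#
# The structural partition comes from the same robust single-layer consensus
# machinery; each state's consensus modules are scored against it by AMI and
# ARI, and edge weights / local efficiency / degree centrality by distance
# correlation. Condition contrasts use two-sided rank tests.

source(file.path("analysis", "00_common.R"))
seed <- get_seed()
cfg <- study_cfg(seed)

structure_w <- read_connectome(file.path(RESULTS, "simulate", "connectome.tsv"),
                               file.path(RESULTS, "simulate", "connectome_labels.txt"))
struct_part <- single_layer_modularity_partition(
  structure_w, resolution_grid = cfg$run$resolution_grid,
  n_runs = cfg$run$n_consensus_runs,
  seed = child_seed(seed, "structure/partition"))
write_table_tsv(data.frame(roi = rownames(structure_w), community = struct_part$labels),
                res_path("compare", "structural_partition.tsv"))
message(sprintf("[compare] structural graph: %d communities (Q=%.3f)",
                length(unique(struct_part$labels)), struct_part$Q))

rows <- list()
for (cond in CONDITIONS) {
  model <- read_model_json(file.path(RESULTS, "fit", cond, "model.json"))
  sg <- state_graphs(model)
  cmp_seed <- child_seed(seed, paste0("compare/", cond))
  cmp <- do.call(rbind, lapply(sg, function(st) {
    compare_state_to_structure(st, structure_w, struct_part$labels,
                               resolution_grid = cfg$run$resolution_grid,
                               n_runs = cfg$run$n_consensus_runs,
                               seed = child_seed(cmp_seed, paste0("state", st$state)))
  }))
  cmp$condition <- cond
  write_table_tsv(cmp, res_path("compare", paste0(cond, ".tsv")))
  rows[[cond]] <- cmp
  message(sprintf("[compare] %s: mean AMI vs structure %.3f; mean edge dcor %.3f",
                  cond, mean(cmp$ami), mean(cmp$edge_dcor)))
}

contrasts <- list(
  ami = rank_tests(rows$anaesthesia$ami, rows$wake$ami),
  edge_dcor = rank_tests(rows$anaesthesia$edge_dcor, rows$wake$edge_dcor),
  local_efficiency_dcor = rank_tests(rows$anaesthesia$local_efficiency_dcor,
                                     rows$wake$local_efficiency_dcor),
  degree_dcor = rank_tests(rows$anaesthesia$degree_dcor, rows$wake$degree_dcor))
write_json17(contrasts, res_path("compare", "contrasts.json"))
message(sprintf("[compare] condition contrasts: AMI p=%.2g, edge dcor p=%.2g",
                contrasts$ami$p_value, contrasts$edge_dcor$p_value))
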