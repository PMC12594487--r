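#!/usr/bin/env Rscript
# Stage 5 -- spatiotemporal consensus communities on the HMGM.
#
# Builds the multilayer hidden Markov graph model (states as layers, absolute
# ROI correlations within layers, symmetrized transition probabilities as
# coupling), optimizes the multilayer modularity with generalized Louvain
# over the (gamma, omega0) grid, aggregates by consensus clustering, and
# derives fractional memberships plus layer/region dendrograms.

source(file.path("analysis", "00_common.R"))
seed <- get_seed()
cfg <- study_cfg(seed)

for (cond in CONDITIONS) {
  model <- read_model_json(file.path(RESULTS, "fit", cond, "model.json"))
  cond_seed <- child_seed(seed, paste0("condition/", cond))
  h <- build_hmgm(model)
  cons <- consensus_communities(h, resolution_grid = cfg$run$resolution_grid,
                                coupling_grid = cfg$run$coupling_grid,
                                n_runs = cfg$run$n_consensus_runs,
                                seed = child_seed(cond_seed, "communities"))
  labels <- cons$partition$labels
  part_df <- data.frame(
    roi = rep(rownames(labels), times = ncol(labels)),
    state = rep(seq_len(ncol(labels)), each = nrow(labels)),
    community = as.vector(labels))
  write_table_tsv(part_df, res_path("communities", cond, "partition.tsv"))
  frac <- fractional_membership(cons$partition, h$pi)
  write_matrix_tsv(frac, res_path("communities", cond, "fractional_membership.tsv"))
  write_matrix_tsv(cons$coclassification,
                   res_path("communities", cond, "coclassification.tsv"))
  if (model$K >= 2) {
    layer_tree <- cluster_layers(cons$partition)$tree
    region_tree <- cluster_regions(cons$partition)$tree
    writeLines(ape::write.tree(ape::as.phylo(layer_tree)),
               res_path("communities", cond, "layers.nwk"))
    writeLines(ape::write.tree(ape::as.phylo(region_tree)),
               res_path("communities", cond, "regions.nwk"))
  }
  message(sprintf(
    "[communities] %s: %d spatiotemporal communities over %d node-layers (Q=%.3f); mean max fractional membership %.3f",
    cond, length(unique(as.vector(labels))), length(labels),
    cons$partition$Q, mean(apply(frac, 1, max))))
}
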