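#!/usr/bin/env Rscript
# Stage 4 -- Markov-chain dynamics of the fitted models.
#
# Sink centrality (stationary probability), strong sinks at the inclusive
# 0.05 threshold, per-subject switching rates and normalized occupancy
# entropies, the model entropy (information) rate in bits, and the subject
# clustering by FO correlation.

source(file.path("analysis", "00_common.R"))
seed <- get_seed()
cfg <- study_cfg(seed)

for (cond in CONDITIONS) {
  model <- read_model_json(file.path(RESULTS, "fit", cond, "model.json"))
  fo <- read_matrix_tsv(file.path(RESULTS, "fit", cond, "fo.tsv"))
  vit <- read_matrix_tsv(file.path(RESULTS, "fit", cond, "viterbi.tsv"))
  boundaries <- utils::read.delim(file.path(RESULTS, "reduce", cond, "boundaries.tsv"))
  rownames(fo) <- boundaries$subject
  decode <- list(fo = fo,
                 viterbi = setNames(lapply(seq_len(nrow(vit)), function(i) vit[i, ]),
                                    boundaries$subject))
  dyn <- summarize_dynamics(model, decode, tr_seconds = cfg$tr, config = cfg$run)
  write_json17(list(
    stationary_distribution = dyn$stationary_distribution,
    strong_sinks = dyn$strong_sinks,
    switching_rate_hz = dyn$switching_rate,
    entropy_rate_bits = dyn$entropy_rate,
    occupancy_entropy = dyn$occupancy_entropy,
    subject_clusters = if (!is.null(dyn$subject_clustering))
      dyn$subject_clustering$clusters else NULL),
    res_path("dynamics", paste0(cond, ".json")))
  message(sprintf(
    "[dynamics] %s: max sink centrality %.3f (%d strong sink(s)); entropy rate %.3f bits; mean switching %.3f Hz",
    cond, max(dyn$stationary_distribution), length(dyn$strong_sinks),
    dyn$entropy_rate, mean(dyn$switching_rate)))
}
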