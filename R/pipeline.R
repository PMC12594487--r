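# End-to-end synthetic study: simulate two conditions at the recording scale
# of the anaesthesia study (N = 13 subjects, D = 63 ROIs, T = 200 volumes at
# TR = 3 s), run reduction -> HMM fit/selection/pruning -> chain dynamics ->
# spatiotemporal communities -> structure comparison, and report the
# condition contrasts.

#' Default configuration of the synthetic study
#'
#' The generator scale matches the study's recordings: 13 subjects, 63 ROIs,
#' 200 volumes per condition at TR = 3 s. The anaesthesia-like condition
#' plants a dominant sink state (stationary mass 0.4, emulating the observed
#' 0.38-dominant state) over static covariance blocks aligned with the
#' structural connectome; the wake-like condition has more states, a uniform
#' stationary distribution, and block assignments reshuffled in every state.
#'
#' @param N,D,T_len,tr Cohort scale.
#' @param block_sizes Planted community sizes (must sum to D).
#' @param K_true_wake,K_true_anaes Planted state counts.
#' @param sink_mass Planted stationary mass of the anaesthesia sink state.
#' @param separation State-mean separation in emission-sd units.
#' @param obs_noise Isotropic observation noise sd.
#' @param connectome_noise Between-block structural weight scale.
#' @param run A [run_config()].
#' @return A list of class `study_config`.
#' @export
study_config <- function(N = 13, D = 63, T_len = 200, tr = 3,
                         block_sizes = c(11, 11, 11, 10, 10, 10),
                         K_true_wake = 8, K_true_anaes = 5,
                         sink_mass = 0.4, separation = 3, obs_noise = 0.5,
                         connectome_noise = 0.1,
                         run = run_config()) {
  stopifnot(sum(block_sizes) == D)
  structure(list(N = N, D = D, T_len = T_len, tr = tr,
                 block_sizes = block_sizes,
                 K_true_wake = K_true_wake, K_true_anaes = K_true_anaes,
                 sink_mass = sink_mass, separation = separation,
                 obs_noise = obs_noise, connectome_noise = connectome_noise,
                 run = run), class = "study_config")
}

#' Simulate the two-condition study inputs
#'
#' @param config A [study_config()].
#' @param seed Integer seed.
#' @return List: `anaesthesia` and `wake` (`synthetic_cohort`s),
#'   `structure` (connectome aligned with the anaesthesia blocks),
#'   `ground_truth` (both planted models).
#' @export
simulate_study <- function(config = study_config(), seed = 1) {
  gt_anaes <- make_ground_truth(config$K_true_anaes, config$D,
                                sink_mass = config$sink_mass,
                                block_sizes = config$block_sizes,
                                separation = config$separation,
                                seed = child_seed(seed, "gt/anaesthesia"),
                                shuffle_blocks = FALSE)
  gt_wake <- make_ground_truth(config$K_true_wake, config$D,
                               sink_mass = NULL,
                               block_sizes = config$block_sizes,
                               separation = config$separation,
                               seed = child_seed(seed, "gt/wake"),
                               shuffle_blocks = TRUE)
  list(
    anaesthesia = simulate_cohort(gt_anaes, config$N, config$T_len,
                                  tr = config$tr, obs_noise = config$obs_noise,
                                  seed = child_seed(seed, "cohort/anaesthesia"),
                                  condition = "anaesthesia"),
    wake = simulate_cohort(gt_wake, config$N, config$T_len,
                           tr = config$tr, obs_noise = config$obs_noise,
                           seed = child_seed(seed, "cohort/wake"),
                           condition = "wake"),
    structure = make_structural_connectome(config$block_sizes,
                                           align_with = gt_anaes,
                                           noise = config$connectome_noise,
                                           seed = child_seed(seed, "structure")),
    ground_truth = list(anaesthesia = gt_anaes, wake = gt_wake))
}

#' Run the full analysis chain on one condition
#'
#' Standardize and concatenate; select the reduced dimension by parallel
#' analysis; PCA-reduce; select K by maximum occupancy entropy; prune weakly
#' expressed states; summarize chain dynamics; build the HMGM and detect
#' consensus spatiotemporal communities; compute per-state graphs.
#'
#' @param cohort An [roi_cohort()].
#' @param config A [study_config()].
#' @param seed Integer seed for this condition.
#' @return List with every stage's artifact: `reduction` (map, d),
#'   `selection` diagnostics, `model`, `decode`, `pruning`, `dynamics`,
#'   `hmgm`, `communities`, `fractional_membership`, `state_graphs`,
#'   `state_metrics` (per-state excitability and normalized efficiency).
#' @export
run_condition <- function(cohort, config = study_config(), seed = 1) {
  rc <- config$run
  std <- standardize_concatenate(cohort)
  d <- horn_parallel_analysis(std$data, n_null = rc$n_permutations,
                              seed = child_seed(seed, "parallel"))
  red <- pca_reduce(std$data, d, center = std$center, scale = std$scale)
  rc_fit <- rc
  rc_fit$seed <- child_seed(seed, "fit")
  sel <- select_model_size(red$reduced, std$boundaries, config = rc_fit,
                           map = red$map)
  model <- sel$models[[as.character(sel$chosen_K)]]
  decode <- sel$decodes[[as.character(sel$chosen_K)]]
  pr <- prune_states(model, decode, pruning_fraction = rc$pruning_fraction,
                     data = red$reduced, boundaries = std$boundaries)
  dyn <- summarize_dynamics(pr$model, pr$decode, cohort$tr_seconds, config = rc)
  h <- build_hmgm(pr$model)
  cons <- consensus_communities(h, resolution_grid = rc$resolution_grid,
                                coupling_grid = rc$coupling_grid,
                                n_runs = rc$n_consensus_runs,
                                seed = child_seed(seed, "communities"))
  frac <- fractional_membership(cons$partition, dyn$stationary_distribution)
  sg <- state_graphs(pr$model)
  metrics <- data.frame(
    state = seq_along(sg),
    excitability = vapply(sg, function(s) excitability(s$activity), numeric(1)),
    normalized_efficiency = vapply(seq_along(sg), function(k) {
      normalized_global_efficiency(sg[[k]]$weights,
                                   n_permutations = rc$n_permutations,
                                   seed = child_seed(seed, paste0("eff", k)))
    }, numeric(1)))
  list(condition = cohort$condition, boundaries = std$boundaries,
       reduction = list(d = d, map = red$map),
       selection = sel$diagnostics, chosen_K = sel$chosen_K,
       model = pr$model, decode = pr$decode,
       pruning = list(kept = pr$kept, subject_fraction = pr$subject_fraction),
       dynamics = dyn, hmgm = h, communities = cons,
       fractional_membership = frac, state_graphs = sg,
       state_metrics = metrics)
}

#' Compare a fitted condition with the structural connectome
#'
#' Per-state consensus partitions (same robust machinery as for structure)
#' are scored against the structural partition by AMI/ARI; edge weights and
#' node profiles by distance correlation.
#'
#' @param condition_result Output of [run_condition()].
#' @param structure_weights Structural adjacency.
#' @param structure_partition Structural community labels (from
#'   [single_layer_modularity_partition()]).
#' @param config A [study_config()].
#' @param seed Integer seed.
#' @return Data frame with one [compare_state_to_structure()] row per state.
#' @export
compare_condition_to_structure <- function(condition_result, structure_weights,
                                           structure_partition,
                                           config = study_config(), seed = 1) {
  rc <- config$run
  rows <- lapply(condition_result$state_graphs, function(st) {
    compare_state_to_structure(
      st, structure_weights, structure_partition,
      resolution_grid = rc$resolution_grid, n_runs = rc$n_consensus_runs,
      seed = child_seed(seed, paste0("state", st$state)))
  })
  do.call(rbind, rows)
}

#' Run the complete synthetic study
#'
#' Simulates both conditions and the structural connectome, runs the full
#' analysis chain per condition, and assembles the condition contrasts
#' (dynamics rank tests, structure-function rank tests).
#'
#' @param seed Global integer seed.
#' @param config A [study_config()].
#' @return A `study_result`: `inputs`, per-condition results, `structure`
#'   (including its consensus partition), `comparison` (per-state rows for
#'   both conditions), and `contrasts` (rank-test results).
#' @export
run_study <- function(seed = 1, config = study_config()) {
  inputs <- simulate_study(config, seed = seed)
  res_an <- run_condition(inputs$anaesthesia$cohort, config,
                          seed = child_seed(seed, "condition/anaesthesia"))
  res_wk <- run_condition(inputs$wake$cohort, config,
                          seed = child_seed(seed, "condition/wake"))
  struct_part <- single_layer_modularity_partition(
    inputs$structure$adjacency,
    resolution_grid = config$run$resolution_grid,
    n_runs = config$run$n_consensus_runs,
    seed = child_seed(seed, "structure/partition"))
  cmp_an <- compare_condition_to_structure(res_an, inputs$structure$adjacency,
                                           struct_part$labels, config,
                                           seed = child_seed(seed, "compare/anaesthesia"))
  cmp_wk <- compare_condition_to_structure(res_wk, inputs$structure$adjacency,
                                           struct_part$labels, config,
                                           seed = child_seed(seed, "compare/wake"))
  contrasts <- list(
    switching_rate = rank_tests(res_wk$dynamics$switching_rate,
                                res_an$dynamics$switching_rate, paired = TRUE),
    occupancy_entropy = rank_tests(res_wk$dynamics$occupancy_entropy,
                                   res_an$dynamics$occupancy_entropy, paired = TRUE),
    ami_vs_structure = rank_tests(cmp_an$ami, cmp_wk$ami),
    edge_dcor_vs_structure = rank_tests(cmp_an$edge_dcor, cmp_wk$edge_dcor))
  structure(list(seed = seed, config = config, inputs = inputs,
                 anaesthesia = res_an, wake = res_wk,
                 structure_partition = struct_part,
                 comparison = list(anaesthesia = cmp_an, wake = cmp_wk),
                 contrasts = contrasts), class = "study_result")
}

#' Flatten the headline numbers of a study run
#'
#' @param study A `study_result`.
#' @return Named list of scalar summaries (state counts, sink centralities,
#'   entropy rates, switching rates, structure-function similarities,
#'   contrast p-values).
#' @export
study_summary <- function(study) {
  an <- study$anaesthesia
  wk <- study$wake
  fo_an <- colMeans(an$decode$fo)
  top2 <- order(fo_an, decreasing = TRUE)[1:2]
  fo_corr_top2 <- if (an$model$K >= 2) {
    cor(an$decode$fo[, top2[1]], an$decode$fo[, top2[2]])
  } else NA_real_
  list(
    n_states_anaesthesia = an$model$K,
    n_states_wake = wk$model$K,
    max_sink_centrality_anaesthesia = max(an$dynamics$stationary_distribution),
    max_sink_centrality_wake = max(wk$dynamics$stationary_distribution),
    n_strong_sinks_anaesthesia = length(an$dynamics$strong_sinks),
    n_strong_sinks_wake = length(wk$dynamics$strong_sinks),
    entropy_rate_anaesthesia_bits = an$dynamics$entropy_rate,
    entropy_rate_wake_bits = wk$dynamics$entropy_rate,
    mean_switching_rate_anaesthesia_hz = mean(an$dynamics$switching_rate),
    mean_switching_rate_wake_hz = mean(wk$dynamics$switching_rate),
    mean_occupancy_entropy_anaesthesia = mean(an$dynamics$occupancy_entropy),
    mean_occupancy_entropy_wake = mean(wk$dynamics$occupancy_entropy),
    fo_correlation_top2_anaesthesia = fo_corr_top2,
    mean_ami_structure_anaesthesia = mean(study$comparison$anaesthesia$ami),
    mean_ami_structure_wake = mean(study$comparison$wake$ami),
    mean_edge_dcor_structure_anaesthesia = mean(study$comparison$anaesthesia$edge_dcor),
    mean_edge_dcor_structure_wake = mean(study$comparison$wake$edge_dcor),
    switching_rate_contrast_p = study$contrasts$switching_rate$p_value,
    occupancy_entropy_contrast_p = study$contrasts$occupancy_entropy$p_value,
    ami_contrast_p = study$contrasts$ami_vs_structure$p_value,
    edge_dcor_contrast_p = study$contrasts$edge_dcor_vs_structure$p_value)
}
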