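# hmgm — hidden Markov graph models of dynamic brain states

`hmgm` is an R package and analysis workflow for studying how the brain's
dynamic functional organization differs between conditions of consciousness
— resting wakefulness versus deep anaesthesia — from multi-subject ROI BOLD
fMRI time series. It implements the full chain from raw ROI series to
condition contrasts:

1. **Reduction.** Per-ROI z-scoring over the concatenated subjects, reduced
   dimension chosen by Horn parallel analysis, projection onto principal
   components.
2. **Brain-state modelling.** Gaussian hidden Markov models fit by
   restarted Baum–Welch EM with subject-boundary-aware recursions; the
   number of states `K` is selected by maximizing the entropy of the
   group-mean fractional occupancy (FO); states expressed in fewer than 20%
   of subjects are pruned and transition rows restandardized.
3. **Chain dynamics.** Sink centrality (the stationary probability `pi_k`
   of each state, with "strong" sinks at `pi_k >= 0.05`), per-subject
   switching rate (state changes per second along the Viterbi path), the
   entropy (information) rate
   `H = -sum_k pi_k sum_j P_kj log2 P_kj` as a temporal-complexity proxy,
   normalized occupancy entropy `H(FO)/log K`, and Ward clustering of
   subjects by FO correlation.
4. **Spatiotemporal communities.** The hidden Markov graph model (HMGM): a
   multilayer graph with one layer per state over the same ROI nodes,
   absolute state correlations as intralayer edges and symmetrized
   transition probabilities as interlayer coupling. Communities of
   (ROI, state) node-layers maximize the multilayer modularity
   `Q = (1/2mu) sum_ijs [A_ijs - gamma k_is k_js / 2m_s] delta(g_is, g_js)
   + (1/2mu) sum_{i, s != r} omega_sr delta(g_is, g_ir)`
   via generalized Louvain, aggregated by consensus clustering over a
   `(gamma, omega0)` grid; fractional membership
   `F_ic = sum_s pi_s 1[g_is = c]` summarizes how statically each region
   belongs to each community.
5. **Structure–function comparison.** Distance correlation of edge weights,
   robust local efficiency and degree centrality against a weighted
   structural connectome; AMI/ARI of consensus partitions; permutation and
   two-sided rank tests for the condition contrasts.

Because the study's subject fMRI is not deposited, the package ships a
first-class synthetic-cohort generator (`make_ground_truth()`,
`simulate_cohort()`, `make_structural_connectome()`) that plants the
structure the analysis assumes — Gaussian states, a dominant sink state
for the anaesthesia-like condition, block covariance communities, and a
structural connectome aligned (or not) with them — so every stage can be
validated against ground truth.

## Worked example

```r
library(hmgm)

# plant a 4-state model with a dominant sink (stationary mass 0.4)
gt <- make_ground_truth(K_true = 4, D = 12, sink_mass = 0.4,
                        block_sizes = c(6, 6), separation = 3, seed = 1)
sc <- simulate_cohort(gt, N = 13, T_len = 300, obs_noise = 0.2, seed = 2)

std <- standardize_concatenate(sc$cohort)
m <- fit_hmm(std$data, std$boundaries, K = 4, n_restarts = 2, seed = 3)
pi_hat <- stationary_distribution(m$transition_matrix)
round(sort(pi_hat, decreasing = TRUE), 3)
#> [1] 0.397 0.203 0.202 0.198
classify_strong_sinks(pi_hat)          # all four exceed 0.05 at this small K
#> [1] 1 2 3 4
entropy_rate(m$transition_matrix)      # bits; the log2(4) = 2 ceiling would
#> [1] 1.35031                          # be attained by a uniform chain
```

The largest recovered sink centrality (0.397) matches the planted mass 0.4;
the entropy rate of the sink-dominated chain sits well below that of a
uniform chain of the same size, the package's synthetic analogue of the
lower information rate under anaesthesia.

The full two-condition study (N = 13 subjects, D = 63 ROIs, T = 200 volumes
per condition at TR = 3 s) runs as a numbered script sequence, each stage a
thin driver over the package that writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R          --seed 1   # cohorts + connectome
Rscript analysis/02_reduce.R            --seed 1   # z-score, parallel analysis, PCA
Rscript analysis/03_fit.R               --seed 1   # HMMs, K selection, pruning
Rscript analysis/04_dynamics.R          --seed 1   # sinks, switching, entropy rate
Rscript analysis/05_communities.R       --seed 1   # HMGM consensus communities
Rscript analysis/06_compare_structure.R --seed 1   # structure-function comparison
Rscript analysis/07_report.R            --seed 1   # gather results/report.json
```

With seed 1 the report stage prints, among other lines:

```
max sink centrality:       anaesthesia 0.300 vs wake 0.136
entropy rate (bits):       anaesthesia 1.827 vs wake 2.082
mean AMI vs structure:     anaesthesia 0.789 vs wake 0.015 (p=0.00085)
mean edge dcor:            anaesthesia 0.912 vs wake 0.034 (p=0.00016)
```

i.e. the anaesthesia-like condition (static, structure-aligned planted
communities and a planted sink) is recovered as markedly more
structure-like than the wake-like condition (reshuffled communities,
uniform dynamics), and its dominant state carries the largest share of the
stationary mass.

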