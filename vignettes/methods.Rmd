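---
title: "Methods: brain-state HMMs, sink dynamics, and spatiotemporal communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-state HMMs, sink dynamics, and spatiotemporal communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters, and numerical choices behind
`hmgm`, in the spirit of the long-form methods sections that accompany other
model-based analysis packages. Nothing here reports an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The generative picture

Each subject's recording is a D-channel ROI BOLD series sampled at a fixed
TR. The working model is that, at every volume, the brain occupies one of K
hidden states; state `k` emits a D-variate Gaussian with mean `mu_k` (the
state's activity map) and covariance `Sigma_k` (its functional
connectivity), and states succeed one another as a first-order Markov chain
with row-stochastic transition matrix `P`. The HMM is a stationary model, so
the analysis targets resting conditions held stable over a recording —
baseline wakefulness or a maintained level of deep anaesthesia — rather than
transitions between them.

Three derived layers of structure carry the scientific contrasts:

* **Chain dynamics.** The stationary distribution `pi` of `P` is read as a
  centrality over states ("sink centrality"); a state with `pi_k >= 0.05`
  (inclusive) is a *strong sink*. Temporal complexity is measured by the
  entropy (information) rate `H = -sum_k pi_k sum_j P_kj log P_kj`, the
  switching rate of the best-fit (Viterbi) path in Hz, and the normalized
  entropy of each subject's fractional occupancy (FO).
* **The HMGM.** The fitted model is recast as a multilayer graph: one layer
  per state over the same D ROI nodes, intralayer weights `A_s` equal to the
  absolute ROI-space correlation of `Sigma_s` (zero diagonal), and
  node-aligned interlayer coupling `omega_sr = omega0 (P_sr + P_rs) / 2`.
  Spatiotemporal communities are partitions of the D x K node-layers
  maximizing the multilayer Newman-Girvan modularity with a per-layer null
  (resolution `gamma`) plus the coupling reward.
* **Structure-function comparison.** Every state graph is scored against a
  weighted structural connectome: distance correlation of upper-triangle
  edge weights and of node profiles (robust local efficiency, strength), and
  AMI/ARI between the state's consensus modules and the structural modules.

## Pipeline stages and their parameters

**Standardization.** All subjects are concatenated in time and each ROI
channel is z-scored over the concatenation (not per subject); a subject
boundary index preserves the segmentation. A constant channel is an error
(it carries no signal and breaks the scaling).

**Dimension selection and reduction.** Horn parallel analysis on the
correlation spectrum: the retained dimension `d` counts the leading sample
eigenvalues exceeding the 95th percentile of eigenvalues from data with
every column independently permuted (`n_null = 100` by default). The
permutation null preserves marginals, which matters for heavy-tailed BOLD
summaries; Gaussian resampling was the obvious alternative and is not
exposed. Counting stops at the first failing eigenvalue and `d >= 1` is
enforced. PCA is plain (no whitening): components keep their variances, so
the HMM's covariances remain interpretable on the component scale; the
choice is recorded in the run manifest.

**HMM fitting.** Maximum-likelihood Baum-Welch EM rather than variational
Bayes: the state-space semantics are identical, every quantity downstream
depends only on point parameters, and ML-EM is verifiable against
closed-form oracles. A `prior_strength` pseudo-count on transitions is
exposed for MAP shrinkage emulating a variational prior (default 0).
Details that matter:

* Restarts (`n_restarts = 5`): k-means initialized means (3 k-means starts),
  pooled covariance, sticky transitions (0.8 self). The best final log
  likelihood wins.
* Recursions are scaled (Rabiner) and restart at every subject boundary;
  no transition is counted across subjects, and decoding a concatenation
  equals decoding each subject alone.
* Covariances carry a `1e-6` diagonal ridge, guaranteeing positive
  definiteness at small T. The ridge makes the M-step infinitesimally
  off-ML, so the monotonicity contract on the log-likelihood trace is
  asserted to `1e-8` relative rather than exactly.
* Convergence: an iteration gaining less than `tol * max(1, |loglik|)`
  stops the run (`tol = 1e-4` by default; recovery experiments in the test
  suite tighten this to `1e-6`-`1e-7`).
* A state whose responsibility mass falls below one observation is
  reinitialized from a random data row; the event is counted
  (`$n_reinit`) and the trace may then dip.

**Model-size selection and pruning.** For each candidate K the entropy of
the group-mean FO is computed; the argmax wins, ties toward the smaller
model. This selection deliberately favors larger models; robustness is
restored by pruning: a state "appears" in a subject iff the subject's
Viterbi path visits it at least once (a deterministic rule; an FO-threshold
variant would be the natural alternative), and states appearing in fewer
than 20% of subjects are deleted with surviving transition rows and the
initial distribution renormalized. Decoding is recomputed under the pruned
model, and all dynamics (including the entropy rate) are computed from the
pruned, restandardized matrix.

**Stationary distributions.** Computed by power iteration on the lazy chain
`(P + I) / 2` from the uniform start — the Cesaro (time-average) limit.
This converges for periodic chains and returns a well-defined occupancy
vector for reducible matrices, which pruning can create; for irreducible
inputs it satisfies `pi P = pi` to 1e-10. Entropies default to base 2
(bits); the base is configurable to nats. The switching-rate denominator is
`(T - 1) * TR` — transitions, not samples — giving a ceiling of `1/TR` Hz.

**Generalized Louvain and consensus.** The modularity kernel is exposed as
a single function (`multilayer_modularity`) and optimized by a dense-matrix
generalized Louvain: local moves in seeded-random node order (best positive
gain, ties to the lowest community index), community aggregation, and a
final node-level refinement pass; deterministic given its seed, and on toy
instances it is validated against exhaustive enumeration of all set
partitions. Consensus runs the optimizer over
`gamma in {0.8, 0.9, 1.0, 1.1, 1.2}`, `omega0 in {0.5, 1.0, 2.0}` and 20
seeds per grid point, thresholds the co-classification matrix at the mean
co-classification of a label-permuted null, and re-clusters until all runs
agree (cap 50 iterations, warning on non-convergence). For uniformly
permuted labels the mean of the permuted co-classification matrix is the
same for every permutation — the pair-agreement rate
`sum_c n_c (n_c - 1) / (n (n - 1))` of each run's label multiset — so the
null mean is computed in closed form rather than by Monte Carlo. All layer
pairs with positive symmetrized transition probability are coupled; no
probability floor is applied.

**Graph metrics.** Efficiency uses edge lengths `1/w`; the permutation
null shuffles the upper-triangle weight multiset only (no degree
preservation — the literal reading of a "randomly permuted edge weights"
null) with 100 seeded shuffles. The robust local efficiency weights each
neighbor pair by the cube root of the incident weights and measures
neighborhood paths on cube-rooted lengths, reducing to the classic binary
local efficiency on 0/1 graphs. Metrics default to absolute-correlation
weights, with signed Pearson matrices retained for sensitivity
comparisons. AMI uses the hypergeometric expected-MI correction with
`max(H_a, H_b)` normalization (recorded in output metadata; the arithmetic
mean is the common alternative). Permutation tests use the add-one
estimator `(1 + #extreme) / (1 + n_perm)`, which cannot return zero. The
condition contrast on AMI-vs-structure is implemented as a state-label
permutation across conditions — an assumption, flagged as such.

## The synthetic cohort: what it emulates, and what it does not

The generator's defaults are the study conditions: N = 13 subjects, D = 63
ROIs, T = 200 volumes per condition at TR = 3 s. The anaesthesia-like
condition plants K = 5 states with a dominant sink at stationary mass 0.4
(emulating the observed single state near 0.4), static covariance blocks
shared by all states, and a structural connectome aligned with those
blocks. The wake-like condition plants K = 8 states, a symmetric transition
matrix (uniform stationary mass), and block assignments reshuffled
independently in every state, so its communities reorganize across layers
and decouple from structure. The sink construction fixes the sink
self-transition at 0.9 and routes the incoming probability
`a = (1 - 0.9) m / (1 - m)` from every other row, which balances the
stationary flow at exactly the target mass `m`; the result is verified
against the eigen-solution at build time. State means are orthonormal
directions scaled by `separation` (default 3 emission standard deviations);
covariances are constant-correlation blocks (0.6 within, 0.15 between — a
4x contrast, comfortably above the 3x floor the generator enforces) and
are positive definite by construction. Observation noise is isotropic
(default sd 0.5); a shared generative model is used for all subjects —
per-subject heterogeneity of the transition matrix is a real feature of
cohort data that the defaults do not emulate.

Not emulated, by design: hemodynamic convolution, scanner drift, motion,
subject-specific anatomy, and any EEG-based exclusion. Passing tests on
this generator therefore show that the pipeline recovers the structure the
model class assumes when it is present at realistic scale and noise — not
that real fMRI satisfies those assumptions.

## Problem sizes used by the validation suite

The suite exercises each claim at the smallest scale at which it is
meaningful: parameter recovery at K = 4, D = 10, N = 8, T = 300;
planted-sink recovery at K = 4, D = 12, N = 13, T = 300 over 20 seeds
(at N * T below roughly 2,000 the planted mass itself fluctuates by more
than the +/-0.05 recovery band, so the subject count matches the study and
T extends to 300); the no-strong-sink control at K = 32, D = 32 — mirroring
the study's larger wakeful models, whose uniform mass 1/32 sits below the
0.05 threshold with margin for estimation noise; community recovery on
12-ROI, 3-state instances over 20 seeds; modularity oracles on instances of
at most 10 node-layers, where exhaustive enumeration of all partitions is
feasible; and the full default-scale study twice for bit-identical
reproducibility. Each stochastic experiment draws its seeds from the single
global seed via the stage-labelled child-seed scheme.

## Known limitations

* ML-EM with restarts can still land in local optima at large K; the
  degenerate-state reinitialization mitigates but does not eliminate this.
* The occupancy-entropy selection rule has no penalty for K, so the chosen
  K tends toward the top of the candidate range; pruning, not selection,
  provides parsimony. On sink-dominated synthetic data this can split the
  planted sink across several fitted states at large K, diluting the
  apparent sink centrality; the recovery experiments therefore fit the
  generative K.
* Distance correlation on long edge-weight vectors is O(n^2) memory
  (about 60 MB of doubles at D = 63); fine at desk scale, a constraint for
  much larger parcellations.
* Multilayer modularity is built and optimized as a dense (D K) x (D K)
  matrix; appropriate up to a few thousand node-layers.
* The Jaccard layer similarity treats all-singleton layer pairs as
  identical (similarity 1), a convention that matters only for degenerate
  partitions.
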