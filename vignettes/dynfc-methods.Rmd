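---
title: "Dynamic functional connectivity and modular organization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional connectivity and modular organization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynfc)
```

## What this package computes

`dynfc` implements a sliding-window dynamic functional connectivity (DFC)
analysis for node-level resting-state time series, asking how a single
bi-nodal connection — amygdala to medial prefrontal cortex (mPFC) — relates
to the large-scale network organization it is embedded in. The pipeline has
six stages:

1. **Motion preprocessing.** Framewise displacement (FD) is the sum of the
   absolute temporal differences of the six rigid-body parameters. Censoring
   applies three rules: any TR with FD > 0.5 is censored together with the
   following TR; a retained TR whose neighbors are both censored is censored;
   a run with more than 50% censored TRs is unusable. Nuisance regression
   removes 24 Volterra motion regressors (parameters, squares, and lag-1
   copies of both) plus mean CSF and WM signals; a zero-phase Butterworth
   bandpass keeps 0.01–0.1 Hz.
2. **Connectivity.** Pearson correlations over retained TRs, Fisher
   r-to-z transformed. For graph analyses the diagonal and negative entries
   are zeroed ("graph-ready"); bi-nodal and network-pair FC keep their sign.
3. **Community detection.** Louvain modularity maximization with resolution
   parameter γ,
   $$Q = \frac{1}{2m}\sum_{ij}\Bigl[w_{ij} - \gamma\frac{k_i k_j}{2m}\Bigr]\,
   \delta(c_i, c_j),$$
   a resolution sweep (γ from 1 to 2 in steps of 0.1, partitions scored by
   mean z-scored Rand similarity), and a consensus partition built by
   iteratively re-clustering the agreement matrix of repeated runs until the
   partitions are unanimous.
4. **Sliding-window dynamics.** 22-TR windows stepped by 5 TRs (41 windows
   for a 225-TR scan); per window: modularity Q at γ = 1.7 (best of 25
   restarts), all K(K−1)/2 between-network correlations of network mean time
   courses, and the a-priori bi-nodal series.
5. **Cross-level inference.** Within each subject the three window series
   are correlated (Fisher-z); at the group level one-sample t-tests, OLS
   regressions with an assault dummy or with five CTQ (Childhood Trauma
   Questionnaire) subscales entered simultaneously (log-transformed and
   z-scored) plus age, verbal IQ, and mean FD.
6. **SVR attribution.** Per subject, a linear ε-insensitive support vector
   regression (cost 1) predicts the bi-nodal series from all 45
   network-pair series; performance is the correlation between held-out
   predictions and observations under leave-one-window-out cross-validation;
   group one-sample t-tests on the per-subject weights are screened at
   p < 0.01 with BH-FDR flags alongside.

## The synthetic cohort: what it emulates and what it does not

The study this analysis is designed for deposits no data, so the package
ships a generative stand-in (`generate_cohort()`) with planted ground truth.
All distributional choices are synthetic and should be read as test
scaffolding, not as a biophysical model: there is no hemodynamic forward
model, no voxel level, no scanner heterogeneity.

Each of K networks has a latent unit-variance Gaussian time course; a node
is its network signal plus independent noise (`noise_sd`, default 0.8).
Networks 3…K share a static global factor with coupling `coupling_base`
minus `trauma_effect_mod` × the subject's z-scored log emotional-abuse
score: more severe abuse lowers between-network coupling, which raises
modularity Q. The limbic and default-mode networks additionally share a
factor whose coupling λ(t) follows a bounded AR(1) state (mean
`coupling_base`, stationary SD `coupling_volatility` = 0.25,
autoregression 0.94 at TR resolution so coupling episodes persist for tens
of seconds, the regime sliding windows are designed to resolve); they also
keep a partial loading (0.4 × `coupling_base`) on the global factor so they
stay embedded in the whole-brain graph — without it their low weighted
degree makes modularity prefer merging them at γ = 1.7. The DMN and limbic
networks receive twice the node share of the remaining networks, as in
real parcellations where the default-mode system is the largest; this also
gives the latent coupling enough weight mass that its effect on Q is
resolvable at realistic sample sizes.

The amygdala (limbic) and mPFC (DMN) nodes carry an extra shared component
constructed so that their model-implied correlation is exactly
$$\rho_w = \lambda_w + \text{binodal\_gain}\,(\lambda_w - \text{base})
+ \text{trauma\_effect\_fc}\cdot z_{\text{abuse}},$$
clamped to [−0.5, 0.95]. In assaulted subjects a fraction
`trauma_effect_tracking` (default 0.25) of the pair's signal variance is
replaced by independent noise, partially decoupling the pair from its
networks. This is the planted counterpart of the weaker cross-level
correspondence observed in assaulted participants; attenuating the λ-gain
alone cannot produce it, because the bi-nodal and network series both
measure the *realized* windowed coupling of the same factor paths, so a
smaller gain leaves their shared fluctuations almost untouched. Caudate
nodes carry limbic network signal only, so the caudate–mPFC control
contrast tracks network coupling but carries no planted trauma effect.

Motion traces are a small-step random walk with step-change spikes
(per-TR probability `motion_spike_prob`); each spike exceeds the FD 0.5
threshold exactly once. TRs whose FD exceeds the threshold also receive a
global signal artifact scaled with the noise floor, so censoring has
something real to remove. Censoring ground truth is emergent, not planted.

Generator defaults were fixed once, by simulation at the study's sample
size (56 subjects), so that every planted effect is comfortably detectable
under the default analysis settings; they were not adjusted afterwards.
Because windowed correlation estimates from 22 TRs are noisy, recovery
tests that target a *specific* per-subject tracking strength use a more
volatile config (`coupling_volatility` 0.35) than the cohort default.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| window length / step | 22 / 5 TRs | 44 s windows at TR 2 s; 41 windows from 225 TRs |
| γ (resolution) | 1.7 | chance-term multiplier in Q; sweep 1–2 in 0.1 steps |
| consensus runs | 300 | Louvain runs per agreement-matrix round |
| per-window restarts | 25 | best-Q-of-n restarts per window |
| FD threshold / run rule | 0.5 / 50% | censoring rules 1 and 3 |
| SVR cost / ε | 1 / 0.1 | ε is not pinned by the reference analysis; results are stable for ε ∈ {0.01, 0.1} |
| `min_valid_fraction` | 2/3 | minimum retained TRs for a window to count |

## Numerical and design choices

- **Louvain** runs on dense matrices with a package-internal xorshift PRNG,
  so partitions are bit-reproducible across platforms for a fixed seed.
  Node visits are shuffled per pass; a move needs strictly positive gain;
  ties keep the first best. Restart/window/subject seeds are derived
  deterministically from the global seed, so any stage can be re-run alone.
- **Consensus rounds** after the first cluster the near-binary agreement
  matrix at γ = 1 (configurable); the first round uses the analysis γ.
  Iteration stops at unanimity or when mean off-diagonal agreement stops
  improving (cap 50), returning the best-agreement round's best-Q partition.
- **z-scored Rand similarity** uses the analytic permutation-null variance
  of the co-assigned pair count; a Monte-Carlo permutation oracle arbitrates
  the formula in the test suite. Degenerate pairs (σ = 0) return 0 with a
  warning.
- **Fisher transform** clips |r| at 1 − 10⁻⁷ so degenerate window
  correlations stay finite.
- **Order of operations**: nuisance regression → bandpass → censoring
  applied only at correlation time. Censored TRs are excluded, never
  interpolated, keeping the temporal grid intact for windowing. Both the
  data and (implicitly) the nuisance series see the same filter; whether
  rotations are in mm is left to the data supplier (FD just sums the six
  columns as given).
- **Group matrix**: subjects are z-scored per node before concatenation so
  between-subject offset/scale differences cannot masquerade as
  correlation.
- **Windows** are 0-based half-open ranges internally reported as 1-based
  inclusive start/end columns; a window enters iff it fits entirely,
  giving floor((T − L)/s) + 1 windows.
- **SVR weights** come from the full-data fit (one weight vector per
  subject); LOOCV is used only for performance, with the z-scoring
  re-estimated inside each training fold. A "paper-style" global z-scoring
  would leak the held-out window's scale; the fold-safe variant is the
  default. LOOCV correlation carries a small conservative (negative) bias
  under the null, which the tests document rather than hide.

## Problem sizes used in tests and the acceptance script

Community detection cost scales with nodes × windows × restarts, so the
validation studies run at reduced node counts chosen to keep the planted
effects detectable: consensus recovery at 60 nodes / 6 networks, the
cross-level cohort study at 60 nodes / 10 networks (full 56-subject cohort,
41 windows, 25 restarts), the repeated-cohort CTQ sign-recovery study at 40
nodes / 6 networks with 10 restarts, and the SVR attribution study at 60
nodes / 10 networks. The exhaustive modularity oracle enumerates all
partitions up to 8 nodes (Bell(8) = 4140). The analysis scripts under
`analysis/` use the same 60-node study so a full run completes in minutes.

## Known limitations

- The generator's factor model yields roughly stationary white node noise;
  real BOLD noise is autocorrelated and spatially structured, so passing
  recovery tests here demonstrates correctness of the estimators, not
  robustness to every empirical artifact.
- Negative-weight information is discarded by the graph-ready transform, as
  in the reference analysis; no signed community model is attempted.
- Whether per-window matrices should also have negatives zeroed is not
  pinned down by the reference analysis; this package zeroes them before
  per-window Louvain (consistent with the group-level construction) and
  keeps signed values for all FC series.
- Modules must be non-overlapping and single-scale; no hierarchical or
  overlapping community structure.
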