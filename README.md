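# dynfc

Sliding-window dynamic functional connectivity (DFC) and modular network
analysis for node-level resting-state fMRI time series, built around one
scientific question: does a classic bi-nodal connection — amygdala to medial
prefrontal cortex (mPFC) — carry information of its own, or does it mostly
reflect the organization of the large-scale networks its nodes belong to,
and how does early-life trauma severity change that picture?

The package is aimed at researchers who have per-subject ROI-by-time
matrices (any parcellation), six-parameter motion traces, and a covariate
table, and want the full chain from motion censoring to group inference as
tested, reproducible code.

## What it implements

- **Motion preprocessing** — framewise displacement
  (FD_t = Σᵢ |Rᵢ(t) − Rᵢ(t−1)| over the six rigid-body parameters), the
  three-rule censoring scheme (FD > 0.5 plus the following TR; isolated
  retained TRs; runs more than 50% censored are unusable), 24 Volterra
  motion regressors + CSF/WM nuisance regression, zero-phase 0.01–0.1 Hz
  bandpass.
- **Connectivity** — Fisher r-to-z matrices at subject, group
  (per-subject z-scored concatenation), and window level; "graph-ready"
  variant with diagonal and negative weights zeroed.
- **Community detection** — Louvain maximization of
  Q = (1/2m) Σᵢⱼ [wᵢⱼ − γ kᵢkⱼ/2m] δ(cᵢ,cⱼ) with resolution γ (Rcpp core,
  deterministic for a fixed seed), a γ sweep (1→2 by 0.1) scored by the
  z-scored Rand index of partition similarity, and agreement-matrix
  consensus clustering.
- **Dynamics** — 22-TR windows stepped by 5 TRs (41 windows from a 225-TR
  scan); per-window modularity Q at γ = 1.7, all K(K−1)/2 between-network
  FC series from network mean time courses, bi-nodal amygdala–mPFC and
  control caudate–mPFC series.
- **Cross-level inference** — within-subject Fisher-z correlations between
  the three window series; group one-sample t-tests; OLS models with an
  assault dummy or five simultaneous CTQ subscales (log-transformed,
  z-scored) plus age, verbal IQ, and mean FD; BH-FDR adjustment.
- **SVR attribution** — per-subject linear support vector regression
  (cost 1) of the bi-nodal series on all 45 network-pair series,
  leave-one-window-out performance, and group t-tests on feature weights.
- **Synthetic cohort generator** — a factor model with a planted AR(1)
  limbic–DMN coupling state, trauma-severity effects on bi-nodal FC and
  modularity, and motion spikes, so every stage is testable against ground
  truth (no real data ship with the package).

## Worked example

```r
library(dynfc)

cfg <- cohort_config(n_nodes = 60, n_modules = 10, seed = 11)  # 56 subjects
res <- run_pipeline(cfg, consensus_runs = 100, do_loocv = FALSE, seed = 11)

res$manifest$n_windows        # 41
res$manifest$n_module_pairs   # 45
res$group_partition           # <partition: 60 nodes, 10 modules, gamma = 1.7, ...>

res$stats$t_binodal_network$t # 14.80  (p = 7.8e-21)
res$stats$t_binodal_q$t       # -5.23  (p = 2.7e-06)
res$stats$t_network_q$t       # -10.93 (p = 2.1e-15)

ctq <- res$stats$ctq_on_median_binodal
ctq[ctq$term == "ctq_emotional_abuse", c("estimate", "p")]
#     estimate            p
#   -0.130     4.1e-06
```

Reading: across 56 synthetic subjects, windowed amygdala–mPFC FC tracks
limbic–DMN network FC positively (t = 14.8), both fall when whole-network
modularity Q rises (t = −5.2 and −10.9), and the emotional-abuse score
predicts lower median bi-nodal FC (B = −0.130) — the planted directions, at
the planted strengths, recovered end to end through censoring, windowing,
community detection, and regression.

The `analysis/` directory holds the same study as numbered narrative
scripts (`01_simulate.R` … `07_svr.R`); each writes its tables under
`results/` and can be re-run independently.

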