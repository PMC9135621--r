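---
title: "Deriving a pharmacological dysconnectivity template and scoring individual similarity"
author: "ketsim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a pharmacological dysconnectivity template and scoring individual similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Resting-state fMRI studies of schizophrenia repeatedly find *thalamic
dysconnectivity*: the thalamus is excessively coupled to sensory and
motor cortex and under-coupled to prefrontal and cerebellar regions.
NMDA-receptor antagonists such as ketamine induce a transient,
schizophrenia-like state in healthy volunteers, and the question this
pipeline operationalises is quantitative: **how similar is an
individual's thalamic connectivity deviation pattern to the pattern a
pharmacological NMDAR-hypofunction probe induces?**

The pipeline has three layers:

1. **Template derivation.** In a within-participant, placebo-controlled
   drug design, each volunteer contributes session days with runs
   acquired during an initial saline infusion (runs 1–3) and during a
   subsequent drug infusion (runs 4–6). Per run, a first-level GLM
   regresses every voxel's time-series on the thalamus-seed mean
   time-series (plus nuisance regressors), producing whole-brain beta
   maps. Fixed-effects averaging and differencing give within-day
   contrasts (drug − saline) and a between-day contrast
   \[active − saline\] − \[placebo − saline\] that isolates the drug
   effect while cancelling run-order effects. A group one-sample t-map
   of the between-day contrasts, converted to z, is the **template**;
   cluster-extent inference at a voxelwise cluster-defining threshold
   |z| > 3.29 (two-tailed p = 0.001) with a corrected cluster threshold
   p < 0.05 identifies the significant hyper-connectivity clusters.

2. **Normative referencing.** In independent clinical cohorts, each
   participant's seed-connectivity map is re-expressed voxelwise as a
   deviation from healthy-control expectation:
   \(z_v = (y_v - \hat y_v) / \mathrm{SE}_v\), where \(\hat y_v\) comes
   from a per-voxel regression fitted **on HC only** — site dummies for
   the multi-site chronic cohort, intercept + linear age for the
   single-site early-illness cohort — and \(\mathrm{SE}_v\) is the
   residual standard error \(\sqrt{RSS/(n_{HC} - k)}\) of that
   regression. "Standard error of the regression" is deliberately the
   residual SE, not a prediction SE with leverage: it is the
   interpretation that gives held-out HC deviations unit variance
   asymptotically, which the calibration study checks directly.

3. **Similarity scoring and clinical statistics.** Template and
   deviation maps are flattened in a fixed voxel order (first axis
   fastest) over one shared mask — the intersection of all finite
   voxels, computed once per cohort so every vector has identical
   length and ordering. The Pearson correlation of the two vectors is a
   participant's **similarity coefficient**; its Fisher transform
   \(\tfrac12\log\frac{1+r}{1-r}\) is the analysis scale. Group
   comparisons use a linear model with sex (and site where applicable),
   initially with a group×sex interaction that is dropped when
   non-significant; pairwise contrasts and within-group mean-vs-zero
   tests use covariate-adjusted (balanced-grid) means on the model's
   residual df, with Cohen's d defined as adjusted difference over
   residual SD (this reduces to classical pooled-SD d when there are no
   covariates). Symptom scores (item sum + global rating; inclusion
   requires a global rating ≥ 2; square-root transform when sample
   skewness exceeds 1) are regressed on similarity with the same
   interaction-dropping procedure, FDR-controlled across the domain
   family (eight positive/negative domains, four psychosis-risk
   domains). A Spearman correlation against chlorpromazine-equivalent
   dose is the medication-confound check.

## What the synthetic-data generator emulates

No clinical fMRI data ship with the package; a generator
(`sim_config()`, `simulate_cohort()`, `simulate_bold_run()`,
`simulate_connectivity_map()`, `simulate_symptoms()`) produces data
with exactly the statistical structure the stages above assume:

- **Sessions**: two-phase days with three runs per infusion phase,
  210 volumes per run at TR = 2 s. Every voxel follows
  \(w_v(\text{condition})\,s(t) + \text{drift} + \varepsilon\) with a
  shared latent seed signal \(s(t)\) (unit-SD AR(1)); under active drug
  the coupling \(w_v\) rises in designated "sensory" voxels in
  proportion to a planted spatial pattern. Pre-treatment with the
  glutamate-release inhibitor does **not** attenuate the increase —
  that is the phenomenon being emulated, and the ROI repeated-measures
  ANOVAs are how it is tested.
- **Clinical maps**: baseline + site offset + age-slope·(age − 30) +
  \(\lambda_i\)·template + white noise, with the template scaled to
  unit SD so loadings are in map-SD units. Baseline, site and age
  fields are Gaussian-smoothed random fields (smoothing SD 1.5 voxels)
  so cluster inference sees realistic spatial autocorrelation; the
  paperless choice here is ours, as is the uniform 18–45 age range.
- **Loadings**: \(\lambda_i \sim N(\lambda_g, 0.2)\) with group means
  0 / 0.15 / 0.30 for the HC / at-risk / early-illness analogues (and
  0.30 for the chronic analogue). The 0.15 gap at within-group SD 0.2
  makes adjacent group separations about d ≈ 0.75, matching the
  magnitude of the reported early-illness effect.
- **Symptoms**: only the hallucination-analogue domain is coupled to
  similarity (slope 4 score-units per unit Fisher-z, latent Gaussian
  noise SD 2 before rounding/truncation), mirroring the specificity of
  the clinical finding; 30% of participants receive a sub-threshold
  global rating to exercise the inclusion filter. A participant's
  "true" Fisher-z similarity is the analytic expectation
  \(\mathrm{atanh}(\lambda/\sqrt{\lambda^2+\sigma^2})\)
  (`expected_fisher_z()`).

What the generator does **not** model: haemodynamic convolution,
scanner artifacts, motion/physiological nuisance structure, non-linear
age effects, and ordinal symptom dynamics. Passing tests therefore
demonstrate statistical correctness of the pipeline under its stated
assumptions, not robustness to real-data nuisance structure.

## Numerical and design choices

- **Cluster correction** uses a sign-flipping permutation null of the
  maximum cluster size (both tails pooled), not Gaussian-random-field
  theory: permutation is assumption-light and exactly testable, and
  its family-wise error is verified by simulation. Because z is a
  monotone function of t, the permutation loop thresholds directly in
  t-space at the t whose z equals the CDT, avoiding per-permutation
  map conversions. Corrected p-values are \((1+b)/(n_{perm}+1)\).
- **Connectivity** for cluster labelling is the 6-neighbourhood
  (faces) by default — conservative — with 18/26 available; positive
  and negative suprathreshold voxels are labelled separately.
- **t→z conversion** composes the t CDF and normal quantile through
  log-tail probabilities, so |t| of 60 still converts without
  underflow; it is odd and strictly increasing by construction.
- **Zero-variance voxels** (first-level) and zero-residual voxels
  (normative) are masked out and counted rather than erroring; the
  similarity mask is the intersection of finite voxels across the
  cohort.
- **Interaction dropping** uses a two-sided α of 0.05; the sqrt
  transform fires at sample skewness > 1. Neither threshold is
  prescribed by the emulated studies; both are stated defaults.
- **Degenerate inputs**: identical repeated-measures conditions report
  F = 0, p = 1 rather than 0/0; single-run phases are averaged as-is
  (the dropped-runs fallback); single-sex subsamples fall back to the
  common slope with a warning; an exactly proportional map yields
  r = ±1 with an infinite Fisher z.
- **Reproducibility**: one root seed (default 20220414) fans out into
  labelled substreams per participant, run and stage
  (`substream_seed()`), so cohorts are extensible without reshuffling
  and a full `run_pipeline()` is bit-reproducible.
- **First-level estimation** is OLS (no prewhitening); the nuisance
  set is intercept + linear drift plus optional user columns. Whether
  the emulated analyses used AR prewhitening and which exact confounds
  is unknowable from the source; OLS is the stated contract.
- The reported-df puzzle in the chronic-cohort group model (a t with
  352 df at n = 361 implies nine parameters, i.e. no interaction term)
  is resolved by making interaction-dropping the default path; both
  variants remain available via `alpha_drop`.

## Validation studies and problem sizes

The `study_*()` functions re-derive the package's statistical
guarantees at desk scale (all on the default 24×24×24 grid):

```{r studies}
study_oracle_errors(seed = 1)            # estimators vs brute force
study_normative_calibration(seed = 1)    # 200 fit + 200 held-out HC
study_cluster_type1(seed = 1)            # 200 null reps x 500 sign flips
study_loading_recovery(seed = 1)         # 100 cohorts of 85/45/74
study_symptom_recovery(seed = 1)         # 50 cohorts, 100 patients
study_determinism(run_config())          # full pipeline twice
```

These sizes are the package's standing validation conditions: large
enough that binomial bands and Monte-Carlo standard errors are
meaningful, small enough to run on a single CPU at a desk. The same
studies back `scripts/acceptance.R` and the acceptance test file.

## Limitations

Similarity coefficients on synthetic data are larger than is typical
of real cohorts (map amplitude is arbitrary in the generator), so
absolute r magnitudes should not be compared against empirical
reports — orderings, calibrations, error rates and df are the
meaningful quantities. The permutation test requires sign-symmetric
null contrasts, which within-participant differencing provides; it is
not a test for arbitrary asymmetric nulls. The normative models are
deliberately minimal (site-only, or linear age); richer normative
modelling is out of scope.
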