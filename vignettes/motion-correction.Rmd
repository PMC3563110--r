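---
title: "Micro-movement correction in developmental functional connectomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-movement correction in developmental functional connectomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Resting-state functional connectivity is estimated by correlating BOLD
time series between brain regions. Abrupt head movement — even
sub-millimetre "micro-movement" — corrupts these estimates in a
structured way: frames acquired during or just after a displacement carry
a spatially coherent artifact that inflates correlations between nearby
regions and, after global-signal regression, deflates long-range ones.
Because children move more than adolescents, this artifact masquerades as
a developmental effect: short-range connections appear to weaken and
long-range connections to strengthen with age more than they truly do. In
clinical samples the stakes are higher still — hyperkinetic populations
such as children with ADHD move more than controls, so motion can
manufacture or mask group differences.

`fcmotion` implements the measurement of micro-movement, ten correction
procedures spanning the strategies in common use, and the downstream
analyses those procedures feed: edge-wise age association with a
short/long-range distance contrast, a frame-removal degradation
simulation, support-vector-regression brain-maturity prediction with a
growth-curve maturity index, leave-one-out cross-validated SVM
classification of ADHD subtypes, and node-strength summaries of the
classifying connections.

## Motion metrics

Head position per frame is described by six rigid-body parameters (three
translations in mm, three rotations). Two frame-to-frame metrics are
computed from them:

* **Framewise displacement (FD)**, the sum of the absolute backward
  differences of the six parameters, with each rotation converted to arc
  length on a 50 mm sphere (about the distance from the cortex to the
  head centre). The first frame, having no predecessor, is assigned
  FD = 0.
* **DVARS**, the spatial root-mean-square of the backward temporal
  difference of the signal over all channels, with the run first rescaled
  to a median intensity of 1000 so the conventional threshold of 4 is
  comparable across runs. Whether that published threshold refers to a
  x1 or x10 scaling of mode-1000 units is not standardized; the
  threshold is configuration-exposed (`fc_config(dvars_threshold = )`) and
  the default documents this assumption.

Run-level movement is summarized as the frame-wise RMS of the six
parameters (rotations again converted at 50 mm); runs strictly exceeding
1.5 mm RMS are flagged for exclusion. All thresholds in the package are
strict inequalities (`>`), matching their usual statements.

Censor masks remove every frame whose metric exceeds the threshold plus
one frame before and two after (band-pass filtering smears the artifact
in time); windows from multiple triggers are unioned and clipped to the
run. Masks use the 1 = keep convention so that `1 - mean(keep)` is the
fraction removed.

## The ten correction procedures

| id | subject-level transform | cohort-level action | eligibility |
|----|------------------------|---------------------|-------------|
| P1 | regression on the 6 motion parameters during cleaning | — | — |
| P2 | P1 + partial correlation with the 6 frame-to-frame parameters | — | — |
| P3 | P1 + partial correlation with FD | — | — |
| P4 | cleaning regression with frame-to-frame parameters instead | — | — |
| P5 | as P1 | mean FD as covariate of the age correlation | — |
| P6 | as P1 | remove subjects until mean FD is unrelated to age | — |
| P7 | FD > 0.2 mm censoring (1 before / 2 after) | — | < 60% frames removed |
| P8 | as P7 | matching on post-censor mean FD | < 60% removed |
| P9 | DVARS > 4 censoring | matching on post-censor mean DVARS | < 60% removed |
| P10 | polynomial r-value correction from the censoring delta | — | >= 40% frames remaining |

Design choices where the common descriptions are silent:

* **Matching algorithm.** "Remove subjects until the motion-age
  correlation is not significant" does not specify an order. We use a
  greedy exhaustive scan — at each step remove the single subject whose
  exclusion most reduces `|r|`, ties broken by lexicographic id — which is
  deterministic and idempotent, and abort with a diagnostic if more than
  half the cohort would be removed. The significance level defaults to
  0.05 (matched cohorts should report p well above it).
* **Polynomial correction (P10).** Per subject, the difference between
  the scrubbed and the original correlations (`delta r`) is regressed on
  inter-ROI Euclidean distance with a polynomial (degree 3 by default,
  configurable; the fit is on r, not z, with z recomputed afterwards),
  and the original values are corrected by the predicted delta:
  `corrected = original + poly(distance)`, approximating the scrubbed
  estimate without frame loss. Because the least-squares fit includes the
  linear term, the residual delta is orthogonal to distance on the fitted
  edges — the self-check statistic ("no residual effect of movement")
  should collapse toward zero, and the package reports both the pre- and
  post-correction delta-distance correlations.
* **P5** is represented as cohort-level metadata (a mean-FD covariate
  consumed by the age analysis), not a subject-level transform.

## Subject-level cleaning and connectivity

Cleaning regresses each ROI series on an intercept, the nuisance channels
(global, white-matter, and ventricular analogs), their backward-difference
derivatives, and the motion regressors of the procedure. An optional
zero-phase order-2 Butterworth band-pass (0.009-0.08 Hz) can be enabled
with `fc_config(bandpass = TRUE)`; it is off by default because the
synthetic cohorts carry AR(1) rather than band-limited temporal structure,
so filtering only costs time without changing the statistics being
tested. Volumetric spatial smoothing has no ROI-level analog and is
deliberately omitted.

Correlation matrices are Pearson over retained frames with Fisher z
computed per edge; degenerate edges (constant channels, |r| = 1) are
carried as invalid rather than raising, so one bad channel cannot lose a
subject. A subject with fewer than 30 retained frames is flagged
ineligible (configurable); procedure-specific eligibility rules
(< 60% removed, >= 40% remaining) are applied at the cohort level with
every exclusion logged. All edge-indexed quantities share one canonical
ordering: the upper triangle of the ROI-by-ROI matrix traversed
row-major, with ROI order fixed by the input table.

The band-pass is applied once, before any censoring; matrices computed on
censored frames use the filtered-then-censored series. Whether filtering
should be re-run after interpolation in the spline simulation is an open
methodological question; we filter once and note it here.

## Age analysis

Each edge's Fisher-z value is correlated with age across subjects
(optionally partially, controlling per-subject mean FD via residual
correlation — the exact equivalence with ordinary partial correlation is
used as a test oracle). Significance is controlled by Benjamini-Hochberg
FDR at q = 0.05 by default (the level is configuration-exposed).
Significant edges are split by sign into age-strengthening and
age-weakening sets and their Euclidean distances compared with a Welch
two-sample t-test (chosen because the two sets have no reason to share a
variance; the usual reports do not name a test).

The frame-removal simulation takes low-motion reference subjects (at most
1% of frames above the FD threshold), applies real censoring patterns
donated by higher-motion subjects, and measures matrix degradation as
`1 - r` between the vectorized upper triangles of the baseline and
degraded matrices. The spline variant imputes censored frames per ROI
with a natural cubic spline over frame index (run edges take the nearest
retained value, since splines extrapolate unreliably) and recomputes the
matrix on all frames.

## SVR maturity prediction and SVM subtype classification

Age prediction uses epsilon-insensitive support-vector regression with an
RBF kernel written in its sigma form,
`K(x, x') = exp(-||x - x'||^2 / (2 sigma^2))` with sigma = 2; the solver's
rate parameterization is `gamma = 1/(2 sigma^2) = 0.125`, a conversion
unit-tested against the explicit kernel formula. The nominally infinite
error penalty is realized as C = 1e6 (a hard-margin surrogate; exposed in
`svr_config()`), with epsilon = 1e-5. Features are Fisher-z edges used
unstandardized. Each leave-one-out fold re-selects the top 300
age-correlated, FDR-passing edges on its training subjects only; when
fewer than 300 edges pass FDR the fold takes all passers (logged via the
`n_passed` attribute), and a fold with no passers falls back to the
training-mean prediction.

Predicted age is summarized by a Von Bertalanffy growth fit
`a (1 - e^{-b x})` (Levenberg-Marquardt, five deterministic multi-starts:
`a0 = max(predicted)` with b0 in {0.1, 0.05, 0.2, 0.02, 0.5}); the
functional connectivity maturity index (fcMI) rescales predictions so the
fitted curve equals 1 at the oldest chronological age. Constant
predictions collapse b to its zero boundary and are flagged degenerate
rather than fitted.

Subtype classification is a soft-margin RBF SVM (C = 1, sigma = 2) on the
top 150 group-separating edges per fold (Welch t for two groups, one-way
ANOVA F for three), with three-group problems handled one-vs-rest and
decided winner-takes-all on the decision values. Groups must be balanced
first: `balance_groups()` subsamples equal group sizes by greedy
nearest-neighbour matching on standardized covariates (age, sex, mean FD
by default), deterministically under a seed. Connectivity features can be
adjusted for site, sex, and IQ while retaining the diagnosis effect
(`confound_adjust()`: per edge, OLS on diagnosis + confounds, returning
intercept + diagnosis term + residual). Whether that regression should be
fit on the balanced subsample or the full cohort is unspecified in common
practice; we fit on the analysis subsample. Sensitivity and specificity
treat the ADHD group as positive.

A calibration worth knowing: under label permutation the LOOCV estimate
of a balanced three-group classifier averages slightly *below* the
analytic 33.3% chance level (about 31% in the package's own calibration).
This is the well-known leave-one-out pessimism — the held-out subject's
class is always underrepresented in its training fold — and is the honest
behaviour of the procedure, not a defect of the implementation.

## Node strength

For a designated edge set (consensus features — those selected in every
LOOCV fold — or the FDR-significant age edges), the strength of a node is
the sum of the absolute weights of its incident edges, zero for nodes
with none. The weight is ambiguous in common usage ("z scores" can mean
a group-difference statistic or a connectivity value); both are supported,
with the diagnosis-contrast t statistic and the Fisher z of the age
correlation as the documented defaults for the two analyses. Strengths
satisfy the handshake identity (total strength = twice the summed
absolute edge weights), which is tested.

## The synthetic cohort generator

Real multi-site ADHD cohort data cannot ship with a package, so
`generate_cohort()` builds cohorts that emulate the *statistical
structure* the procedures must confront, with full ground truth for
recovery testing. Defaults mirror the study conditions throughout:
three diagnostic groups (TDC, ADHD-I, ADHD-C) of 52 children aged 7-14,
160 ROIs in six networks, 200-frame runs at TR 2.5 s.

* **Geometry.** ROI centres are uniform in a head-sized box; network
  labels come from spatial k-means into twelve clusters paired into six
  two-lobe networks, so networks are locally coherent yet spatially
  distributed — which is what makes "long-range within-network" edges
  possible, as in real functional systems.
* **Covariance.** Baseline Fisher-z connectivity is
  within-network 0.30 / between-network 0.05 (as correlations) plus a
  proximity term `0.2 exp(-d / 30 mm)`. Age effects (+0.025 z/yr on 400
  sampled longer-half within-network edges, -0.025 on 400 shorter-half
  between-network edges) and subtype offsets (-0.12 z on default-network
  edges for ADHD-C, -0.12 on fronto-parietal/cerebellar edges for ADHD-I,
  -0.08 on sensorimotor edges for both) are planted additively in z space,
  mapped back to correlations, and the matrix projected to the nearest
  positive definite by eigenvalue clipping (floor 1e-4; the projection
  errors out if it would distort any correlation by more than 0.05).
  Sampling is multivariate normal with AR(1) temporal smoothing
  (phi = 0.3) plus a rank-8 subject-variability component contributing
  about 0.06 s.d. of per-edge correlation heterogeneity.
* **Motion.** Per-subject spike propensity is drawn with correlation
  -0.45 with age (younger children move more; the propensity drives both
  the per-frame spike rate and the spike magnitude). Each spike adds a
  one-frame displacement pulse to the realignment parameters whose
  summed magnitude is lognormal (median 0.5 mm), and an artifact
  component in the signal: a spatially smooth loading vector (exponential
  kernel, 40 mm length scale), fresh per spike, scaled by
  `gain * FD^1.5` and bleeding into the following two frames with weights
  0.4 and 0.15. The supra-linear exponent reflects the empirically
  non-linear relationship between displacement and BOLD disruption — it
  is what prevents linear motion regression from fully removing the
  artifact. Because the loadings are spatially smooth, proximal ROI pairs
  share artifact systematically while distant pairs do not; after
  global-signal regression this yields the characteristic
  inflation-of-short-range / deflation-of-long-range motion bias, with
  magnitude proportional to the subject's motion burden and therefore
  confounded with age. The artifact's spatial kernel and exponent are
  modelling choices exposed in `synth_config()`, not claims about any
  particular dataset.
* **Channels.** Each ROI expands to four noisy channel replicates on a
  nominal intensity of 1000, plus a global intensity change at spike
  frames (the echo-planar signal loss that abrupt displacement causes),
  so DVARS is computable and its threshold of 4 separates spikes from the
  ~2-unit baseline.
* **Determinism.** Every subject is generated under a seed derived from
  the master seed, and equal seeds give bit-identical cohorts.

What the generator does *not* emulate: hemodynamics, band-limited
spectra, scanner drift and physiological noise, site effects on
connectivity (sites are labels only), non-Gaussian edge distributions,
and slow within-run motion. Passing recovery tests on these cohorts
therefore demonstrates that the pipeline's statistics behave as designed
under the planted structure — not that any particular real dataset is
free of artifact.

## Problem sizes and numerical choices

The test-suite and reproduction runs use the scales the analyses are
designed for where the claim depends on scale (160 ROIs / 12,720 edges;
120 typically developing subjects for the age analyses; 52 per group for
classification; 20 label permutations for the chance calibration; 10
cohort replicates for the directional procedure comparison) and small
cohorts elsewhere. Tolerances: oracle equivalences at 1e-10; the
hand-computed FD value at 1e-5; noiseless growth-curve recovery at 1e-6.
Ties in feature ranking break by edge index; matching ties break by
subject id; degenerate inputs (constant channels, |r| = 1 edges, empty
covariate sets, constant growth predictions) are carried as flagged
values rather than errors wherever a single subject should not abort a
cohort.

## Limitations

The generator's artifact model is phenomenological; its parameters were
chosen once to realize the documented artifact structure at realistic
magnitudes and are not fitted to any dataset. The matching algorithm and
the polynomial degree are reasonable defaults for under-specified
procedures, and alternative choices (matching order, fitting delta on z
rather than r) are switchable but untested against real data. Volumetric
preprocessing (slice-timing, spatial normalization, smoothing) is out of
scope: the package starts from ROI time series and realignment
parameters.
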