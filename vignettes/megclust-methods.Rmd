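---
title: "Methods: covariate-adjusted cluster-based permutation inference for source-space power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: covariate-adjusted cluster-based permutation inference for source-space power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megclust)
```

## The inference problem

A source-reconstructed power study compares relative power between two
groups at every cell of a nodes × frequency-bins matrix. With ~150–1200
nodes and ~113 bins, the search space holds 10^4–10^5 strongly correlated
tests. The cluster-based permutation test (CBPT) solves the multiplicity
problem without modelling that correlation: it thresholds the cell-wise
statistic map, aggregates supra-threshold cells into spatio-spectrally
connected clusters, scores each cluster by its mass (the sum of member
statistics), and calibrates masses against the distribution of the
*maximum* surrogate cluster mass under group-label permutations. Because
every observed cluster is compared with the permutation maximum over the
whole search space, the probability of any false-positive cluster — the
family-wise error rate (FWER) — is controlled at the cluster-level alpha.

Group membership in this design is confounded: the vascular group is
older, and age itself shifts power spectra. The cell-wise statistic is
therefore not a t statistic but a nested-model ANCOVA F,

$$F = \frac{(\mathrm{SSE}_{\mathrm{red}} - \mathrm{SSE}_{\mathrm{full}})/1}
          {\mathrm{SSE}_{\mathrm{full}}/(n - p - 2)},$$

where the full model regresses cell power on intercept, group and $p$
covariates (age and total white-matter volume by default) and the reduced
model omits group. The sign of the fitted group coefficient (group 1 −
group 0, adjusted) decides which of the two sign-specific masks a
supra-threshold cell enters; clusters never mix signs.

### Permutation scheme and its assumptions

Labels are shuffled over subjects while covariates stay attached to their
subjects — the simple label-permutation scheme. Under the null of no group
effect given covariates, subjects are exchangeable with respect to the
label, and the adjusted F removes the covariate contribution in both the
observed and permuted pipelines. With a strong covariate–outcome effect
*and* a covariate–group imbalance this scheme is approximate (residual
permutation schemes such as Freedman–Lane are exact to higher order and
are deliberately not implemented here); the test suite verifies
empirically that the adjusted pipeline holds its nominal level under an
age confound that makes the unadjusted variant reject wildly.

Two p-value conventions exist; the default is the plain proportion
$\#\{M^{(b)} \ge M_{\mathrm{obs}}\}/B$, so an observed mass above every
surrogate maximum reports $p = 0$. The positively biased
$(1+\#)/(1+B)$ estimate is available via
`cbpt_config(pvalue_correction = TRUE)`. The observed labelling is not
included in the null, matching the plain-proportion definition. When the
number of distinct relabellings $\binom{n}{n_1}$ does not exceed the
requested permutation count the engine switches to exhaustive
enumeration automatically.

### Null pooling across signs

One maximal null is built per permutation from the maximum mass over
*both* signs (a two-sided FWER statement and the conservative reading of
a max-statistic protocol). `cbpt_config(null_pooling = "per_sign")` keeps
separate positive and negative nulls for users who want per-sign
calibration.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `cluster_alpha` | 0.005 | p | cell-level threshold via the F quantile; lower values favour compact, strong clusters |
| `n_permutations` | 10 000 | count | Monte-Carlo resolution of the null; p-values live on a 1/B grid |
| `min_extent_fraction` | 0.01 | fraction of nodes | discards spatially tiny clusters; 1% of a 1202-node space is 12 nodes |
| `cluster_level_alpha` | 0.05 | p | significance level for cluster p-values |
| `extent_rule` | unique_nodes | — | the minimum extent counts unique nodes of the whole spatio-spectral cluster; `per_freq_slice` instead requires one bin to reach it |
| `mass_cap` | 1e12 | F units | mass contributed by an infinite-F (perfectly separated) cell, keeping masses finite and such clusters maximally ranked |

The minimum extent uses the floor rule `max(1, floor(fraction * n_nodes))`.
On the 150-node validation grid this equals 1, i.e. effectively no extent
filter — the max-statistic calibration alone carries the error control
there, which the FWER simulations confirm.

## Spectral estimation

`multitaper_psd()` implements the mtmfft-style estimator: per segment,
demean (no detrend), taper with $K = 2\,T W - 1$ dpss sequences of
time-bandwidth $NW = T\,W$ (the smoothing parameter $W$ in Hz is the
concentration half-bandwidth; 4-s segments with 1 Hz smoothing give
$NW = 4$, $K = 7$), Fourier transform, average squared magnitudes over
tapers, then over segments. The output grid is the natural one,
$0, 1/T, \dots, f_s/2$; band endpoints are inclusive, which is what makes
(30 − 2)/0.25 + 1 = 113 bins. Absolute power is defined up to a fixed
constant that cancels in `relative_power()`, the supported downstream
normalisation: each bin divided by the band total, so every spectrum sums
to exactly 1 over the band.

No R package in the package's dependency set provides Slepian tapers, so
`dpss_tapers()` computes them from the classical symmetric tridiagonal
operator that commutes with the concentration problem: the top $K$
eigenvalues are isolated by Sturm-sequence bisection and eigenvectors
recovered by inverse iteration with a pivoted tridiagonal solve — $O(nK)$
overall, so 4000-sample tapers cost well under a second. Polarity follows
the common convention (symmetric tapers positive on average,
antisymmetric ones starting positive), and the unit tests pin the result
to reference Slepian sequences to 10^-9.

## The synthetic cohort generator

`simulate_cohort()` is the package's test bed; its defaults *are* the
validation conditions used throughout the tests.

* **Baseline spectrum**: relative power ∝ $f^{-a_s} + A_s\,
  e^{-(f-\mu_s)^2/2}$ on 2–30 Hz at 0.25 Hz, with per-subject jitter
  $a_s \sim N(1, 0.08)$, $A_s \sim 0.35\,e^{N(0,0.25)}$,
  $\mu_s \sim N(9.5, 0.4)$ — a 1/f trend with an eyes-closed alpha peak,
  and realistic between-subject spectral variability that correlates cells
  across the spectrum.
* **Planted effects**: group 1 has theta-range power (4.75–8 Hz)
  multiplied by 1.25 on a widespread central block of 36/150 nodes, and
  beta-range power (≈12–19.5 Hz) multiplied by 0.7 on two lateral blocks
  of 24 nodes each; spectra are then renormalised per node, so effects
  couple across bands exactly the way relative power does (a theta
  increase slightly depresses all other bins). Effect sizes are
  calibration choices — chosen once so that planted effects are reliably
  detectable at n = 30/group — not literature values.
* **Noise**: additive $N(0, 0.0015)$ per cell, truncated at zero,
  followed by renormalisation; every per-node spectrum sums to 1 within
  1e-9 by construction. Typical cell magnitudes are 0.005–0.015, so this
  is ~10–30% cell-level noise on top of the subject-level jitter.
* **Covariates**: ages $N(72.1, 5.1)$ in group 0 with a +3-year group
  shift (SD 4.2) in group 1 — an age confound that exercises the
  adjustment; white-matter volume $N(392\,000, 53\,000)$ mm³ independent
  of group; WMH volumes lognormal per group (medians ≈ 800 and 8500 mm³,
  log-SDs 0.9 and 0.6) straddling the 3448 mm³ reference landmark, so
  cut-point dichotomization reproduces the generating groups up to ~6%
  boundary misassignment.
* **Scores**: each score is a monotone transform of the subject's
  planted-cluster mean power plus noise, with correlation-like strength
  `score_link_strength` (default 0.5) and fixed directions: negative for
  the theta cluster (worse cognition with more theta), positive for the
  beta clusters.
* **Reproducibility**: one seeded RNG stream per simulate call with a
  fixed draw order (spectral shape parameters, ages, per-subject noise,
  volumes, scores); identical seeds give bit-identical cohorts.
* **Reference volumes**: `simulate_reference_volumes()` defaults (median
  800 mm³, log-SD 0.9) put the 95th percentile of a cognitively intact
  reference sample near the 3448 mm³ landmark.

What the generator does *not* emulate: spatial correlation of noise
between neighbouring nodes, non-Gaussian artifact residues, frequency-
dependent source leakage, and realistic ROI geometry. Passing tests
therefore demonstrate the correctness and calibration of the inference
machinery under a clean, known model — not field performance on real MEG,
where leakage and spatially structured noise make cluster extents
harder to interpret.

## Numerical choices

* **Fast F maps**: the reduced-model projection is computed once; each
  permutation costs one $n \times$ cells cross-product using the
  added-regressor identity $\mathrm{SSE}_{\mathrm{red}} -
  \mathrm{SSE}_{\mathrm{full}} = (g_\perp^\top Y_r)^2 / \|g_\perp\|^2$,
  where $g_\perp$ is the permuted group indicator residualised against
  the covariates. A loop-based `lm()` reference implementation in the
  test suite pins the fast path to 1e-8.
* **Degenerate cells**: zero-variance cells get $F = 0$, sign 0;
  perfectly separated cells get an infinite-F sentinel that always
  crosses the threshold and contributes `mass_cap` to its cluster.
  A group indicator collinear with the covariates raises a
  degenerate-design error.
* **Clustering**: connected components by union-find with path halving
  over supra-threshold cells only; the graph joins spatial neighbours
  within a bin (face-neighbour lattice adjacency, distance ≤ 1.05 ×
  spacing) and consecutive bins at a node. A breadth-first flood-fill
  oracle verifies components cell-for-cell.
* **Quantile convention**: the cut point uses the linear-interpolation
  quantile $x_{(1+(n-1)p)}$ (configurable via `type`); ties exactly at
  the cut value go to the lower group ("strictly above" defines the
  vascular group).
* **Spearman p-values**: t approximation on $n-2$ df with average ranks;
  listwise deletion of incomplete pairs.
* **Tie-breaks**: clusters are reported sorted by p-value, then by
  descending mass.

## Validation problem sizes

The test suite exercises the full pipeline at the generator's default
scale (150 nodes × 113 bins × 60 subjects, 500 permutations), verifies
FWER on 200 null cohorts of 40 subjects at the same grid with 500
permutations each, and checks exact oracle equivalence on grids of ≤ 30
nodes × ≤ 10 bins where an all-loops reference is affordable. These sizes
were chosen to make the whole validation run in minutes on a single CPU
while keeping the search space genuinely high-dimensional (≈17 000
cells).

## Known limitations

* Simple label permutation (not Freedman–Lane); approximate under strong
  covariate–group dependence, empirically calibrated here.
* Relative power couples bands: a planted (or real) increase in one band
  necessarily produces small opposite-signed shifts elsewhere, and
  strong bilateral effects can merge into one spanning cluster through
  bridging cells. Cluster extents should be read as evidence regions,
  not effect boundaries.
* The spectral module expects clean, artifact-free segments; no
  preprocessing (filtering, ICA, source reconstruction) is provided.
* p-values have 1/B resolution; with 500 permutations the smallest
  nonzero p is 0.002.
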