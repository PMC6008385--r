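---
title: "Graph-theoretic analysis of default mode network connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretic analysis of default mode network connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmnet)
```

## The analysis in one paragraph

`dmnet` turns per-subject regional fMRI time series into binary brain
graphs and asks whether the topology of the default mode network (DMN)
differs between two groups — in the motivating application, male
patients with severe obstructive sleep apnea (OSA) versus good sleepers
(GS). Each subject contributes a 20×20 Pearson correlation matrix over
a fixed DMN parcellation; the matrix is thresholded at every sparsity
level on a fixed grid, global and nodal topology metrics are computed
at each level against a degree-preserving random-network null, each
metric's curve is reduced to its area under the curve (AUC), and
covariate-adjusted two-sample tests compare the groups at the global,
nodal, and edgewise level. Clinical indices are then correlated with
the metrics that differ.

## Pipeline stages and their assumptions

### Denoising (`preprocess`)

The time-series stages mirror standard resting-state practice:
per-node linear detrending, ideal bandpass filtering to 0.01–0.08 Hz,
and nuisance regression of white-matter, CSF and global signals plus
the Friston-24 motion expansion (`[R(t), R(t−1), R(t)², R(t−1)²]` for
the six rigid-body parameters). Head-motion quality control excludes a
subject when the maximum rotation exceeds 2.0°, the maximum
translation exceeds 2.0 mm, or the mean volume-to-volume RMS
displacement of the three translations exceeds 0.2 mm. Two
conventions here are choices that the package documents rather than
inherits:

* **Relative RMS is computed from translations only.** The rotational
  excursions are policed by the 2.0° rule; a combined displacement
  would need an arbitrary head-radius conversion.
* **Filtering order.** The default order is detrend → bandpass →
  regression, following the conventional listing;
  `order = "regress_first"` switches the last two. When filtering
  comes first, the regressors are passed through the *same* bandpass
  before the fit. Regressing full-band confounds from band-limited
  data removes shared variance only partially — in our synthetic
  benchmark the recovered edge correlation was 0.27 instead of the
  0.45 ground truth until the regressors were filtered too.

The bandpass is an ideal discrete-frequency mask (components with
`low ≤ f ≤ high` kept, boundary inclusive, DC removed when
`low > 0`). An ideal mask is bit-reproducible, exactly idempotent,
and trivial to reason about in tests; its sharp transition is harmless
here because all downstream statistics are correlations of identically
filtered signals.

### Connectivity (`connectivity`)

The packaged parcellation has 20 DMN nodes (posterior cingulate,
anterior/dorsal/ventral medial prefrontal, temporo-parietal, lateral
temporal, temporal pole, posterior inferior parietal, retrosplenial,
parahippocampal, hippocampal; left/right where applicable) with MNI
coordinates. Signals may be supplied directly as a T×N matrix or
extracted from a 4-D volume as the mean over a 6-mm sphere. Sphere
membership uses voxel-center distance, boundary inclusive — voxel
counts differ between conventions, so the choice is fixed and tested
against exhaustive enumeration. Connectivity is the raw Pearson r with
the diagonal fixed at zero; no Fisher transform is stored, because the
abnormal-connectivity composite score is defined as a mean of
correlation coefficients. Variance stabilization happens only inside
the edgewise test.

### Topology (`graph_metrics`)

At sparsity `Sp` the strongest `K = round(Sp·N(N−1)/2)` edges are kept
(rounding half away from zero — banker's rounding would change edge
counts at `.5` boundaries) and set to 1. Edges are ranked by signed
correlation by default (`rank = "abs"` is available): positive-weight
ranking is the dominant convention in this literature and the
motivating analysis gives no reason to privilege strong
anticorrelations. Ties break by lexicographic node-pair order so a
run is reproducible even on degenerate inputs.

On each binary graph the package computes:

* clustering coefficient `Cᵢ = 2tᵢ/(kᵢ(kᵢ−1))` (0 when `kᵢ < 2`) and
  its mean `Cp`;
* harmonic-mean characteristic path length
  `Lp = n(n−1)/Σᵢ≠ⱼ 1/dᵢⱼ` with `1/∞ = 0`, finite on disconnected
  graphs, and its exact inverse, global efficiency `Eglob`;
* local efficiency `Eloc` (mean global efficiency of each node's
  neighbor-induced subgraph; subgraphs smaller than 2 contribute 0);
* nodal degree, unnormalized betweenness (sum over unordered pairs of
  shortest-path fractions; the group t-test is invariant to common
  scaling, so normalization is cosmetic), and nodal efficiency;
* largest connected component size (isolated nodes are size-1
  components, so an empty graph reports 1).

The small-world normalization compares `Cp` and `Lp` to their means
over an ensemble of Maslov–Sneppen degree-preserving rewirings:
`γ = Cp/Cp_rand`, `λ = Lp/Lp_rand`, `σ = γ/λ`, with `γ > 1, λ ≈ 1,
σ > 1` the small-world signature. The rewiring preserves the degree
sequence only, not connectedness — the reference analysis does not
state that its null preserved connectedness, and degree-only is the
default elsewhere. Candidate swaps that would create self-loops or
duplicate edges are rejected and count against the swap budget
(default 100 candidate swaps per edge; ensemble default 1,000
networks). If an ensemble has zero clustering, `γ` (and `σ`) are
reported as missing with a warning, never as infinity.

Curves are reduced by the trapezoid rule over the default grid
0.05–0.50 in steps of 0.01 (46 levels); the trapezoid is exact for
linear curves and the AUC of a constant `c` is `0.45·c`. Missing
levels are dropped pairwise with a warning; fewer than two finite
points is an error.

All hot loops (BFS distances, Brandes betweenness, the rewiring
ensemble across the grid) are implemented in C++ and draw from a
local generator seeded from R's RNG, so every stochastic result is a
pure function of `set.seed`-style integer seeds while the cohort-scale
sweep (46 levels × ensemble × 92 subjects) stays tractable.

### Group statistics (`group_stats`)

`summary_ttest()` is the pooled-variance two-sample t from printed
means/SDs (identical to Welch for equal group sizes), used to
reproduce published demographic and polysomnographic comparisons from
the bundled summary table.

For the network metrics, covariate adjustment (age, BMI, education by
default) is implemented as the **group-coefficient t-test in the joint
linear model** `y ~ group + covariates`. This was a genuinely open
design point: the obvious two-step — residualize `y` on the
covariates, then run a plain two-sample t — is *structurally
conservative* whenever a covariate co-varies with group membership,
because the regression silently removes part of the group contrast's
sampling variability that the subsequent t-test still budgets for. BMI
differs strongly between OSA patients and good sleepers, and with the
two-step approach our null cohorts rejected at ≈1% instead of the
nominal 5%. The joint model (equivalent by Frisch–Waugh–Lovell to
residualizing both the outcome and the group indicator, with the
correct degrees of freedom) restores nominal type-I error — measured
≈5.0% edgewise under null cohorts — and reduces exactly to the pooled
two-sample t when no covariates are supplied. The standalone
`residualize()` utility is still exported for explicit two-step
workflows.

Edgewise tests run on Fisher-z transformed correlations (|r| = 1 is
clipped to 1−10⁻⁷ with a warning); the composite "abnormal
connectivity" score averages *raw* r over the significant edges, which
is how the composite is defined in the motivating analysis. Nodal
tests are Bonferroni-corrected within each metric family with the
number of nodes as multiplier, capped at 1; both corrected and
uncorrected flags are reported because exploratory analyses in this
field conventionally report both. The significant-edge set for the
composite is determined within the analyzed cohort unless an explicit
edge list is supplied.

## The synthetic cohort: what it emulates and what it does not

No subject-level data accompany the motivating study, so the package
ships a generator whose defaults mirror the study conditions: two
groups of 46 subjects, 230 volumes at TR = 2 s, 20 nodes. The
ground-truth model is deliberately minimal:

* a two-point modular correlation structure — within-module r = 0.45,
  between-module r = 0.15, modules being the anterior (8 nodes) and
  posterior (12 nodes) DMN subsystems;
* a planted case-group effect: δ = −0.25 added to 8 posterior edges
  along the PCC–hippocampal–retrosplenial axis (the axis where
  case-control differences are reported in this population);
* Gaussian lag-1 autoregressive signals (AR coefficient 0.3, a typical
  BOLD autocorrelation at TR = 2 s) whose innovation correlation
  carries the target structure — with a common AR coefficient the
  stationary correlation equals the innovation correlation exactly;
* additive linear drift and three shared nuisance signals
  (white-matter-, CSF-, and global-like), both at amplitude 1 (same
  order as the neural signal), which the denoising stages must remove;
* bounded-random-walk motion traces with 0.05 mm/° per-volume steps,
  which makes roughly 4 of 92 subjects fail motion QC — the same
  exclusion count as the motivating study;
* clinical indices drawn from the bundled group summary table, with
  case-group values constructed to correlate at specified strengths
  (MoCA −0.35, delayed memory −0.30, nadir SaO₂ +0.32) with each
  subject's mean connectivity over the affected edges.

If the target correlation matrix stops being positive definite after
delta injection, it is repaired by eigenvalue clipping at 10⁻⁶
followed by re-normalization to unit diagonal, iterated until the
spectrum is positive; an unrepairable matrix is an error that lists
the offending eigenvalues.

**What passing tests show — and what they do not.** The generator
carries exactly the statistical structure the analysis assumes
(stationary Gaussian signals with a modular correlation pattern and a
localized group difference). Recovery results on it validate the
*machinery*: denoising removes what it should, thresholding and
topology are computed correctly, the tests are calibrated, planted
edge effects are detected with high power (edgewise t ≈ −6…−9 on
affected edges, nominal 5% elsewhere). They do not validate the
*biology*: real BOLD data have hemodynamic smoothing, non-stationarity,
spatially structured artifacts, and graded (not two-point) correlation
hierarchies. One consequence of the two-point structure is worth
knowing: because every within-module edge shares the same base
correlation, the attenuated edges rank strictly between the
within- and between-module blocks, so group differences in the
*binarized* graphs are concentrated near the top of the sparsity grid
and AUC summaries of global metrics (notably `Cp`) dilute the planted
effect more than they would on real, graded connectivity. The
per-replicate sign of the `Cp`-AUC contrast is negative in roughly
70 of 100 replicate cohorts under the default conditions — direction
is recovered in the clear majority, but not with the near-certainty
that the enormous edge-level effect might suggest.

## Problem sizes used by the test suite

The replicate studies in the test suite are sized to validate the
claims while staying comfortably inside an ordinary development
machine's patience: the power study runs 100 replicate cohorts at full
study scale with the null ensemble disabled (the clustering
coefficient needs no normalization); the null-calibration study runs
60 replicate cohorts with `n_random = 50` and 10 candidate swaps per
edge; the type-I study runs 200 replicate cohorts without the
ensemble (the edgewise and nodal tests do not use it). The ensemble
defaults for real analyses remain 1,000 networks and 100 swaps per
edge.

## Known limitations

* Image-space preprocessing (slice timing, realignment, segmentation,
  normalization, smoothing) is out of scope: the package starts from
  regional time series, or from an already-normalized 4-D volume for
  sphere extraction only.
* Weighted-graph metrics, community detection, rich-club and
  network-based statistics are not implemented.
* The clinical variables in the generator are cross-sectionally
  correlated with connectivity; no causal or longitudinal structure is
  emulated.
* Betweenness is reported unnormalized; users comparing against tools
  that normalize by `(n−1)(n−2)/2` should rescale.
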