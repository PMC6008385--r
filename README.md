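# dmnet

Graph-theoretic analysis of default mode network (DMN) functional
connectivity for two-group resting-state fMRI studies.

## The problem

In populations such as patients with severe obstructive sleep apnea
(OSA), cognitive complaints are thought to reflect a reorganization of
the DMN rather than damage to any single region. The standard way to
test this is to treat each subject's DMN as a graph — 20 regions of
interest as nodes, thresholded Pearson correlations between their
time series as edges — and compare the two groups' graph topology.
`dmnet` implements that pipeline end to end for R users: time-series
denoising and motion QC, seed-based connectivity, sparsity-thresholded
binary graphs, small-world and efficiency metrics against a
degree-preserving random-network null, threshold-free AUC summaries,
covariate-adjusted group statistics, and clinical correlations. A
synthetic cohort generator with a known planted effect makes every
stage testable against ground truth.

## The model in brief

For each subject, the 20×20 correlation matrix is binarized at every
sparsity level Sp on a fixed grid (0.05–0.50, step 0.01), keeping the
K = round(Sp·N(N−1)/2) strongest edges. At each level the package
computes the clustering coefficient Cp, the harmonic-mean
characteristic path length Lp = n(n−1)/Σ 1/dᵢⱼ (finite even for
disconnected graphs; its exact inverse is the global efficiency
Eglob), the local efficiency Eloc, the largest component size, and
per-node degree kᵢ, betweenness bᵢ and nodal efficiency eᵢ. Cp and Lp
are normalized by their means over an ensemble of Maslov–Sneppen
degree-preserving rewirings:

    γ = Cp / Cp_rand,   λ = Lp / Lp_rand,   σ = γ / λ

with γ > 1, λ ≈ 1, σ > 1 the small-world signature. Each metric's
curve over the grid is reduced to its trapezoidal AUC, and groups are
compared with two-sample t statistics adjusted for age, BMI and
education (the group coefficient of the joint linear model, which is
exactly the pooled two-sample t when no covariates are used). Edgewise
comparisons run on Fisher-z correlations; nodal comparisons are
Bonferroni-corrected within each metric family; the per-subject
"abnormal connectivity" composite is the mean raw r over the
significant edges.

## Worked example

```r
library(dmnet)

# a two-group cohort with 8 posterior DMN edges attenuated by -0.25
co  <- simulate_cohort(n_per_group = 12, t_points = 230, seed = 7)
cfg <- run_config(n_random = 50, swaps_per_edge = 10, seed = 7)
rep <- analyze_cohort(co, cfg)

rep$global_comparison
#>              metric      t df     p
#> 1                cp -0.773 17 0.450
#> 2             eglob  0.801 17 0.434
#> 3              eloc -0.311 17 0.760
#> 4             gamma  0.649 17 0.525
#> 5            lambda -0.616 17 0.546
#> 6 largest_component  0.617 17 0.546
#> 7                lp -0.309 17 0.761
#> 8             sigma  1.015 17 0.324
```

Each row is the covariate-adjusted group contrast of one global
metric's AUC (positive t = first group higher). At n = 12 per group
nothing survives — topological group effects need the full study size
(the test suite demonstrates recovery at 46 + 46). The small-world
regime is nevertheless clear at any size: the mean σ AUC across
subjects, divided by the grid span, is 1.69 here (σ > 1 throughout the
grid), and every subject's largest component reaches all 20 nodes at
high sparsity.

Published summary statistics can be checked directly:

```r
tt <- summary_ttest(58.26, 20.37, 46, 2.51, 1.21, 46)  # AHI, OSA vs GS
#> t = 18.53, df = 90, p = 1.8e-32
```

`write_report(rep, "out/")` writes the group tables (global, edgewise,
nodal), per-subject AUCs, largest-component curves, composite scores,
correlations, the QC report, and a serialized copy of the run
configuration as plain CSV/JSON.

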