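---
title: "Low- and high-order functional connectivity analysis with hofcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low- and high-order functional connectivity analysis with hofcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

hofcnet implements a complete two-group comparison of brain functional
networks built from region-of-interest (ROI) rs-fMRI time series, at two
levels of description:

* **Low-order functional connectivity (LOFC).** Entry $(i,j)$ is the
  Pearson correlation between the averaged BOLD-like signals of regions
  $i$ and $j$ — the classical FC matrix, capturing temporal
  synchronization.
* **High-order functional connectivity (HOFC).** Each region is first
  summarized by its whole-brain connectivity *profile* — its row of the
  Fisher-z transformed LOFC matrix, $z = \operatorname{arctanh}(r)$. The
  HOFC entry $(i,j)$ is the Pearson correlation between the two profiles,
  a "correlation of correlations" capturing topographical similarity of
  the regions' connectivity patterns rather than of their raw signals.

On either matrix the package computes, per subject and per sparsity
threshold: global metrics (clustering coefficient $C_p$, characteristic
path length $L_p$, global and local efficiency $E_{glob}$, $E_{loc}$),
small-world indices ($\gamma = C_p/C_r$, $\lambda = L_p/L_r$,
$\sigma = \gamma/\lambda$, normalized by degree-preserving rewired
nulls), nodal metrics (betweenness $B_c$, degree $D_c$, nodal efficiency
$N_e$), modular intra/inter-connection strengths over a fixed five-module
partition, rich-club organization, the network-based statistic (NBS),
and a LASSO + linear SVM diagnostic classifier under nested
leave-one-out cross-validation.

# Profile correlation: the HOFC construction

Before the second-round correlation, LOFC values are mapped through the
Fisher transform so that the profile entries are approximately normal.
When the profiles of regions $i$ and $j$ are correlated, the entries at
positions $i$ and $j$ are removed from **both** profiles (the default,
`exclude = "both"`). The self-entry of each profile is stored as zero, and
leaving those zeros in place would mechanically depress, while keeping the
cross-entries $z_{ij}$, $z_{ji}$ would mechanically inflate, the profile
similarity; removing the pair from both rows avoids both artifacts. The
alternative conventions remain available via the `exclude` argument.
Negative LOFC values are retained (the transform preserves sign); the
zero-before-transform alternative changes the profiles and is
deliberately not the default.

The implementation computes all $P(P-1)/2$ profile correlations with
sum-corrected closed-form Pearson terms (possible because the stored
diagonal is zero), and the test suite checks it against a loop-wise
brute-force oracle.

# Thresholding and graph metrics

Graphs are formed by **sparsity thresholding**: at sparsity $S$ the
$\lfloor S \cdot P(P-1)/2 \rfloor$ strongest positive off-diagonal values
become binary edges (ties broken by value then edge index, so the edge
set is reproducible). Negative correlations are excluded by default
(`edge_sign = "absolute"` ranks by magnitude instead). The default grid
is $S = 0.06$ to $0.40$ in steps of $0.01$ (35 points); each metric is
additionally summarized by its trapezoidal area under the curve (AUC)
over the grid, and group comparisons default to those AUC values, which
avoids picking a favoured threshold.

All of $C_p$, $L_p$, $\gamma$, $\lambda$, $\sigma$, $E_{glob}$,
$E_{loc}$, $B_c$, $D_c$, $N_e$ use **binary-graph definitions**. This is
the common default of the GRETNA-style tooling this pipeline mirrors, and
it makes closed-form oracles possible (complete graphs, ring lattices,
paths) so every metric is testable against exhaustive enumeration.
Weighted local clustering is used *only* as the classifier's feature
representation, where the weighted form is explicitly the point.
Specific conventions on fragmented graphs: $L_p$ averages over connected
pairs only (the disconnected fraction is reported alongside), while
$E_{glob}$ counts disconnected pairs as zero efficiency, so the two
metrics together still distinguish fragmentation from long paths.

Small-world normalization uses degree-preserving double-edge-swap
rewiring with $10\,E$ attempted swaps per null and a default of 100 nulls
per graph per sparsity; every ensemble is seeded and reproducible. At
desk scale (tests, acceptance script) 20 nulls are used, which is enough
for the calibration bands checked there.

# Mesoscale organization

The five-module partition (SMN, DMN, FPN, VN, SN) is a fixed template,
not data-driven. Published five-module groupings of the 90-region AAL
atlas differ in detail, and the exact assignment behind any given study
is rarely printed; the shipped `aal90_partition()` assigns regions by
standard anatomical membership and is documented as a replaceable
approximation — every function that needs it takes a `partition`
argument, and cohort directories carry their own `partition.csv`.

Rich-club nodes are the 10 regions with the highest binary degree of the
group-averaged network, averaged across the sparsity grid ("top 10" of
90 regions is 11.1%, sometimes quoted as 12%; the count 10 is
implemented exactly). A weighted-strength ranking on the unthresholded
mean matrix is available by flag. Rich sets are derived per group.
Edges then partition into rich-club (both endpoints rich), feeder (one),
and local (neither) connections; group comparisons run on per-subject
class means with the group-level rich set, and on modular strengths
computed from the full weighted matrices.

# NBS

Edgewise statistics come from a least-squares fit of each edge on
intercept + group + covariates (age, gender, education by default), the
exact equivalent of a covariate-adjusted two-sample t-test. Edges with
$p$ below the primary threshold (default $10^{-3}$) form candidate
components; each observed component's edge count is scored against the
permutation distribution of the *maximal* null component size. Group
labels are permuted with covariates kept attached to their subjects —
simple and valid under exchangeability of the group assignment.
Corrected p-values use +1 smoothing, $(1 + \#\{null \ge s\})/(1 + B)$,
so no finite run reports zero. The default corrected threshold is 0.01
with 1000 permutations; 0.05 is the other conventional choice, and both
are plain thresholds on the returned values.

# Classification

Features are per-node Onnela weighted clustering coefficients of the
unthresholded positive-weight matrix,
$c_i = \sum_{j,h}(\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3} / (k_i(k_i-1))$
with weights scaled by the matrix maximum. The protocol is strictly
nested leave-one-out: per fold, standardization parameters, the LASSO
penalty (inner 5-fold CV, logistic LASSO, 50-point log grid) and the
selected feature set are computed on the training fold only, then a
linear SVM with $C = 1$ (the standard soft-margin default) produces the
held-out decision value.
Folds where the LASSO selects nothing fall back to all features and are
flagged. ROC-AUC is the normalized Mann-Whitney statistic on pooled
held-out decision values (decision values, not calibrated
probabilities). Patient is the positive class throughout.

# The synthetic cohort generator

No subject data are distributed with the package, so `generate_cohort()`
produces cohorts with the statistical structure the analyses assume:

* **Sizes and scan length.** 60 patients / 50 controls; 90 regions;
  $T = 239$ timepoints (244 volumes at TR = 2 s minus 5 dropped).
* **Connectivity structure.** Block correlation targets over the module
  partition: within-module $r = 0.35$, between-module $r = 0.10$,
  values in the range typical of band-passed ROI correlations. The
  patient group gets planted effects in the pattern hearing-loss
  cohorts tend to show: $+\delta$ on the SMN–DMN and DMN–VN inter-module
  blocks and $-\delta$ within DMN, with $\delta = 0.12$ — large enough
  that the direction is recoverable at these sample sizes, small
  relative to the baseline contrast. Targets that lose positive
  definiteness are repaired by eigenvalue clamping at $10^{-6}$
  (alternated with unit-diagonal rescaling until stable) and the repair
  distance is reported.
* **Temporal structure.** Signals are a stationary lag-1 autoregressive
  process (default $\phi = 0.3$, in the range seen for band-passed BOLD
  at TR = 2 s) whose innovation covariance is scaled so the stationary
  cross-sectional covariance equals the target exactly.
* **Covariates.** Group-specific normals/Bernoulli describing an
  elderly hearing-loss case-control cohort (age 62.75 ± 7.15 vs
  61.08 ± 3.93 years; education 10.93 ± 2.02 vs 10.78 ± 1.79;
  male fractions 26/60 vs 24/50; per-ear pure-tone averages
  33.10/33.34 vs 17.93/17.40 dB HL, both-ear mean = their average).
  Covariates are independent of connectivity by default; a
  `confound_covariates` switch couples connectivity to age for testing
  covariate adjustment.

What the generator does **not** emulate: voxel-level BOLD physics, head
motion and scanner artifacts, spatial autocorrelation between
neighbouring regions beyond the module blocks, non-stationarity, or
site/batch effects. Passing tests therefore demonstrate the pipeline's
statistical correctness — calibration, recovery of planted effects,
absence of information leakage — not that any particular clinical
finding generalizes.

# Numerical choices and degenerate inputs

* All randomness flows through explicit seeds; one master seed fans out
  to per-stage child seeds (`derive_seed`), so stages rerun
  independently yet reproducibly, and identical configurations produce
  byte-identical output files.
* Correlations at $|r| \ge 1$ are clipped to 0.999999 before the Fisher
  transform (count reported). Constant profiles yield a 0 HOFC entry
  with a warning. Zero-variance regions are a named error.
* The band-pass is a 4th-order zero-phase Butterworth (forward-backward
  application); zero-phase filtering avoids phase distortion of
  correlations. Filter edge transients are intrinsic to finite-length
  zero-phase IIR filtering; re-filtering changes interior samples by
  less than $10^{-6}$ relative norm.
* Rank-deficient nuisance designs use the pseudoinverse with a warning
  rather than erroring, since motion-expansion regressor sets are often
  collinear.
* Thresholding ties are broken by (value, edge index); rich-club ties by
  (mean degree, region index); both deterministic and reported.
* Edges with zero residual variance in the NBS fit get $p \in \{0, 1\}$
  by effect sign, with a log message.

# Problem sizes in the shipped checks

The test-suite and acceptance-script simulations run at desk scale,
chosen so the whole suite completes in minutes while each check retains
its statistical meaning: NBS null calibration uses 40 runs of 20-region,
20-per-group cohorts at 200 permutations; recovery uses a planted
10-edge subnetwork at $\delta = 0.25$, $n = 30/30$; chance-level
classification uses label permutations at the full 60/50 sizes;
modular-effect recovery regenerates the full default cohort across 20
seeds. Small-world calibration uses Erdős–Rényi graphs (their own null
family, so $\gamma \approx \lambda \approx 1$) and Watts–Strogatz graphs
(the canonical small-world regime, $\sigma > 1$) at $N = 90$.

# Known limitations

* The template partition is an approximation; analyses sensitive to
  exact module boundaries should supply their own table.
* Static HOFC only — no sliding-window or dynamic variants.
* Binary-graph metrics only for topology (weighted variants exist in the
  literature but are not needed here and are out of scope).
* The permutation schemes assume exchangeability of group labels given
  covariates; strong covariate imbalance would call for restricted
  permutations, which are not implemented.
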