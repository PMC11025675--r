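# hofcnet

Graph-theoretic analysis of **low-order** and **high-order** functional
connectivity networks from region-of-interest rs-fMRI time series, for
two-group (patient vs control) study designs.

Low-order functional connectivity (LOFC) is the classical FC matrix: entry
(i, j) is the Pearson correlation r between the averaged BOLD signals of
regions i and j. High-order functional connectivity (HOFC) treats each
region's whole-brain connectivity profile — its row of the Fisher-z matrix
z = arctanh(r) — as the object of interest, and correlates *profiles*:

    HOFC(i, j) = cor( z[i, -(i,j)], z[j, -(i,j)] )

a "correlation of correlations" that measures how similar two regions'
connectivity topographies are, independently of their raw signal
synchronization. The package builds both networks per subject and runs the
full downstream comparison a connectomics study needs:

- sparsity thresholding (S = 0.06–0.40, step 0.01) with AUC-over-sparsity
  summaries;
- global metrics (Cp, Lp, Eglob, Eloc) and small-world indices
  gamma = Cp/Cr, lambda = Lp/Lr, sigma = gamma/lambda, normalized by
  degree-preserving rewired null networks;
- nodal metrics (betweenness Bc, degree Dc, nodal efficiency Ne) with
  Bonferroni control;
- modular intra/inter-connection strengths over a five-module template
  (SMN, DMN, FPN, VN, SN) and rich-club / feeder / local edge classes;
- the network-based statistic (NBS): covariate-adjusted edgewise tests,
  suprathreshold components, permutation FWE correction;
- a diagnostic classifier: Onnela weighted clustering features, LASSO
  selection, linear SVM, nested leave-one-out cross-validation with
  ACC / SEN / SPE / F-score / ROC-AUC;
- a synthetic two-group cohort generator with planted modular effects that
  stands in for clinical data, plus plain-text cohort I/O and BrainNet
  Viewer `.node`/`.edge` export.

## Worked example

```r
library(hofcnet)

# a small synthetic cohort: 10 patients + 10 controls, 20 regions
cfg <- generator_config(n_patient = 10, n_control = 10, p = 20, t_len = 120,
                        partition = setNames(rep(c("SMN","DMN","FPN","VN","SN"),
                                                 each = 4), paste0("R", 1:20)),
                        seed = 42)
cohort <- generate_cohort(cfg)
cohort
#> cohort_dataset: 20 subjects ( 10 patients / 10 controls ), 20 regions, 120 timepoints, TR = 2 s

# LOFC -> Fisher z -> HOFC for one subject
lofc <- lofc_matrix(cohort$timeseries[[1]], cohort$region_labels)
hofc <- hofc_matrix(fisher_z(lofc))
hofc
#> connectivity_matrix [HOFC], 20 regions, range [-0.773, 0.890]

# threshold at 25% sparsity and compute graph metrics
g  <- threshold_by_sparsity(hofc, 0.25)
unlist(global_metrics(g))[1:4]
#>        cp        lp     eglob      eloc
#> 0.6571429 1.7340426 0.3556140 0.7341071
sw <- small_world(g, rewired_nulls(g, 20, seed = 1))
c(gamma = sw$gamma, lambda = sw$lambda_, sigma = sw$sigma)
#>     gamma    lambda     sigma
#> 2.3461574 0.8666792 2.7070656
```

`gamma > 1` with `lambda` near 1 (hence `sigma > 1`) is the small-world
signature: more clustered than degree-matched random graphs at similar
path length. The planted patient effect (+0.12 on the SMN–DMN block) is
visible in the modular strengths:

```r
d <- sapply(cohort$subjects$subject_id, function(id) {
  ms <- modular_strengths(lofc_matrix(cohort$timeseries[[id]],
                                      cohort$region_labels), cohort$partition)
  inter_strength(ms, "SMN", "DMN")
})
tapply(d, cohort$subjects$group, mean)
#>   control   patient
#> 0.1119969 0.2066116
```

`run_pipeline(run_config(...))` chains every stage (preprocessing,
networks, metrics, mesoscale, NBS, classification, group statistics) and
writes all artifacts plus an md5-hashed manifest to an output directory;
reruns with the same configuration are byte-identical.

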