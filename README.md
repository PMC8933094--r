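# iciLandscape

Immune cell infiltration (ICI) landscape analysis for bulk tumor expression
cohorts, modeled on low-grade glioma (LGG).

Bulk tumor transcriptomes mix malignant cells with infiltrating immune and
stromal cells, and the composition of that infiltrate stratifies patients:
"cold" tumors dominated by M2 macrophages tend to do worse than
immunologically diverse "hot" ones. `iciLandscape` implements the complete
workflow that turns a gene × sample expression matrix plus clinical
follow-up into that stratification:

1. **Deconvolution** — per-sample fractions of 22 leukocyte subsets by
   linear-kernel ν-support-vector regression against an LM22-style signature
   matrix *S* (model *m = S f*, *f* on the unit simplex), with a
   deterministic NNLS mode and permutation p-values.
2. **Immune/stromal scores** — rank-based single-sample enrichment
   (ssGSEA statistic, weight rank^0.25).
3. **ICI subtypes** — Monti consensus clustering of the samples on the
   fraction/score features, with consensus-CDF/delta-area model selection
   (k = 3 by convention for LGG).
4. **Differential expression** — moderated t with empirical-Bayes variance
   shrinkage; DEGs at |FC| > 2 and BH-adjusted p < 0.05 across subtype
   contrasts.
5. **ICI score** — DEG gene clusters (k = 4), signatures A/B split by the
   sign of each gene's correlation with the PC1 cluster axis, Boruta
   all-relevant reduction, and the per-sample score
   **ICI = PC1\_A − PC1\_B**, dichotomized at a maximally selected log-rank
   cutpoint.
6. **Evaluation** — Kaplan–Meier/log-rank survival, Kruskal–Wallis/Wilcoxon
   panels, tumor mutation burden (variants per Mb) with Spearman
   correlation, weighted-KS GSEA between score groups, and Connectivity-Map
   style drug connectivity with a mechanism-of-action summary.

A synthetic cohort generator (`generateCohort()`) plants immune subtypes,
subtype-coupled hazards and mutation burdens, so the whole pipeline is
testable end to end without any external downloads. See the methods
vignette (`vignettes/ici-landscape-methods.Rmd`) for the model details and
design decisions.

## Worked example

```r
library(iciLandscape)

sig    <- generateSignatureMatrix(seed = 1)            # 550 genes x 22 cell types
cohort <- generateCohort(cohortConfig(nSamples = 120, seed = 1), sig)
cohort
#> IciCohort: 620 genes x 120 samples
#>   events: 74/120  median time: 26.4
#>   planted fractions: 22 cell types
#>   variants: 5354 records

fractions <- deconvolveCohort(cohort, sig, nPerm = 0)
fractions
#> CellFractions: 120 samples x 22 cell types
#>   median fit r = 0.987, median RMSE = 0.702

feats <- apply(cellFractions(fractions), 2, scale)
rownames(feats) <- colnames(cohort)
subtypes <- consensusCluster(feats, kRange = 2:9, nResamples = 100,
                             seed = 1, forceK = 3)
table(clusterLabels(subtypes), clinicalTable(cohort)$subtype_true)
#>     subtype1 subtype2 subtype3
#>   1       60        0        0
#>   2        0        0       44
#>   3        0       16        0

cl <- clinicalTable(cohort)
logrankTest(cl$time, cl$event, clusterLabels(subtypes))
#> log-rank chi-square = 47.48 (df = 2), p = 4.9e-11
```

The deconvolved fractions recover the three planted subtypes exactly
(adjusted Rand index 1 in the cross-table), and the subtypes separate
sharply on overall survival — the cold, M2-dominated subtype carries the
planted 0.030/month hazard versus 0.012 and 0.008 for the other two.

`runPipeline(pipelineConfig(...))` chains all stages (deconvolution →
scores → subtypes → DEGs → gene clusters → signatures → ICI score → cutoff →
survival/TMB/GSEA/connectivity), writing one TSV per stage plus a JSON
manifest with parameter values and MD5 hashes; reruns with the same
configuration are bit-identical. A thin command-line wrapper lives at
`inst/scripts/ici-pipeline.R`:

```sh
Rscript inst/scripts/ici-pipeline.R simulate --out cohort_dir --n 500 --seed 1
Rscript inst/scripts/ici-pipeline.R run --config config.yaml --out results
```

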