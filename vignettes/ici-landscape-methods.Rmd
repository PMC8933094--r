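---
title: "Methods: the immune cell infiltration landscape workflow"
author: "iciLandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the immune cell infiltration landscape workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`iciLandscape` reconstructs, as one reproducible pipeline, the
immune-cell-infiltration (ICI) analysis style used for bulk tumor cohorts such
as low-grade glioma: per-sample immune cell fractions are estimated from a
leukocyte signature matrix, samples are grouped into ICI subtypes by consensus
clustering, differentially expressed genes between subtypes are condensed into
two opposing gene signatures, and a per-sample scalar — the ICI score — is
formed from their principal components and evaluated against survival,
mutation burden, pathway enrichment, and drug-connectivity readouts.

This vignette documents the statistical model behind each stage, the tunable
parameters and their defaults, the design decisions taken where the
methodology was genuinely open, and what the synthetic cohorts used for
testing do and do not establish.

# Deconvolution

The mixture model is linear: a bulk expression vector $m$ is assumed to be
$m = S f$ with $S$ the genes-by-cell-types signature matrix (LM22-style, 22
leukocyte subsets) and $f$ a non-negative fraction vector summing to one.
Following the published CIBERSORT recipe, the signature matrix is
standardized by a *single* global mean and standard deviation (per-column
z-scoring would destroy the proportionality between regression coefficients
and fractions), the mixture vector is z-scored over the shared genes, and a
linear-kernel $\nu$-support-vector regression is fitted at
$\nu \in \{0.25, 0.5, 0.75\}$; the fit with the lowest reconstruction RMSE is
kept, negative coefficients are clipped, and the rest normalized to the unit
simplex. The reported diagnostics are the reconstruction RMSE, its Pearson
correlation with the observed mixture, and a permutation p-value.

Two points deserve emphasis:

* **An exact deterministic mode.** `deconvolveSample(method = "nnls")` solves
  the same problem by non-negative least squares on the linear scale. On
  noiseless full-rank mixtures it is exact to machine precision, which the
  SVR is not (its regularization leaves residual error, around $10^{-4}$ in
  fractions at the 550-gene scale and much larger on tiny toy systems). The
  NNLS route is therefore the reference for exact-recovery checks, and the
  two routes are required to agree within a fraction RMSE of 0.05 on
  noiseless input.
* **A shared permutation null.** `deconvolveCohort()` builds one null
  distribution of reconstruction correlations from `nPerm` gene-permuted
  mixtures drawn across the cohort (the behavior of the original batch
  implementation) rather than permuting per sample; `permutationPvalue()`
  still offers the per-sample variant. All permutation p-values use the
  add-one estimator $(1 + \#\{r_\text{null} \ge r\})/(n_\text{perm}+1)$ and can
  never be zero.

# Immune and stromal scores

Stromal and immune content are summarized by a rank-based single-sample
enrichment statistic (the ssGSEA form): within a sample, genes are ranked,
the in-set empirical CDF is weighted by $\text{rank}^\alpha$ (default
$\alpha = 0.25$), and the score is the summed difference between the in-set
and out-set CDFs. The statistic is invariant to monotone transformations of
expression within a sample. The published 141-gene stromal/immune signatures
of the original ESTIMATE method are **not** bundled (they are third-party
supplementary data); the pipeline takes a user GMT with sets named `immune`
and `stromal`, and `tmeGeneSets()` derives synthetic stand-ins from a block
signature matrix for testing. No score-to-purity conversion is provided.

# Consensus clustering

Cluster stability is assessed in the resampling framework of Monti et al.:
`nResamples = 100` subsamples of `pItem = 80%` of samples are each clustered
hierarchically for every $k$ in 2..9, and the consensus index of a pair is
its co-clustering frequency among the subsamples containing both. Model
selection uses the area under the consensus CDF: `chosenK` is the largest
$k$ whose relative area increase (delta area) reaches 0.1; both pipeline
stages can force $k$ instead (3 for ICI subtypes, 4 for gene clusters, the
conventional choices).

**Linkage.** The inner and final clusterer default to Ward (`ward.D2`)
linkage rather than the average linkage many consensus-clustering wrappers
default to. On compositional cell-fraction features, average linkage chains:
single outlier samples (a consequence of the Dirichlet tails) are peeled off
as singleton "clusters" while two genuine subtypes stay merged; in repeated
synthetic cohorts this reduced the planted-partition adjusted Rand index from
1.0 to below 0.5 in about half of the runs, while Ward recovered the planted
partition essentially always. The `linkage` argument restores the
average-linkage behavior when desired.

Subtype clustering operates by default on the 22 estimated cell fractions
plus the immune and stromal scores, each z-scored (`clusterFeatures =
"fractions"` restricts to fractions alone). `pcaValidate()` projects the
samples onto the first two principal components and reports the
between-cluster to total variance ratio in that plane; the projection is
centered but *not* scaled to unit variance, because after unit-variance
scaling uncorrelated features are indistinguishable to the PCA and a
separation carried by a single feature is hidden.

# Differential expression

Expression enters the tests as $\log_2(\text{TPM}+1)$. The per-gene
statistic is a moderated t: the pooled two-group variance $s_g^2$ on $d_g$
degrees of freedom is shrunk toward a prior,
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, with $(d_0, s_0^2)$
estimated by moment matching on the log-variances (the scaled-F model,
including the Newton inversion of the trigamma function). The total degrees
of freedom are capped at the pooled residual df of the data set. `priorDf`
exposes the prior: 0 recovers the ordinary two-sample t exactly, `Inf` fully
pools. The implementation agrees with the established empirical-Bayes
reference implementation to near machine precision on shared inputs, which
the test suite verifies.

DEGs among the (three) ICI subtypes are the union over all pairwise
contrasts of genes with $|\log_2 FC| > 1$ and Benjamini-Hochberg adjusted
$p < 0.05$; a one-vs-rest design is available (`deMode`), and the retaining
contrasts are recorded per gene. Over-representation of gene sets uses the
one-sided hypergeometric tail with BH adjustment across terms.

# The ICI score

Gene clusters (default $k = 4$) come from consensus clustering of the
samples on z-scored DEG expression. "Positive and negative correlation to
the gene clusters" is operationalized through a continuous **cluster axis**:
the first principal component of the sample-by-DEG z-score matrix, oriented
to correlate positively with the ordering of the gene clusters by mean
expression (clusters are categorical, so a correlation against them directly
is undefined; the PC1 axis is the natural continuous surrogate). DEGs
correlating positively with the axis form signature A, negatively signature
B.

Each signature is then reduced by Boruta, implemented in-package: in every
iteration, column-shuffled "shadow" copies of all live features join a
random-forest fit (via `ranger`), and a feature scores a hit when its
importance exceeds the best shadow's. Importance is **out-of-bag permutation
importance**: impurity importance is computed on the training splits and
rewards noise features whose chance in-sample correlation persists across
iterations, which produced spurious confirmations on pure-noise inputs;
OOB permutation importance does not. Decisions use a two-sided binomial test
on the hit counts with a Bonferroni guard across features
(`alpha = 0.01`, `maxIter = 100`); features still undecided at the end are
resolved by comparing their median importance to the median shadow maximum.
As an all-relevant selector, duplicated informative features are both kept.

For each confirmed signature a PCA on the z-scored expression yields
unit-norm PC1 loadings, a centering vector, and a sign fixed so the
component correlates positively with the signature's mean z-expression (PCA
signs are otherwise arbitrary; without this convention the score's direction
would be seed-dependent). The per-sample score is
$\text{ICI} = \text{PC1}_A - \text{PC1}_B$, reading the summation in the
published score formula as one component per signature. Validation cohorts
are z-scored within themselves and projected through the stored loadings
without refitting (a refit is a one-line alternative); signature genes
missing from a validation cohort are dropped, with an error once more than
half a signature is absent.

The high/low split replaces the interactive cutpoint-optimization software
with a **maximally selected log-rank scan**: every midpoint between sorted
unique scores that leaves at least `minGroupFrac = 10%` of the cohort on
each side is evaluated by the two-group log-rank chi-square and the maximum
is taken, ties resolved toward the median. This reproduces the intent
(an outcome-optimal cutpoint) deterministically.

# Survival statistics, TMB, GSEA, connectivity

Kaplan-Meier estimation and the log-rank statistic are delegated to the
`survival` package; Kruskal-Wallis and Wilcoxon tests and the hypergeometric
tail come from base R. Spearman's $\rho$ is computed as Pearson on average
ranks (the tie-robust form of the classical $1 - 6\sum d^2/(n(n^2-1))$
formula) with the two-sided t approximation for its p-value. TMB is the
variant count per sample divided by the interrogated exome length, default
38 Mb (the analysis defines the ratio but not the denominator; 38 Mb is the
conventional whole-exome size), counting non-synonymous classes by default
with an all-classes switch. Panel comparisons (fractions, checkpoint and
immune-activity genes by group) report raw-threshold significance stars with
no cross-feature adjustment, matching the usual figure presentation.

GSEA is the weighted Kolmogorov-Smirnov running sum (weight $p = 1$),
with **gene-set permutation** as the default null — the analysis description
names gene-set permutation even though a phenotype label is set, and a
sample-permutation mode is provided for the alternative reading. NES divides
the ES by the mean same-sign permuted ES; the FDR q follows the standard
procedure over the signed null NES pool.

Connectivity scoring follows the 2006 Connectivity Map formulation: for each
reference rank profile the two-sided KS statistics of the up and the down
tag set are combined (zero when they share a sign, $ks_{up} - ks_{down}$
otherwise) and scaled into $[-1, 1]$ by the extreme raw value across
instances. Compound-level statistics mirror the classical result table:
mean score, instance count, a KS enrichment of the compound's instances
within the score-ordered instance list, an add-one permutation p from
equal-size random instance sets, a specificity defined as the fraction of
that null panel reaching the observed $|enrichment|$ (an approximation — the
original service's specificity panel is not public), and the percent of
instances sharing the mean's sign. Real reference data is not bundled;
`generateReferenceProfiles()` builds synthetic rank collections with planted
signature-reversing compounds.

# The synthetic cohort generator

`generateCohort()` defines the study conditions under which every stage is
tested. Per sample: a subtype is drawn (defaults: three subtypes at
48/15/37%), a cell-fraction vector comes from the subtype's Dirichlet,
expression is $S f$ with multiplicative log-normal noise
(`noiseSd = 0.1`) rescaled to TPM, survival is exponential with the
subtype's hazard under independent exponential censoring, and variant counts
are Poisson. The default design plants the biology the downstream analysis
is meant to detect:

* subtype 1 ("cold", 48%) concentrates its Dirichlet mass on M2 macrophages,
  dendritic and resting mast cells, carries the highest hazard
  (0.030/month vs 0.012 and 0.008) and the highest expected mutation count
  (60 vs 35 and 30);
* subtypes 2 and 3 spread over complementary lymphoid/myeloid panels, so
  that many marker blocks are elevated in the "hot" samples and the
  DEG-wide mean expression — which orients the cluster axis — is higher in
  them. Low ICI scores therefore coincide with the poor-prognosis,
  high-TMB subtype, and the score-TMB Spearman correlation is negative by
  construction.
* a small stromal gene block outside the signature tracks the latent
  stromal-adjacent cell content (coupling 0.8 on the log scale), giving the
  immune/stromal scores a planted positive correlation, and 50 unstructured
  background genes provide null material.

The signature matrix default is 22 cell types with 25 markers each, marker
fold 30 over background with 15% log-normal jitter. The fold is chosen so
that between-subtype marker fold changes clear the $|FC| > 2$ DEG cutoff for
all subtypes (at fold 10 only the cold subtype's markers passed, which
starves the signatures); concentration parameters (12/8/8 over a baseline of
1) keep the fraction vectors compact enough that the planted partition is
recoverable, an explicit design requirement of the generator.

What the generator does **not** emulate: real gene-level abundance
distributions, gene-gene correlation beyond the mixture structure, batch or
platform effects, covariate-dependent hazards, or mutational signatures.
Passing tests demonstrate that the machinery is correct and powered under
the linear mixture model with log-normal noise — not that any particular
biological conclusion transfers to real cohorts.

# Numerical choices and degenerate inputs

* Z-scoring maps zero-variance genes to zero rather than NaN; zero-variance
  features are dropped before PCA.
* All-zero expression columns, all-zero mixtures, constant feature matrices,
  single-class targets, gene sets covering the whole universe, cohorts with
  no admissible survival cutpoint, and zero-event survival data raise
  immediate, named errors.
* All-tied rank tests return p = 1 by convention; singleton clusters have
  item and cluster consensus 1.
* Samples with survival time 0 are removed at load.
* Every stochastic stage takes an explicit seed; the pipeline fans a master
  seed out to fixed per-stage seeds recorded in the manifest, and two runs
  with one configuration are bit-identical (hash-checked in the tests).

# Problem sizes

The test suite and the acceptance script exercise: 550-gene/22-type
signatures; 50-sample noisy deconvolution; consensus clustering at $n = 120$
with 100 resamples over 50 seeds; 2000-gene DE calibration; log-rank power
at $n = 200$ over 100 replicates; and two full 200-sample pipeline runs
(250 permutations, 100 resamples) for the end-to-end and reproducibility
checks. These sizes keep a complete run on one CPU within a few minutes
while leaving every statistical check well-powered.

# Known limitations

* The SVR deconvolution inherits CIBERSORT's limitations: closely collinear
  cell types trade fractions, and absolute (non-simplex) abundances are out
  of scope.
* Boruta on strongly correlated signatures confirms liberally (by design —
  it is an all-relevant selector), so confirmed signature sizes should not
  be read as minimal gene sets.
* The connectivity "specificity" column approximates the original service's
  non-public reference panel with the permutation null.
* The moderated t assumes a common variance prior across genes; no
  mean-variance trend (voom-style weighting) is modeled.
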