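Package: iciLandscape
Title: Immune Cell Infiltration Landscape Analysis for Bulk Tumor Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes the immune cell infiltration (ICI) landscape of bulk
    tumor expression cohorts, modeled on low-grade glioma. Provides
    support-vector-regression deconvolution of immune cell fractions against a
    leukocyte signature matrix, rank-based single-sample immune and stromal
    enrichment scores, Monti consensus clustering with CDF/delta-area model
    selection for ICI subtyping, moderated-t differential expression,
    Boruta all-relevant gene selection, a PCA-based per-sample ICI score with a
    survival-optimal high/low cutoff, Kaplan-Meier/log-rank and tumor mutation
    burden statistics, gene set enrichment analysis, and Connectivity-Map-style
    drug connectivity scoring. A synthetic cohort generator with planted
    immune subtypes, subtype-coupled hazards and mutation burdens makes the
    whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    pracma,
    ranger,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
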