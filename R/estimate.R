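#' Single-sample gene set enrichment score
#'
#' Rank-based single-sample enrichment statistic (the ssGSEA form underlying
#' stromal/immune scoring): genes are ranked by expression within the sample
#' (ties by average rank), the in-set empirical CDF is weighted by
#' `rank^alpha` (normalized), the out-set CDF is unweighted, and the score is
#' the sum over the ranked list of the difference between the two CDFs. The
#' statistic depends on the expression values only through their ranks, so it
#' is invariant to monotone transformations within the sample.
#'
#' @param expression named numeric vector of expression over genes.
#' @param geneSet character vector of gene identifiers.
#' @param alpha rank-weighting exponent (default 0.25).
#' @return Single numeric enrichment score.
#' @export
ssgseaScore <- function(expression, geneSet, alpha = 0.25) {
  shared <- intersect(geneSet, names(expression))
  if (length(shared) == 0)
    stop("gene set has no genes in common with the expression vector")
  if (length(shared) == length(expression))
    stop("gene set covers every gene; the out-of-set CDF is undefined")
  z <- rank(expression, ties.method = "average")
  ord <- order(z, decreasing = TRUE)
  inSet <- names(expression)[ord] %in% shared
  w <- (z[ord]^alpha) * inSet
  pin <- cumsum(w) / sum(w)
  pout <- cumsum(!inSet) / sum(!inSet)
  sum(pin - pout)
}

#' Immune and stromal enrichment scores for a cohort
#'
#' Computes per-sample [ssgseaScore()] values for an immune and a stromal
#' gene set (the ESTIMATE-style tumor-microenvironment readout). No
#' cross-sample normalization is applied; scores are comparable within a
#' cohort through the common gene universe.
#'
#' @param expression genes x samples matrix or an [IciCohort-class].
#' @param stromalSet,immuneSet character vectors of gene identifiers.
#' @param alpha rank-weighting exponent (default 0.25).
#' @return data.frame with columns `sample`, `immune_score`, `stromal_score`.
#' @export
estimateCohort <- function(expression, stromalSet, immuneSet, alpha = 0.25) {
  if (methods::is(expression, "IciCohort"))
    expression <- SummarizedExperiment::assay(expression, "tpm")
  if (!length(stromalSet) || !length(immuneSet))
    stop("both gene sets must be non-empty")
  immune <- apply(expression, 2, ssgseaScore, geneSet = immuneSet, alpha = alpha)
  stromal <- apply(expression, 2, ssgseaScore, geneSet = stromalSet, alpha = alpha)
  data.frame(sample = colnames(expression), immune_score = immune,
             stromal_score = stromal, row.names = NULL,
             stringsAsFactors = FALSE)
}
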