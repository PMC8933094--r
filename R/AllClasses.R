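#' @import methods
#' @importFrom stats cor prcomp sd var rnorm rexp rpois rgamma runif rbinom
#'   quantile median pt pf pchisq phyper p.adjust hclust cutree dist as.dist
#'   kruskal.test wilcox.test cor.test ks.test pbinom setNames
#' @importFrom utils read.delim write.table head packageVersion combn
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Cohort container for ICI landscape analysis
#'
#' `IciCohort` extends [SummarizedExperiment::SummarizedExperiment] with a
#' TPM-scale expression assay and per-sample clinical annotation
#' (`time`, `event`, and optional covariates) in `colData`. Synthetic cohorts
#' additionally carry the planted ground truth: the per-sample cell-type
#' fraction matrix (`trueFractions`) and a MAF-like variant table
#' (`variantTable`) in the object metadata.
#'
#' @slot .Data inherited `SummarizedExperiment` slots.
#' @seealso [generateCohort()], [writeCohort()], [readCohort()]
#' @export
setClass("IciCohort", contains = "SummarizedExperiment")

setValidity("IciCohort", function(object) {
  msg <- character()
  if (!"tpm" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'tpm' is required")
  cd <- SummarizedExperiment::colData(object)
  for (col in c("time", "event"))
    if (!col %in% colnames(cd)) msg <- c(msg, sprintf("colData column '%s' is required", col))
  if ("time" %in% colnames(cd) && any(cd$time <= 0))
    msg <- c(msg, "survival times must be strictly positive")
  if ("event" %in% colnames(cd) && !all(cd$event %in% c(0, 1)))
    msg <- c(msg, "event must be 0 (censored) or 1 (death)")
  tf <- S4Vectors::metadata(object)$trueFractions
  if (!is.null(tf)) {
    if (nrow(tf) != ncol(object))
      msg <- c(msg, "trueFractions rows must match samples")
    else if (any(abs(rowSums(tf) - 1) > 1e-9))
      msg <- c(msg, "trueFractions rows must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an IciCohort
#'
#' @param expression numeric gene x sample matrix on a linear (TPM-like) scale.
#' @param clinical data.frame with one row per sample; must contain `time`
#'   (positive survival time) and `event` (1 = death, 0 = censored).
#' @param trueFractions optional sample x cell-type simplex matrix (ground
#'   truth of a synthetic cohort).
#' @param variants optional MAF-like data.frame (`Tumor_Sample_Barcode`,
#'   `Hugo_Symbol`, `Variant_Classification`, `Start_Position`).
#' @param signature optional signature matrix used to generate the cohort.
#' @return An [IciCohort-class] object.
#' @export
IciCohort <- function(expression, clinical, trueFractions = NULL,
                      variants = NULL, signature = NULL) {
  expression <- as.matrix(expression)
  stopifnot(!is.null(rownames(expression)))
  if (is.null(colnames(expression))) {
    if (ncol(expression) > 0) stop("expression columns must be named by sample")
    colnames(expression) <- character(0)
  }
  if (!is.null(clinical$sample)) rownames(clinical) <- clinical$sample
  clinical <- clinical[colnames(expression), , drop = FALSE]
  md <- list()
  if (!is.null(trueFractions)) md$trueFractions <- as.matrix(trueFractions)
  if (!is.null(variants)) md$variants <- variants
  if (!is.null(signature)) md$signature <- as.matrix(signature)
  new("IciCohort", SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = expression),
    colData = S4Vectors::DataFrame(clinical),
    metadata = md))
}

#' @describeIn IciCohort planted sample x cell-type fraction matrix (or NULL).
#' @param x an `IciCohort`.
#' @export
trueFractions <- function(x) S4Vectors::metadata(x)$trueFractions

#' @describeIn IciCohort MAF-like variant table (or NULL).
#' @export
variantTable <- function(x) S4Vectors::metadata(x)$variants

#' @describeIn IciCohort clinical annotation as a plain data.frame.
#' @export
clinicalTable <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

setMethod("show", "IciCohort", function(object) {
  cat(sprintf("IciCohort: %d genes x %d samples\n", nrow(object), ncol(object)))
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("  events: %d/%d  median time: %.3g\n",
              sum(cd$event), ncol(object), median(cd$time)))
  if (!is.null(trueFractions(object)))
    cat(sprintf("  planted fractions: %d cell types\n", ncol(trueFractions(object))))
  if (!is.null(variantTable(object)))
    cat(sprintf("  variants: %d records\n", nrow(variantTable(object))))
  invisible(NULL)
})

#' Per-sample immune cell fraction estimates
#'
#' Holds the output of [deconvolveCohort()]: a sample x cell-type fraction
#' matrix (rows on the unit simplex) together with per-sample fit diagnostics
#' (reconstruction RMSE, Pearson r, permutation p-value).
#'
#' @slot fractions numeric sample x cell-type matrix; rows sum to 1 (all-zero
#'   rows flag samples whose fit failed).
#' @slot stats data.frame with columns `sample`, `rmse`, `pearson_r`, `perm_p`.
#' @export
setClass("CellFractions",
         representation(fractions = "matrix", stats = "data.frame"))

setValidity("CellFractions", function(object) {
  msg <- character()
  fr <- object@fractions
  if (any(fr < -1e-12)) msg <- c(msg, "fractions must be non-negative")
  rs <- rowSums(fr)
  if (!all(abs(rs - 1) < 1e-9 | rs == 0))
    msg <- c(msg, "fraction rows must sum to 1 (or be all-zero for unfit samples)")
  st <- object@stats
  if (nrow(st) != nrow(fr)) msg <- c(msg, "stats rows must match fraction rows")
  if (any(!is.na(st$perm_p) & (st$perm_p < 0 | st$perm_p > 1)))
    msg <- c(msg, "perm_p must lie in [0, 1]")
  if (any(!is.na(st$rmse) & st$rmse < 0)) msg <- c(msg, "rmse must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn CellFractions the sample x cell-type fraction matrix.
#' @param object a `CellFractions` object.
#' @export
setGeneric("cellFractions", function(object) standardGeneric("cellFractions"))

#' @rdname CellFractions-class
#' @export
setMethod("cellFractions", "CellFractions", function(object) object@fractions)

#' @describeIn CellFractions per-sample fit diagnostics.
#' @export
setGeneric("fitStats", function(object) standardGeneric("fitStats"))

#' @rdname CellFractions-class
#' @export
setMethod("fitStats", "CellFractions", function(object) object@stats)

setMethod("show", "CellFractions", function(object) {
  cat(sprintf("CellFractions: %d samples x %d cell types\n",
              nrow(object@fractions), ncol(object@fractions)))
  cat(sprintf("  median fit r = %.3f, median RMSE = %.3f\n",
              median(object@stats$pearson_r, na.rm = TRUE),
              median(object@stats$rmse, na.rm = TRUE)))
  invisible(NULL)
})

#' Consensus clustering result
#'
#' Stores, for every candidate cluster number k, the resampling-based
#' consensus matrix (pairwise co-clustering frequency), the empirical CDF of
#' its off-diagonal entries, the area under that CDF and its relative
#' increase (delta area), the final sample labels, and item/cluster consensus
#' summaries. `chosenK` is the cluster number selected by the delta-area
#' criterion (or forced by the caller).
#'
#' @slot kRange integer vector of evaluated k.
#' @slot consensus named list of sample x sample consensus matrices, one per k.
#' @slot labels named list of integer label vectors, one per k.
#' @slot cdf named list of data.frames (`grid`, `cdf`), one per k.
#' @slot area numeric area under the consensus CDF per k.
#' @slot deltaArea numeric relative area increase per k (`area` itself at k=2).
#' @slot itemConsensus named list of per-sample mean within-cluster consensus.
#' @slot clusterConsensus named list of per-cluster mean consensus.
#' @slot chosenK selected cluster number.
#' @export
setClass("ConsensusResult",
         representation(kRange = "integer", consensus = "list", labels = "list",
                        cdf = "list", area = "numeric", deltaArea = "numeric",
                        itemConsensus = "list", clusterConsensus = "list",
                        chosenK = "integer"))

setValidity("ConsensusResult", function(object) {
  msg <- character()
  for (k in object@kRange) {
    m <- object@consensus[[as.character(k)]]
    if (is.null(m)) { msg <- c(msg, sprintf("missing consensus matrix for k=%d", k)); next }
    if (max(abs(m - t(m))) > 1e-12) msg <- c(msg, sprintf("consensus matrix k=%d not symmetric", k))
    if (any(m < -1e-12 | m > 1 + 1e-12)) msg <- c(msg, sprintf("consensus entries k=%d outside [0,1]", k))
    if (any(abs(diag(m) - 1) > 1e-12)) msg <- c(msg, sprintf("consensus diagonal k=%d must be 1", k))
  }
  if (!(object@chosenK %in% object@kRange))
    msg <- c(msg, "chosenK must be one of kRange")
  if (length(msg)) msg else TRUE
})

#' @describeIn ConsensusResult consensus matrix at a given k.
#' @param object a `ConsensusResult`.
#' @param k cluster number (defaults to `chosenK`).
#' @export
setGeneric("consensusMatrix", function(object, k) standardGeneric("consensusMatrix"))

#' @rdname ConsensusResult-class
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(object, k) {
  if (missing(k)) k <- object@chosenK
  object@consensus[[as.character(k)]]
})

#' @describeIn ConsensusResult cluster labels at a given k.
#' @export
setGeneric("clusterLabels", function(object, k) standardGeneric("clusterLabels"))

#' @rdname ConsensusResult-class
#' @export
setMethod("clusterLabels", "ConsensusResult", function(object, k) {
  if (missing(k)) k <- object@chosenK
  object@labels[[as.character(k)]]
})

#' @describeIn ConsensusResult delta-area profile over k.
#' @export
setGeneric("deltaArea", function(object) standardGeneric("deltaArea"))

#' @rdname ConsensusResult-class
#' @export
setMethod("deltaArea", "ConsensusResult", function(object) object@deltaArea)

#' @describeIn ConsensusResult selected cluster number.
#' @export
setGeneric("chosenK", function(object) standardGeneric("chosenK"))

#' @rdname ConsensusResult-class
#' @export
setMethod("chosenK", "ConsensusResult", function(object) object@chosenK)

setMethod("show", "ConsensusResult", function(object) {
  n <- nrow(object@consensus[[1]])
  cat(sprintf("ConsensusResult: %d samples, k in %d..%d, chosen k = %d\n",
              n, min(object@kRange), max(object@kRange), object@chosenK))
  cat("  delta area:",
      paste(sprintf("k%d=%.3f", object@kRange, object@deltaArea), collapse = " "), "\n")
  invisible(NULL)
})

#' Fitted ICI score model
#'
#' Captures everything needed to score a new cohort: the two ICI gene
#' signatures (A: genes positively associated with the gene-cluster axis;
#' B: negatively associated), the Boruta-confirmed subsets actually used for
#' scoring, the unit-norm PC1 loadings of each confirmed signature with the
#' PCA centering vector and a fixed sign convention, and the gene-cluster
#' labels the signatures were derived from.
#'
#' @slot signatureA,signatureB character gene identifiers (disjoint).
#' @slot confirmedA,confirmedB Boruta-confirmed subsets of the signatures.
#' @slot loadingsA,loadingsB named unit-norm PC1 loadings.
#' @slot centerA,centerB named PCA centering vectors (z-score scale).
#' @slot signA,signB +1/-1 sign fixing each PC1 to correlate positively with
#'   its signature's mean z-expression.
#' @slot geneClusters factor of gene-cluster labels per training sample.
#' @export
setClass("IciModel",
         representation(signatureA = "character", signatureB = "character",
                        confirmedA = "character", confirmedB = "character",
                        loadingsA = "numeric", loadingsB = "numeric",
                        centerA = "numeric", centerB = "numeric",
                        signA = "numeric", signB = "numeric",
                        geneClusters = "factor"))

setValidity("IciModel", function(object) {
  msg <- character()
  if (length(intersect(object@signatureA, object@signatureB)))
    msg <- c(msg, "signatures A and B must be disjoint")
  if (!all(object@confirmedA %in% object@signatureA))
    msg <- c(msg, "confirmedA must be a subset of signatureA")
  if (!all(object@confirmedB %in% object@signatureB))
    msg <- c(msg, "confirmedB must be a subset of signatureB")
  for (nm in c("loadingsA", "loadingsB")) {
    v <- slot(object, nm)
    if (length(v) && abs(sqrt(sum(v^2)) - 1) > 1e-6)
      msg <- c(msg, sprintf("%s must have unit norm", nm))
  }
  if (!object@signA %in% c(-1, 1) || !object@signB %in% c(-1, 1))
    msg <- c(msg, "sign conventions must be +1 or -1")
  if (length(msg)) msg else TRUE
})

#' @describeIn IciModel gene identifiers of a signature.
#' @param object an `IciModel`.
#' @param which `"A"` or `"B"`.
#' @param confirmed return only the Boruta-confirmed subset?
#' @export
setGeneric("signatureGenes",
           function(object, which = c("A", "B"), confirmed = FALSE)
             standardGeneric("signatureGenes"))

#' @rdname IciModel-class
#' @export
setMethod("signatureGenes", "IciModel", function(object, which = c("A", "B"),
                                                 confirmed = FALSE) {
  which <- match.arg(which)
  if (confirmed) {
    if (which == "A") object@confirmedA else object@confirmedB
  } else {
    if (which == "A") object@signatureA else object@signatureB
  }
})

setMethod("show", "IciModel", function(object) {
  cat(sprintf("IciModel: signature A %d genes (%d confirmed), signature B %d genes (%d confirmed)\n",
              length(object@signatureA), length(object@confirmedA),
              length(object@signatureB), length(object@confirmedB)))
  cat(sprintf("  gene clusters: %s\n",
              paste(sprintf("%s=%d", levels(object@geneClusters),
                            tabulate(object@geneClusters)), collapse = " ")))
  invisible(NULL)
})
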