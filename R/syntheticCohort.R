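#' Names of the 22 leukocyte reference cell types
#'
#' The standard 22 leukocyte subsets of the LM22 reference signature, in
#' their conventional order. Used to label synthetic signature matrices of
#' 22 cell types.
#'
#' @return Character vector of length 22.
#' @export
lm22CellTypes <- function() {
  c("B cells naive", "B cells memory", "Plasma cells", "T cells CD8",
    "T cells CD4 naive", "T cells CD4 memory resting",
    "T cells CD4 memory activated", "T cells follicular helper",
    "T cells regulatory (Tregs)", "T cells gamma delta", "NK cells resting",
    "NK cells activated", "Monocytes", "Macrophages M0", "Macrophages M1",
    "Macrophages M2", "Dendritic cells resting", "Dendritic cells activated",
    "Mast cells resting", "Mast cells activated", "Eosinophils", "Neutrophils")
}

#' Generate a block-structured leukocyte signature matrix
#'
#' Builds an LM22-like reference profile matrix: each cell type owns a block
#' of `markersPerType` marker genes elevated `markerFold`-fold over the
#' `baseLevel` background, with multiplicative log-normal jitter. The result
#' has full column rank by construction, so noiseless mixtures are exactly
#' identifiable.
#'
#' @param nTypes number of cell types (>= 2); with 22, columns are named
#'   after the standard LM22 subsets.
#' @param markersPerType marker genes per cell type (>= 1).
#' @param baseLevel background expression level (linear scale, > 0).
#' @param markerFold fold elevation of a marker in its own type (> 0).
#' @param jitterSd sd of the log-normal jitter; 0 gives the exact block design.
#' @param seed integer seed; the same seed reproduces the matrix bit-identically.
#' @return Numeric genes x cell-types matrix (`nTypes * markersPerType` rows).
#' @examples
#' s <- generateSignatureMatrix(nTypes = 2, markersPerType = 1,
#'                              baseLevel = 1, markerFold = 10, jitterSd = 0)
#' @export
generateSignatureMatrix <- function(nTypes = 22, markersPerType = 25,
                                    baseLevel = 1, markerFold = 30,
                                    jitterSd = 0.15, seed = 1) {
  if (nTypes < 2 || markersPerType < 1)
    stop("nTypes must be >= 2 and markersPerType >= 1")
  if (baseLevel <= 0 || markerFold <= 0)
    stop("baseLevel and markerFold must be positive")
  set.seed(seed)
  types <- if (nTypes == 22) lm22CellTypes() else sprintf("CellType%02d", seq_len(nTypes))
  nGenes <- nTypes * markersPerType
  mat <- matrix(baseLevel, nrow = nGenes, ncol = nTypes)
  for (t in seq_len(nTypes)) {
    rows <- (t - 1) * markersPerType + seq_len(markersPerType)
    mat[rows, t] <- baseLevel * markerFold
  }
  if (jitterSd > 0)
    mat <- mat * exp(matrix(rnorm(length(mat), 0, jitterSd), nrow = nGenes))
  rownames(mat) <- unlist(lapply(seq_len(nTypes), function(t)
    sprintf("mk%02d_%02d", t, seq_len(markersPerType))))
  colnames(mat) <- types
  mat
}

#' Marker gene sets of a block signature matrix
#'
#' Assigns every gene to the cell type in which it is most expressed and
#' returns the per-type marker lists, usable as GMT-style gene sets.
#'
#' @param signature genes x cell-types matrix.
#' @return Named list of character vectors (one per cell type).
#' @export
markerGeneSets <- function(signature) {
  idx <- apply(signature, 1, which.max)
  split(rownames(signature), factor(colnames(signature)[idx],
                                    levels = colnames(signature)))
}

#' Configuration of a synthetic LGG-like cohort
#'
#' Bundles and validates every knob of the generator. The defaults describe
#' the study conditions the package is exercised under: a ~500-sample cohort
#' with three planted immune subtypes in roughly 48/15/37 percent proportions,
#' a "cold" majority subtype dominated by M2 macrophages and resting
#' stromal-adjacent cell types with the worst survival and the highest
#' mutation burden, and two immunologically diverse subtypes with better
#' outcomes.
#'
#' @param nSamples cohort size.
#' @param nSubtypes number of planted immune subtypes.
#' @param subtypeProportions simplex weights over subtypes (sum to 1).
#' @param dirichletConcentration `nSubtypes` x `nTypes` matrix of positive
#'   Dirichlet concentrations, one row per subtype; `NULL` builds the default
#'   three-subtype design for 22 cell types.
#' @param noiseSd sd of the multiplicative log-normal expression noise.
#' @param hazardPerSubtype exponential death hazard per subtype (1/month).
#' @param censorRate exponential censoring rate (0 = no censoring).
#' @param tmbMeanPerSubtype expected variant count per subtype.
#' @param exomeLengthMb interrogated exome length in megabases.
#' @param nStromalGenes stromal marker genes appended outside the signature.
#' @param stromalCoupling log-scale slope tying stromal genes to the latent
#'   stromal content (fractions of M2/dendritic/mast types).
#' @param nNullGenes unstructured background genes appended.
#' @param seed integer seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohortConfig <- function(nSamples = 500,
                         nSubtypes = 3,
                         subtypeProportions = c(0.48, 0.15, 0.37),
                         dirichletConcentration = NULL,
                         noiseSd = 0.1,
                         hazardPerSubtype = c(0.030, 0.012, 0.008),
                         censorRate = 0.008,
                         tmbMeanPerSubtype = c(60, 35, 30),
                         exomeLengthMb = 38,
                         nStromalGenes = 20,
                         stromalCoupling = 0.8,
                         nNullGenes = 50,
                         seed = 1) {
  cfg <- list(nSamples = nSamples, nSubtypes = nSubtypes,
              subtypeProportions = subtypeProportions,
              dirichletConcentration = dirichletConcentration,
              noiseSd = noiseSd, hazardPerSubtype = hazardPerSubtype,
              censorRate = censorRate, tmbMeanPerSubtype = tmbMeanPerSubtype,
              exomeLengthMb = exomeLengthMb, nStromalGenes = nStromalGenes,
              stromalCoupling = stromalCoupling, nNullGenes = nNullGenes,
              seed = seed)
  class(cfg) <- "cohort_config"
  .validateCohortConfig(cfg)
  cfg
}

.validateCohortConfig <- function(cfg) {
  stopifnot(cfg$nSamples >= cfg$nSubtypes)
  if (abs(sum(cfg$subtypeProportions) - 1) > 1e-9)
    stop("subtypeProportions must sum to 1")
  if (length(cfg$subtypeProportions) != cfg$nSubtypes)
    stop("subtypeProportions length must equal nSubtypes")
  if (any(c(cfg$noiseSd, cfg$hazardPerSubtype, cfg$censorRate,
            cfg$tmbMeanPerSubtype) < 0))
    stop("rates and standard deviations must be non-negative")
  if (length(cfg$hazardPerSubtype) != cfg$nSubtypes ||
      length(cfg$tmbMeanPerSubtype) != cfg$nSubtypes)
    stop("hazardPerSubtype and tmbMeanPerSubtype must have one entry per subtype")
  if (!is.null(cfg$dirichletConcentration)) {
    dc <- cfg$dirichletConcentration
    if (any(dc <= 0)) stop("Dirichlet concentrations must all be positive")
    if (nrow(dc) != cfg$nSubtypes)
      stop("dirichletConcentration needs one row per subtype")
  }
  invisible(cfg)
}

# default three-subtype Dirichlet design over the 22 LM22 cell types:
# subtype 1 concentrates on M2/dendritic/mast compartments ("cold"),
# subtypes 2 and 3 spread over complementary lymphoid/myeloid panels ("hot")
.defaultConcentration <- function(nSubtypes, nTypes) {
  base <- matrix(1, nrow = nSubtypes, ncol = nTypes)
  if (nSubtypes == 3 && nTypes == 22) {
    base[1, c(16, 17, 18, 19)] <- 12           # M2, DCs, resting mast
    base[2, c(3, 4, 6, 9, 14, 22)] <- 8        # plasma, CD8, CD4mr, Treg, M0, neut
    base[3, c(2, 4, 8, 12, 13, 20, 21)] <- 8   # Bmem, CD8, Tfh, NKact, mono, mast, eos
  } else {
    # spread the mass cyclically so every subtype favors a distinct block
    per <- max(1L, floor(nTypes / nSubtypes))
    for (s in seq_len(nSubtypes)) {
      idx <- ((s - 1) * per + seq_len(per) - 1L) %% nTypes + 1L
      base[s, idx] <- 6
    }
  }
  base
}

#' Generate a synthetic cohort with planted immune subtypes
#'
#' Draws a subtype per sample, a cell-fraction vector from that subtype's
#' Dirichlet, and forms bulk expression as `signature %*% fractions` with
#' multiplicative log-normal noise, TPM-rescaled. Survival is exponential
#' with the subtype's hazard under independent exponential censoring;
#' per-sample variant counts are Poisson with the subtype's mean. A small
#' block of stromal marker genes (tied to the latent stromal-adjacent cell
#' content) and unstructured background genes are appended outside the
#' signature so that enrichment scoring and null behavior are exercisable.
#'
#' @param config a [cohortConfig()] list.
#' @param signature genes x cell-types signature matrix; its column count must
#'   match the Dirichlet design.
#' @return An [IciCohort-class] carrying expression, clinical annotation
#'   (`time`, `event`, `subtype_true`, Table-1-style covariates), the true
#'   fraction matrix and a MAF-like variant table.
#' @export
generateCohort <- function(config = cohortConfig(),
                           signature = generateSignatureMatrix()) {
  .validateCohortConfig(config)
  nTypes <- ncol(signature)
  dc <- config$dirichletConcentration
  if (is.null(dc)) dc <- .defaultConcentration(config$nSubtypes, nTypes)
  if (ncol(dc) != nTypes)
    stop("Dirichlet design has ", ncol(dc), " cell types but signature has ", nTypes)
  set.seed(config$seed)
  n <- config$nSamples
  ids <- sprintf("S%04d", seq_len(n))

  subtype <- sample.int(config$nSubtypes, n, replace = TRUE,
                        prob = config$subtypeProportions)
  fractions <- matrix(NA_real_, n, nTypes,
                      dimnames = list(ids, colnames(signature)))
  for (s in seq_len(config$nSubtypes)) {
    idx <- which(subtype == s)
    if (length(idx)) fractions[idx, ] <- .rdirichlet(length(idx), dc[s, ])
  }

  expr <- signature %*% t(fractions)
  if (config$noiseSd > 0)
    expr <- expr * exp(matrix(rnorm(length(expr), 0, config$noiseSd),
                              nrow = nrow(expr)))

  extra <- NULL
  if (config$nStromalGenes > 0) {
    stromalTypes <- intersect(c("Macrophages M2", "Dendritic cells resting",
                                "Dendritic cells activated", "Mast cells resting"),
                              colnames(signature))
    latent <- if (length(stromalTypes))
      .zscore(rowSums(fractions[, stromalTypes, drop = FALSE]))
    else .zscore(fractions[, 1])
    stromal <- outer(rep(3 * mean(signature), config$nStromalGenes),
                     exp(config$stromalCoupling * latent))
    stromal <- stromal * exp(matrix(rnorm(length(stromal), 0, config$noiseSd + 0.05),
                                    nrow = nrow(stromal)))
    rownames(stromal) <- sprintf("str_%02d", seq_len(config$nStromalGenes))
    extra <- stromal
  }
  if (config$nNullGenes > 0) {
    nullg <- matrix(mean(signature) * exp(rnorm(config$nNullGenes * n, 0, 0.3)),
                    nrow = config$nNullGenes)
    rownames(nullg) <- sprintf("hk_%02d", seq_len(config$nNullGenes))
    extra <- rbind(extra, nullg)
  }
  if (!is.null(extra)) {
    colnames(extra) <- ids
    expr <- rbind(expr, extra)
  }
  colnames(expr) <- ids
  expr <- .tpmRescale(expr)

  deathTime <- rexp(n, rate = config$hazardPerSubtype[subtype])
  censTime <- if (config$censorRate > 0) rexp(n, rate = config$censorRate) else rep(Inf, n)
  time <- pmin(deathTime, censTime)
  event <- as.integer(deathTime <= censTime)

  clinical <- data.frame(
    sample = ids,
    time = time,
    event = event,
    subtype_true = paste0("subtype", subtype),
    age_group = sample(c("<=50", ">50"), n, TRUE, prob = c(0.70, 0.30)),
    gender = sample(c("female", "male"), n, TRUE, prob = c(0.45, 0.55)),
    idh = sample(c("mutant", "wildtype"), n, TRUE, prob = c(0.80, 0.20)),
    codel_1p19q = sample(c("codel", "non-codel"), n, TRUE, prob = c(0.30, 0.70)),
    mgmt = sample(c("methylated", "unmethylated"), n, TRUE, prob = c(0.80, 0.20)),
    stringsAsFactors = FALSE)

  nVar <- rpois(n, lambda = config$tmbMeanPerSubtype[subtype])
  classes <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
               "Frame_Shift_Ins", "Splice_Site", "Silent")
  classProb <- c(0.55, 0.08, 0.07, 0.05, 0.05, 0.20)
  total <- sum(nVar)
  variants <- data.frame(
    Tumor_Sample_Barcode = rep(ids, nVar),
    Hugo_Symbol = sample(rownames(expr), total, replace = TRUE),
    Variant_Classification = sample(classes, total, TRUE, prob = classProb),
    Start_Position = sample.int(3e7L, total, replace = TRUE),
    stringsAsFactors = FALSE)

  IciCohort(expr, clinical, trueFractions = fractions, variants = variants,
            signature = signature)
}

#' Write a cohort to a directory of TSV files
#'
#' Emits `expression.tsv` (first column `gene`, one column per sample),
#' `clinical.tsv`, `variants.tsv` (MAF-like minimal columns) and, when the
#' cohort carries one, `signature.tsv`. The files round-trip losslessly
#' through [readCohort()].
#'
#' @param cohort an [IciCohort-class].
#' @param directory output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeCohort <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  expr <- SummarizedExperiment::assay(cohort, "tpm")
  paths <- c(expression = file.path(directory, "expression.tsv"),
             clinical = file.path(directory, "clinical.tsv"),
             variants = file.path(directory, "variants.tsv"))
  exprDf <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                       stringsAsFactors = FALSE)
  write.table(exprDf, paths["expression"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(clinicalTable(cohort), paths["clinical"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  variants <- variantTable(cohort)
  if (is.null(variants))
    variants <- data.frame(Tumor_Sample_Barcode = character(),
                           Hugo_Symbol = character(),
                           Variant_Classification = character(),
                           Start_Position = integer())
  write.table(variants, paths["variants"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  sig <- S4Vectors::metadata(cohort)$signature
  if (!is.null(sig)) {
    paths <- c(paths, signature = file.path(directory, "signature.tsv"))
    sigDf <- data.frame(gene = rownames(sig), sig, check.names = FALSE,
                        stringsAsFactors = FALSE)
    write.table(sigDf, paths["signature"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param directory directory containing `expression.tsv` and `clinical.tsv`
#'   (and optionally `variants.tsv`, `signature.tsv`).
#' @return An [IciCohort-class].
#' @export
readCohort <- function(directory) {
  expr <- loadExpression(file.path(directory, "expression.tsv"))
  clinical <- loadClinical(file.path(directory, "clinical.tsv"))
  vp <- file.path(directory, "variants.tsv")
  variants <- if (file.exists(vp)) loadVariants(vp) else NULL
  sp <- file.path(directory, "signature.tsv")
  signature <- if (file.exists(sp)) loadExpression(sp) else NULL
  IciCohort(expr, clinical, variants = variants, signature = signature)
}

#' Generate synthetic drug-perturbation reference rank profiles
#'
#' Builds a genes x instances matrix of expression ranks emulating a
#' Connectivity-Map-style reference collection: each compound contributes
#' several instances whose profiles follow a compound-specific template with
#' noise. Compounds listed in `reversers` are given profiles anti-correlated
#' with `template` (genes high in the template rank low), i.e. planted
#' signature-reversing hits; the rest are unrelated.
#'
#' @param genes gene universe (character).
#' @param nCompounds number of compounds.
#' @param instancesPerCompound instances (replicate profiles) per compound.
#' @param template optional named numeric vector over (a subset of) `genes`;
#'   larger values mean higher expression in the query phenotype.
#' @param reversers indices of compounds whose profiles reverse the template.
#' @param noiseSd sd of the Gaussian noise added before ranking.
#' @param seed integer seed.
#' @return List with `ranks` (genes x instances, rank 1 = highest),
#'   `instances` (data.frame instance/compound), and `moa` (compound
#'   mechanism-of-action annotation; reversers share one mechanism).
#' @export
generateReferenceProfiles <- function(genes, nCompounds = 8,
                                      instancesPerCompound = 3,
                                      template = NULL, reversers = integer(),
                                      noiseSd = 0.5, seed = 1) {
  set.seed(seed)
  nG <- length(genes)
  tpl <- rep(0, nG); names(tpl) <- genes
  if (!is.null(template)) {
    shared <- intersect(names(template), genes)
    tpl[shared] <- .zscore(template[shared])
  }
  compounds <- sprintf("compound_%02d", seq_len(nCompounds))
  inst <- expand.grid(rep = seq_len(instancesPerCompound),
                      compound = compounds, stringsAsFactors = FALSE)
  inst$instance <- sprintf("%s_i%d", inst$compound, inst$rep)
  ranks <- matrix(NA_integer_, nG, nrow(inst),
                  dimnames = list(genes, inst$instance))
  for (i in seq_len(nrow(inst))) {
    ci <- match(inst$compound[i], compounds)
    base <- if (ci %in% reversers) -2 * tpl else rnorm(nG, 0, 0.2)
    score <- base + rnorm(nG, 0, noiseSd)
    # rank 1 = most up-regulated by the perturbation
    ranks[, i] <- rank(-score, ties.method = "first")
  }
  mech <- sample(c("dopamine receptor antagonist", "PPAR receptor agonist",
                   "HDAC inhibitor", "adrenergic receptor agonist"),
                 nCompounds, replace = TRUE)
  mech[reversers] <- "dopamine receptor antagonist"
  list(ranks = ranks,
       instances = inst[, c("instance", "compound")],
       moa = data.frame(compound = compounds, mechanism = mech,
                        stringsAsFactors = FALSE))
}
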