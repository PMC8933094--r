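#' Convert FPKM to TPM
#'
#' Per sample: `tpm_g = fpkm_g / sum(fpkm) * 1e6`, so every column sums to
#' one million.
#'
#' @param fpkm non-negative genes x samples matrix.
#' @return TPM matrix of the same shape.
#' @export
fpkmToTpm <- function(fpkm) {
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  .tpmRescale(fpkm)
}

#' Load a genes x samples expression TSV
#'
#' First column gene identifiers, remaining columns one per sample, linear
#' scale. Duplicate gene rows are collapsed by keeping the highest-expressed
#' row (largest mean), with a warning counting the duplicates.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames.
#' @export
loadExpression <- function(path) {
  if (!file.size(path) > 0) stop("empty expression file: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed expression header in ", path,
                         ": need a gene column plus at least one sample")
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    badRow <- which(is.na(suppressWarnings(as.numeric(df[[bad + 1]]))))[1]
    stop("non-numeric expression value near line ", badRow + 1, " of ", path)
  }
  rownames(mat) <- genes
  if (anyDuplicated(genes)) {
    nDup <- sum(duplicated(genes))
    warning(nDup, " duplicated gene row(s) collapsed by maximum expression")
    ord <- order(genes, -rowMeans(mat))
    mat <- mat[ord, , drop = FALSE]
    mat <- mat[!duplicated(rownames(mat)), , drop = FALSE]
    mat <- mat[unique(genes), , drop = FALSE]
  }
  mat
}

#' Load a clinical TSV
#'
#' Requires columns `sample`, `time`, `event`. Samples with a survival time
#' of zero are excluded at load, with a message.
#'
#' @param path TSV path.
#' @return data.frame keyed by `sample`.
#' @export
loadClinical <- function(path) {
  if (!file.size(path) > 0) stop("empty clinical file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("clinical file ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.numeric(df$time) || !is.numeric(df$event))
    stop("clinical time/event must be numeric in ", path)
  zero <- df$time <= 0
  if (any(zero)) {
    message(sum(zero), " sample(s) with survival time 0 removed at load")
    df <- df[!zero, , drop = FALSE]
  }
  rownames(df) <- df$sample
  df
}

#' Load a MAF-like variants TSV
#'
#' Minimal dialect: `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification`, `Start_Position`.
#'
#' @param path TSV path.
#' @return data.frame of variant records.
#' @export
loadVariants <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("variants file ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Immune/stromal gene sets for a synthetic signature
#'
#' Builds the two tumor-microenvironment gene sets the enrichment-scoring
#' stage expects: `immune` collects the marker genes of the lymphoid cell
#' types (T, B and NK cells) of a block signature matrix, `stromal` is the
#' supplied stromal gene list (e.g. the generator's appended stromal block).
#'
#' @param signature genes x cell-types matrix.
#' @param stromalGenes character vector of stromal marker genes.
#' @return Named list with elements `immune` and `stromal`.
#' @export
tmeGeneSets <- function(signature, stromalGenes) {
  markers <- markerGeneSets(signature)
  lymphoid <- grepl("T cells|B cells|NK cells|Plasma", names(markers))
  if (!any(lymphoid)) lymphoid <- seq_along(markers) <= ceiling(length(markers) / 2)
  list(immune = unname(unlist(markers[lymphoid])),
       stromal = stromalGenes)
}

#' Pipeline configuration
#'
#' Collects every input path and stage parameter of [runPipeline()], with the
#' analysis defaults surfaced as named keys: fold-change cutoff 2, adjusted-p
#' cutoff 0.05, GSEA FDR cutoff 0.05, 3 immune subtypes, 4 gene clusters,
#' 1000 permutations.
#'
#' @param expression path to the expression TSV (linear scale).
#' @param clinical path to the clinical TSV.
#' @param signature path to the signature-matrix TSV.
#' @param variants optional path to a MAF-like TSV (TMB stage skipped when
#'   absent).
#' @param tmeGmt optional GMT with sets `immune` and `stromal` (enrichment
#'   scoring skipped when absent; clustering then uses fractions only).
#' @param pathwaysGmt optional GMT of pathway sets for ORA and GSEA (those
#'   stages are skipped when absent).
#' @param referenceRanks optional path to a genes x instances rank TSV for
#'   connectivity scoring.
#' @param instanceInfo optional TSV (`instance`, `compound`).
#' @param moa optional TSV (`compound`, `mechanism`).
#' @param validateExpression,validateClinical optional validation-cohort
#'   paths; the trained model is projected onto this cohort and re-split at
#'   its own optimal cutoff.
#' @param outDir output directory.
#' @param isFpkm input expression is FPKM and must be converted to TPM.
#' @param nPerm permutations (deconvolution null, GSEA, connectivity).
#' @param deconvMethod `"nusvr"` (default) or the deterministic `"nnls"`
#'   deconvolution mode.
#' @param fcCut,adjpCut DEG cutoffs (`|FC| > 2`, adjusted p < 0.05).
#' @param fdrCut GSEA FDR cutoff.
#' @param kSubtypes,kGeneClusters forced cluster numbers (3 and 4).
#' @param nResamples,pItem consensus clustering parameters.
#' @param clusterFeatures `"fractions_estimate"` (default) clusters on cell
#'   fractions plus immune/stromal scores; `"fractions"` on fractions alone.
#' @param deMode `"pairwise"` or `"one_vs_rest"` DEG design.
#' @param minGroupFrac minimum group fraction for the score cutoff scan.
#' @param exomeLengthMb TMB denominator (default 38).
#' @param ssgseaAlpha rank-weight exponent of the enrichment scores.
#' @param gseaWeight GSEA weighting exponent.
#' @param minSetSize minimum GSEA set size.
#' @param borutaTrees,borutaMaxIter,borutaAlpha Boruta parameters.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return A validated list of class `pipeline_config`.
#' @export
pipelineConfig <- function(expression, clinical, signature,
                           variants = NULL, tmeGmt = NULL, pathwaysGmt = NULL,
                           referenceRanks = NULL, instanceInfo = NULL,
                           moa = NULL, validateExpression = NULL,
                           validateClinical = NULL, outDir = "ici_results",
                           isFpkm = FALSE, nPerm = 1000,
                           deconvMethod = c("nusvr", "nnls"),
                           fcCut = 2, adjpCut = 0.05, fdrCut = 0.05,
                           kSubtypes = 3, kGeneClusters = 4,
                           nResamples = 100, pItem = 0.8,
                           clusterFeatures = c("fractions_estimate", "fractions"),
                           deMode = c("pairwise", "one_vs_rest"),
                           minGroupFrac = 0.1, exomeLengthMb = 38,
                           ssgseaAlpha = 0.25, gseaWeight = 1, minSetSize = 5,
                           borutaTrees = 300, borutaMaxIter = 100,
                           borutaAlpha = 0.01, seed = 1) {
  cfg <- as.list(environment())
  cfg$clusterFeatures <- match.arg(clusterFeatures)
  cfg$deMode <- match.arg(deMode)
  cfg$deconvMethod <- match.arg(deconvMethod)
  required <- c("expression", "clinical", "signature")
  for (key in required)
    if (!file.exists(cfg[[key]]))
      stop("required input file missing: ", key, " = ", cfg[[key]])
  for (key in c("variants", "tmeGmt", "pathwaysGmt", "referenceRanks",
                "instanceInfo", "moa", "validateExpression", "validateClinical"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("configured input file missing: ", key, " = ", cfg[[key]])
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipelineConfig()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  pathKeys <- c("expression", "clinical", "signature", "variants", "tmeGmt",
                "pathwaysGmt", "referenceRanks", "instanceInfo", "moa",
                "validateExpression", "validateClinical")
  for (key in intersect(pathKeys, names(raw)))
    if (!startsWith(raw[[key]], "/")) raw[[key]] <- file.path(base, raw[[key]])
  do.call(pipelineConfig, raw)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full ICI landscape pipeline
#'
#' Executes the whole workflow in order: load and TPM-normalize, immune-cell
#' deconvolution, immune/stromal enrichment scores, ICI subtype consensus
#' clustering (k = 3 by default), subtype survival and cell-fraction panels,
#' DEGs among subtypes, gene clusters (k = 4), ICI gene signatures A/B with
#' Boruta reduction, per-sample ICI scores and the survival-optimal high/low
#' cutoff, group survival and fraction/checkpoint/activity panels, TMB
#' comparison with Spearman correlation, GSEA between score groups, DEGs
#' between score groups, and connectivity scoring with a
#' mechanism-of-action summary. Every stage writes its table before the next
#' starts; optional inputs that are absent skip their stage with a notice.
#' A JSON manifest with parameter values and MD5 hashes of every output
#' accompanies the tables; runs with an identical configuration are
#' bit-identical.
#'
#' @param config a [pipelineConfig()] list.
#' @return Invisibly, a list with the key result objects (`fractions`,
#'   `estimate`, `subtypes`, `degs`, `geneClusters`, `model`, `scores`,
#'   `stats`, `validation`) and the `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "iciLandscape",
                   version = as.character(packageVersion("iciLandscape")),
                   seed = config$seed,
                   parameters = config[!(names(config) %in% c("outDir"))],
                   stages = list())
  results <- list()
  outputs <- character()

  record <- function(stage, paths, notes = NULL) {
    manifest$stages[[length(manifest$stages) + 1]] <<- list(
      stage = stage,
      outputs = as.list(setNames(as.character(tools::md5sum(paths)),
                                 basename(paths))),
      notes = notes)
    outputs <<- c(outputs, paths)
  }
  runStage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- load ------------------------------------------------------------------
  runStage("load", function() {
    expr <- loadExpression(config$expression)
    if (config$isFpkm) expr <- fpkmToTpm(expr)
    clinical <- loadClinical(config$clinical)
    shared <- intersect(colnames(expr), clinical$sample)
    droppedExpr <- setdiff(colnames(expr), shared)
    droppedClin <- setdiff(clinical$sample, shared)
    if (length(droppedExpr) || length(droppedClin))
      message("sample intersection: ", length(droppedExpr),
              " expression-only and ", length(droppedClin),
              " clinical-only sample(s) excluded")
    results$expression <<- expr[, shared, drop = FALSE]
    results$clinical <<- clinical[shared, , drop = FALSE]
    results$signatureMatrix <<- loadExpression(config$signature)
    manifest$stages[[length(manifest$stages) + 1]] <<- list(
      stage = "load", n_samples = length(shared),
      excluded = c(droppedExpr, droppedClin))
  })
  expr <- results$expression
  clinical <- results$clinical
  sig <- results$signatureMatrix
  logExpr <- log2(expr + 1)

  # -- deconvolution ---------------------------------------------------------
  runStage("deconvolve", function() {
    fr <- deconvolveCohort(expr, sig, nPerm = config$nPerm,
                           seed = .stageSeed(config$seed, "deconvolve"),
                           method = config$deconvMethod)
    results$fractions <<- fr
    tab <- data.frame(sample = fitStats(fr)$sample, cellFractions(fr),
                      fitStats(fr)[, c("rmse", "pearson_r", "perm_p")],
                      check.names = FALSE)
    record("deconvolve", .writeTsv(tab, file.path(outDir, "cell_fractions.tsv")))
  })

  # -- immune / stromal scores ----------------------------------------------
  if (!is.null(config$tmeGmt)) runStage("estimate", function() {
    sets <- readGmt(config$tmeGmt)
    if (!all(c("immune", "stromal") %in% names(sets)))
      stop("tmeGmt must contain sets named 'immune' and 'stromal'")
    est <- estimateCohort(expr, sets$stromal, sets$immune,
                          alpha = config$ssgseaAlpha)
    results$estimate <<- est
    record("estimate", .writeTsv(est, file.path(outDir, "estimate_scores.tsv")))
  }) else message("notice: no tmeGmt configured; enrichment scoring skipped")

  # -- ICI subtype clustering ------------------------------------------------
  runStage("cluster", function() {
    feats <- apply(cellFractions(results$fractions), 2, .zscore)
    if (config$clusterFeatures == "fractions_estimate" &&
        !is.null(results$estimate)) {
      feats <- cbind(feats,
                     immune_score = .zscore(results$estimate$immune_score),
                     stromal_score = .zscore(results$estimate$stromal_score))
    }
    rownames(feats) <- colnames(expr)
    cc <- consensusCluster(feats, kRange = 2:9,
                           nResamples = config$nResamples, pItem = config$pItem,
                           seed = .stageSeed(config$seed, "cluster"),
                           forceK = config$kSubtypes)
    results$subtypes <<- factor(LETTERS[clusterLabels(cc)])
    results$subtypeConsensus <<- cc
    pv <- pcaValidate(feats, results$subtypes)
    labTab <- data.frame(sample = colnames(expr),
                         subtype = results$subtypes,
                         pc1 = pv$coordinates[, 1], pc2 = pv$coordinates[, 2])
    da <- cdfDeltaArea(cc)$table
    p1 <- .writeTsv(labTab, file.path(outDir, "ici_subtypes.tsv"))
    p2 <- .writeTsv(da, file.path(outDir, "subtype_delta_area.tsv"))
    record("cluster", c(p1, p2),
           notes = sprintf("pca separation %.3f", pv$separation))
  })

  # -- subtype survival and fraction panels ---------------------------------
  runStage("survival_subtypes", function() {
    lr <- logrankTest(clinical$time, clinical$event, results$subtypes)
    km <- kmEstimate(clinical$time, clinical$event, results$subtypes)
    panel <- groupPanel(cellFractions(results$fractions), results$subtypes)
    results$stats$subtype_logrank <<- lr
    p1 <- .writeTsv(km, file.path(outDir, "subtype_km.tsv"))
    p2 <- .writeTsv(panel, file.path(outDir, "subtype_fraction_panel.tsv"))
    p3 <- .writeTsv(data.frame(chisq = lr$chisq, df = lr$df, p = lr$p),
                    file.path(outDir, "subtype_logrank.tsv"))
    record("survival_subtypes", c(p1, p2, p3))
  })

  # -- DEGs among subtypes ---------------------------------------------------
  runStage("de", function() {
    de <- degsAmongSubtypes(logExpr, results$subtypes, fcCut = config$fcCut,
                            adjpCut = config$adjpCut, mode = config$deMode)
    if (length(de$degs) < 2)
      stop("fewer than 2 DEGs among subtypes; nothing to build signatures from")
    results$degs <<- de
    allTab <- do.call(rbind, de$tables)
    p1 <- .writeTsv(allTab, file.path(outDir, "de_subtypes.tsv"))
    p2 <- .writeTsv(de$provenance, file.path(outDir, "deg_list.tsv"))
    record("de", c(p1, p2), notes = sprintf("%d DEGs", length(de$degs)))
  })

  # -- gene clusters and ICI model ------------------------------------------
  runStage("score_model", function() {
    degExpr <- logExpr[results$degs$degs, , drop = FALSE]
    gc <- buildGeneClusters(degExpr, k = config$kGeneClusters,
                            nResamples = config$nResamples,
                            pItem = config$pItem,
                            seed = .stageSeed(config$seed, "geneclusters"))
    results$geneClusters <<- gc
    model <- fitIciModel(degExpr, gc, boruta = TRUE,
                         nTrees = config$borutaTrees,
                         maxIter = config$borutaMaxIter,
                         alpha = config$borutaAlpha,
                         seed = .stageSeed(config$seed, "boruta"))
    results$model <<- model
    bundle <- rbind(
      data.frame(gene = model@signatureA, signature = "A",
                 confirmed = model@signatureA %in% model@confirmedA),
      data.frame(gene = model@signatureB, signature = "B",
                 confirmed = model@signatureB %in% model@confirmedB))
    bundle$loading <- NA_real_
    bundle$loading[match(names(model@loadingsA), bundle$gene)] <- model@loadingsA
    bundle$loading[match(names(model@loadingsB), bundle$gene)] <- model@loadingsB
    bundle$pc1_sign <- ifelse(bundle$signature == "A", model@signA, model@signB)
    p1 <- .writeTsv(data.frame(sample = colnames(expr), gene_cluster = gc),
                    file.path(outDir, "gene_clusters.tsv"))
    p2 <- .writeTsv(bundle, file.path(outDir, "ici_model.tsv"))
    record("score_model", c(p1, p2))
  })

  # -- ICI scores and optimal cutoff ----------------------------------------
  runStage("score", function() {
    sc <- computeIciScores(logExpr, results$model)
    cut <- optimalCutoff(sc$ici_score, clinical$time, clinical$event,
                         minGroupFrac = config$minGroupFrac)
    sc$group <- as.character(cut$groups)
    sc$cutoff <- cut$cutoff
    results$scores <<- sc
    results$stats$score_cutoff <<- cut[c("cutoff", "chisq", "p")]
    record("score", .writeTsv(sc, file.path(outDir, "ici_scores.tsv")))
  })
  scoreGroup <- factor(results$scores$group, levels = c("low", "high"))

  # -- score-group survival, panels, TMB ------------------------------------
  runStage("survival_groups", function() {
    lr <- logrankTest(clinical$time, clinical$event, scoreGroup)
    results$stats$group_logrank <<- lr
    km <- kmEstimate(clinical$time, clinical$event, scoreGroup)
    panel <- groupPanel(cellFractions(results$fractions), scoreGroup)
    paths <- c(.writeTsv(km, file.path(outDir, "score_group_km.tsv")),
               .writeTsv(panel, file.path(outDir, "score_group_fraction_panel.tsv")),
               .writeTsv(data.frame(chisq = lr$chisq, df = lr$df, p = lr$p),
                         file.path(outDir, "score_group_logrank.tsv")))
    panelGenes <- intersect(c(immuneCheckpointGenes(), immuneActivityGenes()),
                            rownames(expr))
    if (length(panelGenes)) {
      gp <- groupPanel(t(logExpr[panelGenes, , drop = FALSE]), scoreGroup)
      paths <- c(paths, .writeTsv(gp, file.path(outDir, "immune_gene_panel.tsv")))
    }
    record("survival_groups", paths)
  })

  if (!is.null(config$variants)) runStage("tmb", function() {
    variants <- loadVariants(config$variants)
    tmb <- computeTmb(variants, exomeLengthMb = config$exomeLengthMb,
                      samples = colnames(expr))
    wt <- wilcoxonRankSum(tmb$tmb, scoreGroup)
    sp <- spearmanCorr(results$scores$ici_score, tmb$tmb)
    results$tmb <<- tmb
    results$stats$tmb_wilcoxon <<- wt
    results$stats$tmb_spearman <<- sp
    paths <- c(.writeTsv(tmb, file.path(outDir, "tmb.tsv")),
               .writeTsv(data.frame(wilcoxon_p = wt$p, spearman_rho = sp$rho,
                                    spearman_p = sp$p),
                         file.path(outDir, "tmb_stats.tsv")))
    record("tmb", paths)
  }) else message("notice: no variants file configured; TMB stage skipped")

  # -- ORA of the signatures and GSEA between score groups ------------------
  if (!is.null(config$pathwaysGmt)) {
    sets <- readGmt(config$pathwaysGmt)
    runStage("ora", function() {
      oraA <- oraTest(results$model@signatureA, sets, rownames(expr))
      oraB <- oraTest(results$model@signatureB, sets, rownames(expr))
      paths <- c(.writeTsv(oraA, file.path(outDir, "ora_signatureA.tsv")),
                 .writeTsv(oraB, file.path(outDir, "ora_signatureB.tsv")))
      record("ora", paths)
    })
    runStage("gsea", function() {
      ranked <- rankGenesByPhenotype(logExpr, scoreGroup)
      gs <- gsea(ranked, sets, p = config$gseaWeight, nPerm = config$nPerm,
                 minSize = config$minSetSize,
                 seed = .stageSeed(config$seed, "gsea"))
      gs$significant <- gs$fdr_q < config$fdrCut
      results$gsea <<- gs
      record("gsea", .writeTsv(gs, file.path(outDir, "gsea.tsv")))
    })
  } else message("notice: no pathwaysGmt configured; ORA and GSEA skipped")

  # -- DEGs between score groups --------------------------------------------
  runStage("de_groups", function() {
    de <- moderatedTTest(logExpr, scoreGroup)
    pass <- abs(de$log2fc) > log2(config$fcCut) & de$adj_p < config$adjpCut
    results$deGroups <<- de
    results$upTags <<- de$gene[pass & de$log2fc > 0]
    results$downTags <<- de$gene[pass & de$log2fc < 0]
    record("de_groups", .writeTsv(de, file.path(outDir, "de_score_groups.tsv")),
           notes = sprintf("%d up / %d down in high vs low",
                           length(results$upTags), length(results$downTags)))
  })

  # -- connectivity ----------------------------------------------------------
  if (!is.null(config$referenceRanks)) runStage("connectivity", function() {
    ranks <- loadExpression(config$referenceRanks)
    info <- if (!is.null(config$instanceInfo))
      read.delim(config$instanceInfo, stringsAsFactors = FALSE) else NULL
    if (!length(results$upTags) || !length(results$downTags))
      stop("no up/down tags available for connectivity scoring")
    conn <- cmapConnectivity(results$upTags, results$downTags, ranks,
                             instanceInfo = info, nPerm = config$nPerm,
                             seed = .stageSeed(config$seed, "connectivity"))
    results$connectivity <<- conn
    paths <- .writeTsv(conn$instances, file.path(outDir, "connectivity_instances.tsv"))
    if (!is.null(conn$compounds)) {
      paths <- c(paths, .writeTsv(conn$compounds,
                                  file.path(outDir, "connectivity_compounds.tsv")))
      if (!is.null(config$moa)) {
        moaTab <- read.delim(config$moa, stringsAsFactors = FALSE)
        hits <- conn$compounds$compound[conn$compounds$perm_p < 0.05 &
                                          conn$compounds$mean < 0]
        ms <- moaSummary(hits, moaTab)
        results$moa <<- ms
        paths <- c(paths, .writeTsv(ms, file.path(outDir, "moa_summary.tsv")))
      }
    }
    record("connectivity", paths)
  }) else message("notice: no reference profiles configured; connectivity skipped")

  # -- validation cohort -----------------------------------------------------
  if (!is.null(config$validateExpression) && !is.null(config$validateClinical))
    runStage("validate", function() {
      vexpr <- loadExpression(config$validateExpression)
      if (config$isFpkm) vexpr <- fpkmToTpm(vexpr)
      vclin <- loadClinical(config$validateClinical)
      shared <- intersect(colnames(vexpr), vclin$sample)
      vexpr <- vexpr[, shared, drop = FALSE]
      vclin <- vclin[shared, , drop = FALSE]
      sc <- computeIciScores(log2(vexpr + 1), results$model)
      cut <- optimalCutoff(sc$ici_score, vclin$time, vclin$event,
                           minGroupFrac = config$minGroupFrac)
      sc$group <- as.character(cut$groups)
      sc$cutoff <- cut$cutoff
      lr <- logrankTest(vclin$time, vclin$event, cut$groups)
      results$validation <<- list(scores = sc, logrank = lr)
      paths <- c(.writeTsv(sc, file.path(outDir, "validation_scores.tsv")),
                 .writeTsv(data.frame(chisq = lr$chisq, df = lr$df, p = lr$p),
                           file.path(outDir, "validation_logrank.tsv")))
      record("validate", paths)
    })

  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  results$manifest <- manifest
  results$outputs <- outputs
  invisible(results)
}
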