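#' Consensus gene clusters from DEG expression
#'
#' Clusters the samples on z-scored DEG expression by [consensusCluster()]
#' with a forced cluster number (4 by default, the conventional choice for
#' ICI gene subtypes) and returns lettered labels.
#'
#' @param degExpression DEG x sample matrix (log2 scale recommended).
#' @param k number of gene clusters (>= 2; forced, no model selection).
#' @param nResamples,pItem,seed passed to [consensusCluster()].
#' @return Factor of cluster labels (`A`, `B`, ...) per sample.
#' @export
buildGeneClusters <- function(degExpression, k = 4, nResamples = 100,
                              pItem = 0.8, seed = 1) {
  if (nrow(degExpression) < 2) stop("at least 2 DEGs are required")
  if (is.null(k) || k < 2) stop("k must be at least 2")
  features <- t(.rowZscore(as.matrix(degExpression)))
  res <- consensusCluster(features, kRange = 2:max(3, k),
                          nResamples = nResamples, pItem = pItem,
                          seed = seed, forceK = k)
  lab <- clusterLabels(res)
  factor(LETTERS[lab], levels = LETTERS[seq_len(k)])
}

#' Partition DEGs into ICI gene signatures A and B
#'
#' Operationalizes "correlation to the gene clusters" through a continuous
#' cluster axis: the first principal component of the sample x DEG z-score
#' matrix, oriented to correlate positively with the ordering of the gene
#' clusters by mean expression. DEGs positively correlated with the axis form
#' signature A, negatively correlated DEGs form signature B; genes with zero
#' correlation are dropped with a warning.
#'
#' @param degExpression DEG x sample matrix.
#' @param geneClusters factor of gene-cluster labels per sample
#'   (from [buildGeneClusters()]).
#' @return List with `signatureA`, `signatureB` (character vectors) and
#'   `axis` (the oriented per-sample cluster axis).
#' @export
partitionSignatures <- function(degExpression, geneClusters) {
  z <- .rowZscore(as.matrix(degExpression))
  pc <- prcomp(t(z), center = TRUE, scale. = FALSE)
  axis <- pc$x[, 1]
  meanExpr <- colMeans(z)
  clusterMean <- tapply(meanExpr, geneClusters, mean)
  ordScore <- rank(clusterMean)[as.character(geneClusters)]
  orient <- suppressWarnings(cor(axis, ordScore))
  if (is.na(orient) || orient == 0) orient <- cor(axis, meanExpr)
  if (!is.na(orient) && orient < 0) axis <- -axis
  r <- apply(z, 1, function(g) suppressWarnings(cor(g, axis)))
  r[is.na(r)] <- 0
  if (any(r == 0))
    warning(sum(r == 0), " gene(s) with zero correlation to the cluster axis dropped")
  sigA <- rownames(degExpression)[r > 0]
  sigB <- rownames(degExpression)[r < 0]
  if (!length(sigA) || !length(sigB))
    stop("degenerate model: all genes correlate with the cluster axis in one direction")
  list(signatureA = sigA, signatureB = sigB, axis = axis)
}

#' Boruta all-relevant feature selection
#'
#' Iteratively compares each feature's random-forest importance to the
#' maximum importance among "shadow" features (column-shuffled copies of the
#' real features). Per iteration a tentative feature scores a hit when it
#' beats the best shadow; across iterations a two-sided binomial test at
#' `alpha` confirms features hitting significantly more than half the time
#' and rejects those hitting significantly less. Rejected features leave the
#' model; after `maxIter` the remaining tentative features are resolved by
#' comparing their median importance with the median of the shadow maxima.
#' Being an all-relevant selector, duplicated informative features are both
#' retained.
#'
#' @param features sample x feature numeric matrix.
#' @param target class label per sample (>= 2 classes).
#' @param nTrees trees per random forest (default 300).
#' @param maxIter maximum iterations (default 100).
#' @param alpha two-sided significance level for the binomial decisions
#'   (default 0.01).
#' @param seed integer seed.
#' @return List with `confirmed`, `rejected`, `tentative` (resolved set is
#'   included in `confirmed`/`rejected`), `decision` (named character) and
#'   `iterations` used.
#' @export
borutaSelect <- function(features, target, nTrees = 300, maxIter = 100,
                         alpha = 0.01, seed = 1) {
  target <- factor(target)
  if (nlevels(target) < 2) stop("target must have at least 2 classes")
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("f%03d", seq_len(ncol(features)))
  feats <- colnames(features)
  state <- setNames(rep("tentative", length(feats)), feats)
  hits <- trials <- setNames(integer(length(feats)), feats)
  impHistory <- vector("list", length(feats)); names(impHistory) <- feats
  shadowMaxHistory <- numeric()

  set.seed(seed)
  iter <- 0
  while (any(state == "tentative") && iter < maxIter) {
    iter <- iter + 1
    active <- feats[state != "rejected"]
    X <- features[, active, drop = FALSE]
    nShadow <- max(5L, ncol(X))
    shadowSrc <- X[, rep_len(seq_len(ncol(X)), nShadow), drop = FALSE]
    shadows <- apply(shadowSrc, 2, sample)
    colnames(shadows) <- sprintf("shadow_%03d", seq_len(nShadow))
    dat <- data.frame(cbind(X, shadows), check.names = FALSE)
    rf <- ranger::ranger(x = dat, y = target, num.trees = nTrees,
                         importance = "permutation",
                         seed = sample.int(.Machine$integer.max, 1),
                         num.threads = 1)
    imp <- rf$variable.importance
    shadowMax <- max(imp[colnames(shadows)])
    shadowMaxHistory <- c(shadowMaxHistory, shadowMax)
    for (f in active) impHistory[[f]] <- c(impHistory[[f]], imp[[f]])
    tent <- feats[state == "tentative"]
    hits[tent] <- hits[tent] + as.integer(imp[tent] > shadowMax)
    trials[tent] <- trials[tent] + 1L
    for (f in tent) {
      pHi <- pbinom(hits[[f]] - 1L, trials[[f]], 0.5, lower.tail = FALSE)
      pLo <- pbinom(hits[[f]], trials[[f]], 0.5)
      # Bonferroni over the features under test guards against chance streaks
      p2 <- min(1, 2 * min(pHi, pLo) * length(feats))
      if (p2 < alpha) {
        state[f] <- if (hits[[f]] > trials[[f]] / 2) "confirmed" else "rejected"
      }
    }
  }
  tentLeft <- feats[state == "tentative"]
  for (f in tentLeft) {
    state[f] <- if (median(impHistory[[f]]) > median(shadowMaxHistory))
      "confirmed" else "rejected"
  }
  list(confirmed = feats[state == "confirmed"],
       rejected = feats[state == "rejected"],
       tentative = tentLeft,
       decision = state,
       iterations = iter)
}

#' Fit the ICI score model
#'
#' Partitions the DEGs into signatures A and B via [partitionSignatures()],
#' optionally reduces each signature to its Boruta-confirmed genes, and fits
#' one PCA per (confirmed) signature on the z-scored expression: the
#' unit-norm PC1 loadings, the centering vector and a sign convention
#' (PC1 oriented to correlate positively with the signature's mean
#' z-expression) are stored so validation cohorts can be projected without
#' refitting.
#'
#' @param degExpression DEG x sample matrix (training cohort).
#' @param geneClusters factor of gene-cluster labels per sample.
#' @param boruta run Boruta reduction on each signature (default TRUE)?
#' @param nTrees,maxIter,alpha,seed Boruta parameters, see [borutaSelect()].
#' @return An [IciModel-class] object.
#' @export
fitIciModel <- function(degExpression, geneClusters, boruta = TRUE,
                        nTrees = 300, maxIter = 100, alpha = 0.01, seed = 1) {
  degExpression <- as.matrix(degExpression)
  part <- partitionSignatures(degExpression, geneClusters)
  z <- .rowZscore(degExpression)
  confirm <- function(genes, offset) {
    if (!boruta || length(genes) < 2) return(genes)
    sel <- borutaSelect(t(z[genes, , drop = FALSE]), geneClusters,
                        nTrees = nTrees, maxIter = maxIter, alpha = alpha,
                        seed = seed + offset)
    if (!length(sel$confirmed)) {
      warning("Boruta confirmed no genes; keeping the full signature")
      return(genes)
    }
    sel$confirmed
  }
  confA <- confirm(part$signatureA, 0L)
  confB <- confirm(part$signatureB, 1L)
  pcaSide <- function(genes) {
    X <- t(z[genes, , drop = FALSE])
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    load <- pc$rotation[, 1]
    scores <- pc$x[, 1]
    s <- suppressWarnings(cor(scores, rowMeans(X)))
    s <- if (is.na(s) || s >= 0) 1 else -1
    list(loadings = load, center = pc$center, sign = s)
  }
  a <- pcaSide(confA)
  b <- pcaSide(confB)
  new("IciModel",
      signatureA = part$signatureA, signatureB = part$signatureB,
      confirmedA = confA, confirmedB = confB,
      loadingsA = a$loadings, loadingsB = b$loadings,
      centerA = a$center, centerB = b$center,
      signA = a$sign, signB = b$sign,
      geneClusters = factor(geneClusters))
}

# project one signature side of the model onto a (z-scored) expression matrix
.projectSide <- function(z, loadings, center, sgn, side) {
  present <- intersect(names(loadings), rownames(z))
  missingFrac <- 1 - length(present) / length(loadings)
  if (missingFrac > 0.5)
    stop(sprintf("more than half of signature %s genes are absent (%.0f%%)",
                 side, 100 * missingFrac))
  if (missingFrac > 0)
    message(sprintf("signature %s: %d gene(s) absent from the cohort, dropped",
                    side, length(loadings) - length(present)))
  X <- t(z[present, , drop = FALSE])
  sgn * as.numeric(sweep(X, 2, center[present]) %*% loadings[present])
}

#' Compute per-sample ICI scores
#'
#' Z-scores the cohort's expression per gene, projects each sample onto the
#' stored PC1 of the confirmed A and B signatures, and forms
#' `ici_score = PC1_A - PC1_B`. When a `cutoff` is supplied samples are
#' classified `high` (score > cutoff) or `low`. Signature genes absent from
#' the cohort are dropped (error if more than half of a signature is
#' missing).
#'
#' @param expression genes x samples matrix (training or validation cohort),
#'   or an [IciCohort-class].
#' @param model an [IciModel-class].
#' @param cutoff optional score cutoff for the high/low split (see
#'   [optimalCutoff()]).
#' @return data.frame with columns `sample`, `pc1_a`, `pc1_b`, `ici_score`,
#'   and, when a cutoff is given, `group` and `cutoff`.
#' @export
computeIciScores <- function(expression, model, cutoff = NULL) {
  if (methods::is(expression, "IciCohort"))
    expression <- SummarizedExperiment::assay(expression, "tpm")
  z <- .rowZscore(as.matrix(expression))
  pc1a <- .projectSide(z, model@loadingsA, model@centerA, model@signA, "A")
  pc1b <- .projectSide(z, model@loadingsB, model@centerB, model@signB, "B")
  out <- data.frame(sample = colnames(expression), pc1_a = pc1a,
                    pc1_b = pc1b, ici_score = pc1a - pc1b,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(cutoff)) {
    out$group <- ifelse(out$ici_score > cutoff, "high", "low")
    out$cutoff <- cutoff
  }
  out
}

#' Survival-optimal score cutoff (maximally selected log-rank)
#'
#' Scans every admissible cutpoint (midpoints between sorted unique scores
#' that leave at least `minGroupFrac` of the cohort in each group) and picks
#' the one maximizing the two-group log-rank chi-square; ties are broken
#' toward the cutpoint nearest the median score. This reproduces the intent
#' of outcome-optimal cutpoint software in a fully deterministic scan.
#'
#' @param scores numeric per-sample scores.
#' @param time positive survival times.
#' @param event event indicator (1 = death, 0 = censored).
#' @param minGroupFrac minimum fraction per group, in (0, 0.5) (default 0.1).
#' @return List with `cutoff`, `chisq`, `p`, and `groups` (`high`/`low`
#'   factor per sample).
#' @export
optimalCutoff <- function(scores, time, event, minGroupFrac = 0.1) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  if (n < 20 || sum(event) < 5)
    stop("need at least 20 samples with at least 5 events")
  if (minGroupFrac <= 0 || minGroupFrac >= 0.5)
    stop("minGroupFrac must lie in (0, 0.5)")
  u <- sort(unique(scores))
  if (length(u) < 2) stop("no admissible cutpoint: scores are constant")
  cand <- (u[-1] + u[-length(u)]) / 2
  minN <- ceiling(minGroupFrac * n)
  cand <- cand[vapply(cand, function(cc)
    sum(scores > cc) >= minN && sum(scores <= cc) >= minN, logical(1))]
  if (!length(cand)) stop("no admissible cutpoint under the group-size constraint")
  chisq <- vapply(cand, function(cc) {
    grp <- scores > cc
    tryCatch(survival::survdiff(survival::Surv(time, event) ~ grp)$chisq,
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(chisq))) stop("log-rank statistic undefined at every cutpoint")
  best <- which(chisq > max(chisq, na.rm = TRUE) - 1e-12)
  if (length(best) > 1)
    best <- best[which.min(abs(cand[best] - median(scores)))]
  cutoff <- cand[best]
  lr <- logrankTest(time, event, factor(ifelse(scores > cutoff, "high", "low")))
  list(cutoff = cutoff, chisq = lr$chisq, p = lr$p,
       groups = factor(ifelse(scores > cutoff, "high", "low"),
                       levels = c("low", "high")))
}
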