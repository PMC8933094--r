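#' Rank genes by a two-class phenotype
#'
#' Signal-to-noise metric per gene, `(mu_1 - mu_2) / (sd_1 + sd_2)`, with
#' each class standard deviation floored at `0.2 * |mean|` (and at 0.2 when
#' the mean is zero), the conventional variance stabilization for expression
#' data. If the labels contain `"high"` and `"low"` the metric is
#' high-minus-low; otherwise the last factor level minus the first.
#'
#' @param expression genes x samples matrix.
#' @param phenotype two-class label per sample (each class >= 3 samples).
#' @return data.frame (`gene`, `metric`) sorted by decreasing metric.
#' @export
rankGenesByPhenotype <- function(expression, phenotype) {
  phenotype <- droplevels(factor(phenotype))
  if (nlevels(phenotype) != 2) stop("phenotype must have exactly two classes")
  if (any(table(phenotype) < 3)) stop("each phenotype class needs >= 3 samples")
  lv <- levels(phenotype)
  if (all(c("high", "low") %in% lv)) lv <- c("high", "low") else lv <- rev(lv)
  expression <- as.matrix(expression)
  fixSd <- function(s, m) {
    s <- pmax(s, 0.2 * abs(m))
    ifelse(s == 0, 0.2, s)
  }
  i1 <- phenotype == lv[1]; i2 <- phenotype == lv[2]
  m1 <- rowMeans(expression[, i1, drop = FALSE])
  m2 <- rowMeans(expression[, i2, drop = FALSE])
  s1 <- fixSd(apply(expression[, i1, drop = FALSE], 1, sd), m1)
  s2 <- fixSd(apply(expression[, i2, drop = FALSE], 1, sd), m2)
  metric <- (m1 - m2) / (s1 + s2)
  out <- data.frame(gene = rownames(expression), metric = metric,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$metric), , drop = FALSE]
}

# weighted Kolmogorov-Smirnov running-sum enrichment score:
# maximum deviation (kept with its sign) of the hit CDF (weights |metric|^p,
# normalized) minus the miss CDF (uniform)
.esWalk <- function(metric, hit, p = 1) {
  N <- length(metric)
  nh <- sum(hit)
  if (nh == 0 || nh == N) stop("gene set must be a proper subset of the list")
  w <- abs(metric)^p * hit
  nr <- sum(w)
  phit <- if (nr > 0) cumsum(w) / nr else cumsum(hit) / nh
  pmiss <- cumsum(!hit) / (N - nh)
  dev <- phit - pmiss
  dev[which.max(abs(dev))]
}

#' Gene set enrichment analysis (weighted-KS running sum)
#'
#' Classic GSEA on a ranked gene list: the enrichment score (ES) of a set is
#' the signed maximum deviation of the running sum that steps up by the
#' normalized `|metric|^p` at set members and down by `1/(N - Nh)` elsewhere.
#' The null distribution is built by gene-set permutation (random sets of
#' equal size); NES divides the ES by the mean of the same-sign null ESs,
#' the nominal p is one-sided over same-sign permutations (add-one
#' estimator), and the FDR q follows the standard GSEA computation over the
#' signed null NES pool. A sample-permutation mode (`permType = "sample"`)
#' rebuilds the ranking metric from label-permuted expression instead.
#'
#' @param ranked data.frame (`gene`, `metric`) as from
#'   [rankGenesByPhenotype()], or a named metric vector.
#' @param geneSets named list of gene sets.
#' @param p rank weighting exponent (default 1).
#' @param nPerm number of permutations (default 1000).
#' @param minSize minimum set size after intersection (default 5; smaller
#'   sets are skipped with a warning).
#' @param permType `"gene_set"` (default) or `"sample"`.
#' @param expression,phenotype required for `permType = "sample"`.
#' @param seed integer seed.
#' @return data.frame (`gene_set`, `size`, `es`, `nes`, `nominal_p`,
#'   `fdr_q`), one row per evaluated set.
#' @export
gsea <- function(ranked, geneSets, p = 1, nPerm = 1000, minSize = 5,
                 permType = c("gene_set", "sample"),
                 expression = NULL, phenotype = NULL, seed = 1) {
  permType <- match.arg(permType)
  if (is.data.frame(ranked)) {
    metric <- setNames(ranked$metric, ranked$gene)
  } else metric <- ranked
  metric <- sort(metric, decreasing = TRUE)
  genes <- names(metric)
  N <- length(genes)

  sets <- lapply(geneSets, intersect, genes)
  sizes <- lengths(sets)
  skip <- sizes < minSize | sizes >= N
  if (any(skip))
    warning(sum(skip), " gene set(s) outside the allowed size range skipped")
  sets <- sets[!skip]
  if (!length(sets))
    return(data.frame(gene_set = character(), size = integer(), es = numeric(),
                      nes = numeric(), nominal_p = numeric(),
                      fdr_q = numeric(), stringsAsFactors = FALSE))

  es <- vapply(sets, function(s) .esWalk(metric, genes %in% s, p), numeric(1))

  set.seed(seed)
  if (permType == "gene_set") {
    nullBySize <- list()
    for (sz in unique(lengths(sets))) {
      key <- as.character(sz)
      nullBySize[[key]] <- vapply(seq_len(nPerm), function(b) {
        idx <- sample.int(N, sz)
        hit <- logical(N); hit[idx] <- TRUE
        .esWalk(metric, hit, p)
      }, numeric(1))
    }
    nullEs <- lapply(lengths(sets), function(sz) nullBySize[[as.character(sz)]])
  } else {
    if (is.null(expression) || is.null(phenotype))
      stop("sample permutation needs expression and phenotype")
    nullMat <- vapply(seq_len(nPerm), function(b) {
      permPheno <- sample(phenotype)
      rk <- rankGenesByPhenotype(expression, permPheno)
      m <- setNames(rk$metric, rk$gene)
      m <- sort(m, decreasing = TRUE)
      vapply(sets, function(s) .esWalk(m, names(m) %in% s, p), numeric(1))
    }, numeric(length(sets)))
    nullMat <- matrix(nullMat, nrow = length(sets))
    nullEs <- lapply(seq_along(sets), function(i) nullMat[i, ])
  }

  normalize <- function(x, null) {
    meanPos <- mean(null[null > 0])
    meanNeg <- mean(abs(null[null < 0]))
    ifelse(x > 0,
           x / ifelse(is.finite(meanPos) && meanPos > 0, meanPos, 1),
           x / ifelse(is.finite(meanNeg) && meanNeg > 0, meanNeg, 1))
  }
  nes <- numeric(length(sets))
  nominalP <- numeric(length(sets))
  nullNesPool <- numeric()
  for (i in seq_along(sets)) {
    null <- nullEs[[i]]
    nes[i] <- normalize(es[i], null)
    sameSign <- if (es[i] >= 0) null[null >= 0] else null[null < 0]
    nominalP[i] <- (1 + sum(abs(sameSign) >= abs(es[i]))) / (1 + length(sameSign))
    nullNesPool <- c(nullNesPool, normalize(null, null))
  }
  fdr <- vapply(seq_along(sets), function(i) {
    if (nes[i] >= 0) {
      nullFrac <- mean(nullNesPool >= nes[i] & nullNesPool >= 0) /
        max(mean(nullNesPool >= 0), 1e-12)
      obsFrac <- mean(nes >= nes[i] & nes >= 0) / max(mean(nes >= 0), 1e-12)
    } else {
      nullFrac <- mean(nullNesPool <= nes[i] & nullNesPool < 0) /
        max(mean(nullNesPool < 0), 1e-12)
      obsFrac <- mean(nes <= nes[i] & nes < 0) / max(mean(nes < 0), 1e-12)
    }
    min(1, nullFrac / max(obsFrac, 1e-12))
  }, numeric(1))

  data.frame(gene_set = names(sets), size = lengths(sets), es = es,
             nes = nes, nominal_p = nominalP, fdr_q = fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

# two-sided Kolmogorov-Smirnov statistic of a tag set inside a ranked list
# (Lamb 2006 form): a if a > b else -b, over the sorted tag positions
.ksTag <- function(positions, N) {
  v <- sort(positions)
  t <- length(v)
  j <- seq_len(t)
  a <- max(j / t - v / N)
  b <- max(v / N - (j - 1) / t)
  if (a > b) a else -b
}

#' Connectivity-Map-style connectivity scoring
#'
#' Scores an up/down query signature against reference rank profiles
#' (genes ranked 1..N per perturbation instance, rank 1 = most up-regulated).
#' Per instance, the two-sided KS statistics of the up and down tag sets are
#' combined: the raw connectivity is 0 when they share a sign and
#' `ks_up - ks_down` otherwise, then scaled into [-1, 1] by the extreme raw
#' value across instances. When instances are annotated with compounds, the
#' compound level reports the mean score, a KS enrichment of the compound's
#' instances within the score-ordered instance list, an add-one permutation
#' p (random instance sets of equal size), the specificity (fraction of that
#' null panel reaching at least the observed |enrichment|), and the percent
#' of instances sharing the mean's sign.
#'
#' @param upTags,downTags disjoint character vectors of query genes.
#' @param referenceRanks genes x instances integer rank matrix.
#' @param instanceInfo optional data.frame (`instance`, `compound`).
#' @param nPerm permutations for the compound-level p (default 1000).
#' @param seed integer seed.
#' @return List with `instances` (per-instance raw and scaled scores) and,
#'   when `instanceInfo` is given, `compounds` (per-compound statistics).
#' @export
cmapConnectivity <- function(upTags, downTags, referenceRanks,
                             instanceInfo = NULL, nPerm = 1000, seed = 1) {
  if (length(intersect(upTags, downTags)))
    stop("up and down tag lists must be disjoint")
  genes <- rownames(referenceRanks)
  N <- length(genes)
  up <- intersect(upTags, genes)
  down <- intersect(downTags, genes)
  dropped <- (length(upTags) - length(up)) + (length(downTags) - length(down))
  if (dropped > 0)
    message(dropped, " tag gene(s) absent from the profile universe dropped")
  if (!length(up) || !length(down))
    stop("both tag lists must retain at least one gene in the universe")
  if (N < length(up) + length(down))
    stop("profiles have fewer genes than tags")

  raw <- vapply(seq_len(ncol(referenceRanks)), function(i) {
    rk <- referenceRanks[, i]
    ksUp <- .ksTag(rk[up], N)
    ksDown <- .ksTag(rk[down], N)
    if (sign(ksUp) == sign(ksDown)) 0 else ksUp - ksDown
  }, numeric(1))
  maxPos <- max(raw)
  minNeg <- min(raw)
  score <- ifelse(raw > 0, raw / maxPos,
                  ifelse(raw < 0, -(raw / minNeg), 0))
  instances <- data.frame(instance = colnames(referenceRanks), raw = raw,
                          score = score, row.names = NULL,
                          stringsAsFactors = FALSE)
  out <- list(instances = instances)
  if (is.null(instanceInfo)) return(out)

  instances <- merge(instances, instanceInfo, by = "instance", sort = FALSE)
  out$instances <- instances
  nInst <- nrow(instances)
  ordIdx <- order(-instances$score)
  posOf <- match(seq_len(nInst), ordIdx) # rank of each instance by score
  set.seed(seed)
  rows <- lapply(split(seq_len(nInst), instances$compound), function(idx) {
    nI <- length(idx)
    enr <- .ksTag(posOf[idx], nInst)
    nullEnr <- vapply(seq_len(nPerm), function(b)
      .ksTag(sample.int(nInst, nI), nInst), numeric(1))
    permP <- (1 + sum(abs(nullEnr) >= abs(enr))) / (nPerm + 1)
    spec <- mean(abs(nullEnr) >= abs(enr))
    mu <- mean(instances$score[idx])
    nonnull <- if (mu == 0) 0 else 100 * mean(sign(instances$score[idx]) == sign(mu))
    data.frame(compound = instances$compound[idx[1]], mean = mu,
               n_instances = nI, enrichment = enr, perm_p = permP,
               specificity = spec, percent_nonnull = nonnull,
               stringsAsFactors = FALSE)
  })
  comp <- do.call(rbind, rows)
  rownames(comp) <- NULL
  out$compounds <- comp[order(comp$perm_p, -abs(comp$enrichment)), ]
  out
}

#' Mechanism-of-action summary of compound hits
#'
#' Counts how many hit compounds share each annotated mechanism of action;
#' compounds without an annotation are grouped under `"unknown"`.
#'
#' @param hits character vector of hit compound names.
#' @param moaTable data.frame (`compound`, `mechanism`).
#' @return data.frame (`mechanism`, `count`) sorted by decreasing count.
#' @export
moaSummary <- function(hits, moaTable) {
  if (!length(hits))
    return(data.frame(mechanism = character(), count = integer(),
                      stringsAsFactors = FALSE))
  mech <- moaTable$mechanism[match(hits, moaTable$compound)]
  mech[is.na(mech)] <- "unknown"
  tab <- sort(table(mech), decreasing = TRUE)
  data.frame(mechanism = names(tab), count = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}
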