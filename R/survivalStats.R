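#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator of the survival function under right censoring,
#' computed with the standard survival machinery and returned as a plain
#' step-function table.
#'
#' @param time positive survival times.
#' @param event event indicator (1 = death, 0 = censored).
#' @param group optional group labels; one curve per group.
#' @return data.frame with columns `group` (if given), `time`, `n_risk`,
#'   `n_event`, `surv`.
#' @export
kmEstimate <- function(time, event, group = NULL) {
  stopifnot(length(time) >= 1, all(time > 0))
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               surv = fit$surv)
  } else {
    fit <- survival::survfit(survival::Surv(time, event) ~ group)
    strata <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
    data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, surv = fit$surv)
  }
}

#' Log-rank test
#'
#' Standard log-rank comparison of k survival curves: observed versus
#' hypergeometric-expected events at every event time, chi-square on k-1
#' degrees of freedom.
#'
#' @param time positive survival times.
#' @param event event indicator (1 = death, 0 = censored).
#' @param group group label per sample (>= 2 non-empty groups).
#' @return List with `chisq`, `df`, `p`.
#' @export
logrankTest <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) stop("at least two non-empty groups are required")
  if (sum(event) == 0) stop("log-rank test undefined without any events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1
  p <- pchisq(sd$chisq, df = df, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), df = df, p = unname(p))
}

#' Kruskal-Wallis test with the all-tied convention
#'
#' Rank-based k-group comparison (tie-corrected). When every value is
#' identical across all groups the test statistic is defined as 0 with
#' p = 1 rather than an undefined 0/0.
#'
#' @param values numeric vector.
#' @param groups group label per value (>= 2 non-empty groups).
#' @return List with `statistic` (H), `df`, `p`.
#' @export
kruskalWallis <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("at least two non-empty groups are required")
  if (length(unique(values)) == 1)
    return(list(statistic = 0, df = nlevels(groups) - 1, p = 1))
  kt <- kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Wilcoxon rank-sum test with the all-tied convention
#'
#' Two-group rank-sum comparison (two-sided, tie-corrected). All-tied input
#' yields p = 1 by convention.
#'
#' @param values numeric vector.
#' @param groups two-group label per value.
#' @return List with `statistic` (W), `p`.
#' @export
wilcoxonRankSum <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2) stop("exactly two non-empty groups are required")
  if (length(unique(values)) == 1)
    return(list(statistic = NA_real_, p = 1))
  wt <- suppressWarnings(wilcox.test(values[groups == levels(groups)[1]],
                                     values[groups == levels(groups)[2]]))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Spearman rank correlation
#'
#' `rho` from the classical `1 - 6*sum(d^2)/(n*(n^2-1))` formula, computed in
#' its tie-robust form as the Pearson correlation of average ranks; two-sided
#' p-value from the t approximation `t = rho*sqrt((n-2)/(1-rho^2))`.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return List with `rho` and `p`.
#' @export
spearmanCorr <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for constant input")
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(t), df = n - 2))
}

#' Per-sample tumor mutation burden
#'
#' TMB is the count of variants per sample divided by the interrogated exome
#' length in megabases. By default only non-synonymous variant classes are
#' counted (`classes = NULL` counts every row). Samples listed in `samples`
#' but absent from the variant table receive a TMB of 0.
#'
#' @param variants MAF-like data.frame with at least `Tumor_Sample_Barcode`
#'   and `Variant_Classification`.
#' @param exomeLengthMb interrogated exome length in megabases (> 0;
#'   default 38).
#' @param samples optional character vector fixing the output samples.
#' @param classes variant classes to count; `NULL` counts all. Defaults to
#'   the conventional non-synonymous classes.
#' @return data.frame with columns `sample`, `n_variants`, `exome_length_mb`,
#'   `tmb`.
#' @export
computeTmb <- function(variants, exomeLengthMb = 38, samples = NULL,
                       classes = c("Missense_Mutation", "Nonsense_Mutation",
                                   "Frame_Shift_Del", "Frame_Shift_Ins",
                                   "In_Frame_Del", "In_Frame_Ins",
                                   "Splice_Site", "Nonstop_Mutation",
                                   "Translation_Start_Site")) {
  if (exomeLengthMb <= 0) stop("exomeLengthMb must be positive")
  v <- variants
  if (!is.null(classes) && "Variant_Classification" %in% colnames(v))
    v <- v[v$Variant_Classification %in% classes, , drop = FALSE]
  if (is.null(samples)) samples <- unique(variants$Tumor_Sample_Barcode)
  counts <- table(factor(v$Tumor_Sample_Barcode, levels = samples))
  data.frame(sample = samples, n_variants = as.integer(counts),
             exome_length_mb = exomeLengthMb,
             tmb = as.numeric(counts) / exomeLengthMb,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Grouped comparison panel with significance stars
#'
#' Tests every feature (column) for a group difference: Wilcoxon rank-sum
#' for two groups, Kruskal-Wallis for three or more, with the conventional
#' star mapping (`ns`, `*` < 0.05, `**` < 0.01, `***` < 0.001). No
#' cross-feature multiplicity adjustment is applied, matching the usual
#' per-panel figure presentation.
#'
#' @param featureTable sample x feature numeric matrix or data.frame
#'   (cell fractions, gene expression, scores, ...).
#' @param groups group label per sample.
#' @return data.frame with columns `feature`, `test`, `statistic`, `p`,
#'   `stars`.
#' @export
groupPanel <- function(featureTable, groups) {
  featureTable <- as.matrix(featureTable)
  groups <- droplevels(factor(groups))
  if (nrow(featureTable) != length(groups))
    stop("groups must align with the rows of featureTable")
  twoGroups <- nlevels(groups) == 2
  rows <- lapply(colnames(featureTable), function(f) {
    v <- featureTable[, f]
    res <- if (twoGroups) wilcoxonRankSum(v, groups) else kruskalWallis(v, groups)
    data.frame(feature = f,
               test = if (twoGroups) "wilcoxon" else "kruskal-wallis",
               statistic = res$statistic, p = res$p,
               stars = .pStars(res$p), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default immune checkpoint gene panel
#' @return Character vector of checkpoint gene symbols.
#' @export
immuneCheckpointGenes <- function() {
  c("LAG3", "CD274", "IDO1", "PDCD1", "HAVCR2", "CTLA4")
}

#' Default immune activity gene panel
#' @return Character vector of immune activity gene symbols.
#' @export
immuneActivityGenes <- function() {
  c("GZMA", "TBX2", "TNF", "PRF1", "IFNG", "CXCL9", "CXCL10")
}
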