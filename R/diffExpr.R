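# Newton inversion of the trigamma function, used by the moment-matched
# empirical Bayes prior; asymptotic starts cover the extreme ranges.
.trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

# moment-matching estimate of the scaled-F prior (d0, s0^2) from the
# per-gene residual variances sg2 on dg degrees of freedom
.fitVariancePrior <- function(sg2, dg) {
  z <- log(sg2[sg2 > 0])
  # too few informative genes to estimate a prior: fall back to mild shrinkage
  if (length(z) < 2) return(list(d0 = 1, s02 = max(mean(sg2), 1e-8)))
  e <- z - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- mean((e - emean)^2) * length(e) / (length(e) - 1) - trigamma(dg / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigammaInverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # non-positive moment estimate: variances are consistent with a single
    # common value, so pool completely (arithmetic mean, as in fitFDist)
    d0 <- Inf
    s02 <- mean(sg2)
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated two-group t-test with empirical Bayes variance shrinkage
#'
#' Per-gene two-group comparison on log2 expression: the pooled residual
#' variance of each gene is shrunk toward a common prior,
#' `s2_tilde = (d0 * s0^2 + dg * s2_g) / (d0 + dg)`, with the prior
#' `(d0, s0^2)` estimated by moment matching on the scaled-F distribution of
#' the sample variances. The moderated t statistic is the log2 fold change
#' divided by `sqrt(s2_tilde * (1/n1 + 1/n2))`, referred to a t distribution
#' on `d0 + dg` degrees of freedom; p-values are Benjamini-Hochberg adjusted.
#' With `priorDf = 0` the statistic reduces exactly to the ordinary
#' two-sample t; as `priorDf` grows it approaches a z-like statistic with the
#' pooled prior variance.
#'
#' @param expression genes x samples matrix on the log2 scale
#'   (e.g. `log2(TPM + 1)`).
#' @param labels two-group factor/character vector over samples; the log2
#'   fold change is second level minus first level.
#' @param priorDf optional fixed prior degrees of freedom (`NULL` estimates
#'   it from the data; `0` disables shrinkage; `Inf` fully pools).
#' @param priorVar optional fixed prior variance `s0^2`.
#' @return data.frame with columns `gene`, `log2fc`, `t_stat`, `p_value`,
#'   `adj_p`, `direction` (`up`/`down`), `contrast`, plus attributes
#'   `prior_df` and `prior_var`.
#' @export
moderatedTTest <- function(expression, labels, priorDf = NULL, priorVar = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("exactly two groups are required")
  if (any(table(labels) < 2)) stop("each group needs at least 2 samples")
  expression <- as.matrix(expression)
  i1 <- labels == levels(labels)[1]
  i2 <- labels == levels(labels)[2]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(expression[, i1, drop = FALSE])
  m2 <- rowMeans(expression[, i2, drop = FALSE])
  v1 <- apply(expression[, i1, drop = FALSE], 1, var)
  v2 <- apply(expression[, i2, drop = FALSE], 1, var)
  dg <- n1 + n2 - 2
  sg2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
  log2fc <- m2 - m1

  if (is.null(priorDf)) {
    prior <- .fitVariancePrior(sg2, dg)
  } else {
    prior <- list(d0 = priorDf,
                  s02 = if (is.null(priorVar)) mean(sg2) else priorVar)
  }
  if (!is.null(priorVar)) prior$s02 <- priorVar
  d0 <- prior$d0; s02 <- prior$s02

  s2tilde <- if (is.infinite(d0)) rep(s02, length(sg2))
  else (d0 * s02 + dg * sg2) / (d0 + dg)
  se <- sqrt(s2tilde * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, log2fc / se,
                  ifelse(log2fc == 0, 0, sign(log2fc) * Inf))
  # cap the total df at the pooled residual df of the whole data set, the
  # usual finite-sample guard when the prior df estimate is huge
  df <- min(d0 + dg, length(sg2) * dg)
  p <- 2 * pt(-abs(tstat), df = df)
  out <- data.frame(gene = rownames(expression), log2fc = log2fc,
                    t_stat = tstat, p_value = p,
                    adj_p = p.adjust(p, method = "BH"),
                    direction = ifelse(log2fc >= 0, "up", "down"),
                    contrast = paste0(levels(labels)[2], "_vs_", levels(labels)[1]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  out
}

#' Differentially expressed genes among subtypes
#'
#' Runs [moderatedTTest()] for every pairwise contrast between subtype labels
#' (or every one-vs-rest contrast) and returns the union of genes passing
#' both the fold-change cutoff (`|FC| > fcCut`, i.e. `|log2fc| > log2(fcCut)`)
#' and the adjusted p cutoff in any contrast, with the retaining contrasts
#' recorded per gene.
#'
#' @param expression genes x samples log2-scale matrix.
#' @param labels subtype label per sample (>= 2 levels).
#' @param fcCut linear fold-change cutoff (default 2).
#' @param adjpCut adjusted-p cutoff (default 0.05).
#' @param mode `"pairwise"` (default) or `"one_vs_rest"`.
#' @param priorDf passed to [moderatedTTest()].
#' @return List with `degs` (character vector), `tables` (one DE table per
#'   contrast) and `provenance` (data.frame `gene`, `contrasts`).
#' @export
degsAmongSubtypes <- function(expression, labels, fcCut = 2, adjpCut = 0.05,
                              mode = c("pairwise", "one_vs_rest"),
                              priorDf = NULL) {
  mode <- match.arg(mode)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("at least two subtypes are required")
  lv <- levels(labels)
  contrasts <- if (mode == "pairwise") {
    utils::combn(lv, 2, simplify = FALSE)
  } else {
    lapply(lv, function(l) c("rest", l))
  }
  tables <- list()
  hits <- list()
  for (ct in contrasts) {
    if (mode == "pairwise") {
      keep <- labels %in% ct
      tab <- moderatedTTest(expression[, keep, drop = FALSE],
                            droplevels(labels[keep]), priorDf = priorDf)
    } else {
      lab2 <- factor(ifelse(labels == ct[2], ct[2], "rest"),
                     levels = c("rest", ct[2]))
      tab <- moderatedTTest(expression, lab2, priorDf = priorDf)
    }
    name <- tab$contrast[1]
    tables[[name]] <- tab
    pass <- abs(tab$log2fc) > log2(fcCut) & tab$adj_p < adjpCut
    hits[[name]] <- tab$gene[pass]
  }
  degs <- sort(unique(unlist(hits)))
  provenance <- data.frame(
    gene = degs,
    contrasts = vapply(degs, function(g)
      paste(names(hits)[vapply(hits, function(h) g %in% h, logical(1))],
            collapse = ";"), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(degs = degs, tables = tables, provenance = provenance)
}

#' Over-representation analysis by the hypergeometric test
#'
#' One-sided hypergeometric upper-tail test of a query gene list against each
#' gene set (GO/KEGG-style over-representation), with Benjamini-Hochberg
#' adjustment across terms. Query genes outside the universe are dropped with
#' a warning.
#'
#' @param queryGenes character vector of genes of interest.
#' @param geneSets named list of gene sets (e.g. from [readGmt()]).
#' @param universe character vector defining the gene universe.
#' @param adjpCut significance threshold on the adjusted p (default 0.05).
#' @return data.frame with columns `term`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p_value`, `adj_p`, `significant`.
#' @export
oraTest <- function(queryGenes, geneSets, universe, adjpCut = 0.05) {
  outside <- setdiff(queryGenes, universe)
  if (length(outside))
    warning(length(outside), " query gene(s) outside the universe were dropped")
  query <- intersect(unique(queryGenes), universe)
  empty <- data.frame(term = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      universe_size = integer(), p_value = numeric(),
                      adj_p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (length(query) == 0) {
    warning("empty query after intersecting with the universe")
    return(empty)
  }
  N <- length(unique(universe))
  n <- length(query)
  rows <- lapply(names(geneSets), function(term) {
    set <- intersect(geneSets[[term]], universe)
    K <- length(set)
    if (K == 0) return(NULL)
    k <- length(intersect(query, set))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, overlap = k, set_size = K, query_size = n,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$adj_p <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$adj_p < adjpCut
  out[order(out$p_value), , drop = FALSE]
}
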