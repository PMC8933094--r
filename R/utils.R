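# Internal numeric helpers shared across modules.

# z-score a vector; zero-variance input maps to zeros rather than NaN
.zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# row-wise (per-gene) z-scoring of a gene x sample matrix
.rowZscore <- function(mat) {
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  s[!is.finite(s) | s == 0] <- 1
  out <- (mat - mu) / s
  out
}

# one Dirichlet draw per row of a concentration matrix (rows = samples)
.rdirichlet <- function(n, alpha) {
  if (any(alpha <= 0)) stop("Dirichlet concentrations must all be positive")
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

# rescale columns of a non-negative matrix to sum to 1e6 (TPM convention)
.tpmRescale <- function(mat) {
  cs <- colSums(mat)
  if (any(cs == 0)) {
    bad <- colnames(mat)[cs == 0]
    stop("all-zero expression column(s): ", paste(bad, collapse = ", "))
  }
  sweep(mat, 2, cs, "/") * 1e6
}

# significance stars at the conventional 0.05 / 0.01 / 0.001 thresholds
.pStars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

# deterministic per-stage seed fan-out; keeps results within 32-bit range
.stageSeed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + match(stage, c(
    "simulate", "deconvolve", "estimate", "cluster", "de", "geneclusters",
    "boruta", "score", "survival", "gsea", "de2", "connectivity")) * 7919L
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then gene identifiers.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors of gene identifiers.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line (need name, description, >=1 gene): ", l)
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set description column (defaults to "na").
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
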