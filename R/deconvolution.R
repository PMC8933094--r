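#' Deconvolve one bulk mixture into immune cell fractions
#'
#' Support-vector-regression deconvolution of a bulk expression vector
#' against a leukocyte signature matrix (the CIBERSORT core). Mixture and
#' signature are brought onto a common z-score scale (a single mean/sd over
#' all signature entries, so that mixture coefficients stay proportional to
#' the underlying fractions), a linear-kernel nu-SVR is fitted at each value
#' of `nuGrid`, the fit with the lowest reconstruction RMSE is kept, negative
#' coefficients are clipped to zero and the remainder normalized to the unit
#' simplex.
#'
#' A deterministic non-negative least squares mode (`method = "nnls"`) solves
#' the same mixture problem on the raw linear scale; it is exact on noiseless
#' full-rank mixtures and serves as a reference for the SVR route.
#'
#' @param mixture named numeric vector of expression over genes (linear scale).
#' @param signature genes x cell-types matrix.
#' @param nuGrid nu values tried for the SVR (default `c(0.25, 0.5, 0.75)`).
#' @param method `"nusvr"` (default) or `"nnls"`.
#' @return List with `fractions` (named, sums to 1), `rmse` and `pearson_r`
#'   of the reconstruction.
#' @export
deconvolveSample <- function(mixture, signature, nuGrid = c(0.25, 0.5, 0.75),
                             method = c("nusvr", "nnls")) {
  method <- match.arg(method)
  shared <- intersect(names(mixture), rownames(signature))
  if (length(shared) < ncol(signature))
    stop("underdetermined: only ", length(shared), " shared genes for ",
         ncol(signature), " cell types")
  m <- mixture[shared]
  S <- signature[shared, , drop = FALSE]
  if (all(m == 0)) stop("all-zero mixture")

  if (method == "nnls") {
    fit <- pracma::lsqnonneg(S, as.numeric(m))
    w <- fit$x
    recon <- as.numeric(S %*% w)
  } else {
    Sz <- (S - mean(S)) / sd(as.vector(S))
    mz <- .zscore(m)
    best <- NULL
    for (nu in nuGrid) {
      model <- e1071::svm(Sz, mz, type = "nu-regression", kernel = "linear",
                          nu = nu, scale = FALSE)
      w <- as.numeric(t(model$coefs) %*% model$SV)
      w[w < 0] <- 0
      if (sum(w) == 0) next
      recon <- as.numeric(Sz %*% (w / sum(w)))
      rmse <- sqrt(mean((recon - mz)^2))
      if (is.null(best) || rmse < best$rmse)
        best <- list(w = w, recon = recon, rmse = rmse)
    }
    if (is.null(best)) {
      fr <- setNames(rep(0, ncol(S)), colnames(S))
      return(list(fractions = fr, rmse = NA_real_, pearson_r = NA_real_))
    }
    w <- best$w
    recon <- best$recon
    m <- mz
  }
  if (sum(w) == 0) {
    fr <- setNames(rep(0, ncol(S)), colnames(S))
    return(list(fractions = fr, rmse = NA_real_, pearson_r = NA_real_))
  }
  fractions <- setNames(w / sum(w), colnames(S))
  list(fractions = fractions,
       rmse = sqrt(mean((recon - m)^2)),
       pearson_r = if (sd(recon) == 0) 0 else cor(recon, m))
}

#' Permutation p-value for one deconvolution fit
#'
#' Builds a null distribution of the reconstruction correlation by
#' deconvolving `nPerm` gene-label-permuted copies of the mixture and applies
#' the add-one estimator `p = (1 + #(null >= observed)) / (nPerm + 1)`, which
#' can never return zero.
#'
#' @inheritParams deconvolveSample
#' @param nPerm number of permutations (>= 1).
#' @param seed integer seed (same seed, same p).
#' @return Permutation p-value in (0, 1].
#' @export
permutationPvalue <- function(mixture, signature, nPerm = 100, seed = 1,
                              nuGrid = c(0.25, 0.5, 0.75),
                              method = c("nusvr", "nnls")) {
  method <- match.arg(method)
  stopifnot(nPerm >= 1)
  obs <- deconvolveSample(mixture, signature, nuGrid, method)$pearson_r
  set.seed(seed)
  nullR <- vapply(seq_len(nPerm), function(b) {
    perm <- setNames(sample(as.numeric(mixture)), names(mixture))
    deconvolveSample(perm, signature, nuGrid, method)$pearson_r
  }, numeric(1))
  (1 + sum(nullR >= obs, na.rm = TRUE)) / (nPerm + 1)
}

#' Deconvolve a whole cohort
#'
#' Applies [deconvolveSample()] to every column of an expression matrix (or
#' the TPM assay of an [IciCohort-class]) and attaches permutation p-values.
#' By default the permutation null is shared across samples: `nPerm` random
#' gene-permuted mixtures (drawn from randomly chosen columns) are
#' deconvolved once and every sample's observed correlation is referred to
#' that common null, as in the original batch implementation. Samples whose
#' fit fails are flagged with an all-zero fraction row and `NA` diagnostics
#' rather than dropped.
#'
#' @param expression genes x samples matrix or an [IciCohort-class].
#' @param signature genes x cell-types matrix.
#' @param nPerm permutations for the p-value (0 skips permutation testing).
#' @param seed integer seed.
#' @param sharedNull share one permutation null across samples (default) or
#'   run a per-sample permutation test.
#' @inheritParams deconvolveSample
#' @return A [CellFractions-class] object.
#' @export
deconvolveCohort <- function(expression, signature, nPerm = 100, seed = 1,
                             nuGrid = c(0.25, 0.5, 0.75),
                             method = c("nusvr", "nnls"), sharedNull = TRUE) {
  method <- match.arg(method)
  if (methods::is(expression, "IciCohort"))
    expression <- SummarizedExperiment::assay(expression, "tpm")
  stopifnot(ncol(expression) >= 1)
  samples <- colnames(expression)
  fractions <- matrix(0, ncol(expression), ncol(signature),
                      dimnames = list(samples, colnames(signature)))
  rmse <- pr <- rep(NA_real_, ncol(expression))
  failed <- character()
  for (i in seq_len(ncol(expression))) {
    fit <- tryCatch(
      deconvolveSample(expression[, i], signature, nuGrid, method),
      error = function(e) e)
    if (inherits(fit, "error")) { failed <- c(failed, samples[i]); next }
    fractions[i, ] <- fit$fractions
    rmse[i] <- fit$rmse
    pr[i] <- fit$pearson_r
  }
  if (length(failed))
    warning("deconvolution failed for sample(s): ", paste(failed, collapse = ", "))

  permP <- rep(NA_real_, ncol(expression))
  if (nPerm > 0) {
    if (sharedNull) {
      set.seed(seed)
      nullR <- vapply(seq_len(nPerm), function(b) {
        col <- expression[, sample.int(ncol(expression), 1)]
        perm <- setNames(sample(as.numeric(col)), rownames(expression))
        tryCatch(deconvolveSample(perm, signature, nuGrid, method)$pearson_r,
                 error = function(e) NA_real_)
      }, numeric(1))
      permP <- vapply(pr, function(r) {
        if (is.na(r)) return(NA_real_)
        (1 + sum(nullR >= r, na.rm = TRUE)) / (nPerm + 1)
      }, numeric(1))
    } else {
      for (i in seq_len(ncol(expression))) {
        if (is.na(pr[i])) next
        permP[i] <- permutationPvalue(expression[, i], signature, nPerm,
                                      seed = seed + i, nuGrid, method)
      }
    }
  }
  new("CellFractions", fractions = fractions,
      stats = data.frame(sample = samples, rmse = rmse, pearson_r = pr,
                         perm_p = permP, stringsAsFactors = FALSE))
}
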