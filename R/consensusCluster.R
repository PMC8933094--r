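# empirical CDF of the off-diagonal consensus entries on a fixed grid,
# plus the trapezoid area under it
.consensusCdf <- function(m, grid = seq(0, 1, by = 0.01)) {
  vals <- m[upper.tri(m)]
  cdf <- vapply(grid, function(t) mean(vals <= t), numeric(1))
  area <- sum((cdf[-1] + cdf[-length(cdf)]) / 2 * diff(grid))
  list(cdf = data.frame(grid = grid, cdf = cdf), area = area)
}

#' Monti-style consensus clustering
#'
#' Resampling-based consensus clustering of samples: in each of
#' `nResamples` iterations a fraction `pItem` of samples is drawn without
#' replacement and clustered (hierarchical on Euclidean distance) at every
#' k in `kRange`; the consensus index of a sample pair is
#' its co-clustering count divided by its co-sampling count. Final labels per
#' k come from hierarchical clustering of `1 - consensus` as a distance.
#' Model selection follows the consensus-CDF criterion: the area under the
#' CDF of off-diagonal consensus entries is computed per k and its relative
#' increase (delta area) is thresholded; `chosenK` is the largest k whose
#' delta area reaches `deltaThreshold`, unless a `forceK` is supplied.
#'
#' @param features sample x feature numeric matrix.
#' @param kRange candidate cluster numbers (default 2:9).
#' @param nResamples number of resampling iterations (default 100).
#' @param pItem subsampling fraction in (0, 1] (default 0.8).
#' @param seed integer seed; the full result is deterministic given the seed.
#' @param forceK optional fixed cluster number overriding model selection.
#' @param deltaThreshold delta-area threshold for model selection (default 0.1).
#' @param linkage hclust linkage for both the inner clusterer and the final
#'   labeling (default `"ward.D2"`, which is robust to the outlier-peeling
#'   that average linkage shows on compositional features).
#' @return A [ConsensusResult-class] object.
#' @export
consensusCluster <- function(features, kRange = 2:9, nResamples = 100,
                             pItem = 0.8, seed = 1, forceK = NULL,
                             deltaThreshold = 0.1, linkage = "ward.D2") {
  features <- as.matrix(features)
  n <- nrow(features)
  kRange <- as.integer(sort(unique(kRange)))
  if (max(kRange) > n) stop("largest k exceeds the number of samples")
  if (pItem <= 0 || pItem > 1) stop("pItem must lie in (0, 1]")
  if (nResamples < 2) stop("nResamples must be at least 2")
  if (all(apply(features, 2, sd) == 0))
    stop("degenerate input: all features are constant")
  if (!is.null(forceK) && (forceK < 2 || forceK > n))
    stop("forceK must lie in [2, n]")
  if (is.null(rownames(features))) rownames(features) <- sprintf("item%03d", seq_len(n))

  set.seed(seed)
  nSub <- ceiling(pItem * n)
  conn <- lapply(kRange, function(k) matrix(0, n, n))
  names(conn) <- as.character(kRange)
  copair <- matrix(0, n, n)
  for (b in seq_len(nResamples)) {
    idx <- sample.int(n, nSub)
    copair[idx, idx] <- copair[idx, idx] + 1
    hc <- hclust(dist(features[idx, , drop = FALSE]), method = linkage)
    for (k in kRange) {
      lab <- cutree(hc, k)
      same <- outer(lab, lab, "==")
      ck <- as.character(k)
      conn[[ck]][idx, idx] <- conn[[ck]][idx, idx] + same
    }
  }

  consensus <- lapply(conn, function(cm) {
    m <- ifelse(copair > 0, cm / pmax(copair, 1), 0)
    diag(m) <- 1
    dimnames(m) <- list(rownames(features), rownames(features))
    m
  })

  labels <- list()
  for (k in kRange) {
    m <- consensus[[as.character(k)]]
    hc <- hclust(as.dist(1 - m), method = linkage)
    labels[[as.character(k)]] <- setNames(cutree(hc, k), rownames(features))
  }

  cdfs <- lapply(consensus, .consensusCdf)
  area <- vapply(cdfs, `[[`, numeric(1), "area")
  delta <- numeric(length(kRange))
  for (i in seq_along(kRange)) {
    delta[i] <- if (i == 1) area[i]
    else if (area[i - 1] <= 0) area[i]
    else (area[i] - area[i - 1]) / area[i - 1]
  }
  names(delta) <- names(area) <- as.character(kRange)

  itemCons <- clustCons <- list()
  res <- new("ConsensusResult", kRange = kRange, consensus = consensus,
             labels = labels, cdf = lapply(cdfs, `[[`, "cdf"),
             area = area, deltaArea = delta,
             itemConsensus = list(), clusterConsensus = list(),
             chosenK = kRange[1])
  for (k in kRange) {
    ic <- itemClusterConsensus(res, k)
    itemCons[[as.character(k)]] <- ic$item
    clustCons[[as.character(k)]] <- ic$cluster
  }
  res@itemConsensus <- itemCons
  res@clusterConsensus <- clustCons

  chosen <- if (!is.null(forceK)) as.integer(forceK) else {
    ok <- kRange[delta >= deltaThreshold]
    if (length(ok)) max(ok) else kRange[1]
  }
  if (!chosen %in% kRange)
    stop("forceK must be one of the evaluated kRange values")
  res@chosenK <- chosen
  methods::validObject(res)
  res
}

#' Consensus CDF and delta-area profile
#'
#' Recomputes, from the stored consensus matrices, the empirical CDF of
#' off-diagonal consensus entries per k (grid 0..1, step 0.01), the trapezoid
#' area under each CDF, and the relative area increase (delta area; the area
#' itself at the smallest k, by the standard convention).
#'
#' @param object a [ConsensusResult-class].
#' @return List with `cdf` (named list of data.frames) and `table`
#'   (data.frame `k`, `area`, `delta_area`).
#' @export
cdfDeltaArea <- function(object) {
  kRange <- object@kRange
  cdfs <- lapply(kRange, function(k)
    .consensusCdf(object@consensus[[as.character(k)]]))
  area <- vapply(cdfs, `[[`, numeric(1), "area")
  delta <- numeric(length(kRange))
  for (i in seq_along(kRange)) {
    delta[i] <- if (i == 1) area[i]
    else if (area[i - 1] <= 0) area[i]
    else (area[i] - area[i - 1]) / area[i - 1]
  }
  list(cdf = setNames(lapply(cdfs, `[[`, "cdf"), as.character(kRange)),
       table = data.frame(k = kRange, area = area, delta_area = delta))
}

#' Item and cluster consensus at a given k
#'
#' Item consensus of a sample is the mean consensus between it and the other
#' members of its cluster; cluster consensus is the mean over all
#' within-cluster pairs. A singleton cluster has item and cluster consensus 1
#' by convention.
#'
#' @param object a [ConsensusResult-class].
#' @param k cluster number (must be in the evaluated range).
#' @return List with `item` (named numeric per sample) and `cluster`
#'   (numeric per cluster).
#' @export
itemClusterConsensus <- function(object, k) {
  ck <- as.character(k)
  m <- object@consensus[[ck]]
  lab <- object@labels[[ck]]
  if (is.null(m) || is.null(lab)) stop("k = ", k, " was not evaluated")
  n <- length(lab)
  item <- setNames(numeric(n), names(lab))
  for (i in seq_len(n)) {
    mates <- which(lab == lab[i])
    mates <- setdiff(mates, i)
    item[i] <- if (length(mates) == 0) 1 else mean(m[i, mates])
  }
  cluster <- vapply(sort(unique(lab)), function(c) {
    members <- which(lab == c)
    if (length(members) < 2) return(1)
    pairs <- m[members, members]
    mean(pairs[upper.tri(pairs)])
  }, numeric(1))
  list(item = item, cluster = cluster)
}

#' PCA validation of a clustering
#'
#' Projects the samples onto the first two principal components (centered;
#' zero-variance features dropped) and quantifies how well the labels
#' separate in that plane as the ratio of between-cluster to total sum of
#' squares of the 2-D coordinates. Scaling is off by default: unit-variance
#' scaling makes uncorrelated features indistinguishable to the PCA and
#' hides a separation carried by a single feature (cluster features are
#' usually z-scored upstream anyway).
#'
#' @param features sample x feature matrix.
#' @param labels cluster assignment per sample.
#' @param scale. scale features to unit variance before the PCA?
#' @return List with `coordinates` (n x 2 matrix `PC1`, `PC2`) and
#'   `separation` (between/total variance ratio in the plane).
#' @export
pcaValidate <- function(features, labels, scale. = FALSE) {
  features <- as.matrix(features)
  keep <- apply(features, 2, sd) > 0
  if (sum(keep) < 2) stop("need at least 2 non-constant features")
  pc <- prcomp(features[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  coords <- pc$x[, 1:2, drop = FALSE]
  colnames(coords) <- c("PC1", "PC2")
  grand <- colMeans(coords)
  total <- sum(sweep(coords, 2, grand)^2)
  between <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    mu <- colMeans(coords[idx, , drop = FALSE])
    between <- between + length(idx) * sum((mu - grand)^2)
  }
  list(coordinates = coords,
       separation = if (total > 0) between / total else 0)
}
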