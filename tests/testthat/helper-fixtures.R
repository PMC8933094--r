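# Shared in-code fixtures; everything is generated deterministically.

# tiny noiseless block signature: nTypes blocks of markersPerType genes
tinySignature <- function(nTypes = 4, markersPerType = 8, fold = 10, seed = 1,
                          jitterSd = 0) {
  generateSignatureMatrix(nTypes = nTypes, markersPerType = markersPerType,
                          baseLevel = 1, markerFold = fold,
                          jitterSd = jitterSd, seed = seed)
}

# mixtures from known fractions: columns are signature %*% fractions with
# optional log-normal noise
mixturesFrom <- function(signature, fractions, noiseSd = 0, seed = 1) {
  set.seed(seed)
  m <- signature %*% t(fractions)
  if (noiseSd > 0)
    m <- m * exp(matrix(rnorm(length(m), 0, noiseSd), nrow = nrow(m)))
  colnames(m) <- sprintf("s%03d", seq_len(nrow(fractions)))
  m
}

# random simplex rows
randomFractions <- function(n, k, seed = 1) {
  set.seed(seed)
  f <- matrix(rgamma(n * k, 1), n, k)
  f / rowSums(f)
}

# well-separated Gaussian blobs: n per blob, dimension d, separation in sd units
blobFeatures <- function(nPerBlob = 20, nBlobs = 3, d = 5, sep = 10, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(nPerBlob * nBlobs * d), nPerBlob * nBlobs, d)
  truth <- rep(seq_len(nBlobs), each = nPerBlob)
  for (b in seq_len(nBlobs)) X[truth == b, 1] <- X[truth == b, 1] + sep * b
  rownames(X) <- sprintf("it%03d", seq_len(nrow(X)))
  list(features = X, truth = truth)
}

# small synthetic cohort shared by several test files
smallCohort <- function(n = 60, seed = 5, ...) {
  generateCohort(cohortConfig(nSamples = n, seed = seed, ...),
                 generateSignatureMatrix(seed = seed))
}

adjRandIndex <- function(a, b) mclust::adjustedRandIndex(a, b)
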