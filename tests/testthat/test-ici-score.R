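# DEG x sample matrix with two anti-correlated planted gene blocks: "axis"
# samples vary along a latent gradient, upGenes rise with it, downGenes fall
antiBlockMatrix <- function(nUp = 10, nDown = 8, n = 60, noise = 0.1, seed = 1) {
  set.seed(seed)
  latent <- seq(-2, 2, length.out = n) + rnorm(n, 0, 0.1)
  up <- outer(rep(1, nUp), latent) + matrix(rnorm(nUp * n, 0, noise), nUp)
  down <- outer(rep(1, nDown), -latent) + matrix(rnorm(nDown * n, 0, noise), nDown)
  m <- rbind(up, down)
  dimnames(m) <- list(c(paste0("up", seq_len(nUp)), paste0("dn", seq_len(nDown))),
                      paste0("s", seq_len(n)))
  list(m = m, latent = latent)
}

test_that("gene clusters recover planted expression blocks deterministically", {
  set.seed(2)
  n <- 80
  truth <- rep(1:4, each = n / 4)
  m <- matrix(rnorm(40 * n, 0, 0.3), 40, n,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:n)))
  for (b in 1:4) m[((b - 1) * 10 + 1):(b * 10), truth == b] <-
      m[((b - 1) * 10 + 1):(b * 10), truth == b] + 4
  gc <- buildGeneClusters(m, k = 4, nResamples = 40, seed = 3)
  expect_equal(adjRandIndex(gc, truth), 1)
  expect_identical(gc, buildGeneClusters(m, k = 4, nResamples = 40, seed = 3))
  expect_error(buildGeneClusters(m, k = 1), "at least 2")
  expect_error(buildGeneClusters(m[1, , drop = FALSE], k = 2), "2 DEGs")
})

test_that("signatures split exactly along the planted correlation signs", {
  ab <- antiBlockMatrix(seed = 4)
  gc <- buildGeneClusters(ab$m, k = 4, nResamples = 40, seed = 5)
  part <- partitionSignatures(ab$m, gc)
  # the axis tracks the latent gradient; up-block genes correlate positively
  oneSide <- sort(part$signatureA); otherSide <- sort(part$signatureB)
  if (startsWith(oneSide[1], "dn")) { tmp <- oneSide; oneSide <- otherSide; otherSide <- tmp }
  expect_identical(oneSide, sort(paste0("up", 1:10)))
  expect_identical(otherSide, sort(paste0("dn", 1:8)))

  flat <- matrix(rep(seq(1, 3, length.out = 20), each = 5), 5, 20, byrow = FALSE,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:20)))
  expect_error(partitionSignatures(flat, factor(rep(1:2, each = 10))),
               "degenerate")
})

test_that("the ICI score is the stated PC1 difference with exact sign symmetry", {
  ab <- antiBlockMatrix(seed = 6)
  gc <- factor(rep(LETTERS[1:4], each = 15))
  model <- fitIciModel(ab$m, gc, boruta = FALSE)
  sc <- computeIciScores(ab$m, model)
  expect_equal(sc$ici_score, sc$pc1_a - sc$pc1_b, tolerance = 1e-12)

  swapped <- new("IciModel",
                 signatureA = model@signatureB, signatureB = model@signatureA,
                 confirmedA = model@confirmedB, confirmedB = model@confirmedA,
                 loadingsA = model@loadingsB, loadingsB = model@loadingsA,
                 centerA = model@centerB, centerB = model@centerA,
                 signA = model@signB, signB = model@signA,
                 geneClusters = model@geneClusters)
  scSwap <- computeIciScores(ab$m, swapped)
  expect_equal(scSwap$ici_score, -sc$ici_score, tolerance = 1e-12)
})

test_that("a single-gene signature scores as the gene's z-score", {
  ab <- antiBlockMatrix(seed = 7)
  model <- new("IciModel",
               signatureA = "up1", signatureB = "dn1",
               confirmedA = "up1", confirmedB = "dn1",
               loadingsA = c(up1 = 1), loadingsB = c(dn1 = 1),
               centerA = c(up1 = 0), centerB = c(dn1 = 0),
               signA = 1, signB = 1,
               geneClusters = factor(rep("A", ncol(ab$m))))
  sc <- computeIciScores(ab$m, model)
  z <- (ab$m["up1", ] - mean(ab$m["up1", ])) / sd(ab$m["up1", ])
  expect_equal(abs(sc$pc1_a), unname(abs(z)), tolerance = 1e-9)
  expect_gt(cor(sc$pc1_a, ab$m["up1", ]), 0.999)
})

test_that("stored loadings project the training cohort onto its own scores", {
  ab <- antiBlockMatrix(seed = 8)
  gc <- buildGeneClusters(ab$m, k = 4, nResamples = 40, seed = 9)
  model <- fitIciModel(ab$m, gc, boruta = FALSE)
  first <- computeIciScores(ab$m, model)
  again <- computeIciScores(ab$m, model)
  expect_equal(first$ici_score, again$ici_score, tolerance = 1e-9)
  # projection equals the PCA scores computed at fit time
  z <- t(scale(t(ab$m[model@confirmedA, ])))
  pcs <- prcomp(t(z), center = TRUE)$x[, 1]
  expect_equal(abs(first$pc1_a), unname(abs(pcs)), tolerance = 1e-9)
})

test_that("missing signature genes are tolerated up to half, then refused", {
  ab <- antiBlockMatrix(nUp = 10, nDown = 8, seed = 10)
  gc <- factor(rep(LETTERS[1:4], each = 15))
  model <- fitIciModel(ab$m, gc, boruta = FALSE)
  dropOne <- ab$m[setdiff(rownames(ab$m), "up1"), ]
  expect_message(scDrop <- computeIciScores(dropOne, model), "absent")
  expect_equal(nrow(scDrop), ncol(ab$m))
  tooFew <- ab$m[c("up1", paste0("dn", 1:8)), ]
  expect_error(computeIciScores(tooFew, model), "more than half")
})

test_that("planted hot samples receive higher scores", {
  set.seed(11)
  n <- 150
  hot <- rep(c(TRUE, FALSE), c(50, 100))
  m <- matrix(rnorm(30 * n, 0, 0.5), 30, n,
              dimnames = list(c(paste0("up", 1:15), paste0("dn", 1:15)),
                              paste0("s", 1:n)))
  m[1:15, hot] <- m[1:15, hot] + 2
  m[16:30, hot] <- m[16:30, hot] - 2
  gc <- buildGeneClusters(m, k = 4, nResamples = 40, seed = 12)
  model <- fitIciModel(m, gc, boruta = FALSE)
  sc <- computeIciScores(m, model)
  # orientation follows mean expression: hot samples (up-genes elevated) high
  expect_lt(wilcox.test(sc$ici_score[hot], sc$ici_score[!hot],
                        alternative = "greater")$p.value, 0.01)
})

test_that("Boruta confirms planted relevance and rejects noise", {
  confirmedInfo <- 0; rejectedNoise <- numeric(0)
  for (s in 1:5) {
    set.seed(20 + s)
    n <- 150
    y <- factor(rep(c("a", "b", "c"), each = n / 3))
    X <- matrix(rnorm(n * 31), n, 31)
    X[, 1] <- as.numeric(y) + rnorm(n, 0, 0.5)
    colnames(X) <- c("info", paste0("noise", 1:30))
    b <- borutaSelect(X, y, nTrees = 150, maxIter = 40, seed = s)
    confirmedInfo <- confirmedInfo + ("info" %in% b$confirmed)
    rejectedNoise <- c(rejectedNoise, length(intersect(b$rejected,
                                                       paste0("noise", 1:30))) / 30)
  }
  expect_gte(confirmedInfo, 4)
  expect_gte(mean(rejectedNoise), 0.9)
})

test_that("Boruta keeps duplicated informative features (all-relevant property)", {
  set.seed(30)
  n <- 150
  y <- factor(rep(c("a", "b"), each = n / 2))
  base <- as.numeric(y) + rnorm(n, 0, 0.4)
  X <- cbind(info = base, twin = base + rnorm(n, 0, 0.05),
             matrix(rnorm(n * 10), n, 10))
  colnames(X)[3:12] <- paste0("noise", 1:10)
  b <- borutaSelect(X, y, nTrees = 200, maxIter = 40, seed = 31)
  expect_true(all(c("info", "twin") %in% b$confirmed))
})

test_that("Boruta confirms nothing on pure noise", {
  set.seed(40)
  y <- factor(rep(c("a", "b", "c"), each = 40))
  X <- matrix(rnorm(120 * 25), 120, 25)
  b <- borutaSelect(X, y, nTrees = 150, maxIter = 30, seed = 41)
  expect_lte(length(b$confirmed), 1)
  expect_error(borutaSelect(X, rep("a", 120)), "2 classes")
})

test_that("the survival-optimal cutoff equals an exhaustive brute-force scan", {
  set.seed(50)
  n <- 60
  scores <- rnorm(n)
  time <- rexp(n, ifelse(scores > 0, 0.05, 0.02))
  event <- rbinom(n, 1, 0.8)
  res <- optimalCutoff(scores, time, event, minGroupFrac = 0.1)

  u <- sort(unique(scores))
  cand <- (u[-1] + u[-length(u)]) / 2
  cand <- cand[vapply(cand, function(cc)
    min(sum(scores > cc), sum(scores <= cc)) >= ceiling(0.1 * n), logical(1))]
  chis <- vapply(cand, function(cc)
    survival::survdiff(survival::Surv(time, event) ~ (scores > cc))$chisq,
    numeric(1))
  expect_equal(res$chisq, max(chis), tolerance = 1e-9)
  expect_equal(res$cutoff, cand[which.max(chis)])
})

test_that("the cutoff lands between two planted score clusters", {
  set.seed(51)
  n <- 120
  grp <- rep(c(0, 1), each = n / 2)
  scores <- rnorm(n, mean = ifelse(grp == 1, 3, 0), sd = 0.4)
  time <- rexp(n, rate = ifelse(grp == 1, 0.005, 0.05))
  res <- optimalCutoff(scores, time, rep(1, n))
  expect_gt(res$cutoff, max(scores[grp == 0]) - 0.4)
  expect_lt(res$cutoff, min(scores[grp == 1]) + 0.4)
})

test_that("degenerate cutoff inputs are refused", {
  expect_error(optimalCutoff(rep(1, 30), rexp(30), rep(1, 30)), "constant")
  expect_error(optimalCutoff(rnorm(10), rexp(10), rep(1, 10)), "at least 20")
  expect_error(optimalCutoff(rnorm(30), rexp(30), rep(0, 30)), "5 events")
})
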