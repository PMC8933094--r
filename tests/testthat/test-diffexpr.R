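nullMatrix <- function(nGenes, n1, n2, sd = 1, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * (n1 + n2), 0, sd), nGenes,
              dimnames = list(paste0("g", seq_len(nGenes)), NULL))
  list(expr = m, labels = rep(c("a", "b"), c(n1, n2)))
}

test_that("null p-values are uniform and mirrored groups give zero fold change", {
  nd <- nullMatrix(2000, 10, 10, seed = 1)
  de <- moderatedTTest(nd$expr, nd$labels)
  expect_gt(ks.test(de$p_value, "punif")$p.value, 0.01)
  expect_true(all(de$adj_p >= 0 & de$adj_p <= 1))

  half <- matrix(rnorm(100 * 5), 100, 5)
  mirrored <- cbind(half, half)          # identical group means by construction
  rownames(mirrored) <- paste0("g", 1:100)
  deM <- moderatedTTest(mirrored, rep(c("a", "b"), each = 5))
  expect_true(all(deM$log2fc == 0))
})

test_that("zero prior df reduces to the ordinary two-sample t", {
  nd <- nullMatrix(60, 8, 12, seed = 2)
  de <- moderatedTTest(nd$expr, nd$labels, priorDf = 0)
  ref <- apply(nd$expr, 1, function(v)
    t.test(v[nd$labels == "b"], v[nd$labels == "a"], var.equal = TRUE)$statistic)
  expect_equal(de$t_stat, unname(ref), tolerance = 1e-12)
  expect_equal(attr(de, "prior_df"), 0)
})

test_that("infinite prior df pools the variance completely", {
  nd <- nullMatrix(50, 6, 6, seed = 3)
  de <- moderatedTTest(nd$expr, nd$labels, priorDf = Inf, priorVar = 1)
  diff <- rowMeans(nd$expr[, 7:12]) - rowMeans(nd$expr[, 1:6])
  expect_equal(de$t_stat, unname(diff / sqrt(1 * (1 / 6 + 1 / 6))),
               tolerance = 1e-12)
})

test_that("the estimated empirical Bayes prior matches the limma reference", {
  nd <- nullMatrix(500, 8, 8, seed = 4)
  de <- moderatedTTest(nd$expr, nd$labels)
  design <- stats::model.matrix(~factor(nd$labels))
  fit <- limma::eBayes(limma::lmFit(nd$expr, design))
  expect_equal(attr(de, "prior_df"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "prior_var"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$t_stat, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(de$p_value, unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("planted four-fold genes are recovered with controlled false positives", {
  set.seed(5)
  nGenes <- 2000; planted <- 1:200
  X <- matrix(rnorm(nGenes * 40, 0, 0.5), nGenes, 40,
              dimnames = list(paste0("g", seq_len(nGenes)), NULL))
  X[planted, 21:40] <- X[planted, 21:40] + 2   # 4-fold on the log2 scale
  de <- moderatedTTest(X, rep(c("a", "b"), each = 20))
  pass <- abs(de$log2fc) > 1 & de$adj_p < 0.05
  expect_gte(mean(pass[planted]), 0.9)
  expect_lte(mean(pass[-planted]), 0.05)
})

test_that("small groups and zero-variance genes are handled", {
  expect_error(moderatedTTest(matrix(1:6, 2), c("a", "a", "b")), "at least 2")
  X <- rbind(flat = rep(c(1, 1, 1, 2, 2, 2)), noisy = rnorm(6))
  de <- moderatedTTest(X, rep(c("a", "b"), each = 3))
  expect_true(all(is.finite(de$t_stat)))
})

test_that("subtype DEG union carries contrast provenance", {
  set.seed(6)
  X <- matrix(rnorm(100 * 30, 0, 0.3), 100, 30,
              dimnames = list(paste0("g", 1:100), NULL))
  lab <- rep(c("A", "B", "C"), each = 10)
  same <- degsAmongSubtypes(X, lab)
  expect_length(same$degs, 0)

  X["g1", lab == "C"] <- X["g1", lab == "C"] + 5
  de <- degsAmongSubtypes(X, lab)
  expect_true("g1" %in% de$degs)
  expect_match(de$provenance$contrasts[de$provenance$gene == "g1"], "C_vs_A")

  ovr <- degsAmongSubtypes(X, lab, mode = "one_vs_rest")
  expect_true("g1" %in% ovr$degs)
})

test_that("planted subtype-specific genes are recovered within ten percent", {
  counts <- vapply(1:5, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(2000 * 36, 0, 0.5), 2000, 36,
                dimnames = list(paste0("g", 1:2000), NULL))
    lab <- rep(c("A", "B", "C"), each = 12)
    X[1:100, lab == "B"] <- X[1:100, lab == "B"] + 2
    length(degsAmongSubtypes(X, lab)$degs)
  }, numeric(1))
  expect_true(all(abs(counts - 100) <= 10))
})

test_that("hypergeometric enrichment equals the exact tail sum", {
  sets <- list(term1 = paste0("g", 1:10), term2 = paste0("g", 11:40))
  universe <- paste0("g", 1:100)
  query <- paste0("g", c(1:5, 41:55))        # overlap 5 with term1
  res <- oraTest(query, sets, universe)
  manual <- sum(vapply(5:10, function(i)
    choose(10, i) * choose(90, 20 - i) / choose(100, 20), numeric(1)))
  expect_equal(res$p_value[res$term == "term1"], manual, tolerance = 1e-12)

  none <- oraTest(paste0("g", 60:79), sets["term1"], universe)
  expect_equal(none$p_value, 1)

  exact <- oraTest(paste0("g", 1:10), sets["term1"], universe)
  other <- oraTest(paste0("g", c(1:9, 50)), sets["term1"], universe)
  expect_lt(exact$p_value, other$p_value)    # full overlap is extremal

  expect_warning(oraTest(c(query, "outside"), sets, universe), "dropped")
  expect_warning(
    expect_warning(empty <- oraTest("outside", sets, universe), "empty"),
    "dropped")
  expect_equal(nrow(empty), 0)
})

test_that("Benjamini-Hochberg adjustment matches a brute-force oracle", {
  bruteBH <- function(p) {
    n <- length(p); o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  for (s in 1:5) {
    nd <- nullMatrix(300, 5, 5, seed = 10 + s)
    de <- moderatedTTest(nd$expr, nd$labels)
    expect_equal(de$adj_p, bruteBH(de$p_value), tolerance = 1e-12)
    ord <- order(de$p_value)
    expect_true(all(diff(de$adj_p[ord]) >= -1e-12))
  }
})
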