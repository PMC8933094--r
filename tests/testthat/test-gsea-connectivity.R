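# brute-force signed maximum deviation of the weighted running sum
bruteEs <- function(metric, set, p) {
  metric <- sort(metric, decreasing = TRUE)
  genes <- names(metric)
  walk <- 0; best <- 0
  nh <- sum(genes %in% set)
  nr <- sum(abs(metric[genes %in% set])^p)
  for (g in genes) {
    if (g %in% set) walk <- walk + abs(metric[[g]])^p / nr
    else walk <- walk - 1 / (length(genes) - nh)
    if (abs(walk) > abs(best)) best <- walk
  }
  best
}

# brute-force two-sided KS tag statistic over all positions
bruteKs <- function(positions, N) {
  v <- sort(positions); t <- length(v)
  a <- max(seq_len(t) / t - v / N)
  b <- max(v / N - (seq_len(t) - 1) / t)
  if (a > b) a else -b
}

test_that("phenotype ranking floors small deviations and is antisymmetric", {
  set.seed(1)
  expr <- matrix(rnorm(20 * 12), 20, 12,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
  pheno <- rep(c("high", "low"), each = 6)
  expr["g1", ] <- 5                      # identical in both classes
  expr["g2", pheno == "high"] <- expr["g2", pheno == "high"] + 4
  rk <- rankGenesByPhenotype(expr, pheno)
  expect_equal(rk$metric[rk$gene == "g1"], 0)
  expect_identical(rk$gene[1], "g2")

  flipped <- rankGenesByPhenotype(expr, rev(pheno))
  expect_equal(setNames(flipped$metric, flipped$gene)[rk$gene], -rk$metric,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(rankGenesByPhenotype(expr, rep(c("high", "low"), c(2, 10))),
               ">= 3 samples")
})

test_that("extremal and hand-enumerated enrichment scores are exact", {
  metric <- setNames(seq(10, 1), paste0("g", 1:10))
  top <- gsea(metric, list(top = "g1"), p = 1, nPerm = 50, minSize = 1, seed = 1)
  expect_equal(top$es, 1)

  set.seed(2)
  m <- setNames(rnorm(10), paste0("g", 1:10))
  sets <- list(s1 = c("g2", "g5", "g9"), s2 = c("g1", "g3", "g4", "g10"))
  res <- gsea(m, sets, p = 0, nPerm = 50, minSize = 3, seed = 3)
  expect_equal(res$es[res$gene_set == "s1"], bruteEs(m, sets$s1, 0))
  expect_equal(res$es[res$gene_set == "s2"], bruteEs(m, sets$s2, 0))
  resW <- gsea(m, sets, p = 1, nPerm = 50, minSize = 3, seed = 3)
  expect_equal(resW$es[resW$gene_set == "s1"], bruteEs(m, sets$s1, 1))
})

test_that("reversing the ranked list flips every enrichment score exactly", {
  set.seed(4)
  m <- setNames(rnorm(50), paste0("g", 1:50))
  sets <- list(a = paste0("g", 1:8), b = paste0("g", c(5, 20, 33, 41, 49)))
  fwd <- gsea(m, sets, nPerm = 20, seed = 5)
  rev <- gsea(-m, sets, nPerm = 20, seed = 5)
  expect_equal(rev$es, -fwd$es, tolerance = 1e-12)
})

test_that("enrichment scores agree with the fgsea reference implementation", {
  set.seed(6)
  m <- setNames(rnorm(200), paste0("g", 1:200))
  sets <- list(s1 = paste0("g", sample(200, 15)),
               s2 = paste0("g", sample(200, 30)))
  ours <- gsea(m, sets, p = 1, nPerm = 10, seed = 7)
  ref <- fgsea::calcGseaStat
  for (s in names(sets)) {
    stats <- sort(m, decreasing = TRUE)
    es <- ref(stats, selectedStats = which(names(stats) %in% sets[[s]]),
              gseaParam = 1)
    expect_equal(ours$es[ours$gene_set == s], es, tolerance = 1e-9)
  }
})

test_that("small sets are skipped and permutation p-values avoid zero", {
  m <- setNames(rnorm(30), paste0("g", 1:30))
  expect_warning(res <- gsea(m, list(tiny = "g1", ok = paste0("g", 1:6)),
                             nPerm = 30, seed = 8), "skipped")
  expect_identical(res$gene_set, "ok")
  expect_true(all(res$nominal_p > 0))
})

test_that("connectivity is +1/-1 for extremal tag placements and 0 for same-sign", {
  genes <- paste0("g", 1:20)
  ranks <- matrix(1:20, 20, 1, dimnames = list(genes, "i1"))
  up <- genes[1:3]; down <- genes[18:20]
  best <- cmapConnectivity(up, down, ranks)
  expect_equal(best$instances$score, 1)
  worst <- cmapConnectivity(down, up, ranks)
  expect_equal(worst$instances$score, -1)
  sameSign <- cmapConnectivity(genes[1:3], genes[4:6], ranks)
  expect_equal(sameSign$instances$raw, 0)
  expect_error(cmapConnectivity(genes[1:3], genes[3:5], ranks), "disjoint")
})

test_that("KS tag statistics equal brute-force enumeration on 20-gene profiles", {
  set.seed(9)
  genes <- paste0("g", 1:20)
  for (i in 1:5) {
    rk <- setNames(sample(20), genes)
    up <- sample(genes, 3); down <- sample(setdiff(genes, up), 3)
    res <- cmapConnectivity(up, down, matrix(rk, 20, 1,
                                             dimnames = list(genes, "i")))
    ksUp <- bruteKs(rk[up], 20); ksDown <- bruteKs(rk[down], 20)
    expected <- if (sign(ksUp) == sign(ksDown)) 0 else ksUp - ksDown
    expect_equal(res$instances$raw, expected, tolerance = 1e-12)
  }
})

test_that("compound-level statistics identify a planted signature reverser", {
  set.seed(10)
  genes <- paste0("g", 1:100)
  template <- setNames(rnorm(100), genes)
  ref <- generateReferenceProfiles(genes, nCompounds = 5,
                                   instancesPerCompound = 4,
                                   template = template, reversers = 1,
                                   noiseSd = 0.3, seed = 11)
  ord <- names(sort(template, decreasing = TRUE))
  res <- cmapConnectivity(ord[1:10], ord[91:100], ref$ranks,
                          instanceInfo = ref$instances, nPerm = 200, seed = 12)
  comp <- res$compounds
  hit <- comp[comp$compound == "compound_01", ]
  expect_lt(hit$mean, 0)                  # reverser: negative connectivity
  expect_lt(hit$perm_p, 0.05)
  expect_equal(hit$percent_nonnull, 100)
  expect_true(all(abs(comp$enrichment) <= 1))
})

test_that("mechanism-of-action counts are plain tallies", {
  moa <- data.frame(compound = c("c1", "c2", "c3"),
                    mechanism = c("dopamine receptor antagonist",
                                  "dopamine receptor antagonist",
                                  "PPAR receptor agonist"))
  ms <- moaSummary(c("c1", "c2", "c3", "c9"), moa)
  expect_equal(ms$count[ms$mechanism == "dopamine receptor antagonist"], 2)
  expect_equal(ms$count[ms$mechanism == "unknown"], 1)
  expect_equal(nrow(moaSummary(character(), moa)), 0)
  unique_ <- moaSummary(c("c1", "c3"), moa)
  expect_true(all(unique_$count == 1))
})
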