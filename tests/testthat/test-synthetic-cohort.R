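test_that("signature matrix has the block design, full rank, and is reproducible", {
  s <- generateSignatureMatrix(nTypes = 2, markersPerType = 1, baseLevel = 1,
                               markerFold = 10, jitterSd = 0, seed = 1)
  expect_equal(unname(s), matrix(c(10, 1, 1, 10), 2, 2))

  big <- generateSignatureMatrix(nTypes = 22, markersPerType = 25, seed = 3)
  expect_equal(dim(big), c(550L, 22L))
  expect_identical(qr(big)$rank, 22L)
  expect_true(all(big > 0))
  expect_identical(colnames(big), lm22CellTypes())

  expect_identical(big, generateSignatureMatrix(nTypes = 22, markersPerType = 25,
                                                seed = 3))
  expect_error(generateSignatureMatrix(nTypes = 1), "nTypes")
  expect_error(generateSignatureMatrix(markerFold = 0), "positive")
})

test_that("marker gene sets recover the generating blocks", {
  s <- tinySignature(nTypes = 3, markersPerType = 4, seed = 2, jitterSd = 0.1)
  sets <- markerGeneSets(s)
  expect_identical(lengths(sets), setNames(rep(4L, 3), colnames(s)))
  expect_identical(sets[[2]], sprintf("mk02_%02d", 1:4))
})

test_that("noiseless uncensored cohort equals the mixture model exactly", {
  cfg <- cohortConfig(nSamples = 30, noiseSd = 0, censorRate = 0,
                      nStromalGenes = 0, nNullGenes = 0, seed = 9)
  sig <- generateSignatureMatrix(seed = 9)
  coh <- generateCohort(cfg, sig)
  expr <- SummarizedExperiment::assay(coh, "tpm")
  expected <- sig %*% t(trueFractions(coh))
  expected <- sweep(expected, 2, colSums(expected), "/") * 1e6
  expect_equal(unname(expr), unname(expected), tolerance = 1e-12)
  expect_true(all(clinicalTable(coh)$event == 1))
})

test_that("cohort invariants hold and a fixed seed is bit-identical", {
  coh <- smallCohort(n = 50, seed = 4)
  expect_s4_class(coh, "IciCohort")
  expect_equal(rowSums(trueFractions(coh)), setNames(rep(1, 50), colnames(coh)),
               tolerance = 1e-9)
  expect_true(all(clinicalTable(coh)$time > 0))
  expect_equal(colSums(SummarizedExperiment::assay(coh, "tpm")),
               setNames(rep(1e6, 50), colnames(coh)), tolerance = 1e-9)
  coh2 <- smallCohort(n = 50, seed = 4)
  expect_identical(SummarizedExperiment::assay(coh, "tpm"),
                   SummarizedExperiment::assay(coh2, "tpm"))
  expect_identical(variantTable(coh), variantTable(coh2))
})

test_that("planted mutation burdens scale as Poisson means over the exome length", {
  dc <- matrix(2, 2, 8)
  dc[1, 1:4] <- 6; dc[2, 5:8] <- 6
  cfg <- cohortConfig(nSamples = 400, nSubtypes = 2,
                      subtypeProportions = c(0.5, 0.5),
                      dirichletConcentration = dc,
                      hazardPerSubtype = c(0.02, 0.02),
                      tmbMeanPerSubtype = c(30, 60), exomeLengthMb = 30,
                      seed = 21)
  coh <- generateCohort(cfg, tinySignature(nTypes = 8, markersPerType = 5))
  tmb <- computeTmb(variantTable(coh), exomeLengthMb = 30,
                    samples = colnames(coh), classes = NULL)
  bySub <- tapply(tmb$tmb, clinicalTable(coh)$subtype_true, mean)
  expect_equal(unname(bySub[["subtype1"]]), 1.0, tolerance = 0.1)
  expect_equal(unname(bySub[["subtype2"]]), 2.0, tolerance = 0.1)
})

test_that("planted hazard ratios separate on the log-rank test", {
  dc <- matrix(2, 2, 8); dc[1, 1:4] <- 6; dc[2, 5:8] <- 6
  pvals <- vapply(1:10, function(s) {
    cfg <- cohortConfig(nSamples = 300, nSubtypes = 2,
                        subtypeProportions = c(0.5, 0.5),
                        dirichletConcentration = dc,
                        hazardPerSubtype = c(0.04, 0.01), censorRate = 0.005,
                        tmbMeanPerSubtype = c(30, 30), seed = 100 + s)
    coh <- generateCohort(cfg, tinySignature(nTypes = 8, markersPerType = 5))
    cl <- clinicalTable(coh)
    logrankTest(cl$time, cl$event, cl$subtype_true)$p
  }, numeric(1))
  expect_true(all(pvals < 0.01))
})

test_that("invalid generator configurations are rejected", {
  expect_error(cohortConfig(subtypeProportions = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(cohortConfig(nSamples = 2), "nSamples")
  expect_error(cohortConfig(noiseSd = -1), "non-negative")
  dc <- matrix(1, 3, 22); dc[1, 1] <- 0
  expect_error(generateCohort(cohortConfig(dirichletConcentration = dc,
                                           nSamples = 10)),
               "positive")
})

test_that("cohorts round-trip losslessly through the TSV writers and readers", {
  coh <- smallCohort(n = 12, seed = 6)
  dir <- withr::local_tempdir()
  writeCohort(coh, dir)
  back <- readCohort(dir)
  expect_equal(SummarizedExperiment::assay(back, "tpm"),
               SummarizedExperiment::assay(coh, "tpm"), tolerance = 1e-12)
  expect_identical(variantTable(back)$Tumor_Sample_Barcode,
                   variantTable(coh)$Tumor_Sample_Barcode)
  expect_equal(clinicalTable(back)$time, clinicalTable(coh)$time,
               tolerance = 1e-12)
})

test_that("written files have the stated shapes, including the empty cohort", {
  dir <- withr::local_tempdir()
  expr <- matrix(1:6 * 1.0, 2, 3,
                 dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  clin <- data.frame(sample = c("a", "b", "c"), time = c(1, 2, 3),
                     event = c(1, 0, 1))
  coh <- IciCohort(fpkmToTpm(expr), clin)
  writeCohort(coh, dir)
  lines <- readLines(file.path(dir, "expression.tsv"))
  expect_length(lines, 3)                       # header + 2 gene rows
  expect_length(strsplit(lines[1], "\t")[[1]], 4) # gene id + 3 samples

  empty <- IciCohort(expr[, 0, drop = FALSE],
                     clin[0, , drop = FALSE])
  dir2 <- withr::local_tempdir()
  writeCohort(empty, dir2)
  expect_length(readLines(file.path(dir2, "clinical.tsv")), 1)
  expect_length(readLines(file.path(dir2, "variants.tsv")), 1)
})
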