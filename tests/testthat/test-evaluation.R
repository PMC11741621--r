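test_that("R^2 matches the definitional cases", {
  expect_equal(r2Score(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(r2Score(c(1, 2, 3), c(2, 2, 2)), 0.0)   # mean predictor
  expect_equal(r2Score(c(1, 2, 3), c(3, 2, 1)), -3.0)  # SS_res 8, SS_tot 2
  expect_error(r2Score(c(2, 2, 2), c(1, 2, 3)), class = "polyenSchemaError")
  expect_error(r2Score(1, 1), class = "polyenSchemaError")
})

test_that("R^2 is invariant to common affine rescaling", {
  withr::with_seed(83, {
    yt <- rnorm(20, 50, 10)
    yp <- yt + rnorm(20, sd = 4)
  })
  base <- r2Score(yt, yp)
  for (ab in list(c(2, 0), c(-1.5, 7), c(0.1, -3)))
    expect_equal(r2Score(ab[1] * yt + ab[2], ab[1] * yp + ab[2]), base,
                 tolerance = 1e-12)
})

test_that("LOO predicts each donor once, never leaks, honors the filter", {
  sim <- smallCohort(seed = 89L, nDonors = 8L, nGenes = 6L, cells = 15)
  cc <- sim$cohort
  config <- pipelineConfig(cellType = "epithelial", minCells = 5L,
                           space = fastSpace())
  ev <- looEvaluate(cc, config, nRuns = 2L, seed = 31)
  pr <- predictions(ev)
  expect_equal(nrow(pr), 2L * 8L)                   # n pairs per run
  expect_true(all(table(pr$run, pr$donor) == 1))
  expect_equal(length(r2PerRun(ev)), 2L)
  expect_equal(meanR2(ev), mean(r2PerRun(ev)))
  # leak assertion: every fold's training set excludes its held-out donor
  for (run in ev@details$folds)
    for (fold in run) {
      expect_false(fold$heldOut %in% fold$trainDonors)
      expect_length(fold$trainDonors, 7L)
    }

  # donor dropped by minCells is excluded from training and scoring
  spec <- cohortSpec(nDonors = 8L, nGenes = 6L,
                     cellTypes = c(epithelial = 15),
                     cellOverrides = list(D01 = 3),
                     signal = polyen:::emptySignal(), seed = 97L)
  cc2 <- generateCohort(spec)$cohort
  ev2 <- looEvaluate(cc2, config, nRuns = 1L, seed = 31)
  expect_false("D01" %in% predictions(ev2)$donor)
  expect_true("D01" %in% ev2@details$dropped)
})

test_that("cross-dataset evaluation enforces donor disjointness and genes", {
  simA <- smallCohort(seed = 101L, nDonors = 8L, nGenes = 8L, cells = 15)
  spec <- cohortSpec(nDonors = 6L, nGenes = 8L, cellTypes = c(epithelial = 15),
                     signal = simA$truth@coefficients |>
                       transform(gene = match(gene, sprintf("G%02d", 1:8))),
                     seed = 107L)
  simB <- generateCohort(spec)
  # rename donors of B to avoid accidental overlap
  ccB <- simB$cohort
  config <- pipelineConfig(cellType = "epithelial", minCells = 5L,
                           space = fastSpace())
  # donors present in both partitions -> integrity error
  expect_error(crossDatasetEvaluate(simA$cohort, simA$cohort, config,
                                    nRuns = 1L, seed = 1),
               class = "polyenIntegrityError")

  # harness self-check: train = test gives the training-set R^2
  self <- crossDatasetEvaluate(simA$cohort, simA$cohort, config,
                               nRuns = 1L, seed = 5, allowOverlap = TRUE)
  fm <- geneFeatures(simA$cohort, "epithelial", minCells = 5L)
  m <- trainModel(fm, "polyen", space = fastSpace(),
                  seed = polyen:::deriveSeed(5, 1))
  expect_equal(meanR2(self), r2Score(fm@y, predict(m, fm)),
               tolerance = 1e-10)

  dB <- as.data.frame(donorData(ccB))
  rownames(dB) <- paste0("X", rownames(dB))
  cB <- as.data.frame(SummarizedExperiment::colData(ccB))
  cB$donor <- paste0("X", cB$donor)
  ccB2 <- CellCohort(base::t(as.matrix(exprValues(ccB))), cB, dB,
                     normalized = TRUE)
  cd <- crossDatasetEvaluate(simA$cohort, ccB2, config, nRuns = 2L,
                             seed = 9)
  expect_equal(cd@scheme, "CD")
  expect_length(intersect(cd@details$trainDonors, cd@details$testDonors), 0L)
  expect_equal(nrow(predictions(cd)), 2L * 6L)

  # disjoint gene panels propagate the intersection error
  ccB3 <- ccB2
  rownames(ccB3) <- paste0("ZZ", rownames(ccB3))
  expect_error(crossDatasetEvaluate(simA$cohort, ccB3, config),
               class = "polyenIntegrityError")
})

test_that("Mann-Whitney comparison matches enumeration and reflects", {
  # identical samples: p near 1
  cmp <- compareMethods(c(0.2, 0.4, 0.6), c(0.2, 0.4, 0.6))
  expect_gt(cmp$p.value, 0.9)
  # complete separation: U = 0 for the lower sample (all 20 arrangements)
  cmp2 <- compareMethods(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(cmp2$U), 0)
  # exact two-sided p for complete separation at n = m = 3 is 2/20
  expect_equal(cmp2$p.value, 0.1, tolerance = 1e-12)
  # U reflects: U_a + U_b = n_a * n_b
  a <- c(0.1, 0.5, 0.3, 0.9); b <- c(0.2, 0.6, 0.4)
  expect_equal(unname(compareMethods(a, b)$U + compareMethods(b, a)$U),
               length(a) * length(b))
  # top-k helper
  expect_equal(topR2(c(0.1, 0.9, 0.5), k = 2), c(0.9, 0.5))
  expect_error(compareMethods(numeric(), 1), class = "polyenSchemaError")
})

test_that("run summaries sort by mean R^2 and flag non-positive rows", {
  mk <- function(r2s, ct) new("AgeEvaluation", scheme = "LOO",
    predictions = S4Vectors::DataFrame(run = 1L, donor = "d1", age = 50,
                                       predicted = 50),
    r2PerRun = r2s, pipeline = list(cellType = ct, geneSet = "AllExpressed",
                                    features = "gene", model = "polyen"),
    nRuns = length(r2s), details = list())
  tab <- summarizeRuns(list(mk(c(0.3, 0.3), "B"), mk(c(0.7, 0.7), "A"),
                            mk(c(-0.2, -0.2), "C")))
  expect_equal(tab$cell_type, c("A", "B", "C"))
  expect_equal(tab$flagged, c(FALSE, FALSE, TRUE))
  expect_equal(nrow(summarizeRuns(mk(0.5, "solo"))), 1L)
})
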