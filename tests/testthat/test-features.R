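test_that("donor aggregation computes means and sample variances", {
  cc <- tinyCohort()
  # d1 T cells for gene GA: values 1, 2, 3 -> mean 2, sample variance 1
  st <- aggregateDonorStats(cc, cellType = "T", minCells = 2L)
  expect_equal(st$U["d1", "GA"], 2)
  expect_equal(st$V["d1", "GA"], 1)
  # gene GB: values 2, 2, 2 -> variance 0
  expect_equal(st$V["d1", "GB"], 0)
  # d2 has one T cell with minCells = 2 -> dropped and reported
  expect_false("d2" %in% rownames(st$U))
  expect_equal(st$dropped, "d2")
  # minCells < 2 refused; unknown cell type reported
  expect_error(aggregateDonorStats(cc, "T", minCells = 1L),
               class = "polyenSchemaError")
  expect_error(aggregateDonorStats(cc, "NK"), "NK",
               class = "polyenIntegrityError")
  # unnormalized input refused
  expect_error(aggregateDonorStats(tinyCohort(normalized = FALSE), "T"),
               class = "polyenStateError")
})

test_that("polynomial expansion concatenates means, variances and squares", {
  U <- matrix(c(1, 0, 2, 2, 1, 0), 3, 2,
              dimnames = list(paste0("D", 1:3), c("g1", "g2")))
  V <- matrix(c(1, 4, 0, 0, 1, 2), 3, 2, dimnames = dimnames(U))
  fm <- polynomialExpand(U, V, y = c(30, 40, 50))
  X <- featureMatrix(fm)
  expect_equal(ncol(X), 8L)                        # 4n columns
  expect_equal(unname(X[, "g1|mean2"]), c(1, 0, 4))  # element-wise square
  expect_equal(colnames(X),
               c("g1|mean1", "g2|mean1", "g1|var1", "g2|var1",
                 "g1|mean2", "g2|mean2", "g1|var2", "g2|var2"))
  expect_equal(as.character(columnMeta(fm)$kind),
               rep(c("mean1", "var1", "mean2", "var2"), each = 2))
  # all-zero input stays all-zero
  z <- polynomialExpand(U * 0, V * 0, y = c(30, 40, 50))
  expect_true(all(featureMatrix(z) == 0))
  # shape mismatch errors
  expect_error(polynomialExpand(U, V[, 1, drop = FALSE], y = c(30, 40, 50)),
               class = "polyenSchemaError")
  expect_error(polynomialExpand(U, V, y = c(30, 40)),
               class = "polyenSchemaError")
})

test_that("aggregation is invariant to cell order and shifts behave affinely", {
  sim <- smallCohort(seed = 13L)
  cc <- sim$cohort
  st <- aggregateDonorStats(cc, "epithelial", minCells = 5L)
  # permute cells
  perm <- withr::with_seed(1, sample(ncol(cc)))
  ccP <- cc[, perm]
  stP <- aggregateDonorStats(ccP, "epithelial", minCells = 5L)
  expect_equal(stP$U, st$U, tolerance = 1e-12)
  expect_equal(stP$V, st$V, tolerance = 1e-12)

  # adding constant c to a gene shifts U, leaves V, squares transform
  m <- as.matrix(exprValues(cc))
  m["G03", ] <- m["G03", ] + 2.5
  cc2 <- CellCohort(base::t(m), as.data.frame(SummarizedExperiment::colData(cc)),
                    as.data.frame(donorData(cc)), normalized = TRUE)
  st2 <- aggregateDonorStats(cc2, "epithelial", minCells = 5L)
  expect_equal(st2$U[, "G03"], st$U[, "G03"] + 2.5, tolerance = 1e-10)
  expect_equal(st2$V[, "G03"], st$V[, "G03"], tolerance = 1e-10)
  fm2 <- polynomialExpand(st2$U, st2$V, donorAges(cc)[rownames(st2$U)])
  expect_equal(fm2@X[, "G03|mean2"], (st$U[, "G03"] + 2.5)^2,
               tolerance = 1e-10)

  # one-pass variance equals two-pass textbook variance
  keep <- cellTypeLabels(cc) == "epithelial"
  vals <- base::t(as.matrix(exprValues(cc))[, keep])
  don <- cellDonors(cc)[keep]
  for (d in unique(don)[1:3]) {
    twoPass <- apply(vals[don == d, , drop = FALSE], 2, var)
    expect_equal(st$V[d, ], twoPass, tolerance = 1e-10)
  }
})

test_that("PCA features project with training loadings and give 4k columns", {
  sim <- smallCohort(seed = 17L)
  cc <- sim$cohort
  fm <- pcaFeatures(cc, "epithelial", k = 10L, minCells = 5L)
  expect_equal(ncol(fm), 40L)                      # 4k
  expect_equal(unique(as.character(columnMeta(fm)$kind)),
               c("mean1", "var1", "mean2", "var2"))

  # held-out projection equals an independent eigendecomposition oracle
  fitDonors <- donorIds(cc)[1:8]
  fmT <- pcaFeatures(cc, "epithelial", k = 3L, fitDonors = fitDonors,
                     minCells = 5L)
  keep <- cellTypeLabels(cc) == "epithelial"
  vals <- base::t(as.matrix(exprValues(cc))[, keep])
  don <- cellDonors(cc)[keep]
  trainX <- vals[don %in% fitDonors, ]
  ev <- eigen(cov(trainX), symmetric = TRUE)
  ctr <- colMeans(trainX)
  holdCells <- !(don %in% fitDonors)
  oracle <- sweep(vals[holdCells, ], 2, ctr) %*% ev$vectors[, 1:3]
  got <- projectCells(fmT@transform, cc, "epithelial")[holdCells, ]
  for (j in 1:3)    # eigenvector sign is arbitrary
    expect_true(max(abs(got[, j] - oracle[, j])) < 1e-8 ||
                max(abs(got[, j] + oracle[, j])) < 1e-8)

  # rank-1 data with k = 1: donor means equal projections exactly
  withr::with_seed(5, {
    t1 <- rnorm(60)
    load <- rnorm(6)
  })
  vals1 <- outer(t1, load) + 3
  rownames(vals1) <- paste0("c", 1:60)
  colnames(vals1) <- paste0("G", 1:6)
  cells <- data.frame(donor = rep(paste0("d", 1:3), each = 20),
                      cell_type = "T", row.names = rownames(vals1))
  donors <- data.frame(age = c(30, 45, 60),
                       row.names = paste0("d", 1:3))
  cc1 <- CellCohort(vals1, cells, donors, normalized = TRUE)
  fm1 <- pcaFeatures(cc1, "T", k = 1L, minCells = 5L)
  sc <- projectCells(fm1@transform, cc1, "T")
  expect_equal(unname(fm1@X[, "PC1|mean1"]),
               as.vector(tapply(sc[, 1], rep(paste0("d", 1:3), each = 20),
                                mean)),
               tolerance = 1e-10)
  # k above rank errors
  expect_error(pcaFeatures(cc1, "T", k = 5L, minCells = 5L),
               class = "polyenSchemaError")
})

test_that("pseudo-bulk pools cells across cell types", {
  values <- matrix(c(1, 3, 5, 7), ncol = 1,
                   dimnames = list(paste0("c", 1:4), "GA"))
  cells <- data.frame(donor = "d1", cell_type = c("T", "T", "B", "B"),
                      row.names = rownames(values))
  # second donor so ages are non-degenerate downstream
  values <- rbind(values, c5 = 2, c6 = 4)
  cells <- rbind(cells, data.frame(donor = c("d2", "d2"), cell_type = "T",
                                   row.names = c("c5", "c6")))
  donors <- data.frame(age = c(40, 55), row.names = c("d1", "d2"))
  cc <- CellCohort(values, cells, donors, normalized = TRUE)
  fm <- pseudoBulkFeatures(cc, minCells = 2L)
  expect_equal(fm@X["d1", "GA|mean1"], 4)          # mean of 1,3,5,7
  expect_equal(fm@X["d1", "GA|var1"], 20 / 3)      # pooled sample variance
  expect_equal(ncol(fm), 4L)                       # 4n columns, n = 1 gene

  # single-cell-type donor: identical to per-type aggregation
  st <- aggregateDonorStats(cc, "T", minCells = 2L)
  expect_equal(fm@X["d2", "GA|mean1"], st$U["d2", "GA"])
  expect_equal(fm@X["d2", "GA|var1"], st$V["d2", "GA"])
})

test_that("meta features concatenate cell types then reduce to PCs", {
  # two cell types with distinct signals
  sig <- rbind(
    data.frame(cell_type = "A", gene = 1:2, b0 = c(2, 2.2),
               b1 = c(0.03, -0.02), b2 = 0, c0 = 0.4, c1 = 0),
    data.frame(cell_type = "B", gene = 3:4, b0 = c(2.1, 2.3),
               b1 = c(0.025, -0.015), b2 = 0, c0 = 0.4, c1 = 0))
  spec <- cohortSpec(nDonors = 10L, nGenes = 8L,
                     cellTypes = c(A = 25, B = 25), signal = sig, seed = 23L)
  cc <- generateCohort(spec)$cohort
  fm <- metaFeatures(cc, cellTypes = c("A", "B"), k = 5L, minCells = 5L)
  expect_equal(ncol(fm), 5L)
  expect_true(all(columnMeta(fm)$kind == "meta_pc"))
  expect_equal(nrow(fm), 10L)

  # donor missing one cell type is dropped with a report
  cc2 <- cc[, !(cellDonors(cc) == "D01" & cellTypeLabels(cc) == "B")]
  fm2 <- metaFeatures(cc2, cellTypes = c("A", "B"), k = 5L, minCells = 5L)
  expect_false("D01" %in% rownames(fm2@X))
  expect_true("D01" %in% fm2@dropped)

  # single cell type, k preserving rank: alpha = 0 fit has the same training
  # R^2 as the raw polynomial features (full-rank linear reparameterization)
  sim <- smallCohort(seed = 29L, nDonors = 14L, nGenes = 4L)
  cc3 <- sim$cohort
  fmRaw <- geneFeatures(cc3, "epithelial", minCells = 5L)
  keff <- qr(scale(fmRaw@X, scale = FALSE))$rank
  fmMeta <- metaFeatures(cc3, "epithelial", k = keff, minCells = 5L)
  mRaw <- fitElasticNet(fmRaw, alpha = 0, rho = 1, tol = 1e-12,
                        maxIter = 500000L)
  mMeta <- fitElasticNet(fmMeta, alpha = 0, rho = 1, tol = 1e-12,
                         maxIter = 500000L)
  expect_equal(r2Score(fmMeta@y, predict(mMeta, fmMeta)),
               r2Score(fmRaw@y, predict(mRaw, fmRaw)), tolerance = 1e-6)
})

test_that("feature matrices serialize to CSV + JSON and back", {
  sim <- smallCohort(seed = 31L)
  fm <- geneFeatures(sim$cohort, "epithelial", minCells = 5L)
  d <- withr::local_tempdir()
  writeFeatureMatrix(fm, d)
  back <- readFeatureMatrix(d)
  expect_equal(back@X, fm@X, tolerance = 1e-12)
  expect_equal(back@y, fm@y)
  expect_equal(as.character(back@columnMeta$kind),
               as.character(fm@columnMeta$kind))
})
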