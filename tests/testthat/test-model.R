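test_that("unpenalized fit interpolates exact linear data", {
  X <- matrix(c(1, 2, 3), dimnames = list(NULL, "g"))
  m <- fitElasticNet(X, alpha = 0, rho = 1, y = c(2, 4, 6), tol = 1e-12)
  expect_equal(unname(m@weights), 2, tolerance = 1e-8)
  expect_equal(m@intercept, 0, tolerance = 1e-8)
})

test_that("ridge solutions match the closed-form oracle", {
  worst <- 0
  for (i in 1:20) {
    pr <- withr::with_seed(100 + i, {
      n <- sample(10:40, 1); m <- sample(3:15, 1)
      X <- matrix(rnorm(n * m), n, m,
                  dimnames = list(NULL, paste0("f", seq_len(m))))
      list(X = X, y = rnorm(n, drop(X %*% rnorm(m)), 0.5),
           a = 10^runif(1, -3, 1))
    })
    fit <- fitElasticNet(pr$X, alpha = pr$a, rho = 0, y = pr$y,
                         tol = 1e-10, maxIter = 100000L,
                         standardize = FALSE)
    Xc <- scale(pr$X, scale = FALSE)
    yc <- pr$y - mean(pr$y)
    wref <- solve(crossprod(Xc) / nrow(Xc) + pr$a * diag(ncol(Xc)),
                  crossprod(Xc, yc) / nrow(Xc))
    worst <- max(worst, max(abs(fit@weights - wref)) / max(abs(wref)))
  }
  expect_lt(worst, 1e-6)
})

test_that("lasso solutions satisfy the KKT conditions and match glmnet", {
  skip_if_not_installed("glmnet")
  pr <- randomProblem(30, 20, seed = 41)
  f <- fitElasticNet(pr$X, alpha = 0.5, rho = 1, y = pr$y, tol = 1e-10,
                     maxIter = 200000L, standardize = FALSE)
  expect_lt(f@convergence$kkt_violation, 1e-6)
  expect_lt(kktViolation(f, pr$X, y = pr$y), 1e-6)
  g <- glmnet::glmnet(pr$X, pr$y, alpha = 1, lambda = 0.5,
                      standardize = FALSE, thresh = 1e-16)
  expect_equal(unname(f@weights), as.numeric(coef(g))[-1],
               tolerance = 1e-6)
})

test_that("heavy L1 penalty shrinks all weights to zero", {
  pr <- randomProblem(20, 4, seed = 43, noise = 5)
  m <- fitElasticNet(scale(pr$X), alpha = 100, rho = 1, y = pr$y)
  expect_true(all(m@weights == 0))
  expect_equal(m@intercept, mean(pr$y))
})

test_that("solver objective is non-increasing and beats the null model", {
  pr <- randomProblem(25, 40, seed = 47)
  m <- fitElasticNet(pr$X, alpha = 0.3, rho = 0.5, y = pr$y)
  tr <- m@convergence$objective_trace
  expect_true(all(diff(tr) <= 1e-10 * abs(tr[-length(tr)]) + 1e-12))
  obj0 <- enetObjective(m, pr$X, y = pr$y,
                        w = rep(0, length(m@weights)))
  expect_lte(m@convergence$final_objective, obj0)
})

test_that("scaling the target scales the unpenalized solution", {
  pr <- randomProblem(20, 5, seed = 53)
  m1 <- fitElasticNet(pr$X, 0, 1, y = pr$y, tol = 1e-12, maxIter = 300000L)
  m2 <- fitElasticNet(pr$X, 0, 1, y = 3 * pr$y, tol = 1e-12,
                      maxIter = 300000L)
  expect_equal(unname(m2@weights), 3 * unname(m1@weights),
               tolerance = 1e-6)
  expect_equal(m2@intercept, 3 * m1@intercept, tolerance = 1e-6)
})

test_that("L1 norm is non-increasing along the alpha path at rho = 1", {
  pr <- randomProblem(30, 10, seed = 59)
  norms <- vapply(c(0.001, 0.01, 0.1, 1, 10, 100), function(a) {
    sum(abs(fitElasticNet(pr$X, a, 1, y = pr$y,
                          tol = 1e-9)@convergence$w_std))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-6 * pmax(norms[-length(norms)], 1)))
})

test_that("alpha = 0 reproduces least-squares fitted values on tall X", {
  pr <- randomProblem(50, 6, seed = 61)
  m <- fitElasticNet(pr$X, 0, 1, y = pr$y, tol = 1e-13, maxIter = 500000L)
  ls <- lm(pr$y ~ pr$X)
  expect_equal(unname(predict(m, pr$X)), unname(fitted(ls)),
               tolerance = 1e-8)
})

test_that("NaN input and tiny cohorts are rejected", {
  X <- matrix(c(1, NA, 3), dimnames = list(NULL, "g"))
  expect_error(fitElasticNet(X, 1, 1, y = 1:3),
               class = "polyenSchemaError")
  expect_error(fitElasticNet(matrix(1, 1, 1, dimnames = list(NULL, "g")),
                             1, 1, y = 5),
               class = "polyenSchemaError")
})

test_that("tuning respects its budget, trace contract and determinism", {
  pr <- randomProblem(30, 8, seed = 67)
  # budget 1 returns the single evaluated configuration
  one <- tuneHyperparameters(pr$X, searchSpace(budget = 1L), seed = 5,
                             y = pr$y)
  expect_equal(nrow(one$trace), 1L)
  expect_equal(one$loss, one$trace$loss[1])

  t1 <- tuneHyperparameters(pr$X, searchSpace(budget = 12L), seed = 9,
                            y = pr$y)
  t2 <- tuneHyperparameters(pr$X, searchSpace(budget = 12L), seed = 9,
                            y = pr$y)
  expect_identical(t1$trace, t2$trace)           # same seed, same trace
  expect_equal(nrow(t1$trace), 12L)
  expect_lte(t1$loss, min(t1$trace$loss))        # best <= all evaluated
  expect_true(all(t1$trace$rho >= 0.1 & t1$trace$rho <= 1))
  expect_true(all(t1$trace$alpha %in% searchSpace()$alphaGrid))

  # degenerate constant target errors
  expect_error(tuneHyperparameters(pr$X, y = rep(50, 30)),
               class = "polyenSchemaError")
})

test_that("SMBO selection is consistent with an exhaustive grid oracle", {
  pr <- randomProblem(30, 8, seed = 71)
  space <- searchSpace(budget = 18L)
  smbo <- tuneHyperparameters(pr$X, space, seed = 3, y = pr$y)
  # brute-force oracle over the alpha grid x three rho values, same folds
  grid <- expand.grid(alpha = space$alphaGrid, rho = c(0.1, 0.55, 1.0))
  gridLoss <- mapply(function(a, r)
    polyen:::cvLoss(pr$X, pr$y, a, r, smbo$foldid, tol = 1e-4,
                    maxIter = 2000L),
    grid$alpha, grid$rho)
  expect_lte(smbo$loss, min(smbo$trace$loss))
  # the SMBO optimum is within sampling slack of the exhaustive optimum
  expect_lt(smbo$loss, min(gridLoss) * 1.5 + 1)
})

test_that("baselines restrict to mean columns and fix rho where required", {
  sim <- smallCohort(seed = 73L)
  fm <- geneFeatures(sim$cohort, "epithelial", minCells = 5L)
  lasso <- fitBaselineLasso(fm, space = fastSpace(), seed = 2)
  expect_equal(length(lasso@weights), ncol(fm) / 4L)   # mean1 columns only
  expect_true(all(grepl("mean1", names(lasso@weights))))
  expect_equal(lasso@rho, 1.0)

  en <- fitBaselineEN(fm, space = fastSpace(), seed = 2)
  expect_equal(length(en@weights), ncol(fm) / 4L)
  expect_true(all(grepl("mean1", names(en@weights))))

  full <- trainModel(fm, "polyen", space = fastSpace(), seed = 2)
  expect_equal(length(full@weights), ncol(fm))
})

test_that("models round-trip through JSON with predictions intact", {
  sim <- smallCohort(seed = 79L)
  fm <- geneFeatures(sim$cohort, "epithelial", minCells = 5L)
  m <- trainModel(fm, "polyen", space = fastSpace(), seed = 4)
  f <- withr::local_tempfile(fileext = ".json")
  writeModel(m, f)
  back <- readModel(f)
  expect_equal(predict(back, fm), predict(m, fm), tolerance = 1e-10)
  expect_equal(back@alpha, m@alpha)
  expect_equal(back@rho, m@rho)
})
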