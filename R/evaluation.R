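#' @include model.R
NULL

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken
#' about the mean of the true ages. Can be negative for predictors worse
#' than the mean; equals 1 only for exact predictions.
#'
#' @param yTrue,yPred numeric vectors of equal length >= 2.
#' @return numeric(1).
#' @export
r2Score <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred) || length(yTrue) < 2L)
    polyenStop("polyenSchemaError",
               "need two equal-length vectors of at least 2 values")
  ssTot <- sum((yTrue - mean(yTrue))^2)
  if (ssTot == 0)
    polyenStop("polyenSchemaError",
               "true ages are constant; R^2 is undefined")
  1 - sum((yTrue - yPred)^2) / ssTot
}

#' Pipeline configuration for evaluation
#'
#' @param cellType cell-type label, or \code{NULL} for pseudo-bulk (all
#'   cells pooled).
#' @param genes \linkS4class{GeneSet}, character vector, or \code{NULL} for
#'   all genes.
#' @param features "gene" (polynomial features in gene space), "pca"
#'   (polynomials of the top-\code{pcaK} PC scores, PCA refit on training
#'   cells in every fold), or "meta" (cross-cell-type meta-regressor).
#' @param pcaK principal components for the PCA variant (default 10) or the
#'   meta variant (default 20 when \code{features = "meta"}).
#' @param cellTypes cell types for the meta variant.
#' @param model "polyen", "baseline_lasso" or "baseline_en".
#' @param minCells per-donor cell-count filter (default 10).
#' @param space a [searchSpace()].
#' @param tol,maxIter solver controls.
#' @return a named list with class \code{"polyenPipeline"}.
#' @export
pipelineConfig <- function(cellType = NULL, genes = NULL,
                           features = c("gene", "pca", "meta"),
                           pcaK = NULL, cellTypes = NULL,
                           model = c("polyen", "baseline_lasso",
                                     "baseline_en"),
                           minCells = 10L, space = searchSpace(),
                           tol = 1e-6, maxIter = 100000L) {
  features <- match.arg(features)
  model <- match.arg(model)
  if (is.null(pcaK)) pcaK <- if (features == "meta") 20L else 10L
  structure(list(cellType = cellType, genes = genes, features = features,
                 pcaK = as.integer(pcaK), cellTypes = cellTypes,
                 model = model, minCells = as.integer(minCells),
                 space = space, tol = tol, maxIter = maxIter),
            class = "polyenPipeline")
}

# Featurize a cohort under a pipeline config. fitDonors restricts every
# data-driven transform (PCA loadings) to training donors; feature rows are
# produced for all retained donors.
featurizeCohort <- function(x, config, fitDonors = NULL) {
  switch(config$features,
    gene = geneFeatures(x, cellType = config$cellType, genes = config$genes,
                        minCells = config$minCells),
    pca = pcaFeatures(x, cellType = config$cellType, genes = config$genes,
                      k = config$pcaK, fitDonors = fitDonors,
                      minCells = config$minCells),
    meta = metaFeatures(x, cellTypes = config$cellTypes,
                        genes = config$genes, k = config$pcaK,
                        fitDonors = fitDonors, minCells = config$minCells))
}

pipelineDescriptor <- function(config) {
  list(cellType = config$cellType %||% "(all cells)",
       geneSet = if (is(config$genes, "GeneSet")) setName(config$genes)
                 else if (is.null(config$genes)) "AllExpressed"
                 else "(custom)",
       features = config$features, pcaK = config$pcaK,
       model = config$model)
}

#' Leave-one-out evaluation
#'
#' For every donor: features are built and hyperparameters tuned without
#' that donor (any PCA transform is refit on the remaining donors' cells),
#' the model is fit, and the held-out donor's age predicted. One R-squared
#' is computed over all retained donors per run; runs are repeated
#' \code{nRuns} times with seeds derived from \code{seed} (runs differ
#' through tuning and fold randomness).
#'
#' @param x a normalized \linkS4class{CellCohort} with >= 3 donors
#'   surviving the cell-count filter.
#' @param config a [pipelineConfig()].
#' @param nRuns repeated runs (default 5).
#' @param seed master seed.
#' @return an \linkS4class{AgeEvaluation} (scheme "LOO"); \code{details}
#'   records per-fold training donors and selected hyperparameters, and the
#'   donors excluded by the cell-count filter.
#' @export
looEvaluate <- function(x, config = pipelineConfig(), nRuns = 5L, seed = 1L) {
  stopifnot(is(x, "CellCohort"))
  full <- featurizeCohort(x, config)           # defines retained donors
  donors <- rownames(full@X)
  if (length(donors) < 3L)
    polyenStop("polyenIntegrityError",
               "need >= 3 donors after the cell-count filter (have %d)",
               length(donors))
  refit <- config$features %in% c("pca", "meta")
  preds <- vector("list", nRuns)
  r2 <- numeric(nRuns)
  folds <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    runSeed <- deriveSeed(seed, r)
    yhat <- setNames(numeric(length(donors)), donors)
    foldInfo <- vector("list", length(donors))
    for (i in seq_along(donors)) {
      d <- donors[i]
      trainDonors <- setdiff(donors, d)
      fm <- if (refit) featurizeCohort(x, config, fitDonors = trainDonors)
            else full
      trainRows <- match(trainDonors, rownames(fm@X))
      testRow <- match(d, rownames(fm@X))
      model <- trainModel(fm[trainRows, ], kind = config$model,
                          space = config$space,
                          seed = deriveSeed(runSeed, i),
                          tol = config$tol, maxIter = config$maxIter)
      yhat[d] <- predict(model, fm[testRow, , drop = FALSE])
      foldInfo[[i]] <- list(heldOut = d, trainDonors = trainDonors,
                            alpha = model@alpha, rho = model@rho,
                            transformFitDonors =
                              if (refit) fm@transform$fitDonors)
    }
    r2[r] <- r2Score(full@y, unname(yhat[donors]))
    preds[[r]] <- DataFrame(run = r, donor = donors, age = full@y,
                            predicted = unname(yhat[donors]))
    folds[[r]] <- foldInfo
  }
  new("AgeEvaluation", scheme = "LOO",
      predictions = do.call(rbind, preds), r2PerRun = r2,
      pipeline = pipelineDescriptor(config), nRuns = as.integer(nRuns),
      details = list(folds = folds, dropped = full@dropped,
                     seed = as.integer(seed)))
}

#' Cross-dataset evaluation
#'
#' Pools the training cohorts, restricts all cohorts to the shared gene
#' panel, fits one tuned model per run on the pooled training donors
#' (any PCA transform fitted on training cells only) and predicts every
#' test donor. Train and test donor sets must be disjoint.
#'
#' @param train,test a \linkS4class{CellCohort} or list of cohorts.
#' @param config a [pipelineConfig()].
#' @param nRuns repeated runs (default 5).
#' @param seed master seed.
#' @param allowOverlap permit train/test donor overlap (harness self-checks
#'   only; default FALSE raises an integrity error).
#' @return an \linkS4class{AgeEvaluation} (scheme "CD").
#' @export
crossDatasetEvaluate <- function(train, test, config = pipelineConfig(),
                                 nRuns = 5L, seed = 1L,
                                 allowOverlap = FALSE) {
  trainList <- if (is(train, "CellCohort")) list(train) else train
  testList <- if (is(test, "CellCohort")) list(test) else test
  trainPool <- combineCohorts(trainList)
  testPool <- combineCohorts(testList)
  overlap <- intersect(donorIds(trainPool), donorIds(testPool))
  selfCheck <- allowOverlap && identical(donorIds(trainPool),
                                         donorIds(testPool))
  if (length(overlap) && !allowOverlap)
    polyenStop("polyenIntegrityError",
               "donors present in both partitions: %s",
               paste(overlap, collapse = ", "))
  shared <- intersectGenes(trainPool, testPool)
  trainPool <- shared$train; testPool <- shared$test
  trainFm <- featurizeCohort(trainPool, config,
                             fitDonors = donorIds(trainPool))
  testFm <- if (selfCheck) trainFm else {
    if (config$features %in% c("pca", "meta")) {
      tf <- trainFm@transform
      if (config$features == "pca") {
        scores <- projectCells(tf, testPool, cellType = config$cellType)
        donors <- cellDonors(testPool)[selectCells(testPool, config$cellType)]
        tab <- table(donors)
        ok <- donorIds(testPool)[donorIds(testPool) %in%
                                   names(tab)[tab >= config$minCells]]
        sel <- donors %in% ok
        mom <- donorMoments(scores[sel, , drop = FALSE],
                            factor(donors[sel], levels = ok))
        polynomialExpand(mom$U, mom$V, donorAges(testPool)[ok],
                         cellType = config$cellType %||% "", nCells = mom$n)
      } else {
        polyenStop("polyenSchemaError",
                   "meta features are not supported in cross-dataset mode")
      }
    } else featurizeCohort(testPool, config)
  }
  preds <- vector("list", nRuns)
  r2 <- numeric(nRuns)
  fits <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    model <- trainModel(trainFm, kind = config$model, space = config$space,
                        seed = deriveSeed(seed, r),
                        tol = config$tol, maxIter = config$maxIter)
    yhat <- predict(model, testFm)
    r2[r] <- r2Score(testFm@y, yhat)
    preds[[r]] <- DataFrame(run = r, donor = rownames(testFm@X),
                            age = testFm@y, predicted = unname(yhat))
    fits[[r]] <- list(alpha = model@alpha, rho = model@rho,
                      trainDonors = rownames(trainFm@X))
  }
  new("AgeEvaluation", scheme = "CD",
      predictions = do.call(rbind, preds), r2PerRun = r2,
      pipeline = pipelineDescriptor(config), nRuns = as.integer(nRuns),
      details = list(fits = fits, dropped = trainFm@dropped,
                     seed = as.integer(seed),
                     trainDonors = rownames(trainFm@X),
                     testDonors = rownames(testFm@X)))
}

#' Top-k selection of per-cell-type scores
#'
#' @param scores numeric vector of per-cell-type mean R-squared values.
#' @param k how many to keep (default 10).
#' @return the k largest values, in decreasing order.
#' @export
topR2 <- function(scores, k = 10L) {
  stopifnot(length(scores) >= 1L)
  head(sort(scores, decreasing = TRUE), k)
}

#' Compare two methods' per-cell-type R-squared samples
#'
#' Two-sided Mann-Whitney U test on the two samples; optionally restricted
#' to the top-k cell types of each method first (as used for headline
#' method comparisons).
#'
#' @param a,b numeric vectors of per-cell-type mean R-squared values.
#' @param k top-k filter applied to each sample before testing, or
#'   \code{NULL} to compare the full samples.
#' @return list with \code{U} (the U statistic of sample \code{a}),
#'   \code{p.value} (two-sided), and the compared samples \code{a},
#'   \code{b}.
#' @export
compareMethods <- function(a, b, k = NULL) {
  if (length(a) == 0L || length(b) == 0L)
    polyenStop("polyenSchemaError", "both samples must be non-empty")
  if (!is.null(k)) { a <- topR2(a, k); b <- topR2(b, k) }
  ht <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  list(U = unname(ht$statistic), p.value = ht$p.value, a = a, b = b)
}

#' Summarize evaluation results as a table
#'
#' @param results list of \linkS4class{AgeEvaluation} objects.
#' @return data.frame with one row per result (scheme, cell type, gene set,
#'   feature space, model, mean and SD of R-squared, number of runs),
#'   sorted by decreasing mean; rows with mean <= 0 are flagged.
#' @export
summarizeRuns <- function(results) {
  if (is(results, "AgeEvaluation")) results <- list(results)
  rows <- lapply(results, function(r) {
    pl <- r@pipeline
    data.frame(scheme = r@scheme, cell_type = pl$cellType %||% "(all cells)",
               gene_set = pl$geneSet %||% "AllExpressed",
               features = pl$features %||% "gene",
               model = pl$model %||% "polyen",
               mean_r2 = meanR2(r), sd_r2 = sdR2(r), n_runs = r@nRuns,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_r2), , drop = FALSE]
  out$flagged <- out$mean_r2 <= 0
  rownames(out) <- NULL
  out
}
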