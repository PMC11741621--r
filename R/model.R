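#' @include features.R
#' @useDynLib polyen, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

asXy <- function(features, y = NULL) {
  if (is(features, "DonorFeatureMatrix"))
    list(X = features@X, y = features@y)
  else
    list(X = as.matrix(features), y = as.numeric(y))
}

#' Elastic-net hyperparameter search space
#'
#' Defaults: penalty strength alpha over the grid
#' \{0.001, 0.01, 0.1, 1, 10, 100\}, L1 fraction rho over the continuous
#' interval [0.1, 1.0], 30 evaluations of the sequential optimizer, and
#' 5 inner cross-validation folds for the tuning loss.
#'
#' @param alphaGrid candidate penalty strengths.
#' @param rhoRange lower/upper bound of the L1 fraction.
#' @param budget maximum optimizer evaluations (>= 1).
#' @param folds inner CV folds.
#' @return a list with class \code{"polyenSearchSpace"}.
#' @export
searchSpace <- function(alphaGrid = c(0.001, 0.01, 0.1, 1, 10, 100),
                        rhoRange = c(0.1, 1.0), budget = 30L, folds = 5L) {
  stopifnot(budget >= 1L, folds >= 2L, length(rhoRange) == 2L,
            rhoRange[1] <= rhoRange[2], all(alphaGrid >= 0))
  structure(list(alphaGrid = alphaGrid, rhoRange = rhoRange,
                 budget = as.integer(budget), folds = as.integer(folds)),
            class = "polyenSearchSpace")
}

#' Fit the elastic-net age regressor at fixed hyperparameters
#'
#' Minimizes \deqn{\frac{1}{2n}\|Xw-y\|_2^2 + \alpha\rho\|w\|_1 +
#' \frac{\alpha(1-\rho)}{2}\|w\|_2^2}{(1/2n)||Xw-y||^2 + alpha*rho*||w||_1 +
#' alpha(1-rho)/2*||w||_2^2} by cyclic coordinate descent, with an
#' unpenalized intercept. Feature columns are standardized (centered and
#' scaled by training statistics) before penalized fitting and coefficients
#' are mapped back to the original coordinates; predictions are unaffected
#' by this reparameterization but shrinkage is applied on a common scale.
#'
#' @param features a \linkS4class{DonorFeatureMatrix}, or a numeric matrix
#'   with \code{y} supplied.
#' @param alpha penalty strength (>= 0).
#' @param rho L1 fraction in [0, 1] (1 = lasso, 0 = ridge).
#' @param y donor ages when \code{features} is a bare matrix.
#' @param tol convergence tolerance on the maximum coefficient change per
#'   sweep (standardized scale; default 1e-6).
#' @param maxIter maximum coordinate-descent sweeps (default 100000).
#' @param standardize center/scale columns before fitting (default TRUE).
#' @param columns optional column names/indices restricting the fit.
#' @param wStart optional warm-start coefficients (standardized scale).
#' @return an \linkS4class{ElasticNetModel}. Non-convergence is recorded in
#'   the \code{convergence} slot (with a warning), never thrown.
#' @examples
#' X <- matrix(c(1, 2, 3), dimnames = list(NULL, "g"))
#' fitElasticNet(X, alpha = 0, rho = 1, y = c(2, 4, 6))
#' @export
fitElasticNet <- function(features, alpha, rho, y = NULL, tol = 1e-6,
                          maxIter = 100000L, standardize = TRUE,
                          columns = NULL, wStart = NULL) {
  xy <- asXy(features, y)
  X <- xy$X
  if (!is.null(columns)) X <- X[, columns, drop = FALSE]
  yv <- xy$y
  if (anyNA(X) || anyNA(yv) || any(!is.finite(X)) || any(!is.finite(yv)))
    polyenStop("polyenSchemaError", "features and ages must be finite")
  if (nrow(X) < 2L)
    polyenStop("polyenSchemaError", "need at least 2 donors to fit")
  stopifnot(alpha >= 0, rho >= 0, rho <= 1)
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("f", seq_len(ncol(X)))
  center <- colMeans(X)
  scl <- if (standardize) apply(X, 2, sd) else rep(1, ncol(X))
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")
  ybar <- mean(yv)
  fit <- .enet_cd(Xs, yv - ybar, alpha, rho, tol, as.integer(maxIter), wStart)
  if (!fit$converged)
    warning(sprintf(
      "coordinate descent did not converge in %d sweeps (max delta %.2e)",
      maxIter, fit$max_delta))
  ws <- as.numeric(fit$w)
  w <- ws / scl
  intercept <- ybar - sum(w * center)
  new("ElasticNetModel",
      weights = setNames(w, cn), intercept = intercept,
      alpha = alpha, rho = rho,
      center = setNames(center, cn), scale = setNames(scl, cn),
      convergence = list(iterations = fit$iterations,
                         converged = fit$converged,
                         objective_trace = as.numeric(fit$objective_trace),
                         final_objective = fit$final_objective,
                         kkt_violation = fit$kkt_violation,
                         max_delta = fit$max_delta, tol = tol,
                         w_std = ws),
      tuning = list())
}

#' Predict donor ages
#'
#' @param object an \linkS4class{ElasticNetModel}.
#' @param newdata a \linkS4class{DonorFeatureMatrix} or matrix carrying at
#'   least the model's feature columns.
#' @param ... ignored.
#' @return numeric vector of predicted ages.
#' @export
setMethod("predict", "ElasticNetModel", function(object, newdata, ...) {
  X <- if (is(newdata, "DonorFeatureMatrix")) newdata@X else as.matrix(newdata)
  want <- names(object@weights)
  miss <- setdiff(want, colnames(X))
  if (length(miss))
    polyenStop("polyenSchemaError",
               "newdata lacks model feature columns: %s",
               paste(head(miss, 5), collapse = ", "))
  drop(X[, want, drop = FALSE] %*% object@weights) + object@intercept
})

#' Objective value of the elastic-net problem at the fitted coefficients
#'
#' Evaluated on the standardized training coordinates the solver worked in.
#'
#' @param model an \linkS4class{ElasticNetModel}.
#' @param features the training features (matrix or DonorFeatureMatrix).
#' @param y ages when \code{features} is a matrix.
#' @param w optional coefficient vector (standardized scale) to evaluate
#'   instead of the fitted one.
#' @return numeric(1).
#' @export
enetObjective <- function(model, features, y = NULL, w = NULL) {
  xy <- asXy(features, y)
  X <- xy$X[, names(model@weights), drop = FALSE]
  Xs <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  yc <- xy$y - mean(xy$y)
  if (is.null(w)) w <- model@convergence$w_std
  r <- yc - drop(Xs %*% w)
  sum(r^2) / (2 * nrow(Xs)) + model@alpha * model@rho * sum(abs(w)) +
    model@alpha * (1 - model@rho) / 2 * sum(w^2)
}

#' KKT optimality certificate
#'
#' Checks the subgradient conditions of the elastic-net objective at the
#' fitted coefficients: for active coordinates the smooth gradient must
#' cancel \eqn{\alpha\rho\,\mathrm{sign}(w_j)}; for inactive ones its
#' magnitude must not exceed \eqn{\alpha\rho}.
#'
#' @inheritParams enetObjective
#' @return the maximum KKT violation (numeric(1)).
#' @export
kktViolation <- function(model, features, y = NULL) {
  xy <- asXy(features, y)
  X <- xy$X[, names(model@weights), drop = FALSE]
  Xs <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  yc <- xy$y - mean(xy$y)
  w <- model@convergence$w_std
  n <- nrow(Xs)
  grad <- -drop(crossprod(Xs, yc - drop(Xs %*% w))) / n +
    model@alpha * (1 - model@rho) * w
  l1 <- model@alpha * model@rho
  viol <- ifelse(w > 0, abs(grad + l1),
                 ifelse(w < 0, abs(grad - l1), pmax(0, abs(grad) - l1)))
  max(viol)
}

cvFoldIds <- function(n, folds, seed) {
  withSeed(seed, sample(rep_len(seq_len(folds), n)))
}

cvLoss <- function(X, y, alpha, rho, foldid, tol, maxIter, warm = NULL) {
  err <- numeric(length(y))
  for (f in unique(foldid)) {
    tr <- foldid != f
    m <- suppressWarnings(
      fitElasticNet(X[tr, , drop = FALSE], alpha, rho, y = y[tr],
                    tol = tol, maxIter = maxIter,
                    wStart = if (!is.null(warm)) warm[[as.character(f)]]))
    if (!is.null(warm)) warm[[as.character(f)]] <- m@convergence$w_std
    err[!tr] <- y[!tr] - predict(m, X[!tr, , drop = FALSE])
  }
  mean(err^2)
}

# TPE-style proposal: model the alpha/rho distribution of the best gamma
# fraction of evaluated configurations (l) and of the rest (g); propose the
# candidate maximizing l/g. Falls back to a random draw while the trace is
# shorter than nInit.
tpePropose <- function(trace, alphaGrid, rhoRange, nInit = 10L,
                       gamma = 0.25, nCand = 24L) {
  randomDraw <- function()
    list(alpha = sample(alphaGrid, 1L),
         rho = runif(1, rhoRange[1], rhoRange[2]))
  if (rhoRange[1] == rhoRange[2])
    return(list(alpha = sample(alphaGrid, 1L), rho = rhoRange[1]))
  t <- nrow(trace)
  if (t < nInit) return(randomDraw())
  ord <- order(trace$loss)
  nGood <- max(1L, ceiling(gamma * t))
  good <- trace[ord[seq_len(nGood)], , drop = FALSE]
  bad <- trace[ord[-seq_len(nGood)], , drop = FALSE]
  if (nrow(bad) == 0L) return(randomDraw())
  aProb <- function(df) {
    p <- tabulate(match(df$alpha, alphaGrid), length(alphaGrid)) + 1
    p / sum(p)
  }
  bw <- max(0.05, diff(rhoRange) / 5 / sqrt(nGood))
  rDens <- function(df, r)
    vapply(r, function(ri) mean(dnorm(ri, df$rho, bw)) + 1e-12, numeric(1))
  pg <- aProb(good); pb <- aProb(bad)
  ca <- sample(alphaGrid, nCand, replace = TRUE, prob = pg)
  cr <- rnorm(nCand, sample(good$rho, nCand, replace = TRUE), bw)
  cr <- pmin(pmax(cr, rhoRange[1]), rhoRange[2])
  score <- log(pg[match(ca, alphaGrid)]) + log(rDens(good, cr)) -
    log(pb[match(ca, alphaGrid)]) - log(rDens(bad, cr))
  best <- which.max(score)
  list(alpha = ca[best], rho = cr[best])
}

#' Tune elastic-net hyperparameters by sequential model-based optimization
#'
#' Explores at most \code{space$budget} (alpha, rho) configurations with a
#' TPE-style sequential optimizer and returns the configuration minimizing
#' the inner k-fold cross-validated mean squared error on the training
#' donors. The full evaluation trace is returned; the selected loss is the
#' minimum of the trace by construction. Deterministic under \code{seed}.
#'
#' @inheritParams fitElasticNet
#' @param space a [searchSpace()].
#' @param seed integer master seed for fold assignment and the optimizer.
#' @param rhoFixed optional fixed L1 fraction (used by the lasso baseline).
#' @return list with \code{alpha}, \code{rho}, \code{loss}, \code{trace}
#'   (data.frame of every evaluated configuration), \code{foldid},
#'   \code{seed}.
#' @export
tuneHyperparameters <- function(features, space = searchSpace(), seed = 1L,
                                y = NULL, columns = NULL, rhoFixed = NULL,
                                tol = 1e-6, maxIter = 100000L) {
  xy <- asXy(features, y)
  X <- xy$X
  if (!is.null(columns)) X <- X[, columns, drop = FALSE]
  yv <- xy$y
  if (length(unique(yv)) < 2L)
    polyenStop("polyenSchemaError",
               "donor ages are constant; the regression target is degenerate")
  folds <- min(space$folds, nrow(X))
  foldid <- cvFoldIds(nrow(X), folds, deriveSeed(seed, 1L))
  rhoRange <- if (is.null(rhoFixed)) space$rhoRange else rep(rhoFixed, 2L)
  trace <- data.frame(alpha = numeric(), rho = numeric(), loss = numeric())
  # inner CV fits may use a looser solver tolerance: the tuning loss only
  # ranks configurations, and warm starts across trials keep it stable
  cvTol <- max(tol, 1e-4)
  cvMaxIter <- min(maxIter, 2000L)
  warm <- new.env(parent = emptyenv())
  withSeed(deriveSeed(seed, 2L), {
    for (i in seq_len(space$budget)) {
      prop <- tpePropose(trace, space$alphaGrid, rhoRange)
      loss <- cvLoss(X, yv, prop$alpha, prop$rho, foldid, cvTol, cvMaxIter,
                     warm = warm)
      trace[i, ] <- c(prop$alpha, prop$rho, loss)
    }
  })
  best <- which.min(trace$loss)
  list(alpha = trace$alpha[best], rho = trace$rho[best],
       loss = trace$loss[best], trace = trace, foldid = foldid,
       seed = as.integer(seed))
}

#' Train an age-prediction model (tuned)
#'
#' \code{polyen}: elastic net on the full polynomial feature matrix, (alpha,
#' rho) tuned. \code{baseline_lasso}: L1-penalized linear regression (rho
#' fixed at 1) on the mean1 columns only, alpha tuned over the same space.
#' \code{baseline_en}: elastic net on the mean1 columns only (no variances,
#' no second-degree features), alpha and rho tuned.
#'
#' @param features a \linkS4class{DonorFeatureMatrix}.
#' @param kind one of "polyen", "baseline_lasso", "baseline_en".
#' @param space a [searchSpace()].
#' @param seed integer seed for the tuner.
#' @param tol,maxIter solver controls.
#' @return an \linkS4class{ElasticNetModel} with the tuning record attached.
#' @export
trainModel <- function(features, kind = c("polyen", "baseline_lasso",
                                          "baseline_en"),
                       space = searchSpace(), seed = 1L,
                       tol = 1e-6, maxIter = 100000L) {
  kind <- match.arg(kind)
  stopifnot(is(features, "DonorFeatureMatrix"))
  columns <- if (kind == "polyen") NULL else
    which(features@columnMeta$kind %in% c("mean1", "meta_pc"))
  rhoFixed <- if (kind == "baseline_lasso") 1.0 else NULL
  tuned <- tuneHyperparameters(features, space = space, seed = seed,
                               columns = columns, rhoFixed = rhoFixed,
                               tol = tol, maxIter = maxIter)
  model <- fitElasticNet(features, tuned$alpha, tuned$rho,
                         columns = columns, tol = tol, maxIter = maxIter)
  model@tuning <- c(tuned[c("alpha", "rho", "loss", "trace", "seed")],
                    list(kind = kind))
  model
}

#' @rdname trainModel
#' @export
fitBaselineLasso <- function(features, space = searchSpace(), seed = 1L, ...)
  trainModel(features, kind = "baseline_lasso", space = space, seed = seed, ...)

#' @rdname trainModel
#' @export
fitBaselineEN <- function(features, space = searchSpace(), seed = 1L, ...)
  trainModel(features, kind = "baseline_en", space = space, seed = seed, ...)

#' Serialize a fitted model to JSON
#'
#' @param model an \linkS4class{ElasticNetModel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeModel <- function(model, path) {
  obj <- list(weights = as.list(model@weights), intercept = model@intercept,
              alpha = model@alpha, rho = model@rho,
              center = as.list(model@center), scale = as.list(model@scale),
              convergence = model@convergence[c("iterations", "converged",
                                                "final_objective",
                                                "kkt_violation")],
              tuning = if (length(model@tuning))
                list(kind = model@tuning$kind, seed = model@tuning$seed,
                     loss = model@tuning$loss) else NULL,
              version = as.character(packageVersion("polyen")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a model written by [writeModel()]
#'
#' Restores what prediction needs (weights, intercept, hyperparameters,
#' standardization statistics); the solver trace is not round-tripped.
#'
#' @param path JSON file.
#' @return an \linkS4class{ElasticNetModel}.
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ElasticNetModel",
      weights = unlist(obj$weights), intercept = obj$intercept,
      alpha = obj$alpha, rho = obj$rho,
      center = unlist(obj$center), scale = unlist(obj$scale),
      convergence = list(), tuning = list())
}
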