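#' @include evaluation.R
NULL

#' Exact SHAP attributions for a linear age model
#'
#' For a linear model the interventional Shapley value of feature j for
#' donor d has the closed form \eqn{w_j (x_{dj} - \bar x_j^{ref})}, where
#' the reference mean is taken over a set of reference examples (default:
#' the donors in \code{features} themselves). The baseline is the expected
#' prediction over the reference set, and local accuracy holds exactly:
#' baseline + row-sum of attributions = prediction.
#'
#' @param model a fitted \linkS4class{ElasticNetModel}.
#' @param features a \linkS4class{DonorFeatureMatrix} (or matrix) to
#'   attribute.
#' @param reference reference examples (same type); default \code{features}.
#' @return list with \code{shap} (donors x features matrix) and
#'   \code{baseline} (numeric(1)).
#' @export
computeShap <- function(model, features, reference = NULL) {
  X <- if (is(features, "DonorFeatureMatrix")) features@X
       else as.matrix(features)
  want <- names(model@weights)
  miss <- setdiff(want, colnames(X))
  if (length(miss))
    polyenStop("polyenSchemaError",
               "features lack model columns: %s",
               paste(head(miss, 5), collapse = ", "))
  X <- X[, want, drop = FALSE]
  R <- if (is.null(reference)) X else {
    R0 <- if (is(reference, "DonorFeatureMatrix")) reference@X
          else as.matrix(reference)
    R0[, want, drop = FALSE]
  }
  refMean <- colMeans(R)
  shap <- sweep(X, 2, refMean) *
    matrix(model@weights, nrow(X), ncol(X), byrow = TRUE)
  dimnames(shap) <- dimnames(X)
  baseline <- model@intercept + sum(model@weights * refMean)
  list(shap = shap, baseline = baseline)
}

#' Aggregate SHAP attributions to per-gene scores
#'
#' score(g) = sum over g's feature kinds of the mean over donors of the
#' absolute attribution. Non-negative; zero only when all of a gene's
#' columns have zero attribution everywhere.
#'
#' @param shap donors x features attribution matrix (columns named
#'   "source|kind").
#' @param columnMeta \code{DataFrame} mapping columns to \code{source} and
#'   \code{kind} (from the feature matrix).
#' @return named numeric of per-source scores, with attributes
#'   \code{geneSpace} (FALSE when the sources are principal components) and
#'   \code{kindScores} (sources x kinds matrix of mean absolute
#'   attributions).
#' @export
aggregateGeneScores <- function(shap, columnMeta) {
  stopifnot(ncol(shap) == nrow(columnMeta))
  src <- as.character(columnMeta$source)
  kind <- as.character(columnMeta$kind)
  colMean <- colMeans(abs(shap))
  scores <- tapply(colMean, factor(src, levels = unique(src)), sum)
  scores <- setNames(as.numeric(scores), unique(src))
  kinds <- unique(kind)
  km <- matrix(0, length(scores), length(kinds),
               dimnames = list(names(scores), kinds))
  for (j in seq_along(colMean)) km[src[j], kind[j]] <- colMean[j]
  attr(scores, "geneSpace") <- all(kind %in% c("mean1", "var1",
                                               "mean2", "var2"))
  attr(scores, "kindScores") <- km
  scores
}

# add-one empirical p-values from a nullScores matrix (permutations x genes)
empiricalPValues <- function(observed, nullScores) {
  stopifnot(ncol(nullScores) == length(observed))
  ge <- sweep(nullScores, 2, observed, ">=")
  (1 + colSums(ge)) / (nrow(nullScores) + 1)
}

#' Permutation-based empirical gene p-values
#'
#' For each of \code{nPerm} permutations, donor ages are shuffled and the
#' full pipeline re-run on the intact feature matrix: hyperparameters
#' re-tuned, the model re-fit, SHAP attributions computed and aggregated to
#' gene scores. The p-value of gene g is
#' (1 + #\{null score >= observed score\}) / (nPerm + 1), so p lies in
#' (0, 1] and is never exactly zero.
#'
#' @param features the training \linkS4class{DonorFeatureMatrix}.
#' @param observed named numeric of observed gene scores (from
#'   [aggregateGeneScores()]).
#' @param nPerm number of permutations (>= 1).
#' @param seed master seed; permutation b uses a derived seed.
#' @param kind model kind (see [trainModel()]).
#' @param space a [searchSpace()].
#' @param tol,maxIter solver controls.
#' @return named numeric p-values, with the null score matrix attached as
#'   attribute \code{nullScores}.
#' @export
permutationPvalues <- function(features, observed, nPerm = 200L, seed = 1L,
                               kind = "polyen", space = searchSpace(),
                               tol = 1e-6, maxIter = 100000L) {
  if (nPerm < 1L)
    polyenStop("polyenSchemaError", "nPerm must be >= 1")
  nullScores <- matrix(NA_real_, nPerm, length(observed),
                       dimnames = list(NULL, names(observed)))
  for (b in seq_len(nPerm)) {
    bSeed <- deriveSeed(seed, 1000L + b)
    perm <- withSeed(bSeed, sample(length(features@y)))
    fmB <- features
    fmB@y <- features@y[perm]
    model <- trainModel(fmB, kind = kind, space = space,
                        seed = deriveSeed(bSeed, 1L),
                        tol = tol, maxIter = maxIter)
    sh <- computeShap(model, fmB)
    sc <- aggregateGeneScores(sh$shap, fmB@columnMeta[
      match(colnames(sh$shap), colnames(fmB@X)), , drop = FALSE])
    nullScores[b, ] <- sc[names(observed)]
  }
  p <- empiricalPValues(as.numeric(observed), nullScores)
  names(p) <- names(observed)
  attr(p, "nullScores") <- nullScores
  p
}

#' Full importance report for a fitted model
#'
#' Combines exact linear SHAP attributions, per-gene aggregated scores and
#' ranks, per-kind attributions, and (optionally) permutation p-values.
#'
#' @inheritParams computeShap
#' @param nPerm permutations for empirical p-values (0 = skip).
#' @param seed master seed for the permutations.
#' @param space a [searchSpace()] used when re-tuning inside permutations.
#' @return an \linkS4class{ImportanceReport}.
#' @export
importanceReport <- function(model, features, reference = NULL, nPerm = 0L,
                             seed = 1L, space = searchSpace()) {
  stopifnot(is(features, "DonorFeatureMatrix"))
  sh <- computeShap(model, features, reference)
  cm <- features@columnMeta[match(colnames(sh$shap), colnames(features@X)), ,
                            drop = FALSE]
  scores <- aggregateGeneScores(sh$shap, cm)
  kindScores <- attr(scores, "kindScores")
  pv <- numeric(0)
  if (nPerm > 0L) {
    kind <- if (length(model@tuning)) model@tuning$kind else "polyen"
    pv <- permutationPvalues(features, scores, nPerm = nPerm, seed = seed,
                             kind = kind, space = space)
    attr(pv, "nullScores") <- NULL
  }
  sc <- as.numeric(scores)
  names(sc) <- names(scores)
  ranks <- setNames(as.integer(rank(-sc, ties.method = "first")), names(sc))
  new("ImportanceReport", shap = sh$shap, baseline = sh$baseline,
      geneScores = sc, kindScores = kindScores,
      pValues = as.numeric(pv) |> setNames(names(pv)),
      nPermutations = as.integer(nPerm), ranks = ranks)
}

#' Export gene scores as a pre-ranked GSEA file
#'
#' Writes a two-column tab-separated \code{.rnk} file (gene, score) sorted
#' by decreasing score, consumable by standard pre-ranked GSEA tools.
#' Only gene-space scores can be exported; PC-space scores are refused.
#'
#' @param scores named numeric gene scores (e.g. from
#'   [aggregateGeneScores()] or \code{geneScores(report)}).
#' @param path output file (conventionally ending in \code{.rnk}).
#' @return \code{path}, invisibly.
#' @export
exportPreranked <- function(scores, path) {
  gs <- attr(scores, "geneSpace")
  if (!is.null(gs) && !gs)
    polyenStop("polyenSchemaError",
               paste("scores are in PC space; rerun the pipeline with",
                     "gene-space featurization to export a .rnk file"))
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    polyenStop("polyenSchemaError", "scores must be named by gene symbol")
  if (anyDuplicated(names(scores)))
    polyenStop("polyenSchemaError", "duplicate gene symbols: %s",
               paste(unique(names(scores)[duplicated(names(scores))]),
                     collapse = ", "))
  ord <- order(-as.numeric(scores))
  df <- data.frame(gene = names(scores)[ord],
                   score = as.numeric(scores)[ord])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a .rnk file
#'
#' @param path a two-column tab-separated pre-ranked file.
#' @return named numeric scores in file order.
#' @export
readPreranked <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}
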