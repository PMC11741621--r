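#' @include AllClasses.R AllGenerics.R
NULL

#' Accessors for CellCohort
#'
#' @param x a \linkS4class{CellCohort}.
#' @return \code{donorData}: the donor annotation \code{DataFrame};
#'   \code{donorIds}: donor identifiers; \code{donorAges}: named numeric ages
#'   in years; \code{cellDonors} / \code{cellTypeLabels}: per-cell vectors;
#'   \code{geneIds}: gene symbols; \code{isNormalized}: logical flag.
#' @name CellCohort-accessors
NULL

#' @rdname CellCohort-accessors
#' @export
setMethod("donorData", "CellCohort", function(x) x@donorData)

#' @rdname CellCohort-accessors
#' @export
setMethod("donorIds", "CellCohort", function(x) rownames(x@donorData))

#' @rdname CellCohort-accessors
#' @export
setMethod("donorAges", "CellCohort", function(x)
  setNames(x@donorData$age, rownames(x@donorData)))

#' @rdname CellCohort-accessors
#' @export
setMethod("cellDonors", "CellCohort", function(x)
  as.character(colData(x)$donor))

#' @rdname CellCohort-accessors
#' @export
setMethod("cellTypeLabels", "CellCohort", function(x)
  as.character(colData(x)$cell_type))

#' @rdname CellCohort-accessors
#' @export
setMethod("geneIds", "CellCohort", function(x) rownames(x))

#' @rdname CellCohort-accessors
#' @export
setMethod("isNormalized", "CellCohort", function(x) x@normalized)

setMethod("show", "CellCohort", function(object) {
  cat(sprintf("CellCohort: %d genes x %d cells, %d donors (%s)\n",
              nrow(object), ncol(object), nrow(object@donorData),
              if (object@normalized) "log-normalized" else "raw counts"))
  ct <- table(cellTypeLabels(object))
  cat("  cell types:", paste(sprintf("%s (%d)", names(ct), ct),
                             collapse = ", "), "\n")
  ages <- donorAges(object)
  cat(sprintf("  donor ages: %.1f - %.1f years\n", min(ages), max(ages)))
})

#' Accessors for DonorFeatureMatrix
#'
#' @param x a \linkS4class{DonorFeatureMatrix}.
#' @return \code{featureMatrix}: the donors x features matrix;
#'   \code{donorAgesOf}: the age vector y; \code{columnMeta}: per-column
#'   source/kind \code{DataFrame}.
#' @name DonorFeatureMatrix-accessors
NULL

#' @rdname DonorFeatureMatrix-accessors
#' @export
setMethod("featureMatrix", "DonorFeatureMatrix", function(x) x@X)

#' @rdname DonorFeatureMatrix-accessors
#' @export
setMethod("donorAgesOf", "DonorFeatureMatrix", function(x) x@y)

#' @rdname DonorFeatureMatrix-accessors
#' @export
setMethod("columnMeta", "DonorFeatureMatrix", function(x) x@columnMeta)

#' @rdname DonorFeatureMatrix-accessors
#' @export
setMethod("dim", "DonorFeatureMatrix", function(x) dim(x@X))

#' Subset a feature matrix by donors (rows) and/or columns
#'
#' @param x a \linkS4class{DonorFeatureMatrix}.
#' @param i donor (row) index.
#' @param j column index.
#' @param ... ignored.
#' @param drop ignored; the class is always preserved.
#' @export
setMethod("[", "DonorFeatureMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@X))
  if (missing(j)) j <- seq_len(ncol(x@X))
  initialize(x,
    X = x@X[i, j, drop = FALSE],
    y = x@y[i],
    columnMeta = x@columnMeta[j, , drop = FALSE],
    nCells = x@nCells[rownames(x@X)[i]])
})

setMethod("show", "DonorFeatureMatrix", function(object) {
  kinds <- table(object@columnMeta$kind)
  cat(sprintf("DonorFeatureMatrix: %d donors x %d features%s\n",
              nrow(object@X), ncol(object@X),
              if (nzchar(object@cellType))
                sprintf(" [cell type: %s]", object@cellType) else ""))
  cat("  kinds:", paste(sprintf("%s (%d)", names(kinds), kinds),
                        collapse = ", "), "\n")
  if (length(object@dropped))
    cat("  dropped donors:", paste(object@dropped, collapse = ", "), "\n")
})

setMethod("show", "ElasticNetModel", function(object) {
  nz <- sum(object@weights != 0)
  cat(sprintf("ElasticNetModel: alpha = %g, rho = %g; %d/%d nonzero weights\n",
              object@alpha, object@rho, nz, length(object@weights)))
  cv <- object@convergence
  if (length(cv))
    cat(sprintf("  converged: %s after %d sweeps (KKT violation %.2e)\n",
                cv$converged, cv$iterations, cv$kkt_violation))
  if (length(object@tuning))
    cat(sprintf("  tuned over %d evaluations (best CV MSE %.4g)\n",
                nrow(object@tuning$trace), object@tuning$loss))
})

#' Accessors for AgeEvaluation
#'
#' @param x an \linkS4class{AgeEvaluation}.
#' @return \code{meanR2}/\code{sdR2}: mean and standard deviation of the
#'   per-run R-squared; \code{r2PerRun}: the per-run values;
#'   \code{predictions}: long \code{DataFrame} of per-donor predictions.
#' @name AgeEvaluation-accessors
NULL

#' @rdname AgeEvaluation-accessors
#' @export
setMethod("meanR2", "AgeEvaluation", function(x) mean(x@r2PerRun))

#' @rdname AgeEvaluation-accessors
#' @export
setMethod("sdR2", "AgeEvaluation", function(x)
  if (length(x@r2PerRun) > 1L) sd(x@r2PerRun) else 0)

#' @rdname AgeEvaluation-accessors
#' @export
setMethod("r2PerRun", "AgeEvaluation", function(x) x@r2PerRun)

#' @rdname AgeEvaluation-accessors
#' @export
setMethod("predictions", "AgeEvaluation", function(x) x@predictions)

setMethod("show", "AgeEvaluation", function(object) {
  cat(sprintf("%s evaluation: %d runs, mean R^2 = %.3f (SD %.3f)\n",
              object@scheme, object@nRuns, meanR2(object), sdR2(object)))
  pl <- object@pipeline
  cat(sprintf("  pipeline: model = %s, cell type = %s, features = %s\n",
              pl$model %||% "polyen", pl$cellType %||% "(all cells)",
              pl$features %||% "gene-space"))
})

#' Accessors for ImportanceReport
#'
#' @param x an \linkS4class{ImportanceReport}.
#' @return \code{shapValues}: donors x features attribution matrix;
#'   \code{geneScores}: aggregated per-source importance;
#'   \code{genePValues}: empirical permutation p-values (may be empty).
#' @name ImportanceReport-accessors
NULL

#' @rdname ImportanceReport-accessors
#' @export
setMethod("shapValues", "ImportanceReport", function(x) x@shap)

#' @rdname ImportanceReport-accessors
#' @export
setMethod("geneScores", "ImportanceReport", function(x) x@geneScores)

#' @rdname ImportanceReport-accessors
#' @export
setMethod("genePValues", "ImportanceReport", function(x) x@pValues)

setMethod("show", "ImportanceReport", function(object) {
  cat(sprintf("ImportanceReport: %d donors x %d features, %d sources\n",
              nrow(object@shap), ncol(object@shap),
              length(object@geneScores)))
  top <- head(names(sort(object@geneScores, decreasing = TRUE)), 5)
  cat("  top sources:", paste(top, collapse = ", "), "\n")
  if (length(object@pValues))
    cat(sprintf("  empirical p-values from %d permutations\n",
                object@nPermutations))
})

#' Accessors for GeneSet
#'
#' @param x a \linkS4class{GeneSet}.
#' @name GeneSet-accessors
NULL

#' @rdname GeneSet-accessors
#' @export
setMethod("setName", "GeneSet", function(x) x@name)

#' @rdname GeneSet-accessors
#' @export
setMethod("members", "GeneSet", function(x) x@members)

#' @rdname GeneSet-accessors
#' @export
setMethod("length", "GeneSet", function(x) length(x@members))

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s': %d genes\n", object@name,
              length(object@members)))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec '%s': %d donors (ages %g-%g), %d genes, noise = %s\n",
    object@scenario, object@nDonors, object@ageRange[1], object@ageRange[2],
    object@nGenes, object@noise))
  cat("  cell types:",
      paste(sprintf("%s (%g cells/donor)", names(object@cellTypes),
                    object@cellTypes), collapse = ", "), "\n")
  cat(sprintf("  signal genes: %d\n", nrow(object@signal)))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth (%s, seed %d): %s\n", object@scenario,
              object@seed,
              paste(sprintf("%s: %d signal genes", names(object@signalGenes),
                            lengths(object@signalGenes)), collapse = "; ")))
})
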