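#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importFrom SummarizedExperiment assay colData rowData
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

#' Cell-level expression cohort with donor annotations
#'
#' A \linkS4class{SingleCellExperiment} carrying one expression assay
#' (genes x cells), per-cell annotations (\code{donor}, \code{cell_type} in
#' \code{colData}), and a per-donor annotation table (\code{age} in years,
#' \code{group}, \code{study}). The \code{normalized} slot records whether the
#' assay holds log-normalized expression (\code{log1p} of size-factor-scaled
#' counts) or raw counts.
#'
#' @slot donorData \code{DataFrame} keyed by donor identifier with columns
#'   \code{age} (years, finite and positive), \code{group}, \code{study}.
#' @slot normalized logical(1); if \code{TRUE} the assay is log-normalized.
#' @seealso [CellCohort()], [logNormalize()], [readExpression()]
#' @export
setClass("CellCohort",
  contains = "SingleCellExperiment",
  slots = c(donorData = "DataFrame", normalized = "logical"))

setValidity("CellCohort", function(object) {
  msgs <- character()
  cd <- colData(object)
  for (col in c("donor", "cell_type"))
    if (!col %in% colnames(cd))
      msgs <- c(msgs, sprintf("colData lacks required column '%s'", col))
  if (length(object@normalized) != 1L || is.na(object@normalized))
    msgs <- c(msgs, "'normalized' must be TRUE or FALSE")
  g <- rownames(object)
  if (is.null(g) || anyDuplicated(g))
    msgs <- c(msgs, "gene identifiers (rownames) must be present and unique")
  dd <- object@donorData
  if (!"age" %in% colnames(dd)) {
    msgs <- c(msgs, "donorData lacks required column 'age'")
  } else {
    age <- dd$age
    if (!is.numeric(age) || any(!is.finite(age)) || any(age <= 0))
      msgs <- c(msgs, "donor ages must be finite and > 0")
  }
  if ("donor" %in% colnames(cd)) {
    unknown <- setdiff(unique(as.character(cd$donor)), rownames(dd))
    if (length(unknown))
      msgs <- c(msgs, sprintf("cells reference donors absent from donorData: %s",
                              paste(unknown, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Donor-by-feature polynomial matrix
#'
#' Rows are donors, columns polynomial features. In gene space the columns are
#' ordered all means, all variances, all squared means, all squared variances
#' (sources in panel order), so a panel of n genes yields exactly 4n columns.
#' \code{columnMeta} records each column's source (gene symbol or PC) and kind
#' (\code{mean1}, \code{var1}, \code{mean2}, \code{var2}, or \code{meta_pc}
#' for meta-regressor principal components).
#'
#' @slot X numeric matrix, donors x features; rownames are donor identifiers.
#' @slot y numeric donor ages (years), aligned with rows of \code{X}.
#' @slot columnMeta \code{DataFrame} with columns \code{source}, \code{kind}.
#' @slot cellType character(1) label ("" for pseudo-bulk / meta features).
#' @slot nCells named integer, cells contributing per retained donor.
#' @slot dropped character, donors removed by the minimum-cell filter.
#' @slot transform list; for PCA-space features the fitted projection
#'   (\code{rotation}, \code{center}, \code{genes}) reused on held-out cells.
#' @export
setClass("DonorFeatureMatrix",
  slots = c(X = "matrix", y = "numeric", columnMeta = "DataFrame",
            cellType = "character", nCells = "integer",
            dropped = "character", transform = "list"))

setValidity("DonorFeatureMatrix", function(object) {
  msgs <- character()
  X <- object@X
  if (nrow(X) != length(object@y))
    msgs <- c(msgs, "nrow(X) must equal length(y)")
  if (is.null(rownames(X)))
    msgs <- c(msgs, "X must carry donor identifiers as rownames")
  cm <- object@columnMeta
  if (ncol(X) != nrow(cm))
    msgs <- c(msgs, "columnMeta must describe every column of X")
  if (!all(c("source", "kind") %in% colnames(cm)))
    return(c(msgs, "columnMeta needs columns 'source' and 'kind'"))
  kinds <- c("mean1", "var1", "mean2", "var2")
  if (all(cm$kind %in% kinds) && nrow(cm) > 0) {
    src <- unique(cm$source)
    if (ncol(X) != 4L * length(src))
      msgs <- c(msgs, "gene-space feature matrix must have 4 columns per source")
    for (k in c("var1")) {
      v <- X[, cm$kind == "var1", drop = FALSE]
      if (length(v) && min(v) < -1e-10)
        msgs <- c(msgs, "var1 columns must be non-negative")
    }
    i1 <- match(paste0(src, "|mean1"), colnames(X))
    i2 <- match(paste0(src, "|mean2"), colnames(X))
    j1 <- match(paste0(src, "|var1"), colnames(X))
    j2 <- match(paste0(src, "|var2"), colnames(X))
    if (!anyNA(c(i1, i2, j1, j2))) {
      if (max(abs(X[, i2, drop = FALSE] - X[, i1, drop = FALSE]^2), 0) > 1e-8)
        msgs <- c(msgs, "mean2 columns must equal element-wise squared mean1")
      if (max(abs(X[, j2, drop = FALSE] - X[, j1, drop = FALSE]^2), 0) > 1e-8)
        msgs <- c(msgs, "var2 columns must equal element-wise squared var1")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Fitted elastic-net age regressor
#'
#' Minimizer of \deqn{\frac{1}{2n}\|Xw-y\|_2^2 + \alpha\rho\|w\|_1 +
#' \frac{\alpha(1-\rho)}{2}\|w\|_2^2}{(1/2n)||Xw-y||^2 + alpha*rho*||w||_1 +
#' alpha*(1-rho)/2*||w||_2^2} with an unpenalized intercept. Weights are
#' stored in the original (unstandardized) feature coordinates; the
#' standardization statistics used at fit time live in \code{center} and
#' \code{scale}. \code{convergence} keeps the per-sweep objective trace, the
#' iteration count and the final KKT violation of the coordinate-descent
#' solver.
#'
#' @slot weights named numeric coefficient vector (original coordinates).
#' @slot intercept numeric(1).
#' @slot alpha,rho numeric(1) penalty strength and L1 fraction.
#' @slot center,scale named numeric standardization statistics.
#' @slot convergence list: \code{iterations}, \code{converged},
#'   \code{objective_trace}, \code{final_objective}, \code{kkt_violation},
#'   \code{max_delta}, \code{tol}.
#' @slot tuning list; hyperparameter-search record when the model was tuned.
#' @export
setClass("ElasticNetModel",
  slots = c(weights = "numeric", intercept = "numeric",
            alpha = "numeric", rho = "numeric",
            center = "numeric", scale = "numeric",
            convergence = "list", tuning = "list"))

setValidity("ElasticNetModel", function(object) {
  msgs <- character()
  if (is.null(names(object@weights)))
    msgs <- c(msgs, "weights must be named by feature column")
  if (length(object@alpha) != 1L || object@alpha < 0)
    msgs <- c(msgs, "alpha must be a single value >= 0")
  if (length(object@rho) != 1L || object@rho < 0 || object@rho > 1)
    msgs <- c(msgs, "rho must lie in [0, 1]")
  if (length(object@weights) != length(object@center) ||
      length(object@weights) != length(object@scale))
    msgs <- c(msgs, "center/scale must match weights in length")
  if (length(msgs)) msgs else TRUE
})

#' Evaluation result for an age-prediction pipeline
#'
#' @slot scheme "LOO" (leave-one-out) or "CD" (cross-dataset).
#' @slot predictions \code{DataFrame} with columns \code{run}, \code{donor},
#'   \code{age}, \code{predicted}; each donor appears exactly once per run.
#' @slot r2PerRun numeric R-squared per repeated run.
#' @slot pipeline list describing the configuration (cell type, gene set,
#'   PCA setting, model kind).
#' @slot nRuns integer(1).
#' @slot details list; per-run fold metadata (held-out donor, training donors,
#'   selected hyperparameters) and donors dropped by the cell-count filter.
#' @export
setClass("AgeEvaluation",
  slots = c(scheme = "character", predictions = "DataFrame",
            r2PerRun = "numeric", pipeline = "list",
            nRuns = "integer", details = "list"))

setValidity("AgeEvaluation", function(object) {
  msgs <- character()
  if (!object@scheme %in% c("LOO", "CD"))
    msgs <- c(msgs, "scheme must be 'LOO' or 'CD'")
  if (length(object@r2PerRun) != object@nRuns)
    msgs <- c(msgs, "r2PerRun must have one entry per run")
  pr <- object@predictions
  if (nrow(pr)) {
    per <- table(pr$run, pr$donor)
    if (any(per > 1))
      msgs <- c(msgs, "each donor must be predicted exactly once per run")
  }
  if (length(msgs)) msgs else TRUE
})

#' SHAP-based feature importance report
#'
#' Exact linear Shapley attributions (interventional, feature-independent
#' closed form) for a fitted \linkS4class{ElasticNetModel}: attribution of
#' feature j for donor d is \eqn{w_j (x_{dj} - \bar x_j^{ref})}. Gene scores
#' aggregate a gene's four polynomial columns as the sum of mean absolute
#' attributions; per-kind means are kept in \code{kindScores} to compare
#' first- versus second-order contributions.
#'
#' @slot shap donors x features attribution matrix.
#' @slot baseline numeric(1), expected model output over the reference set;
#'   baseline + rowSums(shap) reproduces each donor's prediction.
#' @slot geneScores named numeric aggregated importance per source.
#' @slot kindScores sources x kinds matrix of mean absolute attributions.
#' @slot pValues named numeric empirical permutation p-values in (0, 1]
#'   (length 0 when permutations were not run).
#' @slot nPermutations integer(1).
#' @slot ranks named integer, 1 = most important source.
#' @export
setClass("ImportanceReport",
  slots = c(shap = "matrix", baseline = "numeric",
            geneScores = "numeric", kindScores = "matrix",
            pValues = "numeric", nPermutations = "integer",
            ranks = "integer"))

setValidity("ImportanceReport", function(object) {
  msgs <- character()
  if (length(object@pValues) &&
      (any(object@pValues <= 0) || any(object@pValues > 1)))
    msgs <- c(msgs, "p-values must lie in (0, 1]")
  if (length(object@ranks) &&
      !identical(sort(unname(object@ranks)), seq_along(object@ranks)))
    msgs <- c(msgs, "ranks must be a permutation of 1..n sources")
  if (length(msgs)) msgs else TRUE
})

#' Named gene set
#'
#' @slot name character(1), e.g. "Fridman", "SenMayo", "Union".
#' @slot members unique, non-empty character vector of gene symbols.
#' @export
setClass("GeneSet", slots = c(name = "character", members = "character"))

setValidity("GeneSet", function(object) {
  msgs <- character()
  if (length(object@members) == 0L)
    msgs <- c(msgs, sprintf("gene set '%s' is empty", object@name))
  if (anyDuplicated(object@members))
    msgs <- c(msgs, sprintf("gene set '%s' has duplicate members", object@name))
  if (length(msgs)) msgs else TRUE
})

#' Specification of a synthetic multi-donor cohort
#'
#' Signal genes follow a polynomial mean trend
#' \eqn{\mu_g(a) = b_0 + b_1 a + b_2 a^2} and a linear cell-level
#' standard-deviation trend \eqn{\sigma_g(a) = c_0 + c_1 a} over donor age a;
#' non-signal genes are age-constant.
#'
#' @slot nDonors integer(1).
#' @slot ageRange numeric(2), years; ages drawn uniformly.
#' @slot cellTypes named numeric, cells per donor for each cell type.
#' @slot cellOverrides named list, donor -> cells per donor (applied to every
#'   cell type), used to plant deliberately under-sampled donors.
#' @slot nGenes integer(1).
#' @slot signal data.frame with columns \code{cell_type}, \code{gene},
#'   \code{b0}, \code{b1}, \code{b2}, \code{c0}, \code{c1}.
#' @slot baselineMu,baselineSigma numeric(2) ranges for age-constant genes.
#' @slot noise "normal" (log-scale values directly) or "nb" (negative-binomial
#'   counts, to be log-normalized downstream).
#' @slot nbSize numeric(1) NB dispersion (counts mode).
#' @slot dropout numeric(1) zero-inflation probability (counts mode only).
#' @slot scenario character(1) tag.
#' @slot seed integer(1).
#' @export
setClass("CohortSpec",
  slots = c(nDonors = "integer", ageRange = "numeric",
            cellTypes = "numeric", cellOverrides = "list",
            nGenes = "integer", signal = "data.frame",
            baselineMu = "numeric", baselineSigma = "numeric",
            noise = "character", nbSize = "numeric", dropout = "numeric",
            scenario = "character", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msgs <- character()
  if (object@nDonors < 2L) msgs <- c(msgs, "need at least 2 donors")
  if (length(object@ageRange) != 2L || diff(object@ageRange) <= 0)
    msgs <- c(msgs, "ageRange must be an increasing pair of years")
  if (is.null(names(object@cellTypes)) || any(object@cellTypes < 1))
    msgs <- c(msgs, "cellTypes must be a named vector of positive cell counts")
  if (!object@noise %in% c("normal", "nb"))
    msgs <- c(msgs, "noise must be 'normal' or 'nb'")
  if (object@dropout < 0 || object@dropout >= 1)
    msgs <- c(msgs, "dropout must lie in [0, 1)")
  if (object@dropout > 0 && object@noise != "nb")
    msgs <- c(msgs, "dropout applies to counts ('nb') mode only")
  sg <- object@signal
  if (nrow(sg)) {
    need <- c("cell_type", "gene", "b0", "b1", "b2", "c0", "c1")
    if (!all(need %in% colnames(sg)))
      return(c(msgs, paste("signal table needs columns",
                           paste(need, collapse = ", "))))
    a <- object@ageRange
    sigLo <- sg$c0 + sg$c1 * a[1]
    sigHi <- sg$c0 + sg$c1 * a[2]
    if (any(pmin(sigLo, sigHi) <= 0))
      msgs <- c(msgs, "sigma(age) must stay positive over the age range")
    if (any(sg$gene > object@nGenes) || any(sg$gene < 1))
      msgs <- c(msgs, "signal gene indices must lie within the gene panel")
  }
  if (any(object@baselineSigma <= 0))
    msgs <- c(msgs, "baseline sigma range must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Ground truth of a generated synthetic cohort
#'
#' @slot signalGenes named list: cell type -> signal gene symbols.
#' @slot coefficients data.frame of the planted trend coefficients.
#' @slot scenario character(1) tag (one of \code{mean_signal},
#'   \code{variance_only}, \code{quadratic}, \code{null}, \code{mixed}).
#' @slot seed integer(1) used for generation.
#' @export
setClass("SyntheticTruth",
  slots = c(signalGenes = "list", coefficients = "data.frame",
            scenario = "character", seed = "integer"))
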