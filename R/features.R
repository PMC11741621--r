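#' @include io.R
NULL

resolveGenes <- function(x, genes) {
  if (is.null(genes)) return(geneIds(x))
  g <- if (is(genes, "GeneSet")) members(genes) else as.character(genes)
  g <- g[g %in% geneIds(x)]           # case-sensitive symbol match
  if (length(g) == 0L)
    polyenStop("polyenIntegrityError",
               "none of the requested genes are present in the dataset")
  g
}

selectCells <- function(x, cellType) {
  if (is.null(cellType)) {
    # pseudo-bulk: every cell, including unannotated ones
    rep(TRUE, ncol(x))
  } else {
    labs <- cellTypeLabels(x)
    if (!cellType %in% labs)
      polyenStop("polyenIntegrityError",
                 "unknown cell type label '%s'", cellType)
    !is.na(labs) & labs == cellType
  }
}

# One-pass donor-level mean/variance of a cells x genes matrix.
# Returns U, V (donors x genes, sample variance with n-1 denominator).
donorMoments <- function(values, donors) {
  if (!is.factor(donors)) donors <- factor(donors, levels = unique(donors))
  donors <- droplevels(donors)
  counts <- as.vector(table(donors))
  sums <- rowsum(values, donors)
  sumsq <- rowsum(values^2, donors)
  U <- sums / counts
  V <- (sumsq - counts * U^2) / (counts - 1)
  V[V < 0] <- 0                       # guard fp cancellation at ~0 variance
  list(U = U, V = V, n = setNames(as.integer(counts), levels(donors)))
}

#' Per-donor expression means and variances
#'
#' Collapses a donor's cells of one cell type into per-gene summary
#' statistics: the mean and the sample variance (n-1 denominator) of
#' log-normalized expression. Donors contributing fewer than \code{minCells}
#' cells of the type are dropped and reported.
#'
#' @param x a normalized \linkS4class{CellCohort}.
#' @param cellType cell-type label, or \code{NULL} to pool all cells
#'   (pseudo-bulk).
#' @param genes \linkS4class{GeneSet}, character vector, or \code{NULL} for
#'   all genes.
#' @param minCells minimum cells per donor (>= 2; default 10).
#' @return list with \code{U}, \code{V} (retained donors x genes),
#'   \code{nCells} (named integer), \code{dropped} (donor ids).
#' @examples
#' cc <- generateCohort(presetScenarios()$strong_mean)$cohort
#' st <- aggregateDonorStats(cc, cellType = "epithelial")
#' dim(st$U)
#' @export
aggregateDonorStats <- function(x, cellType = NULL, genes = NULL,
                                minCells = 10L) {
  stopifnot(is(x, "CellCohort"))
  if (!isNormalized(x))
    polyenStop("polyenStateError",
               "dataset must be log-normalized before aggregation")
  if (minCells < 2L)
    polyenStop("polyenSchemaError",
               "minCells must be >= 2 so variances are defined")
  keep <- selectCells(x, cellType)
  g <- resolveGenes(x, genes)
  donors <- cellDonors(x)[keep]
  values <- base::t(as.matrix(assay(x)[g, keep, drop = FALSE]))  # cells x genes
  tab <- table(donors)
  ok <- names(tab)[tab >= minCells]
  dropped <- setdiff(donorIds(x), ok)
  if (length(ok) == 0L)
    polyenStop("polyenIntegrityError",
               "no donor retains >= %d cells%s", minCells,
               if (is.null(cellType)) "" else sprintf(" of type '%s'", cellType))
  ok <- donorIds(x)[donorIds(x) %in% ok]   # canonical donor order
  sel <- donors %in% ok
  mom <- donorMoments(values[sel, , drop = FALSE],
                      factor(donors[sel], levels = ok))
  list(U = mom$U, V = mom$V, n = mom$n, dropped = dropped)
}

#' Expand donor summary statistics into polynomial features
#'
#' Builds the column-wise concatenated feature matrix
#' \{u_1..u_n, v_1..v_n, u_1^2..u_n^2, v_1^2..v_n^2\}: per-gene donor-level
#' means, variances, and their element-wise squares, in that fixed order.
#'
#' @param U,V donors x sources matrices of means and variances (aligned).
#' @param y donor ages in years, aligned with rows.
#' @param cellType label recorded on the result ("" if unspecific).
#' @param nCells optional named integer of cells per donor.
#' @param dropped optional donor ids removed upstream.
#' @return a \linkS4class{DonorFeatureMatrix} with 4 x ncol(U) columns.
#' @export
polynomialExpand <- function(U, V, y, cellType = "", nCells = integer(),
                             dropped = character()) {
  U <- as.matrix(U); V <- as.matrix(V)
  if (!identical(dim(U), dim(V)))
    polyenStop("polyenSchemaError",
               "mean and variance matrices must have identical shape")
  if (nrow(U) != length(y))
    polyenStop("polyenSchemaError",
               "age vector must align with the donor rows")
  src <- colnames(U)
  if (is.null(src)) src <- paste0("f", seq_len(ncol(U)))
  X <- cbind(U, V, U^2, V^2)
  kinds <- rep(c("mean1", "var1", "mean2", "var2"), each = ncol(U))
  colnames(X) <- paste0(rep(src, 4), "|", kinds)
  if (length(nCells) == 0L)
    nCells <- setNames(rep(NA_integer_, nrow(U)), rownames(U))
  new("DonorFeatureMatrix", X = X, y = as.numeric(y),
      columnMeta = DataFrame(source = rep(src, 4), kind = kinds),
      cellType = cellType, nCells = nCells,
      dropped = as.character(dropped), transform = list())
}

#' Gene-space polynomial features for one cell type
#'
#' Convenience wrapper: [aggregateDonorStats()] followed by
#' [polynomialExpand()], pairing the feature rows with donor ages.
#'
#' @inheritParams aggregateDonorStats
#' @return a \linkS4class{DonorFeatureMatrix} (4 columns per gene).
#' @export
geneFeatures <- function(x, cellType = NULL, genes = NULL, minCells = 10L) {
  st <- aggregateDonorStats(x, cellType = cellType, genes = genes,
                            minCells = minCells)
  ages <- donorAges(x)[rownames(st$U)]
  polynomialExpand(st$U, st$V, ages, cellType = cellType %||% "",
                   nCells = st$n, dropped = st$dropped)
}

#' Pseudo-bulk polynomial features
#'
#' Per-donor mean and variance over all cells regardless of cell type,
#' then polynomial expansion. Cells lacking a cell-type label contribute.
#'
#' @inheritParams aggregateDonorStats
#' @return a \linkS4class{DonorFeatureMatrix}.
#' @export
pseudoBulkFeatures <- function(x, genes = NULL, minCells = 10L) {
  geneFeatures(x, cellType = NULL, genes = genes, minCells = minCells)
}

#' PCA-space polynomial features
#'
#' Projects cell-level expression onto the top-k principal components
#' (fitted on training cells only: genes mean-centered, not scaled), computes
#' per-donor mean/variance of the PC scores, and applies the polynomial
#' expansion, giving 4k columns. The fitted transform is returned on the
#' object so held-out cells are projected with the training loadings.
#'
#' @inheritParams aggregateDonorStats
#' @param k number of principal components (default 10).
#' @param fitDonors donors whose cells fit the PCA (default: all donors).
#'   Feature rows are still produced for every retained donor; cells of
#'   non-fit donors are only projected, never used to fit.
#' @return a \linkS4class{DonorFeatureMatrix} with a \code{transform} slot
#'   (\code{rotation}, \code{center}, \code{genes}).
#' @export
pcaFeatures <- function(x, cellType = NULL, genes = NULL, k = 10L,
                        fitDonors = NULL, minCells = 10L) {
  stopifnot(is(x, "CellCohort"))
  if (!isNormalized(x))
    polyenStop("polyenStateError", "dataset must be log-normalized")
  keep <- selectCells(x, cellType)
  g <- resolveGenes(x, genes)
  if (length(g) < k)
    polyenStop("polyenSchemaError",
               "k = %d exceeds the %d-gene panel", k, length(g))
  values <- base::t(as.matrix(assay(x)[g, keep, drop = FALSE]))  # cells x genes
  donors <- cellDonors(x)[keep]
  if (is.null(fitDonors)) fitDonors <- donorIds(x)
  fit <- donors %in% fitDonors
  if (!any(fit))
    polyenStop("polyenIntegrityError", "no cells available to fit the PCA")
  pc <- prcomp(values[fit, , drop = FALSE], center = TRUE, scale. = FALSE,
               rank. = k)
  if (ncol(pc$rotation) < k || pc$sdev[k] < 1e-12)
    polyenStop("polyenSchemaError",
               "k = %d exceeds the rank of the training expression matrix", k)
  scores <- sweep(values, 2, pc$center) %*% pc$rotation
  tab <- table(donors)
  ok <- donorIds(x)[donorIds(x) %in% names(tab)[tab >= minCells]]
  dropped <- setdiff(donorIds(x), ok)
  if (length(ok) == 0L)
    polyenStop("polyenIntegrityError", "no donor retains >= %d cells", minCells)
  sel <- donors %in% ok
  mom <- donorMoments(scores[sel, , drop = FALSE],
                      factor(donors[sel], levels = ok))
  fm <- polynomialExpand(mom$U, mom$V, donorAges(x)[ok],
                         cellType = cellType %||% "", nCells = mom$n,
                         dropped = dropped)
  fm@transform <- list(rotation = pc$rotation, center = pc$center, genes = g,
                       fitDonors = fitDonors)
  fm
}

#' Project cells of a cohort with a previously fitted PCA transform
#'
#' @param transform the \code{transform} list of a PCA-space
#'   \linkS4class{DonorFeatureMatrix}.
#' @param x a \linkS4class{CellCohort}.
#' @param cellType cell-type label or \code{NULL}.
#' @return cells x k matrix of PC scores.
#' @export
projectCells <- function(transform, x, cellType = NULL) {
  stopifnot(!is.null(transform$rotation))
  keep <- selectCells(x, cellType)
  values <- base::t(as.matrix(assay(x)[transform$genes, keep, drop = FALSE]))
  sweep(values, 2, transform$center) %*% transform$rotation
}

#' Meta-regressor features across cell types
#'
#' Concatenates each donor's per-cell-type polynomial features column-wise
#' across the listed cell types (every gene x cell-type combination is a
#' candidate feature), then projects the donor-level concatenated matrix onto
#' its top-k principal components. The PC scores are fed to the regressor
#' as-is. Donors lacking \code{minCells} cells of any listed type are dropped
#' and reported.
#'
#' @inheritParams aggregateDonorStats
#' @param cellTypes character vector of cell-type labels (>= 1).
#' @param k number of donor-level principal components (default 20).
#' @param fitDonors donors on which the PCA is fitted (default all retained).
#' @return a \linkS4class{DonorFeatureMatrix} with k \code{meta_pc} columns.
#' @export
metaFeatures <- function(x, cellTypes, genes = NULL, k = 20L,
                         fitDonors = NULL, minCells = 10L) {
  stopifnot(length(cellTypes) >= 1L)
  parts <- lapply(cellTypes, function(ct)
    geneFeatures(x, cellType = ct, genes = genes, minCells = minCells))
  ok <- Reduce(intersect, lapply(parts, function(p) rownames(p@X)))
  if (length(ok) == 0L)
    polyenStop("polyenIntegrityError",
               "no donor retains enough cells of every listed cell type")
  ok <- donorIds(x)[donorIds(x) %in% ok]
  dropped <- setdiff(donorIds(x), ok)
  blocks <- lapply(seq_along(parts), function(i) {
    b <- parts[[i]]@X[ok, , drop = FALSE]
    colnames(b) <- paste0(colnames(b), "@", cellTypes[i])
    b
  })
  wide <- do.call(cbind, blocks)
  if (is.null(fitDonors)) fitDonors <- ok
  fitRows <- ok %in% fitDonors
  pc <- prcomp(wide[fitRows, , drop = FALSE], center = TRUE, scale. = FALSE,
               rank. = k)
  keff <- min(k, sum(pc$sdev > 1e-12))
  if (keff < 1L)
    polyenStop("polyenSchemaError", "meta feature matrix has rank 0")
  rot <- pc$rotation[, seq_len(keff), drop = FALSE]
  scores <- sweep(wide, 2, pc$center) %*% rot
  colnames(scores) <- paste0("metaPC", seq_len(keff))
  nc <- Reduce(`+`, lapply(parts, function(p) p@nCells[ok]))
  new("DonorFeatureMatrix", X = scores, y = as.numeric(donorAges(x)[ok]),
      columnMeta = DataFrame(source = colnames(scores),
                             kind = rep("meta_pc", keff)),
      cellType = paste(cellTypes, collapse = "+"),
      nCells = setNames(as.integer(nc), ok),
      dropped = dropped,
      transform = list(rotation = rot, center = pc$center,
                       cellTypes = cellTypes))
}

#' Serialize a feature matrix to CSV plus a metadata sidecar
#'
#' Writes \code{features.csv} (rows = donors, header = "source|kind") and
#' \code{features.json} (ages, cell type, column metadata, cell counts).
#'
#' @param fm a \linkS4class{DonorFeatureMatrix}.
#' @param path output directory (created).
#' @return \code{path}, invisibly.
#' @export
writeFeatureMatrix <- function(fm, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(fm@X), file.path(path, "features.csv"),
            quote = FALSE)
  meta <- list(y = fm@y, donor_ids = rownames(fm@X),
               cell_type = fm@cellType,
               source = as.character(fm@columnMeta$source),
               kind = as.character(fm@columnMeta$kind),
               n_cells = as.list(fm@nCells), dropped = fm@dropped)
  jsonlite::write_json(meta, file.path(path, "features.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a feature matrix written by [writeFeatureMatrix()]
#'
#' @param path directory holding \code{features.csv} and \code{features.json}.
#' @return a \linkS4class{DonorFeatureMatrix}.
#' @export
readFeatureMatrix <- function(path) {
  X <- as.matrix(read.csv(file.path(path, "features.csv"), row.names = 1,
                          check.names = FALSE))
  meta <- jsonlite::read_json(file.path(path, "features.json"),
                              simplifyVector = TRUE)
  nc <- unlist(meta$n_cells)
  new("DonorFeatureMatrix", X = X, y = as.numeric(meta$y),
      columnMeta = DataFrame(source = meta$source, kind = meta$kind),
      cellType = meta$cell_type %||% "",
      nCells = setNames(as.integer(nc), names(nc)),
      dropped = as.character(meta$dropped %||% character()),
      transform = list())
}
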