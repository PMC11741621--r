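#' @include AllClasses.R accessors.R
#' @importFrom Matrix readMM writeMM t
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

#' Construct a cell-level expression cohort
#'
#' @param values expression matrix, cells x genes (rows = cells); dense or
#'   sparse. Stored internally genes x cells per Bioconductor convention.
#' @param cellData data.frame/DataFrame with one row per cell; must contain
#'   \code{donor} and \code{cell_type}. Rownames (or a \code{cell} column)
#'   give cell identifiers.
#' @param donorData data.frame/DataFrame with one row per donor; must contain
#'   \code{age} (years); \code{group} and \code{study} default to "unknown".
#'   Rownames (or a \code{donor} column) give donor identifiers.
#' @param normalized logical(1); \code{TRUE} if \code{values} already holds
#'   log-normalized expression.
#' @return a validated \linkS4class{CellCohort}.
#' @examples
#' m <- matrix(rpois(12, 5), nrow = 3,
#'             dimnames = list(paste0("c", 1:3), paste0("G", 1:4)))
#' cells <- data.frame(donor = c("d1", "d1", "d2"), cell_type = "T cell",
#'                     row.names = rownames(m))
#' donors <- data.frame(age = c(35, 62), row.names = c("d1", "d2"))
#' cc <- CellCohort(m, cells, donors)
#' @export
CellCohort <- function(values, cellData, donorData, normalized = FALSE) {
  cellData <- as.data.frame(cellData)
  donorData <- as.data.frame(donorData)
  if (!is.null(cellData[["cell"]])) {
    rownames(cellData) <- as.character(cellData[["cell"]])
    cellData[["cell"]] <- NULL
  }
  if (!is.null(donorData[["donor"]])) {
    rownames(donorData) <- as.character(donorData[["donor"]])
    donorData[["donor"]] <- NULL
  }
  for (col in c("donor", "cell_type"))
    if (!col %in% colnames(cellData))
      polyenStop("polyenSchemaError",
                 "cell annotation is missing required column '%s'", col)
  if (!"age" %in% colnames(donorData))
    polyenStop("polyenSchemaError",
               "donor annotation is missing required column 'age'")
  if (is.null(donorData$group)) donorData$group <- "unknown"
  if (is.null(donorData$study)) donorData$study <- "unknown"
  unknown <- setdiff(unique(as.character(cellData$donor)), rownames(donorData))
  if (length(unknown))
    polyenStop("polyenIntegrityError",
               "cells reference donors absent from donor annotation: %s",
               paste(unknown, collapse = ", "))
  m <- Matrix::t(methods::as(values, "CsparseMatrix"))
  if (is.null(rownames(m)))
    polyenStop("polyenSchemaError", "expression matrix lacks gene identifiers")
  if (nrow(cellData) != ncol(m))
    polyenStop("polyenSchemaError",
               "cell annotation has %d rows but matrix has %d cells",
               nrow(cellData), ncol(m))
  sce <- SingleCellExperiment(
    assays = setNames(list(m), if (normalized) "logcounts" else "counts"),
    colData = DataFrame(cellData))
  new("CellCohort", sce,
      donorData = DataFrame(donorData), normalized = normalized)
}

#' Expression values of a cohort
#'
#' @param x a \linkS4class{CellCohort}.
#' @param dense return a base dense matrix (default) or keep sparse.
#' @return genes x cells matrix.
#' @export
exprValues <- function(x, dense = TRUE) {
  m <- assay(x, if (x@normalized) "logcounts" else "counts")
  if (dense) as.matrix(m) else m
}

#' Read an expression dataset with annotations
#'
#' Reads a directory holding either a dense CSV (\code{expression.csv}, rows =
#' cells, first column = cell ID, header = gene symbols) or a MatrixMarket
#' triplet (\code{matrix.mtx} genes x cells, \code{features.tsv},
#' \code{barcodes.tsv}), plus annotation tables \code{cells.tsv} (columns
#' \code{cell}, \code{donor}, \code{cell_type}) and \code{donors.tsv}
#' (columns \code{donor}, \code{age}, optional \code{group}, \code{study}).
#'
#' @param path directory containing the files above.
#' @param format "csv" or "mtx_dir".
#' @param normalized logical(1); whether the stored values are already
#'   log-normalized (e.g. an atlas export) or raw counts.
#' @return a \linkS4class{CellCohort}.
#' @seealso [writeExpression()] for the inverse operation.
#' @export
readExpression <- function(path, format = c("csv", "mtx_dir"),
                           normalized = FALSE) {
  format <- match.arg(format)
  if (!dir.exists(path))
    polyenStop("polyenSchemaError", "input directory '%s' does not exist", path)
  readTab <- function(f, what) {
    fp <- file.path(path, f)
    if (!file.exists(fp))
      polyenStop("polyenSchemaError", "missing %s table '%s'", what, f)
    read.table(fp, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               check.names = FALSE)
  }
  cells <- readTab("cells.tsv", "cell annotation")
  donors <- readTab("donors.tsv", "donor annotation")
  for (col in c("cell", "donor", "cell_type"))
    if (!col %in% colnames(cells))
      polyenStop("polyenSchemaError",
                 "cell annotation is missing required column '%s'", col)
  for (col in c("donor", "age"))
    if (!col %in% colnames(donors))
      polyenStop("polyenSchemaError",
                 "donor annotation is missing required column '%s'", col)
  if (format == "csv") {
    fp <- file.path(path, "expression.csv")
    if (!file.exists(fp))
      polyenStop("polyenSchemaError", "missing expression file '%s'", fp)
    df <- read.csv(fp, row.names = 1, check.names = FALSE)
    values <- as.matrix(df)                      # cells x genes
  } else {
    mm <- file.path(path, "matrix.mtx")
    if (!file.exists(mm))
      polyenStop("polyenSchemaError", "missing MatrixMarket file '%s'", mm)
    m <- Matrix::readMM(mm)                      # genes x cells (10x layout)
    feats <- read.table(file.path(path, "features.tsv"), header = FALSE,
                        sep = "\t", stringsAsFactors = FALSE)
    bcs <- read.table(file.path(path, "barcodes.tsv"), header = FALSE,
                      sep = "\t", stringsAsFactors = FALSE)
    rownames(m) <- feats[[1]]
    colnames(m) <- bcs[[1]]
    values <- Matrix::t(m)                       # cells x genes
  }
  rn <- if (format == "csv") rownames(values) else rownames(values)
  cells <- cells[match(rn, cells$cell), , drop = FALSE]
  if (anyNA(cells$cell))
    polyenStop("polyenIntegrityError",
               "cells present in the matrix are absent from cells.tsv")
  CellCohort(values, cells, donors, normalized = normalized)
}

#' Write a cohort in the format understood by [readExpression()]
#'
#' @param x a \linkS4class{CellCohort}.
#' @param path output directory (created).
#' @param format "csv" or "mtx_dir".
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path, format = c("csv", "mtx_dir")) {
  format <- match.arg(format)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fullPrec <- function(df) {      # keep doubles exact across the round trip
    for (j in seq_along(df))
      if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    df
  }
  cd <- as.data.frame(colData(x))
  cells <- fullPrec(cbind(cell = colnames(x), cd))
  write.table(cells, file.path(path, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dd <- as.data.frame(donorData(x))
  donors <- fullPrec(cbind(donor = rownames(dd), dd))
  write.table(donors, file.path(path, "donors.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  m <- assay(x)
  if (format == "csv") {
    dm <- as.matrix(Matrix::t(m))                  # cells x genes
    ch <- matrix(sprintf("%.17g", dm), nrow(dm), ncol(dm),
                 dimnames = dimnames(dm))
    write.csv(as.data.frame(ch), file.path(path, "expression.csv"),
              quote = FALSE)
  } else {
    Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(m), file.path(path, "features.tsv"))
    writeLines(colnames(m), file.path(path, "barcodes.tsv"))
  }
  invisible(path)
}

#' Log-normalize raw counts
#'
#' Scales each cell to a common library size and applies \code{log1p}:
#' value = log(1 + sizeFactor * count / totalCount), natural log.
#'
#' @param x a \linkS4class{CellCohort} holding raw counts.
#' @param sizeFactor positive library-size target (default 10000).
#' @return a log-normalized \linkS4class{CellCohort}.
#' @export
logNormalize <- function(x, sizeFactor = 10000) {
  stopifnot(is(x, "CellCohort"), sizeFactor > 0)
  if (isNormalized(x))
    polyenStop("polyenStateError",
               "dataset is already log-normalized; refusing to normalize twice")
  m <- assay(x, "counts")
  if (any(m@x < 0))
    polyenStop("polyenSchemaError", "counts must be non-negative")
  totals <- Matrix::colSums(m)
  if (any(totals == 0))
    polyenStop("polyenIntegrityError",
               "cells with zero total count (filter upstream): %s",
               paste(colnames(m)[totals == 0], collapse = ", "))
  norm <- m %*% Matrix::Diagonal(ncol(m), sizeFactor / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m)
  sce <- SingleCellExperiment(assays = list(logcounts = norm),
                              colData = colData(x))
  new("CellCohort", sce, donorData = donorData(x), normalized = TRUE)
}

#' Read gene sets from a table
#'
#' @param path CSV/TSV file with columns \code{set_name} and \code{gene}
#'   (separator inferred from the extension).
#' @return named list of \linkS4class{GeneSet} objects.
#' @export
readGeneSets <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  for (col in c("set_name", "gene"))
    if (!col %in% colnames(df))
      polyenStop("polyenSchemaError",
                 "gene-set table is missing required column '%s'", col)
  sets <- split(as.character(df$gene), df$set_name)
  mapply(function(g, nm) new("GeneSet", name = nm, members = unique(g)),
         sets, names(sets), SIMPLIFY = FALSE)
}

#' Union of gene sets
#'
#' @param sets list of \linkS4class{GeneSet} objects (or character vectors).
#' @param name name of the combined set (default "Union").
#' @return a \linkS4class{GeneSet} with each symbol exactly once.
#' @export
unionGeneSets <- function(sets, name = "Union") {
  if (length(sets) == 0L)
    polyenStop("polyenSchemaError", "cannot take the union of zero gene sets")
  mem <- unlist(lapply(sets, function(s)
    if (is(s, "GeneSet")) members(s) else as.character(s)), use.names = FALSE)
  new("GeneSet", name = name, members = unique(mem))
}

#' Restrict two cohorts to their shared genes
#'
#' Cross-dataset models are trained and applied on the genes expressed in
#' both sets; this restricts both cohorts to the gene intersection in one
#' canonical order (the training cohort's order).
#'
#' @param train,test \linkS4class{CellCohort} objects.
#' @return list with elements \code{train} and \code{test}.
#' @export
intersectGenes <- function(train, test) {
  common <- intersect(geneIds(train), geneIds(test))
  if (length(common) == 0L)
    polyenStop("polyenIntegrityError",
               "train and test share no genes; cannot build a common panel")
  list(train = train[common, ], test = test[common, ])
}

#' Pool cohorts into one dataset
#'
#' Cohorts must share an identical gene panel (apply [intersectGenes()]
#' first) and have disjoint donors.
#'
#' @param cohorts list of \linkS4class{CellCohort} objects.
#' @return a single \linkS4class{CellCohort}.
#' @export
combineCohorts <- function(cohorts) {
  stopifnot(length(cohorts) >= 1L)
  if (length(cohorts) == 1L) return(cohorts[[1]])
  genes <- geneIds(cohorts[[1]])
  for (cc in cohorts[-1])
    if (!identical(geneIds(cc), genes))
      polyenStop("polyenIntegrityError",
                 "cohorts must share an identical gene panel before pooling")
  allDonors <- unlist(lapply(cohorts, donorIds))
  if (anyDuplicated(allDonors))
    polyenStop("polyenIntegrityError",
               "duplicate donor identifiers across pooled cohorts: %s",
               paste(unique(allDonors[duplicated(allDonors)]), collapse = ", "))
  norm <- vapply(cohorts, isNormalized, logical(1))
  if (!all(norm == norm[1]))
    polyenStop("polyenStateError",
               "cannot pool normalized with unnormalized cohorts")
  m <- do.call(cbind, lapply(cohorts, function(cc) assay(cc)))
  cd <- do.call(rbind, lapply(cohorts, function(cc) as.data.frame(colData(cc))))
  dd <- do.call(rbind, lapply(cohorts, function(cc) {
    d <- as.data.frame(donorData(cc))
    d[, c("age", "group", "study"), drop = FALSE]
  }))
  colnames(m) <- rownames(cd) <- make.unique(unlist(lapply(cohorts, colnames)))
  CellCohort(Matrix::t(m), cd, dd, normalized = norm[1])
}
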