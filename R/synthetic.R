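#' @include io.R
NULL

#' Construct a synthetic cohort specification
#'
#' Defines a multi-donor, multi-cell-type single-cell cohort in which signal
#' genes follow a polynomial mean trend \eqn{\mu_g(a) = b_0 + b_1 a + b_2
#' a^2} and a linear cell-level standard-deviation trend \eqn{\sigma_g(a) =
#' c_0 + c_1 a} in donor age a, while non-signal genes are age-constant.
#'
#' @param nDonors donors (default 40).
#' @param ageRange years, ages drawn uniformly (default 20-80, an adult
#'   cohort).
#' @param cellTypes named vector of cells per donor per type (default
#'   \code{c(epithelial = 200)}).
#' @param cellOverrides named list donor -> cells per donor, to plant
#'   under-sampled donors (e.g. \code{list(D01 = 3)}).
#' @param nGenes gene panel size (default 50).
#' @param signal data.frame with columns \code{cell_type}, \code{gene}
#'   (index into the panel), \code{b0}, \code{b1}, \code{b2}, \code{c0},
#'   \code{c1}; zero rows for a null cohort.
#' @param baselineMu,baselineSigma ranges for the age-constant mean and
#'   cell-level SD of non-signal genes (log-normalized scale).
#' @param noise "normal" draws log-scale expression directly; "nb" draws
#'   negative-binomial counts to be passed through [logNormalize()].
#' @param nbSize NB dispersion (counts mode; default 10).
#' @param dropout zero-inflation probability (counts mode only).
#' @param scenario tag carried through to the ground truth.
#' @param seed integer generation seed.
#' @return a validated \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nDonors = 40L, ageRange = c(20, 80),
                       cellTypes = c(epithelial = 200),
                       cellOverrides = list(), nGenes = 50L,
                       signal = emptySignal(), baselineMu = c(1.5, 3.5),
                       baselineSigma = c(0.3, 0.6),
                       noise = c("normal", "nb"), nbSize = 10,
                       dropout = 0, scenario = "custom", seed = 1L) {
  noise <- match.arg(noise)
  new("CohortSpec", nDonors = as.integer(nDonors),
      ageRange = as.numeric(ageRange), cellTypes = cellTypes,
      cellOverrides = cellOverrides, nGenes = as.integer(nGenes),
      signal = signal, baselineMu = baselineMu,
      baselineSigma = baselineSigma, noise = noise, nbSize = nbSize,
      dropout = dropout, scenario = scenario, seed = as.integer(seed))
}

emptySignal <- function() {
  data.frame(cell_type = character(), gene = integer(), b0 = numeric(),
             b1 = numeric(), b2 = numeric(), c0 = numeric(), c1 = numeric(),
             stringsAsFactors = FALSE)
}

signalRows <- function(cellType, genes, b0, b1, b2 = 0, c0 = 0.45, c1 = 0) {
  data.frame(cell_type = cellType, gene = genes, b0 = b0, b1 = b1, b2 = b2,
             c0 = c0, c1 = c1, stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Deterministic under the spec's seed (optionally overridden): donor ages
#' are drawn once, then each cell's expression for gene g is drawn with
#' mean \eqn{\mu_g(age)} and SD \eqn{\sigma_g(age)} on the log scale
#' (clamped at zero), or as the negative-binomial count analogue with
#' optional dropout, to be log-normalized downstream.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param seed overrides \code{spec@seed} when given.
#' @return list with \code{cohort} (a \linkS4class{CellCohort}; already
#'   log-normalized in "normal" mode, raw counts in "nb" mode) and
#'   \code{truth} (a \linkS4class{SyntheticTruth}).
#' @examples
#' sim <- generateCohort(presetScenarios()$null)
#' sim$truth
#' @export
generateCohort <- function(spec, seed = NULL) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  seed <- as.integer(seed %||% spec@seed)
  genes <- sprintf("G%02d", seq_len(spec@nGenes))
  withSeed(seed, {
    ages <- runif(spec@nDonors, spec@ageRange[1], spec@ageRange[2])
    donors <- sprintf("D%02d", seq_len(spec@nDonors))
    baseMu <- runif(spec@nGenes, spec@baselineMu[1], spec@baselineMu[2])
    baseSd <- runif(spec@nGenes, spec@baselineSigma[1], spec@baselineSigma[2])
    blocks <- list(); cellMeta <- list()
    for (ct in names(spec@cellTypes)) {
      sg <- spec@signal[spec@signal$cell_type == ct, , drop = FALSE]
      for (d in seq_along(donors)) {
        a <- ages[d]
        mu <- baseMu
        sdv <- baseSd
        if (nrow(sg)) {
          mu[sg$gene] <- sg$b0 + sg$b1 * a + sg$b2 * a^2
          sdv[sg$gene] <- sg$c0 + sg$c1 * a
        }
        nc <- spec@cellOverrides[[donors[d]]] %||% spec@cellTypes[[ct]]
        nc <- as.integer(nc)
        if (spec@noise == "normal") {
          m <- matrix(rnorm(nc * spec@nGenes, rep(mu, each = nc),
                            rep(sdv, each = nc)), nrow = nc)
          m[m < 0] <- 0
        } else {
          lam <- expm1(pmax(mu, 0))
          m <- matrix(rnbinom(nc * spec@nGenes, mu = rep(lam, each = nc),
                              size = spec@nbSize), nrow = nc)
          if (spec@dropout > 0)
            m[matrix(runif(length(m)) < spec@dropout, nrow = nc)] <- 0
        }
        blocks[[length(blocks) + 1L]] <- m
        cellMeta[[length(cellMeta) + 1L]] <-
          data.frame(donor = donors[d], cell_type = ct, n = nc,
                     stringsAsFactors = FALSE)
      }
    }
    values <- do.call(rbind, blocks)
    meta <- do.call(rbind, cellMeta)
    cells <- data.frame(
      donor = rep(meta$donor, meta$n), cell_type = rep(meta$cell_type, meta$n),
      stringsAsFactors = FALSE)
    rownames(cells) <- sprintf("%s_%s_c%04d", cells$donor, cells$cell_type,
                               unlist(lapply(meta$n, seq_len)))
    colnames(values) <- genes
    rownames(values) <- rownames(cells)
    grp <- if (spec@scenario == "small_smoker_like")
      rep_len(c("smoker", "nonsmoker"), spec@nDonors) else "nonsmoker"
    dd <- data.frame(age = ages, group = grp, study = "synthetic",
                     row.names = donors, stringsAsFactors = FALSE)
    cohort <- CellCohort(values, cells, dd,
                         normalized = spec@noise == "normal")
    sig <- split(genes[spec@signal$gene], spec@signal$cell_type)
    coefs <- spec@signal
    if (nrow(coefs)) coefs$gene <- genes[coefs$gene]
    truth <- new("SyntheticTruth",
                 signalGenes = lapply(sig, unique),
                 coefficients = coefs, scenario = spec@scenario, seed = seed)
    list(cohort = cohort, truth = truth)
  })
}

#' Named preset cohort scenarios
#'
#' \describe{
#'   \item{strong_mean}{40 donors, 50 genes, 5 signal genes with linear mean
#'     trends (slopes 0.015-0.030 per year, mixed signs), 200 cells/donor.}
#'   \item{quadratic}{as above but rise-then-fall quadratic mean trends,
#'     mimicking genes that participate in part of the aging process and
#'     then decline.}
#'   \item{variance_only}{means age-constant; the cell-level SD of the 5
#'     signal genes grows linearly with age (0.30 + 0.010/yr), so the age
#'     signal lives exclusively in donor-level variances.}
#'   \item{null}{no signal genes; every gene age-independent.}
#'   \item{small_smoker_like}{12 donors, 100 genes, 50 cells/donor, weak
#'     signal, smoker/nonsmoker groups, and one deliberately under-sampled
#'     donor (3 cells) to exercise the cell-count filter.}
#' }
#'
#' @return named list of \linkS4class{CohortSpec} objects.
#' @export
presetScenarios <- function() {
  ct <- "epithelial"
  strongSig <- signalRows(ct, 1:5,
                          b0 = c(2.0, 2.2, 3.3, 1.8, 2.1),
                          b1 = c(0.020, 0.025, -0.018, 0.015, 0.030))
  quadSig <- signalRows(ct, 1:5,
                        b0 = c(0.8, 1.0, 3.6, 0.9, 1.2),
                        b1 = c(0.080, 0.070, -0.060, 0.065, 0.075),
                        b2 = c(-8, -7, 6, -6.5, -7.5) * 1e-4)
  varSig <- signalRows(ct, 1:5,
                       b0 = c(2.4, 2.6, 2.2, 2.8, 2.5), b1 = 0,
                       c0 = 0.30, c1 = 0.010)
  weakSig <- signalRows(ct, 1:5,
                        b0 = c(2.0, 2.2, 2.4, 1.8, 2.1),
                        b1 = c(0.008, -0.007, 0.009, 0.006, 0.008))
  list(
    strong_mean = cohortSpec(signal = strongSig, scenario = "mean_signal",
                             seed = 101L),
    quadratic = cohortSpec(signal = quadSig, scenario = "quadratic",
                           seed = 102L),
    variance_only = cohortSpec(signal = varSig, scenario = "variance_only",
                               seed = 103L),
    null = cohortSpec(signal = emptySignal(), scenario = "null",
                      seed = 104L),
    small_smoker_like = cohortSpec(
      nDonors = 12L, nGenes = 100L, cellTypes = c(epithelial = 50),
      cellOverrides = list(D01 = 3), signal = weakSig,
      scenario = "small_smoker_like", seed = 105L))
}
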