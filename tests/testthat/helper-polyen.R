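# Shared fixture builders; all data are generated in code.

# tiny hand-built cohort: 2 donors, 5 cells, 3 genes, values on the log scale
tinyCohort <- function(normalized = TRUE) {
  values <- matrix(
    c(1, 2, 3,    # d1 cell 1
      2, 2, 1,    # d1 cell 2
      3, 2, 2,    # d1 cell 3
      0, 1, 4,    # d2 cell 1
      2, 1, 0),   # d2 cell 2
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("c", 1:5), c("GA", "GB", "GC")))
  cells <- data.frame(donor = c("d1", "d1", "d1", "d2", "d2"),
                      cell_type = c("T", "T", "T", "T", "B"),
                      row.names = rownames(values))
  donors <- data.frame(age = c(35, 62), group = c("nonsmoker", "smoker"),
                       study = "toy", row.names = c("d1", "d2"))
  CellCohort(values, cells, donors, normalized = normalized)
}

# random regression problem with named columns
randomProblem <- function(n, m, seed, noise = 0.5) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * m), n, m,
                dimnames = list(paste0("D", seq_len(n)),
                                paste0("f", seq_len(m))))
    w <- rnorm(m)
    list(X = X, y = drop(X %*% w) + rnorm(n, sd = noise), w = w)
  })
}

# small synthetic cohort for fast end-to-end tests
smallCohort <- function(seed = 7L, nDonors = 12L, nGenes = 12L,
                        cells = 30, signal = TRUE) {
  sig <- if (signal)
    data.frame(cell_type = "epithelial", gene = 1:2,
               b0 = c(2, 2.4), b1 = c(0.03, -0.02), b2 = 0,
               c0 = 0.4, c1 = 0)
  else polyen:::emptySignal()
  spec <- cohortSpec(nDonors = nDonors, nGenes = nGenes,
                     cellTypes = c(epithelial = cells), signal = sig,
                     scenario = if (signal) "mean_signal" else "null",
                     seed = seed)
  generateCohort(spec)
}

# fast hyperparameter space for tests that only need the mechanics
fastSpace <- function(budget = 4L, folds = 3L)
  searchSpace(alphaGrid = c(0.1, 1), budget = budget, folds = folds)
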