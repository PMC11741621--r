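---
title: "Polynomial elastic-net aging clocks from single-cell expression"
author: "polyen package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polynomial elastic-net aging clocks from single-cell expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyen)
```

## The model

Chronological age is a property of a donor, not of a cell, so any
transcriptomic aging clock built from single-cell RNA-seq must first decide
how to pool information across a donor's cells. `polyen` does this with
donor-level summary statistics: for each gene $g$ and each donor $d$, the
mean $u_{dg}$ and the sample variance $v_{dg}$ of log-normalized expression
over that donor's cells of one cell type. Variances are first-class
features, not nuisance: cell-to-cell expression variability itself
increases with age in many tissues, so the dispersion of a gene can carry
age signal even when its mean does not.

Age trends are modeled as low-degree polynomials. Genes that rise or fall
monotonically over adult life are captured by a first-degree term; genes
that participate in only part of the aging process — up then down — need a
second-degree term. The feature matrix for one cell type is the column-wise
concatenation

$$X = \{u_1,\dots,u_n,\; v_1,\dots,v_n,\; u_1^{\circ 2},\dots,u_n^{\circ 2},
\; v_1^{\circ 2},\dots,v_n^{\circ 2}\},$$

where $u_i^{\circ 2}$ is the element-wise square, giving exactly $4n$
columns for an $n$-gene panel, in that fixed order so that models and
attribution outputs are reproducible bit for bit. Third-degree terms are
deliberately out of scope: they add parameters without predictive benefit
at cohort sizes of tens of donors.

The regressor is an elastic net with an unpenalized intercept:

$$\min_w \; \frac{1}{2n}\lVert Xw - y\rVert_2^2
  + \alpha\rho\lVert w\rVert_1
  + \frac{\alpha(1-\rho)}{2}\lVert w\rVert_2^2,$$

with $y$ the donor ages in years, $\alpha$ the penalty strength and $\rho$
the L1 fraction. The L1 part performs gene selection; the L2 part spreads
weight over correlated features (a gene's mean and its square are almost
collinear by construction, and co-regulated genes are correlated across
donors), which stabilizes both prediction and downstream attribution.

## Parameters that matter

* **`sizeFactor` (10000)** — library-size target of `logNormalize()`;
  values are `log1p(sizeFactor * count / total)`, natural log. Atlas-style
  inputs that arrive already log-normalized are flagged as such and never
  re-normalized.
* **`minCells` (10, per donor and cell type)** — donors contributing fewer
  cells are dropped from both training and scoring and reported. At least
  2 cells are required so the sample variance (denominator $n-1$) exists.
* **`alpha` grid $\{0.001, 0.01, 0.1, 1, 10, 100\}$ and `rho` interval
  $[0.1, 1.0]$** — the hyperparameter search space; 30 evaluations of a
  TPE-style sequential optimizer, scored by inner 5-fold cross-validated
  MSE on the training donors.
* **`k` (10)** — for the PCA variant, cell-level expression is projected
  onto the top `k` principal components (genes centered, not scaled) and
  the polynomial machinery is applied to PC scores, giving $4k$ columns.
  The meta-regressor concatenates each donor's per-cell-type polynomial
  features across cell types and keeps the top 20 donor-level PCs.
* **`tol` (1e-6) and `maxIter` (100000)** — coordinate-descent convergence
  is declared when the largest coefficient change in a sweep (standardized
  scale) falls below `tol`. The sweep cap is generous because the
  mean/squared-mean column pairs are nearly collinear and cyclic descent
  can need over ten thousand sweeps to settle the last digits; sweeps cost
  microseconds at these problem sizes. Non-convergence is recorded in the
  model's convergence slot (with a warning), never raised as an error.

## Design choices where the design was open

**Standardization.** Feature columns are centered and scaled by training
statistics before penalized fitting, and coefficients are mapped back.
Without this, squared-mean columns — on a scale roughly the square of the
mean columns — would absorb arbitrary shrinkage simply because of their
units. Predictions are invariant to the reparameterization; the
standardization statistics are stored in the model.

**Tuning objective.** Hyperparameters are selected by inner 5-fold
cross-validated MSE on the training donors. Selecting on training loss
would always prefer the weakest penalty and defeat regularization;
cross-validation is the defensible objective for a tuned penalty. Fold
assignment and the optimizer's proposals are deterministic given the seed.
During the search, inner fits run at a looser tolerance (1e-4, capped
sweeps, warm-started across proposals): the tuning loss only ranks
configurations, and the final model is always refit at full tolerance.

**Leakage discipline.** In leave-one-out evaluation the held-out donor is
excluded from hyperparameter tuning and from every data-driven transform:
the PCA loadings of the PCA variant are refit on the training donors' cells
in every fold, and held-out cells are only projected. Donor-level means and
variances are donor-local statistics, so gene-space features need no
refitting. The per-fold training-donor sets and transform-fit donors are
recorded on the result object and asserted in the test suite. Cross-dataset
evaluation requires provably disjoint donor sets and restricts both sides
to the shared gene panel before any fitting.

**Run-to-run variability.** An evaluation is repeated (default five runs)
with seeds derived deterministically from a master seed; runs differ
through fold assignment and optimizer randomness. The reported quantity is
the mean and SD of the per-run $R^2$, where $R^2 = 1 - SS_{res}/SS_{tot}$
about the mean of the true ages and can be negative.

**Attribution.** The fitted model is linear in its features, so Shapley
attributions under feature independence have the exact closed form
$\phi_{dj} = w_j (x_{dj} - \bar x_j^{\mathrm{ref}})$, with the training
donors as the default reference population. This makes local accuracy —
baseline plus attribution row-sum equals the prediction — hold to machine
precision, with no sampling. A gene's score aggregates its four columns as
the sum of mean absolute attributions; per-kind means are kept separately
so first- versus second-order contributions can be compared. Empirical
p-values shuffle donor ages and re-run the entire tune/fit/attribute
pipeline per permutation, with the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{perm}+1)$, so $p = 0$ is
impossible. Since the features do not depend on the ages, shuffling ages is
implemented as permuting $y$ against the intact feature matrix, which is
the same null.

## The synthetic cohort generator

Real multi-donor atlases cannot be bundled, so the generator produces
cohorts in which the ground truth is known and every pipeline property is
testable. Donor ages are uniform on 20–80 years (an adult cohort). Signal
genes follow a polynomial mean trend $\mu_g(a) = b_0 + b_1 a + b_2 a^2$
and a linear cell-level SD trend $\sigma_g(a) = c_0 + c_1 a$; non-signal
genes are age-constant with baseline means drawn from 1.5–3.5 and SDs from
0.3–0.6 on the log-normalized scale. Cell values are drawn normally on the
log scale (clamped at zero), or as negative-binomial counts with optional
dropout to exercise the normalization path.

The preset scenarios fix the study conditions used throughout the tests:
`strong_mean` (40 donors, 50 genes, 5 signal genes with slopes
0.015–0.030/yr of mixed sign, 200 cells/donor), `quadratic` (rise-then-fall
trends), `variance_only` ($b_1 = b_2 = 0$, $\sigma_g(a) = 0.30 + 0.010a$ —
the age signal lives exclusively in the donor-level variances), `null`
(no signal), and `small_smoker_like` (12 donors, weak signal, smoker and
non-smoker groups, one donor deliberately under-sampled at 3 cells so the
cell-count filter is exercised in both directions).

What the generator does *not* emulate: library-size gradients, batch
effects, doublets, cell-type hierarchies beyond a few flat labels, or gene-
gene correlation beyond what the shared age covariate induces. Passing
tests therefore demonstrate that the pipeline recovers the signal structure
it models — polynomial mean trends and age-increasing dispersion — under
realistic sampling noise; they do not certify performance on any real
atlas.

```{r quick-demo, eval = FALSE}
sim <- generateCohort(presetScenarios()$strong_mean)
ev <- looEvaluate(sim$cohort, pipelineConfig(cellType = "epithelial"),
                  nRuns = 5, seed = 1)
summarizeRuns(ev)
```

## Numerical choices and degenerate inputs

* Variances use the unbiased $n-1$ denominator; one-pass aggregation is
  guarded against floating-point cancellation at zero variance and agrees
  with the two-pass formula to 1e-10 relative tolerance in the tests.
* Constant feature columns get unit scale and necessarily zero weight;
  constant donor ages are rejected (the target is degenerate).
* PCA requests beyond the rank of the training matrix are errors, not
  silent truncation, except in the meta-regressor where the donor-level
  matrix routinely has fewer donors than requested components and the rank
  is capped explicitly.
* Ties in gene ranking are broken by first occurrence; empirical p-values
  are invariant to monotone rescaling of the score.
* Cells with a missing cell-type label are excluded from cell-type-specific
  analyses but retained in pseudo-bulk mode; zero-total cells make
  `logNormalize()` fail with the offending cell identifiers listed rather
  than being dropped silently.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on generated
cohorts: 40 donors x 50 genes x 200 cells/donor for the three headline
scenarios, 200 label permutations for p-value calibration, and five
repeated runs per evaluation. These sizes were chosen so that each
scientific property (signal recovery, variance superiority over the
mean-only baseline, null calibration) is decisively powered while the whole
suite remains a desk-scale computation.

## Known limitations

* The elastic-net clock is linear in its polynomial features; interactions
  between genes are only captured insofar as the penalty spreads weight
  over correlated features.
* SHAP values use the interventional, feature-independence closed form;
  with strongly correlated features the attribution of shared signal among
  collinear columns is determined by the penalty, not by the data alone.
* Permutation p-values inherit the discreteness of $n_{perm}$ and are
  computed per gene without multiplicity adjustment; downstream enrichment
  (via the `.rnk` export) is the intended consumer of the full ranking.
* On data with no age signal at all, the cross-validated penalty correctly
  shrinks every weight to zero, so all importance scores are exactly 0 and
  all permutation p-values equal 1. The p-values are therefore
  conservative — never anti-conservative — under the global null rather
  than uniform; an exactly uniform null distribution would require an
  importance score that never degenerates to zero, which a properly
  regularized sparse model does not provide.
* Cross-dataset evaluation assumes the shared gene panel is expressed
  comparably in both cohorts; no batch correction is applied in-package.
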