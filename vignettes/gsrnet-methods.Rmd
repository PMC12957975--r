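---
title: "Sparse and group-sparse connectivity networks for case-control classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse and group-sparse connectivity networks for case-control classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Resting-state fMRI case-control studies summarize each subject as a
functional connectivity (FC) network: an `R x R` matrix of statistical
dependencies between the time series of `R` atlas regions (ROIs).  Whether a
network representation supports individual-level diagnosis is then a
classification question: can a classifier trained on network edges separate
patients from controls under honest cross-validation?

`gsrnet` implements and compares three network constructions:

* **PC** — pairwise Pearson correlation, Fisher r-to-z transformed.  Dense,
  purely bivariate.
* **SR** — sparse representation.  Each ROI's signal $x_r$ is regressed on
  all other ROIs under an $\ell_1$ penalty,
  $\min_w \tfrac12\lVert x_r - X_{-r} w\rVert_2^2 + \lambda \lVert w\rVert_1$,
  so an edge weight reflects a conditional (partial) association.  Estimated
  per subject, so edge supports vary across subjects.
* **GSR** — group sparse representation.  The node-wise regressions of all
  $N$ subjects are solved jointly under an $\ell_{2,1}$ penalty
  $\lambda \sum_j \lVert W_{j\cdot}\rVert_2$ on the matrix whose columns are
  subjects and whose rows are candidate predictors.  Whole rows are zeroed,
  so all subjects share one edge support while keeping subject-specific
  weights — a compromise between SR's individual detail and group-level
  reproducibility.

For all three, nonzero weights are Fisher z-transformed, the asymmetric
weight matrix is symmetrized by bidirectional averaging, and the diagonal is
zero.  The upper triangle (length $R(R-1)/2$) is the subject's feature
vector.

## Classification protocol

Subjects are classified with a linear soft-margin SVM after LASSO feature
selection, inside a *nested* leave-one-out cross-validation (LOOCV):

1. Outer fold: one subject is held out for testing; `N - 1` remain.
2. Inner folds: each of the `N - 1` training subjects is held out once more.
   Networks are constructed from the remaining `N - 2` subjects only; for
   GSR the group problem sees only those subjects and both held-out subjects
   are *encoded* on the learned support (below).
3. Per inner fold and per grid point (network $\lambda$ $\times$ LASSO
   $\lambda$), features are selected by LASSO and an SVM is trained; the
   grid point that classifies the inner held-out subject correctly wins.
   With a single 0/1 inner score, ties are the rule rather than the
   exception, so the tie-break is load-bearing: among equally correct grid
   points a non-empty selection beats the degenerate majority-class model,
   then the sparser model wins (larger LASSO $\lambda$, then larger network
   $\lambda$).  Breaking ties toward *denser* models instead measurably
   degrades the tuned networks (the densest grid point is also the
   noisiest).
4. The `N - 1` winning classifiers vote on the outer test subject; the
   majority label is the prediction and the fraction of positive votes is
   the subject's ROC score.  Accuracy, sensitivity, specificity are computed
   from the confusion counts with patients (+1) positive; AUC comes from the
   vote fractions by the rank (midrank-tie) formula.

The outer test subject never enters network construction, `lambda_max`
computation, feature-selection statistics, or SVM fitting of its own fold:
leakage is excluded by construction, and the null-cohort tests verify the
resulting chance-level calibration empirically.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| network grid `net_grid` | 0.1–0.5 step 0.1 (relative) | fraction of `lambda_max`; scale-free sparsity control |
| LASSO grid `lasso_grid` | 0.01–0.10 step 0.01 | selection strength on standardized features (the `1/(2n)` objective convention) |
| SVM cost `C` | 1 | fixed; not tuned, so only the two lambdas are searched |
| solver tolerances | KKT `1e-8` (exported solvers) | certified by the KKT checkers |

The network grid is expressed *relative* to `lambda_max` (the smallest
penalty that zeroes the solution), which the package computes exactly for
both the $\ell_1$ and $\ell_{2,1}$ problems.  Five grid points over
0.1–0.5 span the useful sparsity range; sparsity varies smoothly in
$\lambda/\lambda_{\max}$, so a finer grid mainly adds compute.  For SR the
reference `lambda_max` is the subject's own (making per-subject sparsity
comparable and the networks reusable across folds, since a subject's SR
network depends on no one else); for GSR it is the training subset's.

## Encoding held-out subjects under GSR

The group solve defines networks only for the subjects inside it.  A
held-out subject is encoded by a per-ROI regression restricted to the
learned support.  Plain restricted least squares turns out to be the wrong
choice: group-penalized training weights are shrunk while OLS weights are
not, so encoded feature vectors have systematically larger norms than the
training features they are compared with (a covariate shift between train
and test).  The engine therefore encodes at the penalty
$\lambda/\sqrt{N}$ — exactly the single-subject problem the group objective
reduces to when all $N$ subjects are identical — so held-out features carry
the same order of shrinkage.  `encode_new_subject()` exposes both variants
(`shrink_lambda = 0` gives restricted OLS with a trace-normalized ridge
fallback of `1e-6` for singular systems).

## Solvers and numerical choices

* $\ell_1$: cyclic coordinate descent with residual updates and an
  active-set strategy (full pass + KKT certificate, then iterate the active
  set).  Orthonormal designs recover the soft-threshold closed form to
  `1e-8`.
* $\ell_{2,1}$: row-wise block coordinate descent.  Because all columns are
  z-scored, every per-subject design has the same diagonal Gram (`T - 1`),
  so each row update is an exact closed-form block soft-threshold; unequal
  curvatures (possible for user-supplied problems) fall back to a majorized
  max-curvature step, still monotone.  Convergence is always certified by
  the KKT conditions (zero rows: $\lVert g_j\rVert_2 \le \lambda$; active
  rows: $g_j = \lambda W_{j\cdot}/\lVert W_{j\cdot}\rVert_2$).
* Linear SVM: deterministic dual coordinate descent on the hinge loss with
  the bias on an augmented constant feature.  Validated against `e1071`
  (libsvm) in the test suite.
* Fisher z of regression weights: magnitudes at or above 1 are clipped to
  `1 - 1e-7` before `atanh` (the transform is undefined at $\pm 1$ and
  regression weights can exceed 1); clip events are counted.  The z
  transform is applied to the raw asymmetric weights first, then
  bidirectional averaging.
* Degenerate inputs: zero-variance ROIs abort conditioning with the ROI
  named; empty feature selections make an inner classifier vote the
  training-majority class (ties toward patients); vote ties (possible with
  an even number of inner classifiers) resolve toward the patient class,
  which favors sensitivity.
* Inside the cross-validation engine the solvers run with capped sweep
  budgets (selection paths in particular may be stopped early at the
  smallest penalties, where the near-interpolating lasso is slow); the caps
  are deterministic, so results are exactly reproducible.  Exported solver
  functions use strict KKT-certified tolerances.

## The synthetic cohort generator

The study conditions the package is tested under come from
`generate_cohort()`: two groups of subjects, each subject's `T x R` signal
drawn i.i.d. in time from a zero-mean multivariate Gaussian whose precision
matrix has (i) a sparse off-diagonal support shared by the whole cohort,
(ii) a designated subset of *effect edges* whose partial-correlation
strength differs between groups by `effect_delta`, (iii) per-subject
symmetric jitter on the support, and (iv) additive white observation noise.
Positive definiteness is enforced by diagonal loading (add $\epsilon I$,
doubling $\epsilon$ until the Cholesky succeeds, at most 10 attempts), with
a loading common to both groups so their diagonal scale matches.  An
i.i.d.-in-time Gaussian is the right level of realism here because all
three network constructions depend only on second-order structure; temporal
autocorrelation, hemodynamics, and motion are deliberately out of scope.

Default strengths place the synthetic task in the qualitative regime
case-control resting-state classification actually occupies — a weak,
distributed group effect inside substantial between-subject heterogeneity,
where a purely bivariate (PC) classifier performs near chance: base partial
correlations are drawn from $\pm U(0.15, 0.35)$ on the support,
`effect_delta = 0.15` shifts effect-edge magnitudes (about one subject-level
standard error of a correlation at `T = 150`–`230`), `subject_jitter_sd =
0.2` makes inter-subject variability comparable to the group effect, and
`noise_sd = 1` roughly halves observed partial correlations.  These were
fixed once, from pilot cohorts, before the package's acceptance checks were
written, and are not adjusted per analysis.

What passing tests on this generator do *not* show about real data: the
generator's support really is shared across subjects (GSR's core
assumption is true by construction), effects are stationary, and noise is
white — real resting-state data can violate all three, so synthetic
performance bounds nothing quantitatively; the tests establish correctness
and qualitative behavior (chance-level nulls, method ordering under shared
structure), not clinical effect sizes.

## Problem sizes used by the test suite

Cohort-level properties are checked at `R = 20`, `T = 150`, 20 subjects per
group (support density 0.15), with 10 generator seeds per property; solver
certificates run on 50 random fixtures up to 20 predictors and 60 samples.
These sizes keep every node-wise regression overdetermined while exercising
all code paths; the full-atlas geometry (`R = 116`, `T = 230`, 6670
features) differs only in scale.

## Known limitations

* LOOCV with inner per-subject tuning is the protocol implemented, not a
  recommendation: its variance is high and fold-level 0/1 inner scores tie
  often (the sparser-model tie-break is then load-bearing).
* The GSR group problem is solved over all training subjects pooled,
  label-free.  Grouping *by diagnosis* would leak labels into feature
  construction under cross-validation, so it is intentionally not offered.
* `demographics_table()` applies no multiple-comparison correction across
  demographic rows.
* No dynamic (sliding-window) connectivity, no graphical-lasso/partial-
  correlation networks, no image-space preprocessing: the package consumes
  extracted ROI time series.
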