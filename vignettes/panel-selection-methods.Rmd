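---
title: "Methods: SVM-RFE-CV biomarker panel selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SVM-RFE-CV biomarker panel selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelselect)
```

`panelselect` selects compact probe panels for two-class (cancer vs normal)
classification of expression matrices. This vignette documents the
statistical model behind each stage, the tunable parameters and their
defaults, the behaviour of the synthetic generator the test-suite relies
on, and the numerical and design decisions that were genuinely open.

## Data model and normalisation

The input is a probe-by-sample matrix of continuous expression values with
a class label per sample, encoded internally as `+1` (cancer) and `-1`
(normal). Values are assumed to be on a log-ratio scale; a raw-scale matrix
can be passed through `log2_transform()` first, but that step is never
applied implicitly because public processed matrices are usually already
logged, and double-logging is a silent corruption. Normalisation proper is
per-probe median centring: for each probe the median across all samples is
subtracted, so every probe has median zero. Per-sample centring is
available via `median_center(by = "sample")` for data where column effects
dominate; per-probe is the default because the screening model below is a
contrast *within* each probe. Centring is idempotent, so re-running a
pipeline on already-centred data is harmless.

## Screening model

For probe $p$ the model is the additive decomposition

$$ y_{pij} = \mu_p + T_{pi} + S_j + \varepsilon_{pij}, \qquad
   S_j \sim N(0, \sigma_S^2), \quad \varepsilon \sim N(0, \sigma^2), $$

with $T_{pi}$ the fixed class effect and $S_j$ a random per-sample effect.
With exactly one observation per probe and sample — the usual microarray
design — $S_j$ and $\varepsilon_{pij}$ are confounded within any single
probe, and the per-probe model reduces to a one-way fixed-effect ANOVA:
`probe_group_test()` computes the F statistic for the class effect on
$(1, n-2)$ degrees of freedom. A genuine mixed-model fit across probes is
out of scope; the reduction is exact for per-probe inference and is the
reason no mixed-model machinery is pulled in.

The screen is a three-step multiplicity treatment: raw p-values,
Benjamini–Hochberg step-up adjustment (`bh_adjust()`), and
Storey–Tibshirani q-values (`storey_qvalue()`) with the single-lambda null
proportion estimate

$$ \hat\pi_0 = \frac{\#\{p_i > \lambda\}}{m(1-\lambda)}, \qquad
   q_i = \hat\pi_0 \cdot \mathrm{BH}_i, $$

clamped to $(0, 1]$. The default $\lambda = 0.5$ is the simplest published
variant; the spline-over-lambda estimator is deliberately not implemented
because the screening decision (`q < 0.01`, strict inequality) is
insensitive to small $\hat\pi_0$ differences at that threshold, and a
single fixed lambda keeps the estimate reproducible and explainable. When
no p-value exceeds lambda the estimate is undefined and $\hat\pi_0$ is set
to 1, the conservative choice. `select_markers()` also reports
`q_threshold x marker count` — the expected *number* (not rate) of false
positives among the declared markers; the accessor is named `fpr` for
continuity with the field's usage, and the unit is documented at every
surface.

## The SVM and its hyperparameters

Classification uses a standard soft-margin SVM (hinge loss, solved by
libsvm through `e1071`), with features unscaled because the matrix is
already on a common log-ratio scale. Defaults, fixed and echoed in every
output:

* `C = 1` — the cost parameter; no tuning loop is built in, because the
  selection procedure's claim is about feature subsets, not about
  hyperparameter optimisation, and a fixed C keeps the LOOCV error
  comparable across iterations.
* `gamma = 1/(n_features * var(X))` for the RBF kernel, recomputed on
  whatever feature subset is being fitted — the scale-aware convention that
  keeps kernel widths sensible as the subset shrinks.
* Decision scores are oriented so positive predicts cancer; a score of
  exactly zero maps to `+1` (a fixed tie-break, relevant only for
  degenerate inputs).

## Recursive elimination with summed LOOCV weights

Each iteration of `svm_rfe_cv()` runs `loocv_pass()`: $n$ folds, each
leaving one sample out. Per fold two quantities are taken:

* the **held-out error** from an SVM with the configured kernel (RBF by
  default, matching the final classifier), and
* the **ranking weight** $|w|$ from a linear-kernel SVM fitted to the same
  fold with the same cost. The primal weight vector
  $w = \sum_i \alpha_i y_i x_i$ only exists for the linear kernel; ranking
  by it while classifying with RBF is the package's resolution of a genuine
  ambiguity (see below).

Weights and errors are summed over folds: $W_f = \sum_k |w_{kf}|$,
$E = \sum_k e_k$. All features tied at the minimum competition rank of $W$
are eliminated together (exact ties leave as a group; at least one feature
always survives), and the loop continues **while E does not exceed the
previous iteration's E** — i.e. elimination proceeds through error
plateaus. The loop therefore exits one step past its best state, and the
returned panel is the trace iteration with minimum $E$, ties broken toward
fewer features. The cross-validation score of a subset is
$\text{ErrorRate} \times n = E$, the number of misclassified held-out
samples; `cv_score()` keeps the identity explicit.

Two design points were genuinely open:

* **Ranking criterion under an RBF kernel.** The procedure's stated
  ranking quantity $|W|$ has no primal definition for RBF. The default
  (`rank_kernel = "linear"`) fits an auxiliary linear SVM per fold for the
  weights; the alternative `rank_kernel = "rbf-margin"` ranks by the
  Guyon-style margin criterion $\Delta J_f = \tfrac12(\alpha^\top K\alpha -
  \alpha^\top K^{(-f)}\alpha)$ computed from the RBF fold model itself.
  Both are first-class code paths; the linear default reproduces the
  stated $|W|$ quantity.
* **Plateau behaviour.** Continuing elimination at equal $E$ is what
  produces the smallest panel at the best score, but it also means that
  when a single strong marker achieves the same summed error as a pair,
  the pair is not returned. This is inherent to the "minimum error, fewest
  features" rule and is visible in the parameter-recovery simulations: at
  moderate effect sizes a small fraction of replicates return a
  sub-panel of the informative set.

Per-iteration weights are recomputed from scratch (no warm starts), so the
whole trace is deterministic and bit-for-bit reproducible.

## Train/test split

`split_train_test()` is stratified by default: the training set receives
`ceiling(fraction * n)` samples, allocated across classes by largest
remainder (ties to the first class name). Stratification is the default
because near-balanced per-class counts cannot be relied on from an
unstratified split at these cohort sizes. The seed is a required,
recorded parameter — reproducibility of any split-based analysis hinges on
it — and the pipeline log stores MD5 hashes of each stage's inputs so it
can be verified that screening and selection never saw the testing half.

## Enumeration validation

`enumerate_panels()` draws M distinct random panels of size N from the
candidate markers (exhaustively when $\binom{|C|}{N} \le M$), estimates
training accuracy by stratified 5-fold cross-validation, refits each panel
on the full training half, and ranks panels by test-set AUC. The 5-fold CV
is an accuracy estimate, not a model-selection loop: the ranking formula
uses a single trained classifier per panel. The default M = 1000 is a
desk-scale setting; the validation is a sanity device, and its best/worst
panels are themselves selected on the test set, so their curves should be
read as descriptive, not inferential.

## Performance measures

`confusion_matrix()` cross-tabulates with cancer as positive;
sensitivity, specificity (`TN/(TN+FP)` — the standard form), precision and
accuracy come with a `NaN`-plus-warning contract for empty denominators
rather than errors, so batch evaluations do not abort on degenerate folds.
`roc_curve()` sweeps thresholds over unique scores (tied scores step
together) and integrates by trapezoid, which equals the Mann–Whitney
concordant-pair probability with half credit for ties; the test-suite
asserts this equivalence against brute-force pair counting and against an
independent reference implementation.

## The synthetic generator

`simulate_expression()` draws
$y_{pj} = \mu_p + T_{p,\text{class}(j)} + S_j + \varepsilon_{pj}$ with a
per-probe baseline $\mu_p \sim N(0,1)$, a shared per-sample effect
$S_j \sim N(0, \sigma_S^2)$ — the component that induces inter-probe
correlation and keeps LOOCV honest — and i.i.d. Gaussian residuals.
Informative probes carry a class-mean shift of `effect_size` residual
standard deviations, direction random per probe so both up- and
down-regulated markers occur.

Defaults emulate a 130-sample peripheral-blood cohort: 67 cancer / 63
normal samples, 2000 probes, 42 informative, $\sigma_S = 0.5$,
$\sigma = 1$. The default effect size of 1.75 residual sd is the weakest
value (on a 0.25-step grid) at which a `q < 0.01` screen of a 65-sample
training half typically recovers the full 42-marker set, i.e. the weakest
signal consistent with the screen-size geometry the defaults emulate.
`make_fixture()` materialises three canned scenarios: `tiny`
(8 samples x 6 probes, small enough for brute-force oracles), `null` (no
informative probes), and `paper_shaped` (the defaults above).

What the generator does **not** emulate: platform-specific probe
distributions, probe-level correlation beyond the shared sample effect,
heterogeneous per-marker effect sizes, batch structure, or heavy-tailed
noise. Consequences worth stating plainly: because all informative probes
share one effect size and FDR screening is well calibrated on this
generator, the screened marker set is almost perfectly clean, and a
classifier using *all* screened markers is near-ceiling on test data —
the degradation that marker-set pruning repairs on noisy real cohorts is
only partially reproducible here. Passing tests therefore demonstrate
correctness and internal consistency of the procedure, not the magnitude
of its real-data advantage.

## Problem sizes and numerical choices

The test-suite and the acceptance script run entirely on generated data at
desk scale: oracle equivalences on the `tiny` fixture (8 x 6),
parameter-recovery at 40 samples x 5 features over 50 replicates,
pipeline properties on 10 `paper_shaped` runs (130 x 2000), and AUC
equivalence on random instances up to n = 200. Weight-symmetry assertions
use a 1e-6 absolute tolerance (libsvm convergence noise); the primal
reconstruction identity is asserted at 1e-8. Degenerate inputs follow a
flag-not-fail policy wherever a batch caller could hit them (constant
probes, zero within-class variance, empty metric denominators) and an
error policy where continuing would be meaningless (single-class labels,
non-finite values, a leave-one-out fold that would lose a class).

## Known limitations

* No probability calibration, multi-class support, or confidence
  intervals on AUC.
* The squared-slack objective in the method's original formulation is
  replaced by the standard hinge-loss soft margin of libsvm; for these
  data the difference is a reweighting of margin violations and does not
  change the selection machinery, but exact coefficient-level agreement
  with a squared-slack solver should not be expected.
* The enumeration stage's best/worst panels are chosen by test-set AUC and
  are thus optimistically biased; they are reported as published, without
  endorsement of that statistic.
* k-fold variants inside the elimination loop are intentionally absent
  (the loop is defined over leave-one-out folds); k-fold appears only in
  the enumeration stage's training-accuracy estimate.
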