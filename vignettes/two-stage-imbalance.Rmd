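---
title: "Two-stage sampling-based classification with decision fusion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage sampling-based classification with decision fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imbfuse)
```

## The problem and the model

Ensemble docking screens chemicals against many conformations of one
protein; only a minority of conformations bind ("conformational
selection"). Given an $n \times d$ table of whole-protein molecular
descriptors and a binary *active binding* label (class 1 = binds, the
minority; class 0 = does not, the majority), a single classifier trained on
such data inherits the imbalance: it maximizes overall accuracy by leaning
on the majority class, so specificity is high and sensitivity — the number
that matters for triaging conformations worth docking — is low.

The package's answer is a division of labor:

* **Stage 1** fits logistic regression to the original, majority-biased
  training split. It is the true-negative specialist.
* **Stage 2** fits Gaussian naive Bayes or KNN to a *class-inverted*
  training set of the same total size: class 0 randomly undersampled to the
  original class-1 count, class 1 grown to the original class-0 count by
  SMOTE interpolation. The induced minority bias makes it the true-positive
  specialist.
* **Fusion** reconciles both stages on the shared test set through a
  per-sample ledger — reconfirmed TP2, New TP2 (positives stage 1 missed,
  stage 2 caught), New TN2 (the mirror image for negatives) — and reports

  $$\mathrm{TotalAccuracy} = 100\,\frac{TP_1 + TN_1 + \mathrm{New}\,TN_2 +
  \mathrm{New}\,TP_2}{N_{test}},\qquad
  \mathrm{TPacc} = 100\,\frac{TP_1 + \mathrm{New}\,TP_2}{N_{test1}},\qquad
  \mathrm{TNacc} = 100\,\frac{TN_1 + \mathrm{New}\,TN_2}{N_{test0}}.$$

### What "fusion" means here — an honest caveat

"Majority voting" between two voters is undefined, and the ledger above is
the only accounting that generates both the published reconciliation counts
and the fused formulas. It credits a test sample as handled correctly if
*either* stage classifies it correctly — which requires knowing the true
label to decide which stage to trust. The fused metrics are therefore an
optimistic upper bound: an audit of the complementary strengths of the two
stages, useful for triage, not the accuracy of a deployable label-free
rule. For prospective use, `fuse_predictions()` implements the label-free
union rule (predict 1 iff either stage predicts 1); it is deliberately
*not* used when reproducing published-table arithmetic. The algebraic
corollary `TotalAccuracy >= stage-1 accuracy` (the fused numerator adds
non-negative counts to the stage-1 cells) is identity-tested, and on
zero-signal data the fused total accuracy is tested to be statistically
indistinguishable from a label-permutation oracle-OR baseline — fusion is
not magic, it is bookkeeping.

## The classifiers and their numerical choices

**Logistic regression.** The cost is the mean cross-entropy plus an L2
penalty $\frac{1}{2C}\lVert\beta_{1..d}\rVert^2$ on the non-intercept
weights. The source formulation prints the cost without a penalty yet
quotes a hyperparameter $C = 5$; the only standard reading of a scalar $C$
for logistic regression is inverse regularization strength, and that is
what the package implements (intercept unpenalized). Optimization is
deterministic full-batch gradient descent with Armijo backtracking from the
zero vector — no seed dependence; the fit records iterations and whether
the cost-decrease tolerance (`tol`, default 1e-8) or `max_iter` (500)
terminated it. Probabilities use the numerically stable
$\log(1+e^z) = \max(z,0) + \log1p(e^{-|z|})$ form, so scores saturate
without overflow. The decision rule is `probability >= threshold` with
threshold 0.5 (the convention when nothing else is stated).

**Gaussian naive Bayes.** Priors are class frequencies; per-class
per-feature moments use the population divisor $n_{class}$. Variances are
clamped from below by a floor defaulting to $10^{-9}\times$ the largest
per-class feature variance (fallback $10^{-12}$ when everything is
constant), so constant features cannot produce infinite densities.
Posteriors are computed in log space and normalized by log-sum-exp; exact
posterior ties go to class 0. "GB" in the source literature denotes this
Gaussian naive Bayes classifier, not gradient boosting.

**KNN.** Euclidean distance, majority vote. Distance ties break toward the
lower training-row index; vote ties (possible for even `K`) break toward
the label of the single nearest neighbor. `K = 5` by default — the source
never states its value, and 5 is the conventional default shared with
SMOTE. The class-1 vote fraction doubles as the ROC score.

**Standardization.** Real descriptor tables mix physical scales across
orders of magnitude (protein mass next to eccentricity). Distance- and
gradient-based learners (KNN, LR) therefore z-score features on training
statistics by default; Gaussian NB is scale-equivariant and is left raw.
A demonstration test shows the motivating failure: with a feature-scale
spread of 1000 and standardization disabled, KNN sensitivity on 20:1 data
collapses toward zero.

## Resampling

SMOTE restricts neighbor search to minority points (the original
algorithm's choice; the source is silent) and interpolates
$x_{base} + w\,(x_{nn} - x_{base})$, $w \sim U[0,1]$, $x_{nn}$ uniform
among the base's `K = 5` nearest minority neighbors. Synthetic counts that
are not multiples of the minority size assign bases round-robin and draw
the remainder at random — every minority point participates while hitting
the target count exactly. `K` is clamped to $n_{minority}-1$ with a warning
rather than an error. Synthetics are generated in raw feature space (the
source does not say whether standardization preceded SMOTE; raw space is
the choice that keeps the generated points inside the minority bounding
box of the data as stored). A `w` test hook pins the interpolation weight,
so `w = 0` provably duplicates minority rows.

`invert_class_balance` takes class roles from the labels, not the counts,
and warns (returning the input unchanged) if class 1 is not actually the
minority. Published per-class tables confirm the rule "new class-0 count =
old class-1 count and vice versa, total preserved" at every training size —
with one exception: the 20:1 dataset's new-training-set table repeats its
30% row in the 10% slot (41/858 where inversion of 289/10 must give
10/289). The package treats that row as a typographical erratum and
implements the stated rule.

## The split

Training rows are drawn uniformly without replacement, `floor(fraction*n)`
of them — the only convention consistent with all published per-class sums
(299/599/899 at 10/20/30% of 2997). The draw is deliberately
*non-stratified*: the published per-class counts are inconsistent with
stratified sampling, and the binomial drift of per-class counts across
seeds is part of the emulated protocol. A `stratify = TRUE` flag exists for
users who want balance, default off. One dataset-level note: the 3:1
dataset is described as 3000 conformations, but its printed class counts
sum to 850 + 2147 = 2997; the package uses 2997 wherever arithmetic must
balance.

## Metrics

Confusion cells are exact integer counts; accuracy is a percentage,
Se/Sp are fractions, all kept at full precision — display rounding is the
caller's business, because the source tables mix rounding and truncation
(87.655 prints there as 87.6). Zero denominators (a test set with no
positives, or no negatives) return `NA_real_` as an explicit undefined
marker; silent zeros corrupt aggregate tables. ROC curves sweep the unique
scores descending; the trapezoidal AUC is identity-tested against
Mann–Whitney pair counting with half-credit ties. F1 is the standard
$2TP/(2TP+FP+FN)$. For the fused system, published AUC/F1 values are not
asserted against: the construction behind them is unstated (some published
fused AUCs are below 0.5, suggesting a construction the text does not
describe). The report instead computes per-stage AUC plus a clearly
labeled stage-score-average AUC, and F1 from the fused ledger cells; one
published fused F1 (0.968) appears to be a truncation of 186/192 = 0.96875,
which the package would print as 0.969.

## The synthetic generator: what it emulates, what it does not

Real descriptor tables for this problem are available only on personal
request, so the generator is a first-class module, not a fixture. It draws
two multivariate Gaussian classes sharing an equicorrelated covariance
$\Sigma = D\,R\,D$, with per-feature scales $D$ log-spaced over
`feature_scale_spread` and the class-mean difference scaled to a chosen
Mahalanobis norm (`separation`). Class counts are exact (no binomial
sampling of labels), and a `n_minority` override reproduces exact published
counts (850 of 2997; 137 of 2999).

The defaults state the emulated world once: `separation = 1.5` (moderate —
enough signal that stage-1 logistic regression lands in the published
regime of high specificity and low sensitivity on 3:1 data, nowhere near
separable), `feature_scale_spread = 10` and `correlation = 0.1` in the CLI
presets (descriptors share physical drivers, so mild positive correlation
and mixed scales are realistic). These values were fixed before the
acceptance runs and are not tuned to test outcomes.

What a green synthetic test does **not** establish: real descriptor tables
are not Gaussian, not equicorrelated, and their minority class is not a
mean-shifted copy of the majority; published numeric results also depend on
unknown split seeds and solver details, so the synthetic suite checks
*qualitative* behavior (specificity bias of stage 1, the sensitivity lift
of SMOTE-rebalanced stage 2, fusion dominance identities) and *exact
arithmetic* on the published confusion/ledger cells — never the regeneration
of published counts. A `marginal = "lognormal"` option produces
right-skewed features so users can separate algorithm bugs from
Gaussian-model misfit.

## Reproducibility

Every stochastic operation (split, undersampling, SMOTE, generation) takes
an explicit seed and restores the caller's RNG state. `run_two_stage`
derives per-stage seeds from one root seed, so a report is a pure function
of (data, config, seed); the CLI records the full config and seeds in every
artifact it writes.

## Known limitations

* The fused metrics are label-aware by construction (see the caveat above);
  the label-free union rule will show lower, honest numbers.
* Binary classification only; no cross-validation or hyperparameter search.
* KNN is exact O(n_train x n_query); fine for ~3000-row tables.
* Computing molecular descriptors from 3-D structures, MD sampling, and
  docking are out of scope — the package starts at the descriptor table.
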