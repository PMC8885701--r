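---
title: "Worst-case predictive performance over patient subpopulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Worst-case predictive performance over patient subpopulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A clinical risk model that is accurate on average can still perform poorly
for particular patient subpopulations — demographic groups defined by age,
sex, or race and ethnicity — and risk-guided care decisions then
systematically underserve those groups. One response is to train for the
*worst case*: instead of minimizing the average loss, seek the model whose
least-favorable subpopulation performance is as good as possible (minimax
over groups). `groupdro` implements this program end to end for tabular
binary-outcome prediction: the training objectives, the sampling and
early-stopping variations, the worst-case model selection rules, and a
disaggregated evaluation engine, together with a synthetic cohort generator
so everything is testable without access to restricted electronic health
records.

## Model and objectives

Data are triples $(x_i, y_i, a_i)$: features $x \in \mathbb{R}^m$, binary
outcome $y$, and a discrete attribute $a$ partitioning the cohort into $K$
subpopulations. A probabilistic classifier $f_\theta(x) \in (0,1)$ is
trained by minibatch gradient descent (Adam) on the cross-entropy loss
$\ell(y, s) = -[y \log s + (1-y)\log(1-s)]$.

**ERM** minimizes the pooled average loss. **GroupDRO** minimizes the
worst-case mixture loss
$\min_\theta \max_{\lambda \in \Delta^{K-1}} \sum_k \lambda_k \ell_k$,
where $\ell_k$ is the per-group expected loss. The online algorithm
alternates, per minibatch, an exponentiated-gradient ascent step on the
simplex weights,
$\lambda_k \leftarrow \lambda_k e^{\eta \ell_k} / \sum_j \lambda_j e^{\eta \ell_j}$,
with a descent step on $\theta$ targeting $\sum_k \lambda_k \ell_k$. The
rate $\eta$ applies only to the $\lambda$ update; $\theta$ uses the model's
own Adam learning rate. Keeping the two rates separate is deliberate: the
classical presentation writes a single step size for both updates, but the
parameter update here is Adam, so a shared scalar would be meaningless.

Three refinements adjust what "worst" means before groups are compared,
each adding a constant $c_k$ inside the exponent of the $\lambda$ update:

* **reciprocal size**, $c_k = C / p_k$ with $p_k = n_k/N$ — boosts small
  groups, on the theory that they overfit faster;
* **proportional size**, $c_k = C \sqrt{n_k/N}$ — the opposite correction;
* **marginal baseline**, $c_k = q_k \log q_k + (1-q_k)\log(1-q_k)$ with
  $q_k$ the group's outcome incidence — subtracts (by adding its negative
  entropy) the part of the loss that merely reflects incidence, so
  low-incidence groups are not mistaken for well-served ones. The incidence
  can be estimated per minibatch (the default used in training) or
  precomputed from the full training set.

A **metric-steered** variant replaces $\ell_k$ in the $\lambda$ update by an
arbitrary per-group performance measure $g(\mathcal{D}_k, f_\theta)$,
leaving the $\theta$ update unchanged. The provided instance uses
$g_{\mathrm{AUC}} = 1 - \widehat{\mathrm{AUC}}$ with *strict* pairwise
comparisons — tied scores earn no credit. This strictness is intentional
and distinct from the evaluation-side AUC, which uses the conventional
tie value of $1/2$; the two conventions are implemented separately
(`g_auc()` vs `auc()`) and must not be conflated. With $g$ set to the group
loss, the metric variant reproduces the unadjusted update exactly, which
the tests verify bit-for-bit.

Lambda starts uniform at $1/K$ — the only initialization for which
$\eta = 0$ degenerates to balanced loss averaging — and persists across
epochs. Groups absent from a minibatch (possible under pooled sampling) or
whose steering metric is undefined there (a single-class AUC sample) simply
keep their unnormalized weight for that step; nothing is imputed.

## Training, sampling, selection

Each training run uses minibatches of 512, up to 150 epochs of 100
minibatches, and early stopping with patience 25 epochs on a development
fold; the criterion is the population loss, the worst-case group loss, the
worst-case group AUC, or (for DRO) the weighted objective itself. The best
snapshot seen is restored. Improvement is a strict decrease with absolute
tolerance `1e-6`, so floating-point jitter cannot reset patience.

Sampling is either *pooled* (uniform minibatches) or *balanced*:
$\lfloor B/K \rfloor$ indices per group per batch, the remainder assigned
one each to the first $B \bmod K$ groups in vocabulary order, with small
groups resampled (reshuffled with replacement across passes) once
exhausted within an epoch. With-replacement refill is the simplest rule
that keeps every batch's composition exact; whether minority rows repeat
within a batch at extreme imbalance is a knowingly arbitrary tie-break.

Data are split 62.5 / 12.5 / 25 percent into train / validation / test at
the individual level (unstratified by design; group-stratified splitting is
a possible extension), and the training portion into five folds. Every grid
configuration is trained five times, each fold serving once as the
development set, and validation metrics are averaged over the five
replicates before selection. Selection mirrors the stopping criteria:
overall loss (the standard rule, used for pooled ERM), worst-case group
loss, or worst-case group AUC, with exact ties resolved by grid order.
The experiment runner enforces the two-stage design: model-class
hyperparameters are chosen by pooled ERM first and held fixed for all DRO
and balanced-sampling runs. Stratified ERM runs the whole pipeline per
group, selecting on that group's own validation loss.

## Evaluation

Test-set metrics are the tie-aware AUC, the mean cross-entropy loss, and
the absolute calibration error (ACE): a one-covariate logistic model is fit
on the evaluation data predicting the outcome from the *natural log* of the
score, and ACE is the mean absolute gap between the scores and the fitted
curve. Reading "log-transformed outputs" as `log(score)` follows the
defining text literally; since the recalibration literature more often uses
the logit, a `transform = "logit"` switch is exposed for sensitivity. The
log and logit transforms nearly coincide at low incidence, so the choice
matters mainly when scores span the full unit interval. ACE differs from
local-regression calibration indices precisely by using a logistic
recalibration fit; no local smoother is involved.

Confidence intervals use the stratified percentile bootstrap: resampling
within each outcome-by-group stratum preserves stratum counts exactly; each
metric is computed for each of the model replicates on each of the $B$
bootstrap samples; the 2.5/97.5 percent quantiles (linear interpolation
between order statistics — the most common convention, fixed here for
reproducibility) of the pooled $5B$ values form the interval. Paired
differences against a reference model reuse the same bootstrap indices, and
the worst-case interval takes the worst case within each (sample,
replicate) before pooling. Groups with an empty test stratum or a
single-class sample yield flagged missing values rather than guesses.
Simulation at $n = 2000$, $B = 200$ puts the realized coverage of the 95%
AUC interval a point or two below nominal — the familiar small-sample
behavior of percentile intervals — which is worth remembering when reading
the reports.

## The synthetic cohort generator

Real inpatient and intensive-care cohorts are access-restricted, so the
generator emulates their statistical structure: $K$ disjoint groups with
unequal fractions (single-digit percent to a majority), low outcome
incidences (down to a fraction of a percent), group-specific Gaussian
features (identity covariance by default, keeping the group-wise
Bayes-optimal predictor logistic in $x$), group-specific logistic outcome
models, and optional label noise below $1/2$. Intercepts are pre-solved by
1-D root finding on a Monte-Carlo estimate ($10^5$ draws) of the marginal
incidence, so empirical incidences match their targets to binomial error.
Each group consumes an independent, named substream of the master seed, and
feature matrices are filled row-major, so adding a group or resizing the
cohort never perturbs another group's draws.

`conflict_scenario()` constructs the regime where worst-case training
provably matters: two groups with identical feature distributions,
incidence 1/2, and exactly opposite true coefficient vectors (norm 1.5 by
default, a strong but realistic signal). A single linear model cannot serve
both; the pooled optimum tracks the majority and is worse than chance on
the minority, while GroupDRO retreats toward the loss-equalizing predictor.
What the generator does *not* emulate — longitudinal structure, informative
missingness, feature correlation with group membership, measurement
drift — bounds what passing tests say about real records: they validate the
optimization and inference machinery, not clinical transportability.

## Numerical choices

* Scores are clipped to $[\varepsilon, 1-\varepsilon]$, $\varepsilon =
  10^{-7}$, before any logarithm (losses, ACE transform, degenerate
  minibatch incidences in the entropy baseline).
* The $\lambda$ update subtracts the maximal exponent before
  exponentiating; the uniform rescaling cancels in the normalization, so
  overflow is impossible and the simplex is preserved to $10^{-9}$ over
  $10^4$-step random sequences (tested).
* Group vocabulary order (schema-declared or sorted-unique) is fixed at
  cohort construction and indexes $\lambda$, adjustments, batches and
  reports everywhere; determinism depends on it.
* Parameters initialize Glorot-uniform with zero biases from a named seed;
  hidden activations are rectifiers; dropout is inverted (scaled at train
  time) and disabled in every evaluation pass.
* Weight decay applies to the logistic family only, as an L2 term added to
  the gradient; feedforward networks regularize via dropout only.
* CSV round trips are bit-exact: features are written as `%.17g` and parsed
  with base R's correctly-rounded `strtod`.

## Problem sizes used in the tests

The shipped test-and-verification suite runs the study design at desk
scale, chosen once as sizes at which every qualitative property is already
stable: cohorts of $10^3$–$2\times10^4$ individuals ($10^5$ for the
incidence-calibration and ACE-consistency checks), logistic models with
Adam learning rates 0.02–0.05, and 3–12 epochs of 6–40 minibatches rather
than the full $150 \times 100 \times 512$ defaults, which remain the
package defaults for real use. The group-conflict benchmark uses minority
fraction 0.1 at $n = 20000$ over five seeds; bootstrap coverage is assessed
with 200 simulation repeats at $n = 2000$, $B = 200$.

## Known limitations

* The trainer targets desk-scale tabular problems; it is plain R linear
  algebra, adequate for logistic models and small feedforward networks, not
  for sequence models over temporal ICU data (out of scope here).
* Worst-case comparisons across groups inherit the conceptual caveats
  discussed above for the loss (incidence-driven) and the AUC
  (within-group ranking only); the adjustments mitigate, not resolve, them.
* The bootstrap treats the five replicate models as fixed; variability from
  retraining is reflected only through pooling their metric values.
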