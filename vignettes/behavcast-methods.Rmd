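---
title: "Forecasting next-day seizures and high-risk behaviors from daily behavior diaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting next-day seizures and high-risk behaviors from daily behavior diaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In residential care settings for individuals with profound autism,
direct-care staff record challenging behaviors (aggression,
self-injurious behavior, elopement, agitation, and so on) across three
daily shifts, and medical staff log seizure episodes. A clinically
useful question is whether tomorrow's high-risk event — a seizure, or a
high-risk behavior — can be anticipated from the recent pattern of
recorded behaviors, giving caregivers time to act.

`behavcast` implements that analysis end to end as a per-subject
supervised learning problem:

1. **Featurization.** The seven most prevalent behavior categories
   across the cohort are kept as named features; everything else is
   bucketed as *Other*, giving 8 binary features per day (a record in
   any shift counts as presence — an OR, not a count). For the seizure
   task a ninth binary row encodes seizure history. A sample is a
   `features x w` window (`w` = 7 or 14 days) labeled by the target
   event's presence on the day immediately after the window.
2. **Model.** One small convolutional network per subject (below),
   trained on the chronologically earliest 80% of that subject's
   windows and evaluated on the remaining 20%.
3. **Inference.** A prevalence-aware permutation test per subject, the
   delta-accuracy effect size, and cohort-level macro/micro summaries.
4. **Attribution.** First-layer Grad-CAM heatmaps over the
   `feature x day-offset` grid, aggregated across windows and subjects.

Because real care-facility diaries cannot be redistributed, the package
ships a synthetic cohort generator with the same file formats and known
ground-truth dynamics; every downstream claim is validated against it.

## The classifier

Each subject's model is a two-block 2-D CNN operating on the binary
window (features as rows, days as columns):

* conv 3x3, 32 filters, ReLU; batch normalization; max-pool 2x2;
* conv 2x2, 64 filters, ReLU; batch normalization; max-pool 2x2;
* dense 64, ReLU; dropout 0.5; dense 1, sigmoid.

Training uses Adam (learning rate $10^{-3}$), batch size 32, binary
cross-entropy, exactly 50 epochs, no early stopping and no validation
split. The implementation is native R/C++ (im2col convolutions with a
fused compiled training step); gradients of every layer are verified
against central finite differences in the test suite, and a per-layer
reference path in R is asserted to agree with the fused step to
machine precision.

Two numerical conventions deserve note, since the architecture's layer
arithmetic does not otherwise close for a 7-day window:

* **Padding.** Convolutions use *same-size* padding (the extra pad
  row/column of an even kernel goes to the bottom/right). With valid
  padding, the second pooling stage would degenerate for `w = 7`.
* **Pooling.** Max-pooling uses non-overlapping 2x2 regions with floor
  division, clamped to one region when a dimension is already 1. An
  `8 x 7` input therefore flattens to `2 x 1 x 64 = 128` units and an
  `8 x 14` input to `2 x 3 x 64 = 384`.

Ties in max pooling route to the first cell in region order (the usual
framework convention); at exact ties the loss is not differentiable and
any subgradient is valid, which is why the finite-difference tests use
continuous inputs. Batch normalization uses population batch statistics
with variance epsilon $10^{-3}$ and running-average momentum 0.9: a
momentum of 0.99 needs on the order of a thousand optimizer steps before
the running statistics reflect the data, but a per-subject fit here
takes 60–750 steps, and with unconverged running statistics
inference-mode predictions disagree wildly with training-mode behavior
on the very same data. Momentum 0.9 converges within ~50 steps and
removes that inconsistency. Adam uses the standard defaults
($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$). Dropout is active only in training mode, so
inference is deterministic. All stochastic steps (initialization,
shuffling, dropout) are pinned by a seed; per-subject seeds derive
deterministically from the run's master seed. Same-platform
reproducibility is asserted; cross-platform bit equality is not
promised.

## The significance test and effect size

Accuracy is compared against *prevalence-aware guessing*: the test
labels are permuted $m = 10^4$ times (class frequencies are preserved
automatically), the fixed hard predictions are rescored against each
permutation, and

$$p = \Pr(A \ge a) = |\{b \in A : b \ge a\}| / m,$$

with rejection at $p < 0.05$. No $+1$ smoothing is applied, so $p$ can
be exactly zero; this matches the definition above and is asserted in
the tests. The effect size is
$\Delta\mathrm{accuracy} = a - \mathrm{mean}(A)$. The permutation acts
on hard predicted labels only — accuracy needs nothing else — and the
null mean has the closed form

$$E[A] = \frac{\hat p k + (n - \hat p)(n - k)}{n^2},$$

where $\hat p$ is the number of predicted positives and $k$ the number
of true positives among $n$ test samples; `expected_null_accuracy()`
implements it and the Monte-Carlo mean is checked against it (and
against exhaustive enumeration for $n \le 8$).

Cohort summaries report macro metrics (per-subject mean ± SD;
population SD by default, configurable — the convention is a reporting
choice, not a modeling one), micro metrics from the pooled confusion
matrix (micro F1 is the positive-class F1 of the pooled table), the
significance count as "X from N", and delta-accuracy mean ± SD.
AUROC/AUPRC are undefined for single-class test sets and are excluded
from macro averages with an exclusion count; such subjects keep their
accuracy, F1 and permutation results. No multiple-testing correction is
applied across subjects.

## Grad-CAM on the first layer

Attribution targets the *first* convolutional layer, so the heatmap
aligns cell-for-cell with the input grid (same-size padding makes the
first-layer maps input-shaped, hence no upsampling). For the positive
class, the class score $Y$ is the pre-sigmoid logit — "class score" is
interpreted as the logit rather than the probability, which only
rescales gradients monotonically. With $A^k$ the post-ReLU feature map
of filter $k$:

$$\alpha_k = \frac{1}{Z}\sum_{i,j} \frac{\partial Y}{\partial A^k_{ij}},
\qquad L = \mathrm{ReLU}\Big(\sum_k \alpha_k A^k\Big).$$

Flipping the class sign negates the pre-ReLU map exactly (asserted).
Cohort aggregation averages maps cell-wise over all test windows and
subjects; each map is max-normalized first by default so subjects with
larger logits do not dominate. Rankings are by aggregated row sums
(per-feature) and per-column orderings (per day offset). Aggregating
over all test windows, rather than positive predictions only, is the
default and is configurable.

## The synthetic cohort generator

The generator is a lagged logistic model chosen as the minimal process
exhibiting the three structures the analysis assumes: day-to-day
persistence, cross-behavior coupling, and a weekly cycle. Behavior $b$
of subject $s$ on day $t$ is Bernoulli with

$$\mathrm{logit}\, p_{b,t} = \beta_{0,b} + \rho_b x_{b,t-1} +
\sum_{b'} C_{b,b'} x_{b',t-1} +
a_b \cos(2\pi t / 7 + \varphi_s),$$

and the target event (a behavior or a seizure) follows its own
logistic model driven by the preceding window,
$\mathrm{logit}\, p_t = \beta_0 + \sum_{f,\ell} \beta_{f,\ell}
x_{f,t-\ell}$, so the predictable signal is planted with known
strength. Defaults, chosen once as realistic study conditions: nine
behavior categories with daily prevalences between 0.10 and 0.40,
logit autocorrelation 0.8, weekly amplitude 0.3 with uniformly random
per-subject phase, uniform shift placement, severe-event fraction 0.2
(an i.i.d. mark on target-behavior events; no severity dynamics), and
a 14-day burn-in discarded before emission so the emitted series is
approximately stationary. Day one of the simulation uses baseline
logits only. Each daily occurrence is emitted in exactly one shift;
featurization ORs over shifts, so multi-shift duplication would be
label-invariant anyway.

What the generator does *not* emulate: seizure durations and recovery
times, within-day event counts, demographic structure, recording gaps
or staff-compliance drift, and any non-stationarity beyond the weekly
cycle. Passing tests on this cohort therefore demonstrate that the
pipeline recovers the structure it models — not that real diaries
contain such structure.

## Validation design, problem sizes, and what the studies show

The validation suite (also recomputed by `scripts/acceptance.R`) runs
four studies, sized to be informative at desk scale. The 10-epoch
schedule used in the simulation studies is a deliberately reduced
surrogate of the 50-epoch default (the separable and entropy-bound unit
tests exercise the full schedule directly).

* **Permutation exactness** (passes). 100 random prediction/label
  cases with $n \le 8$: Monte-Carlo $p$ and null mean agree with
  exhaustive enumeration within Monte-Carlo error (with ~200
  three-sigma comparisons, a fraction of a percent of exceedances is
  expected by chance and allowed for); 100 cases with $n$ up to 200
  agree with the closed-form null mean.
* **Type-I behavior** (valid; more conservative than nominal). 200
  subjects, 120 days each, target coupling zero and a balanced event
  rate, full pipeline at 10 epochs. Mean delta-accuracy is within
  $\pm 0.02$ of zero, confirming the effect size is unbiased under the
  null. The rejection rate at $\alpha = 0.05$, however, is essentially
  zero rather than near-nominal: the inclusive-tie $p = \Pr(A \ge a)$
  on a discrete accuracy support is stochastically larger than uniform
  (an exact hypergeometric computation gives a ceiling of about 0.02
  at test sets of 23 windows even for ideal label-independent
  predictions), and a CNN trained on null labels adds to this by
  producing constant or heavily imbalanced predictions, for which $p$
  is 1 or near 1. The test never inflates type-I error; at small test
  sets it is strongly conservative. Users should read "not significant"
  accordingly.
* **Planted-effect recovery** (negative result, retained as such). 60
  subjects, 600 days, coupling $\beta = 3$ from Disruptive Behavior
  (lag 1) into a seizure target at baseline prevalence 0.25 — a signal
  a logistic regression on the same windows detects with test accuracy
  around 0.7–0.87. The CNN does not recover it: across replicate
  cohorts almost no subjects reach significance and delta-accuracy
  stays near zero, at any epoch count and at both window lengths. The
  cause is architectural, not an implementation defect (the
  implementation is verified cell-by-cell against a direct convolution,
  by finite differences for every parameter group, and by an
  independent per-layer reference path that matches the fused training
  step to machine precision over entire fits). After two 2x2 pools a
  7-day window collapses to a single column and two row-cells, erasing
  the position information a single-(feature, lag) rule lives on;
  weight sharing further dilutes cell-specific gradients across all
  positions. On *spatially distributed* signals (e.g. recent overall
  behavioral load) the same network learns readily, and on a local
  motif task it outperforms a same-size multilayer perceptron — the
  architecture's inductive bias simply does not match pinpoint
  single-cell rules. Consequently the Grad-CAM aggregation cannot rank
  the planted driver first either (its finite-difference correctness
  and non-negativity are verified independently and pass). This is a
  finding about the architecture worth knowing before interpreting
  attribution maps on real data: features whose predictive content is
  concentrated in a single cell of the window are the ones this model
  class is most likely to miss.
* **Determinism** (passes). Identical configuration and seed reproduce
  the serialized cohort report exactly.

## Open choices made here

* The 80/20 split is over windows ordered by label date; train-window
  *inputs* may extend toward the boundary, but train and test label
  days are disjoint and ordered, which is the leakage property that
  matters for next-day evaluation and is property-tested.
* "Prevalence" for top-7 selection means record count (not subject
  count); ties break lexicographically and the counts are stored in the
  returned `category_map` for reproducibility.
* When the target behavior is not among the top 7, labels are computed
  from the raw diary, not from the *Other* row, so bucketing never
  corrupts labels; severe-event relabeling works the same way.
* Subjects with fewer than 5 windows are skipped and listed in the run
  report rather than silently dropped.
* Calendar gaps in observation are handled by windowing each subject's
  gap-free range; the generator emits gap-free ranges, so segmented
  windowing is exercised only trivially here.

## Limitations

Binary daily presence discards frequency and intensity within a day;
absence of a record is treated as absence of behavior, which is
defensible under continuous staffing but wrong for unobserved periods;
per-subject models need months of diary data before the 80/20 split
yields a usable test set; and nothing here supports causal or
biological claims about preictal behavior — the pipeline measures
predictability, not mechanism.
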