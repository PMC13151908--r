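# behavcast

Per-subject forecasting of next-day seizure episodes and high-risk
behaviors (aggression, self-injurious behavior, elopement) from daily
binary behavior vectors derived from shift-level care diaries — the
kind of data direct-care staff collect continuously in residential
settings for individuals with profound autism.

The package implements the full analysis as a tested pipeline:

* **Featurization** — the top-7 most prevalent behavior categories plus
  an *Other* bucket give an 8-entry binary vector per day (presence in
  any of the three shifts, an OR not a count); a 9th row encodes
  seizure history for the seizure task. Samples are `features x w`
  windows (`w` = 7 or 14 days) labeled by the target event on the next
  day, split 80/20 chronologically per subject.
* **Model** — one small CNN per subject: conv 3x3/32 + ReLU + batch
  norm + max-pool 2x2, conv 2x2/64 + ReLU + batch norm + max-pool 2x2,
  dense 64 + ReLU, dropout 0.5, sigmoid output; Adam, batch 32, binary
  cross-entropy, 50 epochs. Implemented natively in R with compiled
  (Rcpp/RcppArmadillo) inner kernels; every gradient is verified
  against finite differences in the test suite.
* **Inference** — per-subject prevalence-aware permutation test:
  `p = Pr(A >= a)` where `A` collects the accuracies of the fixed
  predictions against `m = 10^4` permutations of the test labels,
  with the effect size `delta accuracy = a - mean(A)`. The null mean
  has the closed form `(p̂·k + (n−p̂)·(n−k)) / n²` for `p̂` predicted
  and `k` true positives among `n` test windows. Cohort reports give
  macro (per-subject mean ± SD) and micro (pooled confusion) metrics
  and the significance count.
* **Attribution** — Grad-CAM on the *first* convolutional layer
  (`alpha_k = (1/Z) Σ ∂Y/∂A^k`, `L = ReLU(Σ alpha_k A^k)`), so heatmaps
  align 1:1 with the `feature x day-offset` input grid, aggregated
  across windows and subjects.
* **Synthetic cohorts** — real care-facility diaries are private, so a
  generator produces multi-subject diaries and seizure logs from a
  lagged logistic model with day-to-day persistence, cross-behavior
  coupling, a 7-day cycle, and a target process whose next-day
  probability depends on the preceding window with known strength;
  ground truth is emitted alongside for end-to-end validation.

## Worked example

```r
library(behavcast)

cfg <- cohort_config(n_subjects = 8, n_days = 365, seed = 42)
coh <- generate_cohort(cfg)
head(coh$diary, 3)
#>   subject_id       date     shift            behavior severe
#> 1       S001 2023-01-01   morning Disruptive Behavior  FALSE
#> 2       S001 2023-01-01 afternoon           Elopement  FALSE
#> 3       S001 2023-01-01   morning                 SIB  FALSE

run <- run_pipeline(run_config(coh$diary, target = "seizure",
                               seizures = coh$seizures, window_days = 7,
                               spec = model_spec(epochs = 10), seed = 7))
print(run)
#> behavcast run — target 'seizure', 7-day windows (hash 1829506b)
#> Cohort report — 8 subjects
#>   macro accuracy: 0.620 +/- 0.063 (n=8)
#>   macro F1:       0.203 +/- 0.123 (n=8)
#>   macro AUROC:    0.550 +/- 0.056 (n=8)
#>   micro accuracy: 0.620  micro F1: 0.215
#>   significance (p < 0.05): 0 from 8
#>   delta accuracy: 0.019 +/- 0.031 (n=8)
```

Reading this: each of the 8 subjects got their own CNN trained on the
earliest 80% of their 7-day windows; `macro accuracy` is the mean ± SD
of per-subject held-out accuracy; `significance` counts subjects whose
accuracy beat their prevalence-aware permutation null at p < 0.05 (none
here — the default generator plants only a weak own-history coupling,
and the permutation test is deliberately conservative); `delta
accuracy` is the mean gain over prevalence-aware guessing. Per-subject
detail and the aggregated Grad-CAM map ride along:

```r
print(run$results[["S001"]]$perm)
#> Permutation test: a = 0.542, null mean = 0.562 (m = 10000)
#>   p = 0.9011, delta accuracy = -0.020

round(unclass(run$importance)[, 5:7], 3)   # last three day offsets
#>                       day
#> feature                Day -3 Day -2 Day -1
#>   Disruptive Behavior   0.214  0.217  0.160
#>   Aggression            0.236  0.229  0.164
#>   ...
```

The closed-form null mean is exposed directly:

```r
expected_null_accuracy(c(1, 1, 0, 0), c(1, 1, 0, 0))
#> [1] 0.5
```

A thin command-line driver ships in `inst/cli/`:

```sh
inst/cli/behavcast simulate --out cohort/ --seed 1
inst/cli/behavcast run --diary cohort/diary.csv \
    --seizures cohort/seizures.csv --target seizure \
    --window-days 7 --m 10000 --seed 7 --out results/
```

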