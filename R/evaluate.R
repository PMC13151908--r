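# Per-subject and cohort evaluation: accuracy, positive-class F1, AUROC,
# AUPRC, the prevalence-aware permutation significance test, its
# closed-form null mean, the delta-accuracy effect size, and macro/micro
# cohort summaries.

auroc_rank <- function(probs, labels) {
  pos <- labels == 1
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(probs)                        # mid-ranks handle ties
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

auprc_step <- function(probs, labels) {
  np <- sum(labels == 1)
  if (np == 0 || np == length(labels)) return(NA_real_)
  ord <- order(probs, decreasing = TRUE)
  p_s <- probs[ord]; y_s <- labels[ord]
  # group tied scores so a tie block contributes a single operating point
  last <- cumsum(rle(p_s)$lengths)
  ctp <- cumsum(y_s)[last]
  cn <- last
  recall <- ctp / np
  precision <- ctp / cn
  sum(diff(c(0, recall)) * precision)
}

#' Per-subject test-set metrics
#'
#' Hard predictions are `probs >= threshold`. F1 is the positive-class F1;
#' AUROC and AUPRC use rank-based integration (mid-ranks for ties) and
#' are undefined (`NA`) when the test labels are single-class, in which
#' case they are excluded from macro averages downstream.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary ground-truth labels, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class `subject_metrics`: `accuracy`, `f1`,
#'   `auroc`, `auprc`, `confusion` (2x2 counts, predicted x truth),
#'   `pred_labels`, `n_test`.
#' @export
subject_metrics <- function(probs, labels, threshold = 0.5) {
  if (length(probs) == 0) stop_bc("empty input")
  if (length(probs) != length(labels)) stop_bc("length mismatch")
  if (!is_binary(labels)) stop_bc("labels must be binary")
  labels <- as.integer(labels)
  preds <- as.integer(probs >= threshold)
  tp <- sum(preds == 1 & labels == 1)
  fp <- sum(preds == 1 & labels == 0)
  fn <- sum(preds == 0 & labels == 1)
  tn <- sum(preds == 0 & labels == 0)
  confusion <- matrix(c(tn, fp, fn, tp), 2, 2,
                      dimnames = list(predicted = c("0", "1"),
                                      truth = c("0", "1")))
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  structure(list(accuracy = (tp + tn) / length(labels),
                 f1 = f1,
                 auroc = auroc_rank(probs, labels),
                 auprc = auprc_step(probs, labels),
                 confusion = confusion,
                 pred_labels = preds,
                 n_test = length(labels)),
            class = "subject_metrics")
}

#' Closed-form mean of the permutation null accuracy
#'
#' For fixed hard predictions with `p_hat` predicted positives against a
#' uniformly permuted label vector with `k` true positives out of `n`,
#' the expected accuracy is `(p_hat * k + (n - p_hat) * (n - k)) / n^2` —
#' exactly the mean of the label-permutation distribution, i.e. the
#' accuracy of prevalence-aware guessing.
#'
#' @param pred_labels Hard 0/1 predictions.
#' @param labels Binary labels, same length.
#' @return Expected null accuracy in \[0, 1\].
#' @export
expected_null_accuracy <- function(pred_labels, labels) {
  if (length(pred_labels) != length(labels)) stop_bc("length mismatch")
  n <- length(labels)
  p_hat <- sum(pred_labels == 1)
  k <- sum(labels == 1)
  (p_hat * k + (n - p_hat) * (n - k)) / n^2
}

#' Prevalence-aware permutation significance test
#'
#' Compares the observed test accuracy `a` against the null distribution
#' `A` obtained by scoring the fixed hard predictions against `m` uniform
#' random permutations of the label vector (class frequencies are
#' preserved automatically). The p-value is the plain proportion
#' `p = |{b in A : b >= a}| / m` with no smoothing, so it can be exactly
#' 0. The effect size is `delta_accuracy = a - mean(A)`, the gain over
#' prevalence-aware guessing.
#'
#' @param pred_labels Hard 0/1 predictions.
#' @param labels Binary labels, same length.
#' @param m Number of permutations (default `1e4`).
#' @param seed Optional seed for the permutation draws.
#' @param keep_null Keep the full null vector `A` (default summary only).
#' @return An object of class `permutation_result`: `a`, `p`,
#'   `delta_accuracy`, `null_mean`, `null_sd`, `m`, `n`, `seed`, and
#'   optionally `null`.
#' @export
permutation_test <- function(pred_labels, labels, m = 1e4, seed = NULL,
                             keep_null = FALSE) {
  if (m < 1) stop_bc("'m' must be >= 1")
  if (length(pred_labels) != length(labels)) stop_bc("length mismatch")
  if (!is_binary(labels) || !is_binary(pred_labels))
    stop_bc("predictions and labels must be binary")
  m <- as.integer(m)
  preds <- as.integer(pred_labels)
  labels <- as.integer(labels)
  a <- mean(preds == labels)
  A <- with_seed(seed,
    vapply(seq_len(m),
           function(i) mean(preds == sample(labels)), numeric(1)))
  structure(list(a = a,
                 p = mean(A >= a - 1e-12),
                 delta_accuracy = a - mean(A),
                 null_mean = mean(A),
                 null_sd = stats::sd(A),
                 m = m,
                 n = length(labels),
                 seed = seed,
                 null = if (keep_null) A else NULL),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: a = %.3f, null mean = %.3f (m = %d)\n",
              x$a, x$null_mean, x$m))
  cat(sprintf("  p = %.4g, delta accuracy = %+.3f\n", x$p,
              x$delta_accuracy))
  invisible(x)
}

msd <- function(x, sd_type) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(mean = NA_real_, sd = NA_real_, n = 0))
  s <- if (length(x) == 1) 0
       else if (sd_type == "population")
         sqrt(mean((x - mean(x))^2))
       else stats::sd(x)
  c(mean = mean(x), sd = s, n = length(x))
}

#' Aggregate per-subject results into a cohort report
#'
#' Macro metrics are the mean and SD of per-subject values (population
#' SD by default; undefined AUROC/AUPRC are excluded with a count).
#' Micro metrics come from the elementwise-pooled confusion matrix.
#' Significance is the number of subjects with permutation p below
#' `alpha`, reported as "X from N", alongside the mean and SD of
#' delta-accuracy.
#'
#' @param results List of per-subject results; each element is a list
#'   with `subject_id`, `metrics` (a `subject_metrics`) and `perm`
#'   (a `permutation_result`).
#' @param alpha Significance level (default 0.05).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return An object of class `cohort_report`.
#' @export
cohort_report <- function(results, alpha = 0.05,
                          sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!length(results)) stop_bc("at least one subject result required")
  get_m <- function(f) vapply(results, function(r) f(r$metrics), numeric(1))
  acc <- get_m(function(m) m$accuracy)
  f1 <- get_m(function(m) m$f1)
  auroc <- get_m(function(m) m$auroc)
  auprc <- get_m(function(m) m$auprc)
  delta <- vapply(results, function(r) r$perm$delta_accuracy, numeric(1))
  pvals <- vapply(results, function(r) r$perm$p, numeric(1))
  pooled <- Reduce(`+`, lapply(results, function(r) r$metrics$confusion))
  tn <- pooled[1, 1]; fp <- pooled[2, 1]; fn <- pooled[1, 2]
  tp <- pooled[2, 2]
  micro_acc <- (tp + tn) / sum(pooled)
  micro_f1 <- if (2 * tp + fp + fn == 0) NA_real_
              else 2 * tp / (2 * tp + fp + fn)
  n_sig <- sum(pvals < alpha)
  structure(list(n_subjects = length(results),
                 subject_ids = vapply(results, function(r)
                   r$subject_id %||% NA_character_, character(1)),
                 macro = list(accuracy = msd(acc, sd_type),
                              f1 = msd(f1, sd_type),
                              auroc = msd(auroc, sd_type),
                              auprc = msd(auprc, sd_type)),
                 n_undefined_auroc = sum(is.na(auroc)),
                 n_undefined_auprc = sum(is.na(auprc)),
                 micro = list(accuracy = micro_acc, f1 = micro_f1,
                              confusion = pooled),
                 significance = list(n_significant = n_sig,
                                     alpha = alpha,
                                     label = sprintf("%d from %d", n_sig,
                                                     length(results))),
                 delta_accuracy = msd(delta, sd_type),
                 p_values = pvals,
                 sd_type = sd_type),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  fmt <- function(m) sprintf("%.3f +/- %.3f (n=%d)", m["mean"], m["sd"],
                             m["n"])
  cat("Cohort report —", x$n_subjects, "subjects\n")
  cat("  macro accuracy:", fmt(x$macro$accuracy), "\n")
  cat("  macro F1:      ", fmt(x$macro$f1), "\n")
  cat("  macro AUROC:   ", fmt(x$macro$auroc),
      if (x$n_undefined_auroc)
        sprintf("(%d undefined excluded)", x$n_undefined_auroc) else "",
      "\n")
  cat(sprintf("  micro accuracy: %.3f  micro F1: %.3f\n",
              x$micro$accuracy, x$micro$f1))
  cat(sprintf("  significance (p < %.2f): %s\n", x$significance$alpha,
              x$significance$label))
  cat("  delta accuracy:", fmt(x$delta_accuracy), "\n")
  invisible(x)
}
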