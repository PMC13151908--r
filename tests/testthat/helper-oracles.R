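# Independent oracles and small fixture builders used across tests.

# Exhaustive permutation-null oracle: enumerate every distinct label
# arrangement (uniform over C(n, k) by symmetry of uniform permutations)
# and score the fixed predictions against each.
exact_perm_null <- function(preds, labels) {
  n <- length(labels)
  k <- sum(labels == 1)
  sets <- utils::combn(n, k)
  accs <- apply(sets, 2, function(pos) {
    lab <- integer(n)
    lab[pos] <- 1L
    mean(preds == lab)
  })
  a <- mean(preds == labels)
  list(a = a,
       p = mean(accs >= a - 1e-12),
       mean = mean(accs),
       sd = sqrt(mean((accs - mean(accs))^2)))
}

# Build a daily_matrix directly from a values matrix (rows = features).
toy_daily_matrix <- function(values, subject_id = "S001",
                             start = as.Date("2023-01-01")) {
  dates <- start + seq_len(ncol(values)) - 1L
  colnames(values) <- as.character(dates)
  structure(list(subject_id = subject_id, dates = dates,
                 values = values),
            class = "daily_matrix")
}

# Diary with exact per-behavior record counts (one record per day each).
diary_with_counts <- function(counts, subject_id = "S001") {
  beh <- rep(names(counts), counts)
  data.frame(subject_id = subject_id,
             date = as.Date("2023-01-01") + seq_along(beh) - 1L,
             shift = "morning", behavior = beh, severe = FALSE,
             stringsAsFactors = FALSE)
}

# Separable two-point training problem: identical positive windows vs
# identical (distinct) negative windows.
separable_windows <- function(n_each = 20, H = 8, W = 7) {
  pos <- matrix(0L, H, W); pos[1, ] <- 1L
  neg <- matrix(0L, H, W)
  x <- array(0L, c(H, W, 2 * n_each))
  for (i in seq_len(n_each)) x[, , i] <- pos
  y <- c(rep(1L, n_each), rep(0L, n_each))
  list(x = x, y = y)
}

# Independent shape oracle: clamped floor-halving applied twice.
pool_dims_oracle <- function(H, W) {
  h1 <- max(1L, H %/% 2L); w1 <- max(1L, W %/% 2L)
  as.integer(c(max(1L, h1 %/% 2L), max(1L, w1 %/% 2L)))
}

calib_cohort_config <- function(n_subjects, n_days, seed,
                                target_base_logit = 0) {
  nb <- length(default_behavior_catalogue())
  beta0 <- matrix(0, nb + 1, 1,
                  dimnames = list(c(default_behavior_catalogue(),
                                    "seizure"), NULL))
  cohort_config(n_subjects = n_subjects, n_days = n_days,
                target_name = "seizure",
                target_base_logit = target_base_logit,
                target_coupling = beta0, seed = seed)
}

# Strong lag-1 coupling from one behavior into a seizure target; the
# planted predictive feature for recovery tests.
effect_cohort_config <- function(n_subjects, n_days, seed,
                                 driver = "Disruptive Behavior",
                                 beta = 3) {
  nb <- length(default_behavior_catalogue())
  bmat <- matrix(0, nb + 1, 1,
                 dimnames = list(c(default_behavior_catalogue(),
                                   "seizure"), NULL))
  bmat[driver, 1] <- beta
  cohort_config(n_subjects = n_subjects, n_days = n_days,
                target_name = "seizure",
                target_base_logit = stats::qlogis(0.25),
                target_coupling = bmat, seed = seed)
}
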