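# Synthetic cohort generator: determinism, degenerate limits, marginal
# rates, autocorrelation and weekly structure.

test_that("identical config and seed reproduce the cohort byte-for-byte", {
  cfg <- cohort_config(n_subjects = 3, n_days = 40, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$diary, b$diary)
  expect_identical(a$seizures, b$seizures)
  expect_identical(a$ground_truth$states, b$ground_truth$states)

  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in c("diary.csv", "seizures.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("emitted diary is structurally valid", {
  coh <- generate_cohort(cohort_config(n_subjects = 4, n_days = 60,
                                       seed = 2))
  d <- coh$diary
  expect_named(d, c("subject_id", "date", "shift", "behavior", "severe"))
  expect_false(anyDuplicated(d[c("subject_id", "date", "shift",
                                 "behavior")]) > 0)
  expect_true(all(d$shift %in% c("morning", "afternoon", "overnight")))
  expect_true(all(coh$seizures$subject_id %in% d$subject_id))
  # with a seizure target no behavior is the target, so no severe marks
  expect_true(all(!d$severe))

  coh_b <- generate_cohort(cohort_config(n_subjects = 4, n_days = 60,
                                         target_name = "Aggression",
                                         severe_frac = 0.5, seed = 2))
  db <- coh_b$diary
  expect_true(all(db$behavior[db$severe] == "Aggression"))
  expect_gt(sum(db$severe), 0)
  expect_identical(nrow(coh_b$seizures), 0L)
})

test_that("degenerate probabilities give empty and saturated cohorts", {
  cfg <- cohort_config(n_subjects = 2, n_days = 20, base_logit = -Inf,
                       autocorr = 0, weekly_amp = 0,
                       target_base_logit = -Inf,
                       target_coupling = matrix(0, 9, 1,
                         dimnames = list(default_behavior_catalogue())),
                       seed = 1)
  coh <- generate_cohort(cfg)
  expect_identical(nrow(coh$diary), 0L)
  expect_identical(nrow(coh$seizures), 0L)

  base <- rep(-Inf, 9); base[1] <- Inf
  cfg2 <- cohort_config(n_subjects = 3, n_days = 20, base_logit = base,
                        autocorr = 0, weekly_amp = 0, coupling = matrix(0, 9, 9),
                        target_base_logit = -Inf,
                        target_coupling = matrix(0, 9, 1,
                          dimnames = list(default_behavior_catalogue())),
                        seed = 1)
  coh2 <- generate_cohort(cfg2)
  always <- default_behavior_catalogue()[1]
  for (s in names(coh2$ground_truth$states)) {
    st <- coh2$ground_truth$states[[s]]
    expect_equal(unname(st[always, ]), rep(1L, 20))
    expect_true(all(st[rownames(st) != always, ] == 0L))
  }
  tab <- table(coh2$diary$behavior)
  expect_identical(as.integer(tab[[always]]), 3L * 20L)
})

test_that("marginal daily prevalence matches the Bernoulli rate when all dynamics are off", {
  p0 <- 0.3
  cfg <- cohort_config(n_subjects = 50, n_days = 365,
                       base_logit = stats::qlogis(p0), autocorr = 0,
                       weekly_amp = 0, target_base_logit = stats::qlogis(0.2),
                       target_coupling = matrix(0, 9, 1,
                         dimnames = list(default_behavior_catalogue())),
                       seed = 4)
  coh <- generate_cohort(cfg)
  states <- do.call(cbind, coh$ground_truth$states)
  phat <- mean(states)
  se <- sqrt(p0 * (1 - p0) / length(states))
  expect_lt(abs(phat - p0), 3 * se)
})

test_that("zero couplings leave no lag-1 autocorrelation", {
  cfg <- cohort_config(n_subjects = 40, n_days = 250,
                       base_logit = stats::qlogis(0.3), autocorr = 0,
                       weekly_amp = 0, seed = 9)
  coh <- generate_cohort(cfg)
  r1 <- vapply(coh$ground_truth$states, function(st) {
    x <- st[1, ]
    abs(stats::cor(x[-1], x[-length(x)]))
  }, numeric(1))
  expect_lt(mean(r1, na.rm = TRUE), 3 / sqrt(250))
})

test_that("weekly modulation puts the periodogram peak at period 7", {
  cfg <- cohort_config(n_subjects = 30, n_days = 210,
                       base_logit = stats::qlogis(0.3), autocorr = 0,
                       weekly_amp = 1.5, weekly_phase_jitter = 0,
                       seed = 5)
  coh <- generate_cohort(cfg)
  daily <- rowMeans(vapply(coh$ground_truth$states, function(st) st[1, ],
                           numeric(210)))
  pg <- stats::spec.pgram(daily - mean(daily), plot = FALSE, taper = 0,
                          detrend = FALSE, fast = FALSE)
  expect_equal(1 / pg$freq[which.max(pg$spec)], 7, tolerance = 1e-8)
})

test_that("configuration validation rejects invalid inputs", {
  expect_error(cohort_config(5, 15), "n_days")
  expect_error(cohort_config(5, 30, target_name = "Juggling"),
               "unknown target")
  expect_error(cohort_config(5, 30, behavior_catalogue = letters[1:7]),
               "at least 8")
  expect_error(cohort_config(5, 30,
                             behavior_catalogue = rep("a", 9)), "unique")
  expect_error(cohort_config(5, 30,
                             shift_probs = c(morning = .5, afternoon = .5,
                                             overnight = .5)), "sum to 1")
})

test_that("CSV round trip preserves the diary and seizure log", {
  coh <- generate_cohort(cohort_config(n_subjects = 2, n_days = 30,
                                       seed = 3))
  dir <- file.path(tempdir(), "rt")
  write_cohort(coh, dir)
  d <- read_diary(file.path(dir, "diary.csv"))
  s <- read_seizure_log(file.path(dir, "seizures.csv"))
  expect_equal(d, coh$diary)
  expect_equal(s, coh$seizures)
})
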