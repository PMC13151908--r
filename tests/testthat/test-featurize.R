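# Category mapping, daily binarization, windowing, cohort filters and
# chronological splits.

test_that("top-7 selection ranks by count with lexicographic tie-break", {
  counts <- c(A = 5, B = 4, C = 3, D = 3, E = 2, F = 2, G = 1, H = 1,
              I = 1)
  map <- select_top_behaviors(diary_with_counts(counts))
  expect_identical(map$selected, c("A", "B", "C", "D", "E", "F", "G"))
  expect_identical(map$other_label, "Other")
  # brute-force oracle: order by count desc then name
  ord <- names(counts)[order(-counts, names(counts))]
  expect_identical(map$selected, ord[1:7])
})

test_that("the two least prevalent catalogue behaviors fall into Other", {
  cats <- default_behavior_catalogue()
  counts <- stats::setNames(seq(90, 10, length.out = 9), cats)
  map <- select_top_behaviors(diary_with_counts(round(counts)))
  expect_setequal(setdiff(cats, map$selected), cats[8:9])
  expect_error(select_top_behaviors(
    diary_with_counts(c(A = 3, B = 2, C = 1))), "3 distinct")
})

test_that("daily binarization ORs shifts and leaves empty days zero", {
  d <- data.frame(subject_id = "S1",
                  date = as.Date(c("2023-01-02", "2023-01-02",
                                   "2023-01-03")),
                  shift = c("morning", "afternoon", "overnight"),
                  behavior = c("A", "A", "C"), severe = FALSE)
  map <- select_top_behaviors(diary_with_counts(
    c(A = 9, B = 8, C = 7, D = 6, E = 5, F = 4, G = 3, H = 2)))
  dm <- daily_binarize(d, map, "S1",
                       seq(as.Date("2023-01-01"), by = "day",
                           length.out = 3))
  expect_identical(dim(dm$values), c(8L, 3L))
  expect_identical(dm$values["A", 2], 1L)   # OR, not count
  expect_identical(sum(dm$values), 2L)
  expect_identical(unname(dm$values[, 1]), rep(0L, 8))

  # subject present in diary but no records in range -> all-zero matrix
  dm0 <- daily_binarize(d, map, "S1",
                        seq(as.Date("2024-05-01"), by = "day",
                            length.out = 10))
  expect_identical(sum(dm0$values), 0L)
  expect_identical(dim(dm0$values), c(8L, 10L))

  expect_error(daily_binarize(d, map, "NOPE",
                              seq(as.Date("2023-01-01"), by = "day",
                                  length.out = 3)), "absent")
  expect_error(daily_binarize(d, map, "S1",
                              as.Date(c("2023-01-01", "2023-01-03"))),
               "gap-free")
})

test_that("seizure log adds a 9th row marking seizure days", {
  d <- diary_with_counts(c(A = 9, B = 8, C = 7, D = 6, E = 5, F = 4,
                           G = 3, H = 2))
  sz <- data.frame(subject_id = "S001",
                   date = as.Date(c("2023-01-02", "2023-01-05")))
  map <- select_top_behaviors(d)
  dm <- daily_binarize(d, map, "S001",
                       seq(as.Date("2023-01-01"), by = "day",
                           length.out = 6), seizures = sz)
  expect_identical(nrow(dm$values), 9L)
  expect_identical(unname(dm$values["seizure", ]),
                   c(0L, 1L, 0L, 0L, 1L, 0L))
})

test_that("window construction counts, aligns and labels correctly", {
  set.seed(7)
  vals <- matrix(rbinom(8 * 21, 1, 0.4), 8, 21)
  dm <- toy_daily_matrix(vals)
  ws <- build_windows(dm, 1, 7)
  expect_identical(length(ws), 14L)           # n_days - w
  for (i in c(1L, 7L, 14L)) {
    expect_identical(ws$x[, , i], vals[, i:(i + 6)])
    expect_identical(ws$y[i], vals[1, i + 7])   # label day not in window
    expect_identical(ws$target_dates[i], dm$dates[i + 7])
  }
  # shifting the calendar by one day shifts every target date by one
  dm2 <- toy_daily_matrix(vals, start = as.Date("2023-01-02"))
  expect_identical(build_windows(dm2, 1, 7)$target_dates,
                   ws$target_dates + 1)

  expect_warning(ws0 <- build_windows(toy_daily_matrix(vals[, 1:14]), 1, 14),
                 "0 samples")
  expect_identical(length(ws0), 0L)
  wsz <- build_windows(toy_daily_matrix(matrix(0L, 8, 20)), 1, 7)
  expect_true(all(wsz$y == 0L))
})

test_that("cohort filter excludes event-free subjects and applies the severe threshold inclusively", {
  d <- rbind(
    data.frame(subject_id = "S1", date = as.Date("2023-01-01") + 0:9,
               shift = "morning", behavior = "Aggression",
               severe = c(TRUE, rep(FALSE, 9))),          # 10% severe
    data.frame(subject_id = "S2", date = as.Date("2023-01-01") + 0:9,
               shift = "morning", behavior = "Aggression",
               severe = FALSE),                            # 0% severe
    data.frame(subject_id = "S3", date = as.Date("2023-01-01") + 0:9,
               shift = "morning", behavior = "SIB", severe = FALSE))
  expect_identical(filter_cohort(d, "Aggression"), c("S1", "S2"))
  expect_identical(filter_cohort(d, "Aggression", severe_only = TRUE),
                   "S1")                                   # >= is inclusive
  expect_identical(filter_cohort(d, "Elopement"), character())
  expect_identical(filter_cohort(d, "SIB"), "S3")
  sz <- data.frame(subject_id = "S3", date = as.Date("2023-01-05"))
  expect_identical(filter_cohort(d, "seizure", seizures = sz), "S3")
  expect_error(filter_cohort(d, "seizure", seizures = sz,
                             severe_only = TRUE), "behavior targets")
})

test_that("chronological split is an ordered 80/20 with a floor", {
  vals <- matrix(rbinom(8 * 17, 1, .3), 8, 17)
  ws <- build_windows(toy_daily_matrix(vals), 1, 7)   # 10 samples
  sp <- chronological_split(ws)
  expect_identical(length(sp$train), 8L)
  expect_identical(length(sp$test), 2L)
  expect_lt(max(sp$train$target_dates), min(sp$test$target_dates))

  ws5 <- build_windows(toy_daily_matrix(vals[, 1:12]), 1, 7)  # 5 samples
  sp5 <- chronological_split(ws5)
  expect_identical(length(sp5$train), 4L)
  expect_identical(length(sp5$test), 1L)

  # input order does not matter: shuffle then split
  set.seed(1)
  shuf <- behavcast:::subset_window_set(ws, sample(length(ws)))
  sp2 <- chronological_split(shuf)
  expect_identical(sp2$train$target_dates, sp$train$target_dates)
  expect_identical(sp2$train$y, sp$train$y)

  ws4 <- build_windows(toy_daily_matrix(vals[, 1:11]), 1, 7)  # 4 samples
  expect_warning(expect_null(chronological_split(ws4)), "skipped")
})

test_that("daily binarization of generator output reproduces ground truth exactly", {
  coh <- generate_cohort(cohort_config(n_subjects = 4, n_days = 50,
                                       seed = 21))
  map <- select_top_behaviors(coh$diary)
  gt <- coh$ground_truth
  dates <- seq(as.Date("2023-01-01"), by = "day", length.out = 50)
  for (sid in names(gt$states)) {
    dm <- daily_binarize(coh$diary, map, sid, dates,
                         seizures = coh$seizures)
    st <- gt$states[[sid]]
    for (b in map$selected)
      expect_identical(unname(dm$values[b, ]), unname(st[b, ]),
                       label = paste(sid, b))
    other <- setdiff(rownames(st), map$selected)
    expect_identical(unname(dm$values["Other", ]),
                     as.integer(colSums(st[other, , drop = FALSE]) > 0))
    expect_identical(unname(dm$values["seizure", ]),
                     as.integer(gt$target[[sid]]))
  }
})

test_that("severe daily indicator tracks severe target records only", {
  d <- data.frame(subject_id = "S1",
                  date = as.Date("2023-01-01") + c(0, 1, 1, 3),
                  shift = "morning",
                  behavior = c("Aggression", "Aggression", "SIB",
                               "Aggression"),
                  severe = c(FALSE, TRUE, TRUE, TRUE))
  sv <- severe_daily(d, "S1", "Aggression",
                     as.Date("2023-01-01") + 0:4)
  expect_identical(sv, c(0L, 1L, 0L, 1L, 0L))
})
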