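# Diary -> model-input featurization: top-7 + Other category mapping,
# daily binarization (OR over shifts), sliding windows with next-day
# labels, cohort filters and chronological train/test splits.

#' Select the most prevalent behavior categories
#'
#' Ranks behaviors by total record count across the whole cohort and keeps
#' the top `k`; every other category maps to the bucket label `"Other"`.
#' Ties are broken by higher count first, then lexicographic name order,
#' so the selection is reproducible from the counts alone.
#'
#' @param diary Behavior diary data.frame (see [read_diary()]).
#' @param k Number of categories to keep (default 7).
#' @return An object of class `category_map` with fields `selected`
#'   (ordered by descending prevalence), `other_label`, and `counts`.
#' @export
select_top_behaviors <- function(diary, k = 7) {
  if (is.null(diary) || nrow(diary) == 0) stop_bc("diary is empty")
  counts <- table(diary$behavior)
  if (length(counts) < k)
    stop_bc(sprintf(
      "only %d distinct behaviors present; %d required for top-%d selection",
      length(counts), k, k))
  nm <- names(counts)
  ord <- order(-as.integer(counts), nm)
  counts <- stats::setNames(as.integer(counts)[ord], nm[ord])
  structure(list(selected = names(counts)[seq_len(k)],
                 other_label = "Other",
                 counts = counts,
                 k = as.integer(k)),
            class = "category_map")
}

#' @export
print.category_map <- function(x, ...) {
  cat("Category map: top", x$k, "behaviors + ", x$other_label, "\n")
  for (b in x$selected) cat(sprintf("  %-24s %d records\n", b, x$counts[[b]]))
  other <- setdiff(names(x$counts), x$selected)
  if (length(other))
    cat(sprintf("  %-24s %d records (%d categories)\n", x$other_label,
                sum(x$counts[other]), length(other)))
  invisible(x)
}

map_features <- function(map, include_seizure = FALSE) {
  c(map$selected, map$other_label, if (include_seizure) "seizure")
}

#' Binarize a subject's diary into a daily feature matrix
#'
#' Builds the per-subject day-by-feature binary matrix: rows are the 7
#' selected behaviors (descending prevalence), the Other bucket, and —
#' when a seizure log is supplied — a seizure-history row; columns are the
#' consecutive days of `date_range`. A cell is 1 iff at least one record
#' of that category occurred on that day in any shift (OR, not count);
#' days without records are all-zero columns.
#'
#' @param diary Behavior diary data.frame.
#' @param map A `category_map` from [select_top_behaviors()].
#' @param subject_id Subject to extract; must appear in the diary.
#' @param date_range Gap-free vector of consecutive `Date`s.
#' @param seizures Optional seizure log data.frame; when supplied (even
#'   empty) the matrix gains a 9th `seizure` row.
#' @return An object of class `daily_matrix` with fields `subject_id`,
#'   `dates`, and `values` (features x days integer matrix).
#' @export
daily_binarize <- function(diary, map, subject_id, date_range,
                           seizures = NULL) {
  stopifnot(inherits(map, "category_map"))
  date_range <- as.Date(date_range)
  if (length(date_range) > 1 &&
      any(as.integer(diff(date_range)) != 1L))
    stop_bc("'date_range' must be gap-free consecutive days")
  if (!subject_id %in% diary$subject_id)
    stop_bc(sprintf("subject '%s' absent from diary", subject_id))
  feats <- map_features(map, include_seizure = !is.null(seizures))
  vals <- matrix(0L, length(feats), length(date_range),
                 dimnames = list(feats, as.character(date_range)))
  sub <- diary[diary$subject_id == subject_id, , drop = FALSE]
  ci <- match(as.Date(sub$date), date_range)
  keep <- !is.na(ci)
  if (any(keep)) {
    beh <- sub$behavior[keep]
    beh[!(beh %in% map$selected)] <- map$other_label
    vals[cbind(match(beh, feats), ci[keep])] <- 1L
  }
  if (!is.null(seizures)) {
    sz <- seizures[seizures$subject_id == subject_id, , drop = FALSE]
    si <- match(as.Date(sz$date), date_range)
    si <- si[!is.na(si)]
    if (length(si)) vals[length(feats), si] <- 1L
  }
  structure(list(subject_id = subject_id, dates = date_range,
                 values = vals),
            class = "daily_matrix")
}

#' Daily indicator of severe target-behavior events
#'
#' @param diary Behavior diary data.frame.
#' @param subject_id Subject to extract.
#' @param target Behavior category whose severe events define the label.
#' @param date_range Gap-free vector of consecutive `Date`s.
#' @return Integer 0/1 vector over `date_range`.
#' @export
severe_daily <- function(diary, subject_id, target, date_range) {
  date_range <- as.Date(date_range)
  sub <- diary[diary$subject_id == subject_id &
                 diary$behavior == target & diary$severe, , drop = FALSE]
  out <- integer(length(date_range))
  ci <- match(as.Date(sub$date), date_range)
  out[ci[!is.na(ci)]] <- 1L
  out
}

#' Build sliding windows with next-day labels
#'
#' One sample per valid position: the window spans `w` consecutive days
#' and the label is the target feature's state on the day immediately
#' after, so the label day's column is never part of the window. Sample
#' count is `n_days - w`.
#'
#' @param dm A `daily_matrix`.
#' @param target_feature Row name or index of the prediction target.
#' @param w Window length in days (7 or 14 in the standard analysis;
#'   other values are accepted).
#' @param labels Optional 0/1 vector over the matrix days overriding the
#'   target row as label source (used for severe-event relabeling).
#' @return An object of class `window_set` with fields `x` (features x w
#'   x n array), `y` (integer labels), `target_dates`, `feature_names`,
#'   `target`, `w`.
#' @export
build_windows <- function(dm, target_feature, w, labels = NULL) {
  stopifnot(inherits(dm, "daily_matrix"))
  vals <- dm$values
  feats <- rownames(vals)
  ti <- if (is.character(target_feature)) match(target_feature, feats)
        else as.integer(target_feature)
  if (is.na(ti) || ti < 1 || ti > nrow(vals))
    stop_bc("unknown target feature")
  lab_src <- if (is.null(labels)) vals[ti, ] else as.integer(labels)
  if (length(lab_src) != ncol(vals))
    stop_bc("'labels' length must equal the number of days")
  n_days <- ncol(vals)
  n <- n_days - w
  if (n <= 0) {
    warning(sprintf("subject %s: %d days admit no %d-day window+label; 0 samples",
                    dm$subject_id, n_days, w), call. = FALSE)
    n <- 0L
  }
  x <- array(0L, dim = c(nrow(vals), w, n))
  for (i in seq_len(n)) x[, , i] <- vals[, i:(i + w - 1)]
  structure(list(x = x,
                 y = as.integer(lab_src[w + seq_len(n)]),
                 target_dates = dm$dates[w + seq_len(n)],
                 feature_names = feats,
                 target = feats[ti],
                 subject_id = dm$subject_id,
                 w = as.integer(w)),
            class = "window_set")
}

subset_window_set <- function(ws, idx) {
  structure(list(x = ws$x[, , idx, drop = FALSE],
                 y = ws$y[idx],
                 target_dates = ws$target_dates[idx],
                 feature_names = ws$feature_names,
                 target = ws$target,
                 subject_id = ws$subject_id,
                 w = ws$w),
            class = "window_set")
}

#' @export
length.window_set <- function(x) length(x$y)

#' Filter subjects eligible for a prediction target
#'
#' Keeps subjects with at least one target event. In severe mode
#' (behavior targets only) keeps subjects for whom the fraction of target
#' records flagged severe is at least `min_severe_frac` (inclusive);
#' downstream, windows are then relabeled by severe-event presence.
#'
#' @param diary Behavior diary data.frame.
#' @param target Behavior category or `"seizure"`.
#' @param seizures Seizure log, required when `target == "seizure"`.
#' @param severe_only Filter on the severe-event subcohort.
#' @param min_severe_frac Inclusion threshold on the severe fraction.
#' @return Sorted character vector of subject ids (possibly empty).
#' @export
filter_cohort <- function(diary, target, seizures = NULL,
                          severe_only = FALSE, min_severe_frac = 0.10) {
  if (target == "seizure") {
    if (severe_only)
      stop_bc("severe mode applies to behavior targets only")
    if (is.null(seizures)) stop_bc("seizure target requires a seizure log")
    return(sort(unique(seizures$subject_id)))
  }
  tgt <- diary[diary$behavior == target, , drop = FALSE]
  if (nrow(tgt) == 0) return(character())
  if (!severe_only) return(sort(unique(tgt$subject_id)))
  frac <- tapply(tgt$severe, tgt$subject_id, mean)
  sort(names(frac)[frac >= min_severe_frac])
}

#' Chronological 80/20 train/test split
#'
#' Orders a subject's samples by label date and assigns the earliest
#' `floor(train_frac * n)` to training and the remainder to testing, so
#' every test label day strictly follows every train label day.
#'
#' @param ws A `window_set`.
#' @param train_frac Training fraction (default 0.8).
#' @param min_samples Minimum samples required; below this the subject is
#'   skipped (returns `NULL` with a warning).
#' @return List with `window_set` elements `train` and `test`, or `NULL`.
#' @export
chronological_split <- function(ws, train_frac = 0.8, min_samples = 5) {
  stopifnot(inherits(ws, "window_set"))
  n <- length(ws)
  if (n < min_samples) {
    warning(sprintf("subject %s: %d samples < %d required; skipped",
                    ws$subject_id %||% "?", n, min_samples), call. = FALSE)
    return(NULL)
  }
  ord <- order(ws$target_dates)
  n_train <- floor(train_frac * n)
  list(train = subset_window_set(ws, ord[seq_len(n_train)]),
       test = subset_window_set(ws, ord[(n_train + 1):n]))
}
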