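#' Select one baseline record per subject
#'
#' Retains, for each subject, the visit row with the smallest time value
#' (the earliest available visit). Ties on the minimal time are broken by
#' stable first occurrence in row order; subjects whose time is missing in
#' every row are excluded with a warning.
#'
#' @param visits data.frame of participant-visit rows.
#' @param id_col,time_col Column names for the subject ID and visit time.
#' @return data.frame with exactly one row per retained subject.
#' @export
select_baseline_records <- function(visits, id_col = "IID",
                                    time_col = "age_months") {
  stopifnot(is.data.frame(visits), id_col %in% names(visits),
            time_col %in% names(visits))
  tm <- visits[[time_col]]
  ok <- !is.na(tm)
  if (!all(ok)) {
    dropped_ids <- setdiff(unique(visits[[id_col]]),
                           unique(visits[[id_col]][ok]))
    if (length(dropped_ids) > 0) {
      warnf("%d subject(s) excluded: missing %s in all rows",
            length(dropped_ids), time_col)
    }
  }
  v <- visits[ok, , drop = FALSE]
  # stable: order by time with original row order as implicit tie-break
  v <- v[order(v[[id_col]], v[[time_col]]), , drop = FALSE]
  v[!duplicated(v[[id_col]]), , drop = FALSE]
}

#' Convert event times from absolute age to follow-up months
#'
#' Subtracts each subject's baseline age (in months) from the recorded
#' event/censoring age. Negative results are flagged invalid and set missing
#' (their labels will later be masked), as are times for subjects without a
#' baseline age.
#'
#' @param tte Long data.frame with `IID`, `task`, `event`, `age_months`.
#' @param baseline_age Named numeric: baseline age in months per subject ID.
#' @return `tte` with an added `time_fu` column (follow-up months; NA when
#'   invalid or unknown).
#' @export
convert_event_times <- function(tte, baseline_age) {
  stopifnot(all(c("IID", "task", "event", "age_months") %in% names(tte)))
  fu <- round(tte$age_months - unname(baseline_age[tte$IID]), 6)
  invalid <- !is.na(fu) & fu < 0
  if (any(invalid)) {
    warnf("%d record(s) with event time before baseline age set missing",
          sum(invalid))
    fu[invalid] <- NA_real_
  }
  tte$time_fu <- fu
  tte
}

#' Censoring-aware binary labels at a fixed prediction horizon
#'
#' For each subject and task, derives a binary initiation label at horizon
#' `H` months of follow-up together with a label-observed mask:
#' \itemize{
#'   \item event with time < H: `y = 1`, `m = 1`;
#'   \item event with time >= H, or no event with follow-up >= H: `y = 0`,
#'     `m = 1`;
#'   \item no event with follow-up < H (censored before the horizon), or
#'     missing event/time information: `m = 0` (label unobserved).
#' }
#' Subjects with no observed label on any task are dropped from the analytic
#' set.
#'
#' @param tte Long data.frame with `IID`, `task`, `event` and `time_fu`
#'   (follow-up months, e.g. from [convert_event_times()]).
#' @param H Prediction horizon in months (primary analysis: 48).
#' @param tasks Task order for the returned matrices.
#' @return List of class `horizon_labels`: `ids`, matrices `y` and `m`
#'   (subjects x tasks; `y` is NA where `m = 0`), `H`, and `n_dropped`.
#' @export
make_horizon_labels <- function(tte, H = 48, tasks = task_names()) {
  stopifnot(H > 0)
  stopifnot(all(c("IID", "task", "event", "time_fu") %in% names(tte)))
  ids <- unique(tte$IID)
  y <- m <- matrix(NA_real_, length(ids), length(tasks),
                   dimnames = list(ids, tasks))
  m[] <- 0
  for (t in tasks) {
    d <- tte[tte$task == t, ]
    idx <- match(d$IID, ids)
    ev <- d$event
    tm <- d$time_fu
    known <- !is.na(ev) & !is.na(tm)
    pos <- known & ev == 1 & tm < H
    neg <- known & ((ev == 1 & tm >= H) | (ev == 0 & tm >= H))
    y[idx[pos], t] <- 1
    m[idx[pos], t] <- 1
    y[idx[neg], t] <- 0
    m[idx[neg], t] <- 1
  }
  keep <- rowSums(m) >= 1
  structure(list(ids = ids[keep],
                 y = y[keep, , drop = FALSE],
                 m = m[keep, , drop = FALSE],
                 H = H, n_dropped = sum(!keep)),
            class = "horizon_labels")
}

#' Expand longitudinal records to a person-period (interval) table
#'
#' Each pair of consecutive visits defines a half-open interval
#' (start, end] in follow-up months. Features are taken from the interval's
#' start visit (known before the outcome); the interval start and end enter
#' as numeric predictors. For each task, the interval label is 1 when the
#' event time falls inside the interval, 0 when the subject is under
#' observation through the interval's end without an event, and the mask is
#' 0 for intervals after the event (the subject has left that task's risk
#' set) or reaching past the censoring time.
#'
#' Subjects with a single visit contribute one interval `(0, w]` with
#' `w = single_visit_window`. Zero-length intervals are rejected.
#'
#' @param visits Visit table with `IID` and `age_months` plus feature columns.
#' @param tte Long time-to-event table with `time_fu` (see
#'   [convert_event_times()]).
#' @param tasks Task order.
#' @param single_visit_window Interval width (months) granted to single-visit
#'   subjects.
#' @return List of class `person_periods`: data.frame `table` with `IID`,
#'   `interval`, `t_start`, `t_end` and the feature columns, plus matrices
#'   `y` and `m` (rows x tasks).
#' @export
expand_to_person_periods <- function(visits, tte, tasks = task_names(),
                                     single_visit_window = 12) {
  stopifnot(all(c("IID", "age_months") %in% names(visits)))
  stopifnot("time_fu" %in% names(tte))
  v <- visits[order(visits$IID, visits$age_months), , drop = FALSE]
  base_age <- tapply(v$age_months, v$IID, min)
  # round to micro-month precision so interval boundaries computed as
  # differences of recorded ages compare exactly against event times
  v$t_fu <- round(v$age_months - as.numeric(base_age[v$IID]), 6)

  # build intervals: one row per consecutive visit pair, features from start
  n_by_id <- table(v$IID)
  last_of_id <- c(v$IID[-1] != v$IID[-nrow(v)], TRUE)
  single <- v$IID %in% names(n_by_id)[n_by_id == 1]
  keep_start <- !last_of_id | single
  starts <- v[keep_start, , drop = FALSE]
  t_end <- c(v$t_fu[-1], NA)[keep_start]
  t_end[single[keep_start]] <- starts$t_fu[single[keep_start]] + single_visit_window
  tab <- starts
  tab$t_start <- starts$t_fu
  tab$t_end <- t_end
  if (any(tab$t_end <= tab$t_start)) {
    stopf("%d zero- or negative-length interval(s); visit times must strictly increase",
          sum(tab$t_end <= tab$t_start))
  }
  tab$interval <- stats::ave(seq_len(nrow(tab)), tab$IID, FUN = seq_along)

  # per-task event/censoring lookup
  y <- m <- matrix(0, nrow(tab), length(tasks),
                   dimnames = list(NULL, tasks))
  for (t in tasks) {
    d <- tte[tte$task == t, ]
    ev <- stats::setNames(d$event, d$IID)[tab$IID]
    tm <- stats::setNames(d$time_fu, d$IID)[tab$IID]
    known <- !is.na(ev) & !is.na(tm)
    # event inside this interval
    in_int <- known & ev == 1 & tm > tab$t_start & tm <= tab$t_end
    # still under observation through the interval end, event-free
    obs_neg <- known & ((ev == 1 & tm > tab$t_end) |
                          (ev == 0 & tm >= tab$t_end))
    y[in_int, t] <- 1
    m[in_int | obs_neg, t] <- 1
  }
  keep <- rowSums(m) >= 1
  tab <- tab[keep, , drop = FALSE]
  y <- y[keep, , drop = FALSE]
  m <- m[keep, , drop = FALSE]
  y[m == 0] <- NA_real_
  rownames(tab) <- NULL
  drop_cols <- c("t_fu")
  tab <- tab[, setdiff(names(tab), drop_cols), drop = FALSE]
  structure(list(table = tab, y = y, m = m, tasks = tasks),
            class = "person_periods")
}

#' Coerce a feature table to numeric and drop empty columns
#'
#' Coerces every non-identifier column to numeric where possible; columns
#' that are entirely missing after coercion (including columns of
#' unparseable strings) are removed and reported. Identifier/bookkeeping
#' columns are excluded via a denylist.
#'
#' @param x data.frame of raw features.
#' @param denylist Columns excluded as identifiers or bookkeeping (defaults
#'   to the package's ID/visit columns).
#' @return List: `matrix` (numeric), `dropped` (all-missing columns removed),
#'   `excluded` (denylist columns present in `x`).
#' @export
clean_features <- function(x, denylist = c("IID", "visit", "split")) {
  stopifnot(is.data.frame(x))
  excluded <- intersect(denylist, names(x))
  keep <- setdiff(names(x), excluded)
  num <- lapply(x[keep], function(col) {
    if (is.numeric(col)) return(as.numeric(col))
    suppressWarnings(as.numeric(as.character(col)))
  })
  mat <- do.call(cbind, num)
  colnames(mat) <- keep
  all_missing <- colSums(!is.na(mat)) == 0
  list(matrix = mat[, !all_missing, drop = FALSE],
       dropped = keep[all_missing],
       excluded = excluded)
}

#' Fit train-only imputation and scaling state
#'
#' Computes, from training rows only: per-column medians for imputation
#' (columns with no observed training values fall back to 0) and per-column
#' means/SDs for z-scoring. Zero-variance columns get a scaling divisor of 1.
#' The same state is applied unchanged to validation and test data, so no
#' information flows from those splits into preprocessing.
#'
#' @param train Numeric matrix of training-row features.
#' @param scale Whether the state should also z-score (the dynamic pathway
#'   standardizes; imputation alone reproduces the baseline pathway).
#' @return Object of class `preprocess_state`.
#' @export
fit_preprocess <- function(train, scale = TRUE) {
  stopifnot(is.matrix(train))
  med <- apply(train, 2, stats::median, na.rm = TRUE)
  all_missing <- colnames(train)[!is.finite(med)]
  med[!is.finite(med)] <- 0
  imputed <- impute_with(train, med)
  mu <- colMeans(imputed)
  sd <- apply(imputed, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  structure(list(columns = colnames(train), median = med, mean = mu, sd = sd,
                 all_missing_in_train = all_missing, scale = scale),
            class = "preprocess_state")
}

impute_with <- function(x, med) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- med[[j]]
  }
  x
}

#' Apply a fitted preprocessing state
#'
#' @param state A `preprocess_state` from [fit_preprocess()].
#' @param x Numeric matrix with the same columns as the training matrix.
#' @return Imputed (and, if fitted so, z-scored) matrix.
#' @export
apply_preprocess <- function(state, x) {
  stopifnot(inherits(state, "preprocess_state"), is.matrix(x))
  if (!identical(colnames(x), state$columns)) {
    x <- x[, state$columns, drop = FALSE]
  }
  x <- impute_with(x, state$median)
  if (state$scale) {
    x <- sweep(sweep(x, 2, state$mean, "-"), 2, state$sd, "/")
  }
  x
}

#' Serialize / restore a preprocessing state
#' @param state A `preprocess_state`.
#' @param path JSON file path.
#' @return `path` (write) or the restored state (read).
#' @export
write_preprocess_state <- function(state, path) {
  jsonlite::write_json(unclass(state), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_preprocess_state
#' @export
read_preprocess_state <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("median", "mean", "sd")) {
    s[[nm]] <- stats::setNames(as.numeric(s[[nm]]), s$columns)
  }
  structure(s, class = "preprocess_state")
}

#' Subject-level train/validation/test split
#'
#' A single seeded random permutation of the unique subject IDs, cut at the
#' cumulative proportion boundaries (default 70/15/15). The split is a
#' disjoint, exhaustive partition with zero subject overlap across sets.
#'
#' @param ids Character vector of subject IDs (deduplicated internally).
#' @param seed Integer seed.
#' @param proportions Length-3 numeric summing to 1 (train, val, test).
#' @return Object of class `split_manifest`: data.frame `manifest` with
#'   columns `IID` and `split`, plus `seed` and `proportions`.
#' @export
split_subjects <- function(ids, seed = 1, proportions = c(0.70, 0.15, 0.15)) {
  ids <- unique(as.character(ids))
  if (length(ids) < 3) stopf("need at least 3 subjects to split, got %d", length(ids))
  stopifnot(length(proportions) == 3, abs(sum(proportions) - 1) < 1e-8)
  perm <- with_seed(seed, sample(ids))
  n <- length(ids)
  n_train <- floor(n * proportions[1])
  n_val <- floor(n * (proportions[1] + proportions[2])) - n_train
  split <- rep("test", n)
  split[seq_len(n_train)] <- "train"
  if (n_val > 0) split[n_train + seq_len(n_val)] <- "val"
  manifest <- data.frame(IID = perm, split = split, stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$IID), , drop = FALSE]
  rownames(manifest) <- NULL
  structure(list(manifest = manifest, seed = as.integer(seed),
                 proportions = proportions),
            class = "split_manifest")
}

#' Save / load a split manifest as two-column CSV
#' @param split A `split_manifest`.
#' @param path CSV file path.
#' @return `path` (write) or the restored manifest data.frame (read).
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(inherits(split, "split_manifest"))
  utils::write.csv(split$manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

split_lookup <- function(split) {
  stats::setNames(split$manifest$split, split$manifest$IID)
}
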