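test_that("baseline selection keeps the earliest visit, one row per subject", {
  v <- data.frame(IID = c("a", "a", "a", "b", "c", "c"),
                  age_months = c(24, 0, 12, 5, 9, 3),
                  x = 1:6)
  b <- select_baseline_records(v)
  expect_equal(nrow(b), 3)
  expect_equal(b$x[b$IID == "a"], 2)  # the month-0 row
  expect_equal(b$x[b$IID == "b"], 4)  # single visit retained
  expect_equal(b$x[b$IID == "c"], 6)
})

test_that("duplicate earliest visits break ties by first occurrence; all-missing times excluded", {
  v <- data.frame(IID = c("a", "a", "b"), age_months = c(10, 10, NA), x = 1:3)
  expect_warning(b <- select_baseline_records(v), "excluded")
  expect_equal(nrow(b), 1)
  expect_equal(b$x, 1)
})

test_that("event times convert from absolute age to follow-up, flagging negatives", {
  tte <- data.frame(IID = c("a", "b", "c"), task = "alcohol",
                    event = c(1, 0, 1), age_months = c(167, 119, 100))
  ba <- c(a = 119, b = 119, c = 119)
  expect_warning(out <- convert_event_times(tte, ba), "before baseline")
  expect_equal(out$time_fu, c(48, 0, NA))
})

test_that("horizon labeling matches the stated censoring-aware rules", {
  tte <- do.call(rbind, lapply(task_names(), function(t) {
    d <- data.frame(IID = c("s1", "s2", "s3", "s4"), task = t,
                    event = c(1, 0, 1, 0), time_fu = c(20, 30, 60, 50))
    if (t == "any") {
      # give the censored subject one observed task so it stays in the set
      d$event[2] <- 1
      d$time_fu[2] <- 30
    }
    d
  }))
  lab <- make_horizon_labels(tte, H = 48)
  expect_equal(unname(lab$y["s1", "alcohol"]), 1)  # event before H
  expect_equal(unname(lab$m["s2", "alcohol"]), 0)  # censored before H
  expect_equal(unname(lab$y["s3", "alcohol"]), 0)  # event after H
  expect_equal(unname(lab$y["s4", "alcohol"]), 0)  # event-free past H
})

test_that("subjects with no observed label on any task are dropped", {
  tte <- do.call(rbind, lapply(task_names(), function(t) {
    data.frame(IID = c("kept", "dropped"), task = t, event = 0,
               time_fu = c(50, 10))
  }))
  lab <- make_horizon_labels(tte, H = 48)
  expect_equal(lab$ids, "kept")
  expect_equal(lab$n_dropped, 1)
})

test_that("person-period expansion follows the interval construction rules", {
  v <- data.frame(IID = "s1", age_months = c(100, 112, 124),
                  f = c(0.1, 0.2, 0.3))
  tte <- do.call(rbind, lapply(task_names(), function(t) {
    data.frame(IID = "s1", task = t,
               event = if (t == "alcohol") 1 else 0,
               time_fu = if (t == "alcohol") 18 else 24)
  }))
  pp <- expand_to_person_periods(v, tte)
  a <- pp$table$IID == "s1"
  expect_equal(pp$table$t_start, c(0, 12))
  expect_equal(pp$table$t_end, c(12, 24))
  # event at month 18: first interval 0, second 1
  expect_equal(unname(pp$y[, "alcohol"]), c(0, 1))
  # features come from the interval's start visit
  expect_equal(pp$table$f, c(0.1, 0.2))
  # event-free task through 24 months: two observed negatives
  expect_equal(unname(pp$y[, "nicotine"]), c(0, 0))
})

test_that("censoring inside an interval masks it; post-event intervals are masked", {
  v <- data.frame(IID = rep(c("cens", "ev"), each = 3),
                  age_months = rep(c(0, 12, 24), 2))
  tte <- do.call(rbind, lapply(task_names(), function(t) {
    data.frame(IID = c("cens", "ev"), task = t,
               event = c(0, 1), time_fu = c(10, 6))
  }))
  pp <- expand_to_person_periods(v, tte)
  # censored at month 10: no observed intervals at all -> dropped
  expect_false("cens" %in% pp$table$IID)
  # event in (0,12]: one observed interval, later ones masked
  expect_equal(sum(pp$table$IID == "ev"), 1)
  expect_equal(unname(pp$y[pp$table$IID == "ev", "alcohol"]), 1)
})

test_that("single-visit subjects get one interval; subjects without events get n-1 intervals", {
  v <- data.frame(IID = c(rep("multi", 4), "solo"),
                  age_months = c(0, 12, 24, 36, 0))
  tte <- do.call(rbind, lapply(task_names(), function(t) {
    data.frame(IID = c("multi", "solo"), task = t, event = 0,
               time_fu = c(36, 12))
  }))
  pp <- expand_to_person_periods(v, tte, single_visit_window = 12)
  expect_equal(sum(pp$table$IID == "multi"), 3)
  solo <- pp$table[pp$table$IID == "solo", ]
  expect_equal(nrow(solo), 1)
  expect_equal(solo$t_end, 12)
})

test_that("clean_features coerces to numeric and drops all-missing columns", {
  x <- data.frame(IID = c("a", "b"), good = c("1.5", "2.5"),
                  empty = c(NA, NA), junk = c("foo", "bar"),
                  num = c(1, 2), stringsAsFactors = FALSE)
  out <- clean_features(x)
  expect_setequal(colnames(out$matrix), c("good", "num"))
  expect_setequal(out$dropped, c("empty", "junk"))
  expect_equal(out$excluded, "IID")
  expect_equal(out$matrix[, "good"], c(1.5, 2.5))
  # no missing columns -> identity on the numeric part
  clean2 <- clean_features(x[, c("good", "num")])
  expect_equal(length(clean2$dropped), 0)
})

test_that("preprocessing imputes train medians, falls back to 0, and z-scores", {
  train <- cbind(a = c(1, 3, NA), b = c(NA, NA, NA), c = c(2, 2, 2))
  state <- fit_preprocess(train)
  expect_equal(unname(state$median["a"]), 2)
  expect_equal(state$all_missing_in_train, "b")
  out_tr <- apply_preprocess(state, train)
  expect_true(all(abs(colMeans(out_tr)) < 1e-9))
  # non-constant columns have unit sd; constant columns divide by 1
  expect_equal(unname(apply(out_tr, 2, sd)), c(1, 0, 0), tolerance = 1e-9)
  # all-missing-in-train column imputed 0 everywhere, including test
  test <- cbind(a = c(NA_real_), b = c(5), c = c(7))
  out_te <- apply_preprocess(state, test)
  expect_equal(unname(out_te[1, "a"]), (2 - state$mean[["a"]]) / state$sd[["a"]])
})

test_that("preprocessing state round-trips through JSON", {
  train <- cbind(a = rnorm(10), b = c(rnorm(9), NA))
  state <- fit_preprocess(train)
  path <- withr::local_tempfile(fileext = ".json")
  write_preprocess_state(state, path)
  state2 <- read_preprocess_state(path)
  expect_equal(apply_preprocess(state2, train), apply_preprocess(state, train))
})

test_that("subject split is a seeded exhaustive partition at the target proportions", {
  ids <- sprintf("id%03d", 1:100)
  sp <- split_subjects(ids, seed = 5)
  tab <- table(sp$manifest$split)
  expect_equal(unname(tab[c("train", "val", "test")]), c(70, 15, 15),
               ignore_attr = TRUE)
  expect_setequal(sp$manifest$IID, ids)
  sp2 <- split_subjects(ids, seed = 5)
  expect_identical(sp$manifest, sp2$manifest)
  sp3 <- split_subjects(ids, seed = 6)
  expect_false(identical(sp$manifest$split, sp3$manifest$split))
  expect_error(split_subjects(c("a", "b")), "at least 3")
})

test_that("split manifest round-trips through CSV", {
  sp <- split_subjects(sprintf("s%d", 1:50), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_split_manifest(sp, path)
  expect_identical(read_split_manifest(path), sp$manifest)
})

test_that("person-period positives within the horizon imply horizon-positive labels", {
  # consistency checked for events in intervals ending strictly before H
  co <- generate_cohort(tiny_cohort_config(n = 250, seed = 9,
                                           censoring_prob_per_interval = 0))
  ba <- setNames(co$covariates$baseline_age_months, co$covariates$IID)
  tte <- convert_event_times(co$tte, ba)
  lab <- make_horizon_labels(tte, H = 48)
  pp <- expand_to_person_periods(co$visits, tte)
  for (t in task_names()) {
    pos_rows <- pp$table$IID[!is.na(pp$y[, t]) & pp$y[, t] == 1 &
                               pp$table$t_end < 48]
    for (id in pos_rows) {
      expect_equal(unname(lab$y[id, t]), 1)
    }
  }
})
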