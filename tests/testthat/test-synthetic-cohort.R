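test_that("identical configs give bit-identical cohorts and reports", {
  c1 <- generate_cohort(tiny_cohort_config(n = 150, seed = 3))
  c2 <- generate_cohort(tiny_cohort_config(n = 150, seed = 3))
  expect_identical(c1$visits, c2$visits)
  expect_identical(c1$tte, c2$tte)
  expect_identical(c1$covariates, c2$covariates)
  expect_identical(generation_report(c1), generation_report(c2))
  c3 <- generate_cohort(tiny_cohort_config(n = 150, seed = 4))
  expect_false(identical(c1$tte, c3$tte))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_subjects = 1), "n_subjects")
  expect_error(cohort_config(ar1_rho = 1), "ar1_rho")
  expect_error(cohort_config(censoring_prob_per_interval = 1.2), "probabilities")
  expect_error(cohort_config(intercepts = c(alcohol = -2)), "substance tasks")
})

test_that("a null generator with logit-0 hazard and one visit events half the cohort", {
  cfg <- cohort_config(
    n_subjects = 4000, n_visits = 1, seed = 5,
    intercepts = c(alcohol = 0, nicotine = 0, cannabis = 0),
    shared_loading = c(alcohol = 0, nicotine = 0, cannabis = 0),
    signal_coef = list(alcohol = numeric(0), nicotine = numeric(0),
                       cannabis = numeric(0)),
    time_varying_effect = 0, censoring_prob_per_interval = 0,
    site_sd = 0, missing_column_fraction = 0, cell_missing_prob = 0)
  rep <- generation_report(generate_cohort(cfg))
  for (t in c("alcohol", "nicotine", "cannabis")) {
    p <- rep$prevalence[rep$task == t]
    expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 4000))
  }
})

test_that("full censoring masks every horizon label", {
  cfg <- tiny_cohort_config(n = 80, seed = 6, censoring_prob_per_interval = 1)
  co <- generate_cohort(cfg)
  expect_equal(sum(co$tte$event), 0)
  ba <- setNames(co$covariates$baseline_age_months, co$covariates$IID)
  tte <- convert_event_times(co$tte, ba)
  lab <- make_horizon_labels(tte, H = 48)
  expect_equal(length(lab$ids), 0)
})

test_that("the any-substance event is the earliest substance event", {
  co <- generate_cohort(tiny_cohort_config(n = 400, seed = 8))
  wide_t <- reshape(co$tte, direction = "wide", idvar = "IID",
                    timevar = "task")
  ev <- wide_t[, paste0("event.", c("alcohol", "nicotine", "cannabis"))]
  tm <- wide_t[, paste0("age_months.", c("alcohol", "nicotine", "cannabis"))]
  has_sub <- rowSums(ev) > 0
  expect_equal(wide_t$event.any[has_sub], rep(1, sum(has_sub)))
  tm_ev <- as.matrix(tm)
  tm_ev[as.matrix(ev) == 0] <- Inf
  expect_equal(wide_t$age_months.any[has_sub],
               unname(apply(tm_ev[has_sub, , drop = FALSE], 1, min)))
  # event times never precede baseline age
  ba <- setNames(co$covariates$baseline_age_months, co$covariates$IID)
  expect_true(all(co$tte$age_months >= ba[co$tte$IID]))
})

test_that("empirical per-interval hazards match the generating hazards", {
  cfg <- tiny_cohort_config(n = 6000, seed = 12)
  co <- generate_cohort(cfg)
  sp <- cfg$visit_spacing_months
  ba <- setNames(co$covariates$baseline_age_months, co$covariates$IID)
  k_cens <- co$truth$censoring_interval_index
  for (t in c("alcohol", "nicotine")) {
    d <- co$tte[co$tte$task == t, ]
    fu <- d$age_months - ba[d$IID]
    k_ev <- ifelse(d$event == 1, round(fu / sp), Inf)
    h <- co$truth$hazards[[t]]
    for (k in 1:2) {
      at_risk <- k_ev >= k & k_cens > k
      emp <- mean(k_ev[at_risk] == k)
      expected <- mean(h[at_risk, k])
      se <- sqrt(expected * (1 - expected) / sum(at_risk))
      expect_lt(abs(emp - expected), 3 * se)
    }
  }
})

test_that("null features carry no association with outcomes", {
  co <- generate_cohort(tiny_cohort_config(n = 4000, seed = 13,
                                           cell_missing_prob = 0,
                                           missing_column_fraction = 0))
  base <- co$visits[co$visits$visit == 1, ]
  d <- co$tte[co$tte$task == "alcohol", ]
  ev <- d$event[match(base$IID, d$IID)]
  for (col in co$truth$null_features[1:5]) {
    expect_lt(abs(cor(base[[col]], ev)), 4 / sqrt(nrow(base)))
  }
  # signal features do associate
  expect_gt(cor(base$exp_01, ev), 4 / sqrt(nrow(base)))
})

test_that("block-missing columns are fully missing and drawn from null features", {
  co <- generate_cohort(tiny_cohort_config(n = 100, seed = 14,
                                           missing_column_fraction = 0.3))
  expect_equal(length(co$truth$missing_columns), round(0.3 * 20))
  for (col in co$truth$missing_columns) {
    expect_true(all(is.na(co$visits[[col]])))
    expect_true(col %in% co$truth$null_features)
  }
  sig_ok <- colSums(!is.na(co$visits[co$truth$signal_features]))
  expect_true(all(sig_ok > 0))
})

test_that("exposures vary across visits with the configured temporal stability", {
  co <- generate_cohort(tiny_cohort_config(n = 2000, seed = 15,
                                           cell_missing_prob = 0,
                                           missing_column_fraction = 0))
  v1 <- co$visits[co$visits$visit == 1, "exp_01"]
  v2 <- co$visits[co$visits$visit == 2, "exp_01"]
  v5 <- co$visits[co$visits$visit == 5, "exp_01"]
  expect_lt(abs(cor(v1, v2) - 0.6), 0.06)
  expect_lt(abs(cor(v1, v5) - 0.6^4), 0.08)
})

test_that("cohorts round-trip through the CSV/JSON exchange format", {
  co <- generate_cohort(tiny_cohort_config(n = 40, seed = 16))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$tte, co$tte, tolerance = 1e-12)
  expect_equal(back$covariates$IID, co$covariates$IID)
  expect_equal(back$truth$intercepts$alcohol,
               unname(co$truth$intercepts["alcohol"]))
})

test_that("degenerate all-event or no-event tasks are flagged in the report", {
  cfg <- cohort_config(
    n_subjects = 60, n_visits = 3, seed = 17,
    intercepts = c(alcohol = 10, nicotine = -30, cannabis = -30),
    censoring_prob_per_interval = 0)
  co <- generate_cohort(cfg)
  expect_warning(rep <- generation_report(co), "degenerate")
  expect_true(rep$degenerate[rep$task == "alcohol"])
  expect_equal(rep$prevalence[rep$task == "alcohol"], 1)
  expect_equal(rep$prevalence[rep$task == "nicotine"], 0)
})
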