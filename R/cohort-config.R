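#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defines the study conditions the generator emulates: a large adolescent
#' cohort followed over regularly spaced visits, four correlated
#' substance-initiation outcomes with strongly unbalanced prevalence (alcohol
#' and any-substance common, nicotine and cannabis rare), right-censoring
#' before the follow-up horizon for a minority of subjects, a time-varying
#' exposure carrying signal, and block-missing covariate columns.
#'
#' Per-interval initiation follows a discrete-time hazard on the logit scale:
#' \deqn{\mathrm{logit}\, h_{ik}^{(t)} = c_t + \sum_j \beta_{tj} x_{ij} +
#'   \lambda_t u_i + \gamma z_i(k) + s_{\mathrm{site}(i)}}
#' where \eqn{u_i} is a standard-normal shared liability, \eqn{z_i(k)} a
#' stationary AR(1) exposure, and \eqn{s} small site intercepts. The "any"
#' outcome is derived as the earliest of the three substance events, never
#' simulated with its own hazard.
#'
#' The default per-task intercepts were calibrated once by bisection
#' ([calibrate_intercepts()]) against the target end-of-follow-up prevalences
#' 36.5% (alcohol), 5.44% (nicotine) and 3.42% (cannabis) at large n, and are
#' frozen here.
#'
#' @param n_subjects Number of subjects (default 10000).
#' @param n_visits Number of visits per subject; consecutive visits bound the
#'   hazard intervals, so `n_visits = 5` gives 4 intervals.
#' @param visit_spacing_months Months between visits (default 12, so 5 visits
#'   span the 48-month horizon).
#' @param baseline_age_mean,baseline_age_sd Baseline age distribution in
#'   months (defaults 119 and 7.4, i.e. about 9.9 +/- 0.6 years).
#' @param intercepts Named numeric: per-substance baseline logit-hazard
#'   intercepts (tasks `alcohol`, `nicotine`, `cannabis`).
#' @param shared_loading Named numeric: loading of each substance task on the
#'   shared latent liability `u`.
#' @param signal_coef Named list of named numeric vectors: per-task
#'   coefficients on feature columns (exposures, covariates or PRS columns).
#' @param n_null_features Number of exposure columns with zero coefficient.
#' @param time_varying_effect Coefficient on the AR(1) time-varying exposure,
#'   shared across substance tasks.
#' @param ar1_rho AR(1) autocorrelation of the time-varying exposure, in (0,1).
#' @param censoring_prob_per_interval Per-interval probability of dropout.
#' @param missing_column_fraction Fraction of null-feature columns set fully
#'   missing (exercises the drop-all-missing preprocessing rule).
#' @param cell_missing_prob Sporadic cell-level missingness rate on exposure
#'   columns.
#' @param n_sites Number of study sites; `site_sd` is the SD of their random
#'   hazard intercepts.
#' @param site_sd SD of site random intercepts on the logit scale.
#' @param seed Integer seed; fully determines the generated cohort.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [calibrate_intercepts()]
#' @export
cohort_config <- function(n_subjects = 10000,
                          n_visits = 5,
                          visit_spacing_months = 12,
                          baseline_age_mean = 119,
                          baseline_age_sd = 7.4,
                          intercepts = c(alcohol = -2.4304, nicotine = -4.8877,
                                         cannabis = -5.3477),
                          shared_loading = c(alcohol = 0.6, nicotine = 0.8,
                                             cannabis = 0.8),
                          signal_coef = default_signal_coef(),
                          n_null_features = 20,
                          time_varying_effect = 0.5,
                          ar1_rho = 0.6,
                          censoring_prob_per_interval = 0.01,
                          missing_column_fraction = 0.15,
                          cell_missing_prob = 0.02,
                          n_sites = 21,
                          site_sd = 0.1,
                          seed = 1) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_visits = as.integer(n_visits),
    visit_spacing_months = visit_spacing_months,
    baseline_age_mean = baseline_age_mean,
    baseline_age_sd = baseline_age_sd,
    tasks = task_names(),
    intercepts = intercepts,
    shared_loading = shared_loading,
    signal_coef = signal_coef,
    n_null_features = as.integer(n_null_features),
    time_varying_effect = time_varying_effect,
    ar1_rho = ar1_rho,
    censoring_prob_per_interval = censoring_prob_per_interval,
    missing_column_fraction = missing_column_fraction,
    cell_missing_prob = cell_missing_prob,
    n_sites = as.integer(n_sites),
    site_sd = site_sd,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' Default per-task signal coefficients
#'
#' Eight baseline exposures (`exp_01`..`exp_08`) carry signal with effect
#' sizes of 0.10-0.40 per SD on the logit scale, shared in direction across
#' substances (rare tasks scaled by 0.9) to reflect common liability; alcohol
#' additionally loads weakly on sex, and nicotine on its polygenic score.
#'
#' @return Named list with one coefficient vector per substance task.
#' @export
default_signal_coef <- function() {
  base <- c(exp_01 = 0.40, exp_02 = 0.35, exp_03 = 0.30, exp_04 = 0.25,
            exp_05 = 0.20, exp_06 = 0.15, exp_07 = 0.10, exp_08 = 0.10)
  list(
    alcohol  = c(base, sex = 0.10),
    nicotine = c(base * 0.9, prs_nicotine = 0.30),
    cannabis = base * 0.9
  )
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_subjects < 2) stopf("n_subjects must be >= 2, got %d", cfg$n_subjects)
  if (cfg$n_visits < 1) stopf("n_visits must be >= 1, got %d", cfg$n_visits)
  if (length(cfg$tasks) != 4) stopf("tasks must have length 4")
  probs <- c(cfg$censoring_prob_per_interval, cfg$missing_column_fraction,
             cfg$cell_missing_prob)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (cfg$ar1_rho <= 0 || cfg$ar1_rho >= 1) stopf("ar1_rho must lie in (0, 1)")
  subst <- setdiff(cfg$tasks, "any")
  for (nm in c("intercepts", "shared_loading")) {
    if (!all(subst %in% names(cfg[[nm]]))) {
      stopf("%s must name all substance tasks", nm)
    }
  }
  if (!all(subst %in% names(cfg$signal_coef))) {
    stopf("signal_coef must name all substance tasks")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d subjects, %d visits every %g months\n",
              x$n_subjects, x$n_visits, x$visit_spacing_months))
  cat(sprintf("  intercepts: %s\n",
              paste(sprintf("%s=%.3f", names(x$intercepts), x$intercepts),
                    collapse = ", ")))
  cat(sprintf("  censoring/interval: %.3f, seed: %d\n",
              x$censoring_prob_per_interval, x$seed))
  invisible(x)
}
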