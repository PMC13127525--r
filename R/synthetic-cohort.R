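#' Generate a synthetic longitudinal cohort with known ground truth
#'
#' Simulates subjects followed over regularly spaced visits and four
#' correlated time-to-event initiation outcomes from a discrete-time hazard
#' model (see [cohort_config()] for the model). Event times within an
#' interval are recorded at the interval's end; dropout (censoring) is drawn
#' independently per interval and recorded mid-interval, so censored subjects
#' have follow-up strictly inside the interval in which they dropped out.
#' The "any" outcome is the earliest observed substance event.
#'
#' All times in the returned time-to-event table are absolute age in months
#' (baseline age plus follow-up), matching the recording convention of large
#' adolescent cohort studies; downstream preparation converts them back to
#' follow-up time.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `synthetic_cohort`: a list with
#'   \describe{
#'     \item{visits}{data.frame, one row per subject-visit: `IID`, `visit`,
#'       `age_months`, the time-varying exposure `tv_exposure`, and exposure
#'       columns (some fully or sporadically missing).}
#'     \item{tte}{long data.frame: `IID`, `task`, `event`, `age_months`.}
#'     \item{covariates}{data.frame: `IID`, `sex`, `baseline_age_months`,
#'       `site`, `PC1`..`PC20`, and four `prs_*` columns.}
#'     \item{truth}{generating parameters, the latent liability `u`, per-task
#'       hazard matrices, and bookkeeping (null/missing column names).}
#'   }
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_subjects
  K <- max(1L, cfg$n_visits - 1L)  # number of hazard intervals
  sp <- cfg$visit_spacing_months
  subst <- setdiff(cfg$tasks, "any")

  iid <- sprintf("S%06d", seq_len(n))
  baseline_age <- round(stats::rnorm(n, cfg$baseline_age_mean, cfg$baseline_age_sd), 1)

  # subject-level covariates
  sex <- stats::rbinom(n, 1, 0.5)
  site <- sample.int(cfg$n_sites, n, replace = TRUE)
  site_effects <- stats::rnorm(cfg$n_sites, 0, cfg$site_sd)
  pcs <- matrix(stats::rnorm(n * 20), n, 20,
                dimnames = list(NULL, paste0("PC", 1:20)))
  prs <- matrix(stats::rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("prs_", c("alcohol", "nicotine",
                                                      "cannabis", "any"))))

  # exposures: signal columns named in signal_coef plus null columns; each
  # evolves across visits as a stationary AR(1) (temporal stability ar1_rho),
  # the hazard at interval k uses the visit-k value x_ij(k)
  sig_names <- sort(unique(unlist(lapply(cfg$signal_coef, names))))
  sig_names <- grep("^exp_", sig_names, value = TRUE)
  null_names <- if (cfg$n_null_features > 0) {
    sprintf("null_%02d", seq_len(cfg$n_null_features))
  } else {
    character(0)
  }
  expo_names <- c(sig_names, null_names)
  rho <- cfg$ar1_rho
  ar1_panel <- function(p) {
    # list over visits of n x p matrices, stationary N(0,1) margins
    out <- vector("list", cfg$n_visits)
    out[[1]] <- matrix(stats::rnorm(n * p), n, p)
    if (cfg$n_visits > 1) {
      for (v in 2:cfg$n_visits) {
        out[[v]] <- rho * out[[v - 1]] +
          sqrt(1 - rho^2) * matrix(stats::rnorm(n * p), n, p)
      }
    }
    out
  }
  expo_by_visit <- ar1_panel(length(expo_names))
  expo_by_visit <- lapply(expo_by_visit, function(mm) {
    colnames(mm) <- expo_names
    mm
  })
  z_by_visit <- ar1_panel(1)
  z <- do.call(cbind, z_by_visit)  # n x n_visits

  u <- stats::rnorm(n)  # shared latent liability

  const_design <- cbind(sex = sex, baseline_age_std =
                          (baseline_age - cfg$baseline_age_mean) /
                            max(cfg$baseline_age_sd, 1e-12),
                        pcs, prs)

  # per-task hazard matrices n x K
  hazards <- list()
  for (t in subst) {
    beta <- cfg$signal_coef[[t]]
    known <- c(expo_names, colnames(const_design))
    missing_cols <- setdiff(names(beta), known)
    if (length(missing_cols) > 0) {
      stopf("signal_coef for task '%s' names unknown columns: %s",
            t, paste(missing_cols, collapse = ", "))
    }
    b_expo <- beta[names(beta) %in% expo_names]
    b_const <- beta[names(beta) %in% colnames(const_design)]
    lin <- cfg$intercepts[[t]] + site_effects[site] + u * cfg$shared_loading[[t]]
    if (length(b_const) > 0) {
      lin <- lin + drop(const_design[, names(b_const), drop = FALSE] %*% b_const)
    }
    eta <- matrix(lin, n, K)
    for (k in seq_len(K)) {
      if (length(b_expo) > 0) {
        eta[, k] <- eta[, k] +
          drop(expo_by_visit[[k]][, names(b_expo), drop = FALSE] %*% b_expo)
      }
      eta[, k] <- eta[, k] + cfg$time_varying_effect * z[, k]
    }
    hazards[[t]] <- sigmoid(eta)
  }

  # event and censoring draws
  ev_draw <- lapply(subst, function(t) {
    matrix(stats::runif(n * K), n, K) < hazards[[t]]
  })
  names(ev_draw) <- subst
  cens_draw <- matrix(stats::runif(n * K), n, K) < cfg$censoring_prob_per_interval
  first_true <- function(m) {
    # index of first TRUE per row, Inf if none
    idx <- apply(m, 1, function(r) {
      w <- which(r)
      if (length(w) == 0) Inf else w[1]
    })
    idx
  }
  k_cens <- first_true(cens_draw)
  cens_fu <- ifelse(is.finite(k_cens), (k_cens - 1) * sp + sp / 2, K * sp)

  tte_rows <- list()
  ev_time_fu <- matrix(Inf, n, length(subst), dimnames = list(NULL, subst))
  for (t in subst) {
    k_ev <- first_true(ev_draw[[t]])
    observed <- is.finite(k_ev) & (k_ev < k_cens)
    time_fu <- ifelse(observed, k_ev * sp, pmin(cens_fu, K * sp))
    ev_time_fu[observed, t] <- k_ev[observed] * sp
    tte_rows[[t]] <- data.frame(
      IID = iid, task = t, event = as.integer(observed),
      age_months = baseline_age + time_fu, stringsAsFactors = FALSE
    )
  }
  any_time <- apply(ev_time_fu, 1, min)
  any_event <- is.finite(any_time)
  any_fu <- ifelse(any_event, any_time, pmin(cens_fu, K * sp))
  tte_rows[["any"]] <- data.frame(
    IID = iid, task = "any", event = as.integer(any_event),
    age_months = baseline_age + any_fu, stringsAsFactors = FALSE
  )
  tte <- do.call(rbind, tte_rows)
  rownames(tte) <- NULL

  # visits table: exposures constant across visits, tv_exposure per visit
  visits <- data.frame(
    IID = rep(iid, each = cfg$n_visits),
    visit = rep(seq_len(cfg$n_visits), times = n),
    age_months = rep(baseline_age, each = cfg$n_visits) +
      (rep(seq_len(cfg$n_visits), times = n) - 1) * sp,
    tv_exposure = as.vector(t(z)),
    stringsAsFactors = FALSE
  )
  # interleave per-visit exposure matrices into subject-major visit order
  expo_rep <- matrix(NA_real_, n * cfg$n_visits, length(expo_names),
                     dimnames = list(NULL, expo_names))
  for (v in seq_len(cfg$n_visits)) {
    expo_rep[seq(v, n * cfg$n_visits, by = cfg$n_visits), ] <- expo_by_visit[[v]]
  }

  # sporadic cell-level missingness on exposures
  if (cfg$cell_missing_prob > 0) {
    miss <- matrix(stats::runif(length(expo_rep)) < cfg$cell_missing_prob,
                   nrow(expo_rep), ncol(expo_rep))
    expo_rep[miss] <- NA_real_
  }
  # block-missing columns drawn from null features only, so ground-truth
  # signal survives for recovery tests
  n_block <- round(cfg$missing_column_fraction * length(null_names))
  block_cols <- if (n_block > 0) {
    sort(sample(null_names, n_block))
  } else {
    character(0)
  }
  expo_rep[, block_cols] <- NA_real_
  visits <- cbind(visits, as.data.frame(expo_rep))

  covariates <- data.frame(
    IID = iid, sex = sex, baseline_age_months = baseline_age, site = site,
    stringsAsFactors = FALSE
  )
  covariates <- cbind(covariates, as.data.frame(pcs), as.data.frame(prs))

  truth <- list(
    intercepts = cfg$intercepts,
    signal_coef = cfg$signal_coef,
    shared_loading = cfg$shared_loading,
    time_varying_effect = cfg$time_varying_effect,
    ar1_rho = cfg$ar1_rho,
    site_effects = site_effects,
    u = u,
    hazards = hazards,
    censoring_interval_index = k_cens,
    signal_features = sig_names,
    null_features = null_names,
    missing_columns = block_cols,
    seed = cfg$seed
  )

  structure(list(visits = visits, tte = tte, covariates = covariates,
                 truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' Summarize a synthetic cohort
#'
#' Per-task event counts, end-of-follow-up prevalence, censoring fraction
#' (no event and follow-up short of the final visit) and mean time-to-event
#' in follow-up months among subjects with events. Degenerate tasks (all or
#' no subjects with events) are flagged.
#'
#' @param cohort A `synthetic_cohort`.
#' @return data.frame with one row per task.
#' @export
generation_report <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (nrow(cohort$tte) == 0) stopf("empty cohort")
  cfg <- cohort$config
  K <- max(1L, cfg$n_visits - 1L)
  full_fu <- K * cfg$visit_spacing_months
  base_age <- stats::setNames(cohort$covariates$baseline_age_months,
                              cohort$covariates$IID)
  out <- lapply(cfg$tasks, function(t) {
    d <- cohort$tte[cohort$tte$task == t, ]
    fu <- d$age_months - base_age[d$IID]
    n <- nrow(d)
    n_event <- sum(d$event)
    data.frame(
      task = t, n = n, n_event = n_event, prevalence = n_event / n,
      censored_fraction = mean(d$event == 0 & fu < full_fu - 1e-9),
      mean_time_to_event = if (n_event > 0) mean(fu[d$event == 1]) else NA_real_,
      degenerate = n_event == 0 || n_event == n,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (any(out$degenerate)) {
    warnf("degenerate task(s): %s", paste(out$task[out$degenerate], collapse = ", "))
  }
  out
}

#' Calibrate hazard intercepts against target prevalences by bisection
#'
#' For each substance task, finds the logit-hazard intercept whose implied
#' end-of-follow-up event prevalence matches a target, by bisection on the
#' Monte-Carlo expectation of the subject-level event probability
#' \eqn{\sum_k h_k \prod_{j<k}(1-h_j)(1-c)^{k-1}(1-c/2)}-style closed form
#' over a large simulated covariate sample (event and censoring draws are
#' integrated out, so the objective is smooth and deterministic given the
#' seed).
#'
#' @param config A [cohort_config()]; its non-intercept fields define the
#'   covariate and exposure distributions.
#' @param targets Named numeric of target prevalences for the substance tasks.
#' @param n_mc Monte-Carlo sample size for the covariate draw.
#' @param tol Bisection tolerance on prevalence.
#' @return Named numeric vector of calibrated intercepts.
#' @export
calibrate_intercepts <- function(config,
                                 targets = c(alcohol = 0.365, nicotine = 0.0544,
                                             cannabis = 0.0342),
                                 n_mc = 200000, tol = 1e-4) {
  validate_cohort_config(config)
  subst <- names(targets)
  K <- max(1L, config$n_visits - 1L)
  cens <- config$censoring_prob_per_interval
  out <- with_seed(config$seed, {
    n <- n_mc
    sex <- stats::rbinom(n, 1, 0.5)
    site <- sample.int(config$n_sites, n, replace = TRUE)
    site_effects <- stats::rnorm(config$n_sites, 0, config$site_sd)
    u <- stats::rnorm(n)
    rho <- config$ar1_rho
    z <- matrix(0, n, K)
    z[, 1] <- stats::rnorm(n)
    if (K > 1) {
      for (v in 2:K) z[, v] <- rho * z[, v - 1] + sqrt(1 - rho^2) * stats::rnorm(n)
    }
    res <- numeric(length(subst))
    names(res) <- subst
    for (t in subst) {
      beta <- config$signal_coef[[t]]
      expo_names <- grep("^exp_", names(beta), value = TRUE)
      lin0 <- site_effects[site] + u * config$shared_loading[[t]]
      if ("sex" %in% names(beta)) lin0 <- lin0 + beta[["sex"]] * sex
      other <- setdiff(names(beta), c(expo_names, "sex"))
      if (length(other) > 0) {
        lin0 <- lin0 + drop(matrix(stats::rnorm(n * length(other)), n) %*% beta[other])
      }
      # time-varying exposure contribution per interval (AR(1) panel)
      bx <- matrix(0, n, K)
      if (length(expo_names) > 0) {
        xk <- matrix(stats::rnorm(n * length(expo_names)), n)
        bx[, 1] <- drop(xk %*% beta[expo_names])
        if (K > 1) {
          for (k in 2:K) {
            xk <- rho * xk + sqrt(1 - rho^2) *
              matrix(stats::rnorm(n * length(expo_names)), n)
            bx[, k] <- drop(xk %*% beta[expo_names])
          }
        }
      }
      prev_at <- function(intercept) {
        eta <- intercept + matrix(lin0, n, K) + bx +
          config$time_varying_effect * z
        h <- sigmoid(eta)
        surv <- 1
        p_event <- 0
        for (k in seq_len(K)) {
          # event observed in interval k requires no dropout in intervals 1..k
          p_event <- p_event + surv * h[, k] * (1 - cens)^k
          surv <- surv * (1 - h[, k])
        }
        mean(p_event)
      }
      lo <- -10; hi <- 2
      while (hi - lo > 1e-6) {
        mid <- (lo + hi) / 2
        if (prev_at(mid) < targets[[t]]) lo <- mid else hi <- mid
        if (abs(prev_at((lo + hi) / 2) - targets[[t]]) < tol) break
      }
      res[t] <- round((lo + hi) / 2, 4)
    }
    res
  })
  out
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `visits.csv`, `tte.csv` (long format) and `covariates.csv` plus
#' `truth.json` holding the generating coefficients (matrices such as the
#' hazard grids and the latent liability are not serialized).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$visits, file.path(dir, "visits.csv"), row.names = FALSE)
  utils::write.csv(cohort$tte, file.path(dir, "tte.csv"), row.names = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  truth <- cohort$truth
  truth$u <- NULL
  truth$hazards <- NULL
  truth$censoring_interval_index <- NULL
  # named vectors become JSON objects, not nameless arrays
  truth$intercepts <- as.list(truth$intercepts)
  truth$shared_loading <- as.list(truth$shared_loading)
  truth$signal_coef <- lapply(truth$signal_coef, as.list)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return A list with `visits`, `tte`, `covariates` and `truth` (class
#'   `synthetic_cohort` is not restored: hazard matrices are not serialized).
#' @export
read_cohort <- function(dir) {
  list(
    visits = utils::read.csv(file.path(dir, "visits.csv"),
                             stringsAsFactors = FALSE),
    tte = utils::read.csv(file.path(dir, "tte.csv"), stringsAsFactors = FALSE),
    covariates = utils::read.csv(file.path(dir, "covariates.csv"),
                                 stringsAsFactors = FALSE),
    truth = jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  )
}
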