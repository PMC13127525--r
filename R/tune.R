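#' Search-space parameter constructors
#'
#' Define the sampling distribution for one hyperparameter in a [tune()]
#' search space: continuous uniform, log-uniform, integer-uniform, or
#' categorical over an explicit value list.
#'
#' @param low,high Bounds (inclusive; `par_loguniform` requires `low > 0`).
#' @param values List of candidate values for a categorical parameter.
#' @return A parameter spec used by [tune()].
#' @name search_space
NULL

#' @rdname search_space
#' @export
par_uniform <- function(low, high) {
  stopifnot(low <= high)
  structure(list(type = "uniform", low = low, high = high), class = "tune_par")
}

#' @rdname search_space
#' @export
par_loguniform <- function(low, high) {
  stopifnot(low > 0, low <= high)
  structure(list(type = "loguniform", low = low, high = high), class = "tune_par")
}

#' @rdname search_space
#' @export
par_int <- function(low, high) {
  stopifnot(low <= high)
  structure(list(type = "int", low = low, high = high), class = "tune_par")
}

#' @rdname search_space
#' @export
par_categorical <- function(values) {
  stopifnot(length(values) >= 1)
  structure(list(type = "categorical", values = values), class = "tune_par")
}

sample_par <- function(spec) {
  switch(spec$type,
         uniform = stats::runif(1, spec$low, spec$high),
         loguniform = exp(stats::runif(1, log(spec$low), log(spec$high))),
         int = sample(seq(spec$low, spec$high), 1),
         categorical = spec$values[[sample.int(length(spec$values), 1)]])
}

# transform numeric parameter values into the space the kernel density
# operates in (log for log-uniform)
par_transform <- function(spec, x) {
  if (spec$type == "loguniform") log(x) else as.numeric(x)
}
par_back <- function(spec, x) {
  out <- if (spec$type == "loguniform") exp(x) else x
  out <- min(max(out, spec$low), spec$high)
  if (spec$type == "int") out <- as.integer(round(out))
  out
}

# Parzen-window score of candidate points given observed values: Gaussian
# kernels at the observations plus a flat prior over the (transformed) range
parzen_score <- function(cand, obs, lo, hi) {
  rng <- max(hi - lo, 1e-12)
  prior <- 1 / rng
  if (length(obs) == 0) return(rep(prior, length(cand)))
  bw <- max(1.06 * stats::sd(obs) * length(obs)^(-1 / 5), rng / 20, 1e-12)
  dens <- vapply(cand, function(x) mean(stats::dnorm(x, obs, bw)), numeric(1))
  (length(obs) * dens + prior) / (length(obs) + 1)
}

#' Hyperparameter search with random or Tree-structured Parzen Estimator
#' sampling
#'
#' Maximizes `eval_fn` over a search space. The TPE sampler splits completed
#' trials into a good fraction (`gamma`) and the rest, models each parameter
#' with Parzen kernel densities l(x) (good) and g(x) (rest), draws
#' candidates from l and keeps the candidate maximizing l/g; categorical
#' parameters use smoothed category frequencies. The first `n_startup`
#' trials are random for either sampler.
#'
#' @param space Named list of parameter specs ([par_uniform()] etc.).
#' @param eval_fn Function taking a named list of parameter values and
#'   returning a scalar objective (larger is better; NA treated as -Inf).
#' @param budget Number of trials (>= 1).
#' @param sampler `"tpe"` or `"random"`.
#' @param seed Integer seed.
#' @param gamma Fraction of trials labelled good for TPE.
#' @param n_startup Random trials before TPE engages.
#' @param n_candidates Candidate draws per parameter per TPE step.
#' @return List of class `tune_result`: `best_params`, `best_value`,
#'   `trials` (data.frame trial log).
#' @export
tune <- function(space, eval_fn, budget, sampler = c("tpe", "random"),
                 seed = 1, gamma = 0.25, n_startup = 10, n_candidates = 24) {
  sampler <- match.arg(sampler)
  stopifnot(is.list(space), length(space) >= 1,
            all(vapply(space, inherits, logical(1), "tune_par")))
  if (budget < 1) stopf("budget must be >= 1")

  trials <- list()
  values <- numeric(0)
  with_seed(child_seed(seed, "tune"), {
    for (trial in seq_len(budget)) {
      params <- if (sampler == "random" || trial <= n_startup) {
        lapply(space, sample_par)
      } else {
        tpe_propose(space, trials, values, gamma, n_candidates)
      }
      v <- eval_fn(params)
      values[trial] <- if (is.na(v)) -Inf else v
      trials[[trial]] <- params
    }
  })

  best <- which.max(values)
  log_df <- do.call(rbind, lapply(seq_along(trials), function(i) {
    row <- data.frame(trial = i, value = values[i])
    for (nm in names(space)) {
      v <- trials[[i]][[nm]]
      row[[nm]] <- if (length(v) == 1 && is.atomic(v)) v else
        paste(unlist(v), collapse = "x")
    }
    row
  }))
  structure(list(best_params = trials[[best]], best_value = values[best],
                 trials = log_df),
            class = "tune_result")
}

tpe_propose <- function(space, trials, values, gamma, n_candidates) {
  n <- length(values)
  n_good <- max(1, ceiling(gamma * n))
  good_idx <- order(values, decreasing = TRUE)[seq_len(n_good)]
  out <- list()
  for (nm in names(space)) {
    spec <- space[[nm]]
    obs_all <- lapply(trials, `[[`, nm)
    if (spec$type == "categorical") {
      key <- vapply(obs_all, function(v) paste(unlist(v), collapse = "x"),
                    character(1))
      keys <- vapply(spec$values, function(v) paste(unlist(v), collapse = "x"),
                     character(1))
      cg <- table(factor(key[good_idx], levels = keys))
      cb <- table(factor(key[-good_idx], levels = keys))
      sm <- 1 / length(keys)
      ratio <- (as.numeric(cg) + sm) / (as.numeric(cb) + sm)
      # sample candidates from the good distribution, keep best l/g
      pg <- (as.numeric(cg) + sm) / sum(as.numeric(cg) + sm)
      cand <- sample.int(length(keys), n_candidates, replace = TRUE, prob = pg)
      out[[nm]] <- spec$values[[cand[which.max(ratio[cand])]]]
    } else {
      lo <- par_transform(spec, spec$low)
      hi <- par_transform(spec, spec$high)
      obs <- vapply(obs_all, function(v) par_transform(spec, v), numeric(1))
      good <- obs[good_idx]
      bad <- obs[-good_idx]
      # draw candidates from the good mixture (kernels + flat prior)
      bw <- max(1.06 * stats::sd(good) * max(length(good), 2)^(-1 / 5),
                (hi - lo) / 20, 1e-12)
      from_prior <- stats::runif(n_candidates) < 1 / (length(good) + 1)
      centers <- sample(good, n_candidates, replace = TRUE)
      cand <- ifelse(from_prior, stats::runif(n_candidates, lo, hi),
                     stats::rnorm(n_candidates, centers, bw))
      cand <- pmin(pmax(cand, lo), hi)
      score <- parzen_score(cand, good, lo, hi) /
        pmax(parzen_score(cand, bad, lo, hi), 1e-300)
      out[[nm]] <- par_back(spec, cand[which.max(score)])
    }
  }
  out
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("<tune_result> %d trials, best value %.4f\n",
              nrow(x$trials), x$best_value))
  utils::str(x$best_params, give.attr = FALSE)
  invisible(x)
}
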