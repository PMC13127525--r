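# Shared fixtures built in code.

# tiny cohort configuration for fast structural tests
tiny_cohort_config <- function(n = 300, seed = 42, ...) {
  cohort_config(n_subjects = n, seed = seed, ...)
}

# brute-force scalar double-loop oracle for the weighted masked loss
oracle_weighted_bce <- function(z, y, m, alpha, pos_weight) {
  total <- 0
  for (t in seq_len(ncol(z))) {
    s <- sum(m[, t])
    if (s == 0) next
    acc <- 0
    for (i in seq_len(nrow(z))) {
      if (m[i, t] == 1) {
        p <- 1 / (1 + exp(-z[i, t]))
        acc <- acc - (pos_weight[t] * y[i, t] * log(p) +
                        (1 - y[i, t]) * log(1 - p))
      }
    }
    total <- total + alpha[t] * acc / s
  }
  total
}

# brute-force oracle for the unweighted masked loss (global mean)
oracle_plain_bce <- function(z, y, m) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(z))) {
    for (t in seq_len(ncol(z))) {
      if (m[i, t] == 1) {
        p <- 1 / (1 + exp(-z[i, t]))
        num <- num - (y[i, t] * log(p) + (1 - y[i, t]) * log(1 - p))
        den <- den + 1
      }
    }
  }
  num / den
}

# random masked-loss problem instance; mask_mode exercises all patterns
random_loss_instance <- function(n, Tn = 4, mask_mode = c("random", "dense",
                                                          "one_task_empty",
                                                          "sparse")) {
  mask_mode <- match.arg(mask_mode)
  z <- matrix(rnorm(n * Tn, sd = 2), n, Tn)
  y <- matrix(rbinom(n * Tn, 1, 0.4), n, Tn)
  m <- switch(mask_mode,
              dense = matrix(1, n, Tn),
              random = matrix(rbinom(n * Tn, 1, 0.6), n, Tn),
              one_task_empty = {
                mm <- matrix(rbinom(n * Tn, 1, 0.7), n, Tn)
                mm[, sample(Tn, 1)] <- 0
                mm
              },
              sparse = {
                mm <- matrix(0, n, Tn)
                mm[sample(length(mm), max(1, n %/% 2))] <- 1
                mm
              })
  # guarantee the instance is not fully masked
  if (sum(m) == 0) m[sample(length(m), 1)] <- 1
  y[m == 0] <- NA
  list(z = z, y = y, m = m)
}

# exhaustive-rule oracle for horizon labeling: literal restatement of the
# outcome-definition rules, case by case
oracle_horizon_label <- function(event, time_fu, H) {
  if (is.na(event) || is.na(time_fu)) return(c(y = NA, m = 0))
  if (event == 1 && time_fu < H) return(c(y = 1, m = 1))
  if (event == 1 && time_fu >= H) return(c(y = 0, m = 1))
  if (event == 0 && time_fu >= H) return(c(y = 0, m = 1))
  c(y = NA, m = 0)  # censored before the horizon
}

# O(n^2) pairwise-comparison oracle for AUROC with tie handling
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# small person-period dataset with a linearly separable task, for training
# sanity tests
separable_data <- function(n = 400, seed = 7) {
  set.seed(seed)
  x <- cbind(a = rnorm(n), b = rnorm(n))
  y0 <- as.numeric(x[, 1] + x[, 2] > 0)
  y <- matrix(y0, n, 4)
  colnames(y) <- task_names()
  m <- matrix(1, n, 4, dimnames = dimnames(y))
  list(x = x, y = y, m = m)
}
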