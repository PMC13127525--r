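#' Area under the ROC curve (rank statistic, ties averaged)
#'
#' @param prob Numeric scores or probabilities.
#' @param labels Binary labels.
#' @return AUROC in \[0, 1\], or NA when labels are single-class.
#' @export
auroc <- function(prob, labels) {
  ok <- !is.na(prob) & !is.na(labels)
  prob <- prob[ok]; labels <- labels[ok]
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(prob, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Uses the step-wise average-precision convention (mean of precision at
#' each positive, scanning scores in decreasing order), avoiding the
#' optimism of trapezoidal interpolation. Score ties are broken by stable
#' input order.
#'
#' @inheritParams auroc
#' @return PR-AUC in \[0, 1\], or NA when labels are single-class.
#' @export
pr_auc <- function(prob, labels) {
  ok <- !is.na(prob) & !is.na(labels)
  prob <- prob[ok]; labels <- labels[ok]
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || n_pos == length(labels)) return(NA_real_)
  o <- order(prob, decreasing = TRUE)
  y <- labels[o]
  precision_at_k <- cumsum(y) / seq_along(y)
  sum(precision_at_k[y == 1]) / n_pos
}

#' Discrimination metrics over observed labels
#'
#' @inheritParams auroc
#' @return List with `auroc` and `pr_auc` (NA when undefined).
#' @export
discrimination <- function(prob, labels) {
  list(auroc = auroc(prob, labels), pr_auc = pr_auc(prob, labels))
}

#' Calibration metrics: Brier score, ECE and reliability curve
#'
#' ECE uses equal-width probability bins:
#' \eqn{\mathrm{ECE} = \sum_b (n_b/N)\,|\bar p_b - \bar y_b|}; empty bins
#' are skipped. The curve reports per-bin mean predicted probability and
#' observed event rate.
#'
#' @inheritParams auroc
#' @param n_bins Number of equal-width bins (default 10).
#' @return List with `brier`, `ece` and data.frame `curve`
#'   (`bin`, `n`, `mean_prob`, `event_rate`).
#' @export
calibration <- function(prob, labels, n_bins = 10) {
  ok <- !is.na(prob) & !is.na(labels)
  prob <- prob[ok]; labels <- labels[ok]
  stopifnot(all(prob >= 0 & prob <= 1))
  brier <- mean((prob - labels)^2)
  bin <- pmin(pmax(ceiling(prob * n_bins), 1L), n_bins)
  nb <- tapply(labels, bin, length)
  mp <- tapply(prob, bin, mean)
  er <- tapply(labels, bin, mean)
  curve <- data.frame(bin = as.integer(names(nb)), n = as.integer(nb),
                      mean_prob = as.numeric(mp), event_rate = as.numeric(er))
  ece <- sum(curve$n / length(prob) * abs(curve$mean_prob - curve$event_rate))
  list(brier = brier, ece = ece, curve = curve)
}

#' Subject-level cumulative risk from interval probabilities
#'
#' Aggregates a subject's per-interval initiation probabilities into the
#' probability of at least one initiation across the observed intervals:
#' \deqn{\mathrm{CumRisk} = 1 - \prod_k (1 - p_k).}
#' Computed in log space (probabilities clamped at \eqn{1 - 10^{-12}}) for
#' numerical stability; an empty interval list yields NA (the subject is
#' excluded for that task).
#'
#' @param p Vector of per-interval probabilities in \[0, 1\].
#' @return Cumulative risk in \[0, 1\], or NA for an empty input.
#' @export
cumulative_risk <- function(p) {
  if (length(p) == 0) return(NA_real_)
  stopifnot(all(p >= 0 & p <= 1))
  if (any(p == 1)) return(1)
  -expm1(sum(log1p(-pmin(p, 1 - 1e-12))))
}

#' Subject-level label from interval labels and masks
#'
#' 1 if any observed interval is positive, 0 if all observed intervals are
#' negative, NA (unobserved) if the subject has no observed interval.
#'
#' @param y Interval labels (NA where masked).
#' @param m Interval masks in \{0, 1\}.
#' @return 0, 1 or NA.
#' @export
subject_label <- function(y, m) {
  obs <- m == 1
  if (!any(obs)) return(NA_real_)
  as.numeric(any(y[obs] == 1))
}

#' Percentile bootstrap over subjects
#'
#' Resamples subject IDs with replacement `B` times, recomputes a metric on
#' each resample, and reports the 2.5th and 97.5th percentiles. Resamples on
#' which the metric is undefined (e.g. single-class labels) are skipped and
#' counted.
#'
#' @param metric_fn Function taking a data.frame (rows of the resampled
#'   subjects, duplicates included) and returning a scalar (NA allowed).
#' @param data data.frame with a subject-ID column `id_col`.
#' @param B Number of bootstrap resamples (>= 2).
#' @param seed Integer seed.
#' @param id_col Subject-ID column name.
#' @param probs CI percentiles.
#' @return List: `lower`, `upper`, `n_skipped`, `B`.
#' @export
bootstrap_ci <- function(metric_fn, data, B = 2000, seed = 1, id_col = "IID",
                         probs = c(0.025, 0.975)) {
  stopifnot(B >= 2, id_col %in% names(data))
  ids <- unique(data[[id_col]])
  rows_by_id <- split(seq_len(nrow(data)), data[[id_col]])
  vals <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      take <- sample(ids, length(ids), replace = TRUE)
      idx <- unlist(rows_by_id[take], use.names = FALSE)
      metric_fn(data[idx, , drop = FALSE])
    }, numeric(1))
  })
  ok <- !is.na(vals)
  if (!any(ok)) stopf("all bootstrap resamples were degenerate; CI undefined")
  q <- stats::quantile(vals[ok], probs, names = FALSE, type = 7)
  list(lower = q[1], upper = q[2], n_skipped = sum(!ok), B = B)
}

#' Per-task metric table for a prediction matrix
#'
#' Computes AUROC, PR-AUC, Brier score, accuracy at the 0.5 threshold and
#' ECE for each task, over observed cells only.
#'
#' @param prob Probability matrix (rows x tasks).
#' @param y Label matrix (NA where masked).
#' @param m Mask matrix.
#' @param level Label for the evaluation level (`"interval"` or
#'   `"subject"`), carried into the output.
#' @param n_bins Calibration bins.
#' @return data.frame with one row per task.
#' @export
task_metrics <- function(prob, y, m, level = "interval", n_bins = 10) {
  stopifnot(is.matrix(prob), all(dim(prob) == dim(y)), all(dim(prob) == dim(m)))
  tasks <- colnames(prob) %||% paste0("task", seq_len(ncol(prob)))
  out <- lapply(seq_len(ncol(prob)), function(t) {
    obs <- m[, t] == 1
    p <- prob[obs, t]; lab <- y[obs, t]
    disc <- discrimination(p, lab)
    cal <- if (length(p) > 0) calibration(p, lab, n_bins) else
      list(brier = NA_real_, ece = NA_real_)
    data.frame(
      task = tasks[t], level = level,
      auroc = disc$auroc, pr_auc = disc$pr_auc,
      brier = cal$brier,
      accuracy = if (length(p) > 0) mean((p >= 0.5) == lab) else NA_real_,
      ece = cal$ece,
      n_observed = sum(obs), n_positive = sum(lab == 1),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Subject-level cumulative-risk predictions from interval predictions
#'
#' Groups interval-level probabilities by subject, aggregates each
#' subject-task pair with [cumulative_risk()] over observed intervals, and
#' derives the subject label ("at least one observed positive interval").
#'
#' @param ids Subject ID per interval row.
#' @param prob Interval probability matrix (rows x tasks).
#' @param y,m Interval label and mask matrices.
#' @return List of subject-level matrices `prob`, `y`, `m` (subjects x
#'   tasks; mask 0 where a subject has no observed interval) and `ids`.
#' @export
aggregate_subject_risk <- function(ids, prob, y, m) {
  stopifnot(length(ids) == nrow(prob))
  uid <- unique(ids)
  Tn <- ncol(prob)
  sp <- sy <- sm <- matrix(NA_real_, length(uid), Tn,
                           dimnames = list(uid, colnames(prob)))
  sm[] <- 0
  rows_by_id <- split(seq_along(ids), ids)
  for (i in seq_along(uid)) {
    idx <- rows_by_id[[uid[i]]]
    for (t in seq_len(Tn)) {
      obs <- idx[m[idx, t] == 1]
      if (length(obs) == 0) next
      sp[i, t] <- cumulative_risk(prob[obs, t])
      sy[i, t] <- as.numeric(any(y[obs, t] == 1))
      sm[i, t] <- 1
    }
  }
  list(ids = uid, prob = sp, y = sy, m = sm)
}
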