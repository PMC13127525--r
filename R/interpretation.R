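#' Permutation feature importance by AUROC degradation
#'
#' Importance of a feature for one task is the decrease in AUROC (over
#' rows with an observed label for that task) after permuting that
#' feature's column within the evaluation split, averaged across a small
#' number of seeded repeats. To bound cost, the evaluated features can be
#' capped at `max_features`, chosen by a pre-screen on the model's absolute
#' first-layer weight norm (networks) or absolute coefficient (linear
#' baselines); the pre-screen is an approximation and is documented as such.
#'
#' @param model An `mtl_fit`, `mtl_network` or `lr_baseline`.
#' @param x Feature matrix of the evaluation split (preprocessed).
#' @param y,m Label and mask matrices aligned with `x`.
#' @param task Task name (a column of `y`) or index.
#' @param repeats Permutation repeats per feature.
#' @param max_features Cap on evaluated features (`NULL` = all).
#' @param seed Integer seed for the permutations.
#' @param model_label Free-text label carried into the output.
#' @return data.frame of class `importance_ranking`: `model`, `task`,
#'   `feature`, `importance` (AUROC drop), `rank` (1 = most important;
#'   ties broken by feature name).
#' @export
permutation_importance <- function(model, x, y, m, task, repeats = 3,
                                   max_features = NULL, seed = 1,
                                   model_label = class(model)[1]) {
  stopifnot(is.matrix(x), nrow(x) == nrow(y))
  t_idx <- if (is.character(task)) match(task, colnames(y)) else as.integer(task)
  if (is.na(t_idx)) stopf("unknown task '%s'", task)
  task_name <- colnames(y)[t_idx] %||% as.character(t_idx)
  obs <- m[, t_idx] == 1
  lab <- y[obs, t_idx]
  if (length(unique(lab)) < 2) {
    stopf("single-class labels for task '%s'; importance undefined", task_name)
  }
  base_auc <- auroc(predict_prob(model, x)[obs, t_idx], lab)

  features <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  eval_idx <- seq_len(ncol(x))
  if (!is.null(max_features) && max_features < ncol(x)) {
    w <- feature_screen_weights(model, x, t_idx)
    eval_idx <- order(w, decreasing = TRUE)[seq_len(max_features)]
  }

  imp <- with_seed(child_seed(seed, paste0("perm_", task_name)), {
    vapply(eval_idx, function(j) {
      drops <- vapply(seq_len(repeats), function(r) {
        xp <- x
        xp[, j] <- xp[sample.int(nrow(xp)), j]
        base_auc - auroc(predict_prob(model, xp)[obs, t_idx], lab)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })

  out <- data.frame(model = model_label, task = task_name,
                    feature = features[eval_idx], importance = imp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("importance_ranking", "data.frame")
  out
}

# probability predictions from any supported model
predict_prob <- function(model, x) {
  if (inherits(model, "mtl_fit") || inherits(model, "mtl_network") ||
      inherits(model, "lr_baseline")) {
    stats::predict(model, x)
  } else if (is.function(model)) {
    model(x)
  } else {
    stopf("unsupported model class: %s", paste(class(model), collapse = "/"))
  }
}

# pre-screen weights: first-layer L2 norm per input (networks) or |coef|
feature_screen_weights <- function(model, x, t_idx) {
  net <- if (inherits(model, "mtl_fit")) model$network else model
  if (inherits(net, "mtl_network")) {
    W1 <- if (length(net$trunk) > 0) net$trunk[[1]]$W else if
      (net$config$head == "joint") net$head$W else net$head[[t_idx]]$A
    sqrt(rowSums(W1^2))
  } else if (inherits(model, "lr_baseline")) {
    co <- coef(model)[[t_idx]]
    if (is.null(co)) rep(1, ncol(x)) else abs(co[-1])
  } else {
    rep(1, ncol(x))
  }
}

#' Jaccard overlap of two feature sets
#'
#' \eqn{|A \cap B| / |A \cup B|}; two empty sets give 0 with a warning.
#'
#' @param a,b Character vectors of feature names.
#' @return Scalar in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0) {
    warnf("both sets empty; Jaccard defined as 0")
    return(0)
  }
  length(intersect(a, b)) / length(u)
}

#' Cross-model consensus of feature rankings
#'
#' Takes top-`k` feature sets from each model's ranking, forms the shared
#' set (features identified by every model), and scores each shared feature
#' by the sum of inverse ranks across models,
#' \eqn{\mathrm{score}(f) = \sum_m 1/\mathrm{rank}_m(f)}, so a feature
#' ranked first everywhere attains the maximal score (the number of
#' models). Also reports the pairwise Jaccard matrix of the top-`k` sets.
#'
#' @param rankings Named list (>= 2) of rankings: either
#'   `importance_ranking` data.frames, data.frames with `feature` and
#'   `rank` columns, or character vectors ordered best-first.
#' @param k Top-k cutoff for set construction (default 20).
#' @return List of class `concordance_result`: `shared` (data.frame with
#'   `feature`, `score` and per-model ranks, sorted by descending score,
#'   ties broken by feature name), `jaccard` (symmetric matrix with unit
#'   diagonal), `k`.
#' @export
consensus_rank <- function(rankings, k = 20) {
  if (length(rankings) < 2) stopf("need rankings from at least 2 models")
  if (is.null(names(rankings)) || any(names(rankings) == "")) {
    names(rankings) <- paste0("model", seq_along(rankings))
  }
  rank_map <- lapply(rankings, function(r) {
    if (is.data.frame(r)) {
      stopifnot(all(c("feature", "rank") %in% names(r)))
      stats::setNames(r$rank, r$feature)
    } else {
      stats::setNames(seq_along(r), as.character(r))
    }
  })
  top_sets <- lapply(rank_map, function(rm) names(rm)[rm <= k])

  mods <- names(rankings)
  J <- matrix(1, length(mods), length(mods), dimnames = list(mods, mods))
  for (i in seq_along(mods)) {
    for (j in seq_along(mods)) {
      if (i < j) {
        J[i, j] <- J[j, i] <- jaccard(top_sets[[i]], top_sets[[j]])
      }
    }
  }

  shared_features <- Reduce(intersect, top_sets)
  shared <- if (length(shared_features) == 0) {
    df <- data.frame(feature = character(0), score = numeric(0))
    for (mname in mods) df[[paste0("rank_", mname)]] <- integer(0)
    df
  } else {
    df <- data.frame(feature = shared_features, stringsAsFactors = FALSE)
    df$score <- vapply(shared_features, function(f) {
      sum(vapply(rank_map, function(rm) 1 / rm[[f]], numeric(1)))
    }, numeric(1))
    for (mname in mods) {
      df[[paste0("rank_", mname)]] <- as.integer(rank_map[[mname]][df$feature])
    }
    df <- df[order(-df$score, df$feature), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  structure(list(shared = shared, jaccard = J, k = k),
            class = "concordance_result")
}

#' Read an externally supplied feature rank list
#'
#' Ingests rankings produced outside the package (e.g. from time-varying
#' Cox models) as a two-column text file: `feature` plus either `rank`
#' (1 = strongest) or `p_value` (converted to ranks, smallest p first,
#' average ties resolved by feature-name order).
#'
#' @param path CSV/TSV file path (delimiter auto-detected from extension).
#' @return data.frame with `feature` and `rank`.
#' @export
read_rank_list <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!"feature" %in% names(d)) stopf("rank file must have a 'feature' column")
  if ("rank" %in% names(d)) {
    d <- d[, c("feature", "rank")]
  } else if ("p_value" %in% names(d)) {
    d <- d[order(d$p_value, d$feature), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d <- d[, c("feature", "rank")]
  } else {
    stopf("rank file must have a 'rank' or 'p_value' column")
  }
  rownames(d) <- NULL
  d
}

#' Plot a pairwise Jaccard heatmap / consensus bar chart
#'
#' Thin ggplot2 visualizations of a [consensus_rank()] result: the pairwise
#' Jaccard overlap between models, and the shared features ordered by
#' consensus score with per-model ranks as labels.
#'
#' @param concordance A `concordance_result`.
#' @return A ggplot object.
#' @export
plot_jaccard_heatmap <- function(concordance) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("ggplot2 is required for plotting")
  }
  J <- concordance$jaccard
  d <- expand.grid(model_a = rownames(J), model_b = colnames(J),
                   stringsAsFactors = FALSE)
  d$jaccard <- as.vector(J)
  ggplot2::ggplot(d, ggplot2::aes(.data$model_a, .data$model_b,
                                  fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$jaccard))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard")
}

#' @rdname plot_jaccard_heatmap
#' @export
plot_consensus <- function(concordance) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("ggplot2 is required for plotting")
  }
  d <- concordance$shared
  if (nrow(d) == 0) stopf("no shared features to plot")
  rank_cols <- grep("^rank_", names(d), value = TRUE)
  d$label <- apply(d[rank_cols], 1, function(r) paste(r, collapse = "/"))
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(.data$score, .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), hjust = -0.1) +
    ggplot2::labs(x = "Consensus score (sum of inverse ranks)", y = NULL)
}
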