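#' Train a multi-task network with Adam, gradient clipping and early stopping
#'
#' Minimizes the masked objective named in the network's config:
#' `"weighted"` uses the task- and class-weighted loss
#' ([masked_weighted_bce()], the static pathway), `"plain"` the unweighted
#' mean over observed cells ([masked_bce()], the dynamic pathway). Training
#' uses minibatch Adam with L2 weight decay folded into the gradient and a
#' global gradient-norm clip. Early stopping monitors the configured
#' validation objective — the masked validation loss, or the mean over tasks
#' of (AUROC + PR-AUC)/2 on validation (tasks whose validation labels are
#' single-class are skipped) — with a fixed patience, and the best-epoch
#' parameters are restored.
#'
#' When `pos_weight` is `NULL` in the config and the weighted loss is used,
#' per-task weights default to (observed negatives)/(observed positives) on
#' the training data.
#'
#' @param net An untrained [build_network()] network.
#' @param train,val Lists with elements `x` (feature matrix), `y` (labels,
#'   NA where masked) and `m` (masks), rows aligned.
#' @return Object of class `mtl_fit`: `network` (best-epoch parameters),
#'   `history` (per-epoch data.frame), `selected_epoch`, `alpha`,
#'   `pos_weight`.
#' @export
train_mtl <- function(net, train, val) {
  cfg <- net$config
  Tn <- length(net$tasks)
  for (d in list(train, val)) {
    stopifnot(is.matrix(d$x), is.matrix(d$y), is.matrix(d$m),
              nrow(d$x) == nrow(d$y), ncol(d$y) == Tn)
  }
  alpha <- rep_len(cfg$alpha, Tn)
  pos_weight <- if (cfg$loss == "weighted") {
    if (is.null(cfg$pos_weight)) {
      vapply(seq_len(Tn), function(t) {
        obs <- train$m[, t] == 1
        np <- sum(train$y[obs, t] == 1)
        nn <- sum(train$y[obs, t] == 0)
        if (np == 0) 1 else nn / np
      }, numeric(1))
    } else {
      rep_len(cfg$pos_weight, Tn)
    }
  } else {
    rep(1, Tn)
  }

  loss_fn <- function(z, y, m) {
    if (cfg$loss == "weighted") masked_weighted_bce(z, y, m, alpha, pos_weight)
    else masked_bce(z, y, m)
  }
  grad_fn <- function(z, y, m) {
    if (cfg$loss == "weighted") grad_masked_weighted_bce(z, y, m, alpha, pos_weight)
    else grad_masked_bce(z, y, m)
  }

  n <- nrow(train$x)
  params <- nn_params(net)
  mom <- lapply(params, function(p) p * 0)
  vel <- mom
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0

  history <- list()
  best_obj <- if (cfg$objective == "val_loss") Inf else -Inf
  best_params <- params
  best_epoch <- 0L
  wait <- 0L

  with_seed(child_seed(cfg$seed, "train"), {
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n)
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1, n)]
        xb <- train$x[idx, , drop = FALSE]
        yb <- train$y[idx, , drop = FALSE]
        mb <- train$m[idx, , drop = FALSE]
        if (sum(mb) == 0) next
        fw <- nn_forward(net, xb, train = TRUE)
        dz <- grad_fn(fw$z, yb, mb)
        grads <- grads_as_params(net, nn_backward(net, xb, fw$cache, dz))
        # L2 weight decay folded into the gradient (coupled, Adam-style)
        if (cfg$weight_decay > 0) {
          for (k in names(grads)) {
            grads[[k]] <- grads[[k]] + cfg$weight_decay * params[[k]]
          }
        }
        gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
        if (!is.finite(gn)) stopf("non-finite gradient at epoch %d", epoch)
        if (gn > cfg$clip_norm) {
          grads <- lapply(grads, function(g) g * (cfg$clip_norm / gn))
        }
        step <- step + 1
        bc1 <- 1 - beta1^step
        bc2 <- 1 - beta2^step
        for (k in names(params)) {
          mom[[k]] <- beta1 * mom[[k]] + (1 - beta1) * grads[[k]]
          vel[[k]] <- beta2 * vel[[k]] + (1 - beta2) * grads[[k]]^2
          params[[k]] <- params[[k]] -
            cfg$lr * (mom[[k]] / bc1) / (sqrt(vel[[k]] / bc2) + eps)
        }
        net <- nn_set_params(net, params)
      }

      z_tr <- nn_forward(net, train$x, train = FALSE)$z
      z_va <- nn_forward(net, val$x, train = FALSE)$z
      train_loss <- loss_fn(z_tr, train$y, train$m)
      val_loss <- loss_fn(z_va, val$y, val$m)
      if (!is.finite(train_loss) || !is.finite(val_loss)) {
        stopf("non-finite loss at epoch %d (train %.4g, val %.4g)",
              epoch, train_loss, val_loss)
      }
      p_va <- sigmoid(z_va)
      per_task <- lapply(seq_len(Tn), function(t) {
        obs <- val$m[, t] == 1
        discrimination(p_va[obs, t], val$y[obs, t])
      })
      aucs <- vapply(per_task, `[[`, numeric(1), "auroc")
      praucs <- vapply(per_task, `[[`, numeric(1), "pr_auc")
      auc_mean <- mean((aucs + praucs) / 2, na.rm = TRUE)

      obj <- if (cfg$objective == "val_loss") val_loss else auc_mean
      improved <- if (cfg$objective == "val_loss") obj < best_obj else obj > best_obj
      row <- data.frame(epoch = epoch, train_loss = train_loss,
                        val_loss = val_loss, val_objective = obj)
      for (t in seq_len(Tn)) {
        row[[paste0("val_auroc_", net$tasks[t])]] <- aucs[t]
        row[[paste0("val_prauc_", net$tasks[t])]] <- praucs[t]
      }
      history[[epoch]] <- row

      if (improved) {
        best_obj <- obj
        best_params <- params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > cfg$patience) break
      }
    }
  })

  net <- nn_set_params(net, best_params)
  history <- do.call(rbind, history)
  structure(list(network = net, history = history,
                 selected_epoch = best_epoch, alpha = alpha,
                 pos_weight = pos_weight),
            class = "mtl_fit")
}

#' @export
predict.mtl_fit <- function(object, x, type = c("prob", "logit"), ...) {
  predict(object$network, x, type = match.arg(type))
}

#' @export
print.mtl_fit <- function(x, ...) {
  cat(sprintf("<mtl_fit> %s loss, %s head, selected epoch %d/%d\n",
              x$network$config$loss, x$network$config$head,
              x$selected_epoch, nrow(x$history)))
  invisible(x)
}

#' Single-task ridge-logistic baselines
#'
#' Fits one independent L2-regularized logistic regression per task on the
#' same preprocessed features, using only rows with an observed label for
#' that task. The regularization strength is chosen by seeded k-fold
#' cross-validation unless a fixed `lambda` is supplied. Tasks whose
#' training labels are single-class are rejected (recorded with a reason,
#' predictions NA).
#'
#' @param x Feature matrix.
#' @param y Label matrix (NA where masked).
#' @param m Mask matrix.
#' @param tasks Task names (defaults to `colnames(y)`).
#' @param lambda Fixed ridge penalty; `NULL` selects `lambda.min` by
#'   cross-validation.
#' @param nfolds CV folds.
#' @param seed Seed for the CV fold assignment.
#' @return Object of class `lr_baseline` with one model (or rejection
#'   reason) per task.
#' @export
fit_lr_baseline <- function(x, y, m, tasks = colnames(y), lambda = NULL,
                            nfolds = 5, seed = 1) {
  stopifnot(is.matrix(x), nrow(x) == nrow(y))
  tasks <- tasks %||% paste0("task", seq_len(ncol(y)))
  fits <- vector("list", length(tasks))
  names(fits) <- tasks
  for (t in seq_along(tasks)) {
    obs <- m[, t] == 1
    yt <- y[obs, t]
    if (length(unique(yt)) < 2) {
      fits[[t]] <- list(rejected = TRUE,
                        reason = "single-class training labels")
      warnf("task '%s' rejected: single-class training labels", tasks[t])
      next
    }
    xt <- x[obs, , drop = FALSE]
    if (is.null(lambda)) {
      foldid <- with_seed(child_seed(seed, paste0("lr_", tasks[t])),
                          sample(rep_len(seq_len(nfolds), length(yt))))
      cvfit <- glmnet::cv.glmnet(xt, yt, family = "binomial", alpha = 0,
                                 foldid = foldid, standardize = FALSE)
      fits[[t]] <- list(rejected = FALSE, fit = cvfit$glmnet.fit,
                        lambda = cvfit$lambda.min)
    } else {
      fit <- glmnet::glmnet(xt, yt, family = "binomial", alpha = 0,
                            lambda = lambda, standardize = FALSE)
      fits[[t]] <- list(rejected = FALSE, fit = fit, lambda = lambda)
    }
  }
  structure(list(fits = fits, tasks = tasks), class = "lr_baseline")
}

#' @export
predict.lr_baseline <- function(object, x, ...) {
  out <- matrix(NA_real_, nrow(x), length(object$tasks),
                dimnames = list(NULL, object$tasks))
  for (t in seq_along(object$tasks)) {
    f <- object$fits[[t]]
    if (isTRUE(f$rejected)) next
    out[, t] <- as.numeric(stats::predict(f$fit, newx = x, s = f$lambda,
                                          type = "response"))
  }
  out
}

#' Extract per-task coefficients of a ridge-logistic baseline
#' @param object An `lr_baseline`.
#' @param ... Unused.
#' @return Named list of coefficient vectors (intercept first), NULL for
#'   rejected tasks.
#' @export
coef.lr_baseline <- function(object, ...) {
  lapply(object$fits, function(f) {
    if (isTRUE(f$rejected)) return(NULL)
    as.numeric(stats::coef(f$fit, s = f$lambda))
  })
}
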