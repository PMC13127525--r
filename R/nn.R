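#' Masked, task- and class-weighted binary cross-entropy (static objective)
#'
#' The training objective of the baseline fixed-horizon multi-task model:
#' \deqn{\mathcal{L} = \sum_t \alpha_t \frac{1}{\sum_i m_{it}}
#'   \sum_i m_{it}\,\mathrm{BCEWithLogits}(z_{it}, y_{it};
#'   \mathrm{pos\_weight}_t)}
#' Each individual contributes only for tasks with an observed label; the
#' per-task mean is taken over observed cells, then tasks are combined with
#' weights \eqn{\alpha_t}. The positive-class weight multiplies the
#' \eqn{-y\log\sigma(z)} term to counteract class imbalance.
#'
#' Tasks with no observed labels contribute 0 with a warning.
#'
#' @param z Numeric matrix of logits (rows x tasks); must be finite.
#' @param y Binary label matrix (NA allowed where masked).
#' @param m Mask matrix in \{0,1\}: 1 where the label is observed.
#' @param alpha Per-task weights (> 0), recycled if scalar.
#' @param pos_weight Per-task positive-class weights (> 0), recycled.
#' @return Scalar loss.
#' @export
masked_weighted_bce <- function(z, y, m, alpha = 1, pos_weight = 1) {
  check_loss_inputs(z, y, m)
  Tn <- ncol(z)
  alpha <- rep_len(alpha, Tn)
  pos_weight <- rep_len(pos_weight, Tn)
  if (any(alpha <= 0) || any(pos_weight <= 0)) {
    stopf("alpha and pos_weight must be positive")
  }
  y0 <- ifelse(is.na(y), 0, y)
  total <- 0
  for (t in seq_len(Tn)) {
    s <- sum(m[, t])
    if (s == 0) {
      warnf("task %d has no observed labels; contributes 0 to the loss", t)
      next
    }
    l <- bce_with_logits(z[, t], y0[, t], pos_weight[t])
    total <- total + alpha[t] * sum(m[, t] * l) / s
  }
  total
}

#' Masked binary cross-entropy (dynamic objective)
#'
#' The training objective of the dynamic discrete-time multi-task model:
#' the unweighted mean of BCE-with-logits over all observed (interval, task)
#' cells,
#' \deqn{\mathcal{L} = \frac{\sum_{i,t} m_{it}\,
#'   \mathrm{BCEWithLogits}(z_{it}, y_{it})}{\sum_{i,t} m_{it}}.}
#' Each interval contributes only for tasks with observed labels.
#'
#' @inheritParams masked_weighted_bce
#' @return Scalar loss.
#' @export
masked_bce <- function(z, y, m) {
  check_loss_inputs(z, y, m)
  s <- sum(m)
  if (s == 0) stopf("all labels are masked; the loss is undefined")
  y0 <- ifelse(is.na(y), 0, y)
  sum(m * bce_with_logits(z, y0)) / s
}

check_loss_inputs <- function(z, y, m) {
  stopifnot(is.matrix(z), is.matrix(y), is.matrix(m))
  if (!all(dim(z) == dim(y)) || !all(dim(z) == dim(m))) {
    stopf("z, y, m must share dimensions")
  }
  if (any(!is.finite(z))) stopf("non-finite logits")
  if (!all(m %in% c(0, 1))) stopf("mask entries must be 0 or 1")
  if (any(m == 1 & (is.na(y) | !(y %in% c(0, 1))))) {
    stopf("observed labels must be 0 or 1")
  }
  invisible(TRUE)
}

# gradient of masked_weighted_bce w.r.t. z
grad_masked_weighted_bce <- function(z, y, m, alpha = 1, pos_weight = 1) {
  Tn <- ncol(z)
  alpha <- rep_len(alpha, Tn)
  pos_weight <- rep_len(pos_weight, Tn)
  y0 <- ifelse(is.na(y), 0, y)
  s <- sigmoid(z)
  g <- matrix(0, nrow(z), Tn)
  for (t in seq_len(Tn)) {
    st <- sum(m[, t])
    if (st == 0) next
    w <- pos_weight[t]
    g[, t] <- alpha[t] / st * m[, t] *
      (s[, t] * (1 + (w - 1) * y0[, t]) - w * y0[, t])
  }
  g
}

# gradient of masked_bce w.r.t. z
grad_masked_bce <- function(z, y, m) {
  y0 <- ifelse(is.na(y), 0, y)
  m * (sigmoid(z) - y0) / sum(m)
}

#' Multi-task network configuration
#'
#' @param hidden Integer vector of trunk hidden-layer sizes (default
#'   `c(256, 128)`); `integer(0)` gives a direct linear model.
#' @param dropout Dropout rate in \[0, 1) applied after each trunk layer.
#' @param head `"joint"` (single linear layer producing all task logits) or
#'   `"adapters"` (per-task bottleneck of width `adapter_dim` plus per-task
#'   output unit).
#' @param adapter_dim Bottleneck width of adapter heads.
#' @param alpha Per-task loss weights (static objective).
#' @param pos_weight Per-task positive-class weights; `NULL` means
#'   (observed negatives)/(observed positives) computed on the training
#'   split.
#' @param lr,weight_decay Adam learning rate and L2 weight decay.
#' @param batch_size Minibatch size.
#' @param max_epochs,patience Training length and early-stopping patience
#'   (epochs without improvement tolerated before stopping).
#' @param clip_norm Global gradient-norm clip.
#' @param loss `"weighted"` (static objective, task/class weights) or
#'   `"plain"` (dynamic objective, unweighted mean over observed cells).
#' @param objective Early-stopping monitor: `"auc_mean"` (maximize the mean
#'   over tasks of (AUROC + PR-AUC)/2 on validation) or `"val_loss"`
#'   (minimize the masked validation loss).
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @return Object of class `mtl_config`.
#' @export
mtl_config <- function(hidden = c(256, 128), dropout = 0.2,
                       head = c("joint", "adapters"), adapter_dim = 32,
                       alpha = 1, pos_weight = NULL,
                       lr = 1e-3, weight_decay = 1e-4, batch_size = 256,
                       max_epochs = 100, patience = 10, clip_norm = 5,
                       loss = c("weighted", "plain"),
                       objective = c("auc_mean", "val_loss"),
                       seed = 1) {
  head <- match.arg(head)
  loss <- match.arg(loss)
  objective <- match.arg(objective)
  stopifnot(dropout >= 0, dropout < 1, all(alpha > 0),
            is.null(pos_weight) || all(pos_weight > 0),
            lr > 0, weight_decay >= 0, batch_size >= 1, max_epochs >= 1,
            patience >= 0, clip_norm > 0)
  structure(list(hidden = as.integer(hidden), dropout = dropout, head = head,
                 adapter_dim = as.integer(adapter_dim), alpha = alpha,
                 pos_weight = pos_weight, lr = lr,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), clip_norm = clip_norm,
                 loss = loss, objective = objective, seed = as.integer(seed)),
            class = "mtl_config")
}

#' Build an untrained multi-task network
#'
#' A shared fully connected trunk with ReLU activations and dropout, and
#' either a single joint linear output layer producing one logit per task or
#' per-task adapter heads (ReLU bottleneck + linear output). Weights use
#' He-scaled Gaussian initialization, deterministic given the config seed.
#'
#' @param config An [mtl_config()].
#' @param n_features Number of input features.
#' @param tasks Character vector of task names (defines the logit columns).
#' @return Object of class `mtl_network`.
#' @export
build_network <- function(config, n_features, tasks = task_names()) {
  stopifnot(inherits(config, "mtl_config"), n_features >= 1)
  Tn <- length(tasks)
  with_seed(config$seed, {
    sizes <- c(n_features, config$hidden)
    trunk <- list()
    for (l in seq_along(config$hidden)) {
      trunk[[l]] <- list(
        W = matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0,
                                sqrt(2 / sizes[l])), sizes[l], sizes[l + 1]),
        b = numeric(sizes[l + 1])
      )
    }
    top <- sizes[length(sizes)]
    head <- if (config$head == "joint") {
      list(W = matrix(stats::rnorm(top * Tn, 0, sqrt(1 / top)), top, Tn),
           b = numeric(Tn))
    } else {
      lapply(seq_len(Tn), function(t) {
        list(A = matrix(stats::rnorm(top * config$adapter_dim, 0,
                                     sqrt(2 / top)), top, config$adapter_dim),
             a = numeric(config$adapter_dim),
             w = matrix(stats::rnorm(config$adapter_dim, 0,
                                     sqrt(1 / config$adapter_dim)),
                        config$adapter_dim, 1),
             c = 0)
      })
    }
    structure(list(trunk = trunk, head = head, config = config,
                   n_features = as.integer(n_features), tasks = tasks),
              class = "mtl_network")
  })
}

# forward pass; when train = TRUE, applies inverted dropout using draws from
# the current RNG stream and returns the cache needed for backprop
nn_forward <- function(net, x, train = FALSE) {
  p <- net$config$dropout
  a <- x
  cache <- list(a = list(a), relu = list(), drop = list())
  for (l in seq_along(net$trunk)) {
    z <- sweep(a %*% net$trunk[[l]]$W, 2, net$trunk[[l]]$b, "+")
    pos <- z > 0
    a <- z * pos
    cache$relu[[l]] <- pos
    if (train && p > 0) {
      keep <- matrix(stats::runif(length(a)) >= p, nrow(a), ncol(a))
      a <- a * keep / (1 - p)
      cache$drop[[l]] <- keep
    }
    cache$a[[l + 1]] <- a
  }
  if (net$config$head == "joint") {
    z_out <- sweep(a %*% net$head$W, 2, net$head$b, "+")
  } else {
    cache$adapter <- vector("list", length(net$head))
    z_out <- matrix(0, nrow(a), length(net$head))
    for (t in seq_along(net$head)) {
      h <- net$head[[t]]
      zb <- sweep(a %*% h$A, 2, h$a, "+")
      posb <- zb > 0
      bact <- zb * posb
      cache$adapter[[t]] <- list(pos = posb, bact = bact)
      z_out[, t] <- bact %*% h$w + h$c
    }
  }
  colnames(z_out) <- net$tasks
  list(z = z_out, cache = cache)
}

# backward pass from dL/dz; returns gradients in the parameter layout of net
nn_backward <- function(net, x, cache, dz) {
  p <- net$config$dropout
  L <- length(net$trunk)
  a_top <- cache$a[[L + 1]]
  grads <- list(trunk = vector("list", L))
  if (net$config$head == "joint") {
    grads$head <- list(W = crossprod(a_top, dz), b = colSums(dz))
    da <- tcrossprod(dz, net$head$W)
  } else {
    grads$head <- vector("list", length(net$head))
    da <- matrix(0, nrow(a_top), ncol(a_top))
    for (t in seq_along(net$head)) {
      h <- net$head[[t]]
      ad <- cache$adapter[[t]]
      dzt <- dz[, t]
      gw <- crossprod(ad$bact, dzt)
      gc <- sum(dzt)
      dbact <- (dzt %*% t(h$w)) * ad$pos  # n x adapter_dim
      gA <- crossprod(a_top, dbact)
      ga <- colSums(dbact)
      grads$head[[t]] <- list(A = gA, a = ga, w = gw, c = gc)
      da <- da + dbact %*% t(h$A)
    }
  }
  for (l in rev(seq_len(L))) {
    if (p > 0) da <- da * cache$drop[[l]] / (1 - p)
    dzl <- da * cache$relu[[l]]
    grads$trunk[[l]] <- list(W = crossprod(cache$a[[l]], dzl),
                             b = colSums(dzl))
    if (l > 1) da <- dzl %*% t(net$trunk[[l]]$W)
  }
  grads
}

#' Predict from a multi-task network
#'
#' @param object An `mtl_network`.
#' @param x Feature matrix (already preprocessed).
#' @param type `"prob"` for sigmoid probabilities, `"logit"` for raw logits.
#' @param ... Unused.
#' @return Matrix (rows x tasks).
#' @export
predict.mtl_network <- function(object, x, type = c("prob", "logit"), ...) {
  type <- match.arg(type)
  z <- nn_forward(object, x, train = FALSE)$z
  if (type == "prob") sigmoid(z) else z
}

# flatten/restore parameters for the optimizer
nn_params <- function(net) {
  ps <- list()
  for (l in seq_along(net$trunk)) {
    ps[[paste0("trunk", l, ".W")]] <- net$trunk[[l]]$W
    ps[[paste0("trunk", l, ".b")]] <- net$trunk[[l]]$b
  }
  if (net$config$head == "joint") {
    ps[["head.W"]] <- net$head$W
    ps[["head.b"]] <- net$head$b
  } else {
    for (t in seq_along(net$head)) {
      for (nm in c("A", "a", "w", "c")) {
        ps[[paste0("head", t, ".", nm)]] <- net$head[[t]][[nm]]
      }
    }
  }
  ps
}

nn_set_params <- function(net, ps) {
  for (l in seq_along(net$trunk)) {
    net$trunk[[l]]$W <- ps[[paste0("trunk", l, ".W")]]
    net$trunk[[l]]$b <- ps[[paste0("trunk", l, ".b")]]
  }
  if (net$config$head == "joint") {
    net$head$W <- ps[["head.W"]]
    net$head$b <- ps[["head.b"]]
  } else {
    for (t in seq_along(net$head)) {
      for (nm in c("A", "a", "w", "c")) {
        net$head[[t]][[nm]] <- ps[[paste0("head", t, ".", nm)]]
      }
    }
  }
  net
}

grads_as_params <- function(net, grads) {
  ps <- list()
  for (l in seq_along(grads$trunk)) {
    ps[[paste0("trunk", l, ".W")]] <- grads$trunk[[l]]$W
    ps[[paste0("trunk", l, ".b")]] <- grads$trunk[[l]]$b
  }
  if (net$config$head == "joint") {
    ps[["head.W"]] <- grads$head$W
    ps[["head.b"]] <- grads$head$b
  } else {
    for (t in seq_along(grads$head)) {
      for (nm in c("A", "a", "w", "c")) {
        ps[[paste0("head", t, ".", nm)]] <- grads$head[[t]][[nm]]
      }
    }
  }
  ps
}

#' Count trainable parameters of a network
#' @param net An `mtl_network`.
#' @return Integer total.
#' @export
n_parameters <- function(net) {
  sum(vapply(nn_params(net), length, integer(1)))
}
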