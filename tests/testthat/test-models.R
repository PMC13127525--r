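test_that("parameter counts follow the closed form for the joint head", {
  cfg <- mtl_config(hidden = c(256, 128), seed = 1)
  net <- build_network(cfg, n_features = 51)
  expect_equal(n_parameters(net),
               51 * 256 + 256 + 256 * 128 + 128 + 128 * 4 + 4)
  expect_equal(n_parameters(net), 46724)
})

test_that("initialization is seed-deterministic and dropout-0 forward passes agree", {
  cfg <- mtl_config(hidden = c(16, 8), dropout = 0, seed = 9)
  net1 <- build_network(cfg, 10)
  net2 <- build_network(cfg, 10)
  x <- matrix(rnorm(50), 5, 10)
  expect_identical(predict(net1, x, type = "logit"),
                   predict(net2, x, type = "logit"))
  # train-mode and eval-mode forward passes coincide without dropout
  fw_train <- dynmtl:::nn_forward(net1, x, train = TRUE)
  fw_eval <- dynmtl:::nn_forward(net1, x, train = FALSE)
  expect_identical(fw_train$z, fw_eval$z)
  net3 <- build_network(mtl_config(hidden = c(16, 8), dropout = 0, seed = 10), 10)
  expect_false(identical(predict(net1, x, type = "logit"),
                         predict(net3, x, type = "logit")))
})

test_that("an empty hidden list yields a working direct linear model", {
  cfg <- mtl_config(hidden = integer(0), dropout = 0, seed = 2)
  net <- build_network(cfg, 3)
  x <- matrix(rnorm(30), 10, 3)
  z <- predict(net, x, type = "logit")
  expect_equal(dim(z), c(10, 4))
  expect_true(all(is.finite(z)))
})

test_that("backpropagation matches finite differences for both heads", {
  set.seed(55)
  for (head in c("joint", "adapters")) {
    cfg <- mtl_config(hidden = c(6, 5), dropout = 0, head = head,
                      adapter_dim = 3, seed = 20)
    net <- build_network(cfg, 4)
    x <- matrix(rnorm(32), 8, 4)
    y <- matrix(rbinom(32, 1, 0.5), 8, 4, dimnames = list(NULL, task_names()))
    m <- matrix(rbinom(32, 1, 0.8), 8, 4)
    if (any(colSums(m) == 0)) m[1, ] <- 1
    y[m == 0] <- NA
    alpha <- c(1, 2, 0.5, 1); pw <- c(1.5, 1, 2, 1)

    loss_at <- function(nn) {
      z <- dynmtl:::nn_forward(nn, x, train = FALSE)$z
      masked_weighted_bce(z, y, m, alpha, pw)
    }
    fw <- dynmtl:::nn_forward(net, x, train = FALSE)
    dz <- dynmtl:::grad_masked_weighted_bce(fw$z, y, m, alpha, pw)
    grads <- dynmtl:::grads_as_params(
      net, dynmtl:::nn_backward(net, x, fw$cache, dz))
    params <- dynmtl:::nn_params(net)
    h <- 1e-6
    for (k in names(params)) {
      idx <- sample(length(params[[k]]), min(3, length(params[[k]])))
      for (i in idx) {
        pp <- params; pp[[k]][i] <- pp[[k]][i] + h
        up <- loss_at(dynmtl:::nn_set_params(net, pp))
        pp[[k]][i] <- pp[[k]][i] - 2 * h
        dn <- loss_at(dynmtl:::nn_set_params(net, pp))
        expect_equal(grads[[k]][i], (up - dn) / (2 * h), tolerance = 1e-4)
      }
    }
  }
})

test_that("training separates a linearly separable problem within 50 epochs", {
  dat <- separable_data(n = 400)
  cfg <- mtl_config(hidden = c(8), dropout = 0, lr = 5e-3, weight_decay = 0,
                    batch_size = 64, max_epochs = 50, patience = 50,
                    loss = "plain", objective = "val_loss", seed = 3)
  net <- build_network(cfg, ncol(dat$x))
  fit <- train_mtl(net, dat, dat)
  p <- predict(fit, dat$x)
  expect_gt(auroc(p[, 1], dat$y[, 1]), 0.999)
})

test_that("training histories are seed-deterministic", {
  dat <- separable_data(n = 200, seed = 11)
  cfg <- mtl_config(hidden = c(6), dropout = 0.3, batch_size = 64,
                    max_epochs = 8, patience = 8, seed = 7)
  f1 <- train_mtl(build_network(cfg, 2), dat, dat)
  f2 <- train_mtl(build_network(cfg, 2), dat, dat)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$network$trunk, f2$network$trunk)
})

test_that("patience 0 stops exactly one epoch after the first non-improvement", {
  dat <- separable_data(n = 150, seed = 13)
  cfg <- mtl_config(hidden = c(4), dropout = 0, batch_size = 32,
                    max_epochs = 40, patience = 0,
                    loss = "plain", objective = "val_loss", seed = 5)
  fit <- train_mtl(build_network(cfg, 2), dat, dat)
  h <- fit$history
  if (nrow(h) < 40) {
    # the run stopped early: the last epoch must be the first one that
    # failed to improve the running best, and none before it did
    best <- cummin(c(Inf, head(h$val_loss, -1)))
    improved <- h$val_loss < best
    expect_true(all(improved[-nrow(h)]))
    expect_false(improved[nrow(h)])
    expect_equal(fit$selected_epoch, nrow(h) - 1)
  } else {
    expect_equal(fit$selected_epoch, which.min(h$val_loss))
  }
})

test_that("non-finite training dynamics abort with a diagnostic", {
  dat <- separable_data(n = 100, seed = 17)
  dat$x[1, 1] <- 1e308  # forces overflow in the gradient accumulation
  cfg <- mtl_config(hidden = c(4), dropout = 0, lr = 1, batch_size = 100,
                    max_epochs = 3, patience = 3, seed = 1)
  expect_error(train_mtl(build_network(cfg, 2), dat, dat), "non-finite")
})

test_that("ridge-logistic baselines honor the regularization limits", {
  set.seed(23)
  n <- 400
  x <- cbind(f1 = rnorm(n), f2 = rnorm(n))
  y0 <- as.numeric(x[, 1] > 0)
  y <- matrix(y0, n, 4, dimnames = list(NULL, task_names()))
  m <- matrix(1, n, 4)
  # vanishing penalty on separable data: perfect training discrimination
  fit_lo <- fit_lr_baseline(x, y, m, lambda = 1e-8)
  expect_gt(auroc(predict(fit_lo, x)[, 1], y0), 0.999)
  # infinite penalty: coefficients ~ 0, predictions ~ constant prevalence
  fit_hi <- fit_lr_baseline(x, y, m, lambda = 1e9)
  expect_lt(max(abs(coef(fit_hi)[[1]][-1])), 1e-6)
  expect_equal(unname(predict(fit_hi, x)[1, 1]), mean(y0), tolerance = 0.01)
})

test_that("ridge-logistic recovers generating coefficients at n = 5000", {
  set.seed(29)
  n <- 5000
  x <- cbind(f1 = rnorm(n), f2 = rnorm(n))
  beta <- c(1.0, -0.7)
  y0 <- rbinom(n, 1, plogis(-0.5 + x %*% beta))
  y <- matrix(y0, n, 4, dimnames = list(NULL, task_names()))
  m <- matrix(1, n, 4)
  fit <- fit_lr_baseline(x, y, m, lambda = 1e-5)
  est <- coef(fit)[[1]][-1]
  expect_lt(max(abs(est - beta) / abs(beta)), 0.10)
})

test_that("single-class tasks are rejected with a warning and predict NA", {
  set.seed(31)
  x <- matrix(rnorm(60), 30, 2)
  y <- matrix(rbinom(120, 1, 0.5), 30, 4, dimnames = list(NULL, task_names()))
  y[, 2] <- 0
  m <- matrix(1, 30, 4)
  expect_warning(fit <- fit_lr_baseline(x, y, m, lambda = 0.1), "single-class")
  p <- predict(fit, x)
  expect_true(all(is.na(p[, 2])))
  expect_true(all(is.finite(p[, 1])))
})

test_that("auto pos_weight defaults to observed negative/positive ratio", {
  set.seed(37)
  dat <- separable_data(n = 60)
  dat$y[, 2] <- rep(c(1, 0, 0, 0), 15)  # 15 pos / 45 neg
  cfg <- mtl_config(hidden = c(4), dropout = 0, max_epochs = 1, patience = 1,
                    batch_size = 60, loss = "weighted", seed = 1)
  fit <- train_mtl(build_network(cfg, 2), dat, dat)
  expect_equal(fit$pos_weight[2], 45 / 15)
})
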