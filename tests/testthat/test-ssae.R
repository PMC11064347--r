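test_that("the bi-output loss honours its endpoint identities", {
  set.seed(1)
  X <- matrix(rnorm(20), 4, 5); Xp <- X + matrix(rnorm(20, 0, 0.3), 4, 5)
  Y <- matrix(rnorm(8), 4, 2); Yp <- Y + matrix(rnorm(8, 0, 0.3), 4, 2)
  expect_equal(ssae_loss(X, X, Y, Y, 0.37), 0)
  expect_equal(ssae_loss(X, Xp, Y, Yp, 1), mean((X - Xp)^2))
  expect_equal(ssae_loss(X, Xp, Y, Yp, 0), mean((Y - Yp)^2))
  # linear in alpha
  a <- c(0.2, 0.5, 0.8)
  l <- vapply(a, function(al) ssae_loss(X, Xp, Y, Yp, al), 0)
  expect_equal(diff(l) / diff(a), rep((l[3] - l[1]) / 0.6, 2))
  # hand example under the mean-MSE convention
  expect_equal(ssae_loss(matrix(c(1, 0), 1), matrix(c(0, 0), 1),
                         matrix(1), matrix(0), 0.5), 0.75)
  expect_error(ssae_loss(X, Xp[, 1:3], Y, Yp, 0.5), "shape")
})

test_that("corruption adds the configured amount of fresh noise", {
  X <- matrix(0, 1000, 1000)
  expect_identical(corrupt(X, 0), X)
  set.seed(2)
  D <- corrupt(X, 0.1) - X
  expect_equal(sd(D), 0.1, tolerance = 0.001)
  set.seed(3); a <- corrupt(X[1:5, 1:5], 0.2)
  set.seed(3); b <- corrupt(X[1:5, 1:5], 0.2)
  expect_identical(a, b)
  expect_error(corrupt(X, -1), "sigma")
})

test_that("parameter counts match exhaustive weight enumeration", {
  arch <- ssae_architecture(10, 4, 2, t = 5, r = 0)
  expect_identical(ssae_n_params(arch), 137L)
  for (dims in list(c(12, 6, 3, 2), c(30, 10, 4, 5), c(5, 5, 5, 1))) {
    a <- ssae_architecture(dims[1], dims[2], dims[3], t = dims[4], r = 0.2)
    m <- build_ssae(a, seed = 1)
    expect_identical(ssae_n_params(a),
                     sum(vapply(m$weights, length, 0L)))
  }
})

test_that("LeakyReLU and architecture validation behave as specified", {
  expect_equal(leaky_relu(-2, 0.1), -0.2)
  expect_equal(leaky_relu(3, 0.1), 3)
  expect_error(ssae_architecture(4, 8, 2), "l <= p <= p_in")
  expect_error(ssae_architecture(8, 4, 6), "l <= p <= p_in")
  expect_error(ssae_architecture(8, 4, 2, r = 1), "dropout")
  expect_error(ssae_architecture(8, 4, 2, alpha = 1.2), "alpha")
})

test_that("weight initialization is reproducible under a seed", {
  a <- ssae_architecture(12, 5, 2, t = 3)
  expect_identical(build_ssae(a, seed = 9)$weights,
                   build_ssae(a, seed = 9)$weights)
  expect_false(identical(build_ssae(a, seed = 9)$weights,
                         build_ssae(a, seed = 10)$weights))
})

test_that("backpropagated gradients match finite differences", {
  set.seed(4)
  arch <- ssae_architecture(6, 4, 2, t = 2, r = 0, alpha = 0.6)
  m <- build_ssae(arch, seed = 3)
  X <- matrix(rnorm(30), 5, 6); Y <- matrix(rnorm(10), 5, 2)
  f <- lateomix:::.ssae_forward(m$weights, X, arch)
  g <- lateomix:::.ssae_backward(m$weights, f, X, Y, arch)
  num_grad <- function(nm, i) {
    eps <- 1e-6
    w <- m$weights
    loss_at <- function(wi) {
      w[[nm]][i] <- wi
      fw <- lateomix:::.ssae_forward(w, X, arch)
      ssae_loss(X, fw$Xhat, Y, fw$Yhat, arch$alpha)
    }
    (loss_at(m$weights[[nm]][i] + eps) -
       loss_at(m$weights[[nm]][i] - eps)) / (2 * eps)
  }
  for (nm in names(m$weights))
    for (i in 1:2)
      expect_equal(g[[nm]][i], num_grad(nm, i), tolerance = 1e-6)
})

test_that("a fully linear network encodes as a matrix product", {
  arch <- ssae_architecture(6, 4, 3, t = 2, r = 0, leaky_slope = 1)
  m <- build_ssae(arch, seed = 5)
  X <- matrix(rnorm(60), 10, 6)
  w <- m$weights
  oracle <- sweep(sweep(X %*% w$W1, 2, w$b1, "+") %*% w$W2, 2, w$b2, "+")
  expect_equal(unname(encode(m, X)), oracle, tolerance = 1e-6)
})

test_that("a hand-set 2-2-1 encoder reproduces manual forward passes", {
  arch <- ssae_architecture(2, 2, 1, t = 1, r = 0, leaky_slope = 0.1)
  m <- build_ssae(arch, seed = 1)
  m$weights$W1 <- matrix(c(1, 0, -1, 2), 2, 2)
  m$weights$b1 <- c(0.5, -0.5)
  m$weights$W2 <- matrix(c(2, -1), 2, 1)
  m$weights$b2 <- 0.25
  lr <- function(u) ifelse(u > 0, u, 0.1 * u)
  x <- c(1, -2)
  h <- lr(c(x %*% m$weights$W1) + m$weights$b1)
  z <- lr(sum(h * c(2, -1)) + 0.25)
  expect_equal(unname(drop(encode(m, matrix(x, 1)))), z)
})

test_that("zero weights encode everything to zero", {
  arch <- ssae_architecture(5, 3, 2, t = 1, r = 0)
  m <- build_ssae(arch, seed = 1)
  m$weights <- lapply(m$weights, function(w) w * 0)
  expect_true(all(encode(m, matrix(rnorm(25), 5, 5)) == 0))
})

test_that("training halves the reconstruction error on low-rank data", {
  for (s in 1:5) {
    set.seed(s)
    n <- 250; Z <- matrix(rnorm(n * 3), n, 3)
    X <- Z %*% matrix(rnorm(3 * 20), 3, 20) +
      matrix(rnorm(n * 20, 0, 0.3), n, 20)
    Y <- matrix(Z[, 1] + rnorm(n, 0, 0.2), ncol = 1)
    fit <- ssae(X, Y, p = 10, l = 3, alpha = 0.9, r = 0.1,
                control = fast_ctl(seed = s, epochs = 60), seed = s)
    h <- fit$history
    expect_lt(h$val_recon_mse[nrow(h)], 0.5 * h$val_recon_mse[1])
  }
})

test_that("alpha = 1 leaves the prediction head untouched", {
  set.seed(6)
  X <- matrix(rnorm(120 * 8), 120, 8)
  arch <- ssae_architecture(8, 4, 2, t = 1, r = 0, alpha = 1)
  m <- build_ssae(arch, seed = 2)
  before <- m$weights[c("H1", "h1", "H2", "h2")]
  fit <- train_ssae(m, X, NULL, fast_ctl(seed = 7, epochs = 10))
  expect_identical(fit$weights[c("H1", "h1", "H2", "h2")], before)
  expect_false(identical(fit$weights$W1, m$weights$W1))
})

test_that("the early-stopping rule fires exactly when specified", {
  # monotone increasing validation curve with window 1: stop right after
  # the minimum epoch count
  expect_false(ssae_should_stop(1:5, min_epochs = 5, stop_window = 1))
  expect_true(ssae_should_stop(1:6, min_epochs = 5, stop_window = 1))
  # improving curve never stops
  expect_false(ssae_should_stop(rev(seq(1, 2, length.out = 20)),
                                min_epochs = 5, stop_window = 10))
  # flat curve stops (no improvement over the window mean)
  expect_true(ssae_should_stop(rep(1, 8), min_epochs = 5, stop_window = 3))
})

test_that("the matched unsupervised control stops at the target MSE", {
  set.seed(8)
  n <- 150
  Z <- matrix(rnorm(n * 2), n, 2)
  X <- Z %*% matrix(rnorm(2 * 10), 2, 10) +
    matrix(rnorm(n * 10, 0, 0.4), n, 10)
  arch <- ssae_architecture(10, 6, 2, t = 1, r = 0)
  # vacuous target: one epoch suffices
  u <- train_usae_matched(arch, X, Inf, fast_ctl(seed = 1, epochs = 30))
  expect_equal(nrow(u$history), 1L)
  # unreachable target: explicit non-convergence error
  expect_error(train_usae_matched(arch, X, 0,
                                  fast_ctl(seed = 1, epochs = 5)),
               "did not reach")
})

test_that("paired SSAE/USAE end within one epoch's improvement in MSE", {
  for (s in 1:5) {
    d <- planted_lowrank(100 + s, n = 250, p_in = 25)
    sc <- fit_scaler(d$X, rep(TRUE, 250), "zscore")
    Xs <- apply_scaler(d$X, sc)
    val <- seq_len(250) %% 5 == 0
    Y <- matrix(scale(d$y), ncol = 1)
    sf <- ssae(Xs, Y, p = 8, l = 2, alpha = 0.5, r = 0.1,
               control = fast_ctl(seed = s, epochs = 50),
               validation = val, seed = s)
    target <- sf$history$val_recon_mse[nrow(sf$history)]
    uf <- train_usae_matched(sf$architecture, Xs, target,
                             fast_ctl(seed = s + 50, epochs = 120),
                             validation = val, seed = s + 50)
    hu <- uf$history$val_recon_mse
    final <- hu[length(hu)]
    one_epoch_gain <- if (length(hu) > 1)
      abs(hu[length(hu) - 1] - final) else final
    expect_lte(abs(final - target), one_epoch_gain + 1e-12)
    expect_lte(final, target)
  }
})

test_that("architecture search picks the smallest feasible candidate", {
  set.seed(10)
  n <- 200
  Z <- matrix(rnorm(n * 2), n, 2)
  X <- Z %*% matrix(rnorm(2 * 12), 2, 12) +
    matrix(rnorm(n * 12, 0, 0.2), n, 12)
  X <- apply_scaler(X, fit_scaler(X, rep(TRUE, n), "zscore"))
  Y <- matrix(Z[, 1], ncol = 1)
  grid <- data.frame(p = c(4, 8), l = c(2, 4))
  sel <- select_architecture(grid, X, Y, fast_ctl(seed = 2, epochs = 40),
                             mse_cap = 10, corr_cap = 1, alpha = 0.9,
                             r = 0, seed = 3)
  # both candidates feasible under the loose caps: fewest parameters wins
  expect_equal(sel$p, 4L)
  expect_equal(sel$l, 2L)
  diag <- attr(sel, "diagnostics")
  expect_true(all(diag$feasible))
  expect_equal(diag$n_params,
               vapply(seq_len(2), function(i) ssae_n_params(
                 ssae_architecture(12, grid$p[i], grid$l[i], t = 1)), 0L))
  expect_error(
    select_architecture(grid, X, Y, fast_ctl(seed = 2, epochs = 5),
                        mse_cap = -1, corr_cap = 0, r = 0, seed = 3),
    "no feasible architecture")
})

test_that("fitted models expose the standard S3 surface", {
  set.seed(11)
  X <- matrix(rnorm(150 * 10), 150, 10)
  Y <- matrix(X[, 1] + rnorm(150, 0, 0.1), ncol = 1)
  fit <- ssae(X, Y, p = 5, l = 2, alpha = 0.8, r = 0,
              control = fast_ctl(seed = 1, epochs = 12), seed = 1)
  expect_output(print(fit), "Semi-supervised")
  expect_named(coef(fit), c("W1", "b1", "W2", "b2", "W3", "b3",
                            "W4", "b4", "H1", "h1", "H2", "h2"))
  expect_equal(dim(predict(fit, X, type = "bottleneck")), c(150L, 2L))
  expect_equal(dim(predict(fit, X, type = "reconstruction")),
               c(150L, 10L))
  expect_equal(dim(predict(fit, X, type = "targets")), c(150L, 1L))
  expect_equal(residuals(fit, X),
               X - predict(fit, X, type = "reconstruction"))
})
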