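# Semi-supervised denoising autoencoder (SSAE). A two-layer encoder maps the
# scaled omic block to a low-dimensional bottleneck; a symmetric decoder
# reconstructs the original (uncorrupted) input, and a one-layer-perceptron
# head grafted on the bottleneck predicts the adjusted targets. The two
# outputs share the bi-output loss
#     L = alpha * MSE(X, X') + (1 - alpha) * MSE(Y, Y'),
# with alpha = 1 recovering a plain unsupervised autoencoder (USAE). MSE is
# the mean over all matrix elements, which makes reconstruction caps
# comparable across blocks of different widths.

#' Autoencoder architecture description
#'
#' @param p_in Input width (number of features).
#' @param p Encoder hidden width.
#' @param l Bottleneck width (`1 <= l <= p <= p_in`).
#' @param t Supervised output width (default 5 targets).
#' @param r Dropout rate on the input layer, in `[0, 1)`.
#' @param leaky_slope LeakyReLU negative-part slope `a`.
#' @param alpha Convexity parameter of the bi-output loss, in `[0, 1]`.
#' @return An object of class `"ssae_architecture"`.
#' @export
ssae_architecture <- function(p_in, p, l, t = 5L, r = 0.5,
                              leaky_slope = 0.1, alpha = 0.9) {
  if (!(1 <= l && l <= p && p <= p_in))
    stop("architecture requires 1 <= l <= p <= p_in")
  if (r < 0 || r >= 1) stop("dropout rate r must lie in [0, 1)")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (t < 1) stop("t must be >= 1")
  structure(list(p_in = as.integer(p_in), p = as.integer(p),
                 l = as.integer(l), t = as.integer(t), r = r,
                 leaky_slope = leaky_slope, alpha = alpha),
            class = "ssae_architecture")
}

#' Trainable-parameter count of an architecture
#'
#' Closed-form sum of weight and bias counts over the encoder, decoder and
#' prediction head.
#'
#' @param arch An [ssae_architecture()].
#' @return Integer parameter count.
#' @export
ssae_n_params <- function(arch) {
  with(arch, (p_in * p + p) + (p * l + l) +       # encoder
         (l * p + p) + (p * p_in + p_in) +        # decoder
         (l * l + l) + (l * t + t))               # head
}

#' Training configuration for [train_ssae()]
#'
#' @param batch_size Mini-batch size (default 64).
#' @param learning_rate Initial Adam learning rate (default 1e-3).
#' @param decay Per-epoch multiplicative learning-rate factor (default 0.9;
#'   epoch e uses `learning_rate * decay^(e-1)`).
#' @param min_epochs Minimum number of epochs before early stopping may
#'   trigger (default 10).
#' @param stop_window Moving-average window of past validation losses used by
#'   the stopping rule (default 10).
#' @param max_epochs Hard epoch cap (default 200).
#' @param corruption_sd SD of the Gaussian input corruption, redrawn every
#'   epoch (0.01 suits min-max-scaled transcriptomic data, 0.1 z-scored
#'   metabolomic data: roughly a tenth of the mean feature sd).
#' @param seed Optional integer seed for corruption, dropout and batching.
#' @return A list of class `"ssae_control"`.
#' @export
ssae_control <- function(batch_size = 64L, learning_rate = 1e-3,
                         decay = 0.9, min_epochs = 10L, stop_window = 10L,
                         max_epochs = 200L, corruption_sd = 0.01,
                         seed = NULL) {
  if (stop_window < 1) stop("stop_window must be >= 1")
  if (corruption_sd < 0) stop("corruption_sd must be >= 0")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, decay = decay,
                 min_epochs = as.integer(min_epochs),
                 stop_window = as.integer(stop_window),
                 max_epochs = as.integer(max_epochs),
                 corruption_sd = corruption_sd, seed = seed),
            class = "ssae_control")
}

#' Corrupt a matrix with Gaussian noise
#'
#' @param X Numeric matrix.
#' @param sigma Noise standard deviation (>= 0); fresh noise on every call.
#' @return `X + N(0, sigma^2)` elementwise.
#' @export
corrupt <- function(X, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(X)
  X + matrix(rnorm(length(X), 0, sigma), nrow(X), ncol(X))
}

#' Bi-output autoencoder loss
#'
#' `alpha * MSE(X, X') + (1 - alpha) * MSE(Y, Y')`, each MSE the mean of
#' squared elementwise differences. `alpha = 1` is exactly the reconstruction
#' MSE and `alpha = 0` exactly the supervised MSE; the loss is linear in
#' `alpha` for fixed inputs.
#'
#' @param X,X_prime Original and reconstructed input matrices.
#' @param Y,Y_prime Target matrix and its prediction (ignored when
#'   `alpha = 1` and `Y` is NULL).
#' @param alpha Convexity parameter in `[0, 1]`.
#' @return Scalar loss.
#' @export
ssae_loss <- function(X, X_prime, Y, Y_prime, alpha) {
  if (!all(dim(as.matrix(X)) == dim(as.matrix(X_prime))))
    stop("shape mismatch between X and X_prime")
  rec <- mean((X - X_prime)^2)
  if (alpha == 1 && is.null(Y)) return(rec)
  if (!all(dim(as.matrix(Y)) == dim(as.matrix(Y_prime))))
    stop("shape mismatch between Y and Y_prime")
  alpha * rec + (1 - alpha) * mean((Y - Y_prime)^2)
}

#' Build an untrained autoencoder
#'
#' Network: dropout(`r`) on the input, dense(`p`, LeakyReLU), dense(`l`,
#' LeakyReLU) bottleneck, then a symmetric decoder dense(`p`, LeakyReLU) ->
#' dense(`p_in`, linear) and a prediction head dense(`l`, LeakyReLU) ->
#' dense(`t`, linear). The decoder and head output layers are linear because
#' they reconstruct z-scored / min-max-scaled variables.
#'
#' @param arch An [ssae_architecture()].
#' @param seed Integer seed; identical seeds give identical initial weights.
#' @return An object of class `"ssae"` with `trained = FALSE`.
#' @export
build_ssae <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "ssae_architecture"))
  set.seed(seed)
  w <- with(arch, {
    e1 <- .init_dense(p_in, p); e2 <- .init_dense(p, l)
    d1 <- .init_dense(l, p);    d2 <- .init_dense(p, p_in)
    h1 <- .init_dense(l, l);    h2 <- .init_dense(l, t)
    list(W1 = e1$W, b1 = e1$b, W2 = e2$W, b2 = e2$b,
         W3 = d1$W, b3 = d1$b, W4 = d2$W, b4 = d2$b,
         H1 = h1$W, h1 = h1$b, H2 = h2$W, h2 = h2$b)
  })
  structure(list(weights = w, architecture = arch, trained = FALSE,
                 history = NULL, seed = as.integer(seed)),
            class = "ssae")
}

# forward pass; when train = TRUE applies the (already seeded) input dropout
.ssae_forward <- function(w, X, arch, train = FALSE) {
  a <- arch$leaky_slope
  Xd <- if (train && arch$r > 0) .dropout(X, arch$r) else X
  Z1 <- .affine(Xd, w$W1, w$b1); A1 <- leaky_relu(Z1, a)
  Z2 <- .affine(A1, w$W2, w$b2); A2 <- leaky_relu(Z2, a)
  Zd <- .affine(A2, w$W3, w$b3); Ad <- leaky_relu(Zd, a)
  Xh <- .affine(Ad, w$W4, w$b4)
  Zh <- .affine(A2, w$H1, w$h1); Ah <- leaky_relu(Zh, a)
  Yh <- .affine(Ah, w$H2, w$h2)
  list(Xd = Xd, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, Zd = Zd, Ad = Ad,
       Xhat = Xh, Zh = Zh, Ah = Ah, Yhat = Yh)
}

# gradients of the bi-output loss wrt all weights for one mini-batch;
# X is the clean reconstruction target, f a cached forward pass on the
# corrupted batch
.ssae_backward <- function(w, f, X, Y, arch) {
  a <- arch$leaky_slope
  alpha <- arch$alpha
  B <- nrow(X)
  dXhat <- 2 * alpha * (f$Xhat - X) / (B * arch$p_in)
  gW4 <- crossprod(f$Ad, dXhat); gb4 <- colSums(dXhat)
  dAd <- dXhat %*% t(w$W4)
  dZd <- dAd * .leaky_relu_grad(f$Zd, a)
  gW3 <- crossprod(f$A2, dZd); gb3 <- colSums(dZd)
  dA2 <- dZd %*% t(w$W3)
  if (alpha < 1) {
    dYhat <- 2 * (1 - alpha) * (f$Yhat - Y) / (B * arch$t)
    gH2 <- crossprod(f$Ah, dYhat); gh2 <- colSums(dYhat)
    dAh <- dYhat %*% t(w$H2)
    dZh <- dAh * .leaky_relu_grad(f$Zh, a)
    gH1 <- crossprod(f$A2, dZh); gh1 <- colSums(dZh)
    dA2 <- dA2 + dZh %*% t(w$H1)
  } else {
    gH2 <- w$H2 * 0; gh2 <- w$h2 * 0
    gH1 <- w$H1 * 0; gh1 <- w$h1 * 0
  }
  dZ2 <- dA2 * .leaky_relu_grad(f$Z2, a)
  gW2 <- crossprod(f$A1, dZ2); gb2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(w$W2)
  dZ1 <- dA1 * .leaky_relu_grad(f$Z1, a)
  gW1 <- crossprod(f$Xd, dZ1); gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3,
       W4 = gW4, b4 = gb4, H1 = gH1, h1 = gh1, H2 = gH2, h2 = gh2)
}

#' Early-stopping decision on a validation-loss history
#'
#' The run stops at the first epoch `e > min_epochs` whose validation loss
#' fails to improve the mean validation loss over the preceding
#' `stop_window` epochs (window truncated early in training).
#'
#' @param val_losses Numeric vector of per-epoch validation losses so far.
#' @param min_epochs,stop_window Stopping-rule parameters.
#' @return `TRUE` if training should stop after the last recorded epoch.
#' @export
ssae_should_stop <- function(val_losses, min_epochs, stop_window) {
  e <- length(val_losses)
  if (e <= min_epochs) return(FALSE)
  w <- min(stop_window, e - 1L)
  val_losses[e] >= mean(val_losses[(e - w):(e - 1L)])
}

#' Train a semi-supervised autoencoder
#'
#' Mini-batch Adam optimization of the bi-output loss. Every epoch draws
#' fresh Gaussian corruption of the inputs; the model reconstructs the
#' original data from the corrupted data. Training stops by the
#' [ssae_should_stop()] rule on the validation loss, or at `max_epochs`.
#'
#' @param model An untrained (or trained) `"ssae"` from [build_ssae()].
#' @param X Scaled training block (training partition rows, including the
#'   validation fifth).
#' @param Y Adjusted-target matrix aligned with `X` rows; may be NULL when
#'   `alpha = 1`.
#' @param control An [ssae_control()].
#' @param validation Logical vector marking validation rows of `X`; default
#'   is a random fifth drawn under the control seed.
#' @param stop_when Optional function `(val_recon_mse) -> logical` checked
#'   after each epoch before the moving-average rule; used by
#'   [train_usae_matched()] to stop at a target reconstruction MSE.
#' @return The model with `trained = TRUE` and a `history` data frame
#'   (per-epoch train/validation loss and reconstruction MSE).
#' @export
train_ssae <- function(model, X, Y = NULL, control = ssae_control(),
                       validation = NULL, stop_when = NULL) {
  stopifnot(inherits(model, "ssae"))
  arch <- model$architecture
  X <- as.matrix(X)
  if (ncol(X) != arch$p_in) stop("X width does not match architecture")
  if (is.null(Y)) {
    if (arch$alpha < 1) stop("Y is required when alpha < 1")
  } else {
    Y <- as.matrix(unclass(Y))
    if (nrow(Y) != nrow(X)) stop("X and Y row mismatch")
    if (ncol(Y) != arch$t) stop("Y width does not match architecture t")
  }
  if (!is.null(control$seed)) set.seed(control$seed)
  if (is.null(validation)) {
    validation <- logical(nrow(X))
    validation[sample.int(nrow(X), max(1L, round(nrow(X) / 5)))] <- TRUE
  }
  Xtr <- X[!validation, , drop = FALSE]
  Xva <- X[validation, , drop = FALSE]
  Ytr <- if (!is.null(Y)) Y[!validation, , drop = FALSE]
  Yva <- if (!is.null(Y)) Y[validation, , drop = FALSE]
  w <- model$weights
  adam <- .adam_init(w)
  hist <- list()
  for (epoch in seq_len(control$max_epochs)) {
    lr <- control$learning_rate * control$decay^(epoch - 1)
    Xc <- corrupt(Xtr, control$corruption_sd)
    ord <- sample.int(nrow(Xtr))
    batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
    tr_loss <- tr_rec <- 0
    for (idx in batches) {
      f <- .ssae_forward(w, Xc[idx, , drop = FALSE], arch, train = TRUE)
      Xb <- Xtr[idx, , drop = FALSE]
      Yb <- if (!is.null(Ytr)) Ytr[idx, , drop = FALSE]
      g <- .ssae_backward(w, f, Xb, Yb, arch)
      step <- .adam_step(adam, w, g, lr)
      adam <- step$state; w <- step$params
      tr_loss <- tr_loss + ssae_loss(Xb, f$Xhat, Yb, f$Yhat, arch$alpha) *
        length(idx)
      tr_rec <- tr_rec + mean((Xb - f$Xhat)^2) * length(idx)
    }
    Xvc <- corrupt(Xva, control$corruption_sd)
    fv <- .ssae_forward(w, Xvc, arch, train = FALSE)
    val_rec <- mean((Xva - fv$Xhat)^2)
    val_loss <- ssae_loss(Xva, fv$Xhat, Yva, fv$Yhat, arch$alpha)
    if (!is.finite(val_loss))
      stop("non-finite validation loss at epoch ", epoch,
           " (lr = ", lr, "); consider a smaller learning rate")
    hist[[epoch]] <- c(epoch = epoch, train_loss = tr_loss / nrow(Xtr),
                       train_recon_mse = tr_rec / nrow(Xtr),
                       val_loss = val_loss, val_recon_mse = val_rec)
    if (!is.null(stop_when) && isTRUE(stop_when(val_rec))) break
    val_hist <- vapply(hist, `[[`, 0, "val_loss")
    if (is.null(stop_when) &&
        ssae_should_stop(val_hist, control$min_epochs, control$stop_window))
      break
  }
  model$weights <- w
  model$trained <- TRUE
  model$history <- as.data.frame(do.call(rbind, hist))
  model$control <- control
  model$validation <- validation
  model
}

#' Fit a semi-supervised autoencoder in one call
#'
#' Convenience wrapper: builds the architecture from the data dimensions and
#' the supplied widths, then trains with [train_ssae()].
#'
#' @param X Scaled training block.
#' @param Y Adjusted targets (NULL for a purely unsupervised fit).
#' @param p,l Encoder hidden and bottleneck widths.
#' @param alpha Loss convexity parameter (default 0.9; 1 = unsupervised).
#' @param r Input dropout rate (default 0.5).
#' @param leaky_slope LeakyReLU slope.
#' @param control An [ssae_control()].
#' @param validation Optional logical validation marker (see [train_ssae()]).
#' @param seed Seed for weight initialization (also used for training when
#'   `control$seed` is NULL).
#' @return A trained `"ssae"` object.
#' @examples
#' X <- matrix(rnorm(200 * 12), 200, 12)
#' fit <- ssae(X, NULL, p = 6, l = 2, alpha = 1, r = 0,
#'             control = ssae_control(max_epochs = 5, min_epochs = 5,
#'                                    seed = 1))
#' dim(predict(fit, X, type = "bottleneck"))
#' @export
ssae <- function(X, Y = NULL, p, l, alpha = 0.9, r = 0.5,
                 leaky_slope = 0.1, control = ssae_control(),
                 validation = NULL, seed = 1L) {
  t <- if (is.null(Y)) 1L else ncol(as.matrix(Y))
  arch <- ssae_architecture(ncol(X), p, l, t = max(1L, t), r = r,
                            leaky_slope = leaky_slope, alpha = alpha)
  model <- build_ssae(arch, seed = seed)
  if (is.null(control$seed)) control$seed <- seed
  train_ssae(model, X, Y, control, validation)
}

#' Train an unsupervised control matched on reconstruction MSE
#'
#' Trains a USAE (`alpha = 1`, head detached from the loss) with the same
#' architecture and stops at the first epoch whose validation reconstruction
#' MSE reaches the final validation reconstruction MSE of the paired SSAE,
#' so the two subspaces reconstruct the omic block equally well (within one
#' epoch's improvement).
#'
#' @param arch The paired SSAE's architecture.
#' @param X Scaled training block.
#' @param target_mse Final validation reconstruction MSE of the paired SSAE.
#' @param control An [ssae_control()].
#' @param validation As in [train_ssae()] (use the SSAE's split for a
#'   paired comparison).
#' @param seed Weight-initialization seed.
#' @return A trained `"ssae"` with `alpha = 1`; errors if `target_mse` is
#'   not reached within `control$max_epochs`.
#' @export
train_usae_matched <- function(arch, X, target_mse,
                               control = ssae_control(),
                               validation = NULL, seed = 1L) {
  arch$alpha <- 1
  model <- build_ssae(arch, seed = seed)
  if (is.null(control$seed)) control$seed <- seed
  model <- train_ssae(model, X, NULL, control, validation,
                      stop_when = function(mse) mse <= target_mse)
  final <- model$history$val_recon_mse[nrow(model$history)]
  if (final > target_mse)
    stop("USAE did not reach the target reconstruction MSE (",
         signif(target_mse, 4), ") within ", control$max_epochs,
         " epochs; best = ", signif(min(model$history$val_recon_mse), 4))
  model
}

#' Constrained architecture search
#'
#' Trains every `(p, l)` candidate and returns the feasible one with the
#' fewest trainable parameters. A candidate is feasible when its validation
#' reconstruction MSE is below `mse_cap` and the mean absolute off-diagonal
#' Pearson correlation among its bottleneck components (on non-validation
#' training samples) does not exceed `corr_cap`. Ties prefer the smaller
#' bottleneck `l`, then the smaller hidden width `p`.
#'
#' @param grid Data frame with columns `p` and `l`.
#' @param X,Y,control,validation As in [train_ssae()].
#' @param mse_cap Reconstruction-MSE cap (0.015 suits min-max-scaled
#'   transcriptomic blocks, 0.25 z-scored metabolomic blocks).
#' @param corr_cap Mean-absolute-correlation cap (0.4 / 0.3 respectively).
#' @param alpha,r,leaky_slope Architecture parameters shared by candidates.
#' @param seed Weight-initialization seed.
#' @return The selected [ssae_architecture()], with a `diagnostics` attribute
#'   tabulating every candidate; errors listing nearest misses when no
#'   candidate is feasible.
#' @export
select_architecture <- function(grid, X, Y, control = ssae_control(),
                                mse_cap, corr_cap, alpha = 0.9, r = 0.5,
                                leaky_slope = 0.1, validation = NULL,
                                seed = 1L) {
  stopifnot(all(c("p", "l") %in% names(grid)))
  t <- if (is.null(Y)) 1L else ncol(as.matrix(Y))
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    arch <- ssae_architecture(ncol(X), grid$p[i], grid$l[i], t = t,
                              r = r, leaky_slope = leaky_slope,
                              alpha = alpha)
    fit <- train_ssae(build_ssae(arch, seed), X, Y, control, validation)
    sub <- encode(fit, X[!fit$validation, , drop = FALSE])
    mean_cor <- if (ncol(sub) < 2) 0 else {
      cm <- abs(cor(sub))
      mean(cm[upper.tri(cm)])
    }
    res[[i]] <- list(arch = arch,
                     mse = fit$history$val_recon_mse[nrow(fit$history)],
                     cor = mean_cor, n_params = ssae_n_params(arch))
  }
  diag <- data.frame(p = grid$p, l = grid$l,
                     n_params = vapply(res, `[[`, 0, "n_params"),
                     val_recon_mse = vapply(res, `[[`, 0, "mse"),
                     mean_abs_cor = vapply(res, `[[`, 0, "cor"))
  diag$feasible <- diag$val_recon_mse < mse_cap & diag$mean_abs_cor <= corr_cap
  if (!any(diag$feasible)) {
    near <- diag[order(diag$val_recon_mse), ][1:min(3, nrow(diag)), ]
    stop("no feasible architecture; nearest misses (p, l, mse, cor): ",
         paste(apply(near, 1L, function(z)
           sprintf("(%g, %g, %.4g, %.3g)", z["p"], z["l"],
                   z["val_recon_mse"], z["mean_abs_cor"])),
           collapse = " "))
  }
  feas <- which(diag$feasible)
  ord <- feas[order(diag$n_params[feas], diag$l[feas], diag$p[feas])]
  out <- res[[ord[1]]]$arch
  attr(out, "diagnostics") <- diag
  out
}

#' Encode samples into the bottleneck subspace
#'
#' Deterministic forward pass to the bottleneck; dropout is disabled and the
#' input is not corrupted.
#'
#' @param model A `"ssae"` object.
#' @param X Matrix scaled with the training scaling statistics.
#' @return Samples x `l` matrix of bottleneck activations.
#' @export
encode <- function(model, X) {
  stopifnot(inherits(model, "ssae"))
  X <- as.matrix(X)
  if (ncol(X) != model$architecture$p_in)
    stop("input width does not match the model")
  f <- .ssae_forward(model$weights, X, model$architecture, train = FALSE)
  out <- f$A2
  rownames(out) <- rownames(X)
  colnames(out) <- sprintf("c%02d", seq_len(ncol(out)))
  out
}

#' @export
print.ssae <- function(x, ...) {
  a <- x$architecture
  kind <- if (a$alpha == 1) "Unsupervised autoencoder (USAE)"
          else "Semi-supervised autoencoder (SSAE)"
  cat(kind, "\n")
  cat(sprintf("  %d -> %d -> %d (bottleneck) | alpha = %g, dropout = %g\n",
              a$p_in, a$p, a$l, a$alpha, a$r))
  cat("  trainable parameters:", ssae_n_params(a), "\n")
  if (x$trained) {
    h <- x$history
    cat(sprintf("  trained %d epochs; final val loss %.5g, recon MSE %.5g\n",
                nrow(h), h$val_loss[nrow(h)], h$val_recon_mse[nrow(h)]))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.ssae <- function(object, ...) {
  print(object)
  if (object$trained) {
    cat("\nTraining history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.ssae <- function(object, ...) object$weights

#' Predict from a fitted autoencoder
#'
#' @param object A trained `"ssae"`.
#' @param newdata Matrix scaled like the training data.
#' @param type `"bottleneck"` (the encoded subspace), `"reconstruction"` or
#'   `"targets"` (head output).
#' @param ... Unused.
#' @return A matrix of the requested quantity.
#' @export
predict.ssae <- function(object, newdata,
                         type = c("bottleneck", "reconstruction",
                                  "targets"), ...) {
  type <- match.arg(type)
  if (type == "bottleneck") return(encode(object, newdata))
  f <- .ssae_forward(object$weights, as.matrix(newdata),
                     object$architecture, train = FALSE)
  if (type == "reconstruction") f$Xhat else f$Yhat
}

#' @export
residuals.ssae <- function(object, newdata, ...) {
  as.matrix(newdata) - predict(object, newdata, type = "reconstruction")
}

#' @export
plot.ssae <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model is untrained")
  matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l", lty = 1,
          col = c("grey40", "firebrick"), xlab = "epoch", ylab = "loss",
          main = "Autoencoder training history", ...)
  legend("topright", c("train", "validation"), lty = 1,
         col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
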