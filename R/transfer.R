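# Transfer learning: the encoder of an autoencoder pre-trained on the base
# cohort is copied (and frozen) into a binary hypertension classifier for an
# external cohort: dropout on the bottleneck, a task-specific hidden layer,
# concatenation with age/sex/BMI, and a logistic score trained with binary
# cross-entropy. A "scratch" clone with identical topology but freshly
# initialized, fully trainable weights is the comparison arm.

#' Label hypertension from blood pressure
#'
#' Default rule: hypertensive iff SBP strictly exceeds `sbp_thresh` OR DBP
#' strictly exceeds `dbp_thresh` (the clinical 140/90 convention); values at
#' exactly the threshold are controls. `rule = "and"` requires both
#' exceedances.
#'
#' @param sbp,dbp Systolic and diastolic blood pressure in mmHg.
#' @param sbp_thresh,dbp_thresh Thresholds (defaults 140 and 90).
#' @param rule `"or"` (default) or `"and"`.
#' @return Integer vector of 0/1 labels.
#' @export
label_hypertension <- function(sbp, dbp, sbp_thresh = 140, dbp_thresh = 90,
                               rule = c("or", "and")) {
  rule <- match.arg(rule)
  if (any(!is.finite(sbp)) || any(!is.finite(dbp)))
    stop("non-finite blood pressure input")
  hi_s <- sbp > sbp_thresh
  hi_d <- dbp > dbp_thresh
  as.integer(if (rule == "or") hi_s | hi_d else hi_s & hi_d)
}

#' Fine-tuning subset size for a given external cohort and fraction
#'
#' The rule used by [run_transfer_experiment()]: `round(fraction * n)`
#' samples fine-tune, the remainder evaluates. For a 310-sample external
#' cohort, 80% gives 248 fine-tuning samples and 20% gives 62.
#'
#' @param n External cohort size.
#' @param fraction Fine-tuning fraction in (0, 1).
#' @return Integer subset size.
#' @export
finetune_subset_size <- function(n, fraction) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  as.integer(round(fraction * n))
}

.transfer_topology <- function(arch, hidden_width) {
  list(p_in = arch$p_in, p = arch$p, l = arch$l,
       h = hidden_width %||% arch$l, slope = arch$leaky_slope)
}

.init_transfer_head <- function(topo) {
  th <- .init_dense(topo$l, topo$h)
  to <- .init_dense(topo$h + 3L, 1L)
  list(Wt = th$W, bt = th$b, wo = to$W, bo = to$b)
}

#' Build a transfer model from a pre-trained autoencoder
#'
#' Copies the encoder weights of `source` (frozen during fine-tuning) and
#' attaches a new task head: dropout on the bottleneck, a task-specific
#' hidden layer of width `hidden_width` (default the bottleneck width),
#' concatenation with the three clinical covariates, and a linear score.
#'
#' @param source A trained `"ssae"` whose input width matches the external
#'   omic block.
#' @param dropout_rate Dropout rate on the bottleneck during fine-tuning.
#' @param hidden_width Task-head hidden width (default `l`).
#' @param seed Head-initialization seed.
#' @return An object of class `"transfer_model"` with `inherited = TRUE`.
#' @export
build_transfer_model <- function(source, dropout_rate = 0.25,
                                 hidden_width = NULL, seed = 1L) {
  stopifnot(inherits(source, "ssae"))
  topo <- .transfer_topology(source$architecture, hidden_width)
  set.seed(seed)
  structure(list(encoder = source$weights[c("W1", "b1", "W2", "b2")],
                 head = .init_transfer_head(topo),
                 topology = topo, dropout_rate = dropout_rate,
                 inherited = TRUE, frozen = TRUE),
            class = "transfer_model")
}

#' Build an identically shaped from-scratch clone
#'
#' Same topology as [build_transfer_model()] but every layer, including the
#' encoder, is freshly initialized and trainable.
#'
#' @param arch The source model's [ssae_architecture()].
#' @param dropout_rate,hidden_width,seed As in [build_transfer_model()].
#' @return A `"transfer_model"` with `inherited = FALSE`.
#' @export
build_scratch_clone <- function(arch, dropout_rate = 0.25,
                                hidden_width = NULL, seed = 1L) {
  stopifnot(inherits(arch, "ssae_architecture"))
  topo <- .transfer_topology(arch, hidden_width)
  set.seed(seed)
  e1 <- .init_dense(topo$p_in, topo$p)
  e2 <- .init_dense(topo$p, topo$l)
  structure(list(encoder = list(W1 = e1$W, b1 = e1$b,
                                W2 = e2$W, b2 = e2$b),
                 head = .init_transfer_head(topo),
                 topology = topo, dropout_rate = dropout_rate,
                 inherited = FALSE, frozen = FALSE),
            class = "transfer_model")
}

# forward pass to the logistic score; dropout only when train = TRUE. A
# fixed affine normalization of the bottleneck (statistics taken once from
# the fine-tuning data when fine-tuning starts) sits between the encoder and
# the task head in both arms: the encoded activations are not centered, and
# without it the head optimizes poorly.
.transfer_forward <- function(model, X, C, train = FALSE) {
  topo <- model$topology
  e <- model$encoder; h <- model$head
  Z1 <- .affine(X, e$W1, e$b1); A1 <- leaky_relu(Z1, topo$slope)
  Z2 <- .affine(A1, e$W2, e$b2); A2 <- leaky_relu(Z2, topo$slope)
  if (!is.null(model$norm))
    A2 <- sweep(sweep(A2, 2L, model$norm$center, "-"), 2L,
                model$norm$scale, "/")
  M <- NULL
  if (train && model$dropout_rate > 0) {
    M <- matrix(rbinom(length(A2), 1L, 1 - model$dropout_rate),
                nrow(A2), ncol(A2)) / (1 - model$dropout_rate)
    A2d <- A2 * M
  } else A2d <- A2
  Zt <- .affine(A2d, h$Wt, h$bt); At <- leaky_relu(Zt, topo$slope)
  F_ <- cbind(At, C)
  s <- .affine(F_, h$wo, h$bo)
  list(Z1 = Z1, A1 = A1, Z2 = Z2, A2d = A2d, drop_mult = M, Zt = Zt,
       At = At, F_ = F_, score = drop(s), prob = drop(.sigmoid(s)))
}

#' Fine-tune a transfer model on labelled external data
#'
#' Minimizes binary cross-entropy of the logistic score by mini-batch Adam.
#' The inherited encoder of a transfer model is frozen (bit-identical after
#' fine-tuning); a scratch clone trains its encoder as well.
#'
#' @param model A `"transfer_model"`.
#' @param X External omic block rows (scaled with the external cohort's own
#'   statistics).
#' @param covariates Matrix/data frame with `age`, `sex`, `bmi` (z-scored by
#'   the caller or raw; kept as supplied).
#' @param labels Binary 0/1 hypertension labels.
#' @param epochs,batch_size,learning_rate Adam settings.
#' @param seed Batching/dropout seed; with equal seeds two models see
#'   identical batch orders.
#' @return The fine-tuned model.
#' @export
fine_tune <- function(model, X, covariates, labels, epochs = 30L,
                      batch_size = 32L, learning_rate = 1e-2, seed = 1L) {
  stopifnot(inherits(model, "transfer_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$topology$p_in)
    stop("external block width does not match the source encoder")
  C <- as.matrix(covariates)
  y <- as.numeric(labels)
  set.seed(seed)
  if (is.null(model$norm)) {
    e <- model$encoder
    A1 <- leaky_relu(.affine(X, e$W1, e$b1), model$topology$slope)
    A2 <- leaky_relu(.affine(A1, e$W2, e$b2), model$topology$slope)
    model$norm <- list(center = colMeans(A2),
                       scale = pmax(apply(A2, 2L, sd), 1e-8))
  }
  params <- c(model$head, if (!model$frozen) model$encoder)
  adam <- .adam_init(params)
  n <- nrow(X)
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    for (idx in split(ord, ceiling(seq_along(ord) / batch_size))) {
      model$head <- params[c("Wt", "bt", "wo", "bo")]
      if (!model$frozen)
        model$encoder <- params[c("W1", "b1", "W2", "b2")]
      f <- .transfer_forward(model, X[idx, , drop = FALSE],
                             C[idx, , drop = FALSE], train = TRUE)
      B <- length(idx)
      ds <- (f$prob - y[idx]) / B             # d BCE / d score
      gwo <- crossprod(f$F_, ds); gbo <- sum(ds)
      dF <- matrix(ds, B, 1L) %*% t(model$head$wo)
      dAt <- dF[, seq_len(model$topology$h), drop = FALSE]
      dZt <- dAt * .leaky_relu_grad(f$Zt, model$topology$slope)
      gWt <- crossprod(f$A2d, dZt); gbt <- colSums(dZt)
      grads <- list(Wt = gWt, bt = gbt, wo = gwo, bo = gbo)
      if (!model$frozen) {
        dA2 <- dZt %*% t(model$head$Wt)
        if (!is.null(f$drop_mult)) dA2 <- dA2 * f$drop_mult
        dA2 <- sweep(dA2, 2L, model$norm$scale, "/")
        dZ2 <- dA2 * .leaky_relu_grad(f$Z2, model$topology$slope)
        gW2 <- crossprod(f$A1, dZ2); gb2 <- colSums(dZ2)
        dA1 <- dZ2 %*% t(model$encoder$W2)
        dZ1 <- dA1 * .leaky_relu_grad(f$Z1, model$topology$slope)
        gW1 <- crossprod(X[idx, , drop = FALSE], dZ1); gb1 <- colSums(dZ1)
        grads <- c(grads, list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
      }
      step <- .adam_step(adam, params, grads, learning_rate)
      adam <- step$state; params <- step$params
    }
  }
  model$head <- params[c("Wt", "bt", "wo", "bo")]
  if (!model$frozen) model$encoder <- params[c("W1", "b1", "W2", "b2")]
  model
}

#' Predict hypertension probabilities from a transfer model
#'
#' @param object A `"transfer_model"`.
#' @param X,covariates As in [fine_tune()].
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.transfer_model <- function(object, X, covariates, ...) {
  .transfer_forward(object, as.matrix(X), as.matrix(covariates),
                    train = FALSE)$prob
}

#' Run the transfer-vs-scratch fine-tuning experiment
#'
#' For every fine-tuning fraction and repeat: randomly split the external
#' cohort into a fine-tuning subset (`round(fraction * n)` samples, e.g. 248
#' of 310 at 80%) and an evaluation remainder; fine-tune the transfer model
#' and an identically shaped scratch clone on the same subset with the same
#' batch order; compute the AUC for hypertension on the evaluation subset.
#' The external block is scaled with the fine-tuning subset's own statistics
#' (the external cohort is preprocessed independently of the base cohort).
#' Repeats whose evaluation subset lacks a class are resampled and logged.
#'
#' @param external A `"multiomics_cohort"` with populated SBP/DBP.
#' @param source A trained `"ssae"` for the matching omic block.
#' @param omic Name of the block the source was trained on.
#' @param fractions Fine-tuning fractions (default 0.2, 0.4, 0.6, 0.8).
#' @param repeats Repeats per fraction (default 100).
#' @param epochs,batch_size,learning_rate,dropout_rate Fine-tuning settings
#'   shared by both arms.
#' @param scale_method Scaling for the external block; must match the
#'   convention the source encoder was trained with (default `"minmax"` for
#'   the transcriptomic block, `"zscore"` otherwise).
#' @param seed Experiment seed.
#' @return A `"transfer_result"`: data frame (fraction, repeat,
#'   auc_transfer, auc_scratch) with a summary method reporting medians and
#'   median paired AUC gains.
#' @export
run_transfer_experiment <- function(external, source, omic = "metabolomic",
                                    fractions = c(0.2, 0.4, 0.6, 0.8),
                                    repeats = 100L, epochs = 30L,
                                    batch_size = 32L, learning_rate = 1e-2,
                                    dropout_rate = 0.25,
                                    scale_method = NULL, seed = 1L) {
  stopifnot(inherits(external, "multiomics_cohort"),
            inherits(source, "ssae"))
  scale_method <- scale_method %||%
    if (omic == "transcriptomic") "minmax" else "zscore"
  X_raw <- external$blocks[[omic]]
  y <- label_hypertension(external$targets[, "sbp"],
                          external$targets[, "dbp"])
  if (length(unique(y)) < 2)
    stop("external cohort contains a single hypertension class")
  Craw <- as.matrix(external$covariates[, c("age", "sex", "bmi")])
  n <- nrow(X_raw)
  rows <- list()
  resampled <- 0L
  for (fi in seq_along(fractions)) {
    n_ft <- finetune_subset_size(n, fractions[fi])
    for (r in seq_len(repeats)) {
      rep_seed <- .stage_seed(seed, sprintf("transfer-%d-%d", fi, r))
      set.seed(rep_seed)
      for (attempt in 1:50) {
        ft <- sample.int(n, n_ft)
        ev <- setdiff(seq_len(n), ft)
        if (length(unique(y[ft])) == 2 && length(unique(y[ev])) == 2) break
        resampled <- resampled + 1L
        if (attempt == 50) stop("could not draw a two-class split")
      }
      sc <- fit_scaler(X_raw[ft, , drop = FALSE],
                       rep(TRUE, n_ft), scale_method)
      Xft <- apply_scaler(X_raw[ft, , drop = FALSE], sc)
      Xev <- apply_scaler(X_raw[ev, , drop = FALSE], sc)
      cs <- function(M, ref) sweep(sweep(M, 2L, colMeans(ref), "-"), 2L,
                                   pmax(apply(ref, 2L, sd), 1e-8), "/")
      Cft <- cs(Craw[ft, , drop = FALSE], Craw[ft, , drop = FALSE])
      Cev <- cs(Craw[ev, , drop = FALSE], Craw[ft, , drop = FALSE])
      tm <- build_transfer_model(source, dropout_rate, seed = rep_seed)
      cl <- build_scratch_clone(source$architecture, dropout_rate,
                                seed = rep_seed + 1L)
      tm <- fine_tune(tm, Xft, Cft, y[ft], epochs, batch_size,
                      learning_rate, seed = rep_seed + 2L)
      cl <- fine_tune(cl, Xft, Cft, y[ft], epochs, batch_size,
                      learning_rate, seed = rep_seed + 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = fractions[fi], repeat_id = r,
        auc_transfer = auc_binary(predict(tm, Xev, Cev), y[ev]),
        auc_scratch = auc_binary(predict(cl, Xev, Cev), y[ev]))
    }
  }
  structure(list(results = do.call(rbind, rows), resampled = resampled,
                 omic = omic),
            class = "transfer_result")
}

#' @export
summary.transfer_result <- function(object, ...) {
  res <- object$results
  out <- do.call(rbind, lapply(split(res, res$fraction), function(d)
    data.frame(fraction = d$fraction[1],
               median_auc_transfer = median(d$auc_transfer),
               median_auc_scratch = median(d$auc_scratch),
               median_gain = median(d$auc_transfer - d$auc_scratch))))
  rownames(out) <- NULL
  out
}

#' @export
print.transfer_result <- function(x, ...) {
  cat("Transfer-vs-scratch experiment on the", x$omic, "block\n")
  print(summary(x), row.names = FALSE)
  if (x$resampled) cat("  (", x$resampled, "one-class splits resampled )\n")
  invisible(x)
}

#' @export
plot.transfer_result <- function(x, ...) {
  s <- summary(x)
  matplot(s$fraction, cbind(s$median_auc_transfer, s$median_auc_scratch),
          type = "b", pch = 19, lty = 1, col = c("firebrick", "grey40"),
          xlab = "fine-tuning fraction", ylab = "median AUC",
          main = "Transfer learning vs scratch", ...)
  legend("bottomright", c("transfer", "scratch"), col =
           c("firebrick", "grey40"), lty = 1, pch = 19, bty = "n")
  invisible(x)
}
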