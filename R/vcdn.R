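# Late integration. Per-omic class probabilities are combined into a
# Cross-omics Discovery Tensor (CoDT): for m omics and c classes, every
# cross-view product of one class probability per omic, flattened to length
# c^m (27 for 3 omics x 3 classes). A small fully connected View Correlation
# Discovery Network (VCDN) with layer widths (c^m, c^2, c) maps the tensor
# to fused class probabilities.

#' Build the Cross-omics Discovery Tensor
#'
#' Entry at multi-index `(i1, ..., im)` is the product of omic 1's
#' probability of class `i1`, ..., omic m's probability of class `im`,
#' flattened lexicographically (first omic's index varies slowest). Before
#' rescaling the entries of each row sum to 1 whenever every input row does
#' (the product of the row sums). The default rescale factor `c^m` gives a
#' uniform tensor unit entries, which keeps early-training gradients
#' well-scaled.
#'
#' @param prob_list List of m probability matrices (samples x c, aligned
#'   rows) or m probability vectors of length c.
#' @param rescale Multiplicative factor applied to all entries (default
#'   `c^m`).
#' @return A samples x `c^m` matrix of class `"codt"` with attributes `m`,
#'   `c` and `rescale`.
#' @export
build_codt <- function(prob_list, rescale = NULL) {
  if (!is.list(prob_list) || length(prob_list) < 2)
    stop("prob_list must list at least two per-omic probability objects")
  mats <- lapply(prob_list, function(p) {
    M <- if (is.null(dim(p))) matrix(p, nrow = 1L) else as.matrix(p)
    if (any(M < 0)) stop("negative probability entry")
    M
  })
  c_ <- ncol(mats[[1]])
  n <- nrow(mats[[1]])
  for (M in mats)
    if (ncol(M) != c_ || nrow(M) != n)
      stop("per-omic probability objects must share dimensions")
  rs_ok <- vapply(mats, function(M)
    all(abs(rowSums(M) - 1) < 1e-6), TRUE)
  m <- length(mats)
  out <- matrix(1, n, 1L)
  for (M in mats)
    out <- out[, rep(seq_len(ncol(out)), each = c_), drop = FALSE] *
      M[, rep(seq_len(c_), times = ncol(out)), drop = FALSE]
  if (all(rs_ok)) {
    # conservation identity: sum over the tensor = product of row sums = 1
    bad <- abs(rowSums(out) - 1) > 1e-6
    if (any(bad)) stop("CoDT conservation violated for ", sum(bad), " rows")
  }
  rescale <- rescale %||% c_^m
  structure(out * rescale, m = m, c = c_, rescale = rescale,
            class = c("codt", "matrix", "array"))
}

#' Train a View Correlation Discovery Network
#'
#' Fully connected net `c^m -> c^2 -> c` with LeakyReLU hidden activation
#' and a softmax output, trained by Adam on the cross-entropy between the
#' output simplex and one-hot 1-sd labels. Inputs should be CoDTs built from
#' out-of-fold training probabilities so the meta-learner does not model
#' classifier overfit. One VCDN is trained per (target, classifier family).
#'
#' @param codts_train Training CoDT matrix from [build_codt()].
#' @param labels_train Training labels in `{-1, 0, 1}` (all classes
#'   present).
#' @param epochs,batch_size,learning_rate Adam settings.
#' @param leaky_slope Hidden-layer LeakyReLU slope.
#' @param seed Seed for initialization and batching.
#' @return An object of class `"vcdn_model"`.
#' @export
train_vcdn <- function(codts_train, labels_train, epochs = 200L,
                       batch_size = 32L, learning_rate = 1e-2,
                       leaky_slope = 0.1, seed = 1L) {
  X <- as.matrix(codts_train)
  y <- factor(as.integer(as.character(factor(labels_train))),
              levels = c(-1, 0, 1))
  if (any(table(y) == 0))
    stop("a 1-sd class is missing from the training labels")
  c_ <- nlevels(y)
  if (attr(codts_train, "c") %||% c_ != c_)
    stop("CoDT class count does not match the labels")
  set.seed(seed)
  l1 <- .init_dense(ncol(X), c_^2)
  l2 <- .init_dense(c_^2, c_)
  w <- list(V1 = l1$W, c1 = l1$b, V2 = l2$W, c2 = l2$b)
  Yhot <- diag(c_)[as.integer(y), , drop = FALSE]
  adam <- .adam_init(w)
  n <- nrow(X)
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    for (idx in split(ord, ceiling(seq_along(ord) / batch_size))) {
      Xb <- X[idx, , drop = FALSE]
      Yb <- Yhot[idx, , drop = FALSE]
      Z1 <- .affine(Xb, w$V1, w$c1)
      A1 <- leaky_relu(Z1, leaky_slope)
      P <- .softmax(.affine(A1, w$V2, w$c2))
      dZ2 <- (P - Yb) / length(idx)          # softmax + cross-entropy
      gV2 <- crossprod(A1, dZ2); gc2 <- colSums(dZ2)
      dA1 <- dZ2 %*% t(w$V2)
      dZ1 <- dA1 * .leaky_relu_grad(Z1, leaky_slope)
      gV1 <- crossprod(Xb, dZ1); gc1 <- colSums(dZ1)
      step <- .adam_step(adam, w,
                         list(V1 = gV1, c1 = gc1, V2 = gV2, c2 = gc2),
                         learning_rate)
      adam <- step$state; w <- step$params
    }
  }
  structure(list(weights = w, c = c_, m = attr(codts_train, "m"),
                 leaky_slope = leaky_slope, levels = levels(y),
                 input_width = ncol(X)),
            class = "vcdn_model")
}

#' Predict fused class probabilities from a trained VCDN
#'
#' @param object A `"vcdn_model"`.
#' @param codts_test CoDT matrix with the training input width.
#' @param ... Unused.
#' @return A `"probability_matrix"` (rows on the simplex); hard labels via
#'   [hard_labels()] break ties toward class 0.
#' @export
predict.vcdn_model <- function(object, codts_test, ...) {
  X <- as.matrix(codts_test)
  if (ncol(X) != object$input_width)
    stop("CoDT width ", ncol(X), " does not match the VCDN input layer (",
         object$input_width, ")")
  w <- object$weights
  A1 <- leaky_relu(.affine(X, w$V1, w$c1), object$leaky_slope)
  P <- .softmax(.affine(A1, w$V2, w$c2))
  colnames(P) <- object$levels
  rownames(P) <- rownames(X)
  .new_prob_matrix(P, classifier = "vcdn", fold_origin = "test")
}

#' @export
print.vcdn_model <- function(x, ...) {
  cat(sprintf("VCDN: %d -> %d -> %d (LeakyReLU %g, softmax output)\n",
              x$input_width, x$c^2, x$c, x$leaky_slope))
  invisible(x)
}
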