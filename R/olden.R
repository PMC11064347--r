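# Connection-Weights (Olden) variable importance: the product of the weight
# matrices along every path from an input feature to a supervised output,
# through the encoder and the grafted prediction head. Biases and
# activations are excluded, and the sign of each feature's contribution is
# preserved. With linear activations the product is exactly the network's
# input-to-head Jacobian.

#' Connection-weights variable importance of a fitted autoencoder
#'
#' Computes the raw importance matrix `RI = W1 W2 H1 H2` (inputs x targets),
#' its per-target column z-scores, and per-target percentile ranks of `|RI|`
#' (mid-rank ties; 0-100, higher percentile = larger absolute importance).
#'
#' @param model A trained `"ssae"` with a supervised head.
#' @return An `"importance_matrix"`: list with elements `raw`, `zscored`
#'   and `percentile`, all inputs x targets.
#' @export
connection_weights <- function(model) {
  stopifnot(inherits(model, "ssae"))
  w <- model$weights
  raw <- w$W1 %*% w$W2 %*% w$H1 %*% w$H2
  rownames(raw) <- rownames(w$W1)
  z <- scale(raw)
  attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL
  pct <- apply(abs(raw), 2L, function(x)
    100 * (rank(x, ties.method = "average") - 0.5) / length(x))
  dimnames(z) <- dimnames(pct) <- dimnames(raw)
  structure(list(raw = raw, zscored = z, percentile = pct),
            class = "importance_matrix")
}

#' @export
print.importance_matrix <- function(x, ...) {
  cat("Connection-weights importance:", nrow(x$raw), "features x",
      ncol(x$raw), "targets\n")
  invisible(x)
}

#' Rank features by absolute importance and locate a focus set
#'
#' For each target, reports the top-`k` features by absolute z-scored
#' importance (with signed values), and for each focus feature the "top
#' percentile" of its absolute importance — 1 means the feature sits within
#' the 1% largest `|RI|` values. Also reports, per target, the top
#' percentile of the focus set's mean `|RI|` among all features.
#'
#' @param imp An `"importance_matrix"` from [connection_weights()].
#' @param feature_ids Feature ids for the rows of `imp` (default rownames).
#' @param focus_ids Features of interest (e.g. literature-reported genes);
#'   ids absent from `feature_ids` produce a warning.
#' @param top_k Rows per target in the ranking table (default 10).
#' @return A list with `top_tables` (per target), `focus_percentiles`
#'   (features x targets, top percentile of `|RI|`) and
#'   `focus_mean_percentile` (per target).
#' @export
rank_importance <- function(imp, feature_ids = rownames(imp$raw),
                            focus_ids = character(0), top_k = 10L) {
  stopifnot(inherits(imp, "importance_matrix"))
  p <- nrow(imp$raw)
  if (!p) stop("empty feature set")
  if (is.null(feature_ids)) feature_ids <- sprintf("f%04d", seq_len(p))
  missing <- setdiff(focus_ids, feature_ids)
  if (length(missing))
    warning("focus ids not present: ", paste(missing, collapse = ", "))
  focus_ids <- intersect(focus_ids, feature_ids)
  targets <- colnames(imp$raw)
  if (is.null(targets)) targets <- sprintf("y%d", seq_len(ncol(imp$raw)))
  top_tables <- lapply(seq_along(targets), function(j) {
    ord <- order(abs(imp$zscored[, j]), decreasing = TRUE)
    k <- min(top_k, p)
    data.frame(feature = feature_ids[ord[1:k]],
               RI = imp$raw[ord[1:k], j],
               zRI = imp$zscored[ord[1:k], j],
               row.names = NULL)
  })
  names(top_tables) <- targets
  # top percentile: 100 * mid-rank position counted from the largest |RI|
  top_pct <- apply(abs(imp$raw), 2L, function(x)
    100 * (rank(-x, ties.method = "average") - 0.5) / length(x))
  rownames(top_pct) <- feature_ids
  focus_pct <- top_pct[match(focus_ids, feature_ids), , drop = FALSE]
  focus_mean <- if (length(focus_ids)) {
    vapply(seq_along(targets), function(j) {
      m <- mean(abs(imp$raw[match(focus_ids, feature_ids), j]))
      100 * (sum(abs(imp$raw[, j]) > m) + 0.5) / p
    }, 0)
  } else rep(NA_real_, length(targets))
  names(focus_mean) <- targets
  list(top_tables = top_tables, focus_percentiles = focus_pct,
       focus_mean_percentile = focus_mean)
}
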