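# Evaluation mathematics: one-vs-rest F1 and macro-F1 for the three 1-sd
# classes, the naive prevalence-proportional baseline, a rank-based AUC, and
# the nested R-squared ladder on predicted probabilities.

.CLASS_LEVELS <- c(-1L, 0L, 1L)

#' Per-class F1 scores and macro-F1
#'
#' One-vs-rest precision `TP/(TP+FP)` and recall `TP/(TP+FN)` per class,
#' `F1 = 2PR/(P+R)`; a class with `TP = 0` and any error gets F1 = 0, and a
#' class absent from both truth and prediction gets F1 = 0 with a warning.
#' Macro-F1 is the unweighted mean of the per-class F1 scores, which rewards
#' performance on the rare deviant classes.
#'
#' @param true_labels,pred_labels Vectors with values in `{-1, 0, 1}` (or
#'   factors with those levels).
#' @param levels Class labels (default `c(-1, 0, 1)`).
#' @return List with `per_class` (named numeric) and `macro` (scalar).
#' @export
f1_scores <- function(true_labels, pred_labels, levels = .CLASS_LEVELS) {
  tl <- factor(as.integer(as.character(factor(true_labels))), levels)
  pl <- factor(as.integer(as.character(factor(pred_labels))), levels)
  if (length(tl) != length(pl)) stop("label length mismatch")
  per <- vapply(levels, function(k) {
    tp <- sum(tl == k & pl == k, na.rm = TRUE)
    fp <- sum(tl != k & pl == k, na.rm = TRUE)
    fn <- sum(tl == k & pl != k, na.rm = TRUE)
    if (tp + fp + fn == 0) {
      warning("class ", k, " absent from truth and prediction; F1 set to 0")
      return(0)
    }
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, 0)
  names(per) <- as.character(levels)
  list(per_class = per, macro = mean(per))
}

#' Expected macro-F1 of a prevalence-proportional random classifier
#'
#' For a predictor that draws labels independently with the class
#' prevalences, the expected per-class precision and recall both equal the
#' class prevalence, so the expected per-class F1 is the prevalence and the
#' macro-F1 is their mean — exactly `1/c` for any prevalence vector on the
#' simplex. With the 15/70/15 design this is 33.3%.
#'
#' @param prevalences Positive class prevalences summing to 1.
#' @return Scalar expected macro-F1.
#' @export
naive_macro_f1 <- function(prevalences) {
  if (any(prevalences <= 0)) stop("all prevalences must be positive")
  if (abs(sum(prevalences) - 1) > 1e-8)
    stop("prevalences must sum to 1")
  mean(prevalences)
}

#' Rank-based binary AUC
#'
#' Mann-Whitney estimator: the probability that a random positive scores
#' above a random negative, with ties counted one half. Equals brute-force
#' counting over all (positive, negative) pairs.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels Binary labels (0/1 or logical); both classes required.
#' @return Scalar AUC in `[0, 1]`.
#' @export
auc_binary <- function(scores, labels) {
  if (any(!is.finite(scores))) stop("non-finite scores")
  y <- as.integer(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' R-squared ladder over nested predictor sets
#'
#' Fits ordinary least squares of a continuous outcome on each predictor set
#' in turn and reports `R^2 = 1 - SSE/SST` (unadjusted). With nested sets
#' (e.g. probability of the high class; + probability of the low class;
#' + age, sex, BMI) the ladder is non-decreasing.
#'
#' @param y_continuous Numeric outcome (e.g. measured blood pressure on test
#'   samples).
#' @param predictor_sets Named list of data frames / matrices, each a
#'   predictor set (typically nested).
#' @return Named numeric vector of R-squared values.
#' @export
prob_regression_r2 <- function(y_continuous, predictor_sets) {
  y <- as.numeric(y_continuous)
  sst <- sum((y - mean(y))^2)
  if (sst < 1e-12) stop("zero-variance outcome")
  out <- vapply(predictor_sets, function(P) {
    P <- as.matrix(P)
    fit <- lm.fit(cbind(1, P), y)
    1 - sum(fit$residuals^2) / sst
  }, 0)
  if (is.null(names(predictor_sets)))
    names(out) <- sprintf("set%d", seq_along(out))
  out
}
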