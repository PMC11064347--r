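# Preprocessing: target residualization on covariates, correlation-based
# transcript filtering, list-based CpG selection, training-statistics
# scaling, and construction of the three 1-sd classes. Every statistic is
# computed on samples flagged "train" only; each returned object carries the
# ids it used so leakage can be audited after the fact.

.train_idx <- function(split) {
  if (is.factor(split) || is.character(split)) split == "train"
  else as.logical(split)
}

.stamp_provenance <- function(obj, ids) {
  attr(obj, "train_ids") <- ids
  obj
}

#' Residualize targets on age, sex and BMI
#'
#' Per target, fits ordinary least squares of the target on intercept + age +
#' sex + BMI using training samples only, applies the fitted coefficients to
#' all samples, and z-scores the residuals by the training residual mean and
#' (sample) standard deviation. The result is the supervision matrix for the
#' semi-supervised autoencoder: on training samples each column has mean ~0
#' and sd ~1.
#'
#' @param targets Samples x targets numeric matrix (NAs allowed only in
#'   targets that are entirely unused).
#' @param covariates Data frame or matrix with columns `age`, `sex`, `bmi`.
#' @param train_split Logical vector, or the cohort `split` factor (samples
#'   labelled `"train"` are the fitting set).
#' @return An `"adjusted_targets"` object: the adjusted matrix with
#'   attributes `coefficients` (4 x targets), `center`/`scale` (training
#'   residual mean and sd) and `train_ids`.
#' @export
residualize_targets <- function(targets, covariates, train_split) {
  targets <- as.matrix(targets)
  tr <- .train_idx(train_split)
  if (sum(tr) < 10) stop("need at least 10 training samples")
  X <- cbind(1, age = as.numeric(covariates[, "age"]),
             sex = as.numeric(covariates[, "sex"]),
             bmi = as.numeric(covariates[, "bmi"]))
  if (anyNA(X)) stop("missing covariates")
  coefs <- matrix(NA_real_, 4L, ncol(targets),
                  dimnames = list(c("(Intercept)", "age", "sex", "bmi"),
                                  colnames(targets)))
  out <- targets
  ctr <- scl <- numeric(ncol(targets))
  for (j in seq_len(ncol(targets))) {
    fit <- lm.fit(X[tr, , drop = FALSE], targets[tr, j])
    coefs[, j] <- fit$coefficients
    res <- targets[, j] - X %*% coefs[, j]
    ctr[j] <- mean(res[tr])
    scl[j] <- sd(res[tr])
    if (!is.finite(scl[j]) || scl[j] < 1e-12)
      stop("degenerate target '", colnames(targets)[j],
           "': residual sd below 1e-12")
    out[, j] <- (res - ctr[j]) / scl[j]
  }
  obj <- structure(out, coefficients = coefs, center = ctr, scale = scl,
                   class = c("adjusted_targets", "matrix", "array"))
  .stamp_provenance(obj, rownames(targets)[tr])
}

# two-sided Pearson correlation nullity p-value via the t transform
.cor_pvalue <- function(r, n) {
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(t, df = n - 2, lower.tail = FALSE)
}

.new_feature_mask <- function(retained, reason, ids) {
  obj <- structure(retained, reason = reason, class = "feature_mask")
  .stamp_provenance(obj, ids)
}

#' Filter transcriptomic features by correlation with adjusted targets
#'
#' A feature is retained iff, on training samples, (a) the two-sided Pearson
#' nullity test against adjusted SBP or adjusted DBP has p < `p_thresh`, or
#' (b) the test against any adjusted diastolic-function target has
#' p < `p_thresh` and the training variance exceeds `var_thresh`.
#' Zero-variance features are excluded (correlation undefined) with a
#' message, not an error.
#'
#' @param block Samples x features matrix.
#' @param adjusted_targets Result of [residualize_targets()]; the first two
#'   columns are taken as the blood-pressure targets.
#' @param train_split As in [residualize_targets()].
#' @param p_thresh Per-feature test level (default 0.05, uncorrected).
#' @param var_thresh Training-variance threshold for the second criterion
#'   (default 0.01, evaluated on the raw pre-scaling values).
#' @return A `"feature_mask"`: named logical vector with a `reason` attribute
#'   in `{bp_corr, lvdd_corr_var, excluded}`.
#' @export
filter_transcripts <- function(block, adjusted_targets, train_split,
                               p_thresh = 0.05, var_thresh = 0.01) {
  tr <- .train_idx(train_split)
  Xtr <- block[tr, , drop = FALSE]
  Ytr <- unclass(adjusted_targets)[tr, , drop = FALSE]
  n <- nrow(Xtr)
  v <- apply(Xtr, 2L, var)
  ok <- v > 0
  if (any(!ok))
    message(sum(!ok), " zero-variance feature(s) excluded from filtering")
  r <- matrix(0, ncol(block), ncol(Ytr))
  r[ok, ] <- cor(Xtr[, ok, drop = FALSE], Ytr)
  p <- .cor_pvalue(r, n)
  bp <- ok & (p[, 1] < p_thresh | p[, 2] < p_thresh)
  lvdd_cols <- seq_len(ncol(Ytr))[-(1:2)]
  lvdd <- ok & v > var_thresh &
    apply(p[, lvdd_cols, drop = FALSE] < p_thresh, 1L, any)
  retained <- bp | lvdd
  reason <- rep("excluded", ncol(block))
  reason[lvdd] <- "lvdd_corr_var"
  reason[bp] <- "bp_corr"  # BP criterion reported when both hold
  names(retained) <- colnames(block)
  .new_feature_mask(retained, reason, rownames(block)[tr])
}

#' Select features from a user-supplied id list
#'
#' Used for the epigenetic block, where a literature-derived CpG panel
#' replaces data-driven filtering.
#'
#' @param block Samples x features matrix with feature-id column names.
#' @param id_list Character vector of feature ids to retain.
#' @return A `"feature_mask"`; warns about ids absent from the block and
#'   errors if none intersect.
#' @export
select_features_by_list <- function(block, id_list) {
  if (!length(id_list)) stop("id_list must be non-empty")
  present <- id_list %in% colnames(block)
  if (!any(present))
    stop("none of the supplied feature ids are present in the block")
  if (any(!present))
    warning("ids not present in block: ",
            paste(id_list[!present], collapse = ", "))
  retained <- colnames(block) %in% id_list
  names(retained) <- colnames(block)
  reason <- ifelse(retained, "supplied_list", "excluded")
  .new_feature_mask(retained, reason, character(0))
}

#' Fit per-feature scaling statistics on training samples
#'
#' `"minmax"` maps training values to \[0,1\] via
#' `u -> (u - min_u) / (max_u - min_u)`; `"zscore"` centers and scales by the
#' training mean and sample sd. Test values scaled with training statistics
#' may fall outside \[0,1\]; they are not clipped.
#'
#' @param block Samples x features matrix.
#' @param train_split As in [residualize_targets()].
#' @param method `"minmax"` (transcriptomic convention) or `"zscore"`
#'   (metabolomic convention).
#' @return A `"scaling_stats"` object.
#' @export
fit_scaler <- function(block, train_split, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  tr <- .train_idx(train_split)
  Xtr <- block[tr, , drop = FALSE]
  if (method == "minmax") {
    mn <- apply(Xtr, 2L, min)
    mx <- apply(Xtr, 2L, max)
    bad <- which(mx - mn <= 0)
    if (length(bad))
      stop("constant training feature(s): ",
           paste(colnames(block)[bad], collapse = ", "))
    stats <- list(method = method, min = mn, max = mx)
  } else {
    mu <- colMeans(Xtr)
    s <- apply(Xtr, 2L, sd)
    bad <- which(s <= 0)
    if (length(bad))
      stop("zero-sd training feature(s): ",
           paste(colnames(block)[bad], collapse = ", "))
    stats <- list(method = method, mean = mu, sd = s)
  }
  obj <- structure(stats, class = "scaling_stats")
  .stamp_provenance(obj, rownames(block)[tr])
}

#' Apply fitted scaling statistics to a block
#'
#' @param block Samples x features matrix with the same columns the scaler
#'   was fitted on.
#' @param stats A `"scaling_stats"` object from [fit_scaler()].
#' @return The scaled matrix.
#' @export
apply_scaler <- function(block, stats) {
  stopifnot(inherits(stats, "scaling_stats"))
  if (stats$method == "minmax")
    sweep(sweep(block, 2L, stats$min, "-"), 2L, stats$max - stats$min, "/")
  else
    sweep(sweep(block, 2L, stats$mean, "-"), 2L, stats$sd, "/")
}

#' Assign 1-sd classes from unadjusted targets
#'
#' Per target, computes the training mean and sd and labels every sample
#' +1 if `y > mean + sd`, -1 if `y < mean - sd`, and 0 otherwise (values at
#' exactly one sd belong to the middle class: the deviant classes require
#' strictly more than one sd of deviation). Labels are invariant to
#' orientation-preserving affine transforms of the target.
#'
#' @param targets Samples x targets matrix of raw (unadjusted) values.
#' @param train_split As in [residualize_targets()].
#' @return An `"sd_class_labels"` object: integer matrix in `{-1, 0, 1}` with
#'   attributes `mean` and `sd` (training statistics) and `train_ids`.
#' @export
assign_sd_classes <- function(targets, train_split) {
  targets <- as.matrix(targets)
  tr <- .train_idx(train_split)
  mu <- colMeans(targets[tr, , drop = FALSE])
  s <- apply(targets[tr, , drop = FALSE], 2L, sd)
  if (any(!is.finite(s)) || any(s < 1e-12))
    stop("degenerate training sd for target(s): ",
         paste(colnames(targets)[!is.finite(s) | s < 1e-12],
               collapse = ", "))
  lab <- matrix(0L, nrow(targets), ncol(targets),
                dimnames = dimnames(targets))
  for (j in seq_len(ncol(targets))) {
    lab[targets[, j] > mu[j] + s[j], j] <- 1L
    lab[targets[, j] < mu[j] - s[j], j] <- -1L
    lab[is.na(targets[, j]), j] <- NA_integer_
  }
  obj <- structure(lab, mean = mu, sd = s,
                   class = c("sd_class_labels", "matrix", "array"))
  .stamp_provenance(obj, rownames(targets)[tr])
}

#' Audit preprocessing objects for information leakage
#'
#' Asserts that the training ids recorded on a preprocessing result are
#' exactly the samples flagged `"train"` in the split: no statistic was
#' derived from validation or test samples.
#'
#' @param obj An object from [residualize_targets()], [filter_transcripts()],
#'   [fit_scaler()] or [assign_sd_classes()].
#' @param sample_ids Cohort sample ids.
#' @param split Cohort split factor.
#' @return `TRUE` invisibly; errors on a leak.
#' @export
audit_leakage <- function(obj, sample_ids, split) {
  ids <- attr(obj, "train_ids")
  if (is.null(ids)) stop("object carries no provenance")
  if (!length(ids)) return(invisible(TRUE))  # no sample statistics involved
  expected <- sample_ids[.train_idx(split)]
  if (!identical(sort(ids), sort(expected)))
    stop("leakage: statistics were not computed on the training samples ",
         "exactly")
  invisible(TRUE)
}
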