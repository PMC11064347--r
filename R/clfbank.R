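# Six-family classifier bank over an encoded omic subspace plus covariates.
# The families are standard algorithms from established packages routed
# through one fit/predict-probability contract; the value added here is the
# stratified cross-validated tuning, the out-of-fold probability plumbing
# needed by the late-integration meta-learner, and the leakage audit.

`%||%` <- function(a, b) if (is.null(a)) b else a

.CLF_FAMILIES <- c("random_forest", "svm_linear", "svm_rbf", "lda",
                   "gbm", "mlp_1hidden")

#' Classifier specification
#'
#' @param family One of `"random_forest"`, `"svm_linear"`, `"svm_rbf"`,
#'   `"lda"`, `"gbm"`, `"mlp_1hidden"`.
#' @param grid Optional data frame of tuning configurations (one row per
#'   candidate); NULL uses a small built-in grid.
#' @param seed Seed used when fitting this family.
#' @return An object of class `"classifier_spec"`.
#' @export
classifier_spec <- function(family, grid = NULL, seed = 1L) {
  family <- match.arg(family, .CLF_FAMILIES)
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Specifications for the full six-family bank
#'
#' @param seed Base seed; each family gets a deterministic offset.
#' @return Named list of [classifier_spec()] objects.
#' @export
default_bank <- function(seed = 1L) {
  specs <- lapply(seq_along(.CLF_FAMILIES), function(i)
    classifier_spec(.CLF_FAMILIES[i], seed = seed + i))
  names(specs) <- .CLF_FAMILIES
  specs
}

.default_grid <- function(family, p) {
  switch(family,
    random_forest = data.frame(mtry = unique(pmax(1L,
      c(floor(sqrt(p)), floor(p / 2))))),
    svm_linear = data.frame(cost = c(0.1, 1, 10)),
    svm_rbf = expand.grid(cost = c(1, 10), gamma = c(0.5, 2) / p),
    lda = data.frame(dummy = 0),
    gbm = expand.grid(nrounds = c(50, 150), max_depth = c(2, 3), eta = 0.1),
    mlp_1hidden = expand.grid(size = c(4L, 8L), decay = c(1e-3, 1e-1)))
}

# one fit/predict-probability contract over the six families; labels are a
# factor with levels "-1", "0", "1"
.clf_fit <- function(family, params, X, y) {
  switch(family,
    random_forest = randomForest::randomForest(
      x = X, y = y, mtry = min(params$mtry, ncol(X)), ntree = 300),
    svm_linear = e1071::svm(x = X, y = y, kernel = "linear",
                            cost = params$cost, probability = TRUE,
                            scale = FALSE),
    svm_rbf = e1071::svm(x = X, y = y, kernel = "radial",
                         cost = params$cost, gamma = params$gamma,
                         probability = TRUE, scale = FALSE),
    lda = MASS::lda(x = X, grouping = y),
    gbm = xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = nlevels(y),
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1L),
      data = xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L),
      nrounds = params$nrounds, verbose = 0),
    mlp_1hidden = nnet::nnet(
      x = X, y = nnet::class.ind(y), size = params$size,
      decay = params$decay, softmax = TRUE, maxit = 250, trace = FALSE,
      MaxNWts = 50000))
}

.clf_prob <- function(family, fit, X, levels) {
  P <- switch(family,
    random_forest = predict(fit, X, type = "prob"),
    svm_linear = ,
    svm_rbf = attr(predict(fit, X, probability = TRUE), "probabilities"),
    lda = predict(fit, X)$posterior,
    gbm = {
      pr <- predict(fit, xgboost::xgb.DMatrix(X))
      if (!is.matrix(pr))
        pr <- matrix(pr, ncol = length(levels), byrow = TRUE)
      colnames(pr) <- levels
      pr
    },
    mlp_1hidden = predict(fit, X))
  P <- as.matrix(P)[, levels, drop = FALSE]
  P <- pmax(P, 0)
  P / rowSums(P)
}

.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.new_prob_matrix <- function(P, classifier = NA, omic = NA,
                             fold_origin = "test", fold_id = NULL) {
  structure(P, classifier = classifier, omic = omic,
            fold_origin = fold_origin, fold_id = fold_id,
            class = c("probability_matrix", "matrix", "array"))
}

#' Hard labels from a class-probability matrix
#'
#' Argmax per row with a deterministic tie-break: if the middle class 0 is
#' among the maxima it wins, otherwise the first maximal class in the order
#' (-1, 0, 1).
#'
#' @param prob Samples x 3 probability matrix with columns `-1`, `0`, `1`.
#' @return Integer vector in `{-1, 0, 1}`.
#' @export
hard_labels <- function(prob) {
  lv <- as.integer(colnames(prob) %||% c("-1", "0", "1"))
  apply(prob, 1L, function(p) {
    cand <- which(p >= max(p) - 1e-12)
    mid <- which(lv == 0L)
    if (mid %in% cand) lv[mid] else lv[cand[1]]
  })
}

#' Assemble classifier features from a subspace and covariates
#'
#' Z-scores the subspace columns (and, by default, the covariates) by
#' training-sample statistics and appends age, sex and BMI in a fixed column
#' order. Test rows are scaled with training statistics only.
#'
#' @param subspace Samples x `l` encoded matrix (all samples).
#' @param covariates Data frame with `age`, `sex`, `bmi` aligned with
#'   `subspace`.
#' @param train_split Logical or split factor marking training rows.
#' @param scale_covariates Z-score the covariates too (default TRUE).
#' @return Numeric matrix with provenance attribute `train_ids`.
#' @export
assemble_features <- function(subspace, covariates, train_split,
                              scale_covariates = TRUE) {
  subspace <- as.matrix(subspace)
  if (nrow(subspace) != nrow(covariates)) stop("misaligned inputs")
  tr <- .train_idx(train_split)
  cov <- as.matrix(covariates[, c("age", "sex", "bmi")])
  zs <- function(M) {
    mu <- colMeans(M[tr, , drop = FALSE])
    s <- apply(M[tr, , drop = FALSE], 2L, sd)
    s[s < 1e-12] <- 1
    sweep(sweep(M, 2L, mu, "-"), 2L, s, "/")
  }
  out <- cbind(zs(subspace), if (scale_covariates) zs(cov) else cov)
  colnames(out) <- c(colnames(subspace) %||%
                       sprintf("c%02d", seq_len(ncol(subspace))),
                     "age", "sex", "bmi")
  rownames(out) <- rownames(subspace)
  .stamp_provenance(out, rownames(subspace)[tr])
}

#' Fit the classifier bank with stratified cross-validated tuning
#'
#' Per specification: every tuning configuration is evaluated by stratified
#' `folds`-fold cross-validation on the training sample, the best
#' configuration by out-of-fold macro-F1 is refit on the full training
#' sample, and the out-of-fold probabilities of the winning configuration
#' are kept for the late-integration meta-learner. A sample's out-of-fold
#' probability never comes from a model that saw it (fold assignments are
#' recorded for auditing).
#'
#' @param features Training-sample feature matrix from
#'   [assemble_features()].
#' @param labels Training 1-sd labels in `{-1, 0, 1}`; every class must
#'   appear at least twice.
#' @param specs List of [classifier_spec()] (default the six-family bank).
#' @param folds Number of CV folds (default 5).
#' @param seed Fold-assignment seed.
#' @param omic Optional omic name recorded in provenance.
#' @return A `"clf_bank"`: per family the refit model, chosen
#'   configuration, CV table, fold ids and out-of-fold
#'   `"probability_matrix"`.
#' @export
fit_bank_cv <- function(features, labels, specs = default_bank(),
                        folds = 5L, seed = 1L, omic = NA) {
  X <- as.matrix(features)
  y <- factor(as.integer(as.character(factor(labels))), levels = c(-1, 0, 1))
  if (any(table(y) < 2))
    stop("every 1-sd class needs at least 2 training samples; got ",
         paste(table(y), collapse = "/"))
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  lv <- levels(y)
  fold <- .stratified_folds(y, folds, seed)
  fits <- lapply(specs, function(spec) {
    grid <- spec$grid %||% .default_grid(spec$family, ncol(X))
    scores <- numeric(nrow(grid))
    oof_by_cfg <- vector("list", nrow(grid))
    for (g in seq_len(nrow(grid))) {
      P <- matrix(NA_real_, nrow(X), length(lv),
                  dimnames = list(rownames(X), lv))
      for (k in seq_len(folds)) {
        set.seed(spec$seed + 131 * k + 7 * g)
        fit_k <- .clf_fit(spec$family, grid[g, , drop = FALSE],
                          X[fold != k, , drop = FALSE], y[fold != k])
        P[fold == k, ] <- .clf_prob(spec$family, fit_k,
                                    X[fold == k, , drop = FALSE], lv)
      }
      scores[g] <- f1_scores(y, hard_labels(P))$macro
      oof_by_cfg[[g]] <- P
    }
    best <- which.max(scores)
    set.seed(spec$seed)
    model <- .clf_fit(spec$family, grid[best, , drop = FALSE], X, y)
    list(family = spec$family, model = model,
         best_params = grid[best, , drop = FALSE],
         cv_results = cbind(grid, oof_macro_f1 = scores),
         fold_id = fold,
         oof_prob = .new_prob_matrix(oof_by_cfg[[best]], spec$family,
                                     omic, "out_of_fold", fold))
  })
  names(fits) <- vapply(fits, `[[`, "", "family")
  structure(list(fits = fits, levels = lv, omic = omic),
            class = "clf_bank")
}

#' Predict class probabilities from a fitted bank
#'
#' @param bank A `"clf_bank"` from [fit_bank_cv()].
#' @param features_test Feature matrix with the training column layout.
#' @return Named list of `"probability_matrix"` objects (rows sum to 1).
#' @export
predict_bank <- function(bank, features_test) {
  stopifnot(inherits(bank, "clf_bank"))
  X <- as.matrix(features_test)
  lapply(bank$fits, function(f)
    .new_prob_matrix(.clf_prob(f$family, f$model, X, bank$levels),
                     f$family, bank$omic, "test"))
}

#' @export
print.clf_bank <- function(x, ...) {
  cat("Classifier bank (", length(x$fits), " families)\n", sep = "")
  for (f in x$fits)
    cat(sprintf("  %-13s oof macro-F1 %.3f  [%s]\n", f$family,
                max(f$cv_results$oof_macro_f1),
                paste(sprintf("%s=%s", names(f$best_params),
                              unlist(f$best_params)), collapse = ", ")))
  invisible(x)
}
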