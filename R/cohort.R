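# Latent-factor synthetic multi-omics cohort generator. The study cohorts
# are access-restricted, so downstream stages are exercised on simulated
# cohorts reproducing the structure the methods rely on: omic blocks of very
# different widths that share latent factors with a panel of approximately
# Gaussian targets, covariate effects on the targets, and an external cohort
# with shifted demographics and per-feature batch effects.

.TARGETS <- c("sbp", "dbp", "e_over_eprime", "e_over_a", "lavi")
.TARGET_MEANS <- c(sbp = 119, dbp = 75.2, e_over_eprime = 4.8,
                   e_over_a = 1.5, lavi = 22.5)
.TARGET_SDS <- c(sbp = 14.2, dbp = 10.6, e_over_eprime = 1,
                 e_over_a = 0.4, lavi = 6.6)

#' Simulation configuration for a synthetic multi-omics cohort
#'
#' Defines the generative model: `n_latent` shared standard-normal latent
#' factors drive a fraction (`signal_density`) of the features in each omic
#' block and, through `target_loadings`, the five continuous targets (SBP
#' and DBP in mmHg, E/e' and E/A ratios, LAVI in mL/m^2). Covariates (age,
#' sex, BMI) act additively on the targets. Targets are scaled so that their
#' theoretical means and standard deviations match typical population values,
#' which yields roughly 15/70/15 1-sd class splits.
#'
#' @param n_samples Number of samples (default 1249).
#' @param n_latent Number of shared latent factors.
#' @param block_sizes Named integer vector of features per omic block
#'   (transcriptomic, metabolomic, epigenetic).
#' @param signal_density Fraction of features per block loaded on latents;
#'   scalar or one value per block, in (0, 1].
#' @param target_loadings 5 x `n_latent` matrix of latent effect sizes on the
#'   internal (standardized) target scale; rows ordered SBP, DBP, E/e', E/A,
#'   LAVI.
#' @param covariate_effects 5 x 3 matrix of effects of standardized age, sex
#'   and BMI on the internal target scale.
#' @param noise_sd List with elements `blocks` (per-block residual sd of
#'   signal features) and `targets` (length-5 residual sd on the internal
#'   target scale).
#' @param seed Integer seed; the same seed reproduces the cohort
#'   bit-identically.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 1249,
                       n_latent = 6,
                       block_sizes = c(transcriptomic = 2000,
                                       metabolomic = 200,
                                       epigenetic = 75),
                       signal_density = c(0.2, 0.4, 0.4),
                       target_loadings = NULL,
                       covariate_effects = NULL,
                       noise_sd = list(blocks = c(1, 1, 1),
                                       targets = rep(0.5, 5)),
                       seed = 1L) {
  if (length(n_samples) != 1L || n_samples < 1)
    stop("n_samples must be a positive count")
  if (any(block_sizes < 1)) stop("block_sizes must all be >= 1")
  if (is.null(names(block_sizes)))
    names(block_sizes) <- c("transcriptomic", "metabolomic",
                            "epigenetic")[seq_along(block_sizes)]
  signal_density <- rep_len(signal_density, length(block_sizes))
  if (any(signal_density <= 0) || any(signal_density > 1))
    stop("signal_density must lie in (0, 1]")
  if (is.null(target_loadings)) {
    target_loadings <- rbind(
      sbp           = c(0.7, 0.3, 0.1, 0.0, 0, 0),
      dbp           = c(0.6, 0.4, 0.0, 0.1, 0, 0),
      e_over_eprime = c(0.2, 0.0, 0.6, 0.3, 0, 0),
      e_over_a      = c(0.1, 0.0, 0.3, 0.6, 0, 0),
      lavi          = c(0.0, 0.2, 0.4, 0.4, 0, 0))[, seq_len(n_latent),
                                                   drop = FALSE]
  }
  target_loadings <- as.matrix(target_loadings)
  if (!all(dim(target_loadings) == c(5L, n_latent)))
    stop("target_loadings must be 5 x n_latent")
  rownames(target_loadings) <- .TARGETS
  if (is.null(covariate_effects)) {
    covariate_effects <- rbind(
      sbp           = c(0.30, -0.10, 0.30),
      dbp           = c(0.25, -0.10, 0.30),
      e_over_eprime = c(0.25,  0.05, 0.20),
      e_over_a      = c(-0.30, 0.00, -0.15),
      lavi          = c(0.15,  0.05, 0.20))
  }
  covariate_effects <- as.matrix(covariate_effects)
  if (!all(dim(covariate_effects) == c(5L, 3L)))
    stop("covariate_effects must be 5 x 3 (age, sex, bmi)")
  dimnames(covariate_effects) <- list(.TARGETS, c("age", "sex", "bmi"))
  noise_sd$blocks <- rep_len(noise_sd$blocks, length(block_sizes))
  noise_sd$targets <- rep_len(noise_sd$targets, 5L)
  if (any(unlist(noise_sd) < 0)) stop("noise_sd must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 n_latent = as.integer(n_latent),
                 block_sizes = block_sizes,
                 signal_density = signal_density,
                 target_loadings = target_loadings,
                 covariate_effects = covariate_effects,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Cohort-invariant generative structure (which features carry signal, their
# loadings, epigenetic feature baselines). Drawn from a seed stream separate
# from the sample draws so a base and an external cohort share it exactly.
.cohort_structure <- function(config) {
  set.seed(.stage_seed(config$seed, "structure"))
  k <- config$n_latent
  blocks <- vector("list", length(config$block_sizes))
  names(blocks) <- names(config$block_sizes)
  for (b in seq_along(blocks)) {
    p <- config$block_sizes[b]
    n_sig <- max(1L, round(config$signal_density[b] * p))
    if (all(config$target_loadings == 0) && config$signal_density[b] <= 0)
      n_sig <- 0L
    sig_idx <- sort(sample.int(p, n_sig))
    L <- matrix(0, k, p)
    for (j in sig_idx) {
      lat <- sample.int(k, 1L)
      L[lat, j] <- runif(1, 0.4, 1.2) * sample(c(-1, 1), 1L)
    }
    baseline <- rnorm(p, 0, 1.2)  # used by the epigenetic squashing
    mask <- logical(p)
    mask[sig_idx] <- TRUE
    blocks[[b]] <- list(loadings = L, signal_mask = mask,
                        baseline = baseline)
  }
  blocks
}

# standardized covariates; centers default to the base-population means and
# are moved to the cohort's own means for a shifted external cohort, so that
# demographic offsets do not mechanically re-shift the targets (those are
# controlled by the explicit target offsets)
.covariate_std <- function(cov, age_center = 41.6, bmi_center = 26.4) {
  cbind(age = (cov$age - age_center) / 5.1,
        sex = (cov$sex - 0.538) / sqrt(0.538 * (1 - 0.538)),
        bmi = (cov$bmi - bmi_center) / 4.7)
}

# draw targets on their natural units from latents + covariates + noise;
# the internal combination is rescaled by its theoretical sd so that each
# target has (population) mean .TARGET_MEANS and sd .TARGET_SDS.
.draw_targets <- function(Z, cov_std, config) {
  eta <- Z %*% t(config$target_loadings) +
    cov_std %*% t(config$covariate_effects)
  n <- nrow(eta)
  out <- matrix(NA_real_, n, 5L, dimnames = list(NULL, .TARGETS))
  for (j in seq_len(5L)) {
    s2 <- sum(config$target_loadings[j, ]^2) +
      sum(config$covariate_effects[j, ]^2) + config$noise_sd$targets[j]^2
    e <- eta[, j] + rnorm(n, 0, config$noise_sd$targets[j])
    out[, j] <- .TARGET_MEANS[j] + .TARGET_SDS[j] * e / sqrt(s2)
  }
  out
}

.draw_blocks <- function(Z, structure, config) {
  n <- nrow(Z)
  blocks <- vector("list", length(structure))
  names(blocks) <- names(structure)
  for (b in seq_along(structure)) {
    p <- config$block_sizes[b]
    X <- Z %*% structure[[b]]$loadings +
      matrix(rnorm(n * p, 0, config$noise_sd$blocks[b]), n, p)
    if (names(structure)[b] == "epigenetic") {
      # beta values: inverse-logit squashing keeps values strictly in (0,1)
      X <- plogis(sweep(X, 2L, structure[[b]]$baseline, "+"))
    }
    colnames(X) <- sprintf("%s_f%04d", substr(names(structure)[b], 1, 4),
                           seq_len(p))
    blocks[[b]] <- X
  }
  blocks
}

.assign_split <- function(n) {
  n_test <- round(0.2 * n)
  idx <- sample.int(n)
  split <- rep("train", n)
  split[idx[seq_len(n_test)]] <- "test"
  train_idx <- idx[-seq_len(n_test)]
  n_val <- round(length(train_idx) / 5)
  split[train_idx[seq_len(n_val)]] <- "validation"
  factor(split, levels = c("train", "validation", "test"))
}

.new_cohort <- function(sample_ids, blocks, covariates, targets, split,
                        ground_truth = NULL, config = NULL) {
  for (b in seq_along(blocks)) rownames(blocks[[b]]) <- sample_ids
  rownames(targets) <- sample_ids
  covariates <- data.frame(covariates, row.names = sample_ids)
  obj <- structure(list(sample_ids = sample_ids, blocks = blocks,
                        covariates = covariates, targets = targets,
                        split = split, ground_truth = ground_truth,
                        config = config),
                   class = "multiomics_cohort")
  validate_cohort(obj)
  obj
}

#' Validate the structural invariants of a multi-omics cohort
#'
#' Checks shared sample ordering across components, strictly-(0,1) epigenetic
#' values, absence of missing values in blocks and covariates, and that the
#' validation flag marks a subset of the training partition.
#'
#' @param cohort A `"multiomics_cohort"` object.
#' @return `cohort`, invisibly; errors describe the first violated invariant.
#' @export
validate_cohort <- function(cohort) {
  n <- length(cohort$sample_ids)
  for (b in names(cohort$blocks)) {
    X <- cohort$blocks[[b]]
    if (nrow(X) != n || !identical(rownames(X), cohort$sample_ids))
      stop("block '", b, "' is not aligned with sample_ids")
    if (anyNA(X)) stop("block '", b, "' contains missing values")
    if (b == "epigenetic" && (any(X <= 0) || any(X >= 1)))
      stop("epigenetic beta values must lie strictly in (0,1)")
  }
  if (nrow(cohort$covariates) != n || anyNA(cohort$covariates))
    stop("covariates misaligned or missing")
  if (nrow(cohort$targets) != n) stop("targets misaligned")
  if (length(cohort$split) != n) stop("split misaligned")
  invisible(cohort)
}

#' Simulate a synthetic multi-omics cohort
#'
#' Draws iid standard-normal latent factors; signal features are
#' `loading x factor + noise` and non-signal features pure noise; the
#' epigenetic block is passed through an inverse-logit squashing into (0,1);
#' targets combine latents, additive covariate effects and noise; samples are
#' split roughly 80/20 into training and test, with one fifth of the training
#' partition flagged as validation. The planted signal masks and loadings are
#' recorded as ground truth.
#'
#' @param config A [sim_config()] object.
#' @return A `"multiomics_cohort"` with components `sample_ids`, `blocks`,
#'   `covariates` (age in years, sex coded 0/1, BMI in kg/m^2), `targets`,
#'   `split` and `ground_truth`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_samples = 50,
#'   block_sizes = c(transcriptomic = 30, metabolomic = 10, epigenetic = 5)))
#' table(coh$split)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  structure_ <- .cohort_structure(config)
  set.seed(.stage_seed(config$seed, "samples"))
  n <- config$n_samples
  Z <- matrix(rnorm(n * config$n_latent), n, config$n_latent)
  covariates <- list(age = rnorm(n, 41.6, 5.1),
                     sex = rbinom(n, 1L, 0.538),
                     bmi = rnorm(n, 26.4, 4.7))
  targets <- .draw_targets(Z, .covariate_std(covariates), config)
  blocks <- .draw_blocks(Z, structure_, config)
  split <- .assign_split(n)
  gt <- list(signal_mask = lapply(structure_, `[[`, "signal_mask"),
             loadings = lapply(structure_, `[[`, "loadings"),
             target_loadings = config$target_loadings,
             latents = Z)
  .new_cohort(sprintf("S%05d", seq_len(n)), blocks, covariates, targets,
              split, gt, config)
}

#' Distribution shift defining a synthetic external cohort
#'
#' @param age_offset Mean age shift in years (default +21, moving a
#'   ~40-year-old cohort to the low 60s).
#' @param sbp_offset,dbp_offset Blood-pressure shifts in mmHg.
#' @param batch_location SD of per-feature additive batch shifts.
#' @param batch_scale SD of per-feature log-normal multiplicative batch
#'   factors (multipliers are strictly positive by construction).
#' @param hypertension_enrichment Oversampling weight (>= 1) applied to
#'   hypertensive candidates when composing the cohort. The default blood
#'   pressure offsets already produce a predominantly hypertensive cohort,
#'   so the default enrichment is mild.
#' @return An object of class `"external_shift"`.
#' @export
external_shift <- function(age_offset = 21, sbp_offset = 32,
                           dbp_offset = 10, batch_location = 0.1,
                           batch_scale = 0.1,
                           hypertension_enrichment = 1.5) {
  if (hypertension_enrichment < 1)
    stop("hypertension_enrichment must be >= 1")
  if (batch_location < 0 || batch_scale < 0)
    stop("batch effect sds must be >= 0")
  structure(list(age_offset = age_offset, sbp_offset = sbp_offset,
                 dbp_offset = dbp_offset, batch_location = batch_location,
                 batch_scale = batch_scale,
                 hypertension_enrichment = hypertension_enrichment),
            class = "external_shift")
}

#' Simulate a distribution-shifted external cohort
#'
#' Uses the same latent structure and feature loadings as the base
#' configuration (so transferring an encoder is meaningful), shifts age and
#' blood pressure per `shift`, enriches for hypertensive samples, and
#' perturbs every feature by additive and multiplicative batch effects (on
#' the logit scale for the epigenetic block, preserving (0,1) support). Only
#' the SBP/DBP targets are populated; the diastolic-function targets are NA.
#'
#' @param base The [sim_config()] shared with the pretraining cohort.
#' @param shift An [external_shift()] object.
#' @param n Number of external samples (>= 2).
#' @param seed Seed for the external draws (defaults to `base$seed + 1`).
#' @return A `"multiomics_cohort"` with `split` set entirely to `"test"`.
#' @export
simulate_external_cohort <- function(base, shift, n, seed = base$seed + 1L) {
  stopifnot(inherits(base, "sim_config"), inherits(shift, "external_shift"))
  if (n < 2) stop("external cohort needs n >= 2")
  structure_ <- .cohort_structure(base)
  set.seed(.stage_seed(seed, "samples-external"))
  n_pool <- ceiling(n * max(2, shift$hypertension_enrichment + 1))
  Z <- matrix(rnorm(n_pool * base$n_latent), n_pool, base$n_latent)
  covariates <- list(age = rnorm(n_pool, 41.6 + shift$age_offset, 5.1),
                     sex = rbinom(n_pool, 1L, 0.538),
                     bmi = rnorm(n_pool, 26.4 + 1.1, 4.8))
  cov_std <- .covariate_std(covariates,
                            age_center = 41.6 + shift$age_offset,
                            bmi_center = 26.4 + 1.1)
  targets <- .draw_targets(Z, cov_std, base)
  targets[, "sbp"] <- targets[, "sbp"] + shift$sbp_offset
  targets[, "dbp"] <- targets[, "dbp"] + shift$dbp_offset
  hyper <- label_hypertension(targets[, "sbp"], targets[, "dbp"])
  w <- ifelse(hyper == 1L, shift$hypertension_enrichment, 1)
  keep <- sort(sample.int(n_pool, n, prob = w))
  Z <- Z[keep, , drop = FALSE]
  covariates <- lapply(covariates, `[`, keep)
  targets <- targets[keep, , drop = FALSE]
  targets[, c("e_over_eprime", "e_over_a", "lavi")] <- NA_real_
  blocks <- .draw_blocks(Z, structure_, base)
  for (b in names(blocks)) {
    p <- ncol(blocks[[b]])
    delta <- rnorm(p, 0, shift$batch_location)
    mult <- exp(rnorm(p, 0, shift$batch_scale))
    if (b == "epigenetic") {
      logit <- qlogis(blocks[[b]])
      blocks[[b]][] <- plogis(sweep(sweep(logit, 2L, mult, "*"),
                                    2L, delta, "+"))
    } else {
      blocks[[b]][] <- sweep(sweep(blocks[[b]], 2L, mult, "*"),
                             2L, delta, "+")
    }
  }
  split <- factor(rep("test", n), levels = c("train", "validation", "test"))
  .new_cohort(sprintf("E%05d", seq_len(n)), blocks, covariates, targets,
              split, NULL, base)
}

#' @export
print.multiomics_cohort <- function(x, ...) {
  cat("Multi-omics cohort:", length(x$sample_ids), "samples\n")
  for (b in names(x$blocks))
    cat(sprintf("  %-14s %5d features\n", b, ncol(x$blocks[[b]])))
  cat("  split:", paste(sprintf("%s=%d", levels(x$split), table(x$split)),
                        collapse = ", "), "\n")
  pops <- colSums(!is.na(x$targets))
  cat("  targets populated:",
      paste(sprintf("%s(%d)", colnames(x$targets), pops), collapse = " "),
      "\n")
  invisible(x)
}
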