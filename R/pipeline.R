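# Configuration-driven orchestration of the full study: simulate (or load) a
# cohort, preprocess, train SSAE and matched-USAE per autoencoded omic,
# compute variable importance, run the classifier bank per omic, fuse with
# VCDNs, evaluate, and optionally run the transfer experiment. Every
# stochastic stage derives its seed deterministically from the global seed
# and the stage name.

# small stable polynomial hash of a deparsed object (hex string)
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Full-run configuration
#'
#' @param cohort A [sim_config()] (synthetic cohort) or a directory path for
#'   [read_cohort()].
#' @param targets Target names to model (default all five).
#' @param classifiers Classifier families (default the six-family bank).
#' @param ae Named list of per-omic autoencoder settings; each element a
#'   list with `p`, `l` and optionally `alpha`, `r`, and [ssae_control()]
#'   arguments. Only the named omics are autoencoded.
#' @param epigenetic_ids Optional CpG id list for the epigenetic block
#'   (NULL keeps all features).
#' @param vcdn_epochs VCDN training epochs.
#' @param usae_compare Also train matched unsupervised controls and compare
#'   downstream macro-F1 (default TRUE).
#' @param transfer NULL, or a list with `shift` ([external_shift()]), `n`,
#'   `omic`, `fractions`, `repeats`, `epochs`.
#' @param seed Global seed.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(cohort = sim_config(),
                       targets = c("sbp", "dbp", "e_over_eprime",
                                   "e_over_a", "lavi"),
                       classifiers = c("random_forest", "svm_linear",
                                       "svm_rbf", "lda", "gbm",
                                       "mlp_1hidden"),
                       ae = list(
                         transcriptomic = list(p = 150, l = 50,
                                               corruption_sd = 0.01),
                         metabolomic = list(p = 55, l = 6,
                                            corruption_sd = 0.1)),
                       epigenetic_ids = NULL,
                       vcdn_epochs = 150L,
                       usae_compare = TRUE,
                       transfer = NULL,
                       seed = 1L) {
  structure(list(cohort = cohort, targets = targets,
                 classifiers = classifiers, ae = ae,
                 epigenetic_ids = epigenetic_ids,
                 vcdn_epochs = as.integer(vcdn_epochs),
                 usae_compare = isTRUE(usae_compare),
                 transfer = transfer, seed = as.integer(seed)),
            class = "run_config")
}

#' Save / load a run configuration as JSON
#'
#' @param config A `"run_config"`.
#' @param path JSON file path.
#' @return `save_run_config` the path invisibly; `load_run_config` the
#'   reconstructed `"run_config"` (round-trip identity up to numeric
#'   representation).
#' @export
save_run_config <- function(config, path) {
  x <- unclass(config)
  if (inherits(x$cohort, "sim_config")) {
    x$cohort <- unclass(x$cohort)
    x$cohort_kind <- "sim_config"
  } else x$cohort_kind <- "directory"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- x$cohort_kind
  x$cohort_kind <- NULL
  if (identical(kind, "sim_config"))
    x$cohort <- do.call(sim_config, x$cohort)
  do.call(run_config, x)
}

.ae_settings <- function(cfg_entry, omic, seed) {
  ctl_args <- cfg_entry[intersect(names(cfg_entry),
                                  names(formals(ssae_control)))]
  ctl <- do.call(ssae_control, ctl_args)
  if (is.null(ctl$seed)) ctl$seed <- .stage_seed(seed, paste0("ae-", omic))
  list(p = cfg_entry$p, l = cfg_entry$l,
       alpha = cfg_entry$alpha %||% 0.9, r = cfg_entry$r %||% 0.5,
       control = ctl)
}

#' Run the full study pipeline
#'
#' Executes simulation/loading, preprocessing, per-omic semi-supervised
#' autoencoding with a matched unsupervised control, connection-weights
#' importance, the classifier bank per omic and target, CoDT/VCDN late
#' integration, evaluation, and the optional transfer experiment.
#'
#' @param config A [run_config()].
#' @return A list of class `"lateomix_run"` with elements `eval_report`
#'   (Table of per-class and macro F1 on the test sample), `importance`,
#'   `ssae_vs_usae` (paired macro-F1 table and the fraction of cases where
#'   the semi-supervised subspace is at least as good), `transfer`
#'   (optional), `models`, and a provenance `manifest`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  cohort <- if (inherits(config$cohort, "sim_config"))
    simulate_cohort(config$cohort) else read_cohort(config$cohort)
  split <- cohort$split
  trainpart <- split %in% c("train", "validation")
  test <- split == "test"
  val_in_trainpart <- split[trainpart] == "validation"
  targets <- cohort$targets[, config$targets, drop = FALSE]

  adj <- residualize_targets(cohort$targets, cohort$covariates, split)
  classes <- assign_sd_classes(targets, split)
  audit_leakage(adj, cohort$sample_ids, split)
  audit_leakage(classes, cohort$sample_ids, split)

  # --- per-omic preprocessing -------------------------------------------
  prepped <- list()
  masks <- list()
  if ("transcriptomic" %in% names(cohort$blocks)) {
    mask <- filter_transcripts(cohort$blocks$transcriptomic, adj, split)
    masks$transcriptomic <- mask
    keep <- cohort$blocks$transcriptomic[, mask, drop = FALSE]
    sc <- fit_scaler(keep, split, "minmax")
    audit_leakage(sc, cohort$sample_ids, split)
    prepped$transcriptomic <- apply_scaler(keep, sc)
  }
  if ("metabolomic" %in% names(cohort$blocks)) {
    sc <- fit_scaler(cohort$blocks$metabolomic, split, "zscore")
    audit_leakage(sc, cohort$sample_ids, split)
    prepped$metabolomic <- apply_scaler(cohort$blocks$metabolomic, sc)
  }
  if ("epigenetic" %in% names(cohort$blocks)) {
    blk <- cohort$blocks$epigenetic
    if (!is.null(config$epigenetic_ids)) {
      mask <- select_features_by_list(blk, config$epigenetic_ids)
      masks$epigenetic <- mask
      blk <- blk[, mask, drop = FALSE]
    }
    prepped$epigenetic <- blk  # beta values kept unscaled
  }

  # --- autoencoding ------------------------------------------------------
  models <- list()
  subspaces <- list()
  usae_subspaces <- list()
  importance <- list()
  for (omic in intersect(names(config$ae), names(prepped))) {
    st <- .ae_settings(config$ae[[omic]], omic, seed)
    Xtr <- prepped[[omic]][trainpart, , drop = FALSE]
    Ytr <- unclass(adj)[trainpart, config$targets, drop = FALSE]
    fit <- ssae(Xtr, Ytr, p = st$p, l = st$l, alpha = st$alpha, r = st$r,
                control = st$control, validation = val_in_trainpart,
                seed = .stage_seed(seed, paste0("init-", omic)))
    models[[omic]] <- fit
    subspaces[[omic]] <- encode(fit, prepped[[omic]])
    importance[[omic]] <- connection_weights(fit)
    if (config$usae_compare) {
      final_mse <- fit$history$val_recon_mse[nrow(fit$history)]
      us <- train_usae_matched(fit$architecture, Xtr, final_mse,
                               st$control, validation = val_in_trainpart,
                               seed = .stage_seed(seed,
                                                  paste0("usae-", omic)))
      models[[paste0(omic, "_usae")]] <- us
      usae_subspaces[[omic]] <- encode(us, prepped[[omic]])
    }
  }
  for (omic in setdiff(names(prepped), names(config$ae)))
    subspaces[[omic]] <- prepped[[omic]]

  # --- classifier bank + fusion, per target ------------------------------
  specs <- lapply(seq_along(config$classifiers), function(i)
    classifier_spec(config$classifiers[i],
                    seed = .stage_seed(seed, paste0("clf-",
                                                    config$classifiers[i]))))
  names(specs) <- config$classifiers
  eval_rows <- list()
  compare_rows <- list()
  run_bank <- function(subspace, omic, target) {
    feats <- assemble_features(subspace, cohort$covariates, split)
    audit_leakage(feats, cohort$sample_ids, split)
    lab_tr <- unclass(classes)[trainpart, target]
    bank <- fit_bank_cv(feats[trainpart, , drop = FALSE], lab_tr, specs,
                        seed = .stage_seed(seed,
                                           paste0("folds-", omic, target)),
                        omic = omic)
    list(bank = bank,
         test_prob = predict_bank(bank, feats[test, , drop = FALSE]))
  }
  for (target in config$targets) {
    lab_test <- unclass(classes)[test, target]
    lab_train <- unclass(classes)[trainpart, target]
    banks <- lapply(names(subspaces), function(omic)
      run_bank(subspaces[[omic]], omic, target))
    names(banks) <- names(subspaces)
    for (omic in names(banks))
      for (fam in names(banks[[omic]]$test_prob)) {
        f1 <- f1_scores(lab_test,
                        hard_labels(banks[[omic]]$test_prob[[fam]]))
        eval_rows[[length(eval_rows) + 1L]] <- data.frame(
          target = target, omics = omic, model = fam,
          f1_low = f1$per_class[["-1"]], f1_mid = f1$per_class[["0"]],
          f1_high = f1$per_class[["1"]], macro_f1 = f1$macro)
      }
    if (length(banks) >= 2) {
      for (fam in config$classifiers) {
        oof <- lapply(banks, function(b) b$bank$fits[[fam]]$oof_prob)
        codt_tr <- build_codt(unname(oof))
        codt_te <- build_codt(unname(lapply(banks, function(b)
          b$test_prob[[fam]])))
        vm <- train_vcdn(codt_tr, lab_train, epochs = config$vcdn_epochs,
                         seed = .stage_seed(seed,
                                            paste0("vcdn-", target, fam)))
        f1 <- f1_scores(lab_test, hard_labels(predict(vm, codt_te)))
        eval_rows[[length(eval_rows) + 1L]] <- data.frame(
          target = target, omics = "multi_omics", model = fam,
          f1_low = f1$per_class[["-1"]], f1_mid = f1$per_class[["0"]],
          f1_high = f1$per_class[["1"]], macro_f1 = f1$macro)
      }
    }
    if (config$usae_compare && length(usae_subspaces)) {
      for (omic in names(usae_subspaces)) {
        ub <- run_bank(usae_subspaces[[omic]], paste0(omic, "_usae"),
                       target)
        for (fam in names(ub$test_prob)) {
          ssae_f1 <- f1_scores(lab_test,
            hard_labels(banks[[omic]]$test_prob[[fam]]))$macro
          usae_f1 <- f1_scores(lab_test,
            hard_labels(ub$test_prob[[fam]]))$macro
          compare_rows[[length(compare_rows) + 1L]] <- data.frame(
            target = target, omics = omic, model = fam,
            macro_f1_ssae = ssae_f1, macro_f1_usae = usae_f1)
        }
      }
    }
  }
  eval_report <- do.call(rbind, eval_rows)
  comparison <- if (length(compare_rows)) {
    tab <- do.call(rbind, compare_rows)
    list(table = tab,
         fraction_ssae_ge_usae =
           mean(tab$macro_f1_ssae >= tab$macro_f1_usae))
  }

  transfer_res <- NULL
  if (!is.null(config$transfer)) {
    tf <- config$transfer
    ext <- simulate_external_cohort(config$cohort,
                                    tf$shift %||% external_shift(),
                                    tf$n %||% 310L,
                                    seed = .stage_seed(seed, "external"))
    omic <- tf$omic %||% "metabolomic"
    # transfer operates on the source model's input features
    if (omic == "transcriptomic" && !is.null(masks$transcriptomic))
      ext$blocks$transcriptomic <-
        ext$blocks$transcriptomic[, masks$transcriptomic, drop = FALSE]
    transfer_res <- run_transfer_experiment(
      ext, models[[omic]], omic = omic,
      fractions = tf$fractions %||% c(0.2, 0.4, 0.6, 0.8),
      repeats = tf$repeats %||% 100L, epochs = tf$epochs %||% 30L,
      seed = .stage_seed(seed, "transfer"))
  }

  manifest <- list(
    config_hash = .config_hash(unclass(config)),
    seed = seed,
    stage_seeds = c(
      vapply(names(config$ae), function(o)
        .stage_seed(seed, paste0("ae-", o)), 0),
      transfer = .stage_seed(seed, "transfer")),
    n_samples = length(cohort$sample_ids),
    blocks = vapply(prepped, ncol, 0L),
    artifacts = c("eval_report", "importance", "ssae_vs_usae",
                  if (!is.null(transfer_res)) "transfer"))

  structure(list(eval_report = eval_report, importance = importance,
                 ssae_vs_usae = comparison, transfer = transfer_res,
                 models = models, masks = masks, cohort = cohort,
                 manifest = manifest),
            class = "lateomix_run")
}

#' @export
print.lateomix_run <- function(x, ...) {
  cat("lateomix run", x$manifest$config_hash, "\n")
  cat("  eval report:", nrow(x$eval_report), "rows\n")
  if (!is.null(x$ssae_vs_usae))
    cat(sprintf("  SSAE >= USAE downstream in %.0f%% of cases\n",
                100 * x$ssae_vs_usae$fraction_ssae_ge_usae))
  best <- x$eval_report[order(-x$eval_report$macro_f1), ]
  cat("  best configuration: ", best$target[1], "/", best$omics[1], "/",
      best$model[1], sprintf(" macro-F1 %.3f\n", best$macro_f1[1]))
  invisible(x)
}
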