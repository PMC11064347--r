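test_that("the same seed reproduces a cohort bit-identically", {
  cfg <- sim_config(n_samples = 80, n_latent = 3,
                    block_sizes = c(transcriptomic = 20, metabolomic = 8,
                                    epigenetic = 5), seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$blocks, b$blocks)
  expect_identical(a$targets, b$targets)
  expect_identical(a$split, b$split)
  cfg2 <- cfg; cfg2$seed <- 8L
  expect_false(identical(simulate_cohort(cfg2)$blocks$metabolomic,
                         a$blocks$metabolomic))
})

test_that("cohort components align and respect their supports", {
  coh <- tiny_cohort(seed = 3, n = 150)
  eb <- coh$blocks$epigenetic
  expect_true(all(eb > 0 & eb < 1))
  expect_false(anyNA(coh$targets))
  for (b in coh$blocks)
    expect_identical(rownames(b), coh$sample_ids)
  # ~80/20 train/test, one fifth of the training partition is validation
  tab <- table(coh$split)
  expect_equal(unname(tab[["test"]]), round(0.2 * 150))
  trainpart <- tab[["train"]] + tab[["validation"]]
  expect_equal(unname(tab[["validation"]]), round(trainpart / 5))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_samples = 0), "positive")
  expect_error(sim_config(signal_density = 0), "signal_density")
  expect_error(sim_config(signal_density = 1.2), "signal_density")
  expect_error(sim_config(noise_sd = list(blocks = -1, targets = 0.5)),
               "noise_sd")
})

test_that("zero target loadings decouple omics from targets", {
  cfg <- sim_config(n_samples = 500, n_latent = 3,
                    block_sizes = c(transcriptomic = 30, metabolomic = 10,
                                    epigenetic = 5),
                    target_loadings = matrix(0, 5, 3), seed = 5)
  coh <- simulate_cohort(cfg)
  r <- abs(cor(coh$blocks$transcriptomic, coh$targets[, "sbp"]))
  # null correlations at n = 500: mean |r| is near sqrt(2/(pi n)) ~ 0.036
  expect_lt(mean(r), 0.08)
  expect_true(all(coh$ground_truth$target_loadings == 0))
})

test_that("planted signal features out-correlate null features", {
  wins <- vapply(1:5, function(s) {
    coh <- simulate_cohort(sim_config(
      n_samples = 1000, n_latent = 3,
      block_sizes = c(transcriptomic = 60, metabolomic = 10,
                      epigenetic = 5),
      signal_density = c(0.3, 0.5, 0.5), seed = 40 + s))
    mask <- coh$ground_truth$signal_mask$transcriptomic
    r <- abs(cor(coh$blocks$transcriptomic, coh$targets))
    mean(r[mask, ]) > mean(r[!mask, ])
  }, TRUE)
  expect_true(all(wins))
})

test_that("external shift moves age and blood pressure by the offsets", {
  cfg <- sim_config(n_samples = 200, n_latent = 3,
                    block_sizes = c(transcriptomic = 20, metabolomic = 8,
                                    epigenetic = 5), seed = 2)
  base_shift <- external_shift(age_offset = 20, sbp_offset = 0,
                               dbp_offset = 0, batch_location = 0,
                               batch_scale = 0, hypertension_enrichment = 1)
  up_shift <- external_shift(age_offset = 20, sbp_offset = 30,
                             dbp_offset = 0, batch_location = 0,
                             batch_scale = 0, hypertension_enrichment = 1)
  d_age <- d_sbp <- numeric(20)
  for (s in 1:20) {
    e0 <- simulate_external_cohort(cfg, base_shift, 310, seed = 100 + s)
    e1 <- simulate_external_cohort(cfg, up_shift, 310, seed = 100 + s)
    d_age[s] <- mean(e0$covariates$age) - 41.6
    d_sbp[s] <- mean(e1$targets[, "sbp"]) - mean(e0$targets[, "sbp"])
  }
  expect_equal(mean(d_age), 20, tolerance = 0.05)
  expect_equal(mean(d_sbp), 30, tolerance = 0.05)
})

test_that("hypertension enrichment raises prevalence over paired seeds", {
  cfg <- sim_config(n_samples = 100, n_latent = 3,
                    block_sizes = c(transcriptomic = 15, metabolomic = 6,
                                    epigenetic = 4), seed = 9)
  prev <- function(shift, s) {
    e <- simulate_external_cohort(cfg, shift, 300, seed = s)
    mean(label_hypertension(e$targets[, "sbp"], e$targets[, "dbp"]))
  }
  sh1 <- external_shift(sbp_offset = 5, dbp_offset = 0,
                        hypertension_enrichment = 1)
  sh3 <- external_shift(sbp_offset = 5, dbp_offset = 0,
                        hypertension_enrichment = 3)
  p1 <- vapply(1:10, function(s) prev(sh1, 200 + s), 0)
  p3 <- vapply(1:10, function(s) prev(sh3, 200 + s), 0)
  expect_gt(mean(p3), mean(p1))
  expect_gt(mean(p3 > p1), 0.8)
})

test_that("external cohort keeps shared structure and valid supports", {
  cfg <- sim_config(n_samples = 100, n_latent = 3,
                    block_sizes = c(transcriptomic = 15, metabolomic = 6,
                                    epigenetic = 4), seed = 9)
  ext <- simulate_external_cohort(cfg, external_shift(), 120, seed = 1)
  expect_true(all(ext$blocks$epigenetic > 0 & ext$blocks$epigenetic < 1))
  expect_true(all(is.na(ext$targets[, c("e_over_eprime", "e_over_a",
                                        "lavi")])))
  expect_false(anyNA(ext$targets[, c("sbp", "dbp")]))
  expect_error(simulate_external_cohort(cfg, external_shift(), 1),
               "n >= 2")
  expect_error(external_shift(hypertension_enrichment = 0.5), ">= 1")
})

test_that("cohorts round-trip through the on-disk layout exactly", {
  coh <- tiny_cohort(seed = 11, n = 30,
                     blocks = c(transcriptomic = 20, metabolomic = 5,
                                epigenetic = 3))
  dir <- file.path(tempdir(), "coh-roundtrip")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  for (b in names(coh$blocks))
    expect_equal(back$blocks[[b]], coh$blocks[[b]], tolerance = 0)
  expect_equal(back$targets, coh$targets, tolerance = 0)
  expect_identical(back$split, coh$split)
  expect_equal(back$covariates$age, coh$covariates$age, tolerance = 0)
  unlink(dir, recursive = TRUE)
})

test_that("reading a damaged cohort directory fails loudly", {
  coh <- tiny_cohort(seed = 12, n = 20,
                     blocks = c(transcriptomic = 10, metabolomic = 4,
                                epigenetic = 3))
  dir <- file.path(tempdir(), "coh-damaged")
  write_cohort(coh, dir)
  file.remove(file.path(dir, "covariates.tsv"))
  expect_error(read_cohort(dir), "missing cohort component")
  write_cohort(coh, dir)
  # permute the sample rows of one block on disk
  p <- file.path(dir, "block_metabolomic.tsv")
  lines <- readLines(p)
  writeLines(c(lines[1], rev(lines[-1])), p)
  expect_error(read_cohort(dir), "do not match")
  unlink(dir, recursive = TRUE)
})
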