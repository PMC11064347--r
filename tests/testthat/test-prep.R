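test_that("residualization matches the normal-equations oracle on a toy", {
  covs <- data.frame(age = seq(30, 75, 5),
                     sex = rep(c(0, 1), 5),
                     bmi = c(22, 25, 24, 28, 27, 23, 26, 29, 21, 30))
  y <- c(1, 2, 3, 4, 6, 5, 7, 9, 8, 11)
  targets <- matrix(y, ncol = 1, dimnames = list(paste0("s", 1:10), "y"))
  adj <- residualize_targets(targets, covs, rep(TRUE, 10))
  X <- cbind(1, covs$age, covs$sex, covs$bmi)
  beta <- solve(crossprod(X), crossprod(X, y))       # independent oracle
  res <- y - drop(X %*% beta)
  expect_equal(drop(unclass(adj)), (res - mean(res)) / sd(res),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(mean(unclass(adj)), 0, tolerance = 1e-8)
  expect_equal(sd(unclass(adj)), 1, tolerance = 1e-8)
})

test_that("a covariate-independent target is nearly unchanged", {
  set.seed(4)
  n <- 1000
  covs <- data.frame(age = rnorm(n, 40, 5), sex = rbinom(n, 1, 0.5),
                     bmi = rnorm(n, 26, 4))
  y <- rnorm(n)
  adj <- residualize_targets(matrix(y, ncol = 1), covs, rep(TRUE, n))
  expect_gt(cor(drop(unclass(adj)), y), 0.99)
})

test_that("an exactly collinear target raises the degeneracy error", {
  covs <- data.frame(age = seq(30, 70, length.out = 20),
                     sex = rep(0:1, 10), bmi = rnorm(20, 26))
  expect_error(
    residualize_targets(matrix(2 * covs$age, ncol = 1), covs,
                        rep(TRUE, 20)),
    "residual sd below")
})

test_that("adjustment coefficients never see non-training samples", {
  set.seed(5)
  n <- 200
  covs <- data.frame(age = rnorm(n, 40, 5), sex = rbinom(n, 1, 0.5),
                     bmi = rnorm(n, 26, 4))
  y <- covs$age * 0.5 + rnorm(n)
  split <- rep(c(TRUE, FALSE), each = 100)
  a1 <- residualize_targets(matrix(y, ncol = 1), covs, split)
  y2 <- y; y2[!split] <- y2[!split] + 100   # corrupt only test samples
  a2 <- residualize_targets(matrix(y2, ncol = 1), covs, split)
  expect_equal(attr(a1, "coefficients"), attr(a2, "coefficients"))
  expect_equal(unclass(a1)[split, ], unclass(a2)[split, ])
})

test_that("transcript filtering agrees with the t-transform test", {
  set.seed(6)
  n <- 1000
  sbp <- rnorm(n); dbp <- rnorm(n)
  lvdd <- matrix(rnorm(n * 3), n, 3)
  adj <- structure(cbind(sbp = sbp, dbp = dbp, e1 = lvdd[, 1],
                         e2 = lvdd[, 2], e3 = lvdd[, 3]),
                   class = c("adjusted_targets", "matrix", "array"))
  X <- matrix(rnorm(n * 100), n, 100)
  X[, 1:10] <- 0.3 * sbp + sqrt(1 - 0.09) * X[, 1:10]  # r ~ 0.3 planted
  colnames(X) <- sprintf("g%03d", 1:100)
  mask <- filter_transcripts(X, adj, rep(TRUE, n))
  expect_true(all(mask[1:10]))
  expect_true(all(attr(mask, "reason")[1:10] == "bp_corr"))
  # oracle: per-feature union test via cor.test
  oracle <- vapply(seq_len(100), function(j) {
    p_bp <- min(cor.test(X[, j], sbp)$p.value,
                cor.test(X[, j], dbp)$p.value)
    p_lv <- min(vapply(1:3, function(k)
      cor.test(X[, j], lvdd[, k])$p.value, 0))
    p_bp < 0.05 || (p_lv < 0.05 && var(X[, j]) > 0.01)
  }, TRUE)
  expect_identical(unname(unclass(mask)[seq_len(100)]), oracle)
  # null false-retention rate near the union-test level
  expect_lt(mean(oracle[-(1:10)]), 0.35)
})

test_that("degenerate and perfectly correlated features are handled", {
  set.seed(7)
  n <- 60
  adj <- structure(matrix(rnorm(n * 5), n, 5,
                          dimnames = list(NULL,
                            c("sbp", "dbp", "e1", "e2", "e3"))),
                   class = c("adjusted_targets", "matrix", "array"))
  X <- cbind(perfect = adj[, "sbp"] + rnorm(n, 0, 1e-4),
             constant = rep(2, n), noise = rnorm(n))
  expect_message(mask <- filter_transcripts(X, adj, rep(TRUE, n)),
                 "zero-variance")
  expect_true(mask[["perfect"]])
  expect_false(mask[["constant"]])
})

test_that("the filter mask is invariant to affine feature maps", {
  set.seed(8)
  n <- 300
  adj <- structure(matrix(rnorm(n * 5), n, 5,
                          dimnames = list(NULL,
                            c("sbp", "dbp", "e1", "e2", "e3"))),
                   class = c("adjusted_targets", "matrix", "array"))
  X <- matrix(rnorm(n * 20), n, 20)
  X[, 1:4] <- 0.4 * adj[, "sbp"] + X[, 1:4]
  colnames(X) <- sprintf("g%02d", 1:20)
  m1 <- filter_transcripts(X, adj, rep(TRUE, n), var_thresh = -Inf)
  X2 <- sweep(sweep(X, 2, runif(20, 0.5, 3), "*"), 2, rnorm(20), "+")
  m2 <- filter_transcripts(X2, adj, rep(TRUE, n), var_thresh = -Inf)
  expect_identical(unclass(m1)[1:20], unclass(m2)[1:20])
})

test_that("list-based selection retains exactly the supplied features", {
  X <- matrix(0, 3, 5, dimnames = list(NULL, paste0("cg", 1:5)))
  m <- select_features_by_list(X, paste0("cg", c(1, 3)))
  expect_equal(sum(m), 2)
  expect_warning(m2 <- select_features_by_list(X, c("cg1", "cg2", "cgX")),
                 "not present")
  expect_equal(sum(m2), 2)
  expect_error(select_features_by_list(X, c("a", "b")), "none of")
  expect_error(select_features_by_list(X, character(0)), "non-empty")
})

test_that("scalers reproduce the min-max and z-score contracts", {
  blk <- matrix(c(2, 4, 6), 3, 1, dimnames = list(NULL, "f1"))
  st <- fit_scaler(blk, rep(TRUE, 3), "minmax")
  expect_equal(drop(apply_scaler(blk, st)), c(0, 0.5, 1))
  # test values outside the training range are preserved, not clipped
  expect_equal(drop(apply_scaler(matrix(8, 1, 1), st)), 1.5)
  blk2 <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "f1"))
  st2 <- fit_scaler(blk2, rep(TRUE, 3), "zscore")
  expect_equal(drop(apply_scaler(blk2, st2)), c(-1, 0, 1))
  expect_error(fit_scaler(matrix(1, 3, 1, dimnames = list(NULL, "flat")),
                          rep(TRUE, 3), "minmax"), "flat")
  expect_error(fit_scaler(matrix(1, 3, 1, dimnames = list(NULL, "flat")),
                          rep(TRUE, 3), "zscore"), "flat")
})

test_that("1-sd classes follow the strict boundary rule", {
  y_tr <- c(-2, -1, 0, 1, 2)  # mean 0, sd sqrt(2.5)
  s <- sd(y_tr)
  y <- c(y_tr, 0, s, -s, 1.5 * s, -1.5 * s, s + 1e-9)
  lab <- assign_sd_classes(matrix(y, ncol = 1),
                           c(rep(TRUE, 5), rep(FALSE, 6)))
  expect_equal(unclass(lab)[6:10, 1], c(0L, 0L, 0L, 1L, -1L))
  expect_equal(unclass(lab)[11, 1], 1L)  # just past the boundary
})

test_that("1-sd classes are invariant to positive affine transforms", {
  set.seed(9)
  y <- rnorm(200)
  tr <- rep(c(TRUE, FALSE), 100)
  l1 <- assign_sd_classes(matrix(y, ncol = 1), tr)
  l2 <- assign_sd_classes(matrix(3.7 * y - 11, ncol = 1), tr)
  expect_identical(as.vector(unclass(l1)), as.vector(unclass(l2)))
  expect_error(assign_sd_classes(matrix(rep(1, 200), ncol = 1), tr),
               "degenerate")
})

test_that("the leakage audit accepts clean and rejects shifted provenance", {
  coh <- tiny_cohort(seed = 13, n = 60)
  st <- fit_scaler(coh$blocks$metabolomic, coh$split, "zscore")
  expect_true(audit_leakage(st, coh$sample_ids, coh$split))
  wrong <- coh$split
  wrong[which(wrong == "train")[1]] <- "test"
  expect_error(audit_leakage(st, coh$sample_ids, wrong), "leakage")
  expect_error(audit_leakage(structure(1, class = "x"), coh$sample_ids,
                             coh$split), "provenance")
})
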