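# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

tiny_cohort <- function(seed = 1, n = 120,
                        blocks = c(transcriptomic = 40, metabolomic = 15,
                                   epigenetic = 8)) {
  simulate_cohort(sim_config(n_samples = n, n_latent = 4,
                             block_sizes = blocks,
                             signal_density = c(0.4, 0.5, 0.5),
                             seed = seed))
}

# control settings that actually converge at toy scale
fast_ctl <- function(seed = 1, epochs = 60, sigma = 0.1, min_epochs = 15) {
  ssae_control(max_epochs = epochs, min_epochs = min_epochs,
               stop_window = 10, corruption_sd = sigma,
               learning_rate = 1e-2, decay = 0.98, seed = seed)
}

# planted data where the target-relevant latents carry little block
# variance: an unsupervised encoder prefers the dominant nuisance latents,
# a supervised one the target latents
planted_lowrank <- function(seed, n = 360, p_in = 40) {
  set.seed(seed)
  Z <- matrix(rnorm(n * 4), n, 4)
  L_weak <- matrix(rnorm(2 * p_in, 0, 0.4), 2, p_in)
  L_strong <- matrix(rnorm(2 * p_in, 0, 1.2), 2, p_in)
  X <- Z[, 1:2] %*% L_weak + Z[, 3:4] %*% L_strong +
    matrix(rnorm(n * p_in, 0, 0.5), n, p_in)
  y <- Z[, 1] + Z[, 2] + rnorm(n, 0, 0.4)
  list(X = X, y = y, Z = Z)
}

# three omic blocks carrying complementary class information: each block
# sees one of three latents whose sum drives the target
complementary_blocks <- function(seed, n = 450, p = 8) {
  set.seed(seed)
  Z <- matrix(rnorm(n * 3), n, 3)
  blocks <- lapply(1:3, function(b) {
    B <- Z[, b] %*% t(rnorm(p, 1, 0.2)) + matrix(rnorm(n * p, 0, 0.8), n, p)
    colnames(B) <- sprintf("f%02d", seq_len(p))
    B
  })
  list(blocks = blocks, y = rowSums(Z))
}

expect_prob_matrix <- function(P) {
  expect_true(all(P >= 0 & P <= 1))
  expect_true(all(abs(rowSums(P) - 1) < 1e-8))
}
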