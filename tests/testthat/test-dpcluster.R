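test_that("prior expected cluster count follows the CRP closed form", {
  expect_equal(dp_expected_k(1, 1), 1)
  expect_equal(dp_expected_k(1, 3), 1 + 1 / 2 + 1 / 3)
  expect_error(dp_expected_k(0, 10), "positive")
  expect_error(dp_expected_k(1, 0), "at least 1")

  # Monte-Carlo oracle: independent CRP draws in the test
  set.seed(123)
  draws <- replicate(4000, oracle_crp_k(1, 100))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - dp_expected_k(1, 100)), 3 * se)
})

test_that("a single transcript always occupies one cluster", {
  prof <- tidyr::expand_grid(transcript_id = "only",
                             time = c(0, 10, 20, 30), rep = 1:2) %>%
    dplyr::mutate(M = rnorm(dplyr::n()))
  fit <- dp_fit(prof, n_sweeps = 150, burn_in = 20, seed = 1)
  expect_true(all(fit$K == 1))
})

test_that("three well-separated planted clusters are recovered exactly", {
  cfg <- sep3_config(n_per = 15, seed = 19)
  e <- synth_expression(cfg)
  fit <- dp_fit(e$expression, n_sweeps = 700, burn_in = 200, seed = 2)
  s <- dp_summarize(fit)
  expect_equal(s$K, 3)
  truth <- e$truth$genes$cluster[match(s$assignments$transcript_id,
                                       e$truth$genes$transcript_id)]
  expect_equal(mclust::adjustedRandIndex(s$assignments$primary, truth), 1.0)

  # recovered mean profiles sit within 2 SE of the planted means
  prof_truth <- e$truth$profiles
  for (k in unique(s$assignments$primary)) {
    members <- s$assignments$transcript_id[s$assignments$primary == k]
    true_k <- unique(truth[s$assignments$primary == k])
    expect_length(true_k, 1)
    mu_hat <- dplyr::filter(s$profiles, cluster == k)$mu
    mu_true <- dplyr::filter(prof_truth, cluster == true_k)$mu
    se <- sqrt(cfg$sigma_c^2 + cfg$sigma_t^2 + cfg$sigma_r^2 / 4) /
      sqrt(length(members))
    expect_true(all(abs(mu_hat - mu_true) < 2 * se + 0.05))
  }
})

test_that("independent chains agree on the co-clustering matrix", {
  cfg <- sep3_config(n_per = 10, seed = 23)
  e <- synth_expression(cfg)
  s1 <- dp_summarize(dp_fit(e$expression, n_sweeps = 500, burn_in = 150,
                            seed = 41))
  s2 <- dp_summarize(dp_fit(e$expression, n_sweeps = 500, burn_in = 150,
                            seed = 42))
  expect_lt(max(abs(s1$coclust - s2$coclust)), 0.05)
})

test_that("co-clustering structure is invariant to transcript order", {
  cfg <- sep3_config(n_per = 8, seed = 29)
  e <- synth_expression(cfg)
  ids <- unique(e$expression$transcript_id)
  perm <- sample(ids)
  shuffled <- e$expression %>%
    dplyr::mutate(transcript_id = factor(transcript_id, levels = perm)) %>%
    dplyr::arrange(transcript_id) %>%
    dplyr::mutate(transcript_id = as.character(transcript_id))
  s1 <- dp_summarize(dp_fit(e$expression, n_sweeps = 400, burn_in = 150,
                            seed = 7))
  s2 <- dp_summarize(dp_fit(shuffled, n_sweeps = 400, burn_in = 150,
                            seed = 8))
  # align the permuted matrix back to original id order
  o1 <- order(s1$assignments$transcript_id)
  o2 <- order(s2$assignments$transcript_id)
  expect_lt(max(abs(s1$coclust[o1, o1] - s2$coclust[o2, o2])), 0.05)
})

test_that("prior-only sampling matches the CRP prior distribution", {
  cfg <- sep3_config(n_per = 10, seed = 37)
  e <- synth_expression(cfg)
  fit <- dp_fit(e$expression, n_sweeps = 1100, burn_in = 100, seed = 6,
                prior_only = TRUE)
  expected <- dp_expected_k(1, 30)
  # autocorrelated chain: assume an effective sample size of S/10
  se <- sd(fit$K) / sqrt(length(fit$K) / 10)
  expect_lt(abs(mean(fit$K) - expected), max(3 * se, 0.5))
})

test_that("MAP means match per-cluster sample means on zero-offset data", {
  cfg <- synth_config(
    n_genes = 30,
    cluster_spec = tibble::tibble(shape = c("early_up", "down"),
                                  amplitude = c(3, 3), n = c(15, 15)),
    sigma_c = 0, sigma_t = 0.02, sigma_r = 0.1, seed = 41)
  e <- synth_expression(cfg)
  fit <- dp_fit(e$expression, n_sweeps = 500, burn_in = 200, seed = 3,
                sigma_init = c(sc = 0.05, st = 0.05, sr = 0.1))
  s <- dp_summarize(fit)
  ybar <- e$expression %>%
    dplyr::group_by(transcript_id, time) %>%
    dplyr::summarise(M = mean(M), .groups = "drop")
  for (k in unique(s$assignments$primary)) {
    members <- s$assignments$transcript_id[s$assignments$primary == k]
    emp <- ybar %>%
      dplyr::filter(transcript_id %in% members) %>%
      dplyr::group_by(time) %>%
      dplyr::summarise(M = mean(M), .groups = "drop")
    mu_hat <- dplyr::filter(s$profiles, cluster == k) %>%
      dplyr::arrange(time) %>% dplyr::pull(mu)
    se <- 0.12 / sqrt(length(members))
    expect_true(all(abs(mu_hat - emp$M) < 2 * se + 0.05))
  }
})

test_that("summaries handle degenerate and tied allocation patterns", {
  # all samples identical: primary probability 1, secondary 0
  n <- 4; S <- 120; T_ <- 3
  z <- matrix(rep(c(1L, 1L, 2L, 2L), each = S), S, n)
  fake <- structure(list(
    z_samples = z, K = rep(2L, S),
    mu_samples = replicate(S, matrix(0, T_, 2), simplify = FALSE),
    sig2_samples = matrix(0.01, S, 3,
                          dimnames = list(NULL, c("sc2", "st2", "sr2"))),
    alpha_samples = rep(1, S),
    transcript_ids = paste0("t", 1:n), times = c(0, 10, 20), n_reps = 2,
    n_sweeps = S, burn_in = 0, accept_rate = c(0, 0, 0), divergent_rate = 0
  ), class = "dp_fit")
  s <- dp_summarize(fake)
  expect_true(all(s$assignments$primary_prob == 1))
  expect_true(all(s$assignments$secondary_prob == 0))

  # one transcript alternating equally between two clusters
  z2 <- z
  z2[seq(1, S, by = 2), 4] <- 1L      # transcript 4 joins cluster 1 half the time
  fake$z_samples <- z2
  s2 <- dp_summarize(fake)
  row4 <- s2$assignments[4, ]
  expect_equal(row4$primary_prob, 0.5)
  expect_equal(row4$secondary_prob, 0.5)
  expect_lt(row4$primary, row4$secondary)   # tie broken by lower index
})

test_that("tidy and glance expose sampler trajectories and diagnostics", {
  cfg <- sep3_config(n_per = 5, seed = 43)
  e <- synth_expression(cfg)
  fit <- dp_fit(e$expression, n_sweeps = 200, burn_in = 50, seed = 5)
  td <- tidy(fit)
  expect_equal(nrow(td), 150)
  expect_true(all(c("sweep", "K", "sc2", "st2", "sr2") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_transcripts, 15)
  s <- dp_summarize(dp_fit(e$expression, n_sweeps = 250, burn_in = 100,
                           seed = 5))
  expect_s3_class(autoplot(s), "ggplot")
})
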