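test_that("interval distance is zero on overlap, else the nearest-end gap", {
  expect_equal(min_distance(100, 200, 150, 300), 0)
  expect_equal(min_distance(100, 200, 210, 260), 10)
  expect_equal(min_distance(210, 260, 100, 200), 10)

  # exhaustive small-coordinate grid vs a brute-force per-base scan:
  # the distance is the number of bases strictly between the two intervals
  brute <- function(a1, a2, b1, b2) {
    pts <- 0:30
    in_a <- pts >= a1 & pts < a2
    in_b <- pts >= b1 & pts < b2
    if (any(in_a & in_b)) return(0)
    left_end <- if (a1 < b1) a2 else b2
    right_start <- if (a1 < b1) b1 else a1
    sum(pts >= left_end & pts < right_start)
  }
  for (a1 in 0:6) for (b1 in 0:6) {
    a2 <- a1 + 3; b2 <- b1 + 2
    expect_equal(min_distance(a1, a2, b1, b2), brute(a1, a2, b1, b2))
  }
})

toy_genes <- function(starts, ends, ids = sprintf("g%02d", seq_along(starts))) {
  tibble::tibble(gene_id = ids, transcript_id = paste0(ids, "-RA"),
                 chrom = "chrS", start = starts, end = ends,
                 strand = "+", tss = starts)
}

toy_peaks <- function(starts, ends, time = 0) {
  tibble::tibble(chrom = "chrS", start = starts, end = ends, time = time)
}

test_that("peak counting respects the inclusive radius boundary", {
  genes <- toy_genes(50000, 52000)
  # peak exactly 9,999 / 10,001 bp upstream of the gene start
  expect_equal(count_peaks_within(genes, toy_peaks(39001, 40001),
                                  radius = 10000)$n_peaks, 1L)
  expect_equal(count_peaks_within(genes, toy_peaks(38999, 39999),
                                  radius = 10000)$n_peaks, 0L)
  # radius is inclusive: distance exactly 10,000 counts
  expect_equal(count_peaks_within(genes, toy_peaks(39000, 40000),
                                  radius = 10000)$n_peaks, 1L)
  # overlapping peak always counts
  expect_gte(count_peaks_within(genes, toy_peaks(51000, 51500),
                                radius = 10000)$n_peaks, 1L)
})

test_that("radius monotonicity holds for peak counts", {
  set.seed(14)
  genes <- toy_genes(seq(0, 90000, by = 10000),
                     seq(2000, 92000, by = 10000))
  peaks <- toy_peaks(sort(sample(0:95000, 15)), NA)
  peaks$end <- peaks$start + 500
  counts <- lapply(c(0, 1000, 5000, 20000), function(r) {
    count_peaks_within(genes, peaks, radius = r)$n_peaks
  })
  for (i in 2:length(counts)) {
    expect_true(all(counts[[i]] >= counts[[i - 1]]))
  }
})

test_that("nearest-2 assignment picks the two closest genes, ties leftmost", {
  # three genes equidistant from one peak; leftmost two win
  genes <- toy_genes(c(0, 4000, 8000), c(1000, 5000, 9000))
  peak <- toy_peaks(2500, 2600)    # 1500 from g01 end, 1400 from g02 start
  res <- count_peaks_within(genes, peak, mode = "nearest2")
  expect_equal(res$n_peaks[res$gene_id == "g02"], 1L)
  expect_equal(sum(res$n_peaks), 2L)

  eq <- toy_genes(c(0, 2000, 4000), c(1000, 3000, 5000))
  peak_eq <- toy_peaks(1500, 1500 + 0)   # zero-width sentinel not used
  peak_eq <- toy_peaks(1400, 1600)       # overlaps nothing, 400 from g01/g02
  res_eq <- count_peaks_within(eq, peak_eq, mode = "nearest2")
  expect_equal(res_eq$n_peaks, c(1L, 1L, 0L))
})

test_that("logistic fit recovers null and planted effects", {
  # predictor independent of outcome: coefficient within 3 SE of 0
  set.seed(20)
  n <- 2000
  tb <- tibble::tibble(
    de = rbinom(n, 1, 0.3),
    suh = rbinom(n, 1, 0.4),
    polii_class = sample(c("UB", "P", "AP", "AU"), n, replace = TRUE),
    logc0 = rnorm(n)
  )
  fit <- fit_de_logistic(tb)
  co <- tidy(fit)
  suh_row <- co[co$term == "suh", ]
  expect_lt(abs(suh_row$estimate), 3 * suh_row$std_error)

  # parameter recovery at the printed effect sizes
  tb2 <- synth_logistic(5000, seed = 101)
  fit2 <- fit_de_logistic(tb2)
  co2 <- tidy(fit2)
  truth <- c(suh = 2.78, polii_classP = 0.77, polii_classAU = -0.49)
  for (term in names(truth)) {
    row <- co2[co2$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 2 * row$std_error)
  }
})

test_that("degenerate predictors are dropped and separation is flagged", {
  set.seed(21)
  n <- 300
  tb <- tibble::tibble(
    de = rbinom(n, 1, 0.4),
    suh = 0L,                                   # constant column
    polii_class = sample(c("UB", "P"), n, replace = TRUE),
    logc0 = rnorm(n)
  )
  expect_warning(fit <- fit_de_logistic(tb), "constant predictor")
  expect_false("suh" %in% tidy(fit)$term)

  # perfectly separating predictor
  tb2 <- tibble::tibble(
    de = rep(0:1, each = 100),
    suh = rep(0:1, each = 100),
    polii_class = sample(c("UB", "P", "AP", "AU"), 200, replace = TRUE),
    logc0 = rnorm(200)
  )
  expect_warning(fit2 <- fit_de_logistic(tb2), "separation")
  expect_true(all(is.finite(tidy(fit2)$estimate)))
})

test_that("log-odds effects convert to the quoted odds multipliers", {
  expect_identical(effect_to_odds(2.78), 16.12)
  expect_identical(effect_to_odds(0.77), 2.16)
  expect_identical(effect_to_odds(-0.49), 0.61)
  expect_identical(effect_to_odds(0), 1)
})

test_that("logC0 class tests handle degenerate, separated and toy cases", {
  # identical values everywhere: no class signal (lm warns on zero residual)
  res <- suppressWarnings(
    logc0_class_tests(rep(5, 40), rep(c("UB", "P", "AP", "AU"), 10)))
  expect_equal(res$anova$F, 0)
  expect_equal(res$anova$p, 1)

  # large separation: one-sided p essentially zero
  set.seed(22)
  res2 <- logc0_class_tests(c(rnorm(100, 0), rnorm(100, 3)),
                            rep(c("UB", "AU"), each = 100))
  pr <- res2$pairwise
  expect_equal(pr$higher, "AU")
  expect_lt(pr$p, 1e-10)

  # ANOVA F against hand-computed sums of squares on a 12-value toy table
  vals <- c(1, 2, 3, 4, 2, 3, 4, 5, 6, 7, 8, 9)
  cls <- rep(c("UB", "P", "AU"), each = 4)
  res3 <- logc0_class_tests(vals, cls)
  grand <- mean(vals)
  ss_b <- sum(tapply(vals, cls, function(x) length(x) * (mean(x) - grand)^2))
  ss_w <- sum(tapply(vals, cls, function(x) sum((x - mean(x))^2)))
  f_oracle <- (ss_b / 2) / (ss_w / 9)
  expect_equal(res3$anova$F, f_oracle)
  expect_error(logc0_class_tests(rnorm(10), rep("UB", 10)), "2 classes")
})

test_that("regime comparison flags dose-sensitive genes and matches OLS", {
  # exact identity triggers the perfect-fit warning from summary.lm
  same <- suppressWarnings(regime_compare(c(1, 2, 3, -1), c(1, 2, 3, -1)))
  expect_equal(same$fit$slope, 1)
  expect_equal(same$fit$r_squared, 1)
  expect_false(any(same$genes$flagged))

  one_off <- regime_compare(c(1, 0.5, 2, 3), c(1, 0.5, 2, 6))
  expect_equal(sum(one_off$genes$flagged), 1)
  expect_true(one_off$genes$flagged[4])

  set.seed(23)
  a <- rnorm(50); b <- 0.8 * a + rnorm(50, 0, 0.2)
  rc <- regime_compare(a, b)
  # closed-form normal equations oracle
  slope_o <- cov(a, b) / var(a)
  int_o <- mean(b) - slope_o * mean(a)
  r2_o <- cor(a, b)^2
  expect_equal(rc$fit$slope, slope_o)
  expect_equal(rc$fit$intercept, int_o)
  expect_equal(rc$fit$r_squared, r2_o)
  expect_error(regime_compare(1:2, 1:2), "at least 3")
})

test_that("master table holds one complete row per transcript", {
  cfg <- synth_config(
    n_genes = 30,
    cluster_spec = tibble::tibble(shape = c("early_up", "flat"),
                                  amplitude = c(2, 0), n = c(10, 20)),
    seed = 44)
  e <- synth_expression(cfg)
  g <- synth_genes(cfg)
  ch <- synth_chip(cfg, g, e$truth)
  tc <- tc_matrix(compute_ma(e$raw))
  de <- timecourse_de(tc)
  pk <- call_peaks(ch$tracks$suh, spacing = 50)
  pol <- classify_polii(ch$tracks$polii, g)
  counts <- count_peaks_within(g, pk)
  logc0 <- compute_logc0(e$raw)
  master <- build_master_table(g, de, NULL, pol, counts, logc0, tc)
  expect_equal(nrow(master), 30)
  expect_equal(sort(master$transcript_id), sort(g$transcript_id))
  expect_false(any(duplicated(master$transcript_id)))
  expect_true(all(paste0("polii_", cfg$chip_times) %in% names(master)))
  expect_true(all(paste0("M_", cfg$expr_times) %in% names(master)))
  expect_true(all(is.finite(master$q)))
})
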