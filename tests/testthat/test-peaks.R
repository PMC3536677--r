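test_that("run-length rule calls exactly the planted block", {
  expect_equal(nrow(call_peaks(track_from_scores(rep(0, 50)), threshold = 1)),
               0)

  scores <- c(rep(0, 10), rep(3, 6), rep(0, 10))
  pk <- call_peaks(track_from_scores(scores), threshold = 1, min_run = 4)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$n_probes, 6L)
  # boundaries: first to last enriched probe +/- half spacing
  pos <- track_from_scores(scores)$pos
  expect_equal(pk$start, pos[11] - 25)
  expect_equal(pk$end, pos[16] + 25)
  expect_equal(pk$max, 3)

  short <- c(rep(0, 10), rep(3, 3), rep(0, 10))
  expect_equal(nrow(call_peaks(track_from_scores(short), threshold = 1,
                               min_run = 4)), 0)
})

test_that("nearby runs are merged across short sub-threshold gaps", {
  scores <- c(rep(0, 5), rep(3, 3), rep(0.2, 2), rep(3, 3), rep(0, 5))
  pk <- call_peaks(track_from_scores(scores), threshold = 1, min_run = 4,
                   merge_gap = 2)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$n_probes, 6L)
  # with merge_gap 1 the two 3-probe runs stay apart and fail min_run
  pk2 <- call_peaks(track_from_scores(scores), threshold = 1, min_run = 4,
                    merge_gap = 1)
  expect_equal(nrow(pk2), 0)
})

test_that("caller agrees with an exhaustive-scan oracle on seeded tracks", {
  for (sd in 1:100) {
    set.seed(sd)
    n <- 120
    scores <- pmax(rnorm(n, 0, 0.4), 0)
    # plant 0-2 bumps
    for (b in seq_len(sample(0:2, 1))) {
      at <- sample(10:(n - 10), 1)
      len <- sample(3:8, 1)
      scores[at:(at + len - 1)] <- runif(1, 1.5, 4)
    }
    pk <- call_peaks(track_from_scores(scores), threshold = 1, min_run = 4,
                     merge_gap = 2)
    oracle <- oracle_call_peaks(scores, threshold = 1, min_run = 4,
                                merge_gap = 2)
    expect_equal(nrow(pk), length(oracle), info = paste("seed", sd))
    if (length(oracle) > 0) {
      pos <- track_from_scores(scores)$pos
      # oracle returns probe indices of enriched extremes
      first_enriched <- vapply(oracle, function(o) {
        idx <- o["first"]:o["last"]
        min(idx[scores[idx] >= 1])
      }, numeric(1))
      last_enriched <- vapply(oracle, function(o) {
        idx <- o["first"]:o["last"]
        max(idx[scores[idx] >= 1])
      }, numeric(1))
      expect_equal(sort(pk$start), sort(pos[first_enriched] - 25))
      expect_equal(sort(pk$end), sort(pos[last_enriched] + 25))
    }
  }
})

test_that("replicates are averaged (or min-combined) before calling", {
  tr <- dplyr::bind_rows(
    track_from_scores(rep(3, 10), rep = 1),
    track_from_scores(rep(0, 10), rep = 2)
  )
  # mean = 1.5 passes threshold 1; min = 0 does not
  expect_equal(nrow(call_peaks(tr, threshold = 1, min_run = 4)), 1)
  expect_equal(nrow(call_peaks(tr, threshold = 1, min_run = 4,
                               combine = "min")), 0)
})

test_that("peak area follows the rectangle rule", {
  scores <- c(rep(0, 4), rep(2, 6), rep(0, 4))
  tr <- track_from_scores(scores)
  pk <- call_peaks(tr, threshold = 1, min_run = 4)
  expect_equal(peak_area(tr, pk[1, ]), 600)

  flat <- track_from_scores(rep(0, 14))
  expect_equal(peak_area(flat, list(chrom = "chrS", start = 200, end = 500,
                                    time = 0)), 0)

  # seeded random bump vs trapezoid oracle (within discretization error)
  set.seed(33)
  x <- seq(25, by = 50, length.out = 40)
  bump <- 3 * exp(-((x - 1000) / 300)^2)
  tr2 <- track_from_scores(bump)
  area <- peak_area(tr2, list(chrom = "chrS", start = 0, end = 2000, time = 0))
  trap <- sum((bump[-1] + bump[-length(bump)]) / 2 * diff(x))
  expect_lt(abs(area - trap) / trap, 0.1)
})

test_that("raising min_run or threshold never adds peaks", {
  set.seed(55)
  # arbitrary noisy tracks for the min_run property
  for (i in 1:20) {
    scores <- pmax(rnorm(150, 0.5, 0.8), 0)
    n_by_run <- vapply(1:8, function(mr) {
      nrow(call_peaks(track_from_scores(scores), threshold = 1, min_run = mr))
    }, numeric(1))
    expect_true(all(diff(n_by_run) <= 0))
  }
  # unimodal planted bumps for the threshold property
  x <- seq(25, by = 50, length.out = 200)
  scores <- 4 * exp(-((x - 2000) / 400)^2) + 3 * exp(-((x - 7000) / 300)^2)
  n_by_thr <- vapply(seq(0.5, 3.5, by = 0.5), function(th) {
    nrow(call_peaks(track_from_scores(scores), threshold = th, min_run = 4))
  }, numeric(1))
  expect_true(all(diff(n_by_thr) <= 0))
})

test_that("planted Su(H) pulse peaks give a unimodal area timecourse", {
  cfg <- synth_config(n_genes = 12, sigma_bg = 0.05, suh_frac_de = 1,
                      suh_frac_other = 1, seed = 3)
  g <- synth_genes(cfg)
  ch <- synth_chip(cfg, g)
  pk <- call_peaks(ch$tracks$suh, threshold = 1, min_run = 4, spacing = 50)
  areas <- peak_area_timecourse(ch$tracks$suh, pk)
  prof <- areas %>%
    dplyr::group_by(time) %>%
    dplyr::summarise(area = mean(area), .groups = "drop") %>%
    dplyr::arrange(time)
  peak_time <- prof$time[which.max(prof$area)]
  expect_true(peak_time %in% c(20, 30))
  # unimodal: increases to the max, decreases after
  i <- which.max(prof$area)
  expect_true(all(diff(prof$area[1:i]) > 0))
  expect_true(all(diff(prof$area[i:nrow(prof)]) < 0))
})

test_that("planted peaks are recovered within one probe spacing", {
  cfg <- synth_config(n_genes = 20, sigma_bg = 0.05, suh_frac_de = 1,
                      suh_frac_other = 1, seed = 8)
  g <- synth_genes(cfg)
  ch <- synth_chip(cfg, g)
  pk <- call_peaks(ch$tracks$suh, threshold = 1, min_run = 4, spacing = 50)
  planted <- ch$truth$peaks %>%
    dplyr::filter(height >= 1 + 3 * cfg$sigma_bg)
  for (tp in unique(planted$time)) {
    pl <- dplyr::filter(planted, time == tp)
    ca <- dplyr::filter(pk, time == tp)
    expect_equal(nrow(ca), nrow(pl))
    pl <- dplyr::arrange(pl, start); ca <- dplyr::arrange(ca, start)
    expect_true(all(abs(ca$start - pl$start) <= 50))
    expect_true(all(abs(ca$end - pl$end) <= 50))
  }
})
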