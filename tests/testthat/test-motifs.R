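test_that("PWM construction produces bit scores against the background", {
  pw <- pwm_from_consensus("CGTGGGAA")
  expect_equal(pw$length, 8)
  expect_equal(pwm_consensus(pw), "CGTGGGAA")
  # max score = sum of per-position maxima, near log2(p_max / 0.25) per column
  expect_gt(pw$max_score, 0)
  expect_error(pwm_build(matrix(1, 3, 4)), "rows A, C, G, T")

  counts <- matrix(c(10, 0, 0, 0,
                     0, 10, 0, 0), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pw2 <- pwm_build(counts)
  # pseudocount 0.5: p(A at 1) = 10.5/12, score = log2(p/0.25)
  expect_equal(unname(pw2$mat["A", 1]), log2((10.5 / 12) / 0.25))
})

test_that("consensus sequence yields exactly one maximal-score match", {
  pw <- pwm_from_consensus("CGTGGGAA")
  hits <- scan_pwm("CGTGGGAA", pw, threshold = pw$max_score - 1e-9)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 0L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, pw$max_score, tolerance = 1e-12)

  # the reverse complement matches on the minus strand at the same position
  hits_rc <- scan_pwm("TTCCCACG", pw, threshold = pw$max_score - 1e-9)
  expect_equal(nrow(hits_rc), 1)
  expect_equal(hits_rc$strand, "-")
})

test_that("poly-A sequence has no matches above a GC-matrix threshold", {
  pw <- pwm_from_consensus("GGCCGGCC")
  hits <- scan_pwm(strrep("A", 200), pw)
  expect_equal(nrow(hits), 0)
})

test_that("windows containing N are skipped", {
  pw <- pwm_from_consensus("CGTGGGAA")
  hits <- scan_pwm("CGTGNGAA", pw, threshold = -100)
  expect_equal(nrow(hits), 0)
})

test_that("scanner agrees with an exhaustive rescoring oracle", {
  set.seed(61)
  seq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
  pw <- pwm_from_consensus("CGTGGGAA", n_obs = 2)   # soft matrix: partial matches score
  th <- 0.2 * pw$max_score
  hits <- scan_pwm(seq, pw, threshold = th)
  oracle <- oracle_scan(seq, pw$mat, th)
  expect_gt(nrow(oracle), 0)
  expect_equal(nrow(hits), nrow(oracle))
  key <- function(d) paste(d$start, d$strand)
  expect_setequal(key(hits), key(oracle))
  merged <- dplyr::inner_join(hits, oracle, by = c("start", "strand"))
  expect_equal(merged$score.x, merged$score.y, tolerance = 1e-9)
})

test_that("forward-strand scores match the Biostrings reference", {
  set.seed(62)
  seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
  pw <- pwm_from_consensus("CACGCG", n_obs = 2)
  hits <- scan_pwm(seq, pw, threshold = 0.2 * pw$max_score)
  fwd <- dplyr::filter(hits, strand == "+")
  if (nrow(fwd) > 0) {
    ref <- Biostrings::PWMscoreStartingAt(
      pw$mat, Biostrings::DNAString(seq), starting.at = fwd$start + 1)
    expect_equal(fwd$score, as.numeric(ref), tolerance = 1e-9)
  }
})

test_that("scanning the reverse complement mirrors the match set", {
  set.seed(63)
  chars <- sample(c("A", "C", "G", "T"), 800, replace = TRUE)
  seq <- paste(chars, collapse = "")
  rc <- paste(rev(chartr("ACGT", "TGCA", chars)), collapse = "")
  pw <- pwm_from_consensus("CGTGGGAA", n_obs = 2)
  th <- 0.2 * pw$max_score
  h1 <- scan_pwm(seq, pw, threshold = th)
  h2 <- scan_pwm(rc, pw, threshold = th)
  # positions reflect, strands swap
  L <- nchar(seq); w <- pw$length
  mirrored <- tibble::tibble(start = L - w - h2$start,
                             strand = ifelse(h2$strand == "+", "-", "+"))
  expect_setequal(paste(h1$start, h1$strand),
                  paste(mirrored$start, mirrored$strand))
})

test_that("shipped example matrices load and score their consensus highest", {
  for (f in c("suh_matrix_synthetic.tsv", "hairy_matrix_synthetic.tsv")) {
    path <- system.file("extdata", f, package = "notchpulse")
    expect_true(nzchar(path))
    pw <- read_pwm(path)
    cons <- pwm_consensus(pw)
    hits <- scan_pwm(cons, pw, threshold = pw$max_score - 1e-9)
    expect_equal(nrow(hits), 1)
  }
  suh <- read_pwm(system.file("extdata", "suh_matrix_synthetic.tsv",
                              package = "notchpulse"))
  expect_equal(pwm_consensus(suh), "CGTGGGAA")
})

test_that("SPS detection enforces opposite strands and the 10-22 nt gap", {
  mk <- function(starts, strands) {
    tibble::tibble(chrom = "chrS", start = starts, strand = strands,
                   score = 10, motif = "suh")
  }
  w <- 8
  expect_equal(nrow(find_sps(mk(c(0, w + 15), c("+", "-")),
                             motif_length = w)), 1)
  for (gap in c(9, 23)) {
    expect_equal(nrow(find_sps(mk(c(0, w + gap), c("+", "-")),
                               motif_length = w)), 0)
  }
  for (gap in c(10, 22)) {                       # inclusive bounds
    expect_equal(nrow(find_sps(mk(c(0, w + gap), c("+", "-")),
                               motif_length = w)), 1)
  }
  # same strand never pairs
  expect_equal(nrow(find_sps(mk(c(0, w + 15), c("+", "+")),
                             motif_length = w)), 0)
  # tail-to-tail (minus then plus) also qualifies
  tt <- find_sps(mk(c(0, w + 15), c("-", "+")), motif_length = w)
  expect_equal(nrow(tt), 1)
  expect_equal(tt$orientation, "tail_to_tail")
  # invariant to input ordering
  sh <- find_sps(mk(c(w + 15, 0), c("-", "+")), motif_length = w)
  expect_equal(sh$left_start, 0L)
})

test_that("gene-level motif fractions use rounded percentages", {
  # 13 genes, 10 with a match within 5 kb -> 77%
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:13), chrom = "chrS",
    start = seq(0, by = 20000, length.out = 13),
    end = seq(2000, by = 20000, length.out = 13))
  matches <- tibble::tibble(
    chrom = "chrS", start = genes$start[1:10] - 3000, strand = "+",
    score = 10, motif = "hairy")
  res <- motif_gene_counts(genes, matches, window = 5000, motif_length = 6)
  expect_equal(res$summary$percent, 77)
  expect_equal(res$summary$n_with_match, 10)

  # 7 of 15 -> 47%
  genes15 <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:15), chrom = "chrS",
    start = seq(0, by = 20000, length.out = 15),
    end = seq(2000, by = 20000, length.out = 15))
  matches7 <- tibble::tibble(
    chrom = "chrS", start = genes15$start[1:7] - 100, strand = "-",
    score = 10, motif = "hairy")
  res15 <- motif_gene_counts(genes15, matches7, window = 5000,
                             motif_length = 6)
  expect_equal(res15$summary$percent, 47)

  # window 0 with a match just outside the gene is not counted
  g1 <- genes[1, ]
  just_out <- tibble::tibble(chrom = "chrS", start = g1$end + 1,
                             strand = "+", score = 10, motif = "hairy")
  res0 <- motif_gene_counts(g1, just_out, window = 0, motif_length = 6)
  expect_equal(res0$counts$n_matches, 0L)
  touching <- tibble::tibble(chrom = "chrS", start = g1$end - 3,
                             strand = "+", score = 10, motif = "hairy")
  expect_equal(motif_gene_counts(g1, touching, window = 0,
                                 motif_length = 6)$counts$n_matches, 1L)

  # widening the window never decreases any count
  set.seed(64)
  rnd <- tibble::tibble(chrom = "chrS",
                        start = sample(0:250000, 40), strand = "+",
                        score = 10, motif = "hairy")
  prev <- motif_gene_counts(genes, rnd, window = 0, motif_length = 6)$counts
  for (wn in c(1000, 5000, 10000)) {
    cur <- motif_gene_counts(genes, rnd, window = wn, motif_length = 6)$counts
    expect_true(all(cur$n_matches >= prev$n_matches))
    prev <- cur
  }
  expect_error(motif_gene_counts(genes[0, ], rnd, motif_length = 6),
               "non-empty")
})
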