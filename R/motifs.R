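
# PWM scanning and paired-site (SPS) detection -------------------------------

#' Build a position weight matrix from base counts
#'
#' Counts (or frequencies) per position are converted to probabilities with a
#' pseudocount and then to log-odds scores in bits against the supplied
#' background composition.
#'
#' @param counts 4 x L numeric matrix with rownames A, C, G, T (columns =
#'   motif positions), or an L x 4 data frame with those column names.
#' @param name Matrix name.
#' @param background Named background probabilities over A/C/G/T (sum 1).
#' @param pseudocount Added to every cell before normalization.
#' @return A `pwm` object: list with `name`, `mat` (4 x L log-odds in bits),
#'   `length`, `max_score`, `background`.
#' @export
pwm_build <- function(counts, name = "motif",
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      pseudocount = 0.5) {
  if (is.data.frame(counts)) counts <- t(as.matrix(counts[, c("A", "C", "G", "T")]))
  counts <- as.matrix(counts)
  assert_that(nrow(counts) == 4 && all(c("A", "C", "G", "T") %in% rownames(counts)),
              "counts must have rows A, C, G, T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  assert_that(abs(sum(background) - 1) < 1e-8, "background must sum to 1")
  probs <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  mat <- log2(probs / background[c("A", "C", "G", "T")])
  structure(
    list(name = name, mat = mat, length = ncol(mat),
         max_score = sum(apply(mat, 2, max)),
         background = background),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$name, ": length ", x$length,
      ", max score ", round(x$max_score, 2), " bits, consensus ",
      pwm_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a PWM (highest-scoring base per position)
#' @param pwm A [pwm_build()] object.
#' @return Character string.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$mat)[apply(pwm$mat, 2, which.max)], collapse = "")
}

#' Build a PWM that scores a consensus string exactly
#'
#' Convenience wrapper planting `n_obs` observations of the consensus; the
#' maximal score is then attained exactly at consensus occurrences.
#'
#' @param consensus Consensus string over A/C/G/T.
#' @inheritParams pwm_build
#' @param n_obs Pseudo-observation count per position.
#' @return A `pwm` object.
#' @export
pwm_from_consensus <- function(consensus, name = consensus,
                               background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                               n_obs = 100) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  assert_that(all(bases %in% c("A", "C", "G", "T")),
              "consensus must be over A/C/G/T")
  counts <- matrix(0, 4, length(bases),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(match(bases, rownames(counts)), seq_along(bases))] <- n_obs
  pwm_build(counts, name = name, background = background)
}

#' Read a position-frequency matrix from TSV
#'
#' Expects columns `A, C, G, T` (one row per motif position), the on-disk
#' format used for the shipped example matrices.
#'
#' @param path TSV file path.
#' @param name Matrix name (default: file stem).
#' @inheritParams pwm_build
#' @return A `pwm` object.
#' @export
read_pwm <- function(path, name = NULL,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                     pseudocount = 0.5) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  pwm_build(as.data.frame(tab),
            name = name %||% sub("\\.[^.]*$", "", basename(path)),
            background = background, pseudocount = pseudocount)
}

# encode a sequence as indices 1..4 (NA for anything else)
encode_seq <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
}

# windowed PWM scores along an encoded sequence; NA where a window has N
score_windows <- function(enc, mat) {
  w <- ncol(mat)
  n <- length(enc) - w + 1
  if (n < 1) return(numeric(0))
  scores <- numeric(n)
  ok <- !logical(n)
  for (j in seq_len(w)) {
    idx <- enc[j:(j + n - 1)]
    miss <- is.na(idx)
    ok <- ok & !miss
    idx[miss] <- 1L
    scores <- scores + mat[cbind(idx, j)]
  }
  scores[!ok] <- NA_real_
  scores
}

#' Scan a sequence with a PWM on both strands
#'
#' Every window of matrix length is scored as the sum of per-position
#' log-odds weights (bits); windows scoring at least `threshold` are
#' reported.  The reverse strand is scanned with the reverse-complement
#' matrix so all coordinates are on the forward axis (0-based start of the
#' matched window).  Windows containing N are skipped.
#'
#' @param seq Character string over A/C/G/T/N (or a `Biostrings::DNAString`).
#' @param pwm A `pwm` object.
#' @param threshold Score threshold in bits; default 60% of the maximal
#'   matrix score (high-affinity regime, config-exposed).
#' @param chrom Chromosome name recorded in the output.
#' @return Tibble `chrom, start, strand, score, motif`, sorted by start.
#' @export
scan_pwm <- function(seq, pwm, threshold = NULL, chrom = "chrS") {
  stopifnot(inherits(pwm, "pwm"))
  seq <- as.character(seq)
  threshold <- threshold %||% (0.6 * pwm$max_score)
  assert_that(threshold <= pwm$max_score + 1e-9,
              "threshold exceeds the maximal achievable score")
  enc <- encode_seq(seq)
  if (length(enc) < pwm$length) {
    return(tibble(chrom = character(), start = integer(), strand = character(),
                  score = numeric(), motif = character()))
  }
  # reverse strand on the forward axis: reverse-complemented matrix
  mat_rc <- pwm$mat[c("T", "G", "C", "A"), rev(seq_len(pwm$length)), drop = FALSE]
  rownames(mat_rc) <- c("A", "C", "G", "T")
  fwd <- score_windows(enc, pwm$mat)
  rev_ <- score_windows(enc, mat_rc)
  hit_f <- which(!is.na(fwd) & fwd >= threshold)
  hit_r <- which(!is.na(rev_) & rev_ >= threshold)
  bind_rows(
    tibble(chrom = chrom, start = hit_f - 1L, strand = "+",
           score = fwd[hit_f], motif = pwm$name),
    tibble(chrom = chrom, start = hit_r - 1L, strand = "-",
           score = rev_[hit_r], motif = pwm$name)
  ) %>% arrange(.data$start, .data$strand)
}

#' Find paired-site (SPS) arrangements
#'
#' Reports every pair of matches on opposite strands whose inter-site gap
#' (bases between the end of the left match and the start of the right
#' match) lies in `[gap_min, gap_max]` inclusive.  Both head-to-head and
#' tail-to-tail orientations qualify; overlapping pairs are reported
#' independently.
#'
#' @param matches Match tibble from [scan_pwm()] (one chromosome, one
#'   matrix).
#' @param motif_length Motif length in bp; inferred from a `width` column or
#'   required explicitly.
#' @param gap_min,gap_max Inclusive gap bounds in nt.
#' @return Tibble `chrom, left_start, left_strand, right_start, right_strand,
#'   gap, orientation` (orientation `head_to_head` when the left site points
#'   right, i.e. `+/-`, else `tail_to_tail`).
#' @export
find_sps <- function(matches, motif_length = NULL, gap_min = 10, gap_max = 22) {
  if (nrow(matches) < 2) {
    return(tibble(chrom = character(), left_start = integer(),
                  left_strand = character(), right_start = integer(),
                  right_strand = character(), gap = integer(),
                  orientation = character()))
  }
  assert_that(length(unique(matches$chrom)) == 1,
              "matches must come from one chromosome")
  assert_that(length(unique(matches$motif)) <= 1,
              "matches must come from one matrix")
  w <- motif_length %||% matches$width[1]
  assert_that(!is.null(w) && is.finite(w), "motif_length required")
  m <- arrange(matches, .data$start)
  pairs <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(nrow(m))) %>%
    filter(.data$i < .data$j) %>%
    mutate(
      gap = m$start[.data$j] - (m$start[.data$i] + w),
      opposite = m$strand[.data$i] != m$strand[.data$j]
    ) %>%
    filter(.data$opposite, .data$gap >= gap_min, .data$gap <= gap_max)
  tibble(
    chrom = m$chrom[pairs$i],
    left_start = m$start[pairs$i],
    left_strand = m$strand[pairs$i],
    right_start = m$start[pairs$j],
    right_strand = m$strand[pairs$j],
    gap = as.integer(pairs$gap),
    orientation = ifelse(m$strand[pairs$i] == "+", "head_to_head",
                         "tail_to_tail")
  )
}

#' Count motif matches near genes and the fraction of genes with a match
#'
#' Per gene, counts matches whose minimum distance to the transcription unit
#' (the gene's transcript extent) is at most `window`; the gene-set summary
#' is the percentage of genes with at least one match, rounded to the
#' nearest integer (the convention in which 10 of 13 genes reads as 77%).
#'
#' @param genes Gene models tibble (`gene_id, chrom, start, end`).
#' @param matches Match tibble from [scan_pwm()].
#' @param window Association window in bp.
#' @param motif_length Motif length in bp (to form match intervals); inferred
#'   from a `width` column when present.
#' @return List with `counts` (tibble `gene_id, n_matches`) and `summary`
#'   (tibble `n_genes, n_with_match, percent`).
#' @export
motif_gene_counts <- function(genes, matches, window = 5000,
                              motif_length = NULL) {
  assert_that(nrow(genes) > 0, "gene set must be non-empty")
  gene_ext <- genes %>%
    group_by(.data$gene_id, .data$chrom) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  if (nrow(matches) == 0) {
    counts <- mutate(gene_ext, n_matches = 0L)
  } else {
    w <- motif_length %||% matches$width[1]
    assert_that(!is.null(w) && is.finite(w), "motif_length required")
    hits <- inner_join(gene_ext,
                       matches %>%
                         mutate(m_start = .data$start,
                                m_end = .data$start + w) %>%
                         select("chrom", "m_start", "m_end"),
                       by = "chrom", relationship = "many-to-many") %>%
      mutate(distance = min_distance(.data$start, .data$end,
                                     .data$m_start, .data$m_end)) %>%
      filter(.data$distance <= window) %>%
      count(.data$gene_id, name = "n_matches")
    counts <- left_join(gene_ext, hits, by = "gene_id") %>%
      mutate(n_matches = as.integer(replace_na(.data$n_matches, 0L)))
  }
  counts <- select(counts, "gene_id", "n_matches")
  list(
    counts = counts,
    summary = tibble(
      n_genes = nrow(counts),
      n_with_match = sum(counts$n_matches >= 1),
      percent = round(100 * sum(counts$n_matches >= 1) / nrow(counts))
    )
  )
}
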