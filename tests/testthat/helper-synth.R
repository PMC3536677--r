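# shared fixtures, all generated in code

# small config with three well-separated response clusters
sep3_config <- function(n_per = 20, seed = 11) {
  synth_config(
    n_genes = 3 * n_per,
    cluster_spec = tibble::tibble(
      shape = c("early_up", "late_up", "down"),
      amplitude = c(3, 2.5, 2.5),
      n = rep(n_per, 3)
    ),
    sigma_c = 0.1, sigma_t = 0.05, sigma_r = 0.15,
    seed = seed
  )
}

# a probe track tibble from a plain score vector (one time, one rep)
track_from_scores <- function(scores, spacing = 50, time = 0, rep = 1) {
  tibble::tibble(
    chrom = "chrS",
    pos = seq(spacing %/% 2, by = spacing, length.out = length(scores)),
    time = time, rep = rep,
    score = scores
  )
}

# independent reference peak caller: plain loop over probes
oracle_call_peaks <- function(scores, threshold, min_run, merge_gap) {
  enriched <- scores >= threshold
  peaks <- list()
  i <- 1
  n <- length(scores)
  while (i <= n) {
    if (enriched[i]) {
      first <- i
      last <- i
      gap <- 0
      j <- i + 1
      while (j <= n) {
        if (enriched[j]) {
          last <- j
          gap <- 0
        } else {
          gap <- gap + 1
          if (gap > merge_gap) break
        }
        j <- j + 1
      }
      if (sum(enriched[first:last]) >= min_run) {
        peaks[[length(peaks) + 1]] <- c(first = first, last = last)
      }
      i <- last + gap + 1
    } else {
      i <- i + 1
    }
  }
  peaks
}

# independent PWM rescoring: per-window loop, both strands
oracle_scan <- function(seq, mat, threshold) {
  bases <- strsplit(seq, "")[[1]]
  w <- ncol(mat)
  rc_map <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- list()
  for (s in seq_len(length(bases) - w + 1)) {
    win <- bases[s:(s + w - 1)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    fw <- sum(mat[cbind(match(win, rownames(mat)), seq_len(w))])
    rv <- sum(mat[cbind(match(unname(rc_map[rev(win)]), rownames(mat)),
                        seq_len(w))])
    if (fw >= threshold) {
      hits[[length(hits) + 1]] <-
        tibble::tibble(start = s - 1L, strand = "+", score = fw)
    }
    if (rv >= threshold) {
      hits[[length(hits) + 1]] <-
        tibble::tibble(start = s - 1L, strand = "-", score = rv)
    }
  }
  dplyr::bind_rows(hits)
}

# draw one CRP partition size count (independent prior oracle)
oracle_crp_k <- function(alpha, n) {
  sizes <- integer()
  for (i in seq_len(n)) {
    p <- c(sizes, alpha)
    k <- sample.int(length(p), 1, prob = p)
    if (k > length(sizes)) sizes <- c(sizes, 1L) else sizes[k] <- sizes[k] + 1L
  }
  length(sizes)
}
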