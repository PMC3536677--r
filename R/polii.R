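
# Pol II state classification ------------------------------------------------
#
# Four states per transcript per timepoint, from promoter / gene-body binding
# and a pausing ratio:
#   UB  unbound            - no Pol II at promoter or body
#   P   poised             - promoter-proximal binding only
#   AP  active poised      - promoter peak plus body binding, ratio >= cutoff
#   AU  active uniform     - body binding with ratio < cutoff
# The pausing ratio is taken on log2 enrichment values as printed on the
# arrays: max log2 enrichment in the promoter window divided by the median
# log2 enrichment over the gene body, the latter floored to avoid division
# blow-up on unbound bodies.

# promoter/body probe values for one transcript at one timepoint
polii_region_values <- function(track, transcript, promoter_window, time) {
  assert_cols(track, c("chrom", "pos", "score"), "track")
  sub <- filter(track, .data$chrom == transcript$chrom)
  if (!is.null(time)) sub <- filter(sub, .data$time == time)
  if ("rep" %in% names(sub)) {
    sub <- sub %>%
      group_by(.data$pos) %>%
      summarise(score = mean(.data$score), .groups = "drop")
  }
  sub <- arrange(sub, .data$pos)
  tss <- transcript$tss %||%
    if (transcript$strand == "+") transcript$start else transcript$end
  prom <- c(tss - promoter_window, tss + promoter_window)
  if (transcript$strand == "+") {
    body <- c(min(prom[2], transcript$end), transcript$end)
  } else {
    body <- c(transcript$start, max(prom[1], transcript$start))
  }
  in_prom <- sub$pos >= prom[1] & sub$pos < prom[2]
  in_body <- sub$pos >= body[1] & sub$pos < body[2] & !in_prom
  list(pos = sub$pos, score = sub$score,
       prom = sub$score[in_prom], body = sub$score[in_body],
       prom_idx = which(in_prom), body_idx = which(in_body),
       spacing = if (length(sub$pos) > 1) median(diff(sub$pos)) else 1)
}

ratio_from_vals <- function(vals, floor, body_only) {
  if (length(vals$prom) == 0) return(NA_real_)
  body_vals <- if (body_only) vals$body else c(vals$prom, vals$body)
  if (length(body_vals) == 0) body_vals <- 0
  max(vals$prom) / max(median(body_vals), floor)
}

classify_from_vals <- function(vals, floor, threshold, min_run, ratio_cutoff,
                               body_only) {
  region_bound <- function(idx) {
    if (length(idx) == 0) return(FALSE)
    run_exists(vals$score[idx], threshold, min(min_run, length(idx)),
               merge_gap = 2)
  }
  promoter_bound <- region_bound(vals$prom_idx)
  body_bound <- region_bound(vals$body_idx)
  ratio <- ratio_from_vals(vals, floor, body_only)

  state <- if (!promoter_bound && !body_bound) {
    "UB"
  } else if (promoter_bound && !body_bound) {
    "P"
  } else if (body_bound && !promoter_bound) {
    "AU"
  } else if (!is.na(ratio) && ratio >= ratio_cutoff) {
    "AP"
  } else {
    "AU"
  }
  list(state = state, ratio = ratio,
       promoter_bound = promoter_bound, body_bound = body_bound)
}

#' Pausing ratio of a transcript
#'
#' `ratio = max(log2 enrichment in [TSS - w, TSS + w]) / max(median(log2
#' enrichment over the body), floor)`, strand-aware.  The ratio is of log2
#' values (not linear fold changes) and the body median is floored at
#' `floor`; both are deliberate conventions documented here because they set
#' the scale of the AP/AU cutoff.
#'
#' @param track Probe track tibble (`chrom, pos, score`, optionally `time`
#'   and `rep`; replicates are averaged).
#' @param transcript One-row tibble/list with `chrom, start, end, strand`
#'   (0-based half-open) and optionally `tss`.
#' @param promoter_window Half-width of the promoter window around the TSS
#'   (bp).
#' @param floor Minimum body median used as denominator (log2 units).
#' @param time Timepoint to use when the track has several.
#' @param body_only If `TRUE` (default) the median is over the body
#'   (promoter window excluded); if `FALSE`, over the whole transcript.
#' @return The pausing ratio, or `NA` when no probes fall in the promoter
#'   window (the state is then decided from the binding flags alone).
#' @export
pausing_ratio <- function(track, transcript, promoter_window = 500,
                          floor = 0.25, time = NULL, body_only = TRUE) {
  vals <- polii_region_values(track, transcript, promoter_window, time)
  ratio_from_vals(vals, floor, body_only)
}

#' Classify one transcript's Pol II state at one timepoint
#'
#' Promoter-bound and body-bound flags use the same run-length logic as
#' [call_peaks()], restricted to the promoter window and the gene body (a
#' region holding fewer than `min_run` probes uses the probes it has); the
#' state then follows the class definitions, with [pausing_ratio()]
#' separating AP from AU at `ratio_cutoff`.
#'
#' @inheritParams pausing_ratio
#' @param threshold,min_run Run-length calling parameters within each region.
#' @param ratio_cutoff AP/AU pausing-ratio cutoff.
#' @return Tibble row: `state, ratio, promoter_bound, body_bound`.
#' @export
classify_polii_transcript <- function(track, transcript,
                                      promoter_window = 500, floor = 0.25,
                                      threshold = 1, min_run = 4,
                                      ratio_cutoff = 2, time = NULL,
                                      body_only = TRUE) {
  vals <- polii_region_values(track, transcript, promoter_window, time)
  assert_that(length(vals$pos) > 0, "transcript lies outside the track")
  as_tibble(classify_from_vals(vals, floor, threshold, min_run, ratio_cutoff,
                               body_only))
}

#' Classify all transcripts at all timepoints
#'
#' @param track Pol II probe track (`chrom, pos, time, rep, score`).
#' @param transcripts Gene-model tibble (`gene_id, transcript_id, chrom,
#'   start, end, strand, tss`).
#' @param promoter_window,floor,threshold,min_run,ratio_cutoff,body_only As
#'   in [classify_polii_transcript()].
#' @return Tibble `gene_id, transcript_id, time, state, ratio,
#'   promoter_bound, body_bound`.
#' @export
classify_polii <- function(track, transcripts, promoter_window = 500,
                           floor = 0.25, threshold = 1, min_run = 4,
                           ratio_cutoff = 2, body_only = TRUE) {
  assert_cols(transcripts, c("gene_id", "transcript_id", "chrom", "start",
                             "end", "strand"), "transcripts")
  avg <- track %>%
    group_by(.data$chrom, .data$time, .data$pos) %>%
    summarise(score = mean(.data$score), .groups = "drop") %>%
    arrange(.data$time, .data$chrom, .data$pos)
  by_time <- split(avg, avg$time)

  tx_tss <- transcripts$tss %||%
    ifelse(transcripts$strand == "+", transcripts$start, transcripts$end)

  out <- purrr::imap(by_time, function(sub, tp) {
    n_tx <- nrow(transcripts)
    state <- character(n_tx); ratio <- numeric(n_tx)
    pb <- logical(n_tx); bb <- logical(n_tx)
    # per chromosome, sorted probe vectors; transcripts slice by findInterval
    for (chr in unique(transcripts$chrom)) {
      cpos <- sub$pos[sub$chrom == chr]
      cscore <- sub$score[sub$chrom == chr]
      spacing <- if (length(cpos) > 1) median(diff(cpos)) else 1
      for (i in which(transcripts$chrom == chr)) {
        tss <- tx_tss[i]
        prom <- c(tss - promoter_window, tss + promoter_window)
        if (transcripts$strand[i] == "+") {
          body <- c(min(prom[2], transcripts$end[i]), transcripts$end[i])
        } else {
          body <- c(transcripts$start[i], max(prom[1], transcripts$start[i]))
        }
        lo <- min(prom[1], body[1]); hi <- max(prom[2], body[2])
        i0 <- findInterval(lo - 1e-9, cpos) + 1
        i1 <- findInterval(hi - 1e-9, cpos)
        pos_w <- cpos[seq2(i0, i1)]
        sc_w <- cscore[seq2(i0, i1)]
        in_prom <- pos_w >= prom[1] & pos_w < prom[2]
        in_body <- pos_w >= body[1] & pos_w < body[2] & !in_prom
        vals <- list(pos = pos_w, score = sc_w,
                     prom = sc_w[in_prom], body = sc_w[in_body],
                     prom_idx = which(in_prom), body_idx = which(in_body),
                     spacing = spacing)
        cl <- classify_from_vals(vals, floor, threshold, min_run,
                                 ratio_cutoff, body_only)
        state[i] <- cl$state; ratio[i] <- cl$ratio
        pb[i] <- cl$promoter_bound; bb[i] <- cl$body_bound
      }
    }
    tibble(gene_id = transcripts$gene_id,
           transcript_id = transcripts$transcript_id,
           time = as.numeric(tp), state = state, ratio = ratio,
           promoter_bound = pb, body_bound = bb)
  })
  bind_rows(out)
}

seq2 <- function(from, to) if (to < from) integer() else seq.int(from, to)

#' Aggregate transcript states to a gene state
#'
#' When the transcripts of a gene carry different Pol II states the gene
#' takes the highest-precedence state under `AU > AP > P > UB`.
#'
#' @param states Character vector of transcript states (subset of
#'   `UB, P, AP, AU`), non-empty.
#' @return A single state.
#' @export
gene_state <- function(states) {
  assert_that(length(states) > 0, "need at least one transcript state")
  precedence <- c("AU", "AP", "P", "UB")
  assert_that(all(states %in% precedence), "unknown Pol II state")
  precedence[min(match(states, precedence))]
}

#' Gene-level Pol II states per timepoint
#'
#' @param transcript_states Output of [classify_polii()].
#' @return Tibble `gene_id, time, state` with precedence-aggregated states.
#' @export
gene_polii_states <- function(transcript_states) {
  assert_cols(transcript_states, c("gene_id", "time", "state"),
              "transcript_states")
  transcript_states %>%
    group_by(.data$gene_id, .data$time) %>%
    summarise(state = gene_state(.data$state), .groups = "drop")
}
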