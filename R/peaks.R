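
# Tiling-array peak calling --------------------------------------------------

#' Call enrichment peaks on a probe-level track
#'
#' Implements the run-length rule for tiling arrays: after averaging
#' replicates per probe, maximal runs of consecutive probes with enrichment
#' at or above `threshold` are found per timepoint; runs separated by at most
#' `merge_gap` sub-threshold probes are merged; merged runs containing at
#' least `min_run` enriched probes become peaks.  Peak boundaries span the
#' first to last enriched probe extended by half the probe spacing on each
#' side (0-based half-open).  The call thus combines the magnitude of the
#' enrichment with the number of consecutive enriched probes.
#'
#' @param track Tibble `chrom, pos, time, rep, score` (positions 0-based
#'   probe midpoints, strictly increasing within chromosome).
#' @param threshold Log2 enrichment threshold.
#' @param min_run Minimum number of enriched probes per peak.
#' @param merge_gap Maximum number of consecutive sub-threshold probes
#'   bridged when merging runs.
#' @param combine How replicate values are combined per probe: `"mean"`
#'   (default) or `"min"` (stringent).
#' @param spacing Probe spacing in bp; inferred from the median position
#'   difference when `NULL`.
#' @return Tibble of peaks: `chrom, start, end, time, summit, max, area,
#'   n_probes`, sorted by time then start.  Empty tibble when nothing passes.
#' @export
call_peaks <- function(track, threshold = 1, min_run = 4, merge_gap = 2,
                       combine = c("mean", "min"), spacing = NULL) {
  assert_cols(track, c("chrom", "pos", "time", "rep", "score"), "track")
  assert_that(min_run >= 1, "min_run must be at least 1")
  combine <- match.arg(combine)
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  time = numeric(), summit = numeric(), max = numeric(),
                  area = numeric(), n_probes = integer())
  if (nrow(track) == 0) return(empty)

  comb_fun <- if (combine == "mean") mean else min
  avg <- track %>%
    group_by(.data$chrom, .data$time, .data$pos) %>%
    summarise(score = comb_fun(.data$score), .groups = "drop") %>%
    arrange(.data$chrom, .data$time, .data$pos)

  out <- avg %>%
    group_by(.data$chrom, .data$time) %>%
    dplyr::group_modify(function(df, key) {
      assert_that(all(diff(df$pos) > 0), "probe positions must be sorted")
      sp <- spacing %||% median(diff(df$pos))
      call_peaks_1d(df$pos, df$score, threshold, min_run, merge_gap, sp)
    }) %>%
    ungroup()
  if (nrow(out) == 0) empty else
    arrange(out, .data$time, .data$chrom, .data$start)
}

# does any merged run of >= min_run enriched probes exist? (flag-only fast
# path of call_peaks_1d)
run_exists <- function(score, threshold, min_run, merge_gap) {
  enriched <- score >= threshold
  if (sum(enriched) < min_run) return(FALSE)
  r <- rle(enriched)
  runs <- which(r$values)
  group <- seq_along(runs)
  if (length(runs) > 1) {
    for (i in 2:length(runs)) {
      between <- sum(r$lengths[(runs[i - 1] + 1):(runs[i] - 1)])
      if (between <= merge_gap) group[i] <- group[i - 1]
    }
  }
  counts <- vapply(split(r$lengths[runs], group), sum, numeric(1))
  any(counts >= min_run)
}

# single-track core: positions sorted, one value per probe
call_peaks_1d <- function(pos, score, threshold, min_run, merge_gap, spacing) {
  enriched <- score >= threshold
  if (!any(enriched)) {
    return(tibble(start = numeric(), end = numeric(), summit = numeric(),
                  max = numeric(), area = numeric(), n_probes = integer()))
  }
  r <- rle(enriched)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  runs <- which(r$values)
  # merge enriched runs separated by short sub-threshold runs
  group <- seq_along(runs)
  if (length(runs) > 1) {
    for (i in 2:length(runs)) {
      between <- sum(r$lengths[(runs[i - 1] + 1):(runs[i] - 1)])
      if (between <= merge_gap) group[i] <- group[i - 1]
    }
  }
  peaks <- purrr::map(split(runs, group), function(rs) {
    probe_idx <- which(run_id %in% rs & enriched)
    if (length(probe_idx) < min_run) return(NULL)
    span <- range(pos[probe_idx])
    inside <- seq(min(probe_idx), max(probe_idx))
    tibble(
      start = span[1] - spacing / 2,
      end = span[2] + spacing / 2,
      summit = pos[inside][which.max(score[inside])],
      max = max(score[inside]),
      area = sum(pmax(score[inside], 0)) * spacing,
      n_probes = length(probe_idx)
    )
  })
  bind_rows(peaks)
}

#' Area under a peak on a probe track
#'
#' Rectangle-rule quadrature of the (non-negative part of the) enrichment
#' over probes falling inside the peak interval: `sum(max(score, 0)) *
#' spacing`.  Replicates are averaged per probe first.
#'
#' @param track Probe track tibble (`chrom, pos, time, rep, score`); only the
#'   peak's timepoint is used when the track carries several.
#' @param peak One-row tibble or list with `chrom, start, end, time`.
#' @param spacing Probe spacing (bp); inferred when `NULL`.
#' @return Area in log2-enrichment x bp units.
#' @export
peak_area <- function(track, peak, spacing = NULL) {
  assert_cols(track, c("chrom", "pos", "time", "rep", "score"), "track")
  sub <- track %>%
    filter(.data$chrom == peak$chrom, .data$time == peak$time) %>%
    group_by(.data$pos) %>%
    summarise(score = mean(.data$score), .groups = "drop") %>%
    arrange(.data$pos)
  assert_that(nrow(sub) > 0 &&
                peak$start >= min(sub$pos) - (spacing %||% median(diff(sub$pos))) &&
                peak$end <= max(sub$pos) + (spacing %||% median(diff(sub$pos))),
              "peak lies outside the track extent")
  sp <- spacing %||% median(diff(sub$pos))
  inside <- sub$pos >= peak$start & sub$pos < peak$end
  sum(pmax(sub$score[inside], 0)) * sp
}

#' Peak-area timecourse over matched peak regions
#'
#' Peaks called at individual timepoints are matched across time by
#' any-overlap union intervals; the enrichment area of every union region is
#' then quantified at every timepoint (whether or not a peak was called
#' there), giving the binding-dynamics profile of each region.
#'
#' @param track Probe track (`chrom, pos, time, rep, score`).
#' @param peaks Peak set from [call_peaks()].
#' @return Tibble `region, chrom, start, end, time, area`.
#' @export
peak_area_timecourse <- function(track, peaks) {
  if (nrow(peaks) == 0) {
    return(tibble(region = integer(), chrom = character(), start = numeric(),
                  end = numeric(), time = numeric(), area = numeric()))
  }
  gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end))
  red <- GenomicRanges::reduce(gr)
  regions <- tibble(
    region = seq_along(red),
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1,
    end = as.numeric(GenomicRanges::end(red))
  )
  # cumulative sums per (chrom, time) make region areas O(1) each
  avg <- track %>%
    group_by(.data$chrom, .data$time, .data$pos) %>%
    summarise(score = mean(.data$score), .groups = "drop") %>%
    arrange(.data$chrom, .data$time, .data$pos)
  out <- avg %>%
    group_by(.data$chrom, .data$time) %>%
    dplyr::group_modify(function(df, key) {
      sp <- median(diff(df$pos))
      cs <- c(0, cumsum(pmax(df$score, 0)))
      reg <- regions[regions$chrom == key$chrom, ]
      lo <- findInterval(reg$start - 1e-9, df$pos) + 1   # first pos >= start
      hi <- findInterval(reg$end - 1e-9, df$pos)         # last pos < end
      tibble(region = reg$region, start = reg$start, end = reg$end,
             area = pmax(cs[hi + 1] - cs[lo], 0) * sp)
    }) %>%
    ungroup()
  select(out, "region", "chrom", "start", "end", "time", "area")
}

#' Plot peak-area timecourses
#'
#' @param areas Output of [peak_area_timecourse()].
#' @return A ggplot object.
#' @export
plot_peak_areas <- function(areas) {
  ggplot2::ggplot(areas, ggplot2::aes(x = .data$time, y = .data$area,
                                      group = .data$region)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "time (min)", y = "peak area (log2 enrichment x bp)",
                  title = "Binding dynamics of peak regions") +
    ggplot2::theme_minimal()
}
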