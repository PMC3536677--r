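
# Two-colour normalization and timecourse differential expression ------------

#' Compute M and A values from raw two-colour intensities
#'
#' The standard transform for two-colour spots: `M = log2(treated) -
#' log2(reference)` and `A = (log2 treated + log2 reference) / 2`.  Spots with
#' a non-positive intensity in either channel cannot be log-transformed and
#' are dropped with a message reporting the count.
#'
#' @param raw Tibble with columns `spot, transcript_id, time, rep,
#'   ch_treated, ch_reference`.
#' @return The input with spots filtered and columns `M` and `A` added.
#' @export
compute_ma <- function(raw) {
  assert_cols(raw, c("spot", "transcript_id", "time", "rep",
                     "ch_treated", "ch_reference"), "raw")
  bad <- raw$ch_treated <= 0 | raw$ch_reference <= 0 |
    !is.finite(raw$ch_treated) | !is.finite(raw$ch_reference)
  if (any(bad)) {
    inform(paste0("dropping ", sum(bad), " spot(s) with non-positive intensity"))
    raw <- raw[!bad, , drop = FALSE]
  }
  mutate(raw,
         M = log2(.data$ch_treated) - log2(.data$ch_reference),
         A = (log2(.data$ch_treated) + log2(.data$ch_reference)) / 2)
}

#' Within-array intensity-dependent normalization
#'
#' Removes intensity-dependent dye trends per array by centring M on a local
#' regression of M against A (loess), then subtracting the residual median so
#' every array has median M of exactly 0.  Arrays are the (time, rep)
#' combinations.  When A carries no information (all values identical) the
#' array falls back to global median centring, with a message.
#'
#' @param ma Tibble from [compute_ma()] (needs `M`, `A`, `time`, `rep`).
#' @param span Loess span (fraction of spots in each local window).
#' @return Input tibble with `M` replaced by the normalized value and the raw
#'   value kept as `M_raw`.
#' @export
normalize_ma <- function(ma, span = 0.4) {
  assert_cols(ma, c("M", "A", "time", "rep"), "ma")
  norm_one <- function(df) {
    assert_that(nrow(df) >= 50,
                "need at least 50 spots per array for loess normalization")
    if (diff(range(df$A)) < .Machine$double.eps^0.5) {
      inform("array has constant A; falling back to global median centring")
      trend <- rep(median(df$M), nrow(df))
    } else {
      fit <- loess(M ~ A, data = df, span = span, degree = 1,
                   family = "symmetric")
      trend <- predict(fit, df$A)
    }
    m <- df$M - trend
    df$M_raw <- df$M
    df$M <- m - median(m)
    df
  }
  ma %>%
    group_by(.data$time, .data$rep) %>%
    dplyr::group_modify(~ norm_one(.x)) %>%
    ungroup()
}

#' Collapse spot-level M values to a transcript timecourse matrix
#'
#' @param ma Normalized tibble with `transcript_id, time, rep, M`.
#' @return Tibble `transcript_id, time, rep, M` (one row per cell) plus
#'   `median_M` per (transcript, time) across replicates.
#' @export
tc_matrix <- function(ma) {
  assert_cols(ma, c("transcript_id", "time", "rep", "M"), "ma")
  ma %>%
    group_by(.data$transcript_id, .data$time, .data$rep) %>%
    summarise(M = mean(.data$M), .groups = "drop") %>%
    group_by(.data$transcript_id, .data$time) %>%
    mutate(median_M = median(.data$M)) %>%
    ungroup()
}

#' Spline F-test for differential expression over a timecourse
#'
#' For each transcript, all replicate M values are regressed on a natural
#' cubic spline basis of time (`spline_df` degrees of freedom) and compared
#' with an intercept-only null by an F test; this detects any smooth temporal
#' structure without specifying its shape, the strategy of timecourse DE
#' tools built on spline bases.  P-values come from the F reference
#' distribution, or optionally from a permutation null that shuffles time
#' labels within each replicate.  Q-values are Benjamini-Hochberg, and
#' transcripts are ranked by p-value.
#'
#' @param tc Tibble `transcript_id, time, rep, M` (missing cells allowed;
#'   complete cases are used per transcript).
#' @param spline_df Spline degrees of freedom; must be below the number of
#'   distinct timepoints.
#' @param n_null Number of permutations for the permutation null (0 = use the
#'   parametric F distribution).
#' @param seed Seed for the permutation null (required when `n_null > 0`).
#' @return Tibble `transcript_id, F, df1, df2, p, q, rank` sorted by rank.
#' @export
timecourse_de <- function(tc, spline_df = 4, n_null = 0, seed = NULL) {
  assert_cols(tc, c("transcript_id", "time", "rep", "M"), "tc")
  tc <- filter(tc, !is.na(.data$M))
  times <- sort(unique(tc$time))
  assert_that(length(times) >= 4, "need at least 4 distinct timepoints")
  assert_that(spline_df < length(times),
              "spline_df must be smaller than the number of timepoints")
  if (n_null > 0) assert_that(!is.null(seed), "seed required for permutation null")

  basis <- splines::ns(times, df = spline_df)

  # fast path: transcripts observed on the full (time, rep) grid share one
  # design matrix, so F statistics reduce to two projections
  grid <- tc %>% count(.data$transcript_id) %>% rename(n_obs = "n")
  full_n <- length(times) * length(unique(tc$rep))

  fstat_matrix <- function(mat, time_vec) {
    # mat: n_obs x n_tx response matrix on a shared time vector
    X <- cbind(1, splines::ns(time_vec, knots = attr(basis, "knots"),
                              Boundary.knots = attr(basis, "Boundary.knots")))
    qrX <- qr(X)
    fit <- qr.fitted(qrX, mat)
    res1 <- mat - fit
    rss1 <- colSums(res1^2)
    res0 <- sweep(mat, 2, colMeans(mat))
    rss0 <- colSums(res0^2)
    df1 <- ncol(X) - 1
    df2 <- nrow(mat) - ncol(X)
    f <- ((rss0 - rss1) / df1) / (rss1 / df2)
    list(F = f, df1 = df1, df2 = df2)
  }

  complete_ids <- grid$transcript_id[grid$n_obs == full_n]
  res <- list()
  if (length(complete_ids) > 0) {
    wide <- tc %>%
      filter(.data$transcript_id %in% complete_ids) %>%
      arrange(.data$transcript_id, .data$time, .data$rep)
    n_tx <- length(complete_ids)
    mat <- matrix(wide$M, nrow = full_n, ncol = n_tx)
    tvec <- wide$time[seq_len(full_n)]
    fs <- fstat_matrix(mat, tvec)
    res[["complete"]] <- tibble(
      transcript_id = sort(complete_ids),
      F = fs$F, df1 = fs$df1, df2 = fs$df2
    )
    if (n_null > 0) {
      set.seed(as.integer(seed))
      reps <- wide$rep[seq_len(full_n)]
      exceed <- rep(0, n_tx)
      rep_groups <- split(seq_len(full_n), reps)
      for (b in seq_len(n_null)) {
        perm <- seq_len(full_n)
        for (g in rep_groups) perm[g] <- sample(g)
        fsb <- fstat_matrix(mat[perm, , drop = FALSE], tvec)
        exceed <- exceed + (fsb$F >= fs$F)
      }
      res[["complete"]]$p_perm <- (1 + exceed) / (1 + n_null)
    }
  }
  partial_ids <- grid$transcript_id[grid$n_obs != full_n]
  if (length(partial_ids) > 0) {
    res[["partial"]] <- tc %>%
      filter(.data$transcript_id %in% partial_ids) %>%
      group_by(.data$transcript_id) %>%
      dplyr::group_modify(function(df, key) {
        if (nrow(df) <= spline_df + 2 || length(unique(df$time)) <= spline_df) {
          return(tibble(F = NA_real_, df1 = NA_real_, df2 = NA_real_))
        }
        X <- splines::ns(df$time, knots = attr(basis, "knots"),
                         Boundary.knots = attr(basis, "Boundary.knots"))
        fit1 <- lm(df$M ~ X)
        fit0 <- lm(df$M ~ 1)
        a <- anova(fit0, fit1)
        tibble(F = a$F[2], df1 = a$Df[2], df2 = fit1$df.residual)
      }) %>%
      ungroup()
  }
  out <- bind_rows(res)
  out$p <- pf(out$F, out$df1, out$df2, lower.tail = FALSE)
  if (n_null > 0 && "p_perm" %in% names(out)) {
    out$p_parametric <- out$p
    out$p <- ifelse(is.na(out$p_perm), out$p, out$p_perm)
  }
  out$q <- p.adjust(out$p, method = "BH")
  out <- arrange(out, .data$p)
  out$rank <- rank(out$p, ties.method = "first")
  out
}

#' Basal absolute-expression proxy from t = 0 intensities
#'
#' Approximates absolute RNA abundance, up to a constant, by the mean over
#' replicates of the log2 reference-channel spot intensity at time zero.
#'
#' @param raw Raw spot tibble (as for [compute_ma()]).
#' @return Tibble `transcript_id, logc0` (transcripts absent at t = 0 are
#'   simply absent from the output).
#' @export
compute_logc0 <- function(raw) {
  assert_cols(raw, c("transcript_id", "time", "rep", "ch_reference"), "raw")
  raw %>%
    filter(.data$time == 0, .data$ch_reference > 0) %>%
    group_by(.data$transcript_id) %>%
    summarise(logc0 = mean(log2(.data$ch_reference)), .groups = "drop")
}
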