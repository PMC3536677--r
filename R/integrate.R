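
# Peak-gene association, DE-odds modelling, master table ---------------------

#' Minimum distance between two intervals on one chromosome
#'
#' 0 when the half-open intervals overlap, otherwise the gap between the
#' nearest ends.  Vectorized over rows.
#'
#' @param a_start,a_end,b_start,b_end Interval coordinates (0-based
#'   half-open).
#' @return Non-negative distances in bp.
#' @export
min_distance <- function(a_start, a_end, b_start, b_end) {
  interval_gap(a_start, a_end, b_start, b_end)
}

#' Associate peaks with genes by minimum distance
#'
#' One row per (gene, peak) pair within `max_distance` of any transcript of
#' the gene; the distance reported is the minimum over the gene's
#' transcripts, with 0 meaning the peak overlaps a transcript.
#'
#' @param genes Gene models (`gene_id, transcript_id, chrom, start, end`).
#' @param peaks Peak set (`chrom, start, end, time`, plus anything else).
#' @param max_distance Maximum association distance in bp (`Inf` keeps all
#'   same-chromosome pairs).
#' @return Tibble `gene_id, transcript_id, peak_id, time, distance`.
#' @export
associate_peaks <- function(genes, peaks, max_distance = Inf) {
  assert_cols(genes, c("gene_id", "transcript_id", "chrom", "start", "end"),
              "genes")
  if (nrow(peaks) == 0) {
    return(tibble(gene_id = character(), transcript_id = character(),
                  peak_id = integer(), time = numeric(), distance = numeric()))
  }
  peaks <- mutate(peaks, peak_id = row_number())
  pairs <- inner_join(
    select(genes, "gene_id", "transcript_id", "chrom",
           tx_start = "start", tx_end = "end"),
    select(peaks, "chrom", "peak_id", "time",
           pk_start = "start", pk_end = "end"),
    by = "chrom", relationship = "many-to-many"
  ) %>%
    mutate(distance = min_distance(.data$tx_start, .data$tx_end,
                                   .data$pk_start, .data$pk_end)) %>%
    filter(.data$distance <= max_distance)
  select(pairs, "gene_id", "transcript_id", "peak_id", "time", "distance")
}

#' Count peaks near each gene
#'
#' In `"radius"` mode (default), counts peaks whose minimum distance to any
#' transcript of the gene is at most `radius` (inclusive).  In `"nearest2"`
#' mode each peak is instead assigned to its 2 nearest genes on any strand,
#' irrespective of distance (ties broken by leftmost gene start), and the
#' count is of peaks assigned to the gene.
#'
#' @param genes Gene models tibble.
#' @param peaks Peaks at one timepoint (or several; counts are per time).
#' @param radius Association radius in bp.
#' @param mode `"radius"` or `"nearest2"`.
#' @return Tibble `gene_id, time, n_peaks` covering every gene (0 when no
#'   peak is near).
#' @export
count_peaks_within <- function(genes, peaks, radius = 10000,
                               mode = c("radius", "nearest2")) {
  mode <- match.arg(mode)
  gene_ids <- distinct(genes, .data$gene_id)
  times <- if (nrow(peaks) > 0) sort(unique(peaks$time)) else numeric()
  base <- tidyr::expand_grid(gene_ids, time = times)
  if (nrow(peaks) == 0) {
    return(mutate(gene_ids, time = NA_real_, n_peaks = 0L))
  }

  if (mode == "radius") {
    hits <- associate_peaks(genes, peaks, max_distance = radius) %>%
      distinct(.data$gene_id, .data$peak_id, .data$time) %>%
      count(.data$gene_id, .data$time, name = "n_peaks")
  } else {
    gene_ext <- genes %>%
      group_by(.data$gene_id, .data$chrom) %>%
      summarise(start = min(.data$start), end = max(.data$end),
                .groups = "drop")
    peaks <- mutate(peaks, peak_id = row_number())
    hits <- inner_join(gene_ext,
                       select(peaks, "chrom", "peak_id", "time",
                              pk_start = "start", pk_end = "end"),
                       by = "chrom", relationship = "many-to-many") %>%
      mutate(distance = min_distance(.data$start, .data$end,
                                     .data$pk_start, .data$pk_end)) %>%
      group_by(.data$peak_id, .data$time) %>%
      arrange(.data$distance, .data$start, .by_group = TRUE) %>%
      slice(1:2) %>%
      ungroup() %>%
      count(.data$gene_id, .data$time, name = "n_peaks")
  }
  left_join(base, hits, by = c("gene_id", "time")) %>%
    mutate(n_peaks = as.integer(replace_na(.data$n_peaks, 0L)))
}

#' Logistic regression of differential-expression odds
#'
#' Fits `DE ~ Su(H) bound + Pol II class + logC0` by maximum likelihood
#' (IRLS via [stats::glm()]), with the UB class as baseline.  Wald tests per
#' coefficient are Holm-adjusted across the reported (non-intercept)
#' coefficients and flagged at adjusted p < 0.005.  Complete separation is
#' detected (fitted probabilities collapsing to 0/1 with exploding
#' coefficients) and triggers a warning plus a ridge-penalized refit for the
#' point estimates.  Constant predictor columns are dropped with a warning.
#'
#' @param table Tibble with columns `de` (0/1 or logical), `suh` (0/1),
#'   `polii_class` (UB/P/AP/AU) and `logc0` (numeric); extra columns ignored.
#' @param alpha_flag Adjusted-p cutoff for the significance flags.
#' @return A `de_logistic` object (see [tidy.de_logistic()]).
#' @export
fit_de_logistic <- function(table, alpha_flag = 0.005) {
  assert_cols(table, c("de", "suh", "polii_class", "logc0"), "table")
  df <- table %>%
    mutate(de = as.integer(.data$de),
           polii_class = factor(.data$polii_class,
                                levels = c("UB", "P", "AP", "AU")))
  preds <- c("suh", "polii_class", "logc0")
  dropped <- character()
  if (length(unique(df$suh)) < 2) { dropped <- c(dropped, "suh") }
  if (length(unique(as.character(df$polii_class))) < 2) {
    dropped <- c(dropped, "polii_class")
  }
  if (length(unique(df$logc0)) < 2) { dropped <- c(dropped, "logc0") }
  if (length(dropped) > 0) {
    warn(paste0("dropping constant predictor(s): ",
                paste(dropped, collapse = ", ")))
    preds <- setdiff(preds, dropped)
  }
  assert_that(length(preds) > 0, "no non-constant predictors left")
  n_events <- sum(df$de)
  if (n_events < 10 * length(preds)) {
    warn(sprintf("only %d events for %d predictors; estimates may be unstable",
                 n_events, length(preds)))
  }

  form <- stats::as.formula(paste("de ~", paste(preds, collapse = " + ")))
  fit <- suppressWarnings(glm(form, data = df, family = binomial()))

  separated <- !fit$converged || any(abs(coef(fit)) > 15) ||
    all(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
  ridge <- NULL
  if (separated) {
    warn(paste("possible complete separation: some coefficients are",
               "effectively infinite; reporting ridge-penalized estimates"))
    X <- model.matrix(form, df)
    ridge <- ridge_logistic(X, df$de, lambda = 1e-3)
  }

  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  wald_p <- 2 * pnorm(-abs(est / se))
  terms <- names(est)
  non_int <- terms != "(Intercept)"
  p_adj <- rep(NA_real_, length(est))
  p_adj[non_int] <- p.adjust(wald_p[non_int], method = "holm")

  coefs <- tibble(
    term = terms,
    estimate = if (separated) ridge[terms] else unname(est),
    std_error = unname(se),
    p_value = unname(wald_p),
    p_adjusted = p_adj,
    odds_multiplier = effect_to_odds(if (separated) ridge[terms] else unname(est)),
    significant = !is.na(p_adj) & p_adj < alpha_flag
  )

  structure(
    list(coefficients = coefs, glm = fit, separated = separated,
         dropped = dropped, n = nrow(df), n_events = n_events,
         alpha_flag = alpha_flag),
    class = "de_logistic"
  )
}

# small ridge-penalized IRLS used only as a separation fallback
ridge_logistic <- function(X, y, lambda = 1e-3, max_iter = 200) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    beta_new <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- drop(beta_new); break }
    beta <- drop(beta_new)
  }
  setNames(drop(beta), colnames(X))
}

#' @export
print.de_logistic <- function(x, ...) {
  cat("<de_logistic> n = ", x$n, " (", x$n_events, " DE)",
      if (x$separated) "; SEPARATION DETECTED" else "", "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_de_logistic
#' @param x,object A `de_logistic` fit.
#' @param ... Unused.
#' @export
tidy.de_logistic <- function(x, ...) x$coefficients

#' @rdname fit_de_logistic
#' @export
glance.de_logistic <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, separated = x$separated,
         null_deviance = x$glm$null.deviance, deviance = x$glm$deviance,
         aic = x$glm$aic)
}

#' Convert a log-odds effect to an odds multiplier
#'
#' `exp(beta)` reported to 2 decimals, the scale on which effects like
#' "binding within 10 kb multiplies the odds of DE by 16.12" are quoted.
#'
#' @param beta Log-odds coefficient(s).
#' @return Odds multiplier(s), rounded to 2 decimals.
#' @export
effect_to_odds <- function(beta) {
  round(exp(beta), 2)
}

#' ANOVA and ordered pairwise tests of logC0 across Pol II classes
#'
#' One-way ANOVA of the basal-expression proxy across the four Pol II
#' classes, plus all pairwise one-sided Welch two-sample t-tests in the
#' direction higher-activity > lower-activity (activity order
#' `AU, AP > P > UB`; the AU/AP pair is tested two-sided since neither
#' dominates a priori).
#'
#' @param logc0 Numeric vector of per-gene logC0.
#' @param class Character/factor vector of Pol II classes, same length.
#' @return List with `anova` (tibble: `F, df1, df2, p`) and `pairwise`
#'   (tibble: `higher, lower, alternative, estimate, p`).
#' @export
logc0_class_tests <- function(logc0, class) {
  assert_that(length(logc0) == length(class), "inputs must have equal length")
  keep <- !is.na(logc0) & !is.na(class)
  logc0 <- logc0[keep]; class <- as.character(class[keep])
  tab <- table(class)
  assert_that(length(tab) >= 2 && all(tab >= 2),
              "need at least 2 classes with at least 2 members each")

  if (var(logc0) < .Machine$double.eps) {
    # no variation anywhere: no evidence of class differences
    fit <- lm(logc0 ~ class)
    a <- anova(fit)
    anova_tbl <- tibble(F = 0, df1 = a$Df[1], df2 = a$Df[2], p = 1)
  } else {
    fit <- lm(logc0 ~ class)
    a <- anova(fit)
    anova_tbl <- tibble(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
                        p = a$`Pr(>F)`[1])
  }

  activity <- c(UB = 1, P = 2, AP = 3, AU = 3)
  lv <- names(tab)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  pairwise <- purrr::map(pairs, function(pr) {
    act <- activity[pr]
    if (is.na(act[1]) || is.na(act[2]) || act[1] == act[2]) {
      hi <- pr[1]; lo <- pr[2]; alt <- "two.sided"
    } else {
      hi <- pr[which.max(act)]; lo <- pr[which.min(act)]; alt <- "greater"
    }
    tt <- tryCatch(
      t.test(logc0[class == hi], logc0[class == lo],
             alternative = alt, var.equal = FALSE),
      error = function(e) NULL)    # essentially-constant data
    tibble(higher = hi, lower = lo, alternative = alt,
           estimate = if (is.null(tt)) mean(logc0[class == hi]) -
             mean(logc0[class == lo]) else unname(diff(rev(tt$estimate))),
           p = if (is.null(tt)) NA_real_ else tt$p.value)
  }) %>% bind_rows()

  list(anova = anova_tbl, pairwise = pairwise)
}

#' Compare per-gene responses under two activation regimes
#'
#' Ordinary least-squares fit of the regime-B log2 fold changes on regime A,
#' with the per-gene linear-scale fold-change ratio `2^|fc_b - fc_a|`; genes
#' whose responses differ by more than `ratio_cutoff`-fold are flagged.
#'
#' @param fc_a,fc_b Paired per-gene log2 fold changes (equal length >= 3).
#' @param ratio_cutoff Fold-difference cutoff on the linear scale.
#' @param gene_id Optional gene identifiers.
#' @return List with `fit` (tibble: `slope, intercept, r_squared, n`) and
#'   `genes` (tibble: `gene_id, fc_a, fc_b, ratio, flagged`).
#' @export
regime_compare <- function(fc_a, fc_b, ratio_cutoff = 2, gene_id = NULL) {
  assert_that(length(fc_a) == length(fc_b), "fold changes must be paired")
  keep <- is.finite(fc_a) & is.finite(fc_b)
  assert_that(sum(keep) >= 3, "need at least 3 complete pairs")
  gene_id <- gene_id %||% sprintf("g%04d", seq_along(fc_a))
  g <- gene_id[keep]; a <- fc_a[keep]; b <- fc_b[keep]

  fit <- lm(b ~ a)
  ratio <- 2^abs(b - a)
  list(
    fit = tibble(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n = length(a)),
    genes = tibble(gene_id = g, fc_a = a, fc_b = b, ratio = ratio,
                   flagged = ratio > ratio_cutoff)
  )
}

#' Assemble the master per-transcript summary table
#'
#' Joins every analysis product into one row per transcript: DE rank/p/q,
#' cluster primary/secondary assignments with allocation probabilities,
#' Pol II state per ChIP timepoint, Su(H) peak counts within the radius per
#' ChIP timepoint, logC0, and median M per expression timepoint.
#'
#' @param genes Gene models tibble.
#' @param de [timecourse_de()] result.
#' @param clusters Optional [dp_summarize()] result (or `NULL`).
#' @param polii_states Optional [classify_polii()] result.
#' @param suh_counts Optional [count_peaks_within()] result.
#' @param logc0 Optional [compute_logc0()] result.
#' @param tc Optional timecourse matrix from [tc_matrix()] for median M
#'   columns.
#' @return Wide tibble, one row per transcript.
#' @export
build_master_table <- function(genes, de, clusters = NULL,
                               polii_states = NULL, suh_counts = NULL,
                               logc0 = NULL, tc = NULL) {
  master <- genes %>%
    distinct(.data$gene_id, .data$transcript_id) %>%
    left_join(select(de, "transcript_id", "F", "p", "q", "rank"),
              by = "transcript_id")

  if (!is.null(clusters)) {
    master <- left_join(master, clusters$assignments, by = "transcript_id")
  } else {
    master <- mutate(master, primary = NA_integer_, primary_prob = NA_real_,
                     secondary = NA_integer_, secondary_prob = NA_real_)
  }
  if (!is.null(polii_states)) {
    pol_wide <- polii_states %>%
      select("transcript_id", "time", "state") %>%
      pivot_wider(names_from = "time", values_from = "state",
                  names_prefix = "polii_")
    master <- left_join(master, pol_wide, by = "transcript_id")
  }
  if (!is.null(suh_counts)) {
    suh_wide <- suh_counts %>%
      filter(!is.na(.data$time)) %>%
      pivot_wider(names_from = "time", values_from = "n_peaks",
                  names_prefix = "suh_")
    master <- left_join(master, suh_wide, by = "gene_id")
  }
  if (!is.null(logc0)) {
    master <- left_join(master, logc0, by = "transcript_id")
  }
  if (!is.null(tc)) {
    m_wide <- tc %>%
      distinct(.data$transcript_id, .data$time, .data$median_M) %>%
      pivot_wider(names_from = "time", values_from = "median_M",
                  names_prefix = "M_")
    master <- left_join(master, m_wide, by = "transcript_id")
  }
  master
}
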