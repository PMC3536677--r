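
# Synthetic data with planted ground truth -----------------------------------
#
# Every generator mirrors one class of input the analysis consumes: replicated
# two-colour expression timecourses, probe-level ChIP enrichment tracks for
# Su(H) and Pol II, gene models, and a genome sequence with planted motif
# instances.  The generating model for expression is
#
#   M(g, t, r) = mu_{k(g)}(t) + c_g + d_{g,t} + e_{g,t,r}
#
# with c_g ~ N(0, sigma_c^2) a gene-level amplitude offset shared across the
# whole profile, d_{g,t} ~ N(0, sigma_t^2) a time-specific deviation shared
# across replicates, and e ~ N(0, sigma_r^2) replicate noise.  This is the
# likelihood the Dirichlet-process clustering assumes, so generator and model
# are two views of the same parameterization.

#' Configuration for the synthetic-data generators
#'
#' Collects every knob of the simulated study in one validated object.  The
#' defaults reproduce the design of the study being emulated: 18 expression
#' timepoints spanning 0--150 min with 4 replicate timecourses, and 7 ChIP
#' timepoints (0, 10, 20, 30, 40, 60, 100 min) with 3 replicates.
#'
#' @param n_genes Number of genes (one transcript each unless
#'   `transcripts_per_gene > 1`).
#' @param expr_times Expression sampling times in minutes; strictly increasing
#'   and starting at 0.
#' @param chip_times ChIP sampling times in minutes.
#' @param n_expr_reps,n_chip_reps Replicate counts for the two platforms.
#' @param cluster_spec Tibble with columns `shape` (one of `"early_up"`,
#'   `"late_up"`, `"down"`, `"transient"`, `"flat"`), `amplitude` (log2
#'   units) and `n` (member count).  `NULL` uses a default mix in which
#'   roughly a third of genes respond and the rest are flat.
#' @param sigma_c,sigma_t,sigma_r Standard deviations (log2 units) of the
#'   gene-offset, time-deviation and replicate-noise components.
#' @param probe_spacing Tiling-probe spacing in bp.
#' @param gene_length,flank Gene body length and intergenic flank (bp) used to
#'   lay genes out in tandem on one synthetic chromosome.
#' @param peak_height Su(H) peak height at its temporal maximum (log2 units).
#' @param peak_width Su(H) peak width in bp.
#' @param sigma_bg ChIP background noise SD (log2 units); background is
#'   truncated at 0 to match non-negative log2 enrichment displays.
#' @param suh_time_profile Multiplier of `peak_height` per `chip_times` entry;
#'   the default rises to its maximum at 20--30 min and declines after.
#' @param polii_class_mix Named proportions over the Pol II classes
#'   `UB`, `P`, `AP`, `AU`; must sum to 1.
#' @param polii_promoter_height,polii_body_height Log2 enrichment of the
#'   promoter-proximal block and the gene body used to draw the class shapes.
#' @param logc0_base,logc0_sd,logc0_class_shift Basal absolute-expression
#'   proxy: per-gene logC0 is `logc0_base + logc0_class_shift[class] +
#'   N(0, logc0_sd)`, so transcriptional activity and spot intensity are
#'   coupled the way the Pol II classes predict.
#' @param suh_frac_de,suh_frac_other Probability that a responding
#'   (respectively flat) gene carries a planted Su(H) enhancer peak.
#' @param sps_gaps Inter-site gaps (nt) used when planting paired Su(H) sites.
#' @param suh_consensus,hairy_consensus Consensus strings planted in the
#'   synthetic genome.
#' @param dye_coef Slope of an intensity-dependent dye offset added to planted
#'   M values when generating raw channels (0 = none).
#' @param transcripts_per_gene Transcript isoforms per gene.
#' @param seed Integer seed; all generators derive stage seeds from it.
#'
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_genes = 500,
                         expr_times = c(0, 5, 10, 15, 20, 25, 30, 40, 50, 60,
                                        70, 80, 90, 100, 110, 120, 135, 150),
                         chip_times = c(0, 10, 20, 30, 40, 60, 100),
                         n_expr_reps = 4,
                         n_chip_reps = 3,
                         cluster_spec = NULL,
                         sigma_c = 0.15,
                         sigma_t = 0.08,
                         sigma_r = 0.2,
                         probe_spacing = 50,
                         gene_length = 2000,
                         flank = 1500,
                         peak_height = 3,
                         peak_width = 300,
                         sigma_bg = 0.1,
                         suh_time_profile = c(0.5, 0.8, 1, 0.95, 0.7, 0.5, 0.3),
                         polii_class_mix = c(UB = 0.4, P = 0.2, AP = 0.2, AU = 0.2),
                         polii_promoter_height = 4,
                         polii_body_height = 1.5,
                         logc0_base = 9,
                         logc0_sd = 0.8,
                         logc0_class_shift = c(UB = 0, P = 1, AP = 2, AU = 2.2),
                         suh_frac_de = 0.8,
                         suh_frac_other = 0.1,
                         sps_gaps = c(12, 15, 18),
                         suh_consensus = "CGTGGGAA",
                         hairy_consensus = "CACGCG",
                         dye_coef = 0,
                         transcripts_per_gene = 1,
                         seed = 1L) {
  if (is.null(cluster_spec)) {
    shaped <- pmax(round(n_genes * c(0.08, 0.10, 0.06, 0.08)), 1)
    cluster_spec <- tibble(
      shape = c("early_up", "late_up", "transient", "down", "flat"),
      amplitude = c(2, 1.5, 1.5, 1.5, 0),
      n = c(shaped, n_genes - sum(shaped))
    )
    cluster_spec <- cluster_spec[cluster_spec$n > 0, , drop = FALSE]
  }
  cluster_spec <- as_tibble(cluster_spec)
  assert_cols(cluster_spec, c("shape", "amplitude", "n"), "cluster_spec")
  assert_that(nrow(cluster_spec) > 0, "cluster_spec must be non-empty")
  assert_that(all(cluster_spec$n > 0), "cluster member counts must be positive")
  assert_that(all(cluster_spec$shape %in%
                    c("early_up", "late_up", "down", "transient", "flat")),
              "unknown cluster shape")
  assert_that(n_genes >= 1 && n_expr_reps >= 1 && n_chip_reps >= 1,
              "counts must be positive")
  assert_that(sum(cluster_spec$n) == n_genes,
              "cluster_spec member counts must sum to n_genes")
  for (tv in list(expr_times, chip_times)) {
    assert_that(all(diff(tv) > 0), "times must be strictly increasing")
    assert_that(tv[1] == 0, "times must include 0")
  }
  assert_that(all(c(sigma_c, sigma_t, sigma_r, sigma_bg) >= 0),
              "variance components must be non-negative")
  assert_that(probe_spacing > 0, "probe_spacing must be positive")
  assert_that(abs(sum(polii_class_mix) - 1) < 1e-8 &&
                all(polii_class_mix >= 0) &&
                identical(sort(names(polii_class_mix)), sort(c("UB", "P", "AP", "AU"))),
              "polii_class_mix must be named proportions over UB/P/AP/AU that sum to 1")
  assert_that(length(suh_time_profile) == length(chip_times),
              "suh_time_profile must match chip_times in length")

  structure(
    list(
      n_genes = n_genes, expr_times = expr_times, chip_times = chip_times,
      n_expr_reps = n_expr_reps, n_chip_reps = n_chip_reps,
      cluster_spec = cluster_spec,
      sigma_c = sigma_c, sigma_t = sigma_t, sigma_r = sigma_r,
      probe_spacing = probe_spacing, gene_length = gene_length, flank = flank,
      peak_height = peak_height, peak_width = peak_width, sigma_bg = sigma_bg,
      suh_time_profile = suh_time_profile,
      polii_class_mix = polii_class_mix,
      polii_promoter_height = polii_promoter_height,
      polii_body_height = polii_body_height,
      logc0_base = logc0_base, logc0_sd = logc0_sd,
      logc0_class_shift = logc0_class_shift,
      suh_frac_de = suh_frac_de, suh_frac_other = suh_frac_other,
      sps_gaps = sps_gaps,
      suh_consensus = suh_consensus, hairy_consensus = hairy_consensus,
      dye_coef = dye_coef, transcripts_per_gene = transcripts_per_gene,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> ", x$n_genes, " genes, ",
      length(x$expr_times), " expression times x ", x$n_expr_reps, " reps, ",
      length(x$chip_times), " ChIP times x ", x$n_chip_reps, " reps\n", sep = "")
  invisible(x)
}

#' Cluster mean temporal profile
#'
#' Canonical response shapes in log2 fold-change units, all anchored at 0 at
#' t = 0: `early_up` peaks near 20 min and relaxes, `late_up` rises
#' sigmoidally after ~60 min, `down` decays towards `-amplitude`,
#' `transient` is a Gaussian bump centred at 30 min, `flat` is identically 0.
#'
#' @param shape Shape name.
#' @param amplitude Peak magnitude in log2 units.
#' @param times Minutes.
#' @return Numeric vector of mean M values, one per time.
#' @export
profile_mean <- function(shape, amplitude, times) {
  switch(shape,
    early_up = amplitude * (times / 20) * exp(1 - times / 20),
    late_up = {
      raw <- 1 / (1 + exp(-(times - 60) / 15))
      amplitude * (raw - raw[1]) / (1 - raw[1])
    },
    down = -amplitude * (1 - exp(-times / 40)),
    transient = {
      raw <- exp(-((times - 30) / 18)^2)
      amplitude * (raw - raw[1])
    },
    flat = rep(0, length(times)),
    abort(paste0("unknown profile shape: ", shape))
  )
}

# gene/transcript/cluster bookkeeping shared by the generators
synth_gene_table <- function(config) {
  spec <- config$cluster_spec
  cluster <- rep(seq_len(nrow(spec)), spec$n)
  gene_id <- sprintf("g%04d", seq_len(config$n_genes))
  genes <- tibble(
    gene_id = gene_id,
    cluster = cluster,
    shape = spec$shape[cluster],
    amplitude = spec$amplitude[cluster],
    de = spec$shape[cluster] != "flat" & spec$amplitude[cluster] != 0
  )
  tx <- tidyr::expand_grid(
    gene_id = gene_id,
    isoform = seq_len(config$transcripts_per_gene)
  ) %>%
    mutate(transcript_id = paste0(.data$gene_id, "-R", LETTERS[.data$isoform])) %>%
    select("gene_id", "transcript_id")
  left_join(tx, genes, by = "gene_id")
}

#' Generate replicated expression timecourses with planted cluster structure
#'
#' Draws M values from the additive three-component Gaussian model described
#' above, plus per-gene basal intensities (logC0) that follow the planted
#' Pol II class, and two-colour raw channel intensities from which the M
#' values can be recomputed.
#'
#' @param config A [synth_config()].
#' @return A list with elements
#'   * `expression`: tibble `transcript_id, gene_id, time, rep, M`,
#'   * `raw`: tibble `spot, transcript_id, time, rep, ch_treated, ch_reference`,
#'   * `truth`: list with `genes` (cluster/class/logC0 per transcript),
#'     `profiles` (planted cluster means), and the generating config.
#' @export
synth_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(stage_seed(config$seed, "expression"))

  genes <- synth_gene_table(config)
  # Pol II class per gene (shared by isoforms), then class-tracking logC0
  g <- distinct(genes, .data$gene_id, .keep_all = TRUE)
  classes <- sample(names(config$polii_class_mix), nrow(g),
                    replace = TRUE, prob = config$polii_class_mix)
  logc0 <- config$logc0_base + config$logc0_class_shift[classes] +
    rnorm(nrow(g), 0, config$logc0_sd)
  g <- mutate(g, polii_class = classes, logc0 = as.numeric(logc0))
  genes <- left_join(genes,
                     select(g, "gene_id", "polii_class", "logc0"),
                     by = "gene_id")

  times <- config$expr_times
  n_t <- length(times)
  n_r <- config$n_expr_reps
  n_tx <- nrow(genes)

  profiles <- config$cluster_spec %>%
    mutate(cluster = row_number()) %>%
    rowwise_profiles(times)

  mu <- matrix(profiles$mu, nrow = nrow(config$cluster_spec), byrow = TRUE)
  mu_tx <- mu[genes$cluster, , drop = FALSE]                 # n_tx x n_t

  c_g <- rnorm(n_tx, 0, config$sigma_c)
  d_gt <- matrix(rnorm(n_tx * n_t, 0, config$sigma_t), n_tx, n_t)
  base <- mu_tx + c_g + d_gt                                  # shared across reps

  expr <- tidyr::expand_grid(
    transcript_id = genes$transcript_id,
    time = times,
    rep = seq_len(n_r)
  )
  idx <- cbind(rep(seq_len(n_tx), each = n_t * n_r),
               rep(rep(seq_len(n_t), each = n_r), times = n_tx))
  expr$M <- base[idx] + rnorm(nrow(expr), 0, config$sigma_r)
  expr <- left_join(expr, select(genes, "transcript_id", "gene_id"),
                    by = "transcript_id") %>%
    select("transcript_id", "gene_id", "time", "rep", "M")

  # raw two-colour channels: reference = basal intensity, treated = ref * 2^M
  # (plus an optional intensity-dependent dye offset in M space)
  raw <- left_join(expr, select(genes, "transcript_id", "logc0"),
                   by = "transcript_id") %>%
    mutate(
      ch_reference = 2^.data$logc0,
      ch_treated = .data$ch_reference *
        2^(.data$M + config$dye_coef * (.data$logc0 - config$logc0_base)),
      spot = paste0(.data$transcript_id, "_t", .data$time, "_r", .data$rep)
    ) %>%
    select("spot", "transcript_id", "time", "rep", "ch_treated", "ch_reference")

  list(
    expression = expr,
    raw = raw,
    truth = list(
      genes = genes,
      profiles = profiles,
      config = config
    )
  )
}

# expand cluster_spec into a long (cluster, time, mu) tibble
rowwise_profiles <- function(spec, times) {
  purrr::pmap(
    list(spec$cluster, spec$shape, spec$amplitude),
    function(k, shape, amp) {
      mu <- profile_mean(shape, amp, times)
      tibble(cluster = k, shape = shape, time = times, mu = mu)
    }
  ) %>% bind_rows()
}

#' Generate synthetic gene models on one chromosome
#'
#' Genes are laid out in tandem slots of `gene_length + 2 * flank` bp with
#' alternating strand; coordinates are 0-based half-open.  The TSS is the
#' strand-aware 5' end.
#'
#' @param config A [synth_config()].
#' @return Tibble `gene_id, transcript_id, chrom, start, end, strand, tss`.
#' @export
synth_genes <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  slot <- config$gene_length + 2 * config$flank
  g <- distinct(synth_gene_table(config), .data$gene_id)
  i <- seq_len(nrow(g))
  genes <- tibble(
    gene_id = g$gene_id,
    chrom = "chrS",
    start = (i - 1) * slot + config$flank,
    end = (i - 1) * slot + config$flank + config$gene_length,
    strand = ifelse(i %% 2 == 1, "+", "-")
  ) %>%
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end))
  tx <- select(synth_gene_table(config), "gene_id", "transcript_id")
  left_join(tx, genes, by = "gene_id") %>%
    select("gene_id", "transcript_id", "chrom", "start", "end", "strand", "tss")
}

synth_genome_length <- function(config) {
  (config$gene_length + 2 * config$flank) * config$n_genes
}

#' Generate ChIP enrichment tracks with planted peaks and Pol II shapes
#'
#' Background enrichment is N(0, `sigma_bg`) truncated at 0.  Each planted
#' Pol II class draws its canonical shape: `UB` background only; `P` a
#' promoter-proximal block only; `AP` a promoter block at
#' `polii_promoter_height` plus gene-body enrichment at `polii_body_height`
#' (so log2(max)/log2(median) >= 2 by construction); `AU` uniform enrichment
#' at `polii_body_height` across promoter and body (ratio < 2).  Su(H) peaks
#' are placed at recorded enhancer coordinates upstream of the TSS with a
#' time-varying height that is maximal at 20--30 min.
#'
#' @param config A [synth_config()].
#' @param genes Gene models from [synth_genes()].
#' @param truth Optional truth list from [synth_expression()]; when supplied,
#'   planted Pol II classes are taken from it and Su(H) peaks are preferentially
#'   placed at differentially expressed genes (`suh_frac_de` vs
#'   `suh_frac_other`).
#' @return A list with `tracks` (named list of long tibbles
#'   `chrom, pos, time, rep, score` for `suh` and `polii`) and `truth`
#'   (`peaks`: planted Su(H) intervals and heights per timepoint;
#'   `classes`: planted class per transcript; `suh_genes`).
#' @export
synth_chip <- function(config, genes, truth = NULL) {
  stopifnot(inherits(config, "synth_config"))
  assert_cols(genes, c("gene_id", "transcript_id", "chrom", "start", "end",
                       "strand", "tss"), "genes")
  glen <- synth_genome_length(config)
  assert_that(all(genes$end <= glen), "genes must fit inside the synthetic genome")
  set.seed(stage_seed(config$seed, "chip"))

  pos <- seq(config$probe_spacing %/% 2, glen - 1, by = config$probe_spacing)
  n_p <- length(pos)
  times <- config$chip_times
  n_t <- length(times)
  n_r <- config$n_chip_reps

  gene_info <- distinct(genes, .data$gene_id, .keep_all = TRUE)
  if (!is.null(truth)) {
    cls <- distinct(truth$genes, .data$gene_id, .keep_all = TRUE)
    gene_info <- left_join(gene_info,
                           select(cls, "gene_id", "polii_class", "de"),
                           by = "gene_id")
  } else {
    gene_info$polii_class <- sample(names(config$polii_class_mix),
                                    nrow(gene_info), replace = TRUE,
                                    prob = config$polii_class_mix)
    gene_info$de <- rbinom(nrow(gene_info), 1, 0.3) == 1
  }

  # deterministic signal component per probe (same at all times for Pol II)
  polii_sig <- numeric(n_p)
  prom_w <- 500
  for (i in seq_len(nrow(gene_info))) {
    cl <- gene_info$polii_class[i]
    if (cl == "UB") next
    s <- gene_info$start[i]; e <- gene_info$end[i]
    if (gene_info$strand[i] == "+") {
      prom <- c(s, min(s + prom_w, e))
    } else {
      prom <- c(max(e - prom_w, s), e)
    }
    in_prom <- pos >= prom[1] & pos < prom[2]
    in_body <- pos >= s & pos < e & !in_prom
    if (cl == "P") {
      polii_sig[in_prom] <- pmax(polii_sig[in_prom], config$polii_promoter_height)
    } else if (cl == "AP") {
      polii_sig[in_prom] <- pmax(polii_sig[in_prom], config$polii_promoter_height)
      polii_sig[in_body] <- pmax(polii_sig[in_body], config$polii_body_height)
    } else if (cl == "AU") {
      polii_sig[in_prom | in_body] <- pmax(polii_sig[in_prom | in_body],
                                           config$polii_body_height)
    }
  }

  # Su(H) enhancers: upstream of the TSS, height modulated over time
  has_suh <- runif(nrow(gene_info)) <
    ifelse(gene_info$de, config$suh_frac_de, config$suh_frac_other)
  suh_genes <- gene_info[has_suh, , drop = FALSE]
  enh_start <- ifelse(suh_genes$strand == "+",
                      suh_genes$tss - 1000 - config$peak_width,
                      suh_genes$tss + 1000)
  enh_start <- pmax(enh_start, 0)
  enh_end <- pmin(enh_start + config$peak_width, glen)
  suh_sig <- matrix(0, n_p, n_t)
  for (i in seq_along(enh_start)) {
    in_peak <- pos >= enh_start[i] & pos < enh_end[i]
    for (j in seq_len(n_t)) {
      h <- config$peak_height * config$suh_time_profile[j]
      suh_sig[in_peak, j] <- pmax(suh_sig[in_peak, j], h)
    }
  }
  planted_peaks <- tidyr::expand_grid(
    idx = seq_along(enh_start), time_idx = seq_len(n_t)
  ) %>%
    mutate(
      gene_id = suh_genes$gene_id[.data$idx],
      chrom = "chrS",
      start = enh_start[.data$idx],
      end = enh_end[.data$idx],
      time = times[.data$time_idx],
      height = config$peak_height * config$suh_time_profile[.data$time_idx]
    ) %>%
    select("gene_id", "chrom", "start", "end", "time", "height")

  make_track <- function(signal_by_time) {
    grid <- tidyr::expand_grid(time = times, rep = seq_len(n_r))
    purrr::pmap(grid, function(time, rep) {
      j <- match(time, times)
      bg <- pmax(rnorm(n_p, 0, config$sigma_bg), 0)
      sig <- if (is.matrix(signal_by_time)) signal_by_time[, j] else signal_by_time
      tibble(chrom = "chrS", pos = pos, time = time, rep = rep,
             score = sig + bg)
    }) %>% bind_rows()
  }

  tracks <- list(suh = make_track(suh_sig), polii = make_track(polii_sig))

  list(
    tracks = tracks,
    truth = list(
      peaks = planted_peaks,
      classes = select(left_join(select(genes, "gene_id", "transcript_id"),
                                 select(gene_info, "gene_id", "polii_class"),
                                 by = "gene_id"),
                       "gene_id", "transcript_id", "polii_class"),
      suh_genes = suh_genes$gene_id
    )
  )
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Generate a genome sequence with planted motif instances
#'
#' Background bases are i.i.d. uniform over A/C/G/T.  For each gene carrying a
#' planted Su(H) enhancer, a paired-site (SPS) arrangement -- the consensus on
#' the forward strand and its reverse complement after a gap drawn from
#' `sps_gaps` -- is written upstream of the TSS, plus a single site further
#' out.  For `down`-cluster style repression targets a Hairy consensus is
#' planted within 5 kb.  Accidental exact-consensus matches arising in the
#' random background are removed by rescanning and redrawing, so exact
#' occurrences equal planted occurrences.
#'
#' @param config A [synth_config()].
#' @param genes Gene models from [synth_genes()].
#' @param suh_gene_ids Genes receiving Su(H) plants (default: every third).
#' @param hairy_gene_ids Genes receiving a Hairy plant (default: every fifth).
#' @return List with `sequence` (single character string), and `truth`: tibble
#'   `motif, gene_id, start, strand, kind, gap` of planted instances
#'   (0-based starts; SPS rows give the gap between the paired sites).
#' @export
synth_genome <- function(config, genes,
                         suh_gene_ids = NULL, hairy_gene_ids = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(stage_seed(config$seed, "genome"))
  glen <- synth_genome_length(config)
  gene_info <- distinct(genes, .data$gene_id, .keep_all = TRUE)
  if (is.null(suh_gene_ids)) {
    suh_gene_ids <- gene_info$gene_id[seq(1, nrow(gene_info), by = 3)]
  }
  if (is.null(hairy_gene_ids)) {
    hairy_gene_ids <- gene_info$gene_id[seq(2, nrow(gene_info), by = 5)]
  }

  seq_chars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)

  suh <- config$suh_consensus
  hairy <- config$hairy_consensus
  w_s <- nchar(suh)
  w_h <- nchar(hairy)

  plant <- list()
  put <- function(chars, at, motif_str) {  # at: 0-based
    stopifnot(at >= 0, at + nchar(motif_str) <= glen)
    chars[(at + 1):(at + nchar(motif_str))] <- strsplit(motif_str, "")[[1]]
    chars
  }

  for (gid in suh_gene_ids) {
    gi <- gene_info[gene_info$gene_id == gid, ]
    up <- if (gi$strand == "+") gi$tss - 800 else gi$tss + 800 - (2 * w_s + 22)
    up <- max(min(up, glen - 60), 0)
    gap <- config$sps_gaps[sample.int(length(config$sps_gaps), 1)]
    # paired sites in opposite orientation: forward site, gap, reverse site
    plant[[length(plant) + 1]] <- tibble(
      motif = "suh", gene_id = gid, start = up, strand = "+",
      kind = "sps", gap = gap)
    plant[[length(plant) + 1]] <- tibble(
      motif = "suh", gene_id = gid, start = up + w_s + gap, strand = "-",
      kind = "sps", gap = gap)
    seq_chars <- put(seq_chars, up, suh)
    seq_chars <- put(seq_chars, up + w_s + gap, revcomp_chr(suh))
    # one isolated site 300 bp further upstream
    single_at <- max(up - 300, 0)
    plant[[length(plant) + 1]] <- tibble(
      motif = "suh", gene_id = gid, start = single_at, strand = "+",
      kind = "single", gap = NA_real_)
    seq_chars <- put(seq_chars, single_at, suh)
  }
  for (gid in hairy_gene_ids) {
    gi <- gene_info[gene_info$gene_id == gid, ]
    at <- max(min(gi$start - 1200, glen - w_h), 0)
    plant[[length(plant) + 1]] <- tibble(
      motif = "hairy", gene_id = gid, start = at, strand = "+",
      kind = "single", gap = NA_real_)
    seq_chars <- put(seq_chars, at, hairy)
  }
  planted <- bind_rows(plant)
  if (nrow(planted) > 0) {
    ends <- planted$start + ifelse(planted$motif == "suh", w_s, w_h)
    ord <- order(planted$start)
    assert_that(all(planted$start[ord][-1] >= ends[ord][-length(ord)]),
                "planted motifs overlap each other")
  }

  seq_chars <- scrub_accidental(
    seq_chars,
    consensi = setNames(c(suh, hairy), c("suh", "hairy")),
    planted = planted
  )

  list(sequence = paste(seq_chars, collapse = ""), truth = planted)
}

# Redraw background wherever an exact consensus (either strand, any motif)
# occurs away from a planted position.  Only bases not covered by a planted
# instance are redrawn, so accidental matches straddling a plant boundary are
# destroyed without damaging the plant itself.  Works on the character
# vector to avoid copying the whole genome per replacement.
scrub_accidental <- function(seq_chars, consensi, planted, max_iter = 25) {
  widths <- nchar(consensi)
  covered <- logical(length(seq_chars))        # 1-based mask of plant bases
  if (nrow(planted) > 0) {
    plant_w <- widths[planted$motif]
    for (i in seq_len(nrow(planted))) {
      covered[(planted$start[i] + 1):(planted$start[i] + plant_w[i])] <- TRUE
    }
  }
  for (iter in seq_len(max_iter)) {
    genome <- paste(seq_chars, collapse = "")
    redraw <- integer()                        # 1-based positions to redraw
    for (m in names(consensi)) {
      cons <- consensi[[m]]
      w <- widths[[m]]
      pf <- planted$start[planted$motif == m & planted$strand == "+"]
      pr <- planted$start[planted$motif == m & planted$strand == "-"]
      for (pat in unique(c(cons, revcomp_chr(cons)))) {
        ok_at <- if (pat == cons) pf else pr
        if (revcomp_chr(cons) == cons) ok_at <- c(pf, pr)
        hits <- gregexpr(pat, genome, fixed = TRUE)[[1]]
        hits <- setdiff(hits[hits > 0] - 1, ok_at)      # 0-based starts
        if (length(hits) > 0) {
          base_pos <- rep(hits, each = w) + seq_len(w)  # 1-based
          redraw <- c(redraw, base_pos[!covered[base_pos]])
        }
      }
    }
    redraw <- unique(redraw)
    if (length(redraw) == 0) return(seq_chars)
    seq_chars[redraw] <- sample(c("A", "C", "G", "T"), length(redraw),
                                replace = TRUE)
  }
  warn("could not remove all accidental consensus matches")
  seq_chars
}

#' Generate a gene-level table from the DE-odds logistic model
#'
#' Draws per-gene predictors (Su(H) bound within 10 kb, Pol II class, centred
#' logC0) and a differential-expression indicator from the logistic model
#' `logit P(DE) = b0 + b_suh * suh + b_P * [P] + b_AP * [AP] + b_AU * [AU] +
#' b_logc0 * logc0`, for parameter-recovery studies of [fit_de_logistic()].
#'
#' @param n Number of genes.
#' @param betas Named coefficients: `intercept`, `suh`, `pol_P`, `pol_AP`,
#'   `pol_AU`, `logc0`.
#' @param p_suh Marginal probability of Su(H) binding.
#' @param class_mix Named Pol II class proportions.
#' @param seed Integer seed.
#' @return Tibble `gene_id, suh, polii_class, logc0, de`.
#' @export
synth_logistic <- function(n,
                           betas = c(intercept = -2.5, suh = 2.78,
                                     pol_P = 0.77, pol_AP = 0.3,
                                     pol_AU = -0.49, logc0 = 0.2),
                           p_suh = 0.35,
                           class_mix = c(UB = 0.4, P = 0.2, AP = 0.2, AU = 0.2),
                           seed = 1L) {
  set.seed(as.integer(seed))
  cls <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
  suh <- rbinom(n, 1, p_suh)
  logc0 <- rnorm(n)
  eta <- betas[["intercept"]] + betas[["suh"]] * suh +
    betas[["pol_P"]] * (cls == "P") + betas[["pol_AP"]] * (cls == "AP") +
    betas[["pol_AU"]] * (cls == "AU") + betas[["logc0"]] * logc0
  tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    suh = suh,
    polii_class = cls,
    logc0 = logc0,
    de = rbinom(n, 1, plogis(eta))
  )
}
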