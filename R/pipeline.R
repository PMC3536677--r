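
# End-to-end pipeline --------------------------------------------------------
#
# Stage order follows the analysis: simulate (or load) -> normalize -> DE ->
# cluster -> peaks -> Pol II -> integrate -> motifs.  One global seed is
# split deterministically per stage, so a config + seed pair reproduces every
# output byte-for-byte.

#' Build a validated pipeline configuration
#'
#' All numeric analysis parameters surface here rather than being hard-coded
#' in the stages.  Stage blocks may be partially specified; unnamed entries
#' keep their defaults.
#'
#' @param synth A [synth_config()] for the simulate stage.
#' @param de List: `spline_df`, `q_cutoff`, `n_null`.
#' @param cluster List: `enabled`, `n_sweeps`, `burn_in`, `alpha`, `tau2`,
#'   `max_transcripts` (clustering is restricted to DE transcripts; this
#'   caps how many, ranked by DE p-value).
#' @param peaks List: `threshold`, `min_run`, `merge_gap`.
#' @param polii List: `promoter_window`, `floor`, `threshold`, `min_run`,
#'   `ratio_cutoff`.
#' @param integrate List: `radius`.
#' @param motifs List: `enabled`, `threshold_frac`, `window`.
#' @param seed Global integer seed.
#' @param write_tracks If `TRUE`, probe tracks are exported as bedGraph (one
#'   file per factor/timepoint/replicate); off by default as these dominate
#'   disk usage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(),
                            de = list(),
                            cluster = list(),
                            peaks = list(),
                            polii = list(),
                            integrate = list(),
                            motifs = list(),
                            seed = 1L,
                            write_tracks = FALSE) {
  merge_block <- function(defaults, user) {
    assert_that(all(names(user) %in% names(defaults)),
                paste("unknown parameter(s):",
                      paste(setdiff(names(user), names(defaults)),
                            collapse = ", ")))
    utils::modifyList(defaults, user)
  }
  structure(
    list(
      synth = synth,
      de = merge_block(list(spline_df = 4, q_cutoff = 0.05, n_null = 0), de),
      cluster = merge_block(list(enabled = TRUE, n_sweeps = 800,
                                 burn_in = 300, alpha = 1, tau2 = 4,
                                 max_transcripts = 200), cluster),
      peaks = merge_block(list(threshold = 1, min_run = 4, merge_gap = 2),
                          peaks),
      polii = merge_block(list(promoter_window = 500, floor = 0.25,
                               threshold = 1, min_run = 4, ratio_cutoff = 2),
                          polii),
      integrate = merge_block(list(radius = 10000), integrate),
      motifs = merge_block(list(enabled = TRUE, threshold_frac = 0.6,
                                window = 5000), motifs),
      seed = as.integer(seed),
      write_tracks = isTRUE(write_tracks)
    ),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @return For `read_pipeline_config()`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  special <- c("cluster_spec", "polii_class_mix", "logc0_class_shift")
  args <- y$synth[setdiff(names(y$synth), special)]
  if (!is.null(y$synth$cluster_spec)) {
    args$cluster_spec <- bind_rows(lapply(y$synth$cluster_spec, as_tibble))
  }
  for (nm in c("polii_class_mix", "logc0_class_shift")) {
    if (!is.null(y$synth[[nm]])) args[[nm]] <- unlist(y$synth[[nm]])
  }
  sc <- do.call(synth_config, args)
  pipeline_config(
    synth = sc,
    de = y$de %||% list(), cluster = y$cluster %||% list(),
    peaks = y$peaks %||% list(), polii = y$polii %||% list(),
    integrate = y$integrate %||% list(), motifs = y$motifs %||% list(),
    seed = y$seed %||% 1L,
    write_tracks = y$write_tracks %||% FALSE
  )
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$synth <- unclass(y$synth)
  y$synth$cluster_spec <- purrr::transpose(as.list(y$synth$cluster_spec)) %||%
    NULL
  y$synth$polii_class_mix <- as.list(y$synth$polii_class_mix)
  y$synth$logc0_class_shift <- as.list(y$synth$logc0_class_shift)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes every enabled stage in dependency order and writes the analysis
#' products to `outdir`: `master_table.tsv` (one row per transcript with DE,
#' cluster, Pol II and Su(H) columns), `de_results.tsv`,
#' `cluster_assignments.tsv` and `cluster_profiles.tsv`,
#' `peaks_<factor>.tsv`/`.bed`, `peak_area_timecourse.tsv`,
#' `polii_states.tsv` and `gene_states.tsv`, `associations.tsv`,
#' `motif_matches.tsv`, `sps.tsv`, `motif_gene_counts.tsv`,
#' `model_report.json` (logistic fit and logC0-by-class tests),
#' `genome.fa`, `genes.gff3`, `truth.json`, and `manifest.json` (parameters,
#' seed, versions, file hashes).
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with every in-memory stage product and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  say <- function(...) if (!quiet) inform(paste0("[notchpulse] ", ...))
  t0 <- Sys.time()
  written <- character()
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    readr::write_tsv(df, p)
    written <<- c(written, p)
    p
  }

  # stage seeds derive from the global seed
  sc <- config$synth
  sc$seed <- stage_seed(config$seed, "synth")

  ## simulate ---------------------------------------------------------------
  say("simulate: ", sc$n_genes, " genes")
  expr <- synth_expression(sc)
  genes <- synth_genes(sc)
  chip <- synth_chip(sc, genes, expr$truth)
  genome <- synth_genome(sc, genes, suh_gene_ids = chip$truth$suh_genes)

  write_genome_fasta(genome$sequence, file.path(outdir, "genome.fa"))
  write_genes_gff3(genes, file.path(outdir, "genes.gff3"))
  written <- c(written, file.path(outdir, c("genome.fa", "genes.gff3")))
  truth_path <- file.path(outdir, "truth.json")
  jsonlite::write_json(
    list(
      genes = expr$truth$genes,
      profiles = expr$truth$profiles,
      peaks = chip$truth$peaks,
      motifs = genome$truth
    ),
    truth_path, digits = NA)
  written <- c(written, truth_path)
  if (config$write_tracks) {
    for (fac in names(chip$tracks)) {
      tr <- chip$tracks[[fac]]
      for (tp in unique(tr$time)) for (rp in unique(tr$rep)) {
        p <- file.path(outdir, sprintf("track_%s_t%g_r%d.bedGraph", fac, tp, rp))
        write_track_bedgraph(filter(tr, .data$time == tp, .data$rep == rp),
                             p, span = sc$probe_spacing)
        written <- c(written, p)
      }
    }
  }

  ## normalize + DE ---------------------------------------------------------
  say("normalize + DE")
  ma <- compute_ma(expr$raw)
  ma <- normalize_ma(ma)
  tc <- tc_matrix(ma)
  de <- timecourse_de(tc, spline_df = config$de$spline_df,
                      n_null = config$de$n_null,
                      seed = stage_seed(config$seed, "de"))
  logc0 <- compute_logc0(expr$raw)
  emit(de, "de_results.tsv")

  ## cluster ----------------------------------------------------------------
  clusters <- NULL
  if (isTRUE(config$cluster$enabled)) {
    de_ids <- de %>%
      filter(.data$q < config$de$q_cutoff) %>%
      arrange(.data$p) %>%
      head(config$cluster$max_transcripts) %>%
      pull(.data$transcript_id)
    if (length(de_ids) >= 2) {
      say("cluster: ", length(de_ids), " DE transcripts, ",
          config$cluster$n_sweeps, " sweeps")
      prof <- tc %>%
        filter(.data$transcript_id %in% de_ids) %>%
        select("transcript_id", "time", "rep", "M")
      fit <- dp_fit(prof, n_sweeps = config$cluster$n_sweeps,
                    burn_in = config$cluster$burn_in,
                    seed = stage_seed(config$seed, "cluster"),
                    alpha = config$cluster$alpha, tau2 = config$cluster$tau2)
      clusters <- dp_summarize(fit)
      emit(clusters$assignments, "cluster_assignments.tsv")
      emit(clusters$profiles, "cluster_profiles.tsv")
    } else {
      say("cluster: fewer than 2 DE transcripts; skipping")
    }
  }

  ## peaks ------------------------------------------------------------------
  say("peaks")
  peak_sets <- purrr::imap(chip$tracks, function(tr, fac) {
    pk <- call_peaks(tr, threshold = config$peaks$threshold,
                     min_run = config$peaks$min_run,
                     merge_gap = config$peaks$merge_gap,
                     spacing = sc$probe_spacing)
    emit(pk, paste0("peaks_", fac, ".tsv"))
    p <- file.path(outdir, paste0("peaks_", fac, ".bed"))
    write_peaks_bed(pk, p)
    written <<- c(written, p)
    pk
  })
  areas <- peak_area_timecourse(chip$tracks$suh, peak_sets$suh)
  emit(areas, "peak_area_timecourse.tsv")

  ## Pol II -----------------------------------------------------------------
  say("Pol II classification")
  pol <- classify_polii(chip$tracks$polii, genes,
                        promoter_window = config$polii$promoter_window,
                        floor = config$polii$floor,
                        threshold = config$polii$threshold,
                        min_run = config$polii$min_run,
                        ratio_cutoff = config$polii$ratio_cutoff)
  gene_states <- gene_polii_states(pol)
  emit(pol, "polii_states.tsv")
  emit(gene_states, "gene_states.tsv")

  ## integrate --------------------------------------------------------------
  say("integrate")
  assoc <- associate_peaks(genes, peak_sets$suh,
                           max_distance = config$integrate$radius)
  emit(assoc, "associations.tsv")
  suh_counts <- count_peaks_within(genes, peak_sets$suh,
                                   radius = config$integrate$radius)
  master <- build_master_table(genes, de, clusters, pol, suh_counts,
                               logc0, tc)
  emit(master, "master_table.tsv")

  # gene-level logistic model of DE odds at t = 0
  gene_de <- master %>%
    group_by(.data$gene_id) %>%
    summarise(de = any(.data$q < config$de$q_cutoff, na.rm = TRUE),
              logc0 = mean(.data$logc0, na.rm = TRUE), .groups = "drop")
  t0_chip <- min(sc$chip_times)
  model_tbl <- gene_de %>%
    left_join(filter(gene_states, .data$time == t0_chip) %>%
                select("gene_id", polii_class = "state"), by = "gene_id") %>%
    left_join(filter(suh_counts, .data$time == t0_chip) %>%
                select("gene_id", "n_peaks"), by = "gene_id") %>%
    mutate(suh = as.integer(replace_na(.data$n_peaks, 0L) > 0),
           polii_class = replace_na(.data$polii_class, "UB"),
           logc0 = .data$logc0 - mean(.data$logc0, na.rm = TRUE))
  logistic <- tryCatch(fit_de_logistic(model_tbl),
                       error = function(e) NULL)
  logc0_tests <- tryCatch(
    logc0_class_tests(model_tbl$logc0, model_tbl$polii_class),
    error = function(e) NULL)
  report <- list(
    logistic = if (!is.null(logistic)) {
      list(coefficients = logistic$coefficients,
           separated = logistic$separated, n = logistic$n,
           n_events = logistic$n_events)
    },
    logc0_by_class = logc0_tests
  )
  report_path <- file.path(outdir, "model_report.json")
  jsonlite::write_json(report, report_path, digits = NA, auto_unbox = TRUE)
  written <- c(written, report_path)

  ## motifs -----------------------------------------------------------------
  motif_out <- NULL
  if (isTRUE(config$motifs$enabled)) {
    say("motifs")
    suh_pwm <- pwm_from_consensus(sc$suh_consensus, name = "suh")
    hairy_pwm <- pwm_from_consensus(sc$hairy_consensus, name = "hairy")
    matches <- bind_rows(
      scan_pwm(genome$sequence, suh_pwm,
               threshold = config$motifs$threshold_frac * suh_pwm$max_score),
      scan_pwm(genome$sequence, hairy_pwm,
               threshold = config$motifs$threshold_frac * hairy_pwm$max_score)
    )
    sps <- find_sps(filter(matches, .data$motif == "suh"),
                    motif_length = suh_pwm$length)
    counts <- motif_gene_counts(genes,
                                filter(matches, .data$motif == "hairy"),
                                window = config$motifs$window,
                                motif_length = hairy_pwm$length)
    emit(matches, "motif_matches.tsv")
    emit(sps, "sps.tsv")
    emit(counts$counts, "motif_gene_counts.tsv")
    motif_out <- list(matches = matches, sps = sps, counts = counts)
  }

  ## manifest ---------------------------------------------------------------
  manifest <- list(
    package = "notchpulse",
    package_version = as.character(utils::packageVersion("notchpulse")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = list(
      de = config$de, cluster = config$cluster, peaks = config$peaks,
      polii = config$polii, integrate = config$integrate,
      motifs = config$motifs,
      synth = list(n_genes = sc$n_genes, seed = sc$seed,
                   sigma = c(sc$sigma_c, sc$sigma_t, sc$sigma_r))
    ),
    files = lapply(setNames(nm = basename(written)), function(b) {
      unname(tools::md5sum(file.path(outdir, b)))
    }),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  say("done in ", round(manifest$elapsed_sec, 1), " s")

  invisible(list(
    config = config, genes = genes, expression = expr, chip = chip,
    genome = genome, ma = ma, tc = tc, de = de, logc0 = logc0,
    clusters = clusters, peaks = peak_sets, peak_areas = areas,
    polii = pol, gene_states = gene_states, associations = assoc,
    suh_counts = suh_counts, master = master, logistic = logistic,
    logc0_tests = logc0_tests, motifs = motif_out, manifest = manifest
  ))
}
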