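
# Standard-format readers/writers --------------------------------------------
#
# Coordinates are 0-based half-open in memory; GFF3 on disk is 1-based
# inclusive and the conversion happens here (via GRanges, which rtracklayer
# serializes correctly).

#' Write a genome sequence to FASTA
#'
#' @param sequence Named character vector of chromosome sequences (a single
#'   unnamed string is written as `chrS`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(sequence, path) {
  if (is.null(names(sequence))) names(sequence) <- "chrS"
  dna <- Biostrings::DNAStringSet(sequence)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Read a genome from FASTA as named character strings
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_genome_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dna), sub("\\s.*$", "", names(dna)))
}

#' Write gene models to GFF3
#'
#' Each transcript becomes an mRNA feature with a Parent gene feature.
#'
#' @param genes Gene-model tibble (`gene_id, transcript_id, chrom, start,
#'   end, strand`), 0-based half-open.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  assert_cols(genes, c("gene_id", "transcript_id", "chrom", "start", "end",
                       "strand"), "genes")
  g <- genes %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  gene_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id)
  tx_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1, genes$end),
    strand = genes$strand, type = "mRNA", ID = genes$transcript_id,
    Parent = genes$gene_id)
  rtracklayer::export(c(gene_gr, tx_gr), path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3 into the package's tibble form
#'
#' @param path GFF3 path.
#' @return Tibble `gene_id, transcript_id, chrom, start, end, strand, tss`
#'   with 0-based half-open coordinates.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tx <- gr[gr$type == "mRNA"]
  parent <- as.character(unlist(tx$Parent))
  tibble(
    gene_id = parent,
    transcript_id = as.character(tx$ID),
    chrom = as.character(GenomicRanges::seqnames(tx)),
    start = GenomicRanges::start(tx) - 1,
    end = as.numeric(GenomicRanges::end(tx)),
    strand = as.character(GenomicRanges::strand(tx))
  ) %>%
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end))
}

#' Write one (factor, timepoint, replicate) track to bedGraph
#'
#' @param track Probe track tibble filtered to a single (time, rep).
#' @param path Output path.
#' @param span Probe footprint in bp (interval written around each midpoint).
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path, span = 50) {
  assert_cols(track, c("chrom", "pos", "score"), "track")
  gr <- GenomicRanges::GRanges(
    track$chrom,
    IRanges::IRanges(pmax(track$pos - span %/% 2, 0) + 1,
                     track$pos + span %/% 2),
    score = track$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into probe-track form
#'
#' @param path bedGraph path.
#' @param time,rep Labels attached to the returned track.
#' @return Tibble `chrom, pos, time, rep, score` (pos = interval midpoint,
#'   0-based).
#' @export
read_track_bedgraph <- function(path, time = 0, rep = 1) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = (GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) %/% 2,
    time = time, rep = rep,
    score = gr$score
  ) %>% arrange(.data$chrom, .data$pos)
}

#' Write peaks to BED6 (+ area, max as extra columns)
#'
#' @param peaks Peak tibble from [call_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- tibble(
    chrom = peaks$chrom,
    start = format(peaks$start, scientific = FALSE, trim = TRUE),
    end = format(peaks$end, scientific = FALSE, trim = TRUE),
    name = sprintf("peak_t%g_%d", peaks$time, seq_len(nrow(peaks))),
    score = pmin(round(peaks$max * 100), 1000),
    strand = ".",
    area = peaks$area,
    max = peaks$max
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write motif matches to BED6 (score in bits x 100 as integer)
#' @param matches Match tibble from [scan_pwm()]; needs the motif length.
#' @param motif_length Motif length in bp.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches_bed <- function(matches, motif_length, path) {
  bed <- tibble(
    chrom = matches$chrom,
    start = matches$start,
    end = matches$start + motif_length,
    name = matches$motif,
    score = as.integer(round(matches$score * 100)),
    strand = matches$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
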