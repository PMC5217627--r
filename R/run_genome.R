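#' Run the full discovery pipeline on genome files and write reports
#'
#' Thin orchestration over [find_motif_pairs()]: reads a FASTA (or
#' GenBank) genome and optional gene annotations, runs the scan, and
#' writes two tab-separated reports into `out_dir`:
#' \describe{
#'   \item{`pairs.tsv`}{one row per reported pair direction: pattern,
#'     spacer length, totals before/after spacer reduction, cutoff and
#'     ratio, reverse-complement status, and (with annotations) the
#'     gene/intergenic/overlap percentages.}
#'   \item{`occurrences.tsv`}{one row per occurrence with 1-based
#'     inclusive coordinates, location class, nearest-gene distance and
#'     flanking orientation.}
#' }
#' Both files start with `#`-prefixed header lines echoing the full
#' configuration, so a report is reproducible from its own header.
#'
#' @param fasta Path to the genome FASTA (or GenBank flat file, from
#'   which annotations are also taken).
#' @param annotation Optional GFF3 path with gene features.
#' @param out_dir Output directory (created if needed).
#' @param genome_name Name written into the reports (default: file stem).
#' @inheritParams find_motif_pairs
#' @return The `pair_scan` object, invisibly.
#' @export
run_genome <- function(fasta, annotation = NULL, out_dir,
                       genome_name = NULL, scan = scan_params(),
                       alpha_family = 0.01, n_tests = 4^(2 * scan$k),
                       n_exact_max = 600, align = align_params(),
                       min_n = 6, merge = TRUE) {
  genome_name <- genome_name %||% sub("\\.[^.]*$", "", basename(fasta))
  is_gb <- grepl("\\.(gb|gbk|gbff|genbank)$", fasta, ignore.case = TRUE)
  genes <- NULL
  if (is_gb) {
    gb <- parse_genbank(fasta)
    genome <- gb$genome
    genes <- gb$genes
  } else {
    genome <- read_genome_fasta(fasta)
  }
  if (!is.null(annotation)) {
    genes <- read_annotation(annotation, format = "gff3",
                             seq_lengths = setNames(genome$length,
                                                    genome$record))
  }
  res <- find_motif_pairs(genome, scan = scan, alpha_family = alpha_family,
                          n_tests = n_tests, n_exact_max = n_exact_max,
                          align = align, genes = genes, min_n = min_n,
                          merge = merge)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- report_header(genome_name, scan, res$stats, align)
  write_pairs_report(res, genome_name,
                     file.path(out_dir, "pairs.tsv"), hdr)
  write_occurrence_report(res, genome_name, genes,
                          file.path(out_dir, "occurrences.tsv"), hdr)
  invisible(res)
}

report_header <- function(genome_name, scan, stats, align) {
  c(sprintf("# genome=%s", genome_name),
    sprintf("# k=%d dmin=%d dmax=%d K=%d", scan$k, scan$dmin, scan$dmax,
            scan$K),
    sprintf("# alpha_family=%g n_tests=%g alpha=%.6g n_exact_max=%d",
            stats$alpha_family, stats$n_tests, stats$alpha,
            stats$n_exact_max),
    sprintf("# identity_cutoff=%g match=%d mismatch=%d gap=%d gapless=%s",
            align$identity, align$match, align$mismatch, align$gap,
            align$gapless),
    "# coordinates=1-based inclusive")
}

write_pairs_report <- function(res, genome_name, path, hdr) {
  df <- tidy(res)
  out <- tibble(
    genome = rep(genome_name, nrow(df)),
    motifA = df$A, motifB = df$B, pattern = df$pattern, d = df$d,
    n = df$n, Initial_n = df$initial_fmax, Reduced_n = df$reduced_fmax,
    Difference = df$initial_fmax - df$reduced_fmax, Cutoff = df$cutoff,
    Reduced_n_over_Cutoff = round(df$ratio, 4),
    rc_significant = df$rc_significant)
  for (col in c("gene_pct", "intergenic_pct", "overlap_pct")) {
    if (col %in% names(df)) out[[col]] <- round(df[[col]], 2)
  }
  writeLines(hdr, path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

write_occurrence_report <- function(res, genome_name, genes, path, hdr) {
  occ <- res$occurrences
  out <- tibble(
    genome = rep(genome_name, nrow(occ)),
    record = occ$record,
    start = occ$start + 1L, # 1-based inclusive for reports
    end = occ$end,
    pattern = occ$pattern,
    class = if ("class" %in% names(occ)) occ$class else NA_character_,
    nearest_gene_distance = if ("nearest_gene_distance" %in% names(occ))
      occ$nearest_gene_distance else NA_integer_,
    orientation = if ("orientation" %in% names(occ)) occ$orientation
      else NA_character_)
  writeLines(hdr, path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
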