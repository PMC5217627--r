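#' Normalize a nucleotide sequence
#'
#' Uppercases and maps every character outside `{A,C,G,T,N}` (ambiguity
#' codes, gaps) to `N`.  K-mers containing `N` are excluded from counting,
#' so ambiguous stretches never contribute occurrences.
#'
#' @param x Character vector of sequences.
#' @return Character vector over `{A,C,G,T,N}`.
#' @export
normalize_sequence <- function(x) {
  x <- toupper(as.character(x))
  gsub("[^ACGTN]", "N", x, perl = TRUE)
}

#' Read a genome from a FASTA file
#'
#' Multi-record files (e.g. chromosomes plus plasmids of one genome) yield
#' one row per record; downstream counting aggregates over all rows of the
#' tibble, so a multi-chromosome genome is analyzed as a whole.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `record` (sequence id), `sequence`
#'   (normalized to `{A,C,G,T,N}`) and `length`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read FASTA file: ", path))
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) abort(paste0("invalid FASTA: ", conditionMessage(e))))
  if (length(ss) == 0) abort(paste0("empty FASTA file: ", path))
  seqs <- normalize_sequence(as.character(ss))
  ids <- sub("\\s.*$", "", names(ss))
  tibble(record = ids, sequence = unname(seqs), length = nchar(seqs))
}

#' Write a genome tibble to FASTA
#'
#' @param genome Tibble with `record` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$record))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

gene_feature_types <- c("CDS", "tRNA", "rRNA", "ncRNA", "tmRNA", "misc_RNA",
                        "ncRNA_gene", "rRNA_gene", "tRNA_gene")

#' Read gene annotations from GFF3 or GenBank
#'
#' Gene-level features (CDS and RNA genes) are returned as 0-based
#' half-open intervals; the 1-based inclusive coordinates of the source
#' formats are converted on read.  If no CDS/RNA features are present,
#' `gene` features are used as a fallback.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"genbank"`.
#' @param seq_lengths Optional named integer vector of record lengths; when
#'   given, intervals extending beyond a record are clamped with a warning.
#' @return Tibble with columns `record`, `start` (0-based inclusive),
#'   `end` (0-based exclusive), `strand` (`"+"`/`"-"`), `label`.
#' @export
read_annotation <- function(path, format = c("gff3", "genbank"),
                            seq_lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("cannot read annotation file: ", path))
  genes <- if (format == "gff3") read_annotation_gff3(path)
           else parse_genbank(path)$genes
  clamp_genes(genes, seq_lengths)
}

read_annotation_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) abort(paste0("unparseable GFF3: ", conditionMessage(e))))
  if (length(gr) == 0) {
    return(tibble(record = character(), start = integer(), end = integer(),
                  strand = character(), label = character()))
  }
  type <- as.character(gr$type)
  keep <- type %in% gene_feature_types
  if (!any(keep)) keep <- type %in% "gene"
  gr <- gr[keep]
  lab <- gr$ID %||% rep(NA_character_, length(gr))
  if (!is.null(gr$locus_tag)) {
    lt <- as.character(gr$locus_tag)
    lab <- ifelse(is.na(lab) & !is.na(lt), lt, lab)
  }
  tibble(
    record = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L, # 1-based incl -> 0-based half-open
    end = BiocGenerics::end(gr),
    strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-", "-", "+"),
    label = as.character(lab)
  ) |> arrange(.data$record, .data$start)
}

clamp_genes <- function(genes, seq_lengths) {
  if (is.null(seq_lengths) || nrow(genes) == 0) return(genes)
  len <- seq_lengths[genes$record]
  bad <- !is.na(len) & (genes$end > len | genes$start < 0)
  if (any(bad)) {
    warn(sprintf("%d gene interval(s) extend beyond their record; clamped",
                 sum(bad)))
    genes$start <- pmax(genes$start, 0L)
    genes$end <- as.integer(pmin(genes$end, ifelse(is.na(len), genes$end, len)))
    genes <- genes[genes$start < genes$end, , drop = FALSE]
  }
  genes
}

#' Read a GenBank flat file (sequence and gene features)
#'
#' A minimal parser for the GenBank flat-file format: record ids from
#' LOCUS/ACCESSION, gene-level features (CDS, tRNA, rRNA, ncRNA, tmRNA)
#' from the FEATURES table, and the sequence from ORIGIN.  Compound
#' locations (`join(...)`, `complement(...)`) are collapsed to their
#' spanning interval; `complement` sets the minus strand.
#'
#' @param path Path to a GenBank flat file.
#' @return A list with `genome` (tibble as [read_genome_fasta()]) and
#'   `genes` (tibble as [read_annotation()]).
#' @export
parse_genbank <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read GenBank file: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(paste0("empty GenBank file: ", path))
  rec_starts <- grep("^LOCUS", lines)
  if (length(rec_starts) == 0) abort("unparseable GenBank file: no LOCUS line")
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))
  genomes <- list(); genes <- list()
  for (r in seq_along(rec_starts)) {
    block <- lines[rec_starts[r]:rec_ends[r]]
    id <- strsplit(trimws(sub("^LOCUS\\s+", "", block[1])), "\\s+")[[1]][1]
    # sequence
    oi <- grep("^ORIGIN", block)
    seq <- ""
    if (length(oi) == 1) {
      body <- block[(oi + 1):length(block)]
      body <- body[!grepl("^//", body)]
      seq <- paste(gsub("[^A-Za-z]", "", body), collapse = "")
    }
    seq <- normalize_sequence(seq)
    genomes[[r]] <- tibble(record = id, sequence = seq, length = nchar(seq))
    # features
    fi <- grep("^FEATURES", block)
    if (length(fi) == 1) {
      fend <- if (length(oi) == 1) oi - 1L else length(block)
      fb <- block[(fi + 1):fend]
      is_feat <- grepl("^ {5}\\S", fb)
      idx <- which(is_feat)
      if (length(idx) > 0) {
        out <- vector("list", length(idx))
        for (q in seq_along(idx)) {
          ln <- fb[idx[q]]
          type <- sub("^ +", "", substr(ln, 1, 21))
          type <- sub(" +$", "", type)
          if (!(type %in% gene_feature_types)) next
          # location may continue over lines until a qualifier (/) starts
          loc <- trimws(substr(ln, 22, nchar(ln)))
          nx <- idx[q] + 1L
          while (nx <= length(fb) && !is_feat[nx] &&
                 !grepl("^ +/", fb[nx])) {
            loc <- paste0(loc, trimws(fb[nx])); nx <- nx + 1L
          }
          strand <- if (grepl("complement", loc)) "-" else "+"
          pos <- as.numeric(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
          if (length(pos) == 0) next
          # label from /locus_tag or /gene qualifier if present
          lab <- NA_character_
          qx <- idx[q] + 1L
          while (qx <= length(fb) && !is_feat[qx]) {
            mm <- regmatches(fb[qx],
                             regexec("/(locus_tag|gene)=\"([^\"]+)\"", fb[qx]))[[1]]
            if (length(mm) == 3 && is.na(lab)) lab <- mm[3]
            qx <- qx + 1L
          }
          out[[q]] <- tibble(record = id, start = as.integer(min(pos)) - 1L,
                             end = as.integer(max(pos)), strand = strand,
                             label = lab)
        }
        genes[[r]] <- bind_rows(out)
      }
    }
  }
  genome <- bind_rows(genomes)
  gene_tbl <- bind_rows(genes)
  if (nrow(gene_tbl) == 0) {
    gene_tbl <- tibble(record = character(), start = integer(),
                       end = integer(), strand = character(),
                       label = character())
  }
  list(genome = genome,
       genes = clamp_genes(arrange(gene_tbl, .data$record, .data$start),
                           setNames(genome$length, genome$record)))
}

#' Reverse complement
#'
#' @param s Character vector of sequences over `{A,C,G,T,N}`.
#' @return Reverse complement of each element; `N` maps to `N`.
#' @examples
#' revcomp("AAGGA") # "TCCTT"
#' @export
revcomp <- function(s) {
  if (any(grepl("[^ACGTN]", s))) abort("sequences must be over {A,C,G,T,N}")
  if (length(s) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Reverse-complement of a spaced motif pair
#'
#' The pattern `A (N)_d B` read on the opposite strand is
#' `revcomp(B) (N)_d revcomp(A)`: the spacer length is preserved and the
#' motifs swap and complement.  `rc_pair` is an involution; pairs fixed by
#' it (e.g. `CGAAA (N)_19 TTTCG`) are palindromic.
#'
#' @param A,B Motif k-mers (character vectors, recycled).
#' @param d Spacer length(s).
#' @return Tibble with columns `A`, `B`, `d` of the opposite-strand pair.
#' @examples
#' rc_pair("AAGGA", "ATGAA", 6) # TTCAT (N)6 TCCTT
#' @export
rc_pair <- function(A, B, d) {
  newA <- revcomp(B)
  newB <- revcomp(A)
  tibble(A = newA, B = newB, d = as.integer(d))
}

#' Test whether strings are valid k-mers
#'
#' @param s Character vector.
#' @param k Required length (default: length of the first element).
#' @return Logical: `TRUE` where `s` has length `k` and only `{A,C,G,T}`
#'   (k-mers containing `N` are not counted).
#' @export
valid_kmer <- function(s, k = nchar(s[1])) {
  nchar(s) == k & grepl("^[ACGT]*$", s)
}

#' Pattern string for a motif pair
#'
#' @param A,B Motif k-mers. @param d Spacer length.
#' @return Character like `"AAGGA(N)6ATGAA"`.
#' @export
pair_pattern <- function(A, B, d) sprintf("%s(N)%d%s", A, d, B)

#' Canonical pattern of a pair and its reverse complement
#'
#' A pair and its reverse complement describe the same double-stranded
#' pattern; the canonical form is the lexicographically smaller of the two
#' pattern strings, letting reports list one strand only.
#'
#' @inheritParams pair_pattern
#' @return Character vector of canonical pattern strings.
#' @export
canonical_pattern <- function(A, B, d) {
  fwd <- pair_pattern(A, B, d)
  rc <- rc_pair(A, B, d)
  rev <- pair_pattern(rc$A, rc$B, d)
  ifelse(fwd <= rev, fwd, rev)
}
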