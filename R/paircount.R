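codes_to_kmers <- function(code, k) {
  # pair code = A_code * 4^k + B_code; bases big-endian, 2 bits each
  bases <- c("A", "C", "G", "T")
  decode1 <- function(x) {
    cols <- vector("list", k)
    for (pos in k:1) {
      cols[[pos]] <- bases[x %% 4L + 1L]
      x <- x %/% 4L
    }
    do.call(paste0, cols)
  }
  nk <- 4L^k
  list(A = decode1(code %/% nk), B = decode1(code %% nk))
}

kmers_to_code <- function(A, B, k) {
  enc1 <- function(s) {
    m <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T")) - 1L
    if (anyNA(m)) abort("motif k-mers must be over {A,C,G,T}")
    sum(m * 4L^((k - 1):0))
  }
  vapply(A, enc1, 0) * 4L^k + vapply(B, enc1, 0)
}

check_genome <- function(genome) {
  if (!is.data.frame(genome) || !all(c("record", "sequence") %in% names(genome)))
    abort("`genome` must be a data frame with columns `record` and `sequence`")
  if (any(grepl("[^ACGTN]", genome$sequence)))
    abort("sequences must be normalized to {A,C,G,T,N}; see normalize_sequence()")
  genome
}

#' Raw pair counts at every spacer distance
#'
#' Counts, for every ordered k-mer pair `(A, B)` and every spacer length
#' `d` in the scan range, the occurrences of `A` followed after `d`
#' intervening nucleotides by `B` on the direct strand of all records.
#' Duplicate spacers are *not* collapsed here (see
#' [unique_spacer_histogram()]); k-mers containing `N` are skipped.
#'
#' @param genome Genome tibble (`record`, `sequence`).
#' @param params A [scan_params()] object.
#' @return Tibble with columns `A`, `B`, `d`, `count` (non-zero rows only).
#' @export
scan_pair_counts <- function(genome, params = scan_params()) {
  check_genome(genome)
  df <- cpp_scan_raw_table(genome$sequence, params$k, params$dmin, params$dmax)
  km <- codes_to_kmers(df$code, params$k)
  tibble(A = km$A, B = km$B, d = df$d, count = df$count)
}

#' Per-pair scan summaries (raw counts)
#'
#' One row per ordered pair with any occurrence: the raw total `n_raw`
#' over the spacer range, the raw maximum `fmax_raw` at any single
#' distance, and `occupied`, the number of distances with at least one
#' occurrence.  `occupied` is a lower bound on the unique-spacer total and
#' drives the conservative candidate screen in [find_motif_pairs()].
#'
#' @inheritParams scan_pair_counts
#' @return Tibble `A`, `B`, `n_raw`, `fmax_raw`, `occupied`.
#' @export
scan_pair_stats <- function(genome, params = scan_params()) {
  check_genome(genome)
  df <- cpp_scan_stats(genome$sequence, params$k, params$dmin, params$dmax)
  km <- codes_to_kmers(df$code, params$k)
  tibble(A = km$A, B = km$B, code = df$code, n_raw = df$n_raw,
         fmax_raw = df$fmax_raw, occupied = df$occupied)
}

#' All occurrences of one motif pair
#'
#' @inheritParams scan_pair_counts
#' @param A,B Motif k-mers over `{A,C,G,T}`.
#' @return Tibble in genome order with `record`, `start` (0-based position
#'   of the first base of `A`), `d` (spacer length) and `spacer` (the `d`
#'   intervening nucleotides).  `B` starts at `start + k + d`.
#' @export
collect_occurrences <- function(genome, A, B, params = scan_params()) {
  check_genome(genome)
  if (!valid_kmer(A, params$k) || !valid_kmer(B, params$k))
    abort("`A` and `B` must be k-mers over {A,C,G,T} of length `params$k`")
  df <- cpp_collect_occurrences(genome$sequence, params$k, A, B,
                                params$dmin, params$dmax)
  tibble(record = genome$record[df$record_index],
         start = as.integer(df$start), d = as.integer(df$d),
         spacer = as.character(df$spacer))
}

#' Unique-spacer histogram of a motif pair
#'
#' Collapses occurrences with exactly the same spacer sequence (at the
#' same distance) to a single count — segments duplicated verbatim are
#' counted once — and derives the totals of the distance-preference test:
#' `n` (unique-spacer total over all distances), the modal distance(s)
#' `d_star`, and `fmax = counts[d_star]`.  Ties for the maximum are all
#' retained.
#'
#' @param occurrences Tibble from [collect_occurrences()] (all for one
#'   ordered pair).
#' @param params A [scan_params()] object.
#' @param A,B Optional motif labels stored on the result.
#' @return A `pair_histogram` object: list with `A`, `B`, `counts`
#'   (tibble `d`, `count` over the full range), `n`, `d_star` (integer
#'   vector, ties included), `fmax`.
#' @export
unique_spacer_histogram <- function(occurrences, params = scan_params(),
                                    A = NA_character_, B = NA_character_) {
  d_range <- params$dmin:params$dmax
  if (nrow(occurrences) > 0) {
    uni <- distinct(occurrences, .data$d, .data$spacer)
    cnt <- table(factor(uni$d, levels = d_range))
  } else {
    cnt <- table(factor(integer(), levels = d_range))
  }
  counts <- tibble(d = d_range, count = as.integer(cnt))
  fmax <- max(counts$count)
  structure(list(A = A, B = B, counts = counts, n = sum(counts$count),
                 d_star = counts$d[counts$count == fmax & fmax > 0],
                 fmax = fmax),
            class = "pair_histogram")
}

#' @export
print.pair_histogram <- function(x, ...) {
  cat(sprintf("<pair_histogram> %s vs %s: n = %d, fmax = %d at d = %s\n",
              x$A, x$B, x$n, x$fmax,
              paste(x$d_star, collapse = ", ")))
  invisible(x)
}

#' @rdname unique_spacer_histogram
#' @param x A `pair_histogram`.
#' @param ... Unused.
#' @export
tidy.pair_histogram <- function(x, ...) {
  mutate(x$counts, A = x$A, B = x$B, modal = .data$d %in% x$d_star)
}
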