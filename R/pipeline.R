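# Dedup + significance decision for one candidate pair at one modal
# distance.  Exact-duplicate spacers were already collapsed in the
# histogram; here near-duplicates (>= identity threshold) reduce fmax
# further.  The cutoff stays fixed at fcut(n) from the pre-dedup total.
evaluate_at_distance <- function(genome, A, B, d, n, fmax, cutoff, scan,
                                 align) {
  occ <- collect_occurrences(genome, A, B, scan_params(scan$k, d, d))
  occ_uni <- distinct(occ, .data$spacer, .keep_all = TRUE)
  red <- greedy_reduce(occ_uni$spacer, align)
  reduced_fmax <- nrow(occ_uni) - red$removed
  retained <- occ_uni[red$keep, , drop = FALSE]
  tibble(A = A, B = B, d = as.integer(d), n = as.integer(n),
         initial_fmax = nrow(occ_uni),
         reduced_fmax = as.integer(reduced_fmax),
         cutoff = as.integer(cutoff),
         significant = reduced_fmax >= cutoff,
         occurrences = list(retained))
}

#' Evaluate a single motif pair against the distance-preference test
#'
#' Runs the full per-pair procedure: collect occurrences over the spacer
#' range, collapse identical spacers, locate the modal distance(s), align
#' and greedily remove near-duplicate spacers at each modal distance, and
#' compare the reduced maximum against the cutoff `fcut(n)` (computed from
#' the pre-reduction unique-spacer total `n` and not recomputed after the
#' reduction).  Ties for the modal distance are each evaluated.
#'
#' @param genome Genome tibble (`record`, `sequence`).
#' @param A,B Motif k-mers.
#' @param scan A [scan_params()] object.
#' @param stats A [stat_params()] object (defaults to the Bonferroni
#'   setting for all ordered pairs of length `scan$k`).
#' @param align An [align_params()] object.
#' @return A tibble with one row per significant modal distance (columns
#'   `A`, `B`, `d`, `n`, `initial_fmax`, `reduced_fmax`, `cutoff`,
#'   `significant`, list-column `occurrences` of retained occurrences), or
#'   `NULL` when the pair is not significant at any modal distance.
#'   Reverse-complement corroboration is *not* applied here; see
#'   [require_rc()].
#' @export
evaluate_pair <- function(genome, A, B, scan = scan_params(),
                          stats = stat_params(K = scan$K,
                                              n_tests = 4^(2 * scan$k)),
                          align = align_params()) {
  check_genome(genome)
  occ <- collect_occurrences(genome, A, B, scan)
  hist <- unique_spacer_histogram(occ, scan, A = A, B = B)
  if (hist$n == 0 || hist$fmax == 0) return(NULL)
  cutoff <- fcut(hist$n, stats$K, stats)
  if (hist$fmax < cutoff) return(NULL)
  rows <- bind_rows(lapply(hist$d_star, function(d) {
    evaluate_at_distance(genome, A, B, d, hist$n, hist$fmax, cutoff,
                         scan, align)
  }))
  rows <- filter(rows, .data$significant)
  if (nrow(rows) == 0) NULL else rows
}

#' Reverse-complement corroboration filter
#'
#' A dispersed double-stranded motif should be over-represented on both
#' strands, so a candidate pair is kept only when its reverse-complement
#' pair is also significant at the same spacer distance.  Palindromic
#' pairs (equal to their own reverse complement) satisfy the requirement
#' by themselves.
#'
#' @param pairs Tibble of significant candidates with columns `A`, `B`,
#'   `d` (one row per candidate; both orderings of a pattern appear as
#'   separate rows).
#' @return The input filtered to corroborated rows, with an added
#'   `rc_significant` column (all `TRUE`).
#' @export
require_rc <- function(pairs) {
  if (nrow(pairs) == 0) return(mutate(pairs, rc_significant = logical(0)))
  key <- paste(pairs$A, pairs$B, pairs$d)
  rc <- rc_pair(pairs$A, pairs$B, pairs$d)
  rckey <- paste(rc$A, rc$B, rc$d)
  filter(mutate(pairs, rc_significant = rckey %in% key), .data$rc_significant)
}

#' Merge motif pairs built from overlapping k-mers
#'
#' Pairs of overlapping pentamers carved out of one longer underlying
#' pattern occur at (almost) the same genomic loci, shifted by a constant
#' offset.  Two pairs are merged when, for some offset `|o| <= k - 1`, at
#' least `min_share` of the smaller pair's occurrence starts coincide
#' with the other's shifted starts; connected groups are combined and a
#' consensus pattern spanning the union of motif positions is reported.
#'
#' @param pairs Tibble of reported pairs (columns `A`, `B`, `d`, and
#'   list-column `occurrences` with `record` and `start`).
#' @param k Motif length.
#' @param min_share Minimum shared-locus fraction (default 0.9).
#' @return Tibble with one row per merged motif: `pattern` (consensus,
#'   e.g. `"GGGACAG(N)15TGTCCC"`), `n_members`, `members` (list of member
#'   pattern strings), `n_occurrences` (distinct merged loci).
#' @export
merge_overlapping <- function(pairs, k = 5, min_share = 0.9) {
  if (nrow(pairs) == 0) {
    return(tibble(pattern = character(), n_members = integer(),
                  members = list(), n_occurrences = integer()))
  }
  m <- nrow(pairs)
  locs <- lapply(pairs$occurrences,
                 function(o) paste(o$record, o$start, sep = "@"))
  starts <- lapply(pairs$occurrences, function(o) o$start)
  recs <- lapply(pairs$occurrences, function(o) o$record)
  offsets <- -(k - 1):(k - 1)
  best_offset <- function(i, j) {
    # offset o such that member j's starts = member i's starts + o
    sh <- vapply(offsets, function(o) {
      length(intersect(paste(recs[[j]], starts[[j]], sep = "@"),
                       paste(recs[[i]], starts[[i]] + o, sep = "@")))
    }, 0L)
    list(o = offsets[which.max(sh)],
         share = max(sh) / min(length(starts[[i]]), length(starts[[j]])))
  }
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  off <- matrix(NA_integer_, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      b <- best_offset(i, j)
      if (b$share >= min_share) {
        off[i, j] <- b$o
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(m), find, 0L)
  out <- lapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    base <- idx[1]
    # offsets of every member relative to the base member
    rel <- vapply(idx, function(j) {
      if (j == base) return(0L)
      as.integer(best_offset(base, j)$o)
    }, 0L)
    cons <- consensus_pattern(pairs$A[idx], pairs$B[idx], pairs$d[idx], rel, k)
    merged_locs <- unique(unlist(lapply(seq_along(idx), function(q) {
      paste(recs[[idx[q]]], starts[[idx[q]]] - rel[q], sep = "@")
    })))
    tibble(pattern = cons, n_members = length(idx),
           members = list(pair_pattern(pairs$A[idx], pairs$B[idx],
                                       pairs$d[idx])),
           n_occurrences = length(merged_locs))
  })
  bind_rows(out)
}

# Union of member motif letters in the base member's coordinates; gaps of
# unconstrained positions are written as (N)g.
consensus_pattern <- function(A, B, d, rel, k) {
  lo <- min(rel)
  hi <- max(rel + 2L * k + d)
  slots <- rep(NA_character_, hi - lo)
  put <- function(s, at) {
    ch <- strsplit(s, "")[[1]]
    for (q in seq_along(ch)) {
      p <- at + q - lo # 1-based slot
      if (is.na(slots[p])) slots[p] <<- ch[q]
    }
  }
  for (i in seq_along(A)) {
    put(A[i], rel[i])
    put(B[i], rel[i] + k + d[i])
  }
  r <- rle(!is.na(slots))
  pos <- 1L
  parts <- character(0)
  for (q in seq_along(r$lengths)) {
    len <- r$lengths[q]
    if (r$values[q]) {
      parts <- c(parts, paste(slots[pos:(pos + len - 1)], collapse = ""))
    } else {
      parts <- c(parts, sprintf("(N)%d", len))
    }
    pos <- pos + len
  }
  paste(parts, collapse = "")
}

#' Genome-wide spaced motif-pair discovery
#'
#' The full discovery pipeline over every ordered k-mer pair:
#' \enumerate{
#'   \item scan all records for raw pair counts at every spacer distance
#'     (direct strand; opposite-strand patterns are covered because each
#'     reverse-complement pair is itself one of the tested pairs);
#'   \item screen candidates conservatively: a pair can only be
#'     significant if its raw maximum reaches `fcut(occupied)`, where
#'     `occupied` (number of non-empty distances) is a lower bound on the
#'     unique-spacer total;
#'   \item recount candidates with identical spacers collapsed, locate
#'     modal distances and test `fmax >= fcut(n)`;
#'   \item align spacers at each modal distance and greedily remove
#'     near-duplicates (segmental duplications), re-testing the reduced
#'     maximum against the unchanged cutoff;
#'   \item require the reverse-complement pair to be significant at the
#'     same distance;
#'   \item merge pairs built from overlapping k-mers into consensus
#'     patterns, and classify occurrences against gene annotations when
#'     provided.
#' }
#'
#' @param genome Genome tibble (`record`, `sequence`); all rows are
#'   aggregated as one genome.
#' @param scan A [scan_params()] object.
#' @param alpha_family Family-wise error rate (Bonferroni-corrected over
#'   `n_tests`).
#' @param n_tests Number of hypotheses (default: all ordered `k`-mer
#'   pairs, `4^(2k)`).
#' @param n_exact_max Switchover from exact to approximate cutoffs.
#' @param align An [align_params()] object (spacer dedup).
#' @param genes Optional gene annotation tibble (see [read_annotation()])
#'   for location statistics.
#' @param min_n Pairs with fewer total occurrences are skipped outright
#'   (6 is the smallest total with an attainable cutoff at the defaults).
#' @param merge Merge overlapping-pentamer pairs into consensus patterns?
#' @return An object of class `pair_scan`: list with `pairs` (reported
#'   pairs, one row per direction), `merged` (consensus patterns),
#'   `occurrences` (per-occurrence table), `candidates` (all pairs that
#'   reached the dedup stage, with their outcome), `stage_counts`, and the
#'   parameter objects.  `tidy()` returns the pair table, `glance()` a
#'   one-row summary.
#' @export
find_motif_pairs <- function(genome, scan = scan_params(),
                             alpha_family = 0.01,
                             n_tests = 4^(2 * scan$k),
                             n_exact_max = 600,
                             align = align_params(), genes = NULL,
                             min_n = 6, merge = TRUE) {
  check_genome(genome)
  stats <- stat_params(K = scan$K, alpha_family = alpha_family,
                       n_tests = n_tests, n_exact_max = n_exact_max)
  raw <- as_tibble(cpp_scan_stats(genome$sequence, scan$k, scan$dmin,
                                  scan$dmax))
  stage <- c(pairs_seen = nrow(raw))

  scr <- filter(raw, .data$n_raw >= min_n,
                .data$fmax_raw >= fcut(.data$occupied, stats$K, stats))
  if (nrow(scr) > 0) {
    km <- codes_to_kmers(scr$code, scan$k)
    scr <- mutate(scr, A = km$A, B = km$B)
  } else {
    scr <- mutate(scr, A = character(0), B = character(0))
  }
  stage["screened"] <- nrow(scr)

  cand <- empty_candidates()
  if (nrow(scr) > 0) {
    uniq <- cpp_candidate_histograms(genome$sequence, scan$k, scan$dmin,
                                     scan$dmax, as.integer(scr$code))
    n_u <- as.integer(rowSums(uniq))
    fmax_u <- as.integer(do.call(pmax, lapply(seq_len(ncol(uniq)),
                                              function(j) uniq[, j])))
    cut_u <- fcut(n_u, stats$K, stats)
    pre <- which(fmax_u >= cut_u & n_u >= min_n)
    stage["pre_dedup_significant"] <- length(pre)
    rows <- lapply(pre, function(i) {
      ds <- scan$dmin - 1L + which(uniq[i, ] == fmax_u[i])
      bind_rows(lapply(ds, function(d) {
        evaluate_at_distance(genome, scr$A[i], scr$B[i], d, n_u[i],
                             fmax_u[i], cut_u[i], scan, align)
      }))
    })
    cand <- bind_rows(rows)
  } else {
    stage["pre_dedup_significant"] <- 0L
  }

  sig <- if (nrow(cand) > 0) filter(cand, .data$significant)
         else cand
  stage["post_dedup_significant"] <- nrow(sig)
  rep_pairs <- require_rc(sig)
  stage["rc_corroborated"] <- nrow(rep_pairs)

  if (nrow(rep_pairs) > 0) {
    rep_pairs <- mutate(rep_pairs,
      pattern = pair_pattern(.data$A, .data$B, .data$d),
      canonical = canonical_pattern(.data$A, .data$B, .data$d),
      ratio = .data$reduced_fmax / .data$cutoff)
  } else {
    rep_pairs <- mutate(rep_pairs, pattern = character(0),
                        canonical = character(0), ratio = numeric(0))
  }

  occ_tbl <- pair_occurrence_table(rep_pairs, scan$k)
  merged <- if (merge) merge_overlapping(rep_pairs, k = scan$k)
            else merge_overlapping(rep_pairs[0, ], k = scan$k)

  location <- NULL
  if (!is.null(genes) && nrow(rep_pairs) > 0) {
    occ_tbl <- annotate_occurrences(occ_tbl, genes)
    location <- occ_tbl |>
      group_by(.data$pattern) |>
      summarise(gene_pct = 100 * mean(.data$class == "gene"),
                intergenic_pct = 100 * mean(.data$class == "intergenic"),
                overlap_pct = 100 * mean(.data$class == "overlap"),
                .groups = "drop")
    rep_pairs <- left_join(rep_pairs, location, by = "pattern")
  }

  structure(list(pairs = rep_pairs, merged = merged, occurrences = occ_tbl,
                 candidates = cand, stage_counts = stage, scan = scan,
                 stats = stats, align = align,
                 genome_length = sum(nchar(genome$sequence)),
                 n_records = nrow(genome)),
            class = "pair_scan")
}

empty_candidates <- function() {
  tibble(A = character(), B = character(), d = integer(), n = integer(),
         initial_fmax = integer(), reduced_fmax = integer(),
         cutoff = integer(), significant = logical(),
         occurrences = list())
}

pair_occurrence_table <- function(pairs, k) {
  if (nrow(pairs) == 0) {
    return(tibble(pattern = character(), record = character(),
                  start = integer(), end = integer(), d = integer()))
  }
  bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
    o <- pairs$occurrences[[i]]
    tibble(pattern = pairs$pattern[i], record = o$record,
           start = o$start, end = o$start + 2L * k + pairs$d[i],
           d = pairs$d[i])
  }))
}

#' @export
print.pair_scan <- function(x, ...) {
  cat(sprintf(
    "<pair_scan> %d record(s), %s bp; k = %d, d in [%d, %d]\n",
    x$n_records, format(x$genome_length, big.mark = ","), x$scan$k,
    x$scan$dmin, x$scan$dmax))
  sc <- x$stage_counts
  cat(sprintf(
    "  %d pairs seen -> %d screened -> %d significant pre-dedup -> %d post-dedup -> %d rc-corroborated\n",
    sc["pairs_seen"], sc["screened"], sc["pre_dedup_significant"],
    sc["post_dedup_significant"], sc["rc_corroborated"]))
  if (nrow(x$pairs) > 0) {
    cat(sprintf("  %d reported pair(s), %d merged pattern(s)\n",
                nrow(x$pairs), nrow(x$merged)))
    print(head(select(x$pairs, -"occurrences"), 10))
  } else {
    cat("  no significant motif pairs\n")
  }
  invisible(x)
}

#' @rdname find_motif_pairs
#' @param x A `pair_scan` object.
#' @param ... Unused.
#' @export
tidy.pair_scan <- function(x, ...) select(x$pairs, -"occurrences")

#' @rdname find_motif_pairs
#' @export
glance.pair_scan <- function(x, ...) {
  tibble(n_records = x$n_records, genome_length = x$genome_length,
         k = x$scan$k, K = x$scan$K, alpha = x$stats$alpha,
         pairs_screened = unname(x$stage_counts["screened"]),
         pairs_reported = nrow(x$pairs),
         patterns_merged = nrow(x$merged))
}
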