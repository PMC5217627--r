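# Independent reference implementations used as oracles; deliberately
# naive and free of any code shared with the package internals.

make_genome <- function(...) {
  seqs <- c(...)
  tibble::tibble(record = paste0("r", seq_along(seqs)), sequence = seqs,
                 length = nchar(seqs))
}

random_dna <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# brute-force raw pair counts: double loop over positions and distances
naive_scan_counts <- function(seqs, k, dmin, dmax) {
  out <- list()
  for (s in seqs) {
    L <- nchar(s)
    for (i in seq_len(max(0, L - 2 * k - dmin + 1))) {
      A <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", A)) next
      for (d in dmin:dmax) {
        j <- i + k + d
        if (j + k - 1 > L) break
        B <- substr(s, j, j + k - 1)
        if (grepl("[^ACGT]", B)) next
        key <- paste(A, B, d)
        out[[key]] <- (out[[key]] %||% 0L) + 1L
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(A = character(), B = character(), d = integer(),
                          count = integer()))
  }
  parts <- strsplit(names(out), " ")
  tibble::tibble(A = vapply(parts, `[`, "", 1),
                 B = vapply(parts, `[`, "", 2),
                 d = as.integer(vapply(parts, `[`, "", 3)),
                 count = unlist(out, use.names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive occupancy distribution: throw n labelled balls into K urns,
# enumerate all K^n outcomes
enum_fmax_cdf <- function(n, K, x) {
  if (n == 0) return(1)
  grid <- do.call(expand.grid, rep(list(seq_len(K)), n))
  below <- apply(grid, 1, function(balls) max(tabulate(balls, K)) < x)
  mean(below)
}

# brute-force global alignment: enumerate all alignments recursively,
# return max score and, among score-optimal, max identity
brute_nw <- function(s1, s2, match = 1, mismatch = -1, gap = -2) {
  best <- new.env()
  best$score <- -Inf; best$ident <- -Inf
  rec <- function(i, j, score, m, len) {
    if (i > nchar(s1) && j > nchar(s2)) {
      id <- m / len
      if (score > best$score) {
        best$score <- score; best$ident <- id
      } else if (score == best$score && id > best$ident) {
        best$ident <- id
      }
      return(invisible())
    }
    if (i <= nchar(s1) && j <= nchar(s2)) {
      eq <- substr(s1, i, i) == substr(s2, j, j)
      rec(i + 1, j + 1, score + if (eq) match else mismatch,
          m + eq, len + 1)
    }
    if (i <= nchar(s1)) rec(i + 1, j, score + gap, m, len + 1)
    if (j <= nchar(s2)) rec(i, j + 1, score + gap, m, len + 1)
  }
  rec(1, 1, 0, 0, 0)
  list(score = best$score, identity = best$ident)
}
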