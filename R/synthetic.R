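#' Specification of a planted motif pair
#'
#' Describes copies of the pattern `A (N)_d B` to write into a synthetic
#' genome at non-overlapping random positions.  Spacer modes emulate the
#' data structures the scan must separate: `"distinct"` — independent
#' random spacers (a genuine distance-constrained motif, "variable
#' sequence, conserved length"); `"duplicated"` — every copy carries one
#' identical spacer (a verbatim segmental duplication, collapsed already
#' by unique-spacer counting); `"mutant"` — spacers are point-mutant
#' relatives of one template at `mutant_identity` expected identity (a
#' diverged duplication family, removed by the alignment step).
#'
#' @param A,B Motif k-mers.
#' @param d Spacer length.
#' @param copies Number of planted copies (>= 1).
#' @param spacer_mode `"distinct"`, `"duplicated"` or `"mutant"`.
#' @param strands `"direct"` (all copies on the plus strand) or `"both"`
#'   (copies alternate strands; minus-strand copies are written as the
#'   reverse-complement pattern).
#' @param mutant_identity Expected per-site identity of mutant-family
#'   spacers to their template.
#' @return A `plant_spec` object.
#' @export
plant_spec <- function(A, B, d, copies,
                       spacer_mode = c("distinct", "duplicated", "mutant"),
                       strands = c("direct", "both"),
                       mutant_identity = 0.8) {
  spacer_mode <- match.arg(spacer_mode)
  strands <- match.arg(strands)
  stopifnot(copies >= 1, d >= 0, nchar(A) == nchar(B))
  if (!valid_kmer(A, nchar(A)) || !valid_kmer(B, nchar(B)))
    abort("planted motifs must be over {A,C,G,T}")
  structure(list(A = A, B = B, d = as.integer(d),
                 copies = as.integer(copies), spacer_mode = spacer_mode,
                 strands = strands, mutant_identity = mutant_identity),
            class = "plant_spec")
}

random_seq <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

plant_spacers <- function(spec, gc) {
  bases <- c("A", "C", "G", "T")
  switch(spec$spacer_mode,
    distinct = {
      out <- character(0)
      while (length(out) < spec$copies) {
        cand <- vapply(seq_len(spec$copies - length(out)),
                       function(i) random_seq(spec$d, gc), "")
        out <- unique(c(out, cand))
      }
      out[seq_len(spec$copies)]
    },
    duplicated = rep(random_seq(spec$d, gc), spec$copies),
    mutant = {
      template <- strsplit(random_seq(spec$d, gc), "")[[1]]
      vapply(seq_len(spec$copies), function(i) {
        hit <- runif(spec$d) > spec$mutant_identity
        s <- template
        if (any(hit)) {
          s[hit] <- vapply(s[hit],
                           function(b) sample(setdiff(bases, b), 1), "")
        }
        paste(s, collapse = "")
      }, "")
    })
}

#' Generate a synthetic genome with planted motif pairs
#'
#' Background is drawn i.i.d. with the given GC content (or from an
#' order-1 Markov chain when `markov` is supplied); planted loci are
#' placed uniformly at random without overlap, and every planted locus is
#' recorded in a truth table.  Fully reproducible from `seed`.
#'
#' @param length Genome length in bp.
#' @param gc GC fraction of the background (and of random spacers).
#' @param plants List of [plant_spec()] objects.
#' @param seed Integer seed (local RNG; global state untouched).
#' @param record Record id of the single output sequence.
#' @param markov Optional 4x4 transition matrix (rows/cols A,C,G,T in that
#'   order, rows summing to 1) for an order-1 Markov background.
#' @return List with `genome` (tibble `record`, `sequence`, `length`) and
#'   `truth` (tibble `record`, `start` (0-based), `strand`, `A`, `B`,
#'   `d`, `spacer`; `A`, `B`, `spacer` are given as planted, i.e. for
#'   minus-strand copies the direct strand carries the reverse-complement
#'   pattern).
#' @export
generate_genome <- function(length, gc = 0.5, plants = list(), seed,
                            record = "synthetic", markov = NULL) {
  if (inherits(plants, "plant_spec")) plants <- list(plants)
  footprint <- sum(vapply(plants, function(p) {
    p$copies * (2L * nchar(p$A) + p$d)
  }, 0))
  if (footprint >= length / 2)
    abort("planted footprint exceeds half the genome; cannot pack")
  withr::with_seed(seed, {
    bg <- if (is.null(markov)) random_seq(length, gc)
          else random_markov_seq(length, markov)
    seqv <- strsplit(bg, "")[[1]]
    taken <- logical(length)
    truth <- list()
    for (p in plants) {
      k <- nchar(p$A)
      w <- 2L * k + p$d
      spacers <- plant_spacers(p, gc)
      strands <- if (p$strands == "both") {
        rep_len(c("+", "-"), p$copies)
      } else rep("+", p$copies)
      for (ci in seq_len(p$copies)) {
        placed <- FALSE
        for (try in 1:10000) {
          s0 <- sample.int(length - w + 1L, 1) - 1L
          if (!any(taken[(s0 + 1):(s0 + w)])) { placed <- TRUE; break }
        }
        if (!placed) abort("could not place planted copy; genome too full")
        text <- paste0(p$A, spacers[ci], p$B)
        if (strands[ci] == "-") text <- revcomp(text)
        seqv[(s0 + 1):(s0 + w)] <- strsplit(text, "")[[1]]
        taken[(s0 + 1):(s0 + w)] <- TRUE
        truth[[length(truth) + 1]] <-
          tibble(record = record, start = s0, strand = strands[ci],
                 A = p$A, B = p$B, d = p$d, spacer = spacers[ci])
      }
    }
    list(genome = tibble(record = record,
                         sequence = paste(seqv, collapse = ""),
                         length = length),
         truth = if (length(truth)) bind_rows(truth)
                 else tibble(record = character(), start = integer(),
                             strand = character(), A = character(),
                             B = character(), d = integer(),
                             spacer = character()))
  })
}

random_markov_seq <- function(n, trans) {
  bases <- c("A", "C", "G", "T")
  stopifnot(is.matrix(trans), all(dim(trans) == c(4, 4)),
            all(abs(rowSums(trans) - 1) < 1e-8))
  out <- integer(n)
  out[1] <- sample.int(4, 1)
  for (i in 2:n) out[i] <- sample.int(4, 1, prob = trans[out[i - 1], ])
  paste(bases[out], collapse = "")
}

#' Generate a random non-overlapping gene annotation
#'
#' Gene lengths are drawn around `mean_len` (+-30%), placed left to right
#' with random intergenic gaps and random strands; reproducible from
#' `seed`.
#'
#' @param length Genome length in bp.
#' @param n_genes Number of genes to place (0 allowed).
#' @param mean_len Mean gene length in bp.
#' @param seed Integer seed.
#' @param record Record id.
#' @return Gene tibble (`record`, `start`, `end`, `strand`, `label`),
#'   0-based half-open, sorted, non-overlapping.
#' @export
generate_annotation <- function(length, n_genes, mean_len, seed,
                                record = "synthetic") {
  if (n_genes == 0) {
    return(tibble(record = character(), start = integer(), end = integer(),
                  strand = character(), label = character()))
  }
  if (n_genes * mean_len >= length)
    abort("genes do not fit: n_genes * mean_len must be < length")
  withr::with_seed(seed, {
    lens <- pmax(1L, as.integer(round(runif(n_genes, 0.7, 1.3) * mean_len)))
    slack <- length - sum(lens)
    gaps <- as.vector(rmultinom(1, slack, rep(1, n_genes + 1)))
    starts <- cumsum(gaps[seq_len(n_genes)]) +
      cumsum(c(0L, lens[-n_genes]))
    tibble(record = record, start = as.integer(starts),
           end = as.integer(starts + lens),
           strand = sample(c("+", "-"), n_genes, replace = TRUE),
           label = sprintf("gene%04d", seq_len(n_genes)))
  })
}

#' Write a gene tibble as GFF3
#'
#' @param genes Gene tibble (0-based half-open intervals).
#' @param path Output path.
#' @param seq_lengths Optional named lengths for `##sequence-region`
#'   headers.
#' @param type Feature type column to emit (default `"CDS"`).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, seq_lengths = NULL, type = "CDS") {
  lines <- "##gff-version 3"
  if (!is.null(seq_lengths)) {
    lines <- c(lines, sprintf("##sequence-region %s 1 %d",
                              names(seq_lengths), seq_lengths))
  }
  if (nrow(genes) > 0) {
    lines <- c(lines, sprintf(
      "%s\tspacedpairs\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
      genes$record, type, genes$start + 1L, genes$end, genes$strand,
      ifelse(is.na(genes$label), sprintf("feat%d", seq_len(nrow(genes))),
             genes$label)))
  }
  writeLines(lines, path)
  invisible(path)
}
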