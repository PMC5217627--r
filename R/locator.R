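#' Classify genomic spans against gene annotations
#'
#' Each span is `"gene"` when fully contained in at least one gene
#' interval (containment is strand-agnostic), `"intergenic"` when
#' disjoint from all genes, and `"overlap"` otherwise (straddling a gene
#' start or end).  The three classes are exhaustive and mutually
#' exclusive.
#'
#' @param spans Tibble with `record`, `start` (0-based inclusive), `end`
#'   (0-based exclusive).
#' @param genes Gene tibble (`record`, `start`, `end`, `strand`), as from
#'   [read_annotation()].
#' @return Character vector in `{"gene", "intergenic", "overlap"}`.
#' @export
classify_occurrence <- function(spans, genes) {
  out <- rep("intergenic", nrow(spans))
  if (nrow(genes) == 0 || nrow(spans) == 0) return(out)
  for (rec in unique(spans$record)) {
    si <- which(spans$record == rec)
    g <- genes[genes$record == rec, , drop = FALSE]
    if (nrow(g) == 0) next
    sr <- IRanges::IRanges(start = spans$start[si] + 1L, end = spans$end[si])
    gr <- IRanges::IRanges(start = g$start + 1L, end = g$end)
    within <- IRanges::countOverlaps(sr, gr, type = "within") > 0
    any_ov <- IRanges::countOverlaps(sr, gr) > 0
    out[si] <- ifelse(within, "gene", ifelse(any_ov, "overlap", "intergenic"))
  }
  out
}

# flanking gene indices (within the record's gene table) for each span;
# NA when no gene lies entirely on that side
flanking_genes <- function(spans, genes) {
  left <- rep(NA_integer_, nrow(spans))
  right <- rep(NA_integer_, nrow(spans))
  ls <- rep(NA_character_, nrow(spans)); rs <- ls
  ld <- rep(NA_integer_, nrow(spans)); rd <- ld
  for (rec in unique(spans$record)) {
    si <- which(spans$record == rec)
    g <- genes[genes$record == rec, , drop = FALSE]
    if (nrow(g) == 0) next
    eo <- order(g$end); so <- order(g$start)
    ends <- g$end[eo]; starts <- g$start[so]
    li <- findInterval(spans$start[si], ends) # genes ending at/before start
    ri <- findInterval(spans$end[si] - 1L, starts) + 1L # first start >= end
    has_l <- li >= 1
    has_r <- ri <= nrow(g)
    ls[si[has_l]] <- g$strand[eo[li[has_l]]]
    ld[si[has_l]] <- spans$start[si[has_l]] - ends[li[has_l]]
    rs[si[has_r]] <- g$strand[so[pmin(ri, nrow(g))[has_r]]]
    rd[si[has_r]] <- starts[pmin(ri, nrow(g))[has_r]] - spans$end[si[has_r]]
  }
  tibble(left_strand = ls, right_strand = rs,
         left_gap = ld, right_gap = rd)
}

#' Orientation of the genes flanking an intergenic span
#'
#' `convergent` when the flanking genes point toward the span
#' (`-> span <-`: left gene on `+`, right gene on `-`), `divergent` when
#' they point away (`<- span ->`), `co_oriented` when both are on the
#' same strand, and `none` when either flank is missing.
#'
#' @inheritParams classify_occurrence
#' @return Character vector in
#'   `{"convergent", "divergent", "co_oriented", "none"}`.
#' @export
orientation_context <- function(spans, genes) {
  fl <- flanking_genes(spans, genes)
  dplyr::case_when(
    is.na(fl$left_strand) | is.na(fl$right_strand) ~ "none",
    fl$left_strand == "+" & fl$right_strand == "-" ~ "convergent",
    fl$left_strand == "-" & fl$right_strand == "+" ~ "divergent",
    TRUE ~ "co_oriented"
  )
}

#' Annotate motif-pair occurrences with gene context
#'
#' Adds the location class, the flanking-gene orientation (intergenic
#' spans only) and a signed nearest-gene distance: bp from the span edge
#' to the nearest gene boundary, negative when the span lies upstream
#' (5' side) of that gene, positive when downstream; 0 for spans touching
#' or inside genes.
#'
#' @param occurrences Tibble with `record`, `start`, `end` (0-based
#'   half-open; as in the `occurrences` table of a [find_motif_pairs()]
#'   result).
#' @param genes Gene tibble.
#' @return `occurrences` with `class`, `orientation`,
#'   `nearest_gene_distance` columns added.
#' @export
annotate_occurrences <- function(occurrences, genes) {
  cls <- classify_occurrence(occurrences, genes)
  fl <- flanking_genes(occurrences, genes)
  orient <- dplyr::case_when(
    cls != "intergenic" ~ NA_character_,
    is.na(fl$left_strand) | is.na(fl$right_strand) ~ "none",
    fl$left_strand == "+" & fl$right_strand == "-" ~ "convergent",
    fl$left_strand == "-" & fl$right_strand == "+" ~ "divergent",
    TRUE ~ "co_oriented"
  )
  use_left <- !is.na(fl$left_gap) &
    (is.na(fl$right_gap) | fl$left_gap <= fl$right_gap)
  ndist <- ifelse(cls != "intergenic", 0L, ifelse(
    use_left,
    # nearest gene ends to the left: downstream of a + gene, upstream of -
    ifelse(fl$left_strand == "+", fl$left_gap, -fl$left_gap),
    ifelse(fl$right_strand == "+", -fl$right_gap, fl$right_gap)))
  ndist[cls == "intergenic" & is.na(fl$left_gap) & is.na(fl$right_gap)] <- NA
  mutate(occurrences, class = cls, orientation = orient,
         nearest_gene_distance = as.integer(ndist))
}

#' Location summary for a set of occurrences
#'
#' Gene / intergenic / overlap percentages (summing to 100) and
#' orientation counts of the intergenic occurrences.
#'
#' @inheritParams annotate_occurrences
#' @return One-row tibble: `n_occurrences`, `gene_pct`, `intergenic_pct`,
#'   `overlap_pct`, `n_convergent`, `n_divergent`, `n_co_oriented`.
#' @export
summarize_locations <- function(occurrences, genes) {
  if (nrow(occurrences) == 0) abort("no occurrences to summarize")
  ann <- annotate_occurrences(occurrences, genes)
  tibble(
    n_occurrences = nrow(ann),
    gene_pct = 100 * mean(ann$class == "gene"),
    intergenic_pct = 100 * mean(ann$class == "intergenic"),
    overlap_pct = 100 * mean(ann$class == "overlap"),
    n_convergent = sum(ann$orientation == "convergent", na.rm = TRUE),
    n_divergent = sum(ann$orientation == "divergent", na.rm = TRUE),
    n_co_oriented = sum(ann$orientation == "co_oriented", na.rm = TRUE)
  )
}
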