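#' Global alignment of two spacers with percent identity
#'
#' Needleman--Wunsch global alignment under the scoring in
#' [align_params()]; identity is the number of identical aligned positions
#' divided by the alignment length (gap columns included).  Among
#' score-optimal alignments the one with the most identities (then fewest
#' gap columns) is reported, making the value deterministic.
#'
#' @param s1,s2 Non-empty nucleotide strings (vectorized, recycled).
#' @param params An [align_params()] object.
#' @return `nw_align()`: tibble `score`, `matches`, `alignment_length`,
#'   `identity`; `global_align_identity()`: the identity fraction(s).
#' @examples
#' global_align_identity("AAAAAAAAAA", "AAAAAAATTT") # 0.7
#' @export
nw_align <- function(s1, s2, params = align_params()) {
  if (length(s1) == 0 || length(s2) == 0 || any(!nzchar(c(s1, s2))))
    abort("spacers must be non-empty strings")
  as_tibble(cpp_nw_align(s1, s2, params$match, params$mismatch, params$gap))
}

#' @rdname nw_align
#' @export
global_align_identity <- function(s1, s2, params = align_params()) {
  nw_align(s1, s2, params)$identity
}

#' Greedy elimination of near-duplicate spacers
#'
#' Walks the spacers in genome order, aligning each surviving spacer
#' against every later one; when the identity reaches the threshold the
#' later spacer is removed (a likely segmental duplication) and never
#' aligned again, until no surviving pair is above the cutoff.  Each
#' removal corresponds to reducing `fmax` by one.
#'
#' @param spacers Character vector of spacers (same distance, genome
#'   order).
#' @param params An [align_params()] object.
#' @return List with `kept` (surviving spacers, a subsequence of the
#'   input), `keep` (logical mask) and `removed` (count).
#' @export
greedy_reduce <- function(spacers, params = align_params()) {
  if (length(spacers) == 0)
    return(list(kept = character(), keep = logical(), removed = 0L))
  res <- cpp_greedy_reduce(spacers, params$match, params$mismatch,
                           params$gap, params$identity, params$gapless)
  list(kept = spacers[res$keep], keep = res$keep,
       removed = as.integer(res$removed))
}
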