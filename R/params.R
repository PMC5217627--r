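#' Scan parameters: motif length and spacer range
#'
#' The scan enumerates every ordered pair of k-mers at every spacer length
#' `d` in `[dmin, dmax]`, where `d` counts the nucleotides strictly between
#' the end of the first motif and the start of the second (the `(N)_d`
#' convention used in pattern strings such as `AAGGA(N)6ATGAA`).
#'
#' @param k Motif length in nucleotides (1--6; pentamers by default).
#' @param dmin,dmax Inclusive spacer-length range. The defaults 5 and 89
#'   give `K = 85` tested distances.
#' @return An object of class `scan_params`: a list with `k`, `dmin`,
#'   `dmax` and the derived number of distance cells `K`.
#' @examples
#' scan_params()$K # 85
#' @export
scan_params <- function(k = 5, dmin = 5, dmax = 89) {
  stopifnot(length(k) == 1, length(dmin) == 1, length(dmax) == 1)
  k <- as.integer(k); dmin <- as.integer(dmin); dmax <- as.integer(dmax)
  if (is.na(k) || k < 1 || k > 6)
    abort("`k` must be between 1 and 6 (pair table size is 4^(2k))")
  if (is.na(dmin) || is.na(dmax) || dmin < 0 || dmin > dmax)
    abort("need 0 <= dmin <= dmax")
  structure(list(k = k, dmin = dmin, dmax = dmax, K = dmax - dmin + 1L),
            class = "scan_params")
}

#' Significance parameters for the uniform-multinomial maximum test
#'
#' Occurrence totals are tested against the null that all `K` spacer
#' distances are equally likely; the family-wise error `alpha_family` is
#' Bonferroni-divided by the number of ordered motif pairs tested
#' (`n_tests`, `4^(2k)`) to give the per-pair threshold `alpha`.  Exact
#' tail probabilities are used for totals up to `n_exact_max`; beyond that
#' an asymptotic percentile approximation takes over.
#'
#' @param K Number of distance cells (85 for the default spacer range).
#' @param alpha_family Family-wise type-I error rate.
#' @param n_tests Number of hypotheses for the Bonferroni correction
#'   (default `4^10`, all ordered pentamer pairs).
#' @param n_exact_max Largest total count evaluated with the exact
#'   occupancy distribution.
#' @return An object of class `stat_params` with the derived per-test
#'   `alpha = alpha_family / n_tests`.
#' @examples
#' stat_params()$alpha # ~9.54e-9
#' @export
stat_params <- function(K = 85, alpha_family = 0.01, n_tests = 4^10,
                        n_exact_max = 600) {
  stopifnot(K >= 2, alpha_family > 0, alpha_family < 1, n_tests >= 1,
            n_exact_max >= 1)
  alpha <- alpha_family / n_tests
  if (alpha <= 0 || alpha >= 1) abort("derived per-test alpha outside (0,1)")
  structure(list(K = as.integer(K), alpha_family = alpha_family,
                 n_tests = n_tests, alpha = alpha,
                 n_exact_max = as.integer(n_exact_max)),
            class = "stat_params")
}

#' Spacer-alignment parameters for duplicate elimination
#'
#' Spacers at the modal distance are aligned pairwise with a global
#' Needleman--Wunsch alignment; when the identity (identical aligned
#' positions over alignment length, gap columns included) reaches
#' `identity`, the later spacer is discarded as a likely segmental
#' duplication.
#'
#' @param match,mismatch,gap Alignment scores (per aligned pair / per gap
#'   position).
#' @param identity Identity threshold in `(0, 1]`; occurrences at least
#'   this similar are collapsed. 0.70 by default; 0.65 and 0.75 reproduce
#'   the published sensitivity settings.
#' @param gapless If `TRUE`, equal-length spacers are compared without
#'   gaps (positional identity), a fast mode; the default is the full
#'   alignment.
#' @return An object of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = -1, gap = -2,
                         identity = 0.70, gapless = FALSE) {
  stopifnot(identity > 0, identity <= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap = as.integer(gap), identity = identity,
                 gapless = isTRUE(gapless)),
            class = "align_params")
}

#' @export
print.scan_params <- function(x, ...) {
  cat(sprintf("<scan_params> k = %d, spacer range [%d, %d] (K = %d)\n",
              x$k, x$dmin, x$dmax, x$K))
  invisible(x)
}

#' @export
print.stat_params <- function(x, ...) {
  cat(sprintf(
    "<stat_params> K = %d, alpha_family = %g / %g tests -> alpha = %.4g, exact for n <= %d\n",
    x$K, x$alpha_family, x$n_tests, x$alpha, x$n_exact_max))
  invisible(x)
}

#' @export
print.align_params <- function(x, ...) {
  cat(sprintf(
    "<align_params> match %+d / mismatch %+d / gap %+d, identity cutoff %.2f%s\n",
    x$match, x$mismatch, x$gap, x$identity,
    if (x$gapless) " (gapless mode)" else ""))
  invisible(x)
}
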