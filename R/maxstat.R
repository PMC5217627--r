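#' Exact distribution of the maximum cell count of a uniform multinomial
#'
#' For `n` occurrences falling independently and uniformly over `K`
#' spacer distances (balls in urns), `exact_cdf()` gives
#' `P(fmax < x)` — the probability that no distance collects `x` or more
#' occurrences — via the occupancy generating function
#' `n!/K^n * [lambda^n] (sum_{j=0}^{x-1} lambda^j / j!)^K`.
#' All series terms are positive, so the floating-point evaluation carries
#' full relative precision; `exact_pvalue()` returns the upper tail
#' `P(fmax >= x)`, switching to a finite inclusion-exclusion expansion for
#' tiny tails where `1 - cdf` would lose precision to cancellation.
#'
#' @param n Total occurrence count (non-negative).
#' @param K Number of distance cells (>= 1).
#' @param x Threshold count (>= 1).
#' @return A probability.
#' @examples
#' exact_cdf(2, 2, 2) # 0.5
#' exact_pvalue(6, 85, 6) # 85^-5, ~2.25e-10
#' @export
exact_cdf <- function(n, K, x) {
  check_nkx(n, K, x)
  cpp_occupancy_cdf(n, as.integer(K), x)
}

#' @rdname exact_cdf
#' @export
exact_pvalue <- function(n, K, x) {
  check_nkx(n, K, x)
  cpp_occupancy_pvalue(n, as.integer(K), x, TRUE)
}

check_nkx <- function(n, K, x) {
  stopifnot(length(n) == 1, length(K) == 1, length(x) == 1)
  if (is.na(x) || x < 1) abort("`x` must be >= 1")
  if (is.na(n) || n < 0) abort("`n` must be >= 0")
  if (is.na(K) || K < 1) abort("`K` must be >= 1")
  invisible(TRUE)
}

#' Asymptotic percentile of the multinomial maximum
#'
#' The `100(1-alpha)%` percentile of `fmax` under the uniform multinomial,
#' from extreme-value asymptotics (natural logarithms):
#' `F_alpha = n/K + sqrt(n log K / K)
#'           - (log log(1/(1-alpha)) + 1.266) * sqrt(n / (2 K log K))`.
#' Accurate for large `K` (> 50) as `n` grows; used above the exact-regime
#' limit `n_exact_max`.
#'
#' @param n Total occurrence count (> 0).
#' @param K Number of cells (>= 2).
#' @param alpha Upper-tail probability in (0, 1).
#' @return The (real-valued) percentile `F_alpha`.
#' @export
approx_percentile <- function(n, K, alpha) {
  stopifnot(n > 0, K >= 2)
  if (!is.numeric(alpha) || is.na(alpha) || alpha <= 0 || alpha >= 1)
    abort("`alpha` must be in (0, 1)")
  n / K + sqrt(n * log(K) / K) -
    (log(log(1 / (1 - alpha))) + 1.266) * sqrt(n / (2 * K * log(K)))
}

#' Significance cutoff for the maximum per-distance count
#'
#' The smallest integer `c` such that a pair with total (unique-spacer)
#' count `n` is declared significant when its maximum per-distance count
#' reaches `c`, i.e. `min { x : P(fmax >= x) <= alpha }`.  Exact tail
#' probabilities are used for `n <= n_exact_max`; beyond that the ceiling
#' of [approx_percentile()] (conservative rounding).  When no attainable
#' `x <= n` qualifies, `n + 1` is returned: such a pair can never be
#' significant (this happens for all `n <= 5` at the defaults, matching a
#' minimum attainable cutoff of 6 at `n = 6`).
#'
#' @param n Total count(s); vectorized.
#' @param K Number of distance cells.
#' @param params A [stat_params()] object (per-test `alpha`,
#'   exact/approximate switchover).
#' @return Integer cutoff(s), `n + 1` where unattainable.
#' @examples
#' fcut(6, 85) # 6
#' fcut(5, 85) # 6 (> n: unattainable)
#' @export
fcut <- function(n, K = 85, params = stat_params(K = K)) {
  n <- as.integer(n)
  stopifnot(all(!is.na(n)), all(n >= 0))
  out <- integer(length(n))
  small <- n <= params$n_exact_max
  if (any(small)) {
    tab <- fcut_table(max(n[small], 1L), K, params)
    out[small] <- ifelse(n[small] == 0, 1L, tab[pmax(n[small], 1L)])
  }
  if (any(!small)) {
    big <- n[!small]
    out[!small] <- as.integer(pmin(
      ceiling(vapply(big, approx_percentile, 0, K = K, alpha = params$alpha)),
      big + 1))
  }
  out
}

fcut_cache <- new.env(parent = emptyenv())

#' Cached table of exact cutoffs
#'
#' @param n_max Largest total count to tabulate.
#' @inheritParams fcut
#' @return Integer vector `fcut(1..n_max)`.
#' @export
fcut_table <- function(n_max, K = 85, params = stat_params(K = K)) {
  key <- sprintf("K%d_a%.17g_n%d", K, params$alpha, n_max)
  hit <- fcut_cache[[key]]
  if (!is.null(hit)) return(hit)
  tab <- cpp_fcut_table(as.integer(n_max), as.integer(K), params$alpha)
  fcut_cache[[key]] <- tab
  tab
}

#' Monte Carlo samples of the multinomial maximum
#'
#' Validation oracle for [exact_cdf()]: throws `n` balls into `K` urns
#' uniformly, `reps` times.
#'
#' @inheritParams exact_cdf
#' @param reps Number of replicates (>= 1).
#' @param seed Integer seed (randomness is local; the global RNG state is
#'   untouched).
#' @return Integer vector of `reps` sampled `fmax` values.
#' @export
simulate_fmax <- function(n, K, reps, seed) {
  stopifnot(reps >= 1)
  withr::with_seed(seed, {
    m <- rmultinom(reps, n, rep(1 / K, K))
    as.integer(do.call(pmax, lapply(seq_len(K), function(i) m[i, ])))
  })
}
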