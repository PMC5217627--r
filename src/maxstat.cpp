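#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// P(fmax < x) for n balls thrown uniformly into K urns (the David & Barton
// occupancy quantity n!/K^n * [lambda^n] (sum_{j<x} lambda^j/j!)^K),
// evaluated by conditioning cell by cell: given the first m-1 cells hold t
// balls, cell m receives Binomial(n - t, 1/(K - m + 1)) of the rest.
// f[t] = P(first m cells all < x and hold t balls); every entry is a
// probability and every update adds positive terms, so the evaluation is
// stable for any n with ~1e-13 relative accuracy.
static double occupancy_cdf_core(long n, int K, long x) {
  if (x > n) return 1.0;
  if ((double) K * (x - 1) < (double) n) return 0.0; // pigeonhole: cdf = 0
  std::vector<double> f(n + 1, 0.0), g(n + 1, 0.0);
  f[0] = 1.0;
  const long jmax_cell = x - 1;
  for (int m = 1; m <= K - 1; ++m) {
    double p = 1.0 / (double) (K - m + 1);
    double lq = std::log1p(-p);
    std::fill(g.begin(), g.end(), 0.0);
    long tmax = std::min<long>(n, (long) (m - 1) * (x - 1));
    for (long t = 0; t <= tmax; ++t) {
      if (f[t] == 0.0) continue;
      long M = n - t;
      double db = std::exp((double) M * lq); // dbinom(0; M, p)
      long jm = std::min(jmax_cell, M);
      for (long j = 0; j <= jm; ++j) {
        if (t + j <= n) g[t + j] += f[t] * db;
        db *= (double) (M - j) / (double) (j + 1) * p / (1.0 - p);
      }
    }
    f.swap(g);
  }
  // last cell takes the remaining n - t balls exactly; need n - t < x
  double cdf = 0.0;
  for (long t = std::max(0L, n - x + 1); t <= n; ++t) cdf += f[t];
  if (cdf > 1.0) cdf = 1.0;
  return cdf;
}

// [[Rcpp::export]]
double cpp_occupancy_cdf(double n, int K, double x) {
  if (x <= 0) stop("x must be >= 1");
  if (n <= 0) return 1.0;
  return occupancy_cdf_core((long) n, K, (long) x);
}

// Upper tail P(fmax >= x) by finite inclusion-exclusion over the set of
// urns reaching x: sum_j (-1)^(j+1) C(K,j) P(urns 1..j all >= x).  The sum
// terminates at j = floor(n/x); used to refine tiny tails where 1 - cdf
// loses relative precision to cancellation.
static double occupancy_tail_incl_excl(long n, int K, long x) {
  long jmax = n / x;
  if (jmax > K) jmax = K;
  if (jmax < 1) return 0.0;
  // g[s] = P(first j urns all >= x and hold s balls total)
  std::vector<double> g(n + 1, 0.0), h;
  for (long s = x; s <= n; ++s)
    g[s] = R::dbinom((double) s, (double) n, 1.0 / K, 0);
  double pv = 0.0, logC = std::log((double) K); // log C(K,j), iteratively
  for (long j = 1; j <= jmax; ++j) {
    double Qj = 0.0;
    for (long s = j * x; s <= n; ++s) Qj += g[s];
    double term = std::exp(logC) * Qj;
    pv += (j % 2 == 1) ? term : -term;
    if (term < 1e-14 * std::fabs(pv) || j == jmax) break;
    // extend to j+1 urns: urn j+1 gets >= x of the remaining balls
    h.assign(n + 1, 0.0);
    double p = 1.0 / (double) (K - j);
    for (long t = j * x; t <= n - x; ++t) {
      if (g[t] == 0.0) continue;
      for (long s = t + x; s <= n; ++s)
        h[s] += g[t] * R::dbinom((double) (s - t), (double) (n - t), p, 0);
    }
    g.swap(h);
    logC += std::log((double) (K - j) / (double) (j + 1));
  }
  if (pv < 0.0) pv = 0.0;
  if (pv > 1.0) pv = 1.0;
  return pv;
}

// [[Rcpp::export]]
double cpp_occupancy_pvalue(double n, int K, double x, bool refine) {
  if (x <= 0) stop("x must be >= 1");
  if (n <= 0) return 0.0;
  if (x > n) return 0.0;
  double cdf = occupancy_cdf_core((long) n, K, (long) x);
  double naive = 1.0 - cdf;
  if (naive < 0) naive = 0.0;
  if (refine && naive < 1e-7)
    return occupancy_tail_incl_excl((long) n, K, (long) x);
  return naive;
}

// Significance cutoffs fcut(n) for n = 1..nmax from the exact tail:
// smallest x with P(fmax >= x) <= alpha (x = n+1, i.e. unattainable, when
// no x <= n qualifies).  Uses monotonicity of fcut in n.
// [[Rcpp::export]]
IntegerVector cpp_fcut_table(int nmax, int K, double alpha) {
  IntegerVector out(nmax);
  long c = 1;
  for (long n = 1; n <= nmax; ++n) {
    while (c <= n) {
      double pv = 1.0 - occupancy_cdf_core(n, K, c);
      if (pv <= alpha) break;
      ++c;
    }
    out[n - 1] = (int) c; // when c == n+1 the cutoff is unattainable at n,
                          // but remains the correct starting point for n+1
    Rcpp::checkUserInterrupt();
  }
  return out;
}
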