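#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

struct NwResult { int score; int matches; int alen; };

// Global (Needleman-Wunsch) alignment with linear gap scoring.  Among
// score-optimal alignments the one with the most identical aligned
// positions is taken, and among those the shortest alignment (fewest gap
// columns); this makes the reported identity deterministic.
static NwResult nw_align_core(const std::string &s1, const std::string &s2,
                              int match, int mismatch, int gap) {
  const int n = (int) s1.size(), m = (int) s2.size();
  // per cell: best score, then max matches, then max diagonal steps
  std::vector<int> S((n + 1) * (m + 1)), M((n + 1) * (m + 1)),
      D((n + 1) * (m + 1));
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  for (int j = 0; j <= m; ++j) { S[at(0, j)] = gap * j; M[at(0, j)] = 0; D[at(0, j)] = 0; }
  for (int i = 0; i <= n; ++i) { S[at(i, 0)] = gap * i; M[at(i, 0)] = 0; D[at(i, 0)] = 0; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      bool eq = s1[i - 1] == s2[j - 1];
      int sd = S[at(i - 1, j - 1)] + (eq ? match : mismatch);
      int md = M[at(i - 1, j - 1)] + (eq ? 1 : 0);
      int dd = D[at(i - 1, j - 1)] + 1;
      int su = S[at(i - 1, j)] + gap, mu = M[at(i - 1, j)], du = D[at(i - 1, j)];
      int sl = S[at(i, j - 1)] + gap, ml = M[at(i, j - 1)], dl = D[at(i, j - 1)];
      int bs = sd, bm = md, bd = dd;
      if (su > bs || (su == bs && (mu > bm || (mu == bm && du > bd)))) {
        bs = su; bm = mu; bd = du;
      }
      if (sl > bs || (sl == bs && (ml > bm || (ml == bm && dl > bd)))) {
        bs = sl; bm = ml; bd = dl;
      }
      S[at(i, j)] = bs; M[at(i, j)] = bm; D[at(i, j)] = bd;
    }
  }
  NwResult r;
  r.score = S[at(n, m)];
  r.matches = M[at(n, m)];
  r.alen = n + m - D[at(n, m)];
  return r;
}

// [[Rcpp::export]]
DataFrame cpp_nw_align(CharacterVector s1, CharacterVector s2, int match,
                       int mismatch, int gap) {
  R_xlen_t n = std::max(s1.size(), s2.size());
  IntegerVector score(n), matches(n), alen(n);
  NumericVector ident(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string a = as<std::string>(s1[i % s1.size()]);
    std::string b = as<std::string>(s2[i % s2.size()]);
    if (a.empty() || b.empty()) stop("sequences must be non-empty");
    NwResult r = nw_align_core(a, b, match, mismatch, gap);
    score[i] = r.score; matches[i] = r.matches; alen[i] = r.alen;
    ident[i] = (double) r.matches / (double) r.alen;
  }
  return DataFrame::create(_["score"] = score, _["matches"] = matches,
                           _["alignment_length"] = alen,
                           _["identity"] = ident);
}

static double pair_identity(const std::string &a, const std::string &b,
                            int match, int mismatch, int gap, bool gapless) {
  if (gapless && a.size() == b.size()) {
    int m = 0;
    for (size_t i = 0; i < a.size(); ++i) if (a[i] == b[i]) ++m;
    return (double) m / (double) a.size();
  }
  NwResult r = nw_align_core(a, b, match, mismatch, gap);
  return (double) r.matches / (double) r.alen;
}

// Greedy near-duplicate elimination: walk ordered pairs i < j; when
// identity(s_i, s_j) reaches the threshold, drop the later spacer s_j and
// never align it again.  Comparison is matches >= threshold * alen to keep
// the >= threshold test exact for rational identities.
// [[Rcpp::export]]
List cpp_greedy_reduce(CharacterVector spacers, int match, int mismatch,
                       int gap, double threshold, bool gapless) {
  const R_xlen_t n = spacers.size();
  LogicalVector keep(n, true);
  std::vector<std::string> s(n);
  for (R_xlen_t i = 0; i < n; ++i) s[i] = as<std::string>(spacers[i]);
  int removed = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!keep[i]) continue;
    for (R_xlen_t j = i + 1; j < n; ++j) {
      if (!keep[j]) continue;
      double id = pair_identity(s[i], s[j], match, mismatch, gap, gapless);
      if (id >= threshold - 1e-9) { keep[j] = false; ++removed; }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["keep"] = keep, _["removed"] = removed);
}
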