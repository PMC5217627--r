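#include <Rcpp.h>
#include <cstring>
#include <unordered_set>
#include <vector>
#include <string>
using namespace Rcpp;

// 2-bit base codes; anything but ACGT (incl. N) is -1 and poisons any k-mer
// window containing it.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// k-mer code at every start position of seq, -1 where the window has an
// invalid base or runs off the end.
static std::vector<int> kmer_codes(const std::string &seq, int k) {
  const long L = (long) seq.size();
  std::vector<int> kc(std::max(0L, L), -1);
  if (L < k) return kc;
  const int mask = (1 << (2 * k)) - 1;
  int code = 0, run = 0; // run = number of consecutive valid bases ending here
  for (long i = 0; i < L; ++i) {
    int b = base_code(seq[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | b) & mask;
    if (++run >= k) kc[i - k + 1] = code;
  }
  return kc;
}

// Pass 1: per ordered k-mer pair over all records, raw (non-deduplicated)
// totals across the spacer range: n_raw, fmax_raw (max raw count at any
// single distance), occupied (number of distances with >= 1 occurrence).
// Dense arrays over all 4^(2k) pair codes; only non-empty pairs returned.
// [[Rcpp::export]]
DataFrame cpp_scan_stats(CharacterVector seqs, int k, int dmin, int dmax) {
  const int Nk = 1 << (2 * k);
  const size_t NP = (size_t) Nk * Nk;
  std::vector<int> n(NP, 0), fmax(NP, 0), occ(NP, 0), cnt(NP, 0);
  std::vector<std::vector<int>> kcs;
  std::vector<const std::string*> ss;
  std::vector<std::string> stor;
  stor.reserve(seqs.size());
  for (R_xlen_t r = 0; r < seqs.size(); ++r)
    stor.push_back(as<std::string>(seqs[r]));
  for (auto &s : stor) kcs.push_back(kmer_codes(s, k));

  for (int d = dmin; d <= dmax; ++d) {
    std::memset(cnt.data(), 0, NP * sizeof(int));
    for (size_t r = 0; r < stor.size(); ++r) {
      const std::vector<int> &kc = kcs[r];
      const long L = (long) stor[r].size();
      const long last = L - (2L * k + d); // last valid start of A
      for (long i = 0; i <= last; ++i) {
        int a = kc[i];
        if (a < 0) continue;
        int b = kc[i + k + d];
        if (b < 0) continue;
        size_t p = (size_t) a * Nk + b;
        int c = ++cnt[p];
        ++n[p];
        if (c == 1) ++occ[p];
        if (c > fmax[p]) fmax[p] = c;
      }
    }
    Rcpp::checkUserInterrupt();
  }

  // collect non-empty pairs
  size_t nz = 0;
  for (size_t p = 0; p < NP; ++p) if (n[p] > 0) ++nz;
  IntegerVector code((R_xlen_t) nz), vn((R_xlen_t) nz), vf((R_xlen_t) nz),
      vo((R_xlen_t) nz);
  size_t j = 0;
  for (size_t p = 0; p < NP; ++p) {
    if (n[p] == 0) continue;
    code[j] = (int) p; vn[j] = n[p]; vf[j] = fmax[p]; vo[j] = occ[p]; ++j;
  }
  return DataFrame::create(_["code"] = code, _["n_raw"] = vn,
                           _["fmax_raw"] = vf, _["occupied"] = vo);
}

// Full raw count table (A,B,d,count) for small inputs / oracle comparisons.
// [[Rcpp::export]]
DataFrame cpp_scan_raw_table(CharacterVector seqs, int k, int dmin, int dmax) {
  const int Nk = 1 << (2 * k);
  const size_t NP = (size_t) Nk * Nk;
  std::vector<int> cnt(NP, 0);
  std::vector<std::string> stor;
  for (R_xlen_t r = 0; r < seqs.size(); ++r)
    stor.push_back(as<std::string>(seqs[r]));
  std::vector<std::vector<int>> kcs;
  for (auto &s : stor) kcs.push_back(kmer_codes(s, k));

  std::vector<int> out_code, out_d, out_cnt;
  for (int d = dmin; d <= dmax; ++d) {
    std::memset(cnt.data(), 0, NP * sizeof(int));
    for (size_t r = 0; r < stor.size(); ++r) {
      const std::vector<int> &kc = kcs[r];
      const long L = (long) stor[r].size();
      const long last = L - (2L * k + d);
      for (long i = 0; i <= last; ++i) {
        int a = kc[i]; if (a < 0) continue;
        int b = kc[i + k + d]; if (b < 0) continue;
        ++cnt[(size_t) a * Nk + b];
      }
    }
    for (size_t p = 0; p < NP; ++p) {
      if (cnt[p] > 0) {
        out_code.push_back((int) p);
        out_d.push_back(d);
        out_cnt.push_back(cnt[p]);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["code"] = wrap(out_code), _["d"] = wrap(out_d),
                           _["count"] = wrap(out_cnt));
}

// Pass 2: unique-spacer histograms for a candidate subset of pair codes.
// Returns an ncand x K matrix of distinct-spacer counts per distance.
// [[Rcpp::export]]
IntegerMatrix cpp_candidate_histograms(CharacterVector seqs, int k, int dmin,
                                       int dmax, IntegerVector cand_codes) {
  const int Nk = 1 << (2 * k);
  const size_t NP = (size_t) Nk * Nk;
  const int K = dmax - dmin + 1;
  const int ncand = cand_codes.size();
  std::vector<int> map(NP, -1);
  for (int c = 0; c < ncand; ++c) map[(size_t) cand_codes[c]] = c;

  std::vector<std::string> stor;
  for (R_xlen_t r = 0; r < seqs.size(); ++r)
    stor.push_back(as<std::string>(seqs[r]));
  std::vector<std::vector<int>> kcs;
  for (auto &s : stor) kcs.push_back(kmer_codes(s, k));

  IntegerMatrix uniq(ncand, K);
  std::unordered_set<std::string> seen;
  for (int d = dmin; d <= dmax; ++d) {
    seen.clear();
    for (size_t r = 0; r < stor.size(); ++r) {
      const std::vector<int> &kc = kcs[r];
      const std::string &s = stor[r];
      const long L = (long) s.size();
      const long last = L - (2L * k + d);
      for (long i = 0; i <= last; ++i) {
        int a = kc[i]; if (a < 0) continue;
        int b = kc[i + k + d]; if (b < 0) continue;
        int idx = map[(size_t) a * Nk + b];
        if (idx < 0) continue;
        std::string key;
        key.reserve(8 + d);
        key += std::to_string(idx);
        key += '#';
        key.append(s, i + k, d);
        if (seen.insert(std::move(key)).second) ++uniq(idx, d - dmin);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return uniq;
}

// All occurrences of one ordered pair (A,B) across the spacer range,
// in genome order, with spacer strings.
// [[Rcpp::export]]
DataFrame cpp_collect_occurrences(CharacterVector seqs, int k,
                                  std::string A, std::string B,
                                  int dmin, int dmax) {
  const int Nk = 1 << (2 * k);
  int acode = 0, bcode = 0;
  for (int i = 0; i < k; ++i) {
    int ca = base_code(A[i]), cb = base_code(B[i]);
    if (ca < 0 || cb < 0) stop("motif k-mers must be over {A,C,G,T}");
    acode = acode * 4 + ca;
    bcode = bcode * 4 + cb;
  }
  (void) Nk;
  std::vector<int> out_rec, out_start, out_d;
  std::vector<std::string> out_sp;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    std::vector<int> kc = kmer_codes(s, k);
    const long L = (long) s.size();
    for (long i = 0; i + 2L * k + dmin <= L; ++i) {
      if (kc[i] != acode) continue;
      for (int d = dmin; d <= dmax; ++d) {
        if (i + 2L * k + d > L) break;
        if (kc[i + k + d] == bcode) {
          out_rec.push_back((int) r + 1);
          out_start.push_back((int) i);
          out_d.push_back(d);
          out_sp.push_back(s.substr(i + k, d));
        }
      }
    }
  }
  return DataFrame::create(_["record_index"] = wrap(out_rec),
                           _["start"] = wrap(out_start),
                           _["d"] = wrap(out_d),
                           _["spacer"] = wrap(out_sp),
                           _["stringsAsFactors"] = false);
}
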