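#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; anything else (N, lowercase handled
// upstream) breaks the current window.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

// Enumerate canonical k-mer codes of one sequence, calling f(code) per window.
template <typename F>
static void for_each_canonical(const char* s, size_t n, int k, F f) {
  if ((int)n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;  // length of current run of valid bases
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++valid >= k) f(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export]]
List cpp_count_canonical_kmers(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_map<uint64_t, double> tab;
  tab.reserve(1 << 20);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t n = LENGTH(STRING_ELT(seqs, i));
    for_each_canonical(s, n, k, [&](uint64_t code) { tab[code] += 1.0; });
  }
  std::vector<std::pair<uint64_t, double>> v(tab.begin(), tab.end());
  std::sort(v.begin(), v.end());
  NumericVector codes(v.size()), counts(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    codes[i] = (double)v[i].first;  // exact: 2k bits <= 62 < 53? no -- k<=26 exact
    counts[i] = v[i].second;
  }
  return List::create(_["code"] = codes, _["count"] = counts);
}

// Forward-strand-only variant (config switch; the default is canonical).
// [[Rcpp::export]]
List cpp_count_plain_kmers(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_map<uint64_t, double> tab;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t n = LENGTH(STRING_ELT(seqs, i));
    uint64_t fwd = 0;
    int valid = 0;
    for (size_t j = 0; j < n; ++j) {
      int c = base_code(s[j]);
      if (c < 0) { valid = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      if (++valid >= k) tab[fwd] += 1.0;
    }
  }
  std::vector<std::pair<uint64_t, double>> v(tab.begin(), tab.end());
  std::sort(v.begin(), v.end());
  NumericVector codes(v.size()), counts(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    codes[i] = (double)v[i].first;
    counts[i] = v[i].second;
  }
  return List::create(_["code"] = codes, _["count"] = counts);
}

// Encode whole k-length strings to (optionally canonical) codes; NA for
// strings of the wrong length or with non-ACGT characters.
// [[Rcpp::export]]
NumericVector cpp_encode_kmers(CharacterVector kmers, int k, bool canonical) {
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if ((int)LENGTH(STRING_ELT(kmers, i)) != k) { out[i] = NA_REAL; continue; }
    uint64_t code = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c = base_code(s[j]);
      if (c < 0) { ok = false; break; }
      code = (code << 2) | (uint64_t)c;
    }
    if (!ok) { out[i] = NA_REAL; continue; }
    if (canonical) {
      uint64_t rc = revcomp_code(code, k);
      if (rc < code) code = rc;
    }
    out[i] = (double)code;
  }
  return out;
}

// Canonical tetramer slot table: maps each of the 256 4-mer codes to one of
// the 136 reverse-complement-collapsed classes, ordered by the smaller code.
// [[Rcpp::export]]
IntegerVector cpp_tnf_slot_table() {
  IntegerVector slot(256, -1);
  int next = 0;
  for (uint64_t code = 0; code < 256; ++code) {
    uint64_t rc = revcomp_code(code, 4);
    uint64_t canon = code < rc ? code : rc;
    if (slot[canon] < 0) slot[canon] = next++;
    slot[code] = slot[canon];
  }
  return slot;  // next == 136
}

// Per-barcode feature counts in one pass: the 400-bin global-frequency
// histogram of canonical `k`-mers and the 136-slot canonical tetramer counts.
// `table_code`/`table_count` is the sorted global k-mer table; k-mers with a
// global count above `max_freq` are discarded (repeat filter).
// [[Rcpp::export]]
List cpp_barcode_feature_counts(CharacterVector seqs,
                                NumericVector table_code,
                                NumericVector table_count,
                                int k, int max_freq, int bin_width,
                                int n_bins) {
  NumericVector hist(n_bins);
  NumericVector tnf(136);
  IntegerVector slot = cpp_tnf_slot_table();
  const double* tc = REAL(table_code);
  const size_t tn = table_code.size();
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t n = LENGTH(STRING_ELT(seqs, i));
    for_each_canonical(s, n, k, [&](uint64_t code) {
      double key = (double)code;
      const double* hit = std::lower_bound(tc, tc + tn, key);
      if (hit == tc + tn || *hit != key) return;  // not in global table
      double f = table_count[hit - tc];
      if (f > max_freq) return;
      int bin = (int)std::ceil(f / bin_width);  // 1-based, (10i-10, 10i]
      if (bin >= 1 && bin <= n_bins) hist[bin - 1] += 1.0;
    });
    for_each_canonical(s, n, 4, [&](uint64_t code) {
      tnf[slot[(int)code]] += 1.0;
    });
  }
  return List::create(_["hist"] = hist, _["tnf"] = tnf);
}
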