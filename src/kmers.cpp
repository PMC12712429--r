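#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
using namespace Rcpp;

// 2-bit encoding A=0, C=1, G=2, T=3; -1 for anything else.
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Rolling scan of one sequence; appends the (canonical) code of every
// k-window made only of A/C/G/T to `out`. Windows touching any other
// symbol are skipped by resetting the fill counter.
static void scan_codes(const char* s, size_t n, int k, bool canonical,
                       std::vector<uint64_t>& out) {
  if ((size_t)k > n) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int rc_shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int filled = 0;
  for (size_t i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { filled = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << rc_shift);
    if (++filled >= k) {
      uint64_t code = fwd;
      if (canonical && rev < code) code = rev;
      out.push_back(code);
    }
  }
}

static std::vector<uint64_t> to_u64(const NumericVector& x) {
  std::vector<uint64_t> v(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) v[i] = (uint64_t)x[i];
  return v;
}

static NumericVector to_dbl(const std::vector<uint64_t>& v) {
  NumericVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = (double)v[i];
  return out;
}

// [[Rcpp::export]]
NumericVector kmer_codes_cpp(CharacterVector seqs, int k, bool canonical) {
  std::vector<uint64_t> codes;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) continue;
    const char* s = CHAR(seqs[i]);
    scan_codes(s, std::strlen(s), k, canonical, codes);
  }
  std::sort(codes.begin(), codes.end());
  codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
  return to_dbl(codes);
}

// Positions (0-based) on one sequence whose k-window canonicalizes to a
// member of the sorted query code set. N-spanning windows never match.
// [[Rcpp::export]]
IntegerVector kmer_hit_positions_cpp(CharacterVector seq, int k, bool canonical,
                                     NumericVector query_codes) {
  std::vector<uint64_t> query = to_u64(query_codes);
  std::vector<int> hits;
  if (seq.size() != 1 || seq[0] == NA_STRING) return IntegerVector(0);
  const char* s = CHAR(seq[0]);
  size_t n = std::strlen(s);
  if ((size_t)k > n) return IntegerVector(0);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int rc_shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int filled = 0;
  for (size_t i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { filled = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << rc_shift);
    if (++filled >= k) {
      uint64_t code = fwd;
      if (canonical && rev < code) code = rev;
      if (std::binary_search(query.begin(), query.end(), code))
        hits.push_back((int)(i) - k + 1);
    }
  }
  return wrap(hits);
}

// [[Rcpp::export]]
CharacterVector decode_kmers_cpp(NumericVector codes, int k) {
  static const char* bases = "ACGT";
  CharacterVector out(codes.size());
  std::string word(k, 'A');
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t c = (uint64_t)codes[i];
    for (int j = k - 1; j >= 0; --j) {
      word[j] = bases[c & 3ULL];
      c >>= 2;
    }
    out[i] = word;
  }
  return out;
}

// Merge-based set algebra on sorted unique code vectors.
// [[Rcpp::export]]
NumericVector sorted_intersect_cpp(NumericVector a, NumericVector b) {
  std::vector<double> out;
  std::set_intersection(a.begin(), a.end(), b.begin(), b.end(),
                        std::back_inserter(out));
  return wrap(out);
}

// [[Rcpp::export]]
NumericVector sorted_union_cpp(NumericVector a, NumericVector b) {
  std::vector<double> out;
  std::set_union(a.begin(), a.end(), b.begin(), b.end(),
                 std::back_inserter(out));
  return wrap(out);
}

// [[Rcpp::export]]
NumericVector sorted_setdiff_cpp(NumericVector a, NumericVector b) {
  std::vector<double> out;
  std::set_difference(a.begin(), a.end(), b.begin(), b.end(),
                      std::back_inserter(out));
  return wrap(out);
}

// Encode explicit words (already length k, ACGT only); canonicalize on
// request; returns sorted unique codes. Errors on bad letters/lengths.
// [[Rcpp::export]]
NumericVector encode_kmers_cpp(CharacterVector words, int k, bool canonical) {
  std::vector<uint64_t> codes;
  codes.reserve(words.size());
  const int rc_shift = 2 * (k - 1);
  for (R_xlen_t i = 0; i < words.size(); ++i) {
    if (words[i] == NA_STRING) stop("NA k-mer word at index %d", (int)i + 1);
    const char* s = CHAR(words[i]);
    if ((int)std::strlen(s) != k)
      stop("word '%s' does not have length k = %d", s, k);
    uint64_t fwd = 0, rev = 0;
    for (int j = 0; j < k; ++j) {
      int b = base_code(s[j]);
      if (b < 0) stop("word '%s' contains a non-ACGT symbol", s);
      fwd = (fwd << 2) | (uint64_t)b;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << rc_shift);
    }
    codes.push_back(canonical && rev < fwd ? rev : fwd);
  }
  std::sort(codes.begin(), codes.end());
  codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
  return to_dbl(codes);
}
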