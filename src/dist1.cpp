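#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Full dynamic-programming Levenshtein distance (unit costs).
// Kept independent of the O(L) predicate below so the two can be
// cross-checked against each other and against external oracles.
static int lev_one(const std::string& a, const std::string& b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0) return (int)m;
  if (m == 0) return (int)n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i;
    for (size_t j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
IntegerVector lev_dist_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  if (b.size() != n) stop("a and b must have equal length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_STRING || b[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    out[i] = lev_one(as<std::string>(a[i]), as<std::string>(b[i]));
  }
  return out;
}

// O(L) predicate: is Levenshtein distance exactly 1?
// Equal lengths -> exactly one mismatching position.
// Lengths differing by 1 -> the longer equals the shorter with one
// character inserted (scan to first mismatch, skip it in the longer,
// require identical suffixes).
static bool dist1_one(const std::string& a, const std::string& b) {
  const size_t n = a.size(), m = b.size();
  if (n == m) {
    int mism = 0;
    for (size_t i = 0; i < n; ++i) {
      if (a[i] != b[i] && ++mism > 1) return false;
    }
    return mism == 1;
  }
  const std::string& s = (n < m) ? a : b;   // shorter
  const std::string& l = (n < m) ? b : a;   // longer
  if (l.size() != s.size() + 1) return false;
  size_t i = 0;
  while (i < s.size() && s[i] == l[i]) ++i;
  return std::equal(s.begin() + i, s.end(), l.begin() + i + 1);
}

// [[Rcpp::export]]
LogicalVector is_dist1_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  if (b.size() != n) stop("a and b must have equal length");
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_STRING || b[i] == NA_STRING) { out[i] = NA_LOGICAL; continue; }
    out[i] = dist1_one(as<std::string>(a[i]), as<std::string>(b[i]));
  }
  return out;
}

// Deletion-variant keys for the distance-1 neighbor index: for each
// sequence, the sequence itself plus every single-character deletion.
// Any pair at Levenshtein distance <= 1 shares at least one key;
// candidates are verified with the exact predicate afterwards.
// [[Rcpp::export]]
List deletion_keys_cpp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  R_xlen_t total = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    total += (R_xlen_t)LENGTH(STRING_ELT(seqs, i)) + 1;
  CharacterVector keys(total);
  IntegerVector id(total);
  R_xlen_t k = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    keys[k] = s; id[k] = (int)(i + 1); ++k;
    for (size_t p = 0; p < s.size(); ++p) {
      std::string v = s;
      v.erase(p, 1);
      keys[k] = v; id[k] = (int)(i + 1); ++k;
    }
  }
  return List::create(_["key"] = keys, _["id"] = id);
}
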