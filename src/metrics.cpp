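#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Plain dynamic-programming Levenshtein with two rolling rows.
// Unit costs for insertion, deletion and substitution.
static int lev_one(const std::string &a, const std::string &b) {
  const size_t la = a.size(), lb = b.size();
  if (la == 0) return (int)lb;
  if (lb == 0) return (int)la;
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (size_t j = 0; j <= lb; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= la; ++i) {
    cur[0] = (int)i;
    for (size_t j = 1; j <= lb; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), sub);
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// Jaro similarity: matches within a window of floor(max(|a|,|b|)/2)-1,
// transpositions counted over matched characters in order.
static double jaro_one(const std::string &a, const std::string &b) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la == 0 && lb == 0) return 1.0;
  if (la == 0 || lb == 0) return 0.0;
  int window = std::max(la, lb) / 2 - 1;
  if (window < 0) window = 0;
  std::vector<char> am(la, 0), bm(lb, 0);
  int m = 0;
  for (int i = 0; i < la; ++i) {
    int lo = std::max(0, i - window), hi = std::min(lb - 1, i + window);
    for (int j = lo; j <= hi; ++j) {
      if (!bm[j] && a[i] == b[j]) {
        am[i] = bm[j] = 1;
        ++m;
        break;
      }
    }
  }
  if (m == 0) return 0.0;
  int t2 = 0, j = 0;  // half-transposition count
  for (int i = 0; i < la; ++i) {
    if (!am[i]) continue;
    while (!bm[j]) ++j;
    if (a[i] != b[j]) ++t2;
    ++j;
  }
  double t = t2 / 2.0;
  return ((double)m / la + (double)m / lb + (m - t) / m) / 3.0;
}

static double jw_one(const std::string &a, const std::string &b, double p) {
  double j = jaro_one(a, b);
  int prefix = 0;
  size_t lim = std::min(std::min(a.size(), b.size()), (size_t)4);
  for (size_t i = 0; i < lim; ++i) {
    if (a[i] == b[i]) ++prefix; else break;
  }
  return j + prefix * p * (1.0 - j);
}

// [[Rcpp::export(name = ".lev_cpp")]]
IntegerVector lev_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  if (a.size() != n && a.size() != 1) stop("length mismatch");
  if (b.size() != n && b.size() != 1) stop("length mismatch");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    String sa = a[a.size() == 1 ? 0 : i], sb = b[b.size() == 1 ? 0 : i];
    if (sa == NA_STRING || sb == NA_STRING) { out[i] = NA_INTEGER; continue; }
    out[i] = lev_one(std::string(sa.get_cstring()), std::string(sb.get_cstring()));
  }
  return out;
}

// [[Rcpp::export(name = ".jw_cpp")]]
NumericVector jw_cpp(CharacterVector a, CharacterVector b, double prefix_weight) {
  if (prefix_weight < 0 || prefix_weight > 0.25)
    stop("prefix_weight must be in [0, 0.25]");
  R_xlen_t n = std::max(a.size(), b.size());
  if (a.size() != n && a.size() != 1) stop("length mismatch");
  if (b.size() != n && b.size() != 1) stop("length mismatch");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    String sa = a[a.size() == 1 ? 0 : i], sb = b[b.size() == 1 ? 0 : i];
    if (sa == NA_STRING || sb == NA_STRING) { out[i] = NA_REAL; continue; }
    out[i] = jw_one(std::string(sa.get_cstring()), std::string(sb.get_cstring()),
                    prefix_weight);
  }
  return out;
}
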