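#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

static const int BIG = 1 << 28;

// Plain Levenshtein, full dynamic program.
static int lev(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] != b[j - 1]);
      cur[j] = std::min(sub, std::min(prev[j], cur[j - 1]) + 1);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Banded Levenshtein with early abandon; returns k+1 when distance > k.
static int lev_bounded(const std::string& a, const std::string& b, int k) {
  const int n = a.size(), m = b.size();
  if (std::abs(n - m) > k) return k + 1;
  const int w = 2 * k + 1;
  std::vector<int> prev(w, BIG), cur(w, BIG);
  // column j stored at index j - (i - k)
  for (int j = 0; j <= std::min(m, k); ++j) prev[j + k] = j;
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(0, i - k), hi = std::min(m, i + k);
    std::fill(cur.begin(), cur.end(), BIG);
    int rowmin = BIG;
    for (int j = lo; j <= hi; ++j) {
      int idx = j - i + k;
      int best = BIG;
      if (j > 0) {
        int diag = prev[idx];  // (i-1, j-1)
        if (diag < BIG) best = diag + (a[i - 1] != b[j - 1]);
        if (idx - 1 >= 0 && cur[idx - 1] < best) best = cur[idx - 1] + 1;  // (i, j-1)
      } else {
        best = i;
      }
      if (idx + 1 < w && prev[idx + 1] < BIG && prev[idx + 1] + 1 < best)
        best = prev[idx + 1] + 1;  // (i-1, j)
      cur[idx] = best;
      if (best < rowmin) rowmin = best;
    }
    if (rowmin > k) return k + 1;
    std::swap(prev, cur);
  }
  int res = prev[m - n + k];
  return res > k ? k + 1 : res;
}

// [[Rcpp::export]]
int cpp_edit_distance(std::string a, std::string b) { return lev(a, b); }

// [[Rcpp::export]]
IntegerVector cpp_bounded_edit_many(std::string center, CharacterVector others, int k) {
  const int n = others.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = lev_bounded(center, std::string(others[i]), k);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_edit_distance_matrix(CharacterVector a, CharacterVector b) {
  const int n = a.size(), m = b.size();
  IntegerVector out(n * m);
  std::vector<std::string> bs(m);
  for (int j = 0; j < m; ++j) bs[j] = std::string(b[j]);
  for (int i = 0; i < n; ++i) {
    std::string ai = std::string(a[i]);
    for (int j = 0; j < m; ++j) out[i + (R_xlen_t)n * j] = lev(ai, bs[j]);
  }
  out.attr("dim") = IntegerVector::create(n, m);
  return out;
}

// Semi-global (infix) alignment: whole pattern against any substring of text.
// Returns 1-based start, end (inclusive) of the best-matching substring and
// its edit count; ties resolved toward fewer edits, then smaller start, then
// smaller end.
// [[Rcpp::export]]
List cpp_best_infix(std::string pattern, std::string text) {
  const int n = pattern.size(), m = text.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<int> pstart(m + 1), cstart(m + 1);
  for (int j = 0; j <= m; ++j) { prev[j] = 0; pstart[j] = j; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i; cstart[0] = 0;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (pattern[i - 1] != text[j - 1]);
      int del = prev[j] + 1;      // consume pattern char, not text
      int ins = cur[j - 1] + 1;   // consume text char
      int best = sub, bstart = pstart[j - 1];
      if (del < best || (del == best && pstart[j] < bstart)) { best = del; bstart = pstart[j]; }
      if (ins < best || (ins == best && cstart[j - 1] < bstart)) { best = ins; bstart = cstart[j - 1]; }
      cur[j] = best; cstart[j] = bstart;
    }
    std::swap(prev, cur);
    std::swap(pstart, cstart);
  }
  int bestj = 0, beste = BIG, bests = 0;
  for (int j = 0; j <= m; ++j) {
    if (prev[j] < beste || (prev[j] == beste && pstart[j] < bests)) {
      beste = prev[j]; bests = pstart[j]; bestj = j;
    }
  }
  return List::create(_["start"] = bests + 1, _["end"] = bestj,
                      _["edits"] = beste);
}
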