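#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Semi-global (containment) edit distance: the whole pattern aligned against
// the best-matching region of the text, gaps at both text ends free.
// D[0][j] = 0, D[i][0] = i, answer = min_j D[m][j].
static int hw_edit(const std::string& p, const std::string& t) {
  const int m = (int)p.size(), n = (int)t.size();
  std::vector<int> col(m + 1);
  for (int i = 0; i <= m; ++i) col[i] = i;
  int best = col[m];
  for (int j = 1; j <= n; ++j) {
    int diag = col[0];
    col[0] = 0;
    const char tc = t[j - 1];
    for (int i = 1; i <= m; ++i) {
      const int up = col[i];
      int v = diag + (p[i - 1] != tc);
      const int del = col[i - 1] + 1;
      if (del < v) v = del;
      const int ins = up + 1;
      if (ins < v) v = ins;
      col[i] = v;
      diag = up;
    }
    if (col[m] < best) best = col[m];
  }
  return best;
}

// [[Rcpp::export]]
int hw_edit_cpp(std::string pattern, std::string text) {
  if (pattern.empty() || text.empty()) stop("sequences must be non-empty");
  return hw_edit(pattern, text);
}

// Containment identity per pair: 1 - d/len(shorter) with d the semi-global
// edit distance of the shorter sequence within the longer. Equal lengths:
// both orientations computed and averaged.
// [[Rcpp::export]]
NumericVector ani_pairs_cpp(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("a and b must have equal length");
  NumericVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    std::string x = as<std::string>(a[i]);
    std::string y = as<std::string>(b[i]);
    if (x.empty() || y.empty()) stop("sequences must be non-empty");
    double id;
    if (x.size() == y.size()) {
      double d = 0.5 * (hw_edit(x, y) + hw_edit(y, x));
      id = 1.0 - d / (double)x.size();
    } else {
      const std::string& s = x.size() < y.size() ? x : y;
      const std::string& l = x.size() < y.size() ? y : x;
      id = 1.0 - (double)hw_edit(s, l) / (double)s.size();
    }
    out[i] = std::max(0.0, std::min(1.0, id));
  }
  return out;
}
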