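// Smith-Waterman local self-alignment with the main diagonal (and the
// whole lower triangle, to drop mirror duplicates) forbidden, plus a
// residue mask so previously extracted repeat footprints can be excluded
// (Waterman-Eggert style iteration). Affine gaps: a gap of length k costs
// open + k * extend.

#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_sw_self(IntegerVector seq, NumericMatrix sub, double gap_open,
                 double gap_extend, LogicalVector mask) {
  const int n = seq.size();
  if (n > 6000) stop("sequence too long for self-alignment scan");
  const double NEG = -1e30;
  const double go = gap_open + gap_extend;  // cost of first gap residue

  std::vector<double> H((n + 1) * (n + 1), 0.0), E((n + 1) * (n + 1), NEG),
      F((n + 1) * (n + 1), NEG);
#define AT(i, j) ((i) * (n + 1) + (j))

  double best = 0.0;
  int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    for (int j = i + 1; j <= n; ++j) {  // upper triangle only
      bool bad = mask[i - 1] || mask[j - 1];
      if (bad) { H[AT(i, j)] = 0.0; E[AT(i, j)] = NEG; F[AT(i, j)] = NEG; continue; }
      double e = std::max(H[AT(i, j - 1)] - go, E[AT(i, j - 1)] - gap_extend);
      double f = std::max(H[AT(i - 1, j)] - go, F[AT(i - 1, j)] - gap_extend);
      double d = H[AT(i - 1, j - 1)] + sub(seq[i - 1] - 1, seq[j - 1] - 1);
      double h = std::max(0.0, std::max(d, std::max(e, f)));
      E[AT(i, j)] = e; F[AT(i, j)] = f; H[AT(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (bi < 0) {
    return List::create(_["score"] = 0.0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER);
  }

  // traceback (diag preferred, then gap states)
  int i = bi, j = bj, qe = bi, se = bj;
  int state = 0;  // 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
  while (true) {
    if (state == 0) {
      double h = H[AT(i, j)];
      if (h <= 0.0) break;
      double d = H[AT(i - 1, j - 1)] + sub(seq[i - 1] - 1, seq[j - 1] - 1);
      if (h == d) { --i; --j; }
      else if (h == E[AT(i, j)]) state = 1;
      else state = 2;
    } else if (state == 1) {
      double e = E[AT(i, j)];
      if (e == H[AT(i, j - 1)] - go) { --j; state = 0; }
      else { --j; }
    } else {
      double f = F[AT(i, j)];
      if (f == H[AT(i - 1, j)] - go) { --i; state = 0; }
      else { --i; }
    }
  }

  // 0-based half-open intervals: query rows (i+1..qe), subject cols
  return List::create(_["score"] = best,
                      _["q_start"] = i, _["q_end"] = qe,
                      _["s_start"] = j, _["s_end"] = se);
#undef AT
}
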