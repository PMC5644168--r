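#include <Rcpp.h>
using namespace Rcpp;

// Fit alignment of a degenerate primer against an ungapped target: the
// primer must be fully aligned, the target offers free ends, and the site
// minimizing the weighted mismatch score is reported.  Because the weighted
// score is a single additive objective and a degenerate position matches a
// target base whenever their IUPAC bitmasks intersect (at zero cost), this
// minimum equals the minimum over all concrete expansions of the primer.
// Bases are IUPAC bitmasks (A=1, C=2, G=4, T=8).
//
// [[Rcpp::export]]
List primer_fit_align(IntegerVector primer, IntegerVector target,
                      LogicalVector in3, double w_mm_non3, double w_mm_3,
                      double w_gap_non3, double w_gap_3) {
  const int m = primer.size(), n = target.size();
  if (m == 0) stop("empty primer");
  const int cols = n + 1;
  std::vector<double> W((m + 1) * cols);
  std::vector<unsigned char> P((m + 1) * cols, 0);  // 1 diag, 2 up, 3 left
  auto idx = [cols](int i, int j) { return i * cols + j; };

  for (int j = 0; j <= n; ++j) W[idx(0, j)] = 0.0;   // free target prefix
  for (int i = 1; i <= m; ++i) {
    W[idx(i, 0)] = W[idx(i - 1, 0)] + (in3[i - 1] ? w_gap_3 : w_gap_non3);
    P[idx(i, 0)] = 2;
  }
  for (int i = 1; i <= m; ++i) {
    const bool hot = in3[i - 1];
    const double mmw = hot ? w_mm_3 : w_mm_non3;
    const double gpw = hot ? w_gap_3 : w_gap_non3;
    for (int j = 1; j <= n; ++j) {
      const bool match = (primer[i - 1] & target[j - 1]) != 0;
      double w = W[idx(i - 1, j - 1)] + (match ? 0.0 : mmw);
      unsigned char p = 1;
      const double w2 = W[idx(i - 1, j)] + gpw;   // primer base over a gap
      if (w2 < w) { w = w2; p = 2; }
      // insertion in the target within the primer span; its 3' flag follows
      // the last consumed primer position
      const double w3 = W[idx(i, j - 1)] + gpw;
      if (w3 < w) { w = w3; p = 3; }
      W[idx(i, j)] = w; P[idx(i, j)] = p;
    }
  }
  int jbest = 0;
  for (int j = 1; j <= n; ++j)
    if (W[idx(m, j)] < W[idx(m, jbest)]) jbest = j;

  // traceback for per-category counts and the site coordinates
  int i = m, j = jbest;
  int mm3 = 0, mmN = 0, gap3 = 0, gapN = 0;
  while (i > 0) {
    const bool hot = in3[i - 1];
    const unsigned char p = P[idx(i, j)];
    if (p == 1) {
      if ((primer[i - 1] & target[j - 1]) == 0) { if (hot) ++mm3; else ++mmN; }
      --i; --j;
    } else if (p == 2) {
      if (hot) ++gap3; else ++gapN;
      --i;
    } else {
      if (hot) ++gap3; else ++gapN;
      --j;
    }
  }
  return List::create(_["score"] = W[idx(m, jbest)],
                      _["start"] = j + 1, _["end"] = jbest,
                      _["mm3"] = mm3, _["mmN"] = mmN,
                      _["gap3"] = gap3, _["gapN"] = gapN);
}
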