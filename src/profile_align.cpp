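#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment of two alignment profiles (columns = frequency
// vectors over A,C,G,T,gap). Column-column score is the expected pairwise
// substitution score (match/mismatch) between residues drawn from the two
// columns; residues paired with existing profile gaps score 0. New gaps pay
// gapOpen to open and gapExt to extend, unscaled.
//
// Returns 1-based source column indices per merged column (0 = new gap).

static inline double colScore(const NumericMatrix &A, const NumericMatrix &B,
                              int i, int j, double match, double mismatch) {
  double s = 0.0;
  for (int x = 0; x < 4; ++x) {
    double fa = A(x, i);
    if (fa == 0.0) continue;
    for (int y = 0; y < 4; ++y) {
      double fb = B(y, j);
      if (fb == 0.0) continue;
      s += fa * fb * (x == y ? match : mismatch);
    }
  }
  return s;
}

// [[Rcpp::export(name = ".cppAlignProfiles")]]
List cppAlignProfiles(NumericMatrix A, NumericMatrix B,
                      double match, double mismatch,
                      double gapOpen, double gapExt) {
  const int la = A.ncol(), lb = B.ncol();
  const double NEG = -1e30;
  // rolling rows of scores; full byte traceback
  std::vector<double> Mprev(lb + 1), Xprev(lb + 1), Yprev(lb + 1);
  std::vector<double> Mcur(lb + 1), Xcur(lb + 1), Ycur(lb + 1);
  // traceback: state 0=M,1=X(gap in B),2=Y(gap in A); value = previous state
  std::vector<unsigned char> tb((size_t)(la + 1) * (lb + 1) * 3);
  auto TB = [&](int i, int j, int s) -> unsigned char & {
    return tb[((size_t)i * (lb + 1) + j) * 3 + s];
  };

  Mprev[0] = 0.0; Xprev[0] = NEG; Yprev[0] = NEG;
  for (int j = 1; j <= lb; ++j) {
    Mprev[j] = NEG;
    Xprev[j] = NEG;
    Yprev[j] = (j == 1 ? -gapOpen : Yprev[j - 1] - gapExt);
    TB(0, j, 2) = (j == 1 ? 0 : 2);
  }
  for (int i = 1; i <= la; ++i) {
    Mcur[0] = NEG;
    Ycur[0] = NEG;
    Xcur[0] = (i == 1 ? -gapOpen : Xprev[0] - gapExt);
    TB(i, 0, 1) = (i == 1 ? 0 : 1);
    for (int j = 1; j <= lb; ++j) {
      // M: consume column i of A and j of B
      double sc = colScore(A, B, i - 1, j - 1, match, mismatch);
      double bm = Mprev[j - 1]; unsigned char pm = 0;
      if (Xprev[j - 1] > bm) { bm = Xprev[j - 1]; pm = 1; }
      if (Yprev[j - 1] > bm) { bm = Yprev[j - 1]; pm = 2; }
      Mcur[j] = bm + sc; TB(i, j, 0) = pm;
      // X: consume column i of A, gap in B
      double bx = Mprev[j] - gapOpen; unsigned char px = 0;
      if (Xprev[j] - gapExt > bx) { bx = Xprev[j] - gapExt; px = 1; }
      Xcur[j] = bx; TB(i, j, 1) = px;
      // Y: consume column j of B, gap in A
      double by = Mcur[j - 1] - gapOpen; unsigned char py = 0;
      if (Ycur[j - 1] - gapExt > by) { by = Ycur[j - 1] - gapExt; py = 2; }
      Ycur[j] = by; TB(i, j, 2) = py;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  int state = 0;
  double best = Mprev[lb];
  if (Xprev[lb] > best) { best = Xprev[lb]; state = 1; }
  if (Yprev[lb] > best) { best = Yprev[lb]; state = 2; }

  std::vector<int> ai, bi;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    unsigned char prev = TB(i, j, state);
    if (state == 0) { ai.push_back(i); bi.push_back(j); --i; --j; }
    else if (state == 1) { ai.push_back(i); bi.push_back(0); --i; }
    else { ai.push_back(0); bi.push_back(j); --j; }
    state = prev;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi),
                      _["score"] = best);
}
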