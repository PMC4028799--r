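#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment of two alignment profiles.
//
// A profile column is a 4-vector of A/C/G/T frequencies (gap/N mass simply
// reduces the column weight). The column-pair score is
//   match * <fa, fb> + mismatch * (wa * wb - <fa, fb>)
// with wa = sum(fa). Three-state DP (match / gap-in-B / gap-in-A) with byte
// traceback; returns, for each output column, the source column in each
// profile (0 = gap).
//
// [[Rcpp::export]]
List align_profiles_cpp(NumericMatrix A, NumericMatrix B,
                        double match, double mismatch,
                        double gap_open, double gap_ext) {
  const int la = A.ncol(), lb = B.ncol();
  const double NEG = -1e30;
  std::vector<double> wa(la), wb(lb);
  for (int i = 0; i < la; ++i) {
    double s = 0; for (int r = 0; r < 4; ++r) s += A(r, i);
    wa[i] = s;
  }
  for (int j = 0; j < lb; ++j) {
    double s = 0; for (int r = 0; r < 4; ++r) s += B(r, j);
    wb[j] = s;
  }
  // DP rows (previous and current) for three states
  std::vector<double> Mprev(lb + 1), Xprev(lb + 1), Yprev(lb + 1),
      Mcur(lb + 1), Xcur(lb + 1), Ycur(lb + 1);
  // traceback: 2 bits per state cell
  std::vector<unsigned char> tbM((la + 1) * (lb + 1)),
      tbX((la + 1) * (lb + 1)), tbY((la + 1) * (lb + 1));
  const int W = lb + 1;
  Mprev[0] = 0; Xprev[0] = NEG; Yprev[0] = NEG;
  for (int j = 1; j <= lb; ++j) {
    Mprev[j] = NEG;
    Xprev[j] = NEG;
    Yprev[j] = -gap_open - gap_ext * j;
    tbY[j] = (j == 1) ? 0 : 2;  // 0: from M, 2: extend
  }
  for (int i = 1; i <= la; ++i) {
    Mcur[0] = NEG;
    Xcur[0] = -gap_open - gap_ext * i;
    tbX[i * W] = (i == 1) ? 0 : 1;
    Ycur[0] = NEG;
    for (int j = 1; j <= lb; ++j) {
      double dot = 0;
      for (int r = 0; r < 4; ++r) dot += A(r, i - 1) * B(r, j - 1);
      double sc = match * dot + mismatch * (wa[i - 1] * wb[j - 1] - dot);
      // M: diagonal from best of three
      double m0 = Mprev[j - 1], m1 = Xprev[j - 1], m2 = Yprev[j - 1];
      int bm = 0; double bv = m0;
      if (m1 > bv) { bv = m1; bm = 1; }
      if (m2 > bv) { bv = m2; bm = 2; }
      Mcur[j] = bv + sc;
      tbM[i * W + j] = (unsigned char)bm;
      // X: gap in B (consume A column i)
      double xo = Mprev[j] - gap_open - gap_ext;
      double xe = Xprev[j] - gap_ext;
      if (xo >= xe) { Xcur[j] = xo; tbX[i * W + j] = 0; }
      else { Xcur[j] = xe; tbX[i * W + j] = 1; }
      // Y: gap in A (consume B column j)
      double yo = Mcur[j - 1] - gap_open - gap_ext;
      double ye = Ycur[j - 1] - gap_ext;
      if (yo >= ye) { Ycur[j] = yo; tbY[i * W + j] = 0; }
      else { Ycur[j] = ye; tbY[i * W + j] = 2; }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  // traceback from the best terminal state
  int state = 0;
  double best = Mprev[lb];
  if (Xprev[lb] > best) { best = Xprev[lb]; state = 1; }
  if (Yprev[lb] > best) { best = Yprev[lb]; state = 2; }
  std::vector<int> ai, bi;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tbM[i * W + j];
      ai.push_back(i); bi.push_back(j);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      int prev = tbX[i * W + j];
      ai.push_back(i); bi.push_back(0);
      --i;
      state = prev;
    } else {
      int prev = tbY[i * W + j];
      ai.push_back(0); bi.push_back(j);
      --j;
      state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi),
                      _["score"] = best);
}
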