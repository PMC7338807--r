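#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Gotoh (affine-gap) global alignment of two alignment profiles.
//
// Profiles are (K+1) x L frequency matrices over a K-letter alphabet plus
// a final gap row; columns sum to 1. The column-pair score averages the
// substitution matrix S (K x K) over residue frequencies; existing gaps
// score 0 against anything, only newly introduced gap columns pay the
// affine penalty (gap_open for a run plus gap_ext per column). End gaps
// are penalised.
//
// Returns the edit path as integers: 0 = both profiles advance,
// 1 = only the first advances (gap column inserted into the second),
// 2 = only the second advances.
// [[Rcpp::export(name = ".profile_align_ops")]]
IntegerVector profile_align_ops(NumericMatrix A, NumericMatrix B,
                                NumericMatrix S,
                                double gap_open = 2.0,
                                double gap_ext = 1.0) {
  const int K = S.nrow();
  if (A.nrow() != K + 1 || B.nrow() != K + 1 || S.ncol() != K)
    stop("profiles must have K+1 rows for a K x K score matrix");
  const int la = A.ncol(), lb = B.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();
  const double first = gap_open + gap_ext;  // cost of a gap's first column

  // precompute S-weighted profile: SB[x][j] = sum_y S[x][y] * B[y][j]
  std::vector<double> SB((size_t)K * lb, 0.0);
  for (int j = 0; j < lb; ++j)
    for (int x = 0; x < K; ++x) {
      double v = 0.0;
      for (int y = 0; y < K; ++y) v += S(x, y) * B(y, j);
      SB[(size_t)x * lb + j] = v;
    }

  const size_t W = (size_t)(lb + 1);
  std::vector<double> M((size_t)(la + 1) * W, NEG);
  std::vector<double> X((size_t)(la + 1) * W, NEG);  // gap in B (A advances)
  std::vector<double> Y((size_t)(la + 1) * W, NEG);  // gap in A (B advances)
  std::vector<unsigned char> tM((size_t)(la + 1) * W, 0);
  std::vector<unsigned char> tX((size_t)(la + 1) * W, 0);
  std::vector<unsigned char> tY((size_t)(la + 1) * W, 0);

  M[0] = 0.0;
  for (int i = 1; i <= la; ++i) {
    X[(size_t)i * W] = -(gap_open + gap_ext * i);
    tX[(size_t)i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= lb; ++j) {
    Y[(size_t)j] = -(gap_open + gap_ext * j);
    tY[(size_t)j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= la; ++i) {
    const size_t ri = (size_t)i * W, rp = (size_t)(i - 1) * W;
    for (int j = 1; j <= lb; ++j) {
      double s = 0.0;
      for (int x = 0; x < K; ++x)
        s += A(x, i - 1) * SB[(size_t)x * lb + (j - 1)];

      double m0 = M[rp + j - 1], m1 = X[rp + j - 1], m2 = Y[rp + j - 1];
      unsigned char tb = 0; double best = m0;
      if (m1 > best) { best = m1; tb = 1; }
      if (m2 > best) { best = m2; tb = 2; }
      M[ri + j] = (best == NEG) ? NEG : best + s;
      tM[ri + j] = tb;

      double xo = (M[rp + j] == NEG) ? NEG : M[rp + j] - first;
      double xe = (X[rp + j] == NEG) ? NEG : X[rp + j] - gap_ext;
      if (xo >= xe) { X[ri + j] = xo; tX[ri + j] = 0; }
      else          { X[ri + j] = xe; tX[ri + j] = 1; }

      double yo = (M[ri + j - 1] == NEG) ? NEG : M[ri + j - 1] - first;
      double ye = (Y[ri + j - 1] == NEG) ? NEG : Y[ri + j - 1] - gap_ext;
      if (yo >= ye) { Y[ri + j] = yo; tY[ri + j] = 0; }
      else          { Y[ri + j] = ye; tY[ri + j] = 2; }
    }
  }

  // traceback from the best end state, preferring M > X > Y on ties
  size_t endc = (size_t)la * W + lb;
  unsigned char state = 0; double best = M[endc];
  if (X[endc] > best) { best = X[endc]; state = 1; }
  if (Y[endc] > best) { best = Y[endc]; state = 2; }

  std::vector<int> ops;
  ops.reserve(la + lb);
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    size_t c = (size_t)i * W + j;
    if (state == 0) {
      if (i == 0 || j == 0) { state = (i == 0) ? 2 : 1; continue; }
      unsigned char prev = tM[c];
      ops.push_back(0); --i; --j; state = prev;
    } else if (state == 1) {
      unsigned char prev = tX[c];
      ops.push_back(1); --i; state = prev;
    } else {
      unsigned char prev = tY[c];
      ops.push_back(2); --j; state = prev;
    }
  }
  IntegerVector out(ops.size());
  for (size_t k = 0; k < ops.size(); ++k)
    out[k] = ops[ops.size() - 1 - k];
  return out;
}
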