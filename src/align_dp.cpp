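#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps over a precomputed
// column-vs-column score matrix S (n x m).  A gap of length L costs
// goc + (L-1)*gec; terminal gaps are charged.  Three-state DP (M = diagonal,
// X = gap in b / consume a, Y = gap in a / consume b).  Tie-break on
// traceback: prefer M, then X (gap in b), then Y.
//
// Returns the optimal score and the edit path encoded as integers:
// 0 = match/mismatch column, 1 = column from a only (gap in b),
// 2 = column from b only (gap in a), ordered from the start of the alignment.

// [[Rcpp::export(name = ".affine_align_cpp")]]
List affine_align_cpp(NumericMatrix S, double goc, double gec) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e300;
  // DP matrices, (n+1) x (m+1)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix bM(n + 1, m + 1), bX(n + 1, m + 1), bY(n + 1, m + 1);
  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -goc - (i - 1) * gec;
    bX(i, 0) = 1; // came from X
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -goc - (j - 1) * gec;
    bY(0, j) = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: consume both
      double s = S(i - 1, j - 1);
      double vM = M(i - 1, j - 1), vX = X(i - 1, j - 1), vY = Y(i - 1, j - 1);
      double best = vM; int who = 0;
      if (vX > best) { best = vX; who = 1; }
      if (vY > best) { best = vY; who = 2; }
      M(i, j) = best + s; bM(i, j) = who;
      // X: gap in b, consume a row i
      double openX = M(i - 1, j) - goc;
      double extX  = X(i - 1, j) - gec;
      double crossX = Y(i - 1, j) - goc; // close one gap, open another
      best = openX; who = 0;
      if (extX > best) { best = extX; who = 1; }
      if (crossX > best) { best = crossX; who = 2; }
      X(i, j) = best; bX(i, j) = who;
      // Y: gap in a, consume b column j
      double openY = M(i, j - 1) - goc;
      double extY  = Y(i, j - 1) - gec;
      double crossY = X(i, j - 1) - goc;
      best = openY; who = 0;
      if (extY > best) { best = extY; who = 2; }
      if (crossY > best) { best = crossY; who = 1; }
      Y(i, j) = best; bY(i, j) = who;
    }
  }
  // final state: prefer M, then X, then Y on ties
  double sc = M(n, m); int st = 0;
  if (X(n, m) > sc) { sc = X(n, m); st = 1; }
  if (Y(n, m) > sc) { sc = Y(n, m); st = 2; }
  // traceback
  std::vector<int> ops;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (st == 0) {
      int who = bM(i, j);
      ops.push_back(0); --i; --j; st = who;
    } else if (st == 1) {
      int who = bX(i, j);
      ops.push_back(1); --i; st = (who == 0) ? 0 : (who == 1 ? 1 : 2);
    } else {
      int who = bY(i, j);
      ops.push_back(2); --j; st = (who == 0) ? 0 : (who == 2 ? 2 : 1);
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = sc, _["ops"] = wrap(ops));
}
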