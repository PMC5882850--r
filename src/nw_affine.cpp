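#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Global (ends-penalized) Needleman-Wunsch with affine gaps.
// A gap of length L costs open + (L-1)*extend.
// Three-state DP (M = match/mismatch, X = gap in b / consume a / "up",
// Y = gap in a / consume b / "left"); traceback tie-break prefers
// M > X > Y at every choice, giving a deterministic optimal alignment.
//
// a, b: integer-encoded sequences (0-based codes into the score matrix).
// score_matrix: symmetric lookup, rows/cols in code order.

// [[Rcpp::export]]
List nw_affine_cpp(IntegerVector a, IntegerVector b,
                   NumericMatrix score_matrix,
                   double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();

  // DP tables, (n+1) x (m+1), row-major
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  // predecessor state per cell/state: 0=M, 1=X, 2=Y, -1 = none
  std::vector<signed char> pM((n + 1) * (m + 1), -1);
  std::vector<signed char> pX((n + 1) * (m + 1), -1);
  std::vector<signed char> pY((n + 1) * (m + 1), -1);

  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[idx(i, 0)] = -(gap_open + (i - 1) * gap_extend);
    pX[idx(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[idx(0, j)] = -(gap_open + (j - 1) * gap_extend);
    pY[idx(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = score_matrix(a[i - 1], b[j - 1]);
      // M: prefer M > X > Y among equal predecessors
      {
        double best = M[idx(i - 1, j - 1)];
        signed char arg = 0;
        if (X[idx(i - 1, j - 1)] > best) { best = X[idx(i - 1, j - 1)]; arg = 1; }
        if (Y[idx(i - 1, j - 1)] > best) { best = Y[idx(i - 1, j - 1)]; arg = 2; }
        if (best > NEG) { M[idx(i, j)] = best + s; pM[idx(i, j)] = arg; }
      }
      // X: gap in b, consume a[i-1] (move up)
      {
        double cand[3] = { M[idx(i - 1, j)] - gap_open,
                           X[idx(i - 1, j)] - gap_extend,
                           Y[idx(i - 1, j)] - gap_open };
        double best = cand[0]; signed char arg = 0;
        if (cand[1] > best) { best = cand[1]; arg = 1; }
        if (cand[2] > best) { best = cand[2]; arg = 2; }
        if (best > NEG) { X[idx(i, j)] = best; pX[idx(i, j)] = arg; }
      }
      // Y: gap in a, consume b[j-1] (move left)
      {
        double cand[3] = { M[idx(i, j - 1)] - gap_open,
                           X[idx(i, j - 1)] - gap_open,
                           Y[idx(i, j - 1)] - gap_extend };
        double best = cand[0]; signed char arg = 0;
        if (cand[1] > best) { best = cand[1]; arg = 1; }
        if (cand[2] > best) { best = cand[2]; arg = 2; }
        if (best > NEG) { Y[idx(i, j)] = best; pY[idx(i, j)] = arg; }
      }
    }
  }

  // final state, tie-break M > X > Y
  double fin[3] = { M[idx(n, m)], X[idx(n, m)], Y[idx(n, m)] };
  int state = 0;
  if (fin[1] > fin[state]) state = 1;
  if (fin[2] > fin[state]) state = 2;
  const double score = fin[state];

  // traceback
  std::vector<int> ops; // 0 = diag, 1 = up (gap in b), 2 = left (gap in a)
  int i = n, j = m;
  while (i > 0 || j > 0) {
    signed char prev;
    if (state == 0) {
      prev = pM[idx(i, j)];
      ops.push_back(0); --i; --j;
    } else if (state == 1) {
      prev = pX[idx(i, j)];
      ops.push_back(1); --i;
    } else {
      prev = pY[idx(i, j)];
      ops.push_back(2); --j;
    }
    state = prev;
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
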