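#include <Rcpp.h>
using namespace Rcpp;

// Global affine profile-to-sequence alignment.
//
// S is an (n x m) score matrix: S(i, j) = column score of new-sequence
// residue i+1 against profile column j+1 (mean substitution score over
// the profile rows, gaps contributing 0). Gaps are penalized affinely:
// a run of length L costs gapOpen + (L - 1) * gapExtend, including
// terminal gaps (true end-to-end global alignment).
//
// Returns an op path from alignment start plus the optimal score.
// ops: 0 = consume both (residue vs column), 1 = gap in the new
// sequence (column consumed), 2 = gap column inserted into the profile
// (residue consumed).
// [[Rcpp::export]]
List profile_align_path(NumericMatrix S, double gapOpen,
                        double gapExtend) {
  const int n = S.nrow();   // new sequence length
  const int m = S.ncol();   // profile length
  const double NEG = -1e30;
  // state 0 = M (diagonal), 1 = X (gap in new seq), 2 = Y (gap column)
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  std::vector<signed char> pM((n + 1) * (m + 1), -1);
  std::vector<signed char> pX((n + 1) * (m + 1), -1);
  std::vector<signed char> pY((n + 1) * (m + 1), -1);
  const int W = m + 1;
#define AT(i, j) ((i) * W + (j))
  M[AT(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) {
    X[AT(0, j)] = (j == 1) ? -gapOpen : X[AT(0, j - 1)] - gapExtend;
    pX[AT(0, j)] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    Y[AT(i, 0)] = (i == 1) ? -gapOpen : Y[AT(i - 1, 0)] - gapExtend;
    pY[AT(i, 0)] = (i == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: deterministic tie order M > X > Y
      double a = M[AT(i - 1, j - 1)], b = X[AT(i - 1, j - 1)],
             c = Y[AT(i - 1, j - 1)];
      double best = a; signed char arg = 0;
      if (b > best) { best = b; arg = 1; }
      if (c > best) { best = c; arg = 2; }
      if (best > NEG / 2) {
        M[AT(i, j)] = best + S(i - 1, j - 1);
        pM[AT(i, j)] = arg;
      }
      // X: gap in new sequence, consume profile column j
      a = M[AT(i, j - 1)] - gapOpen;
      b = X[AT(i, j - 1)] - gapExtend;
      c = Y[AT(i, j - 1)] - gapOpen;
      best = a; arg = 0;
      if (b > best) { best = b; arg = 1; }
      if (c > best) { best = c; arg = 2; }
      if (best > NEG / 2) { X[AT(i, j)] = best; pX[AT(i, j)] = arg; }
      // Y: gap column inserted, consume sequence residue i
      a = M[AT(i - 1, j)] - gapOpen;
      b = X[AT(i - 1, j)] - gapOpen;
      c = Y[AT(i - 1, j)] - gapExtend;
      best = a; arg = 0;
      if (b > best) { best = b; arg = 1; }
      if (c > best) { best = c; arg = 2; }
      if (best > NEG / 2) { Y[AT(i, j)] = best; pY[AT(i, j)] = arg; }
    }
  }
  double sM = M[AT(n, m)], sX = X[AT(n, m)], sY = Y[AT(n, m)];
  double score = sM; int state = 0;
  if (sX > score) { score = sX; state = 1; }
  if (sY > score) { score = sY; state = 2; }
  // traceback
  std::vector<int> ops;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = pM[AT(i, j)];
      ops.push_back(0); --i; --j; state = prev;
    } else if (state == 1) {
      int prev = pX[AT(i, j)];
      ops.push_back(1); --j; state = prev;
    } else {
      int prev = pY[AT(i, j)];
      ops.push_back(2); --i; state = prev;
    }
  }
  std::reverse(ops.begin(), ops.end());
#undef AT
  return List::create(_["path"] = wrap(ops), _["score"] = score);
}
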