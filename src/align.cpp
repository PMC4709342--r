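#include <Rcpp.h>
using namespace Rcpp;

// Global profile-profile alignment with affine gaps (Gotoh three-state DP).
//
// A and B are integer profiles: rows = sequences, columns = alignment
// columns; entry 0 is a gap, k > 0 indexes row/column k of the substitution
// matrix S. Column-pair score is the mean over all cross-profile residue
// pairs, with residue-vs-gap scored as -gap_extend and gap-vs-gap as 0.
// A gap run of length L costs gap_open + (L - 1) * gap_extend.
//
// Ties are broken deterministically: diagonal (match/mismatch) is preferred
// over a gap in the first profile (A), which is preferred over a gap in the
// second (B). Moves returned: 0 = consume both, 1 = consume B only (gap
// column inserted into A), 2 = consume A only (gap column inserted into B).

static inline double col_score(const IntegerMatrix& A, const IntegerMatrix& B,
                               const NumericMatrix& S, double gap_extend,
                               int i, int j) {
  double s = 0.0;
  const int nA = A.nrow(), nB = B.nrow();
  for (int r = 0; r < nA; ++r) {
    const int a = A(r, i);
    for (int q = 0; q < nB; ++q) {
      const int b = B(q, j);
      if (a > 0 && b > 0) s += S(a - 1, b - 1);
      else if (a > 0 || b > 0) s -= gap_extend;
    }
  }
  return s / (double)(nA * nB);
}

// [[Rcpp::export(name = ".align_profiles_cpp")]]
List align_profiles_cpp(IntegerMatrix A, IntegerMatrix B, NumericMatrix S,
                        double gap_open, double gap_extend) {
  const int la = A.ncol(), lb = B.ncol();
  const double NEG = -1e30;
  // state 0 = M (diagonal), 1 = Y (gap in A, consume B), 2 = X (gap in B)
  NumericMatrix M(la + 1, lb + 1), Y(la + 1, lb + 1), X(la + 1, lb + 1);
  M(0, 0) = 0.0; Y(0, 0) = NEG; X(0, 0) = NEG;
  for (int i = 1; i <= la; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -(gap_open + (i - 1) * gap_extend);
  }
  for (int j = 1; j <= lb; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -(gap_open + (j - 1) * gap_extend);
  }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      const double cs = col_score(A, B, S, gap_extend, i - 1, j - 1);
      double m = M(i - 1, j - 1), y = Y(i - 1, j - 1), x = X(i - 1, j - 1);
      M(i, j) = cs + std::max(m, std::max(y, x));
      // Y consumes B: predecessors at (i, j-1)
      double ym = M(i, j - 1) - gap_open;
      double yy = Y(i, j - 1) - gap_extend;
      double yx = X(i, j - 1) - gap_open;
      Y(i, j) = std::max(ym, std::max(yy, yx));
      // X consumes A: predecessors at (i-1, j)
      double xm = M(i - 1, j) - gap_open;
      double xy = Y(i - 1, j) - gap_open;
      double xx = X(i - 1, j) - gap_extend;
      X(i, j) = std::max(xm, std::max(xy, xx));
    }
  }
  // terminal state with tie priority M > Y > X
  int state;
  double best;
  if (la == 0 && lb == 0) { state = 0; best = 0.0; }
  else {
    best = M(la, lb); state = 0;
    if (Y(la, lb) > best) { best = Y(la, lb); state = 1; }
    if (X(la, lb) > best) { best = X(la, lb); state = 2; }
  }
  std::vector<int> moves;
  moves.reserve(la + lb);
  int i = la, j = lb;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) { state = (i == 0) ? 1 : 2; continue; }
      moves.push_back(0);
      const double cs = col_score(A, B, S, gap_extend, i - 1, j - 1);
      const double target = M(i, j) - cs;
      if (std::abs(M(i - 1, j - 1) - target) < eps) state = 0;
      else if (std::abs(Y(i - 1, j - 1) - target) < eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {           // gap in A, consume B
      moves.push_back(1);
      const double v = Y(i, j);
      if (j >= 1 && std::abs(M(i, j - 1) - gap_open - v) < eps) state = 0;
      else if (j >= 1 && std::abs(Y(i, j - 1) - gap_extend - v) < eps) state = 1;
      else state = 2;
      --j;
    } else {                           // gap in B, consume A
      moves.push_back(2);
      const double v = X(i, j);
      if (i >= 1 && std::abs(M(i - 1, j) - gap_open - v) < eps) state = 0;
      else if (i >= 1 && std::abs(Y(i - 1, j) - gap_open - v) < eps) state = 1;
      else state = 2;
      --i;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["score"] = best, _["moves"] = wrap(moves));
}
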