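#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment over a precomputed pair-score matrix.
//
// The caller supplies S where S(i, j) is the score of pairing row unit i
// (query/profile A column) with column unit j (subject/profile B column);
// one DP core thus serves residue-residue and profile-profile alignment.
// Gap cost: a gap of length L costs gap_open + L * gap_extend (open and
// extend are both charged on the first gap unit).
//
// Tie-breaks are fixed for determinism: diagonal > up (gap in B, consumes a
// row unit) > left (gap in A); in local mode the end cell is the smallest
// (row, column) among maximal cells.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

enum State { SM = 0, SX = 1, SY = 2, START = 3 };

// [[Rcpp::export]]
List align_affine_cpp(NumericMatrix S, double gap_open, double gap_extend,
                      bool local) {
  const int n = S.nrow(), m = S.ncol();
  const double gopen1 = gap_open + gap_extend; // cost of the first gap unit

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix PM(n + 1, m + 1), PX(n + 1, m + 1), PY(n + 1, m + 1);

  for (int i = 0; i <= n; ++i) {
    M(i, 0) = (i == 0) ? 0.0 : NEG_INF;
    Y(i, 0) = NEG_INF;
    X(i, 0) = (i == 0 || local) ? NEG_INF : -gopen1 - (i - 1) * gap_extend;
    PX(i, 0) = (i == 1) ? SM : SX;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF;
    X(0, j) = NEG_INF;
    Y(0, j) = local ? NEG_INF : -gopen1 - (j - 1) * gap_extend;
    PY(0, j) = (j == 1) ? SM : SY;
  }

  double best = 0.0;
  int best_i = 0, best_j = 0;
  bool any_positive = false;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: pair row unit i with column unit j
      double pm = M(i - 1, j - 1), px = X(i - 1, j - 1), py = Y(i - 1, j - 1);
      double prev = pm; int pstate = SM;
      if (px > prev) { prev = px; pstate = SX; }
      if (py > prev) { prev = py; pstate = SY; }
      if (local && prev <= 0.0) { prev = 0.0; pstate = START; }
      M(i, j) = prev + S(i - 1, j - 1);
      PM(i, j) = pstate;

      // X: gap in B (consume row unit i); open from M/Y or extend X
      double xo = std::max(M(i - 1, j), Y(i - 1, j)) - gopen1;
      double xe = X(i - 1, j) - gap_extend;
      if (xo >= xe) { X(i, j) = xo; PX(i, j) = (M(i - 1, j) >= Y(i - 1, j)) ? SM : SY; }
      else          { X(i, j) = xe; PX(i, j) = SX; }

      // Y: gap in A (consume column unit j)
      double yo = std::max(M(i, j - 1), X(i, j - 1)) - gopen1;
      double ye = Y(i, j - 1) - gap_extend;
      if (yo >= ye) { Y(i, j) = yo; PY(i, j) = (M(i, j - 1) >= X(i, j - 1)) ? SM : SX; }
      else          { Y(i, j) = ye; PY(i, j) = SY; }

      if (local && M(i, j) > best) { // strict > keeps the smallest (row, col)
        best = M(i, j); best_i = i; best_j = j;
        any_positive = true;
      }
    }
  }

  int end_i, end_j, state;
  double score;
  if (local) {
    if (!any_positive) {
      return List::create(_["score"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
                          _["s_start"] = 0, _["s_end"] = 0,
                          _["moves"] = IntegerVector(0));
    }
    end_i = best_i; end_j = best_j; state = SM; score = best;
  } else {
    end_i = n; end_j = m;
    double sm = M(n, m), sx = X(n, m), sy = Y(n, m);
    state = SM; score = sm;
    if (sx > score) { score = sx; state = SX; }
    if (sy > score) { score = sy; state = SY; }
  }

  // traceback: moves coded 1 = diagonal, 2 = up (gap in B), 3 = left (gap in A)
  std::vector<int> moves;
  int i = end_i, j = end_j, st = state;
  while (i > 0 || j > 0) {
    if (st == SM) {
      int p = PM(i, j);
      moves.push_back(1);
      i -= 1; j -= 1;
      if (p == START) break; // local alignment opened here
      st = p;
    } else if (st == SX) {
      int p = PX(i, j);
      moves.push_back(2);
      i -= 1;
      st = p;
    } else {
      int p = PY(i, j);
      moves.push_back(3);
      j -= 1;
      st = p;
    }
  }
  std::reverse(moves.begin(), moves.end());

  int q_start = 1, s_start = 1;
  if (local) {
    q_start = i + 1;
    s_start = j + 1;
  } else {
    q_start = n > 0 ? 1 : 0;
    s_start = m > 0 ? 1 : 0;
  }

  return List::create(_["score"] = score,
                      _["q_start"] = q_start, _["q_end"] = end_i,
                      _["s_start"] = s_start, _["s_end"] = end_j,
                      _["moves"] = IntegerVector(moves.begin(), moves.end()));
}

// Score-only local DP (linear memory), for proteome scans where tracebacks
// of sub-threshold pairs would be wasted work. qi/si are 0-based indices
// into the rows/columns of S.
// [[Rcpp::export]]
double local_score_cpp(IntegerVector qi, IntegerVector si, NumericMatrix S,
                       double gap_open, double gap_extend) {
  const int n = qi.size(), m = si.size();
  const double gopen1 = gap_open + gap_extend;
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG_INF);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diag = 0.0;  // H(i-1, j-1)
    double F = NEG_INF; // gap in subject, along the row
    double h0 = 0.0;    // H(i, j-1)
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(H[j] - gopen1, E[j] - gap_extend);
      F = std::max(h0 - gopen1, F - gap_extend);
      double h = diag + S(qi[i - 1], si[j - 1]);
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      h0 = h;
      if (h > best) best = h;
    }
  }
  return best;
}
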