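#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment (Needleman-Wunsch, three-state recurrence).
// a, b: 1-based indices into the substitution matrix S.
// go: score added when a gap is opened (applies to its first residue),
// ge: score for each further residue of the same gap; go <= ge <= 0.
// Tie-breaks are fixed so the traceback is deterministic:
// diagonal (match state) > up (gap in b) > left (gap in a).

static const double NEG_INF = -1e18;

// state codes: 0 = M (diagonal), 1 = X (up, consumes a), 2 = Y (left, consumes b)

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double go, double ge) {
  const int n = a.size(), m = b.size();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix pm(n + 1, m + 1), px(n + 1, m + 1), py(n + 1, m + 1);

  M(0, 0) = 0.0;
  X(0, 0) = Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = Y(i, 0) = NEG_INF;
    X(i, 0) = go + (i - 1) * ge;
    px(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = X(0, j) = NEG_INF;
    Y(0, j) = go + (j - 1) * ge;
    py(0, j) = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: substitution, predecessor any state at (i-1, j-1)
      double s = S(a[i - 1] - 1, b[j - 1] - 1);
      double cm = M(i - 1, j - 1), cx = X(i - 1, j - 1), cy = Y(i - 1, j - 1);
      int best = 0; double bv = cm;
      if (cx > bv) { bv = cx; best = 1; }
      if (cy > bv) { bv = cy; best = 2; }
      M(i, j) = s + bv;
      pm(i, j) = best;

      // X: gap in b (consume a residue i)
      double xo = M(i - 1, j) + go, xe = X(i - 1, j) + ge, xy = Y(i - 1, j) + go;
      best = 0; bv = xo;
      if (xe > bv) { bv = xe; best = 1; }
      if (xy > bv) { bv = xy; best = 2; }
      X(i, j) = bv;
      px(i, j) = best;

      // Y: gap in a (consume b residue j)
      double yo = M(i, j - 1) + go, yx = X(i, j - 1) + go, ye = Y(i, j - 1) + ge;
      best = 0; bv = yo;
      if (yx > bv) { bv = yx; best = 1; }
      if (ye > bv) { bv = ye; best = 2; }
      Y(i, j) = bv;
      py(i, j) = best;
    }
  }

  int state = 0;
  double score = M(n, m);
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }

  std::string moves;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      moves.push_back('D');
      state = pm(i, j); --i; --j;
    } else if (state == 1) {
      moves.push_back('U');
      state = px(i, j); --i;
    } else {
      moves.push_back('L');
      state = py(i, j); --j;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["score"] = score, _["moves"] = moves);
}
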