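#include <Rcpp.h>
using namespace Rcpp;

// Gotoh global alignment with affine gaps over a precomputed column-score
// matrix S (n1 x n2). gap_open is charged for the first position of a gap
// run, gap_extend for each further position. Returns the traceback as two
// integer vectors: path1[t] / path2[t] give the 1-based column of each
// profile contributing to merged column t, or 0 for a gap.
// Tie-break order (deterministic): diagonal, then gap-in-2 (up), then
// gap-in-1 (left).
// [[Rcpp::export(name = ".affine_align_path")]]
List affine_align_path(NumericMatrix S, double gap_open, double gap_extend) {
  const int n1 = S.nrow(), n2 = S.ncol();
  const double NEG = -1e30;

  NumericMatrix M(n1 + 1, n2 + 1), X(n1 + 1, n2 + 1), Y(n1 + 1, n2 + 1);
  // X: gap in profile 2 (consume profile 1 column); Y: gap in profile 1.
  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n1; ++i) {
    M(i, 0) = NEG;
    X(i, 0) = gap_open + (i - 1) * gap_extend;
    Y(i, 0) = NEG;
  }
  for (int j = 1; j <= n2; ++j) {
    M(0, j) = NEG;
    X(0, j) = NEG;
    Y(0, j) = gap_open + (j - 1) * gap_extend;
  }
  for (int i = 1; i <= n1; ++i) {
    for (int j = 1; j <= n2; ++j) {
      double best = M(i - 1, j - 1);
      if (X(i - 1, j - 1) > best) best = X(i - 1, j - 1);
      if (Y(i - 1, j - 1) > best) best = Y(i - 1, j - 1);
      M(i, j) = best + S(i - 1, j - 1);

      double xo = M(i - 1, j) + gap_open;
      double yc = Y(i - 1, j) + gap_open;
      if (yc > xo) xo = yc;
      double xe = X(i - 1, j) + gap_extend;
      X(i, j) = xo > xe ? xo : xe;

      double yo = M(i, j - 1) + gap_open;
      double xc = X(i, j - 1) + gap_open;
      if (xc > yo) yo = xc;
      double ye = Y(i, j - 1) + gap_extend;
      Y(i, j) = yo > ye ? yo : ye;
    }
  }

  // traceback
  std::vector<int> p1, p2;
  int i = n1, j = n2;
  int state;  // 0 = M, 1 = X, 2 = Y
  {
    double m = M(i, j), x = X(i, j), y = Y(i, j);
    state = (m >= x && m >= y) ? 0 : (x >= y ? 1 : 2);
  }
  double score = (state == 0) ? M(i, j) : (state == 1 ? X(i, j) : Y(i, j));
  while (i > 0 || j > 0) {
    if (state == 0) {
      p1.push_back(i); p2.push_back(j);
      double prev = M(i, j) - S(i - 1, j - 1);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) - prev) < 1e-9) state = 0;
      else if (std::abs(X(i, j) - prev) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) {
      p1.push_back(i); p2.push_back(0);
      double cur = X(i, j);
      --i;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) + gap_open - cur) < 1e-9) state = 0;
      else if (std::abs(Y(i, j) + gap_open - cur) < 1e-9) state = 2;
      else state = 1;
    } else {
      p1.push_back(0); p2.push_back(j);
      double cur = Y(i, j);
      --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) + gap_open - cur) < 1e-9) state = 0;
      else if (std::abs(X(i, j) + gap_open - cur) < 1e-9) state = 1;
      else state = 2;
    }
  }
  std::reverse(p1.begin(), p1.end());
  std::reverse(p2.begin(), p2.end());
  return List::create(_["path1"] = wrap(p1), _["path2"] = wrap(p2),
                      _["score"] = score);
}
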