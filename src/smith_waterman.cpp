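#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman. Sequences arrive as 0-based integer indices
// into the substitution matrix; a gap of length k costs open + k * ext.
// Gotoh three-state recursion; traceback from the best cell.

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double open, double ext, bool traceback) {
  const int m = a.size(), n = b.size();
  const double NEG = -1e30;
  // DP matrices, (m+1) x (n+1), row-major
  std::vector<double> M((m + 1) * (n + 1), 0.0);
  std::vector<double> X((m + 1) * (n + 1), NEG);  // gap in b (up moves)
  std::vector<double> Y((m + 1) * (n + 1), NEG);  // gap in a (left moves)
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int idx = i * (n + 1) + j;
      const int up = (i - 1) * (n + 1) + j;
      const int left = i * (n + 1) + (j - 1);
      const int diag = (i - 1) * (n + 1) + (j - 1);
      double x = std::max(M[up] - (open + ext), X[up] - ext);
      double y = std::max(M[left] - (open + ext), Y[left] - ext);
      double s = S(a[i - 1], b[j - 1]);
      double mm = std::max(std::max(M[diag], X[diag]), Y[diag]) + s;
      if (mm < 0.0) mm = 0.0;
      // local: only M may restart at zero
      M[idx] = mm;
      X[idx] = x;
      Y[idx] = y;
      double cell = std::max(mm, std::max(x, y));
      if (cell > best) { best = cell; bi = i; bj = j; }
    }
  }
  if (!traceback || best <= 0.0) {
    return List::create(_["score"] = best,
                        _["a_span"] = IntegerVector::create(0, 0),
                        _["b_span"] = IntegerVector::create(0, 0),
                        _["a_aln"] = IntegerVector(0),
                        _["b_aln"] = IntegerVector(0));
  }
  // traceback: state 0 = M, 1 = X, 2 = Y
  int i = bi, j = bj, state;
  {
    const int idx = i * (n + 1) + j;
    if (M[idx] >= X[idx] && M[idx] >= Y[idx]) state = 0;
    else if (X[idx] >= Y[idx]) state = 1;
    else state = 2;
  }
  std::vector<int> aa, bb;  // -1 encodes a gap
  while (i > 0 || j > 0) {
    const int idx = i * (n + 1) + j;
    if (state == 0) {
      if (M[idx] <= 0.0) break;  // local start
      const int diag = (i - 1) * (n + 1) + (j - 1);
      double s = S(a[i - 1], b[j - 1]);
      aa.push_back(a[i - 1]);
      bb.push_back(b[j - 1]);
      double prev = M[idx] - s;
      if (std::abs(prev - M[diag]) < 1e-9) state = 0;
      else if (std::abs(prev - X[diag]) < 1e-9) state = 1;
      else state = 2;
      --i; --j;
      if (state == 0 && M[i * (n + 1) + j] <= 0.0) break;
    } else if (state == 1) {
      const int up = (i - 1) * (n + 1) + j;
      aa.push_back(a[i - 1]);
      bb.push_back(-1);
      if (std::abs(X[idx] - (M[up] - (open + ext))) < 1e-9) state = 0;
      else state = 1;
      --i;
    } else {
      const int left = i * (n + 1) + (j - 1);
      aa.push_back(-1);
      bb.push_back(b[j - 1]);
      if (std::abs(Y[idx] - (M[left] - (open + ext))) < 1e-9) state = 0;
      else state = 2;
      --j;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["score"] = best,
                      _["a_span"] = IntegerVector::create(i + 1, bi),
                      _["b_span"] = IntegerVector::create(j + 1, bj),
                      _["a_aln"] = wrap(aa),
                      _["b_aln"] = wrap(bb));
}

// Score-only screen of many targets against many queries; returns a
// queries x targets score matrix.
// [[Rcpp::export(name = ".sw_score_matrix_cpp")]]
NumericMatrix sw_score_matrix_cpp(List queries, List targets, NumericMatrix S,
                                  double open, double ext) {
  const int nq = queries.size(), nt = targets.size();
  NumericMatrix out(nq, nt);
  for (int q = 0; q < nq; ++q) {
    IntegerVector A = queries[q];
    for (int t = 0; t < nt; ++t) {
      IntegerVector B = targets[t];
      const int m = A.size(), n = B.size();
      std::vector<double> Mp(n + 1, 0.0), Xp(n + 1, -1e30), Yp(n + 1, -1e30);
      double best = 0.0;
      for (int i = 1; i <= m; ++i) {
        double Mdiag = Mp[0], Xdiag = Xp[0], Ydiag = Yp[0];
        Mp[0] = 0.0; Xp[0] = -1e30; Yp[0] = -1e30;
        for (int j = 1; j <= n; ++j) {
          double Mup = Mp[j], Xup = Xp[j], Yup = Yp[j];
          double x = std::max(Mup - (open + ext), Xup - ext);
          double y = std::max(Mp[j - 1] - (open + ext), Yp[j - 1] - ext);
          double mm = std::max(std::max(Mdiag, Xdiag), Ydiag)
            + S(A[i - 1], B[j - 1]);
          if (mm < 0.0) mm = 0.0;
          Mdiag = Mup; Xdiag = Xup; Ydiag = Yup;
          Mp[j] = mm; Xp[j] = x; Yp[j] = y;
          double cell = std::max(mm, std::max(x, y));
          if (cell > best) best = cell;
        }
      }
      out(q, t) = best;
    }
  }
  return out;
}
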