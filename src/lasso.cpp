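#include <Rcpp.h>
using namespace Rcpp;

// Covariance-update cyclic coordinate descent for the lasso over a
// decreasing lambda grid with warm starts. Expects standardised columns
// (XtX = X'X/n with unit diagonal up to rounding) and centered y.
// Returns a p x n_lambda coefficient matrix.
// [[Rcpp::export(name = ".lasso_path_cd")]]
NumericMatrix lasso_path_cd(NumericVector Xty, NumericMatrix XtX,
                            NumericVector grid, int max_iter, double tol) {
  const int p = Xty.size(), nl = grid.size();
  NumericVector b(p), s(p);  // s = XtX %*% b, updated incrementally
  NumericMatrix out(p, nl);
  for (int gi = 0; gi < nl; ++gi) {
    const double lam = grid[gi];
    for (int it = 0; it < max_iter; ++it) {
      double delta_max = 0.0;
      for (int j = 0; j < p; ++j) {
        const double cjj = XtX(j, j);
        if (cjj <= 0) continue;
        const double r = Xty[j] - s[j] + cjj * b[j];
        double bj = 0.0;
        if (r > lam) bj = (r - lam) / cjj;
        else if (r < -lam) bj = (r + lam) / cjj;
        const double d = bj - b[j];
        if (d != 0.0) {
          b[j] = bj;
          for (int k = 0; k < p; ++k) s[k] += XtX(k, j) * d;
          if (std::abs(d) > delta_max) delta_max = std::abs(d);
        }
      }
      if (delta_max < tol) break;
    }
    for (int j = 0; j < p; ++j) out(j, gi) = b[j];
  }
  return out;
}
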