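#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Block coordinate-descent graphical LASSO (Friedman-Hastie-Tibshirani scheme).
// Maximises log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|;
// the diagonal is unpenalised, so diag(W) stays equal to diag(S).
// Each column problem  min_b  0.5 b' W11 b - s12' b + lambda |b|_1
// is solved by coordinate descent with soft-thresholding.

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export(name = ".glasso_cd")]]
List glasso_cd(NumericMatrix S, double lambda, double tol = 1e-6,
               int max_iter = 200, int inner_max = 200) {
  const int p = S.nrow();
  NumericMatrix W(clone(S));          // working covariance estimate
  NumericMatrix B(p, p);              // column regression coefficients
  std::vector<double> s12(p - 1), b(p - 1), wcol(p - 1);
  std::vector<int> idx(p - 1);

  int it = 0;
  double max_change = R_PosInf;
  for (it = 0; it < max_iter && max_change > tol; ++it) {
    max_change = 0.0;
    for (int j = 0; j < p; ++j) {
      int m = 0;
      for (int i = 0; i < p; ++i) if (i != j) idx[m++] = i;
      for (int l = 0; l < p - 1; ++l) {
        s12[l] = S(idx[l], j);
        b[l]   = B(idx[l], j);
      }
      // coordinate descent on the lasso subproblem
      for (int sweep = 0; sweep < inner_max; ++sweep) {
        double delta = 0.0;
        for (int l = 0; l < p - 1; ++l) {
          double g = s12[l];
          for (int mth = 0; mth < p - 1; ++mth)
            if (mth != l) g -= W(idx[mth], idx[l]) * b[mth];
          double wll = W(idx[l], idx[l]);
          double bnew = soft(g, lambda) / wll;
          delta = std::max(delta, std::fabs(bnew - b[l]));
          b[l] = bnew;
        }
        if (delta < tol * 0.1) break;
      }
      // w12 = W11 b
      for (int l = 0; l < p - 1; ++l) {
        double acc = 0.0;
        for (int mth = 0; mth < p - 1; ++mth)
          acc += W(idx[l], idx[mth]) * b[mth];
        wcol[l] = acc;
      }
      for (int l = 0; l < p - 1; ++l) {
        double ch = std::fabs(W(idx[l], j) - wcol[l]);
        if (ch > max_change) max_change = ch;
        W(idx[l], j) = wcol[l];
        W(j, idx[l]) = wcol[l];
        B(idx[l], j) = b[l];
      }
    }
  }

  // recover Theta column-wise: theta_jj = 1/(w_jj - w12' b), theta_12 = -b * theta_jj
  NumericMatrix Theta(p, p);
  for (int j = 0; j < p; ++j) {
    double q = W(j, j);
    for (int i = 0; i < p; ++i)
      if (i != j) q -= W(i, j) * B(i, j);
    double tjj = 1.0 / q;
    Theta(j, j) = tjj;
    for (int i = 0; i < p; ++i)
      if (i != j) Theta(i, j) = -B(i, j) * tjj;
  }
  // symmetrise (numerical asymmetry only)
  for (int j = 0; j < p; ++j)
    for (int i = j + 1; i < p; ++i) {
      double v = 0.5 * (Theta(i, j) + Theta(j, i));
      Theta(i, j) = v; Theta(j, i) = v;
    }

  return List::create(_["w"] = W, _["theta"] = Theta,
                      _["iterations"] = it, _["max_change"] = max_change,
                      _["converged"] = (max_change <= tol));
}
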