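#include <Rcpp.h>
using namespace Rcpp;

// Regression NCA objective and analytic gradient.
//
// Weighted distance  D_ij = sum_m w_m^2 |x_im - x_jm|
// Kernel             k(z) = exp(-z / sigma)
// Soft-neighbor probabilities (leave-one-out, row-normalized; invariant to a
// per-row shift of D, which is exploited for numerical stability):
//   gamma_ij = k(D_ij) / sum_{j' != i} k(D_ij')
// Loss l_ij = |y_i - y_j| (MAD) or 1 - exp(-|y_i - y_j|) (robust)
// F(w) = (1/n) sum_i sum_{j != i} gamma_ij l_ij + lambda sum_m w_m^2
//
// dF/dw_m = (2 w_m / (n sigma)) *
//           sum_i [ L_i * sum_j gamma_ij d_ijm - sum_j gamma_ij l_ij d_ijm ]
//           + 2 lambda w_m,   with d_ijm = |x_im - x_jm|.
// [[Rcpp::export]]
List nca_objective_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                       double sigma, double lambda, int loss_kind,
                       bool want_gamma = false) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least 2 observations");
  NumericMatrix D(n, n);
  for (int m = 0; m < p; ++m) {
    const double wm2 = w[m] * w[m];
    if (wm2 == 0.0) continue;
    for (int i = 0; i < n; ++i) {
      const double xim = X(i, m);
      for (int j = i + 1; j < n; ++j) {
        const double d = wm2 * std::fabs(xim - X(j, m));
        D(i, j) += d;
        D(j, i) += d;
      }
    }
  }
  NumericMatrix G(n, n);       // gamma
  NumericVector Li(n);
  bool overflow = true;
  for (int i = 0; i < n; ++i) {
    double dmin = R_PosInf;
    for (int j = 0; j < n; ++j) if (j != i && D(i, j) < dmin) dmin = D(i, j);
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      G(i, j) = std::exp(-(D(i, j) - dmin) / sigma);
      s += G(i, j);
    }
    if (s > 0.0 && R_finite(s)) overflow = false; else stop("kernel normalization overflow");
    double li = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      G(i, j) /= s;
      const double ad = std::fabs(y[i] - y[j]);
      const double l = (loss_kind == 0) ? ad : (1.0 - std::exp(-ad));
      li += G(i, j) * l;
    }
    Li[i] = li;
  }
  (void)overflow;
  double reg = 0.0;
  for (int m = 0; m < p; ++m) reg += w[m] * w[m];
  double value = mean(Li) + lambda * reg;

  NumericVector grad(p);
  for (int m = 0; m < p; ++m) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      double gd = 0.0, gld = 0.0;
      const double xim = X(i, m);
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double d = std::fabs(xim - X(j, m));
        const double g = G(i, j);
        gd += g * d;
        const double ad = std::fabs(y[i] - y[j]);
        const double l = (loss_kind == 0) ? ad : (1.0 - std::exp(-ad));
        gld += g * l * d;
      }
      acc += Li[i] * gd - gld;
    }
    grad[m] = 2.0 * w[m] / (n * sigma) * acc + 2.0 * lambda * w[m];
  }
  List out = List::create(_["value"] = value, _["gradient"] = grad,
                          _["Li"] = Li);
  if (want_gamma) out["gamma"] = G;
  return out;
}

// Soft-neighbor prediction for new points against a training reference set.
// yhat_i = sum_j gamma_ij y_j with gamma over training points only.
// [[Rcpp::export]]
NumericVector nca_predict_cpp(NumericMatrix Xtr, NumericVector ytr,
                              NumericMatrix Xnew, NumericVector w,
                              double sigma) {
  const int n = Xtr.nrow(), m = Xnew.nrow(), p = Xtr.ncol();
  NumericVector out(m);
  std::vector<double> dist(n);
  for (int i = 0; i < m; ++i) {
    double dmin = R_PosInf;
    for (int j = 0; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < p; ++k)
        d += w[k] * w[k] * std::fabs(Xnew(i, k) - Xtr(j, k));
      dist[j] = d;
      if (d < dmin) dmin = d;
    }
    double s = 0.0, acc = 0.0;
    for (int j = 0; j < n; ++j) {
      const double g = std::exp(-(dist[j] - dmin) / sigma);
      s += g;
      acc += g * ytr[j];
    }
    out[i] = acc / s;
  }
  return out;
}
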