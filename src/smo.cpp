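// Sequential minimal optimisation for the soft-margin kernel classifier.
//
// Solves the C-SVC dual
//     min_a  1/2 a' Q a - e' a,   0 <= a_i <= C,  y' a = 0,
// with Q_ij = y_i y_j K_ij, using maximal-violating-pair working-set
// selection and an analytic two-variable update.  Kernel matrices are
// precomputed (problem sizes here are at most a few thousand fragments).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
arma::mat rbf_kernel_cpp(const arma::mat& X, const arma::mat& Y, double gamma) {
  arma::vec xs = arma::sum(arma::square(X), 1);
  arma::vec ys = arma::sum(arma::square(Y), 1);
  arma::mat D = -2.0 * (X * Y.t());
  D.each_col() += xs;
  D.each_row() += ys.t();
  D.clamp(0.0, arma::datum::inf);
  return arma::exp(-gamma * D);
}

// [[Rcpp::export]]
List smo_solve(const arma::mat& K, const arma::ivec& y, double C,
               double eps = 1e-3, int max_iter = 0) {
  const int n = K.n_rows;
  if (n != (int)y.n_elem) stop("kernel/label size mismatch");
  if (max_iter <= 0) max_iter = std::max(200000, 100 * n);

  arma::vec alpha(n, arma::fill::zeros);
  // G_i = y_i * sum_j alpha_j y_j K_ij - 1  (gradient of the dual objective)
  arma::vec G(n);
  G.fill(-1.0);

  int iter = 0;
  double Gmax = 0.0, Gmin = 0.0;
  for (iter = 0; iter < max_iter; ++iter) {
    Gmax = -arma::datum::inf;
    Gmin = arma::datum::inf;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      const double v = -double(y[t]) * G[t];
      const bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      const bool low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) break;

    // step d along (alpha_i += y_i d, alpha_j -= y_j d)
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = 1e-12;
    double d = (Gmax - Gmin) / quad;

    // box constraints on d
    double dmin, dmax;
    if (y[i] == 1) { dmin = -alpha[i]; dmax = C - alpha[i]; }
    else           { dmin = alpha[i] - C; dmax = alpha[i]; }
    double dmin2, dmax2;
    if (y[j] == 1) { dmin2 = alpha[j] - C; dmax2 = alpha[j]; }
    else           { dmin2 = -alpha[j]; dmax2 = C - alpha[j]; }
    dmin = std::max(dmin, dmin2);
    dmax = std::min(dmax, dmax2);
    d = std::min(std::max(d, dmin), dmax);
    if (d == 0.0) break;

    alpha[i] += y[i] * d;
    alpha[j] -= y[j] * d;
    // G_t += y_t d (K_ti - K_tj)
    for (int t = 0; t < n; ++t) {
      G[t] += double(y[t]) * d * (K(t, i) - K(t, j));
    }
  }

  // intercept: average of -y_t G_t over free support vectors
  double b = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-8 && alpha[t] < C - 1e-8) {
      b += -double(y[t]) * G[t];
      ++nfree;
    }
  }
  if (nfree > 0) b /= nfree;
  else b = (Gmax + Gmin) / 2.0;

  // training decision values f_t = sum_j alpha_j y_j K_tj + b = y_t (G_t + 1) + b
  arma::vec f(n);
  for (int t = 0; t < n; ++t) f[t] = double(y[t]) * (G[t] + 1.0) + b;

  return List::create(_["alpha"] = alpha, _["b"] = b,
                      _["decision"] = f, _["iterations"] = iter,
                      _["converged"] = (iter < max_iter));
}
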