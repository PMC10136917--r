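// Graphical lasso via block coordinate descent (Friedman-style covariance
// updates with an inner lasso solved by cyclic coordinate descent).
// The diagonal is NOT penalized: at lambda = 0 and positive definite input
// the solver converges to the plain matrix inverse.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Inner lasso: minimize 0.5 b' W11 b - b' s12 + lambda ||b||_1,
// warm-started from `beta`. W11 is (p-1) x (p-1).
static void lasso_cd(const mat& W11, const vec& s12, double lambda,
                     vec& beta, double tol, int maxit) {
  const uword m = s12.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword k = 0; k < m; ++k) {
      double old = beta(k);
      // partial residual: s12_k - sum_{l != k} W11(k,l) beta_l
      double r = s12(k) - dot(W11.row(k), beta) + W11(k, k) * old;
      double b = soft_threshold(r, lambda) / W11(k, k);
      if (b != old) {
        beta(k) = b;
        double d = std::abs(b - old);
        if (d > dmax) dmax = d;
      }
    }
    if (dmax < tol) break;
  }
}

// One glasso fit with warm starts supplied through W (working covariance)
// and B (nodewise regression coefficients, p x p with zero diagonal).
// Returns true on convergence.
static bool glasso_one(const mat& S, double lambda, mat& W, mat& B,
                       mat& K, double tol, int maxit, int inner_maxit) {
  const uword p = S.n_rows;
  // unpenalized diagonal: working covariance keeps the sample diagonal
  W.diag() = S.diag();

  bool converged = false;
  for (int sweep = 0; sweep < maxit; ++sweep) {
    double dmax = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx(p - 1);
      uword c = 0;
      for (uword i = 0; i < p; ++i) if (i != j) idx(c++) = i;

      mat W11 = W(idx, idx);
      vec s12 = S.col(j);
      s12 = s12(idx);
      vec beta = B.col(j);
      beta = beta(idx);

      lasso_cd(W11, s12, lambda, beta, tol * 0.1, inner_maxit);

      vec w12 = W11 * beta;
      for (uword k = 0; k < p - 1; ++k) {
        double d = std::abs(W(idx(k), j) - w12(k));
        if (d > dmax) dmax = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        B(idx(k), j) = beta(k);
      }
    }
    if (dmax < tol) { converged = true; break; }
  }

  // recover the precision matrix from the final regressions
  K.set_size(p, p);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    uword c = 0;
    for (uword i = 0; i < p; ++i) if (i != j) idx(c++) = i;
    vec beta = B.col(j);
    beta = beta(idx);
    vec w12 = W.col(j);
    w12 = w12(idx);
    double kjj = 1.0 / (W(j, j) - dot(w12, beta));
    K(j, j) = kjj;
    for (uword k = 0; k < p - 1; ++k) K(idx(k), j) = -beta(k) * kjj;
  }
  K = 0.5 * (K + K.t());
  return converged;
}

//' @noRd
// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda,
                      double tol = 1e-6, int maxit = 1000,
                      int inner_maxit = 1000) {
  mat W = S;
  mat B = zeros<mat>(S.n_rows, S.n_cols);
  mat K;
  bool ok = glasso_one(S, lambda, W, B, K, tol, maxit, inner_maxit);
  return Rcpp::List::create(Rcpp::Named("K") = K,
                            Rcpp::Named("W") = W,
                            Rcpp::Named("converged") = ok);
}

//' @noRd
// [[Rcpp::export(name = ".glasso_path_cpp")]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double tol = 1e-6, int maxit = 1000,
                           int inner_maxit = 1000) {
  const uword p = S.n_rows, L = lambdas.n_elem;
  cube Ks(p, p, L);
  Rcpp::LogicalVector conv(L);
  // warm start down the (decreasing) path
  mat W = S;
  mat B = zeros<mat>(p, p);
  mat K;
  for (uword l = 0; l < L; ++l) {
    bool ok = glasso_one(S, lambdas(l), W, B, K, tol, maxit, inner_maxit);
    Ks.slice(l) = K;
    conv(l) = ok;
  }
  return Rcpp::List::create(Rcpp::Named("K") = Ks,
                            Rcpp::Named("converged") = conv);
}
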