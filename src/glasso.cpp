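// Graphical lasso by block coordinate descent (Friedman-style), with an
// unpenalised diagonal: maximises log det K - tr(SK) - lambda * sum_{i!=j} |K_ij|.
// Each column update solves an L1-penalised regression on the current
// covariance block via cyclic coordinate descent.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda,
                      double tol = 1e-4, int max_iter = 200,
                      int inner_max_iter = 500) {
  const uword p = S.n_rows;
  if (p == 1) {
    mat K(1, 1); K(0, 0) = 1.0 / S(0, 0);
    return Rcpp::List::create(Rcpp::Named("K") = K,
                              Rcpp::Named("W") = S,
                              Rcpp::Named("iterations") = 0,
                              Rcpp::Named("converged") = true);
  }

  mat W = S;                 // working covariance; diagonal stays = diag(S)
  mat B(p - 1, p, fill::zeros);  // per-column regression coefficients

  // convergence measured against the average absolute off-diagonal of S
  double off_scale = (accu(abs(S)) - trace(abs(S))) / double(p * (p - 1));
  if (off_scale < 1e-12) off_scale = 1e-12;
  const double thr = tol * off_scale;
  const double inner_thr = 0.1 * thr;

  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    double max_delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx(p - 1);
      for (uword k = 0, m = 0; k < p; ++k) if (k != j) idx(m++) = k;
      mat W11 = W(idx, idx);
      vec s12 = S.col(j); s12 = s12(idx);
      vec beta = B.col(j);

      // coordinate descent on 0.5 b'W11 b - s12'b + lambda |b|_1
      for (int it2 = 0; it2 < inner_max_iter; ++it2) {
        double del = 0.0;
        for (uword k = 0; k < p - 1; ++k) {
          double r = s12(k) - dot(W11.col(k), beta) + W11(k, k) * beta(k);
          double bnew = soft(r, lambda) / W11(k, k);
          double d = std::abs(bnew - beta(k));
          if (d > del) del = d;
          beta(k) = bnew;
        }
        if (del < inner_thr) break;
      }
      B.col(j) = beta;

      vec w12 = W11 * beta;
      for (uword k = 0; k < p - 1; ++k) {
        double d = std::abs(W(idx(k), j) - w12(k));
        if (d > max_delta) max_delta = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
    }
    if (max_delta < thr) { converged = true; break; }
  }

  // recover K from W and the final regression coefficients
  mat K(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    for (uword k = 0, m = 0; k < p; ++k) if (k != j) idx(m++) = k;
    vec beta = B.col(j);
    vec w12 = W.col(j); w12 = w12(idx);
    double k22 = 1.0 / (W(j, j) - dot(w12, beta));
    K(j, j) = k22;
    for (uword k = 0; k < p - 1; ++k) K(idx(k), j) = -beta(k) * k22;
  }
  K = 0.5 * (K + K.t());

  return Rcpp::List::create(Rcpp::Named("K") = K,
                            Rcpp::Named("W") = W,
                            Rcpp::Named("iterations") = iter,
                            Rcpp::Named("converged") = converged);
}
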