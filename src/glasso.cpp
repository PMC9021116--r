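// Blockwise coordinate-descent graphical lasso (Friedman-type) with a
// warm-started penalty path. Used by ebic_glasso(); model selection (EBIC,
// gamma schedule) happens on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Coordinate descent for the lasso subproblem
//   min_b 0.5 * b' V b - u' b + rho * ||b||_1
// V is symmetric positive definite with strictly positive diagonal.
static void lasso_cd(const mat& V, const vec& u, vec& beta,
                     const double rho, const int maxit, const double tol) {
  const uword p = u.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double dlx = 0.0;
    for (uword j = 0; j < p; ++j) {
      const double bj = beta(j);
      // partial residual: u_j - sum_{k != j} V_jk b_k
      double x = u(j) - dot(V.col(j), beta) + V(j, j) * bj;
      double b = 0.0;
      if (x > rho) {
        b = (x - rho) / V(j, j);
      } else if (x < -rho) {
        b = (x + rho) / V(j, j);
      }
      beta(j) = b;
      const double d = std::fabs(b - bj);
      if (d > dlx) dlx = d;
    }
    if (dlx < tol) break;
  }
}

// One glasso fit at penalty rho, warm-started from W and B (p x p matrix of
// regression coefficients, column j = beta for block column j).
static void glasso_fit(const mat& S, const double rho, mat& W, mat& B,
                       const int maxit, const double thr_scale,
                       const bool penalize_diag) {
  const uword p = S.n_cols;
  // convergence threshold: thr_scale * mean |off-diagonal of S|
  double s_off = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j) s_off += std::fabs(S(i, j));
  double thr = thr_scale * s_off / double(p * (p - 1));
  if (thr <= 0) thr = thr_scale;

  // diagonal is fixed throughout: S_ii (+ rho when penalized)
  W.diag() = S.diag() + (penalize_diag ? rho : 0.0);

  uvec all = regspace<uvec>(0, p - 1);
  for (int it = 0; it < maxit; ++it) {
    double dw = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec rest = find(all != j);
      mat V = W.submat(rest, rest);
      vec u = S.col(j);
      u = u.elem(rest);
      vec beta = B.col(j);
      beta = beta.elem(rest);
      lasso_cd(V, u, beta, rho, 200, 1e-7);
      vec w12 = V * beta;
      for (uword k = 0; k < rest.n_elem; ++k) {
        const uword i = rest(k);
        dw = std::max(dw, std::fabs(W(i, j) - w12(k)));
        W(i, j) = w12(k);
        W(j, i) = w12(k);
        B(i, j) = beta(k);
      }
      B(j, j) = 0.0;
    }
    if (dw < thr) break;
  }
}

// Recover the precision matrix from W and B.
static mat theta_from(const mat& W, const mat& B) {
  const uword p = W.n_cols;
  mat Theta(p, p, fill::zeros);
  uvec all = regspace<uvec>(0, p - 1);
  for (uword j = 0; j < p; ++j) {
    uvec rest = find(all != j);
    vec beta = B.col(j);
    beta = beta.elem(rest);
    vec w12 = W.col(j);
    w12 = w12.elem(rest);
    const double t22 = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = t22;
    for (uword k = 0; k < rest.n_elem; ++k) {
      Theta(rest(k), j) = -beta(k) * t22;
    }
  }
  // symmetrize (numerically near-symmetric already)
  return 0.5 * (Theta + Theta.t());
}

//' @noRd
// [[Rcpp::export]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& rho,
                           const int maxit = 100,
                           const double thr_scale = 1e-4,
                           const bool penalize_diag = false) {
  const uword p = S.n_cols;
  const uword nl = rho.n_elem;
  mat W = S;
  if (penalize_diag) W.diag() += rho(0);
  mat B(p, p, fill::zeros);
  cube thetas(p, p, nl);
  for (uword l = 0; l < nl; ++l) {
    glasso_fit(S, rho(l), W, B, maxit, thr_scale, penalize_diag);
    thetas.slice(l) = theta_from(W, B);
  }
  return Rcpp::List::create(Rcpp::Named("theta") = thetas);
}
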