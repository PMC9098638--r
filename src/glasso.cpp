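#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

// Graphical lasso by block coordinate descent (Friedman-style): maximizes
//   log det Theta - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|
// (penalty on off-diagonals only, so diag(W) = diag(S) exactly). Each
// column's subproblem is an L1 regression solved by coordinate descent;
// warm starts on (W, B) make a descending lambda path cheap.

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// One glasso solve. W and B are updated in place (warm start / output).
// Returns true on convergence.
static bool glasso_solve(const mat &S, double lambda, mat &W, mat &B,
                         double thr, int maxit, int inner_maxit) {
  const uword p = S.n_rows;
  if (p == 1) { W(0, 0) = S(0, 0); return true; }
  W.diag() = S.diag();
  const double inner_thr = thr / 10.0;

  for (int it = 0; it < maxit; ++it) {
    double dw = 0.0;
    for (uword j = 0; j < p; ++j) {
      // coordinate descent on beta = B.col(j) (entry j unused, kept 0)
      for (int in = 0; in < inner_maxit; ++in) {
        double db = 0.0;
        for (uword k = 0; k < p; ++k) {
          if (k == j) continue;
          double r = S(k, j);
          for (uword l = 0; l < p; ++l) {
            if (l == j || l == k) continue;
            r -= W(k, l) * B(l, j);
          }
          double bnew = soft(r, lambda) / W(k, k);
          double d = std::fabs(bnew - B(k, j));
          if (d > db) db = d;
          B(k, j) = bnew;
        }
        if (db < inner_thr) break;
      }
      for (uword k = 0; k < p; ++k) {
        if (k == j) continue;
        double wkj = 0.0;
        for (uword l = 0; l < p; ++l) {
          if (l == j) continue;
          wkj += W(k, l) * B(l, j);
        }
        double d = std::fabs(wkj - W(k, j));
        if (d > dw) dw = d;
        W(k, j) = wkj;
        W(j, k) = wkj;
      }
    }
    if (dw < thr) return true;
  }
  return false;
}

// Precision matrix from the final (W, B) sweep; exact zeros where beta is 0.
static mat recover_theta(const mat &W, const mat &B) {
  const uword p = W.n_rows;
  mat Theta(p, p, arma::fill::zeros);
  for (uword j = 0; j < p; ++j) {
    double q = W(j, j);
    for (uword l = 0; l < p; ++l)
      if (l != j) q -= W(l, j) * B(l, j);
    double tjj = 1.0 / q;
    Theta(j, j) = tjj;
    for (uword k = 0; k < p; ++k)
      if (k != j) Theta(k, j) = -B(k, j) * tjj;
  }
  // symmetrize, preserving the joint zero pattern
  for (uword j = 0; j < p; ++j) {
    for (uword k = j + 1; k < p; ++k) {
      if (Theta(k, j) == 0.0 && Theta(j, k) == 0.0) continue;
      double v = 0.5 * (Theta(k, j) + Theta(j, k));
      Theta(k, j) = v;
      Theta(j, k) = v;
    }
  }
  return Theta;
}

//' @noRd
// [[Rcpp::export(name = ".glasso_cpp")]]
List glasso_cpp(arma::mat S, double lambda, double tol, int maxit) {
  mat W = S, B(S.n_rows, S.n_rows, arma::fill::zeros);
  double thr = tol * arma::mean(arma::abs(
      S.elem(arma::find(arma::trimatu(arma::ones<arma::umat>(S.n_rows, S.n_rows), 1)))));
  if (!(thr > 0)) thr = tol;
  bool conv = glasso_solve(S, lambda, W, B, thr, maxit, 1000);
  mat Theta = recover_theta(W, B);
  return List::create(_["theta"] = Theta, _["w"] = W, _["converged"] = conv);
}

//' @noRd
// [[Rcpp::export(name = ".glasso_path_cpp")]]
List glasso_path_cpp(arma::mat S, arma::vec lambdas, double tol, int maxit) {
  const uword p = S.n_rows, m = lambdas.n_elem;
  arma::cube thetas(p, p, m);
  LogicalVector conv(m);
  IntegerVector edges(m);
  NumericVector logliks(m);
  mat W = S, B(p, p, arma::fill::zeros);
  double thr = tol * arma::mean(arma::abs(
      S.elem(arma::find(arma::trimatu(arma::ones<arma::umat>(p, p), 1)))));
  if (!(thr > 0)) thr = tol;
  for (uword i = 0; i < m; ++i) {  // descending lambdas, warm-started
    conv[i] = glasso_solve(S, lambdas(i), W, B, thr, maxit, 1000);
    mat Theta = recover_theta(W, B);
    thetas.slice(i) = Theta;
    int e = 0;
    for (uword j = 0; j < p; ++j)
      for (uword k = j + 1; k < p; ++k)
        if (std::fabs(Theta(k, j)) > 1e-8) ++e;
    edges[i] = e;
    double ldet, sign;
    arma::log_det(ldet, sign, Theta);
    if (sign <= 0) {
      conv[i] = false;
      logliks[i] = NA_REAL;
    } else {
      logliks[i] = ldet - arma::accu(S % Theta);
    }
  }
  return List::create(_["thetas"] = thetas, _["converged"] = conv,
                      _["edges"] = edges, _["loglik"] = logliks);
}
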