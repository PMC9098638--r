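#include <Rcpp.h>
#include "bvn.h"

using namespace Rcpp;

// Two-step polychoric likelihood: thresholds fixed from the marginals, the
// latent correlation rho estimated by bounded 1-D maximization of
//   l(rho) = sum_ij n_ij log P_ij(rho),
// P_ij the bivariate-normal rectangle probability between consecutive
// thresholds, floored at 1e-12 so empty-corner tables stay finite.

static double poly_loglik(double rho, const NumericMatrix &counts,
                          const NumericVector &tx, const NumericVector &ty) {
  const int kx = counts.nrow(), ky = counts.ncol();
  // CDF grid over augmented thresholds (-Inf, t..., +Inf)
  std::vector<double> grid((kx + 1) * (ky + 1));
  for (int i = 0; i <= kx; ++i) {
    double a = (i == 0) ? R_NegInf : (i == kx ? R_PosInf : tx[i - 1]);
    for (int j = 0; j <= ky; ++j) {
      double b = (j == 0) ? R_NegInf : (j == ky ? R_PosInf : ty[j - 1]);
      grid[i * (ky + 1) + j] = bvn_cdf_scalar(a, b, rho);
    }
  }
  double ll = 0.0;
  for (int i = 0; i < kx; ++i) {
    for (int j = 0; j < ky; ++j) {
      double n = counts(i, j);
      if (n > 0) {
        double p = grid[(i + 1) * (ky + 1) + (j + 1)] -
                   grid[i * (ky + 1) + (j + 1)] -
                   grid[(i + 1) * (ky + 1) + j] + grid[i * (ky + 1) + j];
        if (p < 1e-12) p = 1e-12;
        ll += n * std::log(p);
      }
    }
  }
  return ll;
}

//' @noRd
// [[Rcpp::export(name = ".poly_loglik_cpp")]]
double poly_loglik_cpp(double rho, NumericMatrix counts, NumericVector tx,
                       NumericVector ty) {
  return poly_loglik(rho, counts, tx, ty);
}

// Brent minimization (localmin of Brent 1973, as in R's optimize) of f on
// [a, b] to absolute x-tolerance tol.
template <typename F>
static double brent_min(F f, double a, double b, double tol) {
  const double c = 0.5 * (3.0 - std::sqrt(5.0));
  const double eps = std::sqrt(DBL_EPSILON);
  double x = a + c * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 200; ++iter) {
    double m = 0.5 * (a + b);
    double tol1 = eps * std::fabs(x) + tol / 3.0;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - m) <= tol2 - 0.5 * (b - a)) break;
    double p = 0.0, q = 0.0, r = 0.0;
    if (std::fabs(e) > tol1) {  // fit parabola
      r = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p; else q = -q;
      r = e;
      e = d;
    }
    if (std::fabs(p) < std::fabs(0.5 * q * r) && p > q * (a - x) &&
        p < q * (b - x)) {
      d = p / q;
      double u = x + d;
      if (u - a < tol2 || b - u < tol2) d = (x < m) ? tol1 : -tol1;
    } else {
      e = (x < m) ? b - x : a - x;
      d = c * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0.0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) {
        v = w; fv = fw; w = u; fw = fu;
      } else if (fu <= fv || v == x || v == w) {
        v = u; fv = fu;
      }
    }
  }
  return x;
}

//' @noRd
// [[Rcpp::export(name = ".polychoric_pair_cpp")]]
List polychoric_pair_cpp(NumericMatrix counts, NumericVector tx,
                         NumericVector ty, double bound_eps, double tol) {
  const double lo = -1.0 + bound_eps, hi = 1.0 - bound_eps;
  auto nll = [&](double rho) { return -poly_loglik(rho, counts, tx, ty); };
  double rho = brent_min(nll, lo, hi, tol);
  // Brent never lands exactly on the boundary; probe it for degenerate
  // (all-mass-on-one-diagonal) tables where the likelihood is monotone.
  double ll = -nll(rho);
  bool boundary = false;
  if (-nll(hi) >= ll) { rho = hi; ll = -nll(hi); boundary = true; }
  if (-nll(lo) > ll)  { rho = lo; ll = -nll(lo); boundary = true; }
  if (std::fabs(rho) >= hi - 10 * tol) boundary = true;
  return List::create(_["rho"] = rho, _["loglik"] = ll,
                      _["boundary"] = boundary);
}
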