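#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Censored beta-binomial machinery for the ploidy mixture likelihood.
//
// The beta-binomial is parameterized by its expectation p and intraclass
// correlation rho:  alpha = p(1-rho)/rho,  beta = (1-p)(1-rho)/rho.
// Densities are renormalized over the censored support
// { y : lo <= y/n <= hi } (bounds inclusive).
//
// Log-pmf over y = 0..n is built from one lbeta evaluation at y = 0 and the
// ratio recurrence
//   pmf(y+1)/pmf(y) = ((n-y)/(y+1)) * ((y+alpha)/(n-y-1+beta)),
// accumulated in log space so extreme tails cannot underflow to hard zeros.

static const double BOUND_EPS = 1e-9;

static void bb_logpmf_vec(int n, double alpha, double beta,
                          std::vector<double> &lp) {
  lp.resize(n + 1);
  // log pmf(0) = lbeta(alpha, n + beta) - lbeta(alpha, beta)
  lp[0] = R::lbeta(alpha, n + beta) - R::lbeta(alpha, beta);
  for (int y = 0; y < n; ++y) {
    double r = std::log((double)(n - y)) - std::log((double)(y + 1)) +
               std::log(y + alpha) - std::log((double)(n - y - 1) + beta);
    lp[y + 1] = lp[y] + r;
  }
}

static double logsumexp_range(const std::vector<double> &lp, int y0, int y1) {
  double mx = -std::numeric_limits<double>::infinity();
  for (int y = y0; y <= y1; ++y)
    if (lp[y] > mx) mx = lp[y];
  if (!R_FINITE(mx)) return mx;
  double s = 0.0;
  for (int y = y0; y <= y1; ++y) s += std::exp(lp[y] - mx);
  return mx + std::log(s);
}

// Log-likelihood of ratio observations (x successes out of n reads) under a
// mixture of censored beta-binomials with component means p_grid and weights
// m, shared correlation rho. Observations must already lie inside the
// censoring window.
// [[Rcpp::export]]
double bbmix_loglik_cpp(IntegerVector x, IntegerVector n,
                        NumericVector p_grid, NumericVector m,
                        double rho, double lo, double hi) {
  const int L = x.size();
  const int J = p_grid.size();
  if (n.size() != L) stop("x and n must have equal length");
  if (m.size() != J) stop("m must match p_grid");
  if (rho <= 0.0 || rho >= 1.0) stop("rho must lie strictly in (0, 1)");

  // per unique n, per component: normalized log-density table over 0..n
  std::map<int, std::vector<std::vector<double> > > tab;
  std::vector<double> lp;
  for (int l = 0; l < L; ++l) {
    int nl = n[l];
    if (nl < 1) stop("total read count must be >= 1");
    if (tab.count(nl)) continue;
    int y0 = (int)std::ceil(lo * nl - BOUND_EPS);
    int y1 = (int)std::floor(hi * nl + BOUND_EPS);
    if (y0 < 0) y0 = 0;
    if (y1 > nl) y1 = nl;
    std::vector<std::vector<double> > comp(J);
    for (int j = 0; j < J; ++j) {
      double p = p_grid[j];
      double alpha = p * (1.0 - rho) / rho;
      double beta = (1.0 - p) * (1.0 - rho) / rho;
      bb_logpmf_vec(nl, alpha, beta, lp);
      double Z = logsumexp_range(lp, y0, y1);
      comp[j].resize(nl + 1);
      for (int y = 0; y <= nl; ++y) comp[j][y] = lp[y] - Z;
    }
    tab[nl] = comp;
  }

  double ll = 0.0;
  for (int l = 0; l < L; ++l) {
    const std::vector<std::vector<double> > &comp = tab[n[l]];
    int xl = x[l];
    if (xl < 0 || xl > n[l]) stop("x out of range for its n");
    double v = 0.0;
    for (int j = 0; j < J; ++j) v += m[j] * std::exp(comp[j][xl]);
    // an observation in the far tail of every component can evaluate to
    // numerical zero; floor at the smallest representable log-density
    ll += (v > 0.0) ? std::log(v) : -745.0;
  }
  return ll;
}
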