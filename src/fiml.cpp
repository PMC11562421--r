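// Pattern-wise Gaussian (FIML) likelihood kernels.
//
// Likelihood evaluation is O(#missingness patterns), not O(n): each pattern
// carries sufficient statistics (count, observed-cell mean, MLE scatter), so
// the optimizer can afford numerical gradients/Hessians even at n ~ 2000.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// patterns: list of (idx [0-based observed cells], n, mean, scatter)
static double pattern_negloglik(const vec& mu, const mat& Sigma, const Rcpp::List& patterns) {
  double nll = 0.0;
  for (int g = 0; g < patterns.size(); ++g) {
    Rcpp::List pat = patterns[g];
    uvec idx = Rcpp::as<uvec>(pat["idx"]);
    double n_g = Rcpp::as<double>(pat["n"]);
    vec m = Rcpp::as<vec>(pat["mean"]);
    mat S = Rcpp::as<mat>(pat["scatter"]);
    mat So = Sigma.submat(idx, idx);
    mat L;
    if (!chol(L, So, "lower")) return datum::inf;
    double ldet = 2.0 * accu(log(L.diag()));
    vec d = m - mu.elem(idx);
    mat Sinv_S = solve(trimatl(L), S, solve_opts::fast);
    Sinv_S = solve(trimatu(L.t()), Sinv_S, solve_opts::fast);
    vec u = solve(trimatl(L), d, solve_opts::fast);
    double quad = dot(u, u);
    nll += 0.5 * n_g * (idx.n_elem * LOG2PI + ldet + trace(Sinv_S) + quad);
  }
  return nll;
}

// theta -> (mu, B, K_zeta, K_B); shared by the R and C++ sides.
// Layout: mu (T*p), B free entries (column-major over maskB), then for each
// precision: p log-diagonal entries followed by free upper-triangle
// off-diagonals (column-major). Fixed entries are exactly zero.
struct GvarPar {
  vec mu;
  mat B, Kz, KB;
  bool ok;
};

static mat unpack_prec(const vec& theta, int& pos, const umat& mask, int p) {
  mat K(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) K(j, j) = std::exp(theta(pos++));
  for (int cc = 0; cc < p; ++cc)
    for (int rr = 0; rr < cc; ++rr)
      if (mask(rr, cc)) { K(rr, cc) = theta(pos); K(cc, rr) = theta(pos); ++pos; }
  return K;
}

static GvarPar unpack_gvar(const vec& theta, int p, int T,
                           const umat& maskB, const umat& maskKz, const umat& maskKB) {
  GvarPar par; par.ok = true;
  int pos = 0;
  par.mu = theta.subvec(0, T * p - 1);
  pos = T * p;
  par.B.zeros(p, p);
  for (int cc = 0; cc < p; ++cc)
    for (int rr = 0; rr < p; ++rr)
      if (maskB(rr, cc)) par.B(rr, cc) = theta(pos++);
  cx_vec ev = eig_gen(par.B);
  double rho = ev.n_elem ? max(abs(ev)) : 0.0;
  if (rho >= 0.99) par.B *= 0.989 / rho;  // smooth stationarity guard
  par.Kz = unpack_prec(theta, pos, maskKz, p);
  par.KB = unpack_prec(theta, pos, maskKB, p);
  return par;
}

// Implied stacked-wave moments: Sigma_W solves Sigma_W = B Sigma_W B' + Kz^-1,
// block (s,t), s>=t is Sigma_B + B^(s-t) Sigma_W.
static bool gvar_implied(const GvarPar& par, int T, vec& mean_out, mat& cov_out) {
  int p = par.B.n_rows;
  mat Sz, SB;
  if (!inv_sympd(Sz, par.Kz)) return false;
  if (!inv_sympd(SB, par.KB)) return false;
  // discrete Lyapunov by doubling: SW = sum_k B^k Sz B'^k, quadratic
  // convergence since the spectral radius is guarded below 0.99
  mat SW = Sz;
  mat A = par.B;
  for (int it = 0; it < 64; ++it) {
    SW += A * SW * A.t();
    A = A * A;
    if (norm(A, "inf") < 1e-15) break;
  }
  SW = 0.5 * (SW + SW.t());
  std::vector<mat> Bpow(T);
  Bpow[0] = eye(p, p);
  for (int k = 1; k < T; ++k) Bpow[k] = Bpow[k - 1] * par.B;
  cov_out.set_size(T * p, T * p);
  for (int t = 0; t < T; ++t)
    for (int s = t; s < T; ++s) {
      mat blk = SB + Bpow[s - t] * SW;  // Cov(y_s, y_t), s >= t
      cov_out.submat(s * p, t * p, (s + 1) * p - 1, (t + 1) * p - 1) = blk;
      if (s != t)
        cov_out.submat(t * p, s * p, (t + 1) * p - 1, (s + 1) * p - 1) = blk.t();
    }
  cov_out = 0.5 * (cov_out + cov_out.t());
  mean_out = par.mu;
  return true;
}

// [[Rcpp::export]]
double gvar_negloglik_cpp(const arma::vec& theta, int p, int T,
                          const arma::umat& maskB, const arma::umat& maskKz,
                          const arma::umat& maskKB, const Rcpp::List& patterns) {
  GvarPar par = unpack_gvar(theta, p, T, maskB, maskKz, maskKB);
  vec mu; mat Sigma;
  if (!gvar_implied(par, T, mu, Sigma)) return 1e10;
  double nll = pattern_negloglik(mu, Sigma, patterns);
  if (!std::isfinite(nll)) return 1e10;
  return nll;
}

// [[Rcpp::export]]
arma::vec gvar_negloglik_grad_cpp(const arma::vec& theta, int p, int T,
                                  const arma::umat& maskB, const arma::umat& maskKz,
                                  const arma::umat& maskKB, const Rcpp::List& patterns,
                                  double eps = 1e-6) {
  int k = theta.n_elem;
  vec g(k);
  vec th = theta;
  for (int j = 0; j < k; ++j) {
    double h = eps * std::max(1.0, std::abs(theta(j)));
    th(j) = theta(j) + h;
    double f1 = gvar_negloglik_cpp(th, p, T, maskB, maskKz, maskKB, patterns);
    th(j) = theta(j) - h;
    double f0 = gvar_negloglik_cpp(th, p, T, maskB, maskKz, maskKB, patterns);
    th(j) = theta(j);
    g(j) = (f1 - f0) / (2.0 * h);
  }
  return g;
}

// [[Rcpp::export]]
arma::mat gvar_negloglik_hess_cpp(const arma::vec& theta, int p, int T,
                                  const arma::umat& maskB, const arma::umat& maskKz,
                                  const arma::umat& maskKB, const Rcpp::List& patterns,
                                  double eps = 1e-4) {
  int k = theta.n_elem;
  mat H(k, k);
  vec th = theta;
  auto f = [&](const vec& x) {
    return gvar_negloglik_cpp(x, p, T, maskB, maskKz, maskKB, patterns);
  };
  vec hstep(k);
  for (int j = 0; j < k; ++j) hstep(j) = eps * std::max(1.0, std::abs(theta(j)));
  double f0 = f(th);
  for (int i = 0; i < k; ++i) {
    for (int j = i; j < k; ++j) {
      if (i == j) {
        th(i) = theta(i) + hstep(i); double fp = f(th);
        th(i) = theta(i) - hstep(i); double fm = f(th);
        th(i) = theta(i);
        H(i, i) = (fp - 2.0 * f0 + fm) / (hstep(i) * hstep(i));
      } else {
        th(i) = theta(i) + hstep(i); th(j) = theta(j) + hstep(j); double fpp = f(th);
        th(j) = theta(j) - hstep(j); double fpm = f(th);
        th(i) = theta(i) - hstep(i); double fmm = f(th);
        th(j) = theta(j) + hstep(j); double fmp = f(th);
        th(i) = theta(i); th(j) = theta(j);
        H(i, j) = H(j, i) = (fpp - fpm - fmp + fmm) / (4.0 * hstep(i) * hstep(j));
      }
    }
  }
  return H;
}

// Unstructured multivariate normal parameterized by mean + log-Cholesky of the
// covariance; used for FIML regression standard errors.
// theta = [mu (d), diag log(L_jj) (d), strict lower triangle of L column-major]
// [[Rcpp::export]]
double mvn_chol_negloglik_cpp(const arma::vec& theta, int d, const Rcpp::List& patterns) {
  vec mu = theta.subvec(0, d - 1);
  mat L(d, d, fill::zeros);
  int pos = d;
  for (int j = 0; j < d; ++j) L(j, j) = std::exp(theta(pos++));
  for (int cc = 0; cc < d; ++cc)
    for (int rr = cc + 1; rr < d; ++rr) L(rr, cc) = theta(pos++);
  mat Sigma = L * L.t();
  double nll = pattern_negloglik(mu, Sigma, patterns);
  if (!std::isfinite(nll)) return 1e10;
  return nll;
}

// [[Rcpp::export]]
double mvn_negloglik_cpp(const arma::vec& mu, const arma::mat& Sigma, const Rcpp::List& patterns) {
  double nll = pattern_negloglik(mu, Sigma, patterns);
  if (!std::isfinite(nll)) return 1e10;
  return nll;
}
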