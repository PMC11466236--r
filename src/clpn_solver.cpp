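// Nodewise lasso engine for cross-lagged panel networks.
//
// Objective per outcome: (1/2n) * RSS + lambda * sum_j pen_j * |beta_j|,
// solved by cyclic coordinate descent on centered sufficient statistics
// (Gram matrix and covariance vector), with warm starts along a decreasing
// log-spaced lambda path. Cross-validation errors are computed from per-fold
// sufficient statistics, so cost per fold is O(p^2) per lambda, independent
// of n once the crossproducts are formed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// One coordinate-descent sweep over the coordinates in `set`; returns the
// maximum absolute coefficient change.
static inline double cd_sweep(const mat& G, const vec& c, const vec& pen,
                              double lambda, vec& beta, const uvec& set) {
  double maxchange = 0.0;
  for (uword t = 0; t < set.n_elem; ++t) {
    const uword j = set[t];
    const double gjj = G(j, j);
    if (gjj < 1e-12) { beta[j] = 0.0; continue; }
    // partial residual covariance for coordinate j
    double grad = c[j] - dot(G.col(j), beta) + gjj * beta[j];
    double bnew = soft(grad, lambda * pen[j]) / gjj;
    double d = bnew - beta[j];
    if (d != 0.0) {
      beta[j] = bnew;
      double ch = std::fabs(d);
      if (ch > maxchange) maxchange = ch;
    }
  }
  return maxchange;
}

// Coordinate descent with the usual active-set strategy: a full sweep
// detects the active set, inner sweeps over the nonzero coordinates run
// until stable, and the cycle repeats until a full sweep changes nothing
// beyond tol. beta is warm-started in place. Returns sweeps used, or -1 on
// non-convergence.
static int cd_solve(const mat& G, const vec& c, const vec& pen, double lambda,
                    vec& beta, double tol, int maxit) {
  const uword p = G.n_cols;
  const uvec all = regspace<uvec>(0, p - 1);
  int used = 0;
  while (used < maxit) {
    double full_change = cd_sweep(G, c, pen, lambda, beta, all);
    ++used;
    if (full_change < tol) return used;
    uvec active = find(beta != 0.0);
    while (used < maxit) {
      double ch = cd_sweep(G, c, pen, lambda, beta, active);
      ++used;
      if (ch < tol) break;
    }
  }
  return -1;
}

// KKT stationarity violation of a solution (0 = exact stationary point).
static double kkt_violation(const mat& G, const vec& c, const vec& pen,
                            double lambda, const vec& beta) {
  vec grad = c - G * beta;
  double v = 0.0;
  for (uword j = 0; j < beta.n_elem; ++j) {
    double thr = lambda * pen[j];
    double viol;
    if (beta[j] == 0.0) {
      viol = std::fabs(grad[j]) - thr;      // |subgradient| must be <= lambda
      if (viol < 0.0) viol = 0.0;
    } else {
      double s = beta[j] > 0.0 ? 1.0 : -1.0;
      viol = std::fabs(grad[j] - thr * s);
    }
    if (viol > v) v = viol;
  }
  return v;
}

// Lasso path on centered sufficient statistics.
// G = X'X/n, c = X'y/n (both centered); pen = per-coefficient penalty factor
// (0 => unpenalized); lambdas in the order they should be visited.
// [[Rcpp::export]]
Rcpp::List cpp_lasso_path_gram(const arma::mat& G, const arma::vec& c,
                               const arma::vec& pen, const arma::vec& lambdas,
                               double tol, int maxit) {
  const int p = G.n_cols;
  const int L = lambdas.n_elem;
  mat beta(p, L, fill::zeros);
  vec b(p, fill::zeros);
  int nonconv = 0;
  vec kkt(L);
  for (int l = 0; l < L; ++l) {
    int st = cd_solve(G, c, pen, lambdas[l], b, tol, maxit);
    if (st < 0) ++nonconv;
    beta.col(l) = b;
    kkt[l] = kkt_violation(G, c, pen, lambdas[l], b);
  }
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("kkt") = kkt,
                            Rcpp::Named("n_nonconverged") = nonconv);
}

struct CenteredStats {
  mat G;   // centered Gram / n
  vec m;   // column means
  double n;
};

static CenteredStats center_gram(const mat& Sxx, const vec& sx, double nn) {
  CenteredStats st;
  st.m = sx / nn;
  st.G = (Sxx - nn * (st.m * st.m.t())) / nn;
  st.n = nn;
  return st;
}

static vec center_cov(const vec& Sxy, const vec& sx, double sy, double nn) {
  return (Sxy - sx * (sy / nn)) / nn;
}

// Full nodewise CV lasso fit for a CLPN: every column of Y regressed on X.
// foldid: 1..K fold assignment; pen: penalty factor per column of X;
// rule_one_se: 0 = CV-minimum lambda, 1 = one-standard-error rule.
// [[Rcpp::export]]
Rcpp::List cpp_cv_clpn(const arma::mat& X, const arma::mat& Y,
                       const arma::ivec& foldid, const arma::vec& pen,
                       int nlambda, double lambda_min_ratio,
                       int rule_one_se, double tol, int maxit) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  const int q = Y.n_cols;
  const int K = foldid.max();

  // full-sample uncentered stats
  mat Sxx = X.t() * X;
  vec sx = sum(X, 0).t();
  mat Sxy = X.t() * Y;
  rowvec sy = sum(Y, 0);
  rowvec Syy = sum(square(Y), 0);

  // per-fold uncentered stats
  std::vector<mat> Sxx_f(K), Sxy_f(K);
  std::vector<vec> sx_f(K);
  std::vector<rowvec> sy_f(K), Syy_f(K);
  std::vector<double> n_f(K);
  for (int k = 0; k < K; ++k) {
    uvec idx = find(foldid == (k + 1));
    mat Xk = X.rows(idx);
    mat Yk = Y.rows(idx);
    Sxx_f[k] = Xk.t() * Xk;
    sx_f[k] = sum(Xk, 0).t();
    Sxy_f[k] = Xk.t() * Yk;
    sy_f[k] = sum(Yk, 0);
    Syy_f[k] = sum(square(Yk), 0);
    n_f[k] = (double)idx.n_elem;
    if (n_f[k] < 1) Rcpp::stop("empty cross-validation fold");
  }

  CenteredStats full = center_gram(Sxx, sx, (double)n);
  uvec unpen = find(pen == 0.0);
  uvec penalized = find(pen > 0.0);

  // train-side centered stats per fold (Gram shared across outcomes)
  std::vector<CenteredStats> tr(K);
  for (int k = 0; k < K; ++k)
    tr[k] = center_gram(Sxx - Sxx_f[k], sx - sx_f[k], (double)n - n_f[k]);

  mat beta_sel(p, q, fill::zeros);
  vec a0_sel(q), lambda_sel(q);
  ivec idx_sel(q);
  mat lambda_grid(nlambda, q), cvm_out(nlambda, q), cvse_out(nlambda, q);
  vec kkt_out(q);
  int nonconv = 0;

  for (int j = 0; j < q; ++j) {
    vec c_full = center_cov(Sxy.col(j), sx, sy[j], (double)n);

    // lambda_max: smallest lambda zeroing all penalized coefficients,
    // after the unpenalized block is fit freely.
    vec r = c_full;
    if (unpen.n_elem > 0) {
      mat Guu = full.G.submat(unpen, unpen);
      vec bu;
      bool ok = solve(bu, Guu, c_full.elem(unpen),
                      solve_opts::no_approx + solve_opts::likely_sympd);
      if (!ok) bu = pinv(Guu) * c_full.elem(unpen);
      r = c_full - full.G.cols(unpen) * bu;
    }
    double lmax = 0.0;
    for (uword t = 0; t < penalized.n_elem; ++t) {
      double v = std::fabs(r[penalized[t]]) / pen[penalized[t]];
      if (v > lmax) lmax = v;
    }
    if (lmax <= 0.0) lmax = 1e-3;   // degenerate outcome: flat grid
    vec lambdas = exp(linspace<vec>(std::log(lmax),
                                    std::log(lmax * lambda_min_ratio),
                                    nlambda));
    lambda_grid.col(j) = lambdas;

    // CV error per lambda from fold-level sufficient statistics
    mat foldmse(K, nlambda);
    for (int k = 0; k < K; ++k) {
      double ntr = tr[k].n;
      vec c_tr = center_cov(Sxy.col(j) - Sxy_f[k].col(j), sx - sx_f[k],
                            sy[j] - sy_f[k][j], ntr);
      double my_tr = (sy[j] - sy_f[k][j]) / ntr;
      vec b(p, fill::zeros);
      for (int l = 0; l < nlambda; ++l) {
        if (cd_solve(tr[k].G, c_tr, pen, lambdas[l], b, tol, maxit) < 0)
          ++nonconv;
        double a0 = my_tr - dot(tr[k].m, b);
        // validation SSE from uncentered fold stats
        double sse = Syy_f[k][j]
          - 2.0 * a0 * sy_f[k][j]
          - 2.0 * dot(b, Sxy_f[k].col(j))
          + 2.0 * a0 * dot(b, sx_f[k])
          + n_f[k] * a0 * a0
          + dot(b, Sxx_f[k] * b);
        foldmse(k, l) = sse / n_f[k];
      }
    }
    vec cvm(nlambda), cvse(nlambda);
    for (int l = 0; l < nlambda; ++l) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) tot += foldmse(k, l) * n_f[k];
      cvm[l] = tot / (double)n;
      cvse[l] = stddev(foldmse.col(l)) / std::sqrt((double)K);
    }
    cvm_out.col(j) = cvm;
    cvse_out.col(j) = cvse;

    uword imin = cvm.index_min();
    uword isel = imin;
    if (rule_one_se) {
      double cut = cvm[imin] + cvse[imin];
      for (uword l = 0; l <= imin; ++l) {
        if (cvm[l] <= cut) { isel = l; break; }
      }
    }

    // final full-data path down to the selected lambda (warm starts)
    vec b(p, fill::zeros);
    for (uword l = 0; l <= isel; ++l) {
      if (cd_solve(full.G, c_full, pen, lambdas[l], b, tol, maxit) < 0)
        ++nonconv;
    }
    beta_sel.col(j) = b;
    a0_sel[j] = sy[j] / (double)n - dot(full.m, b);
    lambda_sel[j] = lambdas[isel];
    idx_sel[j] = (int)isel + 1;
    kkt_out[j] = kkt_violation(full.G, c_full, pen, lambdas[isel], b);
  }

  return Rcpp::List::create(
    Rcpp::Named("beta") = beta_sel,
    Rcpp::Named("a0") = a0_sel,
    Rcpp::Named("lambda") = lambda_sel,
    Rcpp::Named("lambda_index") = idx_sel,
    Rcpp::Named("lambda_grid") = lambda_grid,
    Rcpp::Named("cvm") = cvm_out,
    Rcpp::Named("cvse") = cvse_out,
    Rcpp::Named("kkt") = kkt_out,
    Rcpp::Named("n_nonconverged") = nonconv);
}
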