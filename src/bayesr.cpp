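#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// scaled inverse chi-square draw: (df * scale) / rchisq(df)
static inline double rinvchisq(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// Single-site Gibbs sampler for the four-component mixture regression
//   y = X b + M m + sum_t Z_t u_t + Q q + e
// with m_j | component k ~ N(0, sigma2_k), sigma2 = ratios * sigma_g2,
// component 1 a point mass at zero, pi ~ Dirichlet(alpha), class-term
// variances and sigma_e2 scaled-inverse-chi-square.
//
// class_idx: list of integer vectors (one per indicator random term),
//   0-based level per observation, -1 for "no level" (e.g. unknown dam).
// class_nlev: number of levels per indicator term.
// Qmat: optional dense covariate matrix for the breed-proportion random
//   term (0 columns to omit).
// pi_fixed: length-4 vector to hold pi fixed, or length-0 to sample it.
//
// Uses R's RNG throughout: identical seed => identical chain.
// [[Rcpp::export]]
List bayesr_gibbs_cpp(const NumericVector& y,
                      const NumericMatrix& X,
                      const NumericMatrix& M,
                      const List& class_idx,
                      const IntegerVector& class_nlev,
                      const NumericVector& class_prior_scale,
                      const NumericMatrix& Qmat,
                      const double q_prior_scale,
                      const NumericVector& ratios,
                      double sigma_g2,
                      const NumericVector& alpha,
                      const int n_iter,
                      const int burn_in,
                      const int thin,
                      const NumericVector& pi_fixed,
                      const bool update_sigma_g,
                      const double nu_class,
                      const double nu_e,
                      const double s_e) {
  const int n = y.size();
  const int p = X.ncol();
  const int m = M.ncol();
  const int K = ratios.size();
  const int n_terms = class_idx.size();
  const int nq = Qmat.ncol();
  if (M.nrow() != n || X.nrow() != n) stop("design dimensions do not match y");
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter");

  // column squared norms
  std::vector<double> xtx(p), mtm(m), qtq(nq);
  for (int j = 0; j < p; ++j) {
    double s = 0; for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  for (int j = 0; j < m; ++j) {
    double s = 0; for (int i = 0; i < n; ++i) s += M(i, j) * M(i, j);
    mtm[j] = s;
  }
  for (int j = 0; j < nq; ++j) {
    double s = 0; for (int i = 0; i < n; ++i) s += Qmat(i, j) * Qmat(i, j);
    qtq[j] = s;
  }
  // level counts per class term
  std::vector< std::vector<int> > lev_count(n_terms);
  for (int t = 0; t < n_terms; ++t) {
    IntegerVector idx = class_idx[t];
    lev_count[t].assign(class_nlev[t], 0);
    for (int i = 0; i < n; ++i) if (idx[i] >= 0) lev_count[t][idx[i]]++;
  }

  // state
  std::vector<double> b(p, 0.0), snp(m, 0.0), qeff(nq, 0.0);
  std::vector<int> comp(m, 0);
  std::vector< std::vector<double> > u(n_terms);
  std::vector<double> u_var(n_terms);
  for (int t = 0; t < n_terms; ++t) {
    u[t].assign(class_nlev[t], 0.0);
    u_var[t] = class_prior_scale[t] > 0 ? class_prior_scale[t] : 1e-4;
  }
  double q_var = nq > 0 ? (q_prior_scale > 0 ? q_prior_scale : 1e-4) : 0.0;
  double sigma_e2 = s_e > 0 ? s_e : 1.0;
  std::vector<double> pi(K);
  if (pi_fixed.size() == K) {
    for (int k = 0; k < K; ++k) pi[k] = pi_fixed[k];
  } else {
    for (int k = 0; k < K; ++k) pi[k] = 1.0 / K;
  }
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i];

  // accumulators
  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  std::vector<double> snp_sum(m, 0.0), b_sum(p, 0.0), q_sum(nq, 0.0);
  std::vector<double> pi_sum(K, 0.0);
  std::vector< std::vector<double> > comp_count(m, std::vector<double>(K, 0.0));
  std::vector< std::vector<double> > u_sum(n_terms);
  std::vector<double> uvar_sum(n_terms, 0.0);
  for (int t = 0; t < n_terms; ++t) u_sum[t].assign(class_nlev[t], 0.0);
  NumericVector sigma_e_trace(n_keep), nnz_trace(n_keep), sigma_g_trace(n_keep);
  int keep = 0;

  std::vector<int> order(m);
  for (int j = 0; j < m; ++j) order[j] = j;
  std::vector<double> sigk(K), logpi(K), logw(K), cum(K);

  for (int it = 0; it < n_iter; ++it) {
    // component variances (sigma_g2 may be resampled)
    for (int k = 0; k < K; ++k) sigk[k] = ratios[k] * sigma_g2;

    // (i) fixed effects
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0) continue;
      double old = b[j], rhs = 0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * (e[i] + X(i, j) * old);
      double mean = rhs / xtx[j];
      double newb = mean + norm_rand() * std::sqrt(sigma_e2 / xtx[j]);
      double d = newb - old;
      for (int i = 0; i < n; ++i) e[i] -= X(i, j) * d;
      b[j] = newb;
    }

    // (ii) indicator random terms + their variances
    for (int t = 0; t < n_terms; ++t) {
      IntegerVector idx = class_idx[t];
      const int L = class_nlev[t];
      std::vector<double> s(L, 0.0);
      for (int i = 0; i < n; ++i)
        if (idx[i] >= 0) s[idx[i]] += e[i] + u[t][idx[i]];
      double lambda = sigma_e2 / u_var[t];
      double ssq = 0;
      for (int l = 0; l < L; ++l) {
        double denom = lev_count[t][l] + lambda;
        double mean = s[l] / denom;
        double newu = mean + norm_rand() * std::sqrt(sigma_e2 / denom);
        ssq += newu * newu;
        s[l] = newu - u[t][l];  // reuse as delta
        u[t][l] = newu;
      }
      for (int i = 0; i < n; ++i) if (idx[i] >= 0) e[i] -= s[idx[i]];
      u_var[t] = rinvchisq(nu_class + L,
                           (ssq + nu_class * class_prior_scale[t]) / (nu_class + L));
    }

    // breed-proportion regression term
    if (nq > 0) {
      double ssq = 0;
      double lambda = sigma_e2 / q_var;
      for (int j = 0; j < nq; ++j) {
        double old = qeff[j], rhs = 0;
        for (int i = 0; i < n; ++i) rhs += Qmat(i, j) * (e[i] + Qmat(i, j) * old);
        double denom = qtq[j] + lambda;
        double newq = rhs / denom + norm_rand() * std::sqrt(sigma_e2 / denom);
        double d = newq - old;
        for (int i = 0; i < n; ++i) e[i] -= Qmat(i, j) * d;
        qeff[j] = newq;
        ssq += newq * newq;
      }
      q_var = rinvchisq(nu_class + nq,
                        (ssq + nu_class * q_prior_scale) / (nu_class + nq));
    }

    // (iii) SNP effects in a fresh random order
    for (int j = m - 1; j > 0; --j) {
      int k = (int)(unif_rand() * (j + 1));
      std::swap(order[j], order[k]);
    }
    int nnz = 0;
    for (int k = 0; k < K; ++k)
      logpi[k] = pi[k] > 0 ? std::log(pi[k]) : R_NegInf;
    const double* Mp = M.begin();
    double* ep = e.data();
    for (int jj = 0; jj < m; ++jj) {
      const int j = order[jj];
      if (mtm[j] <= 0) { snp[j] = 0.0; comp[j] = 0; continue; }
      const double* col = Mp + (R_xlen_t)n * j;
      double old = snp[j];
      double rhs = 0;
      if (old != 0.0) {
        for (int i = 0; i < n; ++i) {
          double ei = ep[i] + col[i] * old;
          ep[i] = ei;
          rhs += col[i] * ei;
        }
      } else {
        for (int i = 0; i < n; ++i) rhs += col[i] * ep[i];
      }
      // component log-weights (effect integrated out)
      double wmax = R_NegInf;
      for (int k = 0; k < K; ++k) {
        if (!std::isfinite(logpi[k])) { logw[k] = R_NegInf; continue; }
        if (sigk[k] <= 0.0) {
          logw[k] = logpi[k];
        } else {
          double v = mtm[j] + sigma_e2 / sigk[k];
          logw[k] = logpi[k]
            - 0.5 * std::log(sigk[k] * mtm[j] / sigma_e2 + 1.0)
            + 0.5 * rhs * rhs / (sigma_e2 * v);
        }
        if (logw[k] > wmax) wmax = logw[k];
      }
      double tot = 0;
      for (int k = 0; k < K; ++k) {
        cum[k] = std::isfinite(logw[k]) ? std::exp(logw[k] - wmax) : 0.0;
        tot += cum[k];
      }
      double uu = unif_rand() * tot, acc = 0;
      int pick = 0;
      for (int k = 0; k < K; ++k) { acc += cum[k]; if (uu <= acc) { pick = k; break; } }
      comp[j] = pick;
      if (sigk[pick] <= 0.0) {
        snp[j] = 0.0;
      } else {
        double v = mtm[j] + sigma_e2 / sigk[pick];
        double newm = rhs / v + norm_rand() * std::sqrt(sigma_e2 / v);
        if (!std::isfinite(newm))
          stop("non-finite SNP effect update at iteration %d", it + 1);
        snp[j] = newm;
        for (int i = 0; i < n; ++i) ep[i] -= col[i] * newm;
        ++nnz;
      }
    }

    // (iv) mixture proportions
    if (pi_fixed.size() != K) {
      std::vector<int> cnt(K, 0);
      for (int j = 0; j < m; ++j) cnt[comp[j]]++;
      double tot = 0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha[k] + cnt[k], 1.0);
        pi[k] = g; tot += g;
      }
      for (int k = 0; k < K; ++k) pi[k] /= tot;
    }

    // optional sigma_g2 update given current nonzero effects
    if (update_sigma_g) {
      double ssq = 0; int nz = 0;
      for (int j = 0; j < m; ++j) {
        if (comp[j] > 0 && ratios[comp[j]] > 0) {
          ssq += snp[j] * snp[j] / ratios[comp[j]];
          ++nz;
        }
      }
      sigma_g2 = rinvchisq(nu_class + nz,
                           (ssq + nu_class * sigma_g2) / (nu_class + nz));
    }

    // (v) residual variance
    double sse = 0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    if (!std::isfinite(sse))
      stop("non-finite residual at iteration %d", it + 1);
    sigma_e2 = rinvchisq(nu_e + n, (sse + nu_e * s_e) / (nu_e + n));

    // accumulate
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < m; ++j) {
        snp_sum[j] += snp[j];
        comp_count[j][comp[j]] += 1.0;
      }
      for (int j = 0; j < p; ++j) b_sum[j] += b[j];
      for (int j = 0; j < nq; ++j) q_sum[j] += qeff[j];
      for (int k = 0; k < K; ++k) pi_sum[k] += pi[k];
      for (int t = 0; t < n_terms; ++t) {
        for (int l = 0; l < class_nlev[t]; ++l) u_sum[t][l] += u[t][l];
        uvar_sum[t] += u_var[t];
      }
      sigma_e_trace[keep] = sigma_e2;
      nnz_trace[keep] = nnz;
      sigma_g_trace[keep] = sigma_g2;
      ++keep;
    }
  }

  // posterior means
  NumericVector snp_mean(m), comp_probs(m * K), b_mean(p), q_mean(nq), pi_mean(K);
  for (int j = 0; j < m; ++j) snp_mean[j] = snp_sum[j] / keep;
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < K; ++k) comp_probs[j + (R_xlen_t)m * k] = comp_count[j][k] / keep;
  comp_probs.attr("dim") = IntegerVector::create(m, K);
  for (int j = 0; j < p; ++j) b_mean[j] = b_sum[j] / keep;
  for (int j = 0; j < nq; ++j) q_mean[j] = q_sum[j] / keep;
  for (int k = 0; k < K; ++k) pi_mean[k] = pi_sum[k] / keep;
  List u_means(n_terms);
  NumericVector uvar_mean(n_terms);
  for (int t = 0; t < n_terms; ++t) {
    NumericVector um(class_nlev[t]);
    for (int l = 0; l < class_nlev[t]; ++l) um[l] = u_sum[t][l] / keep;
    u_means[t] = um;
    uvar_mean[t] = uvar_sum[t] / keep;
  }

  // residual drift check: recompute e from current state
  double drift = 0;
  for (int i = 0; i < n; ++i) {
    double fit = 0;
    for (int j = 0; j < p; ++j) fit += X(i, j) * b[j];
    for (int j = 0; j < nq; ++j) fit += Qmat(i, j) * qeff[j];
    for (int t = 0; t < n_terms; ++t) {
      IntegerVector idx = class_idx[t];
      if (idx[i] >= 0) fit += u[t][idx[i]];
    }
    for (int j = 0; j < m; ++j) if (snp[j] != 0.0) fit += M(i, j) * snp[j];
    double d = std::fabs((y[i] - fit) - e[i]);
    if (d > drift) drift = d;
  }

  return List::create(
    _["snp_effect_means"] = snp_mean,
    _["component_probs"] = comp_probs,
    _["pi_mean"] = pi_mean,
    _["fixed_means"] = b_mean,
    _["breed_means"] = q_mean,
    _["class_means"] = u_means,
    _["class_var_means"] = uvar_mean,
    _["sigma_e_trace"] = sigma_e_trace,
    _["sigma_g_trace"] = sigma_g_trace,
    _["nnz_trace"] = nnz_trace,
    _["n_saved"] = keep,
    _["residual_drift"] = drift);
}
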