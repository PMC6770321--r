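#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Meiosis: one gamete from a pair of haplotypes under the Haldane map
// (crossover count ~ Poisson(L/100), positions uniform, no interference).
// pos: cM positions of all SNPs, concatenated chromosome by chromosome.
// chr_start: 0-based offset of each chromosome's first SNP; chr_nsnp: counts;
// chr_len: genetic lengths in cM. Uses R's RNG so set.seed() governs output.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".gamete_cpp")]]
IntegerVector gamete_cpp(const IntegerVector& h1, const IntegerVector& h2,
                         const NumericVector& pos, const IntegerVector& chr_start,
                         const IntegerVector& chr_nsnp, const NumericVector& chr_len) {
  const int nchr = chr_start.size();
  IntegerVector out(h1.size());
  for (int c = 0; c < nchr; ++c) {
    const int s0 = chr_start[c], ns = chr_nsnp[c];
    const double L = chr_len[c];
    int ncx = (L > 0) ? (int) R::rpois(L / 100.0) : 0;
    std::vector<double> cx(ncx);
    for (int k = 0; k < ncx; ++k) cx[k] = unif_rand() * L;
    std::sort(cx.begin(), cx.end());
    int phase = (unif_rand() < 0.5) ? 0 : 1;
    int k = 0;
    for (int j = 0; j < ns; ++j) {
      const double p = pos[s0 + j];
      while (k < ncx && cx[k] <= p) { phase = 1 - phase; ++k; }
      out[s0 + j] = phase == 0 ? h1[s0 + j] : h2[s0 + j];
    }
  }
  return out;
}

// Inverse-Gaussian sampler (Michael, Schucany & Haas).
static double rinvgauss(double mu, double lambda) {
  double z = norm_rand();
  double y = z * z;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
    (mu / (2.0 * lambda)) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0) x = 1e-12;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// Truncated Gamma(shape, rate) on (0, upper] via rejection (upper far in the
// tail for all realistic inputs, so acceptance is ~1).
static double rgamma_trunc(double shape, double rate, double upper) {
  for (int it = 0; it < 1000; ++it) {
    double x = R::rgamma(shape, 1.0 / rate);
    if (x <= upper) return x;
  }
  return upper;
}

// ---------------------------------------------------------------------------
// Bayesian Power Lasso MCMC.
// Model: y = X b + W u + e, e ~ N(0, sigma_e2 I); prior on each SNP effect
// p(u_i) = beta * lambda^(1/beta) / (2 Gamma(1/beta)) * exp(-lambda |u_i|^beta)
// (properly normalized exponential power density); flat priors on b, sigma_e2
// and on lambda in (0, lambda_max].
// beta == 1: conjugate scale-mixture Gibbs (Laplace as normal-exponential mix).
// beta  < 1: adaptive Metropolis-within-Gibbs per SNP, adaptation frozen at
// the end of burn-in.
// fix_sigma_e2 / fix_lambda: NA => sampled; a value => held fixed.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".pl_mcmc_cpp")]]
List pl_mcmc_cpp(const NumericVector& y, const NumericMatrix& X,
                 const NumericMatrix& W, double beta_shape,
                 int chain, int burnin, int thin,
                 double fix_sigma_e2, double fix_lambda,
                 double lambda_max, bool store_u,
                 const NumericVector& u_init, double lambda_init) {
  const int n = y.size(), p = X.ncol(), m = W.ncol();
  const bool upd_se = NumericVector::is_na(fix_sigma_e2);
  const bool upd_la = NumericVector::is_na(fix_lambda);
  const int nstore = (chain - burnin) / thin;

  std::vector<double> b(p, 0.0), u(m, 0.0), tau2(m, 1.0);
  for (int j = 0; j < m && j < u_init.size(); ++j) u[j] = u_init[j];
  double sigma_e2 = upd_se ? 1.0 : fix_sigma_e2;
  double lambda = upd_la ? lambda_init : fix_lambda;

  // column norms
  std::vector<double> xtx(p), wtw(m);
  for (int j = 0; j < p; ++j) {
    double s = 0; for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  for (int j = 0; j < m; ++j) {
    double s = 0; for (int i = 0; i < n; ++i) s += W(i, j) * W(i, j);
    wtw[j] = s;
  }
  // init sigma_e2 from var(y)
  if (upd_se) {
    double my = mean(y), s = 0;
    for (int i = 0; i < n; ++i) s += (y[i] - my) * (y[i] - my);
    sigma_e2 = s / std::max(1, n - 1);
    if (sigma_e2 <= 0) sigma_e2 = 1.0;
  }

  std::vector<double> r(n);  // residual y - Xb - Wu
  for (int i = 0; i < n; ++i) {
    double wu = 0;
    for (int j = 0; j < m; ++j) if (u[j] != 0) wu += W(i, j) * u[j];
    r[i] = y[i] - wu;
  }

  // MH proposal scales and acceptance bookkeeping (beta < 1)
  std::vector<double> prop_sd(m, 0.1), acc(m, 0.0), tries(m, 0.0);
  std::vector<double> acc_all(m, 0.0), tries_all(m, 0.0);

  // accumulators over all post-burn-in cycles
  std::vector<double> u_sum(m, 0.0), u_sq(m, 0.0), b_sum(p, 0.0);
  double se_sum = 0, la_sum = 0;
  long n_acc = 0;

  NumericMatrix scalars(nstore, 3 + p);  // sigma_e2, lambda, deviance, b
  NumericMatrix u_draws = store_u ? NumericMatrix(nstore, m) : NumericMatrix(0, 0);
  int istore = 0;

  const double LOG2PI = std::log(2.0 * M_PI);

  for (int iter = 0; iter < chain; ++iter) {
    // --- fixed effects: coordinate Gibbs, flat prior ---
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0) continue;
      double xr = 0; for (int i = 0; i < n; ++i) xr += X(i, j) * r[i];
      double mean_j = b[j] + xr / xtx[j];
      double bnew = mean_j + norm_rand() * std::sqrt(sigma_e2 / xtx[j]);
      double d = bnew - b[j];
      for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
      b[j] = bnew;
    }

    // --- SNP effects ---
    if (beta_shape >= 1.0) {
      for (int j = 0; j < m; ++j) {
        if (wtw[j] <= 0) { u[j] = 0; continue; }
        double wr = 0; for (int i = 0; i < n; ++i) wr += W(i, j) * r[i];
        wr += wtw[j] * u[j];  // w_j' (r + w_j u_j)
        double prec = wtw[j] / sigma_e2 + 1.0 / tau2[j];
        double mu_j = (wr / sigma_e2) / prec;
        double unew = mu_j + norm_rand() / std::sqrt(prec);
        double d = unew - u[j];
        for (int i = 0; i < n; ++i) r[i] -= W(i, j) * d;
        u[j] = unew;
      }
    } else {
      for (int j = 0; j < m; ++j) {
        if (wtw[j] <= 0) { u[j] = 0; continue; }
        double ustar = u[j] + norm_rand() * prop_sd[j];
        double wr = 0; for (int i = 0; i < n; ++i) wr += W(i, j) * r[i];
        double d = ustar - u[j];
        double dss = -2.0 * d * wr + d * d * wtw[j];  // change in r'r
        double logacc = -dss / (2.0 * sigma_e2) -
          lambda * (std::pow(std::fabs(ustar), beta_shape) -
                    std::pow(std::fabs(u[j]), beta_shape));
        tries[j] += 1; tries_all[j] += 1;
        if (std::log(unif_rand()) < logacc) {
          for (int i = 0; i < n; ++i) r[i] -= W(i, j) * d;
          u[j] = ustar;
          acc[j] += 1; acc_all[j] += 1;
        }
      }
      // adapt proposal scales during burn-in only
      if (iter < burnin && (iter + 1) % 50 == 0) {
        for (int j = 0; j < m; ++j) {
          if (tries[j] > 0) {
            double rate = acc[j] / tries[j];
            if (rate < 0.30) prop_sd[j] *= 0.8;
            else if (rate > 0.45) prop_sd[j] *= 1.25;
            acc[j] = 0; tries[j] = 0;
          }
        }
      }
    }

    // --- lambda | u (tau integrated out), flat prior on (0, lambda_max] ---
    double sab = 0;
    for (int j = 0; j < m; ++j) sab += std::pow(std::fabs(u[j]), beta_shape);
    if (upd_la)
      lambda = rgamma_trunc(m / beta_shape + 1.0, std::max(sab, 1e-12), lambda_max);

    // --- tau2 | u, lambda for the scale-mixture representation ---
    if (beta_shape >= 1.0) {
      for (int j = 0; j < m; ++j) {
        double au = std::max(std::fabs(u[j]), 1e-10);
        double eta = rinvgauss(lambda / au, lambda * lambda);
        tau2[j] = 1.0 / std::max(eta, 1e-12);
      }
    }

    // --- sigma_e2 | r, flat prior ---
    double rr = 0; for (int i = 0; i < n; ++i) rr += r[i] * r[i];
    if (upd_se) {
      double shape = n / 2.0 - 1.0;
      if (shape < 0.5) shape = 0.5;
      double eta = R::rgamma(shape, 2.0 / std::max(rr, 1e-12));
      sigma_e2 = 1.0 / std::max(eta, 1e-12);
    }

    if (iter >= burnin) {
      for (int j = 0; j < m; ++j) { u_sum[j] += u[j]; u_sq[j] += u[j] * u[j]; }
      for (int j = 0; j < p; ++j) b_sum[j] += b[j];
      se_sum += sigma_e2; la_sum += lambda; ++n_acc;
      if ((iter - burnin) % thin == thin - 1 && istore < nstore) {
        double dev = n * (LOG2PI + std::log(sigma_e2)) + rr / sigma_e2;
        if (!R_finite(dev)) stop("divergent chain: non-finite deviance at iteration %d", iter + 1);
        scalars(istore, 0) = sigma_e2;
        scalars(istore, 1) = lambda;
        scalars(istore, 2) = dev;
        for (int j = 0; j < p; ++j) scalars(istore, 3 + j) = b[j];
        if (store_u) for (int j = 0; j < m; ++j) u_draws(istore, j) = u[j];
        ++istore;
      }
    }
  }

  NumericVector um(m), usd(m), bm(p), psd(m), arate(m);
  for (int j = 0; j < m; ++j) {
    um[j] = u_sum[j] / n_acc;
    double v = u_sq[j] / n_acc - um[j] * um[j];
    usd[j] = std::sqrt(std::max(v, 0.0));
    psd[j] = prop_sd[j];
    arate[j] = tries_all[j] > 0 ? acc_all[j] / tries_all[j] : NA_REAL;
  }
  for (int j = 0; j < p; ++j) bm[j] = b_sum[j] / n_acc;

  return List::create(
    _["u_mean"] = um, _["u_sd"] = usd, _["b_mean"] = bm,
    _["sigma_e2_mean"] = se_sum / n_acc, _["lambda_mean"] = la_sum / n_acc,
    _["scalars"] = scalars, _["u_draws"] = u_draws,
    _["accept_rate"] = arate, _["prop_sd"] = psd, _["n_stored"] = istore);
}
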