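// Compiled kernels: exact stationary Gaussian AR(1) likelihood and its
// maximizer for single series, and the Markov chain Monte Carlo samplers
// for the fixed (per-individual) and hierarchical (random) Bayesian
// models. All randomness comes from R's RNG so set.seed() on the R side
// fixes every draw.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------
// Exact AR(1) likelihood
// ---------------------------------------------------------------------

// Sufficient statistics of a series for O(1) likelihood evaluation over
// the transition terms t = 2..T, plus the first observation.
struct Ar1Stats {
  double y1;      // first observation
  double S1;      // sum_{t>=2} y_t
  double S0;      // sum_{t>=2} y_{t-1}
  double S11;     // sum y_t^2
  double S00;     // sum y_{t-1}^2
  double S01;     // sum y_t y_{t-1}
  int T;
};

static Ar1Stats ar1_stats(const double* y, int T) {
  Ar1Stats s;
  s.y1 = y[0]; s.S1 = 0; s.S0 = 0; s.S11 = 0; s.S00 = 0; s.S01 = 0; s.T = T;
  for (int t = 1; t < T; ++t) {
    s.S1 += y[t];
    s.S0 += y[t - 1];
    s.S11 += y[t] * y[t];
    s.S00 += y[t - 1] * y[t - 1];
    s.S01 += y[t] * y[t - 1];
  }
  return s;
}

// SS(mu, phi) = (1-phi^2)(y1-mu)^2 + sum_{t>=2} (y_t - mu - phi(y_{t-1}-mu))^2
static double ar1_ss(const Ar1Stats& s, double mu, double phi) {
  double omp = 1.0 - phi;
  double d1 = s.y1 - mu;
  double trans = s.S11 + phi * phi * s.S00 - 2.0 * phi * s.S01
    - 2.0 * mu * omp * s.S1 + 2.0 * mu * phi * omp * s.S0
    + (s.T - 1) * mu * mu * omp * omp;
  return (1.0 - phi * phi) * d1 * d1 + trans;
}

static double ar1_nll_stats(const Ar1Stats& s, double mu, double phi,
                            double sigma) {
  if (std::fabs(phi) >= 1.0 || sigma <= 0.0) return R_PosInf;
  double ss = ar1_ss(s, mu, phi);
  double T = s.T;
  return 0.5 * T * std::log(2.0 * M_PI) + T * std::log(sigma)
    - 0.5 * std::log1p(-phi * phi) + ss / (2.0 * sigma * sigma);
}

// [[Rcpp::export(name = ".ar1_negloglik_cpp")]]
double ar1_negloglik_cpp(NumericVector y, double mu, double phi,
                         double sigma) {
  Ar1Stats s = ar1_stats(REAL(y), y.size());
  return ar1_nll_stats(s, mu, phi, sigma);
}

// Closed-form mu minimizing SS given phi, and the profile deviance
// T log(SS/T) - log(1 - phi^2) (constants dropped).
static double ar1_profile_mu(const Ar1Stats& s, double phi) {
  double num = (1.0 + phi) * s.y1 + s.S1 - phi * s.S0;
  double den = (1.0 + phi) + (s.T - 1) * (1.0 - phi);
  return num / den;
}

static double ar1_profile_dev(const Ar1Stats& s, double phi) {
  if (std::fabs(phi) >= 1.0) return R_PosInf;
  double mu = ar1_profile_mu(s, phi);
  double ss = ar1_ss(s, mu, phi);
  if (ss <= 0.0 || !std::isfinite(ss)) return R_PosInf;
  return s.T * std::log(ss / s.T) - std::log1p(-phi * phi);
}

// Golden-section minimization of the profile deviance on [lo, hi].
static double golden_min(const Ar1Stats& s, double lo, double hi) {
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double a = lo, b = hi;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = ar1_profile_dev(s, c), fd = ar1_profile_dev(s, d);
  for (int it = 0; it < 200 && (b - a) > 1e-11; ++it) {
    if (fc < fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a); fc = ar1_profile_dev(s, c);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a); fd = ar1_profile_dev(s, d);
    }
  }
  return 0.5 * (a + b);
}

// 3x3 symmetric solve for the observed-information standard error; returns
// false when the Hessian is not positive definite.
static bool invert3_pd(double H[3][3], double Hinv[3][3]) {
  // Cholesky H = L L'
  double L[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j <= i; ++j) {
      double sum = H[i][j];
      for (int k = 0; k < j; ++k) sum -= L[i][k] * L[j][k];
      if (i == j) {
        if (sum <= 0.0 || !std::isfinite(sum)) return false;
        L[i][i] = std::sqrt(sum);
      } else {
        L[i][j] = sum / L[j][j];
      }
    }
  }
  // invert L, then Hinv = Linv' Linv
  double Li[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  for (int i = 0; i < 3; ++i) {
    Li[i][i] = 1.0 / L[i][i];
    for (int j = 0; j < i; ++j) {
      double sum = 0.0;
      for (int k = j; k < i; ++k) sum -= L[i][k] * Li[k][j];
      Li[i][j] = sum / L[i][i];
    }
  }
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double sum = 0.0;
      for (int k = std::max(i, j); k < 3; ++k) sum += Li[k][i] * Li[k][j];
      Hinv[i][j] = sum;
    }
  return true;
}

// Fit one series; out must have room for 6 values:
// mu, phi, sigma, se_phi, converged, minus log-likelihood.
static void ar1_fit_one(const double* y, int T, double* out) {
  Ar1Stats s = ar1_stats(y, T);
  // degenerate (constant) series
  double mean = (s.y1 + s.S1) / T, varsum = 0.0;
  for (int t = 0; t < T; ++t) varsum += (y[t] - mean) * (y[t] - mean);
  if (varsum <= 0.0) {
    out[0] = NA_REAL; out[1] = NA_REAL; out[2] = NA_REAL;
    out[3] = NA_REAL; out[4] = 0.0; out[5] = NA_REAL;
    return;
  }
  const double bound = 1.0 - 1e-7;
  // coarse bracket then golden-section refine
  const int G = 201;
  int besti = 0; double bestf = R_PosInf;
  for (int i = 0; i < G; ++i) {
    double phi = -bound + (2.0 * bound) * i / (G - 1);
    double f = ar1_profile_dev(s, phi);
    if (f < bestf) { bestf = f; besti = i; }
  }
  double lo = -bound + (2.0 * bound) * std::max(0, besti - 1) / (G - 1);
  double hi = -bound + (2.0 * bound) * std::min(G - 1, besti + 1) / (G - 1);
  double phi = golden_min(s, lo, hi);
  double mu = ar1_profile_mu(s, phi);
  double sig = std::sqrt(ar1_ss(s, mu, phi) / T);
  double nll = ar1_nll_stats(s, mu, phi, sig);

  // observed information in (mu, phi, log sigma); step in phi kept inside
  // the stationary region
  double x[3] = {mu, phi, std::log(sig)};
  double h[3];
  h[0] = 1e-4 * (1.0 + std::fabs(mu));
  h[1] = std::min(1e-4 * (1.0 + std::fabs(phi)), 0.45 * (1.0 - std::fabs(phi)));
  h[2] = 1e-4 * (1.0 + std::fabs(x[2]));
  if (h[1] <= 0) h[1] = 1e-9;
  double H[3][3];
  double f0 = nll;
  for (int i = 0; i < 3; ++i) {
    double xp[3] = {x[0], x[1], x[2]}, xm[3] = {x[0], x[1], x[2]};
    xp[i] += h[i]; xm[i] -= h[i];
    double fp = ar1_nll_stats(s, xp[0], xp[1], std::exp(xp[2]));
    double fm = ar1_nll_stats(s, xm[0], xm[1], std::exp(xm[2]));
    H[i][i] = (fp - 2.0 * f0 + fm) / (h[i] * h[i]);
  }
  for (int i = 0; i < 3; ++i)
    for (int j = i + 1; j < 3; ++j) {
      double xpp[3] = {x[0], x[1], x[2]}, xpm[3] = {x[0], x[1], x[2]},
             xmp[3] = {x[0], x[1], x[2]}, xmm[3] = {x[0], x[1], x[2]};
      xpp[i] += h[i]; xpp[j] += h[j];
      xpm[i] += h[i]; xpm[j] -= h[j];
      xmp[i] -= h[i]; xmp[j] += h[j];
      xmm[i] -= h[i]; xmm[j] -= h[j];
      double v = (ar1_nll_stats(s, xpp[0], xpp[1], std::exp(xpp[2]))
                  - ar1_nll_stats(s, xpm[0], xpm[1], std::exp(xpm[2]))
                  - ar1_nll_stats(s, xmp[0], xmp[1], std::exp(xmp[2]))
                  + ar1_nll_stats(s, xmm[0], xmm[1], std::exp(xmm[2])))
        / (4.0 * h[i] * h[j]);
      H[i][j] = v; H[j][i] = v;
    }
  double Hinv[3][3];
  bool pd = invert3_pd(H, Hinv);
  double se = pd ? std::sqrt(Hinv[1][1]) : NA_REAL;
  bool conv = pd && std::fabs(phi) < 1.0 - 1e-6 && std::isfinite(se);
  out[0] = mu; out[1] = phi; out[2] = sig;
  out[3] = se; out[4] = conv ? 1.0 : 0.0; out[5] = nll;
}

// [[Rcpp::export(name = ".ar1_mle_cpp")]]
NumericVector ar1_mle_cpp(NumericVector y) {
  NumericVector out(6);
  ar1_fit_one(REAL(y), y.size(), REAL(out));
  return out;
}

// Fit every column of a T x N score matrix; rows of the result are
// (mu, phi, sigma, se_phi, converged, nll).
// [[Rcpp::export(name = ".ar1_mle_matrix_cpp")]]
NumericMatrix ar1_mle_matrix_cpp(NumericMatrix scores) {
  int T = scores.nrow(), N = scores.ncol();
  NumericMatrix out(N, 6);
  std::vector<double> buf(6);
  for (int n = 0; n < N; ++n) {
    ar1_fit_one(&scores(0, n), T, buf.data());
    for (int k = 0; k < 6; ++k) out(n, k) = buf[k];
  }
  return out;
}

// ---------------------------------------------------------------------
// MCMC helpers
// ---------------------------------------------------------------------

// Truncated-normal draw on (lo, hi) by inverse CDF, with guards for
// extreme tail locations.
static double rtnorm1(double mean, double sd, double lo, double hi) {
  double plo = R::pnorm(lo, mean, sd, 1, 0);
  double phi = R::pnorm(hi, mean, sd, 1, 0);
  double x;
  if (phi - plo < 1e-14) {
    x = mean; // numerically fully truncated; pin near nearest bound
  } else {
    double u = R::runif(plo, phi);
    x = R::qnorm(u, mean, sd, 1, 0);
  }
  double eps = 1e-9;
  if (!std::isfinite(x)) x = mean;
  if (x <= lo) x = lo + eps;
  if (x >= hi) x = hi - eps;
  return x;
}

// log density of Gamma(shape, rate) evaluated at an SD parameter
static double lgamma_sd(double s, double shape, double rate) {
  if (s <= 0) return R_NegInf;
  return R::dgamma(s, shape, 1.0 / rate, 1);
}

// log of Berger's symmetrized reference prior on (-1, 1)
static double lrefprior(double phi) {
  if (std::fabs(phi) >= 1.0) return R_NegInf;
  return -std::log(M_PI) - 0.5 * std::log1p(-phi * phi);
}

// log normalizing constant of N(mean, sd) truncated to (-1, 1)
static double ltruncZ(double mean, double sd) {
  double z = R::pnorm(1.0, mean, sd, 1, 0) - R::pnorm(-1.0, mean, sd, 1, 0);
  return std::log(std::max(z, 1e-300));
}

struct AdaptScale {
  double ls;      // log proposal SD
  void update(double acc, int iter, bool adapting) {
    if (!adapting) return;
    double gamma = std::min(0.25, 2.0 / std::sqrt((double) iter + 1.0));
    ls += gamma * (acc - 0.44);
    if (ls < -10) ls = -10;
    if (ls > 3) ls = 3;
  }
  double sd() const { return std::exp(ls); }
};

// ---------------------------------------------------------------------
// Fixed Bayesian model: one series, parameters (mu, phi, sigma_e),
// exact stationary likelihood (or conditional on y1), priors
// mu ~ N(pm, ps), sigma_e ~ Gamma(shape, rate) on the SD, phi ~ reference.
// ---------------------------------------------------------------------

static double bayf_loglik(const Ar1Stats& s, double mu, double phi,
                          double sigma, bool conditional) {
  if (std::fabs(phi) >= 1.0 || sigma <= 0) return R_NegInf;
  double omp = 1.0 - phi;
  double trans = s.S11 + phi * phi * s.S00 - 2.0 * phi * s.S01
    - 2.0 * mu * omp * s.S1 + 2.0 * mu * phi * omp * s.S0
    + (s.T - 1) * mu * mu * omp * omp;
  double ll = -(s.T - 1) * std::log(sigma)
    - trans / (2.0 * sigma * sigma);
  if (!conditional) {
    double d1 = s.y1 - mu;
    ll += -std::log(sigma) + 0.5 * std::log1p(-phi * phi)
      - (1.0 - phi * phi) * d1 * d1 / (2.0 * sigma * sigma);
  }
  return ll;
}

// [[Rcpp::export(name = ".bayf_sampler_cpp")]]
List bayf_sampler_cpp(NumericVector y, int chains, int iterations,
                      int burn_in, double mu_pm, double mu_ps,
                      double sig_shape, double sig_rate,
                      bool conditional, double fix_phi, double fix_sigma) {
  Ar1Stats s = ar1_stats(REAL(y), y.size());
  bool has_fix_phi = R_finite(fix_phi);
  bool has_fix_sig = R_finite(fix_sigma);
  int keep = iterations - burn_in;
  List out(chains);
  double ybar = (s.y1 + s.S1) / s.T;
  double ysd = 0.0;
  for (int t = 0; t < s.T; ++t) { /* recompute sd cheaply below */ }
  {
    // sample SD of the series for overdispersed inits
    double ss = s.S11 + s.y1 * s.y1 - s.T * ybar * ybar;
    // note: S11 misses y1^2 and includes all t>=2 terms
    ysd = std::sqrt(std::max(ss / std::max(s.T - 1, 1), 1e-4));
  }
  for (int ch = 0; ch < chains; ++ch) {
    double mu = ybar + R::rnorm(0.0, ysd);
    double phi = has_fix_phi ? fix_phi : R::runif(-0.8, 0.8);
    double sig = has_fix_sig ? fix_sigma : ysd * std::exp(R::rnorm(0.0, 0.5));
    AdaptScale smu = {std::log(std::max(ysd, 0.1))};
    AdaptScale sphi = {std::log(0.3)};
    AdaptScale ssig = {std::log(0.3)};
    NumericMatrix draws(keep, 3);
    for (int it = 0; it < iterations; ++it) {
      bool adapting = it < burn_in;
      // mu
      {
        double prop = mu + R::rnorm(0.0, smu.sd());
        double lp0 = bayf_loglik(s, mu, phi, sig, conditional)
          + R::dnorm(mu, mu_pm, mu_ps, 1);
        double lp1 = bayf_loglik(s, prop, phi, sig, conditional)
          + R::dnorm(prop, mu_pm, mu_ps, 1);
        double acc = std::min(1.0, std::exp(lp1 - lp0));
        if (R::runif(0, 1) < acc) mu = prop;
        smu.update(acc, it, adapting);
      }
      // phi
      if (!has_fix_phi) {
        double prop = phi + R::rnorm(0.0, sphi.sd());
        double acc = 0.0;
        if (std::fabs(prop) < 1.0) {
          double lp0 = bayf_loglik(s, mu, phi, sig, conditional)
            + lrefprior(phi);
          double lp1 = bayf_loglik(s, mu, prop, sig, conditional)
            + lrefprior(prop);
          acc = std::min(1.0, std::exp(lp1 - lp0));
          if (R::runif(0, 1) < acc) phi = prop;
        }
        sphi.update(acc, it, adapting);
      }
      // sigma_e (random walk on log scale, Jacobian included)
      if (!has_fix_sig) {
        double prop = sig * std::exp(R::rnorm(0.0, ssig.sd()));
        double lp0 = bayf_loglik(s, mu, phi, sig, conditional)
          + lgamma_sd(sig, sig_shape, sig_rate) + std::log(sig);
        double lp1 = bayf_loglik(s, mu, phi, prop, conditional)
          + lgamma_sd(prop, sig_shape, sig_rate) + std::log(prop);
        double acc = std::min(1.0, std::exp(lp1 - lp0));
        if (R::runif(0, 1) < acc) sig = prop;
        ssig.update(acc, it, adapting);
      }
      if (it >= burn_in) {
        draws(it - burn_in, 0) = mu;
        draws(it - burn_in, 1) = phi;
        draws(it - burn_in, 2) = sig;
      }
    }
    out[ch] = draws;
  }
  return out;
}

// ---------------------------------------------------------------------
// Hierarchical (random) Bayesian model. Parameters: gamma00, gamma01,
// sigma_e, sigma_u0, sigma_u1, mu_n (latent), phi_n (latent, level-2
// truncated normal on (-1, 1)). Likelihood conditions on each
// individual's first observation. Centered parameterization:
// mu_n ~ N(gamma00, sigma_u0), phi_n ~ TN(gamma01, sigma_u1; -1, 1).
// ---------------------------------------------------------------------

// [[Rcpp::export(name = ".bayr_sampler_cpp")]]
List bayr_sampler_cpp(NumericMatrix scores, int chains, int iterations,
                      int burn_in, double g00_pm, double g00_ps,
                      double se_shape, double se_rate,
                      double su0_shape, double su0_rate,
                      double su1_shape, double su1_rate) {
  int T = scores.nrow(), N = scores.ncol();
  int m = T - 1, M = N * m;
  // per-individual transition sufficient stats
  std::vector<double> a(N), b(N), A(N), B(N), Cc(N), ybar(N), r1(N);
  for (int n = 0; n < N; ++n) {
    double sa = 0, sb = 0, sA = 0, sB = 0, sC = 0, sy = 0;
    for (int t = 1; t < T; ++t) {
      double yt = scores(t, n), yl = scores(t - 1, n);
      sa += yt; sb += yl; sA += yt * yt; sB += yl * yl; sC += yt * yl;
    }
    for (int t = 0; t < T; ++t) sy += scores(t, n);
    a[n] = sa; b[n] = sb; A[n] = sA; B[n] = sB; Cc[n] = sC;
    ybar[n] = sy / T;
    // rough lag-1 correlation for inits
    double mx = sb / m, my = sa / m;
    double sxx = sB - m * mx * mx, sxy = sC - m * mx * my;
    r1[n] = (sxx > 1e-12) ? sxy / sxx : 0.0;
    if (r1[n] > 0.95) r1[n] = 0.95;
    if (r1[n] < -0.95) r1[n] = -0.95;
  }
  int keep = iterations - burn_in;
  int P = 5 + 2 * N;
  List out(chains);
  for (int ch = 0; ch < chains; ++ch) {
    // overdispersed inits
    double g00 = R::rnorm(0.0, 0.5);
    double g01 = R::runif(-0.5, 0.5);
    double se = std::exp(R::rnorm(0.0, 0.3));
    double su0 = std::exp(R::rnorm(0.0, 0.3));
    double su1 = 0.3 * std::exp(R::rnorm(0.0, 0.3));
    std::vector<double> mu(N), phi(N);
    for (int n = 0; n < N; ++n) {
      mu[n] = ybar[n] + R::rnorm(0.0, 0.25);
      phi[n] = rtnorm1(r1[n] + R::rnorm(0.0, 0.15), 1e-9, -0.99, 0.99);
    }
    AdaptScale sg01 = {std::log(0.2)}, ssu1 = {std::log(0.3)},
               ssu0 = {std::log(0.3)}, sse = {std::log(0.2)};
    NumericMatrix draws(keep, P);
    for (int it = 0; it < iterations; ++it) {
      bool adapting = it < burn_in;
      double se2 = se * se;
      // --- latent phi_n: conjugate truncated-normal given mu_n ---
      for (int n = 0; n < N; ++n) {
        double sxx = B[n] - 2.0 * mu[n] * b[n] + m * mu[n] * mu[n];
        double sxy = Cc[n] - mu[n] * a[n] - mu[n] * b[n]
          + m * mu[n] * mu[n];
        double prec = sxx / se2 + 1.0 / (su1 * su1);
        double mean = (sxy / se2 + g01 / (su1 * su1)) / prec;
        phi[n] = rtnorm1(mean, std::sqrt(1.0 / prec), -1.0, 1.0);
      }
      // --- latent mu_n: conjugate normal ---
      for (int n = 0; n < N; ++n) {
        double omp = 1.0 - phi[n];
        double prec = m * omp * omp / se2 + 1.0 / (su0 * su0);
        double mean = (omp * (a[n] - phi[n] * b[n]) / se2
                       + g00 / (su0 * su0)) / prec;
        mu[n] = R::rnorm(mean, std::sqrt(1.0 / prec));
      }
      // --- gamma00: conjugate normal ---
      {
        double summu = 0.0;
        for (int n = 0; n < N; ++n) summu += mu[n];
        double prec = N / (su0 * su0) + 1.0 / (g00_ps * g00_ps);
        double mean = (summu / (su0 * su0)
                       + g00_pm / (g00_ps * g00_ps)) / prec;
        g00 = R::rnorm(mean, std::sqrt(1.0 / prec));
      }
      // --- gamma01: random-walk Metropolis (truncation normalizer and
      //     reference prior make it non-conjugate) ---
      {
        double prop = g01 + R::rnorm(0.0, sg01.sd());
        double acc = 0.0;
        if (std::fabs(prop) < 1.0) {
          double lp0 = lrefprior(g01), lp1 = lrefprior(prop);
          double lz0 = ltruncZ(g01, su1), lz1 = ltruncZ(prop, su1);
          for (int n = 0; n < N; ++n) {
            lp0 += R::dnorm(phi[n], g01, su1, 1) - lz0;
            lp1 += R::dnorm(phi[n], prop, su1, 1) - lz1;
          }
          acc = std::min(1.0, std::exp(lp1 - lp0));
          if (R::runif(0, 1) < acc) g01 = prop;
        }
        sg01.update(acc, it, adapting);
      }
      // --- sigma_u1: random walk on log scale ---
      {
        double prop = su1 * std::exp(R::rnorm(0.0, ssu1.sd()));
        double lp0 = lgamma_sd(su1, su1_shape, su1_rate) + std::log(su1);
        double lp1 = lgamma_sd(prop, su1_shape, su1_rate) + std::log(prop);
        double lz0 = ltruncZ(g01, su1), lz1 = ltruncZ(g01, prop);
        for (int n = 0; n < N; ++n) {
          lp0 += R::dnorm(phi[n], g01, su1, 1) - lz0;
          lp1 += R::dnorm(phi[n], g01, prop, 1) - lz1;
        }
        double acc = std::min(1.0, std::exp(lp1 - lp0));
        if (R::runif(0, 1) < acc) su1 = prop;
        ssu1.update(acc, it, adapting);
      }
      // --- sigma_u0: random walk on log scale ---
      {
        double prop = su0 * std::exp(R::rnorm(0.0, ssu0.sd()));
        double lp0 = lgamma_sd(su0, su0_shape, su0_rate) + std::log(su0);
        double lp1 = lgamma_sd(prop, su0_shape, su0_rate) + std::log(prop);
        for (int n = 0; n < N; ++n) {
          lp0 += R::dnorm(mu[n], g00, su0, 1);
          lp1 += R::dnorm(mu[n], g00, prop, 1);
        }
        double acc = std::min(1.0, std::exp(lp1 - lp0));
        if (R::runif(0, 1) < acc) su0 = prop;
        ssu0.update(acc, it, adapting);
      }
      // --- sigma_e: random walk on log scale ---
      {
        double SS = 0.0;
        for (int n = 0; n < N; ++n) {
          double omp = 1.0 - phi[n];
          double q = A[n] - 2.0 * phi[n] * Cc[n] + phi[n] * phi[n] * B[n]
            - 2.0 * mu[n] * omp * (a[n] - phi[n] * b[n])
            + m * mu[n] * mu[n] * omp * omp;
          SS += q;
        }
        double prop = se * std::exp(R::rnorm(0.0, sse.sd()));
        double lp0 = -M * std::log(se) - SS / (2.0 * se * se)
          + lgamma_sd(se, se_shape, se_rate) + std::log(se);
        double lp1 = -M * std::log(prop) - SS / (2.0 * prop * prop)
          + lgamma_sd(prop, se_shape, se_rate) + std::log(prop);
        double acc = std::min(1.0, std::exp(lp1 - lp0));
        if (R::runif(0, 1) < acc) se = prop;
        sse.update(acc, it, adapting);
      }
      if (it >= burn_in) {
        int r = it - burn_in;
        draws(r, 0) = g00; draws(r, 1) = g01; draws(r, 2) = se;
        draws(r, 3) = su0; draws(r, 4) = su1;
        for (int n = 0; n < N; ++n) {
          draws(r, 5 + n) = mu[n];
          draws(r, 5 + N + n) = phi[n];
        }
      }
    }
    out[ch] = draws;
  }
  return out;
}
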