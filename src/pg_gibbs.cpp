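// Polya-Gamma data-augmentation Gibbs sampler for the hierarchical
// logistic model
//
//   y_c ~ Binomial(n_c, p_c),  logit(p_c) = theta_1 + theta_{j(c)} + alpha_c
//   theta_j ~ N(0, theta_sd),  alpha_c ~ N(0, sigma_a),
//   sigma_a ~ half-Normal(0, sigma_hyper_sd)
//
// Data are collapsed to one binomial record per cluster (all members of a
// cluster share one linear predictor).  Augmentation: omega_c ~ PG(n_c, psi_c)
// makes (theta, alpha) conditionally Gaussian (Polson, Scott & Windle 2013);
// PG(1, z) draws use Devroye's alternating-series rejection sampler; sigma_a
// is updated by slice sampling on log sigma_a.
//
// Uses R's RNG (unif_rand / norm_rand / exp_rand) so draws are reproducible
// under any RNG kind set in R, including L'Ecuyer-CMRG substreams.

#include <Rcpp.h>
using namespace Rcpp;

static const double PG_TRUNC = 0.64;  // Devroye's crossover point t

// coefficients a_n(x) of the alternating series for the Jacobi density
static inline double pg_a_coef(int n, double x) {
  double nh = n + 0.5;
  if (x > PG_TRUNC)
    return M_PI * nh * std::exp(-nh * nh * M_PI * M_PI * x * 0.5);
  double v = 2.0 / (M_PI * x);
  return M_PI * nh * v * std::sqrt(v) * std::exp(-2.0 * nh * nh / x);
}

static inline double std_norm_cdf(double x) {
  return 0.5 * std::erfc(-x * M_SQRT1_2);
}

// CDF of inverse-Gaussian(mu = 1/z, lambda = 1) at t; z >= 0 (z = 0 is Levy)
static inline double pg_pigauss(double t, double z) {
  double rt = std::sqrt(t);
  if (z <= 0.0) return 2.0 * std_norm_cdf(-1.0 / rt);
  return std_norm_cdf((t * z - 1.0) / rt) +
         std::exp(2.0 * z) * std_norm_cdf(-(t * z + 1.0) / rt);
}

// inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, t]
static double pg_rtigauss(double z, double t) {
  double mu = (z > 0.0) ? 1.0 / z : R_PosInf;
  if (mu > t) {
    // mode below t is not guaranteed; sample truncated Levy then thin by
    // the exp(-z^2 x / 2) tilt (Devroye)
    for (;;) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      double x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (z <= 0.0 || unif_rand() <= std::exp(-0.5 * z * z * x)) return x;
    }
  } else {
    // ordinary IG draws (Michael-Schucany-Haas) until one lands in (0, t]
    for (;;) {
      double y = norm_rand();
      y = y * y;
      double muy = mu * y;
      double x = mu + 0.5 * mu * (muy - std::sqrt(4.0 * muy + muy * muy));
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
      if (x <= t) return x;
    }
  }
}

// one J*(1, z) draw given precomputed proposal constants (Devroye's
// alternating-series rejection sampler); zh = |z|/2, k and ratio as below
static double pg_draw1_pre(double zh, double k, double ratio) {
  for (;;) {
    double x;
    if (unif_rand() < ratio) {
      x = PG_TRUNC + exp_rand() / k;        // exponential tail beyond t
    } else {
      x = pg_rtigauss(zh, PG_TRUNC);        // truncated IG body
    }
    double s = pg_a_coef(0, x);
    double y = unif_rand() * s;
    for (int n = 1;; ++n) {
      if (n & 1) {
        s -= pg_a_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += pg_a_coef(n, x);
        if (y > s) break;                   // reject, propose again
      }
    }
  }
}

// PG(b, z) for integer b as a sum of b PG(1, z) draws (exact); the proposal
// constants depend only on z and are shared across the b draws
static double pg_draw(int b, double z) {
  double zh = 0.5 * std::fabs(z);
  double k = M_PI * M_PI * 0.125 + 0.5 * zh * zh;
  double p = (M_PI / (2.0 * k)) * std::exp(-k * PG_TRUNC);
  double q = 2.0 * std::exp(-zh) * pg_pigauss(PG_TRUNC, zh);
  double ratio = p / (p + q);
  double s = 0.0;
  for (int i = 0; i < b; ++i) s += pg_draw1_pre(zh, k, ratio);
  return s;
}

// [[Rcpp::export(name = ".rpg_cpp")]]
NumericVector rpg_cpp(int num, int b, double z) {
  NumericVector out(num);
  for (int i = 0; i < num; ++i) out[i] = pg_draw(b, z);
  return out;
}

// in-place Cholesky solve of (small) P x = b; P overwritten
static void chol_solve(std::vector<double> &P, std::vector<double> &b, int d,
                       std::vector<double> &L) {
  // Cholesky P = L L'
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = P[i * d + j];
      for (int r = 0; r < j; ++r) s -= L[i * d + r] * L[j * d + r];
      if (i == j)
        L[i * d + i] = std::sqrt(s);
      else
        L[i * d + j] = s / L[j * d + j];
    }
  }
  // forward then back substitution, result in b
  for (int i = 0; i < d; ++i) {
    double s = b[i];
    for (int r = 0; r < i; ++r) s -= L[i * d + r] * b[r];
    b[i] = s / L[i * d + i];
  }
  for (int i = d - 1; i >= 0; --i) {
    double s = b[i];
    for (int r = i + 1; r < d; ++r) s -= L[r * d + i] * b[r];
    b[i] = s / L[i * d + i];
  }
}

// log posterior kernel of u = log(sigma_a) given (omega, theta) with the
// cluster effects integrated out: the pseudo-data residual r_c is
// N(0, 1/omega_c + sigma^2), plus half-normal prior and log-scale Jacobian
struct SigmaCollapsed {
  const double *r2;      // squared residuals (z_c - x_c'theta)^2
  const double *winv;    // 1 / omega_c
  int K;
  double hsd;
  double operator()(double u) const {
    double s2 = std::exp(2.0 * u);
    double lp = -0.5 * s2 / (hsd * hsd) + u;
    for (int c = 0; c < K; ++c) {
      double v = winv[c] + s2;
      lp += -0.5 * std::log(v) - 0.5 * r2[c] / v;
    }
    return lp;
  }
};

// stepping-out slice sampler for u = log(sigma_a) on the collapsed density
static double slice_log_sigma(double u0, const SigmaCollapsed &lp) {
  const double w = 1.0;
  double ly = lp(u0) - exp_rand();
  double L = u0 - w * unif_rand();
  double R = L + w;
  int m = 50;
  while (m-- > 0 && lp(L) > ly) L -= w;
  m = 50;
  while (m-- > 0 && lp(R) > ly) R += w;
  for (;;) {
    double u1 = L + unif_rand() * (R - L);
    if (lp(u1) > ly) return u1;
    if (u1 < u0) L = u1; else R = u1;
  }
}

// Gibbs sampler.  y, n: per-cluster successes/sizes; xidx: 0-based contrast
// index per cluster (0 = reference arm, 1..A-1 = treatment contrasts);
// A = number of arms present.  Returns draws of theta (A columns: intercept
// then contrasts), sigma_a, and optionally alpha, per chain.
// [[Rcpp::export(name = ".pg_gibbs_cpp")]]
List pg_gibbs_cpp(IntegerVector y, IntegerVector n, IntegerVector xidx, int A,
                  double theta_sd, double sigma_hyper_sd, int chains,
                  int warmup, int draws, bool store_alpha) {
  int K = y.size();
  int d = A;  // intercept + (A-1) contrasts
  std::vector<double> kappa(K);
  for (int c = 0; c < K; ++c) kappa[c] = y[c] - 0.5 * n[c];
  double theta_prec = 1.0 / (theta_sd * theta_sd);

  List theta_out(chains), sigma_out(chains), alpha_out(chains);

  for (int ch = 0; ch < chains; ++ch) {
    std::vector<double> theta(d, 0.0), alpha(K, 0.0), omega(K, 0.0);
    // dispersed initial values so chains start apart
    for (int j = 0; j < d; ++j) theta[j] = 0.5 * norm_rand();
    double u = std::log(0.5 * sigma_hyper_sd) + 0.25 * norm_rand();

    NumericMatrix th(draws, d);
    NumericVector sg(draws);
    NumericMatrix al(store_alpha ? draws : 0, store_alpha ? K : 0);

    std::vector<double> P(d * d), b(d), Lc(d * d);

    std::vector<double> winv(K), r2(K);

    for (int it = 0; it < warmup + draws; ++it) {
      // 1. omega_c ~ PG(n_c, psi_c)
      for (int c = 0; c < K; ++c) {
        double psi = theta[0] + (xidx[c] > 0 ? theta[xidx[c]] : 0.0) + alpha[c];
        omega[c] = pg_draw(n[c], psi);
      }
      // 2. sigma_a | omega, theta with alpha integrated out (slice on the
      // log scale); collapsing removes the sigma-alpha random walk
      for (int c = 0; c < K; ++c) {
        double fix = theta[0] + (xidx[c] > 0 ? theta[xidx[c]] : 0.0);
        winv[c] = 1.0 / omega[c];
        double r = kappa[c] * winv[c] - fix;
        r2[c] = r * r;
      }
      SigmaCollapsed lp{r2.data(), winv.data(), K, sigma_hyper_sd};
      u = slice_log_sigma(u, lp);
      double sigma2 = std::exp(2.0 * u);
      // 3. theta | omega, sigma (alpha integrated out):  given omega the
      // pseudo-data z_c = kappa_c / omega_c are N(x_c'theta + alpha_c,
      // 1/omega_c), so marginally N(x_c'theta, 1/omega_c + sigma2) with
      // effective weight w*_c = omega_c / (1 + omega_c * sigma2)
      std::fill(P.begin(), P.end(), 0.0);
      std::fill(b.begin(), b.end(), 0.0);
      for (int c = 0; c < K; ++c) {
        double w = omega[c] / (1.0 + omega[c] * sigma2);
        double r = kappa[c] / (1.0 + omega[c] * sigma2);
        int j = xidx[c];
        P[0] += w;
        b[0] += r;
        if (j > 0) {
          P[j * d + j] += w;
          P[j * d + 0] += w;  // lower triangle
          b[j] += r;
        }
      }
      for (int j = 0; j < d; ++j) P[j * d + j] += theta_prec;
      chol_solve(P, b, d, Lc);  // b := mean
      // draw: mean + L'^{-T} z
      std::vector<double> z(d);
      for (int j = 0; j < d; ++j) z[j] = norm_rand();
      for (int i = d - 1; i >= 0; --i) {
        double s = z[i];
        for (int r = i + 1; r < d; ++r) s -= Lc[r * d + i] * z[r];
        z[i] = s / Lc[i * d + i];
      }
      for (int j = 0; j < d; ++j) theta[j] = b[j] + z[j];
      // 4. alpha_c | omega, theta, sigma (independent scalars)
      for (int c = 0; c < K; ++c) {
        double fix = theta[0] + (xidx[c] > 0 ? theta[xidx[c]] : 0.0);
        double prec = omega[c] + 1.0 / sigma2;
        double mean = (kappa[c] - omega[c] * fix) / prec;
        alpha[c] = mean + norm_rand() / std::sqrt(prec);
      }

      if (it >= warmup) {
        int s = it - warmup;
        for (int j = 0; j < d; ++j) th(s, j) = theta[j];
        sg[s] = std::exp(u);
        if (store_alpha)
          for (int c = 0; c < K; ++c) al(s, c) = alpha[c];
      }
    }
    theta_out[ch] = th;
    sigma_out[ch] = sg;
    if (store_alpha) alpha_out[ch] = al;
  }
  return List::create(_["theta"] = theta_out, _["sigma"] = sigma_out,
                      _["alpha"] = alpha_out);
}
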