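#include <Rcpp.h>
using namespace Rcpp;

// Exact sampler for the Polya-Gamma distribution PG(1, z), by rejection from
// a two-piece proposal (truncated inverse-Gaussian body + exponential tail)
// with the alternating-series acceptance test on the Jacobi density
// (Devroye-type scheme; the standard augmentation backend for Bernoulli-logit
// Gibbs sampling).  Uses R's RNG so draws are reproducible under set.seed().

static const double TRUNC = 0.64;

// series coefficients a_n(x) of the J*(1) density expansion
static double a_coef(int n, double x) {
  double nph = n + 0.5;
  if (x > TRUNC) {
    return M_PI * nph * std::exp(-nph * nph * M_PI * M_PI * x / 2.0);
  }
  return M_PI * nph * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * nph * nph / x);
}

// CDF at t of inverse-Gaussian(mu = 1/z, lambda = 1); z = 0 is the Levy limit
static double pigauss(double t, double z) {
  double s = std::sqrt(1.0 / t);
  double a = s * (t * z - 1.0);
  double b = -s * (t * z + 1.0);
  double y = R::pnorm(a, 0.0, 1.0, 1, 0);
  if (z > 0) {
    // exp(2z) * Phi(b), computed on the log scale to dodge overflow
    y += std::exp(2.0 * z + R::pnorm(b, 0.0, 1.0, 1, 1));
  } else {
    y += R::pnorm(b, 0.0, 1.0, 1, 0);
  }
  return y;
}

// inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, t]
static double rtigauss(double z, double t) {
  double x;
  if (z == 0.0 || 1.0 / z > t) {
    // mean beyond the truncation point: sample the truncated Levy and
    // thin with the exp(-z^2 x / 2) tilt
    for (;;) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (unif_rand() <= std::exp(-0.5 * z * z * x)) return x;
    }
  }
  double mu = 1.0 / z;
  for (;;) {
    double y = norm_rand();
    y = y * y;
    double muy = mu * y;
    x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
    if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    if (x <= t) return x;
  }
}

static double rpg1(double zin) {
  double z = std::fabs(zin) * 0.5;
  double K = M_PI * M_PI / 8.0 + z * z / 2.0;
  double p = (M_PI / (2.0 * K)) * std::exp(-K * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);

  for (;;) {
    double x;
    if (unif_rand() < p / (p + q)) {
      x = TRUNC + exp_rand() / K;       // exponential tail piece
    } else {
      x = rtigauss(z, TRUNC);           // truncated inverse-Gaussian body
    }
    // alternating-series squeeze
    double s = a_coef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x / 4.0;     // accept: J*(1, z/2)/4 ~ PG(1, z)
      } else {
        s += a_coef(n, x);
        if (y > s) break;               // reject, retry proposal
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector rpg_devroye(NumericVector z) {
  R_xlen_t n = z.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!R_finite(z[i])) stop("non-finite tilt parameter in PG sampler");
    out[i] = rpg1(z[i]);
  }
  return out;
}
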