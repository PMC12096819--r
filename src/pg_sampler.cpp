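#include <Rcpp.h>

// Polya-Gamma PG(b, c) random variates.
//
// PG(1, c) uses the exact alternating-series rejection sampler of
// Devroye (2009) as specialised by Polson, Scott & Windle (2013):
// a PG(1, c) variate is J*(1, c/2) / 4 where J* is the Jacobi-type
// distribution. Integer b sums b independent PG(1, c) draws; fractional
// b falls back on the (truncated) infinite convolution-of-gammas
// representation. All randomness flows through R's RNG so set.seed()
// gives reproducible draws.

namespace {

const double TRUNC = 0.64;          // series crossover point of J*(1, z)

inline double a_coef(int n, double x) {
  const double c = n + 0.5;
  if (x <= TRUNC) {
    return M_PI * c * std::pow(2.0 / (M_PI * x), 1.5) *
           std::exp(-2.0 * c * c / x);
  }
  return M_PI * c * std::exp(-c * c * M_PI * M_PI * x / 2.0);
}

// log P(IG(mu = 1/z, lambda = 1) <= t); z = 0 gives the Levy limit.
inline double lpigauss(double t, double z) {
  const double rt = std::sqrt(1.0 / t);
  if (z <= 0.0)
    return M_LN2 + R::pnorm(-rt, 0.0, 1.0, 1, 1);
  double lp = R::pnorm(rt * (t * z - 1.0), 0.0, 1.0, 1, 1);
  double lq = 2.0 * z + R::pnorm(-rt * (t * z + 1.0), 0.0, 1.0, 1, 1);
  // log(exp(lp) + exp(lq)) stably
  double m = std::max(lp, lq);
  return m + std::log(std::exp(lp - m) + std::exp(lq - m));
}

// inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, t)
double rtinvgauss(double z, double t) {
  double x;
  if (z < 1.0 / t) {            // large-mean regime: truncated-Levy rejection
    for (;;) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (R::unif_rand() <= std::exp(-z * z * x / 2.0)) return x;
    }
  }
  const double mu = 1.0 / z;
  for (;;) {
    double y = R::norm_rand();
    y *= y;
    x = mu + 0.5 * mu * mu * y -
        0.5 * mu * std::sqrt(4.0 * mu * y + mu * mu * y * y);
    if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    if (x <= t) return x;
  }
}

// one PG(1, c) draw
double pg1_draw(double c) {
  const double z = std::fabs(c) / 2.0;
  const double K = M_PI * M_PI / 8.0 + z * z / 2.0;
  // branch masses on the log scale: both underflow for large |c|
  const double lp = std::log(M_PI / (2.0 * K)) - K * TRUNC;
  const double lq = M_LN2 - z + lpigauss(TRUNC, z);
  const double p_ratio = 1.0 / (1.0 + std::exp(lq - lp));
  for (;;) {
    double x;
    if (R::unif_rand() < p_ratio) {
      x = TRUNC + R::exp_rand() / K;
    } else {
      x = rtinvgauss(z, TRUNC);
    }
    double s = a_coef(0, x);
    const double y = R::unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x / 4.0;
      } else {
        s += a_coef(n, x);
        if (y > s) break;      // reject, restart
      }
    }
  }
}

// fractional shape: truncated convolution-of-gammas representation
double pg_gamma_series(double b, double c, int terms = 200) {
  const double zc = c / (2.0 * M_PI);
  double s = 0.0;
  for (int k = 1; k <= terms; ++k) {
    const double d = (k - 0.5) * (k - 0.5) + zc * zc;
    s += R::rgamma(b, 1.0) / d;
  }
  return s / (2.0 * M_PI * M_PI);
}

double pg_draw_one(double b, double c) {
  if (b <= 0.0) Rcpp::stop("Polya-Gamma shape 'b' must be > 0");
  if (ISNAN(c)) Rcpp::stop("Polya-Gamma tilt 'c' is NaN");
  // beyond this magnitude the draw is numerically b/(2|c|) * Exp-like;
  // clamping keeps the rejection sampler in its stable regime
  if (!R_FINITE(c) || std::fabs(c) > 1e8) c = (c > 0 ? 1e8 : -1e8);
  const double br = std::round(b);
  if (std::fabs(b - br) < 1e-12) {
    double s = 0.0;
    for (int j = 0; j < static_cast<int>(br); ++j) s += pg1_draw(c);
    return s;
  }
  return pg_gamma_series(b, c);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector pg_draw_cpp(int n, Rcpp::NumericVector b,
                                Rcpp::NumericVector c) {
  Rcpp::NumericVector out(n);
  const int nb = b.size(), nc = c.size();
  for (int i = 0; i < n; ++i)
    out[i] = pg_draw_one(b[i % nb], c[i % nc]);
  return out;
}
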