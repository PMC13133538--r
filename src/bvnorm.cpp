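#include <Rcpp.h>
using namespace Rcpp;

// Standard-normal CDF
static inline double phid(double x) {
  return 0.5 * erfc(-x * M_SQRT1_2);
}

// Gauss-Legendre abscissae/weights (6-, 12-, 20-point rules, positive half)
static const double GL_X[3][10] = {
  {0.9324695142031522, 0.6612093864662647, 0.2386191860831970, 0, 0, 0, 0, 0, 0, 0},
  {0.9815606342467191, 0.9041172563704750, 0.7699026741943050,
   0.5873179542866171, 0.3678314989981802, 0.1252334085114692, 0, 0, 0, 0},
  {0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
   0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
   0.5108670019508271, 0.3737060887154196, 0.2277858511416451,
   0.07652652113349733}
};
static const double GL_W[3][10] = {
  {0.1713244923791704, 0.3607615730481386, 0.4679139345726910, 0, 0, 0, 0, 0, 0, 0},
  {0.04717533638651183, 0.1069393259953184, 0.1600783285433462,
   0.2031674267230659, 0.2334925365383548, 0.2491470458134028, 0, 0, 0, 0},
  {0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
   0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
   0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
   0.1527533871307259}
};

// Upper-right orthant probability P(X > h, Y > k), standard bivariate normal,
// correlation r.  Genz (2004) hybrid quadrature; absolute accuracy ~1e-15.
static double bvnu(double h, double k, double r) {
  if (h > 37.5 || k > 37.5) return 0.0;
  if (h < -37.5) return phid(-k);
  if (k < -37.5) return phid(-h);

  int ng;
  double ar = std::fabs(r);
  if (ar < 0.3) ng = 0; else if (ar < 0.75) ng = 1; else ng = 2;
  int lg = (ng == 0) ? 3 : (ng == 1 ? 6 : 10);

  double hk = h * k;
  double bvn = 0.0;
  if (ar < 0.925) {
    if (ar > 0) {
      double hs = (h * h + k * k) / 2.0;
      double asr = std::asin(r) / 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double sn = std::sin(asr * (is * GL_X[ng][i] + 1.0));
          bvn += GL_W[ng][i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
        }
      }
      bvn *= asr / (2.0 * M_PI);
    }
    bvn += phid(-h) * phid(-k);
  } else {
    if (r < 0) { k = -k; hk = -hk; }
    if (ar < 1) {
      double as = (1.0 - r) * (1.0 + r);
      double a = std::sqrt(as);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0;
      double d = (12.0 - hk) / 16.0;
      double asr = -(bs / as + hk) / 2.0;
      if (asr > -100.0)
        bvn = a * std::exp(asr) *
              (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
               c * d * as * as / 5.0);
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        double sp = std::sqrt(2.0 * M_PI) * phid(-b / a);
        bvn -= std::exp(-hk / 2.0) * sp * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a /= 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double x = a * (is * GL_X[ng][i] + 1.0);
          double xs = x * x;
          double rs = std::sqrt(1.0 - xs);
          double asr2 = -(bs / xs + hk) / 2.0;
          if (asr2 > -100.0) {
            double sp = 1.0 + c * xs * (1.0 + d * xs);
            double ep = std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs;
            bvn += a * GL_W[ng][i] * std::exp(asr2) * (ep - sp);
          }
        }
      }
      bvn = -bvn / (2.0 * M_PI);
    }
    if (r > 0) {
      bvn += phid(-std::max(h, k));
    } else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  if (bvn < 0) bvn = 0; else if (bvn > 1) bvn = 1;
  return bvn;
}

// Lower CDF P(X <= h, Y <= k)
static inline double bvn_cdf1(double h, double k, double r) {
  return bvnu(-h, -k, r);
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_bvn_cdf(NumericVector h, NumericVector k, double r) {
  R_xlen_t n = h.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = bvn_cdf1(h[i], k[i], r);
  return out;
}

// Rectangle probabilities for ordinal cells given thresholds and rho.
// tau vectors are the finite interior cut-points; +/-Inf added implicitly.
// [[Rcpp::export]]
NumericMatrix cpp_cell_probs(NumericVector tau_r, NumericVector tau_c, double rho) {
  int nr = tau_r.size() + 1, nc = tau_c.size() + 1;
  // cumulative CDF on the augmented grid
  std::vector<double> a(nr + 1), b(nc + 1);
  a[0] = -38.0; b[0] = -38.0;
  for (int i = 0; i < nr - 1; i++) a[i + 1] = tau_r[i];
  for (int j = 0; j < nc - 1; j++) b[j + 1] = tau_c[j];
  a[nr] = 38.0; b[nc] = 38.0;
  std::vector<double> F((nr + 1) * (nc + 1));
  for (int i = 0; i <= nr; i++)
    for (int j = 0; j <= nc; j++)
      F[i * (nc + 1) + j] = bvn_cdf1(a[i], b[j], rho);
  NumericMatrix P(nr, nc);
  for (int i = 0; i < nr; i++)
    for (int j = 0; j < nc; j++) {
      double p = F[(i + 1) * (nc + 1) + j + 1] - F[i * (nc + 1) + j + 1] -
                 F[(i + 1) * (nc + 1) + j] + F[i * (nc + 1) + j];
      P(i, j) = (p > 0) ? p : 0.0;
    }
  return P;
}

// Negative multinomial log-likelihood of a two-way table under the
// bivariate-normal model with fixed thresholds.
// [[Rcpp::export]]
double cpp_pair_nll(NumericMatrix tab, NumericVector tau_r, NumericVector tau_c,
                    double rho) {
  NumericMatrix P = cpp_cell_probs(tau_r, tau_c, rho);
  double nll = 0.0;
  for (int i = 0; i < tab.nrow(); i++)
    for (int j = 0; j < tab.ncol(); j++)
      if (tab(i, j) > 0) {
        double p = P(i, j);
        if (p < 1e-300) p = 1e-300;
        nll -= tab(i, j) * std::log(p);
      }
  return nll;
}
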