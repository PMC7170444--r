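// Numerical core for liability-threshold twin likelihoods.
//
// - phid / bvn: standard and bivariate normal CDFs (Drezner-Wesolowsky with
//   Genz's refinements; absolute error ~1e-15).
// - tvn: trivariate normal CDF by conditioning on the last variable and
//   Gauss-Legendre integration in probability scale.
// - pair_pattern_probs: all 2^(2k) joint response-pattern probabilities for a
//   twin pair, exploiting the biometrical structure: conditional on the
//   family-shared factors (cross-twin covariance Sx = W W') the two twins are
//   independent; the residual within-twin covariance Su = Sw - Sx is split
//   into <=2 common factors plus a diagonal, so the innermost terms are
//   products of univariate normal CDFs. Deterministic Gauss-Hermite grids.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double TWOPI = 6.283185307179586476925287;

static inline double phid(double x) {
  return 0.5 * std::erfc(-x * 0.7071067811865475244);
}

// Fast normal CDF (Zelen-Severo rational approximation, |err| < 7.5e-8);
// used only in the quadrature hot loop, where node weights dominate the
// overall error budget anyway.
static inline double phif(double x) {
  double ax = std::fabs(x);
  if (ax > 37.0) return x > 0.0 ? 1.0 : 0.0;
  double t = 1.0 / (1.0 + 0.2316419 * ax);
  double poly =
      t * (0.319381530 +
           t * (-0.356563782 +
                t * (1.781477937 + t * (-1.821255978 + t * 1.330274429))));
  double tail = 0.3989422804014327 * std::exp(-0.5 * ax * ax) * poly;
  return x > 0.0 ? 1.0 - tail : tail;
}

// P(X > dh, Y > dk) for standard bivariate normal with correlation r.
// Port of the Drezner-Wesolowsky / Genz algorithm.
static double bvnd(double dh, double dk, double r) {
  static const double x6[3] = {0.9324695142031522, 0.6612093864662647,
                               0.2386191860831970};
  static const double w6[3] = {0.1713244923791705, 0.3607615730481384,
                               0.4679139345726904};
  static const double x12[6] = {0.9815606342467191, 0.9041172563704750,
                                0.7699026741943050, 0.5873179542866171,
                                0.3678314989981802, 0.1252334085114692};
  static const double w12[6] = {0.04717533638651177, 0.1069393259953183,
                                0.1600783285433464,  0.2031674267230659,
                                0.2334925365383547,  0.2491470458134029};
  static const double x20[10] = {0.9931285991850949, 0.9639719272779138,
                                 0.9122344282513259, 0.8391169718222188,
                                 0.7463319064601508, 0.6360536807265150,
                                 0.5108670019508271, 0.3737060887154196,
                                 0.2277858511416451, 0.07652652113349733};
  static const double w20[10] = {0.01761400713915212, 0.04060142980038694,
                                 0.06267204833410906, 0.08327674157670475,
                                 0.1019301198172404,  0.1181945319615184,
                                 0.1316886384491766,  0.1420961093183821,
                                 0.1491729864726037,  0.1527533871307259};
  const double *x;
  const double *w;
  int ng;
  double ar = std::fabs(r);
  if (ar < 0.3) {
    x = x6; w = w6; ng = 3;
  } else if (ar < 0.75) {
    x = x12; w = w12; ng = 6;
  } else {
    x = x20; w = w20; ng = 10;
  }
  double h = dh, k = dk, hk = h * k, bvn = 0.0;
  if (ar < 0.925) {
    double hs = (h * h + k * k) / 2.0;
    double asr = std::asin(r);
    for (int i = 0; i < ng; i++) {
      for (int is = -1; is <= 1; is += 2) {
        double sn = std::sin(asr * (is * x[i] + 1.0) / 2.0);
        bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
      }
    }
    bvn = bvn * asr / (2.0 * TWOPI) + phid(-h) * phid(-k);
  } else {
    if (r < 0.0) {
      k = -k;
      hk = -hk;
    }
    if (ar < 1.0) {
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
        double sp = std::sqrt(TWOPI) * phid(-b / a);
        bvn -= std::exp(-hk / 2.0) * sp * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a = a / 2.0;
      for (int i = 0; i < ng; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * x[i] + 1.0);
          xs = xs * xs;
          double rs = std::sqrt(1.0 - xs);
          double asr0 = -(bs / xs + hk) / 2.0;
          if (asr0 > -100.0) {
            double sp = 1.0 + c * xs * (1.0 + d * xs);
            double ep = std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs;
            bvn += a * w[i] * std::exp(asr0) * (ep - sp);
          }
        }
      }
      bvn = -bvn / TWOPI;
    }
    if (r > 0.0) {
      bvn += phid(-std::max(h, k));
    } else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  if (bvn < 0.0) bvn = 0.0;
  if (bvn > 1.0) bvn = 1.0;
  return bvn;
}

// P(X <= h, Y <= k), correlation r, handling infinite limits.
static double phi2s(double h, double k, double r) {
  if (h == R_NegInf || k == R_NegInf) return 0.0;
  if (h == R_PosInf && k == R_PosInf) return 1.0;
  if (h == R_PosInf) return phid(k);
  if (k == R_PosInf) return phid(h);
  if (r > 1.0) r = 1.0;
  if (r < -1.0) r = -1.0;
  if (r == 1.0) return phid(std::min(h, k));
  if (r == -1.0) {
    double p = phid(h) + phid(k) - 1.0;
    return p > 0.0 ? p : 0.0;
  }
  return bvnd(-h, -k, r);
}

// P(X1 <= b1, X2 <= b2, X3 <= b3) by integrating out X3 on probability scale.
static double tvn(double b1, double b2, double b3, double r12, double r13,
                  double r23, bool hi = false) {
  if (b3 == R_NegInf || b1 == R_NegInf || b2 == R_NegInf) return 0.0;
  if (b3 == R_PosInf) return phi2s(b1, b2, r12);
  if (b1 == R_PosInf) return phi2s(b2, b3, r23);
  if (b2 == R_PosInf) return phi2s(b1, b3, r13);
  double s1 = 1.0 - r13 * r13;
  double s2 = 1.0 - r23 * r23;
  s1 = s1 > 1e-14 ? std::sqrt(s1) : 1e-7;
  s2 = s2 > 1e-14 ? std::sqrt(s2) : 1e-7;
  double rc = (r12 - r13 * r23) / (s1 * s2);
  if (rc > 1.0) rc = 1.0;
  if (rc < -1.0) rc = -1.0;
  double u3 = phid(b3);
  if (u3 <= 1e-300) return 0.0;
  // paneled 24-point Gauss-Legendre on u in (0, u3), z = qnorm(u)
  static const double gx[12] = {
      0.9951872199970213, 0.9747285559713095, 0.9382745520027328,
      0.8864155270044011, 0.8200019859739029, 0.7401241915785544,
      0.6480936519369755, 0.5454214713888396, 0.4337935076260451,
      0.3150426796961634, 0.1911188674736163, 0.0640568928626056};
  static const double gw[12] = {
      0.0123412297999872, 0.0285313886289337, 0.0442774388174198,
      0.0592985849154368, 0.0733464814110803, 0.0861901615319533,
      0.0976186521041139, 0.1074442701159656, 0.1155056680537256,
      0.1216704729278034, 0.1258374563468283, 0.1279381953467522};
  static const double cuts8[9] = {0.0, 0.005, 0.05, 0.25, 0.5,
                                  0.75, 0.95, 0.995, 1.0};
  static const double cuts18[19] = {0.0,  0.001, 0.004, 0.01, 0.025, 0.05,
                                    0.1,  0.2,   0.35,  0.5,  0.65,  0.8,
                                    0.9,  0.95,  0.975, 0.99, 0.996, 0.999,
                                    1.0};
  const double *cuts = hi ? cuts18 : cuts8;
  const int nseg = hi ? 18 : 8;
  double p = 0.0;
  for (int seg = 0; seg < nseg; seg++) {
    double slo = u3 * cuts[seg], shi = u3 * cuts[seg + 1];
    double c = (shi - slo) / 2.0, mid = (shi + slo) / 2.0;
    double sum = 0.0;
    for (int i = 0; i < 12; i++) {
      for (int is = -1; is <= 1; is += 2) {
        double u = mid + is * c * gx[i];
        double z = R::qnorm(u, 0.0, 1.0, 1, 0);
        double a1 = (b1 - r13 * z) / s1;
        double a2 = (b2 - r23 * z) / s2;
        sum += gw[i] * phi2s(a1, a2, rc);
      }
    }
    p += c * sum;
  }
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

// [[Rcpp::export(name = ".phi2Cpp")]]
NumericVector phi2Cpp(NumericVector h, NumericVector k, NumericVector r) {
  int n = h.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = phi2s(h[i], k[i], r[i]);
  return out;
}

// [[Rcpp::export(name = ".phi3Cpp")]]
double phi3Cpp(double b1, double b2, double b3, double r12, double r13,
               double r23, bool hi = false) {
  return tvn(b1, b2, b3, r12, r13, r23, hi);
}

// Rectangle probabilities for all 2^k outcome patterns of one twin given
// standardized thresholds t (length k <= 3) and residual correlation matrix R.
// out[i], bit j of i set <=> variable j exceeds its threshold.
static void rect_probs_exact(const double *t, const double *R, int k,
                             double *out, bool hi = false) {
  if (k == 1) {
    double F1 = phid(t[0]);
    out[0] = F1;
    out[1] = 1.0 - F1;
  } else if (k == 2) {
    double F1 = phid(t[0]), F2 = phid(t[1]);
    double F12 = phi2s(t[0], t[1], R[1]);
    out[0] = F12;
    out[1] = F2 - F12;
    out[2] = F1 - F12;
    out[3] = 1.0 - F1 - F2 + F12;
  } else {
    double r12 = R[1], r13 = R[2], r23 = R[5];
    double F1 = phid(t[0]), F2 = phid(t[1]), F3 = phid(t[2]);
    double F12 = phi2s(t[0], t[1], r12);
    double F13 = phi2s(t[0], t[2], r13);
    double F23 = phi2s(t[1], t[2], r23);
    double F123 = tvn(t[0], t[1], t[2], r12, r13, r23, hi);
    out[0] = F123;
    out[1] = F23 - F123;
    out[2] = F13 - F123;
    out[3] = F3 - F13 - F23 + F123;
    out[4] = F12 - F123;
    out[5] = F2 - F12 - F23 + F123;
    out[6] = F1 - F12 - F13 + F123;
    out[7] = 1.0 - F1 - F2 - F3 + F12 + F13 + F23 - F123;
  }
  int K = 1 << k;
  for (int i = 0; i < K; i++)
    if (out[i] < 0.0) out[i] = 0.0;
}

// Joint pattern probabilities for a twin pair.
//
// W      k x q loadings of the family-shared factors (Sx = W W')
// V      k x r loadings of residual common factors (fast path)
// sdres  k residual standard deviations (fast path; all > 0)
// Rres   k x k residual correlation matrix (exact path)
// sres   k residual standard deviations for standardization (exact path)
// tau1/tau2 thresholds per twin (equal for same-sex pairs)
// outN (m0 x q), outW: Gauss-Hermite grid for the shared factors
// inN  (m1 x r), inW : grid for the residual common factors (fast path)
// fast  TRUE -> factor+diagonal inner representation; FALSE -> exact
//       (bi/trivariate CDF) conditional rectangles.
//
// Returns 2^(2k) probabilities; index = twin1 bits (low) + 2^k * twin2 bits,
// bit j set <=> trait j above threshold.
// [[Rcpp::export(name = ".pairPatternCpp")]]
NumericVector pairPatternCpp(NumericMatrix W, NumericMatrix V,
                             NumericVector sdres, NumericMatrix Rres,
                             NumericVector sres, NumericVector tau1,
                             NumericVector tau2, NumericMatrix outN,
                             NumericVector outW, NumericMatrix inN,
                             NumericVector inW, bool same, bool fast,
                             bool hi = false) {
  const int k = tau1.size();
  const int K = 1 << k;
  const int q = W.ncol();
  const int r = V.ncol();
  const int m0 = outW.size();
  const int m1 = inW.size();
  NumericVector out(K * K);
  std::vector<double> v1(K), v2(K), mu(k), t(k), p1(k);
  double Rloc[9];
  if (!fast)
    for (int a = 0; a < k; a++)
      for (int b = 0; b < k; b++) Rloc[a + 3 * b] = Rres(a, b);

  // inner-node shifts do not depend on the outer node: precompute
  // NUs[b][j] = (V g_b)_j / sd_j once (fast path only)
  std::vector<double> NUs;
  std::vector<double> invsd(k);
  if (fast) {
    for (int j = 0; j < k; j++) invsd[j] = 1.0 / sdres[j];
    NUs.assign((size_t)m1 * k, 0.0);
    for (int b = 0; b < m1; b++)
      for (int j = 0; j < k; j++) {
        double nu = 0.0;
        for (int s = 0; s < r; s++) nu += V(j, s) * inN(b, s);
        NUs[(size_t)b * k + j] = nu * invsd[j];
      }
  }

  for (int a = 0; a < m0; a++) {
    for (int j = 0; j < k; j++) {
      double m = 0.0;
      for (int s = 0; s < q; s++) m += W(j, s) * outN(a, s);
      mu[j] = m;
    }
    for (int twin = 0; twin < (same ? 1 : 2); twin++) {
      const NumericVector &tau = twin == 0 ? tau1 : tau2;
      std::vector<double> &v = twin == 0 ? v1 : v2;
      std::fill(v.begin(), v.end(), 0.0);
      if (fast) {
        double c0 = (tau[0] - mu[0]) * invsd[0];
        double c1 = k > 1 ? (tau[1] - mu[1]) * invsd[1] : 0.0;
        double c2 = k > 2 ? (tau[2] - mu[2]) * invsd[2] : 0.0;
        for (int b = 0; b < m1; b++) {
          double wgt = inW[b];
          const double *nus = &NUs[(size_t)b * k];
          p1[0] = 1.0 - phif(c0 - nus[0]);
          if (k > 1) p1[1] = 1.0 - phif(c1 - nus[1]);
          if (k > 2) p1[2] = 1.0 - phif(c2 - nus[2]);
          if (k == 1) {
            v[0] += wgt * (1.0 - p1[0]);
            v[1] += wgt * p1[0];
          } else if (k == 2) {
            double q0 = 1.0 - p1[0], q1 = 1.0 - p1[1];
            v[0] += wgt * q0 * q1;
            v[1] += wgt * p1[0] * q1;
            v[2] += wgt * q0 * p1[1];
            v[3] += wgt * p1[0] * p1[1];
          } else {
            double q0 = 1.0 - p1[0], q1 = 1.0 - p1[1], q2 = 1.0 - p1[2];
            double w01 = q0 * q1, w11 = p1[0] * q1, w02 = q0 * p1[1],
                   w12 = p1[0] * p1[1];
            v[0] += wgt * w01 * q2;
            v[1] += wgt * w11 * q2;
            v[2] += wgt * w02 * q2;
            v[3] += wgt * w12 * q2;
            v[4] += wgt * w01 * p1[2];
            v[5] += wgt * w11 * p1[2];
            v[6] += wgt * w02 * p1[2];
            v[7] += wgt * w12 * p1[2];
          }
        }
      } else {
        for (int j = 0; j < k; j++) t[j] = (tau[j] - mu[j]) / sres[j];
        rect_probs_exact(t.data(), Rloc, k, v.data(), hi);
      }
    }
    if (same) v2 = v1;
    double wa = outW[a];
    for (int i2 = 0; i2 < K; i2++) {
      double f = wa * v2[i2];
      if (f == 0.0) continue;
      for (int i1 = 0; i1 < K; i1++) out[i1 + K * i2] += f * v1[i1];
    }
  }
  return out;
}
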