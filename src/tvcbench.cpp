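#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Spatial-distance TVC estimates for one pair of series.
//
// `space` (T x R) supplies the amplitude vectors used for the inverse
// Euclidean distance weights (R = 2 in bivariate mode, all ROIs in
// multivariate mode); `x`, `y` are the pair being correlated. The weight
// of time point u for target t is 1 / D(t, u); the whole off-diagonal
// weight matrix is min-max scaled to [0, 1] (one global scaling, so
// relative proximity is comparable across targets), coincident points
// (D = 0) take the largest finite weight, self weights are set to 1, and
// the estimate at t is the weighted Pearson correlation of (x, y).
//
// Pass 1 finds the global min/max squared distance (monotone in the
// weight, so no sqrt needed); pass 2 accumulates the weighted raw moments
// in a single sweep per target.
// [[Rcpp::export]]
NumericVector cpp_sd_tvc(NumericMatrix space, NumericVector x,
                         NumericVector y) {
  const int T = space.nrow();
  const int R = space.ncol();
  if (x.size() != T || y.size() != T)
    stop("'x' and 'y' must match the rows of 'space'");
  NumericVector out(T);
  const double* sp = space.begin();

  // pass 1: global extremes of the squared off-diagonal distances
  double d2min = R_PosInf, d2max = 0.0;
  for (int t = 0; t < T; ++t) {
    for (int u = t + 1; u < T; ++u) {
      double d2 = 0.0;
      for (int k = 0; k < R; ++k) {
        const double diff = sp[u + k * T] - sp[t + k * T];
        d2 += diff * diff;
      }
      if (d2 > d2max) d2max = d2;
      if (d2 > 0.0 && d2 < d2min) d2min = d2;
    }
  }
  const bool allCoincident = !(d2min < R_PosInf);
  const double wmaxFinite = allCoincident ? 1.0 : 1.0 / std::sqrt(d2min);
  const double wmin = d2max > 0.0 ? 1.0 / std::sqrt(d2max) : 0.0;
  const double range = wmaxFinite - wmin;

  // pass 2: weighted raw moments per target
  for (int t = 0; t < T; ++t) {
    double sw = 0.0, swx = 0.0, swy = 0.0;
    double swxx = 0.0, swyy = 0.0, swxy = 0.0;
    for (int u = 0; u < T; ++u) {
      double w;
      if (u == t) {
        w = 1.0;
      } else if (allCoincident || range <= 0.0) {
        w = 1.0;  // every pair equidistant: uniform weights
      } else {
        double d2 = 0.0;
        for (int k = 0; k < R; ++k) {
          const double diff = sp[u + k * T] - sp[t + k * T];
          d2 += diff * diff;
        }
        const double wu = d2 > 0.0 ? 1.0 / std::sqrt(d2) : wmaxFinite;
        w = (wu - wmin) / range;
      }
      const double xu = x[u], yu = y[u];
      sw += w;
      swx += w * xu;
      swy += w * yu;
      swxx += w * xu * xu;
      swyy += w * yu * yu;
      swxy += w * xu * yu;
    }
    const double vx = sw * swxx - swx * swx;
    const double vy = sw * swyy - swy * swy;
    if (vx <= 0.0 || vy <= 0.0)
      stop("degenerate input: zero weighted variance at time point %d", t + 1);
    out[t] = (sw * swxy - swx * swy) / std::sqrt(vx * vy);
  }
  return out;
}

// Streaming WAIC for the Gaussian tracking model.
//
// Given pooled posterior draws (intercept a, slope b, noise sd sigma) and
// the observed (x, y), accumulates per-observation pointwise quantities
// without materializing the S x N log-likelihood matrix:
//   lppd_i = log mean_s p(y_i | a_s, b_s, sigma_s)   (log-sum-exp guarded)
//   p_i    = var_s log p(y_i | ...)                  (sample variance)
// and returns waic = -2 * sum(lppd_i - p_i) together with
// se = sqrt(N * var_i(-2 (lppd_i - p_i))).
// [[Rcpp::export]]
List cpp_waic(NumericVector a, NumericVector b, NumericVector sigma,
              NumericVector x, NumericVector y) {
  const int S = a.size();
  const int N = x.size();
  if (b.size() != S || sigma.size() != S)
    stop("draw vectors must share a length");
  if (y.size() != N) stop("'x' and 'y' must share a length");
  if (S < 2) stop("need at least 2 draws");

  const double LOG2PI = std::log(2.0 * M_PI);
  std::vector<double> lconst(S), inv2s2(S), ll(S);
  for (int s = 0; s < S; ++s) {
    if (sigma[s] <= 0.0) stop("all sigma draws must be positive");
    lconst[s] = -std::log(sigma[s]) - 0.5 * LOG2PI;
    inv2s2[s] = 0.5 / (sigma[s] * sigma[s]);
  }

  NumericVector lppd(N), pwaic(N);
  double waic = 0.0, sumC = 0.0, sumC2 = 0.0;
  for (int i = 0; i < N; ++i) {
    double llmax = R_NegInf, llsum = 0.0;
    for (int s = 0; s < S; ++s) {
      const double r = y[i] - a[s] - b[s] * x[i];
      const double v = lconst[s] - r * r * inv2s2[s];
      ll[s] = v;
      if (v > llmax) llmax = v;
      llsum += v;
    }
    const double llmean = llsum / S;
    double expsum = 0.0, ss = 0.0;
    for (int s = 0; s < S; ++s) {
      expsum += std::exp(ll[s] - llmax);
      const double d = ll[s] - llmean;
      ss += d * d;
    }
    lppd[i] = llmax + std::log(expsum / S);
    pwaic[i] = ss / (S - 1);
    const double c = -2.0 * (lppd[i] - pwaic[i]);
    waic += c;
    sumC += c;
    sumC2 += c * c;
  }
  const double varC = (sumC2 - sumC * sumC / N) / (N - 1);
  return List::create(_["waic"] = waic,
                      _["se"] = std::sqrt(N * varC),
                      _["lppd"] = lppd,
                      _["pWaic"] = pwaic);
}
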