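// Constrained least-squares fitting of the five encoding models.
//
// The split-half consistency protocol needs on the order of 10^5-10^6
// model fits (neurons x repeats x halves x models x restarts), so the
// objective (mid-range-normalized model pattern vs data pattern, SSE over
// grid bins) and a box-clamped Nelder-Mead polisher live here. Results are
// deterministic: all randomness (starting points) is drawn on the R side.

#include <Rcpp.h>
#include <Rmath.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// raw model values; returns false if parameters are invalid (Sigma not PD)
static bool eval_model_raw(int model_id, const double *par, int n,
                           const double *theta, const double *r,
                           const double *x, const double *y, double *out) {
  switch (model_id) {
  case 1: {
    double t0 = par[0];
    for (int i = 0; i < n; ++i) out[i] = std::cos(theta[i] - t0);
    return true;
  }
  case 2: {
    double t0 = par[0], k = par[1];
    for (int i = 0; i < n; ++i) out[i] = std::cos(theta[i] - t0) * k * r[i];
    return true;
  }
  case 3:
  case 4: {
    double t0 = par[0], s = par[1];
    // exponentially-scaled I0 keeps the normalizer finite for large sigma
    double denom = 2.0 * M_PI * Rf_bessel_i(s, 0.0, 2.0);
    for (int i = 0; i < n; ++i) {
      double v = std::exp(s * (std::cos(theta[i] - t0) - 1.0)) / denom;
      out[i] = (model_id == 4) ? v * par[2] * r[i] : v;
    }
    return true;
  }
  case 5: {
    double mx = par[0], my = par[1], sx = par[2], sy = par[3], rho = par[4];
    double a = sx * sx, d = sy * sy, b = rho * sx * sy;
    double det = a * d - b * b;
    if (det <= 0.0 || sx <= 0.0 || sy <= 0.0) return false;
    for (int i = 0; i < n; ++i) {
      double dx = x[i] - mx, dy = y[i] - my;
      double q = (d * dx * dx - 2.0 * b * dx * dy + a * dy * dy) / det;
      out[i] = std::exp(-0.5 * q);
    }
    return true;
  }
  }
  return false;
}

// SSE between the mid-range-normalized model pattern and the data pattern
static double objective(int model_id, const double *par, int n,
                        const double *theta, const double *r,
                        const double *x, const double *y,
                        const double *target, double *buf) {
  if (!eval_model_raw(model_id, par, n, theta, r, x, y, buf)) return 1e30;
  double lo = buf[0], hi = buf[0];
  for (int i = 1; i < n; ++i) {
    if (buf[i] < lo) lo = buf[i];
    if (buf[i] > hi) hi = buf[i];
  }
  double range = hi - lo;
  double sse = 0.0;
  if (range <= 0.0) {
    for (int i = 0; i < n; ++i) sse += target[i] * target[i];
    return sse;
  }
  for (int i = 0; i < n; ++i) {
    double m = (buf[i] - lo) / range - target[i];
    sse += m * m;
  }
  return sse;
}

// Nelder-Mead with parameters clamped to [lo, hi] at every evaluation
static double nelder_mead(int model_id, std::vector<double> &par,
                          const double *lo, const double *hi, int n,
                          const double *theta, const double *r,
                          const double *x, const double *y,
                          const double *target, double *buf,
                          int maxeval, double tol) {
  const int d = (int)par.size();
  const double alpha = 1.0, gamma = 2.0, beta = 0.5, delta = 0.5;
  std::vector<std::vector<double>> simplex(d + 1, par);
  std::vector<double> fv(d + 1);
  auto clamp_eval = [&](std::vector<double> &p) {
    for (int j = 0; j < d; ++j) {
      if (p[j] < lo[j]) p[j] = lo[j];
      if (p[j] > hi[j]) p[j] = hi[j];
    }
    return objective(model_id, p.data(), n, theta, r, x, y, target, buf);
  };
  for (int j = 0; j < d; ++j) {
    double step = 0.1 * (hi[j] - lo[j]);
    if (step > 1.0) step = 1.0; // sigma cap: keep the initial simplex local
    simplex[j + 1][j] += (simplex[j + 1][j] + step <= hi[j]) ? step : -step;
  }
  int neval = 0;
  for (int j = 0; j <= d; ++j) { fv[j] = clamp_eval(simplex[j]); ++neval; }
  while (neval < maxeval) {
    // order
    std::vector<int> idx(d + 1);
    for (int j = 0; j <= d; ++j) idx[j] = j;
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return fv[a] < fv[b]; });
    std::vector<std::vector<double>> s2(d + 1);
    std::vector<double> f2(d + 1);
    for (int j = 0; j <= d; ++j) { s2[j] = simplex[idx[j]]; f2[j] = fv[idx[j]]; }
    simplex = s2; fv = f2;
    if (fv[d] - fv[0] <= tol * (std::fabs(fv[0]) + tol)) break;
    std::vector<double> centroid(d, 0.0);
    for (int j = 0; j < d; ++j) {
      for (int k = 0; k < d; ++k) centroid[k] += simplex[j][k];
    }
    for (int k = 0; k < d; ++k) centroid[k] /= d;
    std::vector<double> xr(d);
    for (int k = 0; k < d; ++k) xr[k] = centroid[k] + alpha * (centroid[k] - simplex[d][k]);
    double fr = clamp_eval(xr); ++neval;
    if (fr < fv[0]) {
      std::vector<double> xe(d);
      for (int k = 0; k < d; ++k) xe[k] = centroid[k] + gamma * (centroid[k] - simplex[d][k]);
      double fe = clamp_eval(xe); ++neval;
      if (fe < fr) { simplex[d] = xe; fv[d] = fe; }
      else { simplex[d] = xr; fv[d] = fr; }
    } else if (fr < fv[d - 1]) {
      simplex[d] = xr; fv[d] = fr;
    } else {
      std::vector<double> xc(d);
      bool outside = fr < fv[d];
      const std::vector<double> &worse = outside ? xr : simplex[d];
      for (int k = 0; k < d; ++k) xc[k] = centroid[k] + beta * (worse[k] - centroid[k]);
      double fc = clamp_eval(xc); ++neval;
      if (fc < std::min(fr, fv[d])) {
        simplex[d] = xc; fv[d] = fc;
      } else { // shrink
        for (int j = 1; j <= d; ++j) {
          for (int k = 0; k < d; ++k)
            simplex[j][k] = simplex[0][k] + delta * (simplex[j][k] - simplex[0][k]);
          fv[j] = clamp_eval(simplex[j]); ++neval;
        }
      }
    }
  }
  int best = 0;
  for (int j = 1; j <= d; ++j) if (fv[j] < fv[best]) best = j;
  par = simplex[best];
  return fv[best];
}

// [[Rcpp::export]]
List fit_model_cpp(int model_id, NumericVector target, NumericVector theta,
                   NumericVector r, NumericVector x, NumericVector y,
                   NumericMatrix starts, NumericVector lower,
                   NumericVector upper, int maxeval, double tol) {
  int n = target.size();
  int d = lower.size();
  std::vector<double> buf(n);
  std::vector<double> best_par(d);
  double best_val = R_PosInf;
  for (int s = 0; s < starts.nrow(); ++s) {
    std::vector<double> par(d);
    for (int j = 0; j < d; ++j) {
      par[j] = starts(s, j);
      if (par[j] < lower[j]) par[j] = lower[j];
      if (par[j] > upper[j]) par[j] = upper[j];
    }
    double v = nelder_mead(model_id, par, lower.begin(), upper.begin(), n,
                           theta.begin(), r.begin(), x.begin(), y.begin(),
                           target.begin(), buf.data(), maxeval, tol);
    if (v < best_val) { best_val = v; best_par = par; }
  }
  return List::create(_["par"] = NumericVector(best_par.begin(), best_par.end()),
                      _["value"] = best_val);
}

// [[Rcpp::export]]
NumericVector eval_model_cpp(int model_id, NumericVector par,
                             NumericVector theta, NumericVector r,
                             NumericVector x, NumericVector y) {
  int n = std::max(theta.size(), x.size());
  NumericVector out(n);
  if (!eval_model_raw(model_id, par.begin(), n, theta.begin(), r.begin(),
                      x.begin(), y.begin(), out.begin()))
    stop("invalid parameters (Sigma not positive-definite)");
  return out;
}
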