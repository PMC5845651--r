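#include <Rcpp.h>
using namespace Rcpp;

// Distribution propagation for the pulse-based accumulator.
//
// The latent variable a evolves over maze position y (meters) with leak
// lambda, diffusion variance sigma2_a per meter, and at each tower an
// impulse of mean sign*C and variance sigma2_s*C^2 (C = adapted pulse
// magnitude). Bounds at +/-B are sticky: mass reaching them is absorbed
// into dedicated edge bins and stays. Between events the linear SDE is
// propagated exactly (decay factor exp(lambda*dy), exact accumulated
// diffusion variance); intervals are subdivided so absorption is checked
// at least every dy_max meters.
//
// The grid has n points from -B to B inclusive; points 0 and n-1 are the
// absorbing bound bins. Deposits use two-point linear interpolation
// (conserves mass and first moment); Gaussian spreads use a discretized
// kernel with subpixel-centered offsets.

static void deposit(std::vector<double>& dst, int n, double B, double dx,
                    double pos, double mass) {
  if (mass <= 0) return;
  if (pos <= -B) { dst[0] += mass; return; }
  if (pos >= B)  { dst[n - 1] += mass; return; }
  double f = (pos + B) / dx;
  int j = (int)std::floor(f);
  double r = f - j;
  if (j >= n - 1) { dst[n - 1] += mass; return; }
  dst[j] += mass * (1.0 - r);
  dst[j + 1] += mass * r;
}

// Spread interior mass by a Gaussian of mean mu and sd sigma; absorbed
// tails go to the bound bins. Bound-bin mass is untouched (sticky).
static void gauss_step(std::vector<double>& p, int n, double B, double dx,
                       double mu, double sigma, double decay) {
  std::vector<double> out(n, 0.0);
  out[0] = p[0];
  out[n - 1] = p[n - 1];
  if (sigma < 0.3 * dx) {
    // near-deterministic: pure shift (and leak contraction) by interpolation
    for (int j = 1; j < n - 1; ++j) {
      if (p[j] <= 0) continue;
      double x = -B + j * dx;
      deposit(out, n, B, dx, decay * x + mu, p[j]);
    }
  } else if (decay == 1.0) {
    // no leak: the shift is source-independent, so one kernel serves every
    // source bin (single O(n*K) convolution)
    int K = (int)std::ceil(6.0 * sigma / dx) + 1;
    if (K > n) K = n; // kernel wider than the domain: clip, tails absorb
    double f0 = mu / dx;
    int m0 = (int)std::floor(f0);
    double r = f0 - m0;
    std::vector<double> w(2 * K + 1);
    double wsum = 0.0;
    for (int k = -K; k <= K; ++k) {
      double d = (k - r) * dx;
      double v = std::exp(-0.5 * d * d / (sigma * sigma));
      w[k + K] = v;
      wsum += v;
    }
    for (int k = -K; k <= K; ++k) w[k + K] /= wsum;
    for (int j = 1; j < n - 1; ++j) {
      if (p[j] <= 0) continue;
      for (int k = -K; k <= K; ++k) {
        int t = j + m0 + k;
        double mm = p[j] * w[k + K];
        if (t <= 0) out[0] += mm;
        else if (t >= n - 1) out[n - 1] += mm;
        else out[t] += mm;
      }
    }
  } else {
    int K = (int)std::ceil(6.0 * sigma / dx) + 1;
    std::vector<double> w(2 * K + 1);
    for (int j = 1; j < n - 1; ++j) {
      if (p[j] <= 0) continue;
      double x = -B + j * dx;
      double center = decay * x + mu;          // mean after leak + impulse
      double f = (center + B) / dx;
      int c = (int)std::floor(f);
      double r = f - c;                        // subpixel offset
      double wsum = 0.0;
      for (int k = -K; k <= K; ++k) {
        double d = (k - r) * dx;
        double v = std::exp(-0.5 * d * d / (sigma * sigma));
        w[k + K] = v;
        wsum += v;
      }
      double m = p[j] / wsum;
      for (int k = -K; k <= K; ++k) {
        int t = c + k;
        double mm = m * w[k + K];
        if (mm <= 0) continue;
        if (t <= 0) out[0] += mm;
        else if (t >= n - 1) out[n - 1] += mm;
        else out[t] += mm;
      }
    }
  }
  p.swap(out);
}

// [[Rcpp::export]]
List ddm_propagate_cpp(NumericVector seg_dy, NumericVector pulse_mean,
                       NumericVector pulse_sd, double lambda,
                       double sigma2_a, double sigma2_i, double bound,
                       double bias, int n_grid) {
  int n = n_grid;
  double B = bound;
  double dx = 2.0 * B / (n - 1);
  std::vector<double> p(n, 0.0);

  // initial value ~ N(0, sigma2_i)
  if (sigma2_i < 1e-12) {
    deposit(p, n, B, dx, 0.0, 1.0);
  } else {
    double si = std::sqrt(sigma2_i);
    double wsum = 0.0;
    std::vector<double> w(n, 0.0);
    for (int j = 0; j < n; ++j) {
      double x = -B + j * dx;
      w[j] = std::exp(-0.5 * x * x / (si * si));
      wsum += w[j];
    }
    for (int j = 0; j < n; ++j) p[j] = w[j] / wsum;
  }

  int nseg = seg_dy.size();
  for (int s = 0; s < nseg; ++s) {
    double dy = seg_dy[s];
    if (dy > 0) {
      double g = std::exp(lambda * dy);
      double v = (std::fabs(lambda) < 1e-12)
        ? sigma2_a * dy
        : sigma2_a * (std::exp(2.0 * lambda * dy) - 1.0) / (2.0 * lambda);
      gauss_step(p, n, B, dx, 0.0, std::sqrt(v), g);
    }
    if (pulse_sd[s] >= 0) { // negative sd encodes "no pulse after segment"
      gauss_step(p, n, B, dx, pulse_mean[s], pulse_sd[s], 1.0);
    }
  }

  double total = 0.0;
  for (int j = 0; j < n; ++j) total += p[j];

  // P(a > bias): interior mass above the threshold (fractional bin at the
  // bias) plus the mass stuck at +B
  double pr = p[n - 1];
  for (int j = 1; j < n - 1; ++j) {
    double x = -B + j * dx;
    double frac = (x + 0.5 * dx - bias) / dx; // cell fraction above bias
    if (frac > 1.0) frac = 1.0;
    if (frac < 0.0) frac = 0.0;
    pr += p[j] * frac;
  }
  // first moment (diagnostic; exact in the noise-free limit)
  double mean = 0.0;
  for (int j = 0; j < n; ++j) mean += p[j] * (-B + j * dx);

  return List::create(_["p_right"] = pr / total,
                      _["mass"] = total,
                      _["mean"] = mean / total,
                      _["density"] = NumericVector(p.begin(), p.end()));
}

// Forward Euler Monte-Carlo simulation of the same accumulator, kept
// algorithmically independent of the propagation above so the two can
// cross-validate. Returns the fraction of paths ending right of the bias
// (sticky-bound paths count by their bound sign); no lapse applied.
// [[Rcpp::export]]
double ddm_mc_cpp(NumericVector pulse_y, NumericVector pulse_mean,
                  NumericVector pulse_sd, double y_end, double lambda,
                  double sigma2_a, double sigma2_i, double bound,
                  double bias, int n_paths, double dy) {
  RNGScope scope;
  int n_steps = (int)std::ceil(y_end / dy);
  int n_pulse = pulse_y.size();
  double sa = std::sqrt(sigma2_a * dy);
  int n_right = 0;
  for (int path = 0; path < n_paths; ++path) {
    double a = (sigma2_i > 0) ? R::rnorm(0.0, std::sqrt(sigma2_i)) : 0.0;
    bool stuck = false;
    int next_pulse = 0;
    double y = 0.0;
    for (int s = 0; s < n_steps && !stuck; ++s) {
      double y1 = std::min(y + dy, y_end);
      double h = y1 - y;
      a += lambda * a * h + ((sigma2_a > 0) ? R::rnorm(0.0, sa * std::sqrt(h / dy)) : 0.0);
      while (next_pulse < n_pulse && pulse_y[next_pulse] <= y1) {
        a += R::rnorm(pulse_mean[next_pulse], pulse_sd[next_pulse]);
        ++next_pulse;
      }
      if (a >= bound) { a = bound; stuck = true; }
      else if (a <= -bound) { a = -bound; stuck = true; }
      y = y1;
    }
    bool right = stuck ? (a > 0) : (a > bias);
    if (right) ++n_right;
  }
  return (double)n_right / n_paths;
}

// Deterministic leak remap: interior mass at x moves to decay*x via
// two-point interpolation (conserves mass and first moment; adds at most
// dx^2/4 of interpolation variance per call, negligible against the
// diffusion applied alongside it during fitting).
static void drift_remap(std::vector<double>& p, int n, double B, double dx,
                        double decay) {
  std::vector<double> out(n, 0.0);
  out[0] = p[0];
  out[n - 1] = p[n - 1];
  for (int j = 1; j < n - 1; ++j) {
    if (p[j] <= 0) continue;
    deposit(out, n, B, dx, decay * (-B + j * dx), p[j]);
  }
  p.swap(out);
}

// Propagate one trial from a raw pulse schedule (positions in meters,
// sorted), subdividing inter-pulse gaps so absorption is checked at least
// every dy_max; returns P(a > bias) including sticky-bound mass. The
// drift is applied by interpolation and the diffusion by one shared
// kernel per interval (O(n K) per step), the speed-oriented counterpart
// of the per-source exact kernels in ddm_propagate_cpp.
static double propagate_trial(const double* pos, const double* pmean,
                              const double* psd, int npulse, double y_end,
                              double dy_max, double lambda, double sigma2_a,
                              double sigma2_i, double bound, double bias,
                              int n) {
  double B = bound;
  double dx = 2.0 * B / (n - 1);
  std::vector<double> p(n, 0.0);
  if (sigma2_i < 1e-12) {
    deposit(p, n, B, dx, 0.0, 1.0);
  } else {
    double si = std::sqrt(sigma2_i);
    double wsum = 0.0;
    for (int j = 0; j < n; ++j) {
      double x = -B + j * dx;
      p[j] = std::exp(-0.5 * x * x / (si * si));
      wsum += p[j];
    }
    for (int j = 0; j < n; ++j) p[j] /= wsum;
  }
  double y = 0.0;
  auto advance = [&](double gap) {
    if (gap <= 0) return;
    int k = (int)std::ceil(gap / dy_max);
    double h = gap / k;
    double g = std::exp(lambda * h);
    double v = (std::fabs(lambda) < 1e-12)
      ? sigma2_a * h
      : sigma2_a * (std::exp(2.0 * lambda * h) - 1.0) / (2.0 * lambda);
    for (int s = 0; s < k; ++s) {
      if (g != 1.0) drift_remap(p, n, B, dx, g);
      gauss_step(p, n, B, dx, 0.0, std::sqrt(v), 1.0);
    }
  };
  for (int i = 0; i < npulse; ++i) {
    advance(pos[i] - y);
    y = pos[i];
    gauss_step(p, n, B, dx, pmean[i], psd[i], 1.0);
  }
  advance(y_end - y);
  double total = 0.0, pr = p[n - 1];
  for (int j = 0; j < n; ++j) total += p[j];
  for (int j = 1; j < n - 1; ++j) {
    double x = -B + j * dx;
    double frac = (x + 0.5 * dx - bias) / dx;
    if (frac > 1.0) frac = 1.0;
    if (frac < 0.0) frac = 0.0;
    pr += p[j] * frac;
  }
  return pr / total;
}

// Bernoulli log-likelihood over many trials; pulse positions and signs
// are concatenated with offsets (length n_trials + 1). Adaptation (shared
// across streams: magnitude C starts at 1, each pulse is delivered at C
// then C *= phi, recovering toward 1 with constant tau_phi) is computed
// here so the schedule can be prebuilt once per dataset.
// [[Rcpp::export]]
double ddm_loglik_cpp(NumericVector pos, NumericVector sgn,
                      IntegerVector offset, IntegerVector choice_right,
                      double y_end, double dy_max, double lambda,
                      double sigma2_a, double sigma2_s, double sigma2_i,
                      double bound, double phi, double tau_phi, double bias,
                      double lapse, int n_grid) {
  int ntr = choice_right.size();
  double ll = 0.0;
  double ss = std::sqrt(sigma2_s);
  std::vector<double> pmean, psd;
  for (int t = 0; t < ntr; ++t) {
    int a = offset[t], b = offset[t + 1];
    int np = b - a;
    pmean.assign(np, 0.0);
    psd.assign(np, 0.0);
    double C = 1.0, y_prev = (np > 0) ? pos[a] : 0.0;
    for (int i = 0; i < np; ++i) {
      double gap = pos[a + i] - y_prev;
      C = 1.0 - (1.0 - C) * std::exp(-gap / tau_phi);
      pmean[i] = sgn[a + i] * C;
      psd[i] = ss * C;
      C *= phi;
      y_prev = pos[a + i];
    }
    double pr = (np > 0)
      ? propagate_trial(&pos[0] + a, pmean.data(), psd.data(), np, y_end,
                        dy_max, lambda, sigma2_a, sigma2_i, bound, bias,
                        n_grid)
      : propagate_trial(&pos[0], pmean.data(), psd.data(), 0, y_end,
                        dy_max, lambda, sigma2_a, sigma2_i, bound, bias,
                        n_grid);
    pr = lapse / 2.0 + (1.0 - lapse) * pr;
    double p = choice_right[t] ? pr : 1.0 - pr;
    if (p < 1e-10) p = 1e-10;
    ll += std::log(p);
  }
  return ll;
}
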