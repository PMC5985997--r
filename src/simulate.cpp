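#include <Rcpp.h>
#include <queue>
#include <vector>
#include "rng.h"

using namespace Rcpp;

// Lookup table for exp(-q), q in [0, QMAX). Linear interpolation; relative
// error < 5e-5, well below the shot-noise floor of any simulated trace.
static const int EXPTAB_N = 4096;
static const double QMAX = 36.0;

struct ExpTab {
  double tab[EXPTAB_N + 1];
  ExpTab() {
    for (int i = 0; i <= EXPTAB_N; ++i)
      tab[i] = std::exp(-QMAX * (double)i / EXPTAB_N);
  }
  inline double operator()(double q) const {
    double t = q * (EXPTAB_N / QMAX);
    int i = (int)t;
    double f = t - i;
    return tab[i] + f * (tab[i + 1] - tab[i]);
  }
};
static const ExpTab exptab;

// Geometric dwell (number of steps spent in the current state before the
// next flip) for a per-step flip probability p: equivalent to flipping a
// Bernoulli(p) coin at every step.
static inline double geom_steps(Xoshiro256pp &rng, double p) {
  if (p <= 0.0) return 1e18;
  double u = rng.unif_pos();
  double k = std::floor(std::log(u) / std::log1p(-p)) + 1.0;
  return k < 1.0 ? 1.0 : k;
}

static inline double wrap_periodic(double v, double half) {
  const double span = 2.0 * half;
  while (v > half) v -= span;
  while (v < -half) v += span;
  return v;
}

// Far-field skipping: a molecule whose distance beyond the detection
// region's bounding slab on some axis exceeds SLEEP_C * sigma * sqrt(k)
// cannot reach the region within k steps (excursion probability < 1e-4 per
// event), so its k intermediate positions are irrelevant to the photon
// record and are replaced by a single exact Gaussian jump of variance
// 2*D*k*dt per axis. Q_SLEEP bounds the detection weight ignored while
// asleep (exp(-10) ~ 5e-5 of the peak).
static const double Q_SLEEP = 10.0;
static const double SLEEP_C = 4.0;
static const int K_MIN = 16;

// Brownian-dynamics photon trace through a 3D Gaussian detection profile
// exp(-2(x^2+y^2)/w^2 - 2 z^2/z0^2) in a periodic box, with two-state
// triplet blinking and Poisson photon counting per bin.
//
// sigma        : per-axis Gaussian step sd, sqrt(2 D dt) [um]
// inv_w2       : 2/w^2, inv_z2 : 2/z0^2 [um^-2]
// eps_dt       : brightness * dt (expected photons per step at profile max)
// bg_per_bin   : expected background counts per bin
// p_bd, p_db   : per-step bright->dark and dark->bright flip probabilities
// dark_frac    : stationary dark (triplet) fraction T
// tau_t_steps  : triplet relaxation time in steps (for sleep bookkeeping)
// init_pos     : optional fixed initial positions (n_mol x 3), else uniform
// [[Rcpp::export(name = ".sim_trace_cpp")]]
NumericVector sim_trace_cpp(int n_mol, double half_x, double half_y,
                            double half_z, double sigma, double inv_w2,
                            double inv_z2, double eps_dt, double bg_per_bin,
                            int n_bins, int steps_per_bin, double p_bd,
                            double p_db, double dark_frac, double tau_t_steps,
                            double seed,
                            Nullable<NumericMatrix> init_pos = R_NilValue,
                            bool allow_skip = true) {
  Xoshiro256pp rng((uint64_t)seed);
  Ziggurat zig(&rng);

  std::vector<double> x(n_mol), y(n_mol), z(n_mol);
  std::vector<unsigned char> bright(n_mol, 1);
  std::vector<double> flip(n_mol, 1e18);
  std::vector<int64_t> slept_at(n_mol, 0);

  if (init_pos.isNotNull()) {
    NumericMatrix ip(init_pos);
    if (ip.nrow() != n_mol || ip.ncol() != 3)
      stop("init_pos must be an n_mol x 3 matrix");
    for (int m = 0; m < n_mol; ++m) {
      x[m] = ip(m, 0);
      y[m] = ip(m, 1);
      z[m] = ip(m, 2);
    }
  } else {
    for (int m = 0; m < n_mol; ++m) {
      x[m] = (2.0 * rng.unif() - 1.0) * half_x;
      y[m] = (2.0 * rng.unif() - 1.0) * half_y;
      z[m] = (2.0 * rng.unif() - 1.0) * half_z;
    }
  }

  const bool blink = dark_frac > 0.0;
  if (blink) {
    for (int m = 0; m < n_mol; ++m) {
      bright[m] = rng.unif() >= dark_frac ? 1 : 0;
      flip[m] = geom_steps(rng, bright[m] ? p_bd : p_db);
    }
  }

  const bool diffuse = sigma > 0.0;
  // bounding slab of the detection region {q < Q_SLEEP} per axis
  const double bnd_x = std::sqrt(Q_SLEEP / inv_w2);
  const double bnd_z = std::sqrt(Q_SLEEP / inv_z2);
  const double sleep_min_d = SLEEP_C * sigma * std::sqrt((double)K_MIN);

  typedef std::pair<int64_t, int> WakeEvent;  // (wake step, molecule)
  std::priority_queue<WakeEvent, std::vector<WakeEvent>,
                      std::greater<WakeEvent> > wake;
  std::vector<int> act(n_mol);
  for (int m = 0; m < n_mol; ++m) act[m] = m;

  const int64_t total_steps = (int64_t)n_bins * steps_per_bin;
  int64_t step = 0;
  NumericVector counts(n_bins);

  for (int b = 0; b < n_bins; ++b) {
    double rate = 0.0;
    for (int s = 0; s < steps_per_bin; ++s, ++step) {
      // wake molecules whose exclusion guarantee has expired
      while (!wake.empty() && wake.top().first <= step) {
        int m = wake.top().second;
        wake.pop();
        // the regular update below advances the final step, so the jump
        // spans the k-1 intermediate ones
        double k = (double)(step - slept_at[m]) - 1.0;
        if (k > 0.0) {
          double sd = sigma * std::sqrt(k);
          x[m] = wrap_periodic(x[m] + sd * zig.rnorm(), half_x);
          y[m] = wrap_periodic(y[m] + sd * zig.rnorm(), half_y);
          z[m] = wrap_periodic(z[m] + sd * zig.rnorm(), half_z);
        }
        if (blink) {
          if (k >= 7.0 * tau_t_steps) {  // fully relaxed
            bright[m] = rng.unif() >= dark_frac ? 1 : 0;
            flip[m] = geom_steps(rng, bright[m] ? p_bd : p_db);
          } else {  // replay the flip sequence over k skipped steps
            double rem = k;
            while (flip[m] <= rem) {
              rem -= flip[m];
              bright[m] ^= 1;
              flip[m] = geom_steps(rng, bright[m] ? p_bd : p_db);
            }
            flip[m] -= rem;
          }
        }
        act.push_back(m);
      }

      for (size_t i = 0; i < act.size();) {
        const int m = act[i];
        if (diffuse) {
          double xm = x[m] + sigma * zig.rnorm();
          double ym = y[m] + sigma * zig.rnorm();
          double zm = z[m] + sigma * zig.rnorm();
          const double tx = 2.0 * half_x, ty = 2.0 * half_y,
                       tz = 2.0 * half_z;
          if (xm > half_x) xm -= tx; else if (xm < -half_x) xm += tx;
          if (ym > half_y) ym -= ty; else if (ym < -half_y) ym += ty;
          if (zm > half_z) zm -= tz; else if (zm < -half_z) zm += tz;
          x[m] = xm; y[m] = ym; z[m] = zm;

          double d = std::fabs(xm) - bnd_x;
          double dy = std::fabs(ym) - bnd_x;
          double dz = std::fabs(zm) - bnd_z;
          if (dy > d) d = dy;
          if (dz > d) d = dz;
          if (allow_skip && d > sleep_min_d && step + 1 < total_steps) {
            double kd = d / (SLEEP_C * sigma);
            int64_t k = (int64_t)(kd * kd);
            int64_t rem_steps = total_steps - (step + 1);
            if (k > rem_steps) k = rem_steps;
            slept_at[m] = step;
            wake.push(WakeEvent(step + k, m));
            act[i] = act.back();
            act.pop_back();
            continue;  // do not advance i; swapped-in molecule next
          }
        }
        if (blink) {
          if (--flip[m] <= 0.0) {
            bright[m] ^= 1;
            flip[m] = geom_steps(rng, bright[m] ? p_bd : p_db);
          }
          if (!bright[m]) { ++i; continue; }
        }
        double q =
            (x[m] * x[m] + y[m] * y[m]) * inv_w2 + z[m] * z[m] * inv_z2;
        if (q < QMAX) rate += exptab(q);
        ++i;
      }
    }
    counts[b] = rpois_one(rng, rate * eps_dt + bg_per_bin);
    if ((b & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}
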