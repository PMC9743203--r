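// Underdamped Langevin (BAOAB) first-passage engine with restart protocols.
// Units: length Angstrom, time ps, mass amu, energy amu*A^2/ps^2,
// kB = 0.83144626 amu*A^2/ps^2/K. RNG is R's generator (seeded from R).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KB = 0.83144626;

// form codes (kept in sync with R/potentials.R):
// 1 double_well_1d        params: k, A, sig2
// 2 entropic_two_basin_2d params: h, x0, kapL, kapR, w
// 3 modified_wolfe_quapp  params: E0, sx, sy, c22, c21, c20, c02, c11, c10, c01
// 4 harmonic              params: k   (any dimension)
// 5 linear_1d             params: slope (U = slope * x)

static double pot_energy(int form, const double* p, const double* x, int d) {
  switch (form) {
  case 1: {
    double k = p[0], A = p[1], s2 = p[2];
    return 0.5 * k * x[0] * x[0] + A * std::exp(-x[0] * x[0] / (2.0 * s2));
  }
  case 2: {
    double h = p[0], x0 = p[1], kapL = p[2], kapR = p[3], w = p[4];
    double q = x[0] / x0, vx = h * (q * q - 1.0) * (q * q - 1.0);
    double kap = kapL + (kapR - kapL) * 0.5 * (1.0 + std::tanh(x[0] / w));
    return vx + 0.5 * kap * x[1] * x[1];
  }
  case 3: {
    double E0 = p[0], u = x[0] / p[1], v = x[1] / p[2];
    double u2 = u * u, v2 = v * v;
    return E0 * (u2 * u2 + v2 * v2 + p[3] * u2 * v2 + p[4] * u2 * v + p[5] * u2 +
                 p[6] * v2 + p[7] * u * v + p[8] * u + p[9] * v);
  }
  case 4: {
    double e = 0.0;
    for (int i = 0; i < d; ++i) e += 0.5 * p[0] * x[i] * x[i];
    return e;
  }
  case 5:
    return p[0] * x[0];
  }
  return NA_REAL;
}

static void pot_force(int form, const double* p, const double* x, int d, double* f) {
  switch (form) {
  case 1: {
    double k = p[0], A = p[1], s2 = p[2];
    f[0] = -k * x[0] + (A * x[0] / s2) * std::exp(-x[0] * x[0] / (2.0 * s2));
    return;
  }
  case 2: {
    double h = p[0], x0 = p[1], kapL = p[2], kapR = p[3], w = p[4];
    double q = x[0] / x0;
    double dvx = 4.0 * h * q * (q * q - 1.0) / x0;
    double th = std::tanh(x[0] / w);
    double kap = kapL + (kapR - kapL) * 0.5 * (1.0 + th);
    double dkap = (kapR - kapL) * 0.5 * (1.0 - th * th) / w;
    f[0] = -dvx - 0.5 * dkap * x[1] * x[1];
    f[1] = -kap * x[1];
    return;
  }
  case 3: {
    double E0 = p[0], sx = p[1], sy = p[2];
    double u = x[0] / sx, v = x[1] / sy;
    double u2 = u * u, v2 = v * v;
    double wu = 4.0 * u * u2 + 2.0 * p[3] * u * v2 + 2.0 * p[4] * u * v +
                2.0 * p[5] * u + p[7] * v + p[8];
    double wv = 4.0 * v * v2 + 2.0 * p[3] * u2 * v + p[4] * u2 +
                2.0 * p[6] * v + p[7] * u + p[9];
    f[0] = -E0 * wu / sx;
    f[1] = -E0 * wv / sy;
    return;
  }
  case 4:
    for (int i = 0; i < d; ++i) f[i] = -p[0] * x[i];
    return;
  case 5:
    f[0] = -p[0];
    return;
  }
}

// [[Rcpp::export]]
NumericVector cpp_energy(int form, NumericVector params, NumericMatrix X) {
  int n = X.nrow(), d = X.ncol();
  NumericVector out(n);
  std::vector<double> x(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) x[j] = X(i, j);
    out[i] = pot_energy(form, params.begin(), x.data(), d);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_force(int form, NumericVector params, NumericMatrix X) {
  int n = X.nrow(), d = X.ncol();
  NumericMatrix out(n, d);
  std::vector<double> x(d), f(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) x[j] = X(i, j);
    pot_force(form, params.begin(), x.data(), d, f.data());
    for (int j = 0; j < d; ++j) out(i, j) = f[j];
  }
  return out;
}

static inline bool passed(const double* x, int idx, int sign, double thr) {
  return sign > 0 ? x[idx] >= thr : x[idx] <= thr;
}

// One first-passage trajectory. Per-step event order: integrate, check
// passage, then check reset; a passage and a reset in the same step count
// as passage. Resets use a pre-drawn interval, re-drawn after each reset.
// protocol: 0 none, 1 poisson (rp = rate ps^-1), 2 sharp (rp = period ps).
// [[Rcpp::export]]
List cpp_run_fpt(int form, NumericVector params, int d, NumericVector x0,
                 double init_sd, double temperature, double mass,
                 double friction, double dt, double max_steps, int protocol,
                 double rp, int crit_index, int crit_sign, double threshold,
                 int record_stride, bool allow_instant) {
  RNGScope scope;
  double kT = KB * temperature;
  double vsd = (temperature > 0.0) ? std::sqrt(kT / mass) : 0.0;
  double c1 = std::exp(-friction * dt);
  double c2 = (temperature > 0.0) ? std::sqrt((1.0 - c1 * c1) * kT / mass) : 0.0;

  std::vector<double> x(d), v(d), f(d);
  std::vector<double> rec_t, rec_x, reset_times;

  auto draw_init = [&](void) {
    for (int j = 0; j < d; ++j) {
      x[j] = x0[j] + (init_sd > 0.0 ? R::rnorm(0.0, init_sd) : 0.0);
      v[j] = vsd > 0.0 ? R::rnorm(0.0, vsd) : 0.0;
    }
  };
  auto draw_interval = [&](void) -> double {
    if (protocol == 1) return R::exp_rand() / rp;
    if (protocol == 2) return rp;
    return R_PosInf;
  };

  draw_init();
  if (passed(x.data(), crit_index, crit_sign, threshold)) {
    if (!allow_instant)
      stop("initial state already satisfies the passage criterion");
    return List::create(_["tau"] = 0.0, _["censored"] = false, _["resets"] = 0,
                        _["trajectory"] = R_NilValue,
                        _["reset_times"] = NumericVector(0));
  }

  double t = 0.0, t_last_reset = 0.0;
  double next_interval = draw_interval();
  long long resets = 0;
  bool rec = record_stride > 0;
  if (rec) {
    rec_t.push_back(0.0);
    for (int j = 0; j < d; ++j) rec_x.push_back(x[j]);
  }

  double tau = NA_REAL;
  bool censored = false;
  pot_force(form, params.begin(), x.data(), d, f.data());
  long long step = 0;
  const long long nmax = (long long)max_steps;
  for (step = 1; step <= nmax; ++step) {
    // BAOAB
    for (int j = 0; j < d; ++j) {
      v[j] += 0.5 * dt * f[j] / mass;
      x[j] += 0.5 * dt * v[j];
      v[j] = c1 * v[j] + c2 * norm_rand();
      x[j] += 0.5 * dt * v[j];
    }
    pot_force(form, params.begin(), x.data(), d, f.data());
    for (int j = 0; j < d; ++j) v[j] += 0.5 * dt * f[j] / mass;
    t = step * dt;

    bool finite = true;
    for (int j = 0; j < d; ++j)
      if (!std::isfinite(x[j]) || !std::isfinite(f[j])) finite = false;
    if (!finite)
      stop("non-finite position or force at t = %g ps (dt too large?)", t);

    if (rec && step % record_stride == 0) {
      rec_t.push_back(t);
      for (int j = 0; j < d; ++j) rec_x.push_back(x[j]);
    }
    if (passed(x.data(), crit_index, crit_sign, threshold)) {
      tau = t;
      break;
    }
    if (t - t_last_reset >= next_interval) {
      draw_init();
      pot_force(form, params.begin(), x.data(), d, f.data());
      t_last_reset = t;
      next_interval = draw_interval();
      ++resets;
      reset_times.push_back(t);
      if (rec) {
        rec_t.push_back(t);
        for (int j = 0; j < d; ++j) rec_x.push_back(x[j]);
      }
    }
    if (step % 1048576 == 0) Rcpp::checkUserInterrupt();
  }
  if (!R_finite(tau)) {
    censored = true;
    tau = nmax * dt;
  } else if (rec && ((step % record_stride) != 0)) {
    rec_t.push_back(tau);
    for (int j = 0; j < d; ++j) rec_x.push_back(x[j]);
  }

  SEXP traj = R_NilValue;
  if (rec) {
    int np = (int)rec_t.size();
    NumericMatrix tm(np, d + 1);
    for (int i = 0; i < np; ++i) {
      tm(i, 0) = rec_t[i];
      for (int j = 0; j < d; ++j) tm(i, j + 1) = rec_x[i * d + j];
    }
    traj = tm;
  }
  return List::create(_["tau"] = tau, _["censored"] = censored,
                      _["resets"] = (double)resets, _["trajectory"] = traj,
                      _["reset_times"] = wrap(reset_times));
}
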