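// Fixed-step Euler-Maruyama engine for the Langevin polarity model.
//
// State layout (8 components): A1 A2 R1 R2 B1 B2 X1 X2.
// Parameter layout (13): k_rA k_a k_ba k_B k_bB k_b k_M k_ab k_R k_bR k_r
//                        k_X k_x  (matching core_rate_names then k_X, k_x).
// The regulated rate is substituted per pole using the local X_i. After
// every update each component is floored at 0 and polar sums exceeding the
// species total are rescaled proportionally onto the bound.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <cstring>
#include <random>

using namespace Rcpp;

namespace {

// splitmix64 finalizer: decorrelates (seed, realization) keys so each
// realization gets an independent, order-independent substream.
inline uint64_t splitmix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct NormalGen {
  std::mt19937_64 gen;
  double spare;
  bool has_spare;
  explicit NormalGen(uint64_t seed) : gen(seed), spare(0), has_spare(false) {}
  inline double unif() {
    // uniform in (0, 1)
    return (static_cast<double>(gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // Marsaglia polar method; avoids libm trig for portability of the stream.
  inline double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double m = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * m;
    has_spare = true;
    return u * m;
  }
};

inline double signal_value(double t, double Xmax, double tau, double lambda) {
  if (Xmax <= 0.0) return 0.0;
  if (lambda <= 0.0) {  // step edges
    return (t >= 0.0 && t < tau) ? Xmax : 0.0;
  }
  if (t < 0.0) return 0.0;
  if (t < tau) return Xmax * (1.0 - std::exp(-lambda * t));
  return Xmax * (1.0 - std::exp(-lambda * tau)) * std::exp(-lambda * (t - tau));
}

inline double regulated(double k, double Xi, int sgn) {
  return sgn > 0 ? k * (1.0 + Xi) : std::max(0.0, k * (1.0 - Xi));
}

// Deterministic derivative d at state x.
inline void deriv(const double* x, double Xt, const double* k,
                  int target, int sgn, double* d) {
  const double Acyt = 1.0 - x[0] - x[1];
  const double Rcyt = 1.0 - x[2] - x[3];
  const double Bcyt = 1.0 - x[4] - x[5];
  const double Xcyt = Xt - x[6] - x[7];
  for (int i = 0; i < 2; ++i) {
    double kk[11];
    std::memcpy(kk, k, 11 * sizeof(double));
    if (target >= 0) kk[target] = regulated(k[target], x[6 + i], sgn);
    const double A = x[i], R = x[2 + i], B = x[4 + i], X = x[6 + i];
    const double den = kk[6] + B;
    const double sat = den > 0.0 ? kk[5] * kk[6] * B / den : 0.0;
    d[i]     = kk[0] * Acyt * R - kk[1] * A - kk[2] * A * B * B;
    d[2 + i] = Rcyt * (kk[8] + kk[9] * B) - kk[10] * R;
    d[4 + i] = Bcyt * (kk[3] + kk[4] * B) - sat - kk[7] * A * B * B;
    d[6 + i] = k[11] * Xcyt * B - k[12] * X;
  }
}

// Noise strengths f: sums of absolute fluxes, evaluated at x.
inline void fluxsum(const double* x, double Xt, const double* k,
                    int target, int sgn, double* f) {
  const double Acyt = 1.0 - x[0] - x[1];
  const double Rcyt = 1.0 - x[2] - x[3];
  const double Bcyt = 1.0 - x[4] - x[5];
  const double Xcyt = Xt - x[6] - x[7];
  for (int i = 0; i < 2; ++i) {
    double kk[11];
    std::memcpy(kk, k, 11 * sizeof(double));
    if (target >= 0) kk[target] = regulated(k[target], x[6 + i], sgn);
    const double A = x[i], R = x[2 + i], B = x[4 + i], X = x[6 + i];
    const double den = kk[6] + B;
    const double sat = den > 0.0 ? kk[5] * kk[6] * B / den : 0.0;
    f[i]     = std::fabs(kk[0] * Acyt * R) + std::fabs(kk[1] * A) +
               std::fabs(kk[2] * A * B * B);
    f[2 + i] = std::fabs(Rcyt * (kk[8] + kk[9] * B)) + std::fabs(kk[10] * R);
    f[4 + i] = std::fabs(Bcyt * (kk[3] + kk[4] * B)) + std::fabs(sat) +
               std::fabs(kk[7] * A * B * B);
    f[6 + i] = std::fabs(k[11] * Xcyt * B) + std::fabs(k[12] * X);
  }
}

inline void clip(double* x, double Xt) {
  for (int j = 0; j < 8; ++j) if (x[j] < 0.0) x[j] = 0.0;
  const double totals[4] = {1.0, 1.0, 1.0, Xt};
  for (int s = 0; s < 4; ++s) {
    const int i = 2 * s;
    const double sum = x[i] + x[i + 1];
    if (sum > totals[s]) {
      if (sum > 0.0) {
        const double scale = totals[s] / sum;
        x[i] *= scale;
        x[i + 1] *= scale;
      } else {
        x[i] = x[i + 1] = 0.0;
      }
    }
  }
}

inline void em_step(double* x, double t, double dt, const double* k,
                    int target, int sgn, double Xmax, double tau,
                    double lambda, double sqrt_dt_over_N, int white,
                    NormalGen& rng) {
  const double Xt = signal_value(t, Xmax, tau, lambda);
  double d[8], f[8];
  deriv(x, Xt, k, target, sgn, d);
  if (white) {
    const double ref[8] = {1.0 / 3, 1.0 / 3, 1.0 / 3, 1.0 / 3,
                           1.0 / 3, 1.0 / 3, Xt / 3, Xt / 3};
    fluxsum(ref, Xt, k, target, sgn, f);
  } else {
    fluxsum(x, Xt, k, target, sgn, f);
  }
  for (int j = 0; j < 8; ++j) {
    x[j] += dt * d[j] + sqrt_dt_over_N * std::sqrt(f[j]) * rng.normal();
  }
  clip(x, signal_value(t + dt, Xmax, tau, lambda));
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_em_simulate(NumericVector init, NumericVector params,
                              int target, int sgn, double Xmax, double tau,
                              double lambda, double t0, double t1, double dt,
                              double N, int seed, int white, int stride) {
  const double* k = params.begin();
  const long nsteps = lround((t1 - t0) / dt);
  const long nrec = nsteps / stride + 1;
  NumericMatrix out(nrec, 10);
  double x[8];
  for (int j = 0; j < 8; ++j) x[j] = init[j];
  NormalGen rng(splitmix64(static_cast<uint64_t>(seed)));
  const double sdn = std::sqrt(dt / N);
  long rec = 0;
  for (long step = 0; step <= nsteps; ++step) {
    const double t = t0 + step * dt;
    if (step % stride == 0) {
      out(rec, 0) = t;
      for (int j = 0; j < 8; ++j) out(rec, 1 + j) = x[j];
      out(rec, 9) = signal_value(t, Xmax, tau, lambda);
      ++rec;
    }
    if (step == nsteps) break;
    em_step(x, t, dt, k, target, sgn, Xmax, tau, lambda, sdn, white, rng);
    if ((step & 0xFFFFF) == 0xFFFFF) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Ensemble of realizations: per-realization switch-event count (sign changes
// of A1 - A2 sampled every `0.01 min`), initial sign after the signal-free
// burn-in of length t_pre (phase 1 of the protocol is itself stochastic),
// final state, and the state at time t_mark (typically the end of the
// signal). Realization r uses the substream keyed by (seed, r), so results
// are order-independent.
// [[Rcpp::export]]
List cpp_em_ensemble(NumericVector init, NumericVector params,
                     int target, int sgn, double Xmax, double tau,
                     double lambda, double t_end, double dt, double N,
                     int seed, int white, int n_real, double t_mark,
                     double t_pre) {
  const double* k = params.begin();
  const long nsteps = lround(t_end / dt);
  long estride = lround(0.01 / dt);
  if (estride < 1) estride = 1;
  long mark_step = lround(t_mark / dt);
  if (mark_step > nsteps) mark_step = nsteps;
  const long npre = t_pre > 0 ? lround(t_pre / dt) : 0;
  IntegerVector n_events(n_real), sign0(n_real);
  NumericMatrix final_states(n_real, 8), mark_states(n_real, 8);
  const double sdn = std::sqrt(dt / N);
  for (int r = 0; r < n_real; ++r) {
    uint64_t key = splitmix64(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL +
                              static_cast<uint64_t>(r) + 1ULL);
    NormalGen rng(key);
    double x[8];
    for (int j = 0; j < 8; ++j) x[j] = init[j];
    for (long step = 0; step < npre; ++step) {
      // signal-free burn-in (negative times): realizations equilibrate
      // around the polarized state before the pulse starts at t = 0
      em_step(x, -1.0, dt, k, target, sgn, 0.0, tau, -1.0, sdn, white, rng);
    }
    int events = 0;
    double diff0 = x[0] - x[1];
    int last_sign = diff0 > 0 ? 1 : (diff0 < 0 ? -1 : 0);
    sign0[r] = last_sign;
    for (long step = 0; step < nsteps; ++step) {
      const double t = step * dt;
      em_step(x, t, dt, k, target, sgn, Xmax, tau, lambda, sdn, white, rng);
      if (step + 1 == mark_step) {
        for (int j = 0; j < 8; ++j) mark_states(r, j) = x[j];
      }
      if ((step + 1) % estride == 0) {
        const double diff = x[0] - x[1];
        const int s = diff > 0 ? 1 : (diff < 0 ? -1 : 0);
        if (s != 0) {
          if (last_sign != 0 && s != last_sign) ++events;
          last_sign = s;
        }
      }
    }
    n_events[r] = events;
    for (int j = 0; j < 8; ++j) final_states(r, j) = x[j];
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["n_events"] = n_events,
                      _["sign0"] = sign0,
                      _["final"] = final_states,
                      _["at_mark"] = mark_states);
}
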