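// Discrete-time simulation of a two-accumulator rectified race.
//
// Each accumulator x is updated per step as
//   x <- max(x + v*dt + sigma*sqrt(dt)*N(0,1), 0)
// until one of them reaches the response boundary A.  Internally every
// evidence-scale parameter is divided by A so the race runs against a unit
// boundary; because rectification commutes with multiplication by a positive
// constant, trial outcomes are bit-identical for parameter sets that differ
// only by a common positive scaling of (A, S_z, v_correct, v_incorrect,
// sigma).  That makes common-random-number comparisons between free- and
// forced-excursion parameterizations exact rather than merely statistical.
//
// Randomness: one deterministic substream per trial, keyed by (seed,
// idx_offset + trial).  A trial therefore reproduces exactly no matter how
// many trials are simulated around it, which lets observation models
// (TMS sampling, epoch generation) re-run the very same trajectories.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

const double BOUND_EPS = 1e-12;  // guards FP drift at the unit boundary

// splitmix64-based per-trial generator with Box-Muller normals
struct TrialRNG {
  uint64_t s;
  bool has_spare;
  double spare;
  TrialRNG(uint64_t seed, uint64_t idx) : has_spare(false), spare(0.0) {
    s = seed ^ (0x9E3779B97F4A7C15ULL * (idx + 1ULL));
    next(); next();  // scramble away from correlated seeds
  }
  uint64_t next() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on (0,1): never exactly 0 or 1
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

struct NormalizedCell {
  double sz, vc, vi, sig;  // all divided by the boundary
  NormalizedCell(double A, double Sz, double v_c, double v_i, double sigma) {
    sz = Sz / A; vc = v_c / A; vi = v_i / A; sig = sigma / A;
  }
};

struct TrialState {
  int choice;     // 1 correct, 2 incorrect, 0 none
  int steps;      // first-crossing step index (max_steps if none)
  double ndt;     // non-decision draw (also accumulation-onset delay)
  double sc, si;  // normalized start points
};

// Runs one trial to first crossing.  If rec != nullptr, the normalized
// (xc, xi) pair after each step is stored there (rec must hold
// 2*(max_steps+1) doubles; slot 0 is the start point).
inline TrialState run_trial(TrialRNG& rng, const NormalizedCell& p,
                            double dt, int max_steps,
                            double ter, double ster,
                            double* rec = nullptr) {
  TrialState out;
  out.sc = rng.unif() * p.sz;
  out.si = rng.unif() * p.sz;
  out.ndt = ter + ster * (rng.unif() - 0.5);
  double sqdt = std::sqrt(dt);
  double xc = out.sc, xi = out.si;
  if (rec) { rec[0] = xc; rec[1] = xi; }
  out.choice = 0;
  out.steps = max_steps;
  for (int k = 1; k <= max_steps; ++k) {
    xc += p.vc * dt + p.sig * sqdt * rng.norm();
    if (xc < 0.0) xc = 0.0;
    xi += p.vi * dt + p.sig * sqdt * rng.norm();
    if (xi < 0.0) xi = 0.0;
    if (rec) { rec[2 * k] = xc; rec[2 * k + 1] = xi; }
    bool hc = xc >= 1.0 - BOUND_EPS;
    bool hi = xi >= 1.0 - BOUND_EPS;
    if (hc || hi) {
      out.steps = k;
      if (hc && hi) {
        if (xc > xi) out.choice = 1;
        else if (xi > xc) out.choice = 2;
        else out.choice = (rng.unif() < 0.5) ? 1 : 2;
      } else {
        out.choice = hc ? 1 : 2;
      }
      break;
    }
  }
  return out;
}

}  // namespace

// Batch trial simulation.  Returns per-trial choice, crossing step,
// non-decision draw and start points (start points in original units).
// [[Rcpp::export]]
DataFrame race_sim_cpp(int n, double A, double Sz, double v_c, double v_i,
                       double sigma, double ter, double ster,
                       double dt, int max_steps,
                       double seed, double idx_offset) {
  NormalizedCell p(A, Sz, v_c, v_i, sigma);
  IntegerVector choice(n), steps(n);
  NumericVector ndt(n), sc(n), si(n);
  uint64_t useed = (uint64_t)seed, uoff = (uint64_t)idx_offset;
  for (int i = 0; i < n; ++i) {
    TrialRNG rng(useed, uoff + (uint64_t)i);
    TrialState t = run_trial(rng, p, dt, max_steps, ter, ster);
    choice[i] = t.choice;
    steps[i] = t.steps;
    ndt[i] = t.ndt;
    sc[i] = t.sc * A;
    si[i] = t.si * A;
  }
  return DataFrame::create(_["choice"] = choice, _["steps"] = steps,
                           _["ndt"] = ndt, _["start_correct"] = sc,
                           _["start_incorrect"] = si);
}

// As race_sim_cpp, but additionally reads both accumulators at a per-trial
// query time (stimulus-locked).  Accumulation begins at the trial's
// non-decision draw; before that the read-out is 0.  Values are reported in
// original (unnormalized) evidence units and are capped at the state reached
// on the crossing step.
// [[Rcpp::export]]
DataFrame race_sample_cpp(int n, double A, double Sz, double v_c, double v_i,
                          double sigma, double ter, double ster,
                          double dt, int max_steps,
                          NumericVector query,
                          double seed, double idx_offset) {
  if (query.size() != n) stop("query must have one time per trial");
  NormalizedCell p(A, Sz, v_c, v_i, sigma);
  IntegerVector choice(n), steps(n);
  NumericVector ndt(n), xc_q(n), xi_q(n);
  uint64_t useed = (uint64_t)seed, uoff = (uint64_t)idx_offset;
  std::vector<double> rec(2 * (size_t)(max_steps + 1));
  for (int i = 0; i < n; ++i) {
    TrialRNG rng(useed, uoff + (uint64_t)i);
    TrialState t = run_trial(rng, p, dt, max_steps, ter, ster, rec.data());
    choice[i] = t.choice;
    steps[i] = t.steps;
    ndt[i] = t.ndt;
    double tq = query[i];
    if (NumericVector::is_na(tq) || tq < t.ndt) {
      xc_q[i] = 0.0; xi_q[i] = 0.0;
    } else {
      int k = (int)std::floor((tq - t.ndt) / dt + 1e-9);
      if (k > t.steps) k = t.steps;
      xc_q[i] = rec[2 * k] * A;
      xi_q[i] = rec[2 * k + 1] * A;
    }
  }
  return DataFrame::create(_["choice"] = choice, _["steps"] = steps,
                           _["ndt"] = ndt, _["x_correct"] = xc_q,
                           _["x_incorrect"] = xi_q);
}

// Summed-accumulator traces for ERP-style predictions.  Accumulation starts
// at te + jitter (jitter uniform of width ster), continues for tr beyond the
// crossing, and the trial's reported RT is onset + crossing + tr.  The trace
// is evaluated on a stimulus-locked grid; samples after the RT (or, for
// non-terminating trials, after the simulated horizon) are NA.
// [[Rcpp::export]]
List race_traces_cpp(int n, double A, double Sz, double v_c, double v_i,
                     double sigma, double te, double ster, double tr,
                     double dt, int max_steps, NumericVector grid,
                     double seed, double idx_offset) {
  NormalizedCell p(A, Sz, v_c, v_i, sigma);
  int G = grid.size();
  int extra = (int)std::lround(tr / dt);
  NumericMatrix tracemat(n, G);
  NumericVector rt(n);
  IntegerVector choice(n);
  uint64_t useed = (uint64_t)seed, uoff = (uint64_t)idx_offset;
  double sqdt = std::sqrt(dt);
  std::vector<double> sum((size_t)(max_steps + extra + 1));
  for (int i = 0; i < n; ++i) {
    TrialRNG rng(useed, uoff + (uint64_t)i);
    double sc = rng.unif() * p.sz;
    double si = rng.unif() * p.sz;
    double onset = te + ster * (rng.unif() - 0.5);
    double xc = sc, xi = si;
    sum[0] = xc + xi;
    int cross = max_steps, ch = 0;
    int total = max_steps;
    for (int k = 1; k <= max_steps + extra; ++k) {
      xc += p.vc * dt + p.sig * sqdt * rng.norm();
      if (xc < 0.0) xc = 0.0;
      xi += p.vi * dt + p.sig * sqdt * rng.norm();
      if (xi < 0.0) xi = 0.0;
      sum[k] = xc + xi;
      if (ch == 0) {
        bool hc = xc >= 1.0 - BOUND_EPS;
        bool hi = xi >= 1.0 - BOUND_EPS;
        if (hc || hi) {
          cross = k;
          total = k + extra;
          if (hc && hi) {
            if (xc > xi) ch = 1;
            else if (xi > xc) ch = 2;
            else ch = (rng.unif() < 0.5) ? 1 : 2;
          } else {
            ch = hc ? 1 : 2;
          }
        } else if (k == max_steps) {
          total = max_steps;
          break;
        }
      } else if (k == total) {
        break;
      }
    }
    choice[i] = ch;
    double this_rt = (ch != 0) ? onset + cross * dt + tr : NA_REAL;
    rt[i] = this_rt;
    double horizon = (ch != 0) ? this_rt : onset + max_steps * dt;
    for (int g = 0; g < G; ++g) {
      double t = grid[g];
      if (t > horizon + 1e-9) { tracemat(i, g) = NA_REAL; continue; }
      if (t < onset) { tracemat(i, g) = 0.0; continue; }
      int k = (int)std::floor((t - onset) / dt + 1e-9);
      if (k > total) k = total;
      tracemat(i, g) = sum[k] * A;
    }
  }
  return List::create(_["trace"] = tracemat, _["rt"] = rt,
                      _["choice"] = choice);
}

// Full per-step trajectories of both accumulators, for small-n diagnostic
// use (memory grows as 2 * n * max_steps).
// [[Rcpp::export]]
List race_record_cpp(int n, double A, double Sz, double v_c, double v_i,
                     double sigma, double ter, double ster,
                     double dt, int max_steps,
                     double seed, double idx_offset) {
  NormalizedCell p(A, Sz, v_c, v_i, sigma);
  NumericMatrix trace_c(n, max_steps + 1), trace_i(n, max_steps + 1);
  IntegerVector choice(n), steps(n);
  NumericVector ndt(n);
  uint64_t useed = (uint64_t)seed, uoff = (uint64_t)idx_offset;
  std::vector<double> rec(2 * (size_t)(max_steps + 1));
  for (int i = 0; i < n; ++i) {
    TrialRNG rng(useed, uoff + (uint64_t)i);
    TrialState t = run_trial(rng, p, dt, max_steps, ter, ster, rec.data());
    choice[i] = t.choice;
    steps[i] = t.steps;
    ndt[i] = t.ndt;
    for (int k = 0; k <= max_steps; ++k) {
      if (k <= t.steps) {
        trace_c(i, k) = rec[2 * k] * A;
        trace_i(i, k) = rec[2 * k + 1] * A;
      } else {
        trace_c(i, k) = NA_REAL;
        trace_i(i, k) = NA_REAL;
      }
    }
  }
  return List::create(_["trace_correct"] = trace_c,
                      _["trace_incorrect"] = trace_i,
                      _["choice"] = choice, _["steps"] = steps,
                      _["ndt"] = ndt);
}
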