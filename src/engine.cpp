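// Simulation core: leaky integrate-and-fire network with pair-based STDP,
// the reduced two-neuron system, and exact closed-walk counting.
//
// Numerical scheme: forward Euler for the membrane equation with
// Euler-Maruyama white-noise increments; synaptic input decays by the exact
// exponential factor between arrivals; spikes are detected after the voltage
// update and take effect one step later (one-step axonal latency).
//
// Randomness: one xoshiro256++ stream per neuron, seeded via splitmix64 from
// (master seed, chunk index, neuron index). All draws are state-independent
// (one normal and, for the pair model, two Poisson counts per neuron per
// step), so runs differing only in the bias share identical noise paths,
// which the bias-gain probe exploits as common random numbers.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];
  bool has_cache;
  double cache;
  Rng() : has_cache(false), cache(0.0) { s[0] = s[1] = s[2] = s[3] = 1; }
  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    has_cache = false;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // Marsaglia polar method with caching; avoids std::normal_distribution,
  // whose output is not reproducible across standard libraries.
  inline double norm() {
    if (has_cache) { has_cache = false; return cache; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s2) / s2);
    cache = v * f; has_cache = true;
    return u * f;
  }
  // Knuth's method; adequate for the per-step background intensities used
  // here (lambda of order 1 or less).
  inline int poisson(double lambda) {
    if (lambda <= 0.0) return 0;
    const double L = std::exp(-lambda);
    double p = 1.0; int k = 0;
    do { ++k; p *= unif(); } while (p > L);
    return k - 1;
  }
};

inline uint64_t stream_seed(uint64_t master, uint64_t chunk, uint64_t id) {
  uint64_t x = master * 0x9E3779B97F4A7C15ULL + chunk * 0xC2B2AE3D27D4EB4FULL + id;
  return splitmix64(x);
}

// STDP window: dt = t_post - t_pre (ms), positive when the presynaptic
// spike leads. dt >= shift falls on the potentiation branch (ties go to
// potentiation); an unshifted window evaluates to zero at dt = 0.
inline double window_val(double dtp, double a_plus, double a_minus,
                         double tau_plus, double tau_minus, double shift) {
  if (shift == 0.0 && dtp == 0.0) return 0.0;
  if (dtp >= shift) return a_plus * std::exp(-(dtp - shift) / tau_plus);
  return -a_minus * std::exp((dtp - shift) / tau_minus);
}

inline double clip01(double w, double w_max) {
  if (w < 0.0) return 0.0;
  if (w > w_max) return w_max;
  return w;
}

} // namespace

// [[Rcpp::export]]
List sim_network_cpp(int n_exc, int n_inh, NumericMatrix W_in,
                     NumericVector mu, double sigma,
                     double tau_m, double v_rest, double v_thresh,
                     double tau_s,
                     double dt, double duration_ms, double t0_ms,
                     bool plastic,
                     double a_plus, double a_minus,
                     double tau_plus, double tau_minus,
                     double shift, bool nearest, double w_max_ee,
                     double record_dt_ms, double spike_record_start_ms,
                     double seed, double chunk,
                     Nullable<List> state_in) {
  const int n = n_exc + n_inh;
  if (W_in.nrow() != n || W_in.ncol() != n) stop("weight matrix dimension mismatch");
  if (dt <= 0.0 || duration_ms <= 0.0) stop("dt and duration must be positive");
  const long nsteps = (long)std::lround(duration_ms / dt);
  const int nwin = (int)std::ceil(duration_ms / record_dt_ms - 1e-9);

  std::vector<double> W(W_in.begin(), W_in.end()); // column-major, (i,j): j -> i
  std::vector<double> V(n, v_rest), syn(n, 0.0);
  std::vector<double> xtr(n_exc, 0.0), ytr(n_exc, 0.0);
  std::vector<double> last_spk(n_exc, -1e18);
  std::vector<int> pending;

  if (state_in.isNotNull()) {
    List st(state_in);
    NumericVector sv = st["V"], ss = st["syn"], sx = st["xtr"], sy = st["ytr"],
                  sl = st["last_spk"];
    IntegerVector sp = st["pending"];
    std::copy(sv.begin(), sv.end(), V.begin());
    std::copy(ss.begin(), ss.end(), syn.begin());
    std::copy(sx.begin(), sx.end(), xtr.begin());
    std::copy(sy.begin(), sy.end(), ytr.begin());
    std::copy(sl.begin(), sl.end(), last_spk.begin());
    pending.assign(sp.begin(), sp.end());
  }

  std::vector<Rng> rng(n);
  for (int i = 0; i < n; ++i)
    rng[i].seed(stream_seed((uint64_t)seed, (uint64_t)chunk, (uint64_t)i));

  const double dec_s = std::exp(-dt / tau_s);
  const double dec_p = std::exp(-dt / tau_plus);
  const double dec_m = std::exp(-dt / tau_minus);
  const double noise_coef = (sigma / tau_m) * std::sqrt(dt);
  const bool all2all = plastic && !nearest;
  const bool nn = plastic && nearest;

  IntegerMatrix counts(n, nwin);
  NumericVector w_mean(nwin), w_var(nwin), win_end(nwin);
  std::vector<double> spike_t;
  std::vector<int> spike_id;
  std::vector<int> cur;
  std::vector<char> cur_e(n_exc, 0);

  auto ee_stats = [&](double &m, double &v2) {
    double s1 = 0.0, s2 = 0.0;
    const long cnt = (long)n_exc * (n_exc - 1);
    for (int j = 0; j < n_exc; ++j) {
      const double *col = &W[(size_t)j * n];
      for (int i = 0; i < n_exc; ++i) {
        if (i == j) continue;
        s1 += col[i]; s2 += col[i] * col[i];
      }
    }
    m = s1 / cnt;
    v2 = s2 / cnt - m * m;
  };

  int prev_win = 0;
  for (long step = 0; step < nsteps; ++step) {
    const double t_rel = (step + 1) * dt;
    const double t = t0_ms + t_rel;
    int win = (int)((step * dt) / record_dt_ms);
    if (win >= nwin) win = nwin - 1;
    if (win != prev_win) {
      ee_stats(w_mean[prev_win], w_var[prev_win]);
      win_end[prev_win] = t0_ms + (prev_win + 1) * record_dt_ms;
      prev_win = win;
    }

    for (int i = 0; i < n; ++i) syn[i] *= dec_s;
    for (size_t k = 0; k < pending.size(); ++k) {
      const int j = pending[k];
      const double sgn = (j < n_exc) ? 1.0 : -1.0;
      const double *col = &W[(size_t)j * n];
      for (int i = 0; i < n; ++i) if (i != j) syn[i] += sgn * col[i];
    }
    if (all2all) {
      for (int j = 0; j < n_exc; ++j) { xtr[j] *= dec_p; ytr[j] *= dec_m; }
    }

    cur.clear();
    for (int i = 0; i < n; ++i) {
      V[i] += (dt / tau_m) * (-(V[i] - v_rest) + mu[i] + syn[i]) +
              noise_coef * rng[i].norm();
      if (V[i] >= v_thresh) { V[i] = v_rest; cur.push_back(i); }
    }

    for (size_t k = 0; k < cur.size(); ++k) {
      const int i = cur[k];
      ++counts(i, win);
      if (t >= spike_record_start_ms) { spike_t.push_back(t); spike_id.push_back(i + 1); }
    }

    if (plastic) {
      if (nn) for (size_t k = 0; k < cur.size(); ++k)
        if (cur[k] < n_exc) cur_e[cur[k]] = 1;
      for (size_t k = 0; k < cur.size(); ++k) {
        const int i = cur[k];
        if (i >= n_exc) continue;
        if (all2all) {
          // post event: potentiate incoming E synapses by the pre traces
          for (int j = 0; j < n_exc; ++j) {
            if (j == i) continue;
            W[(size_t)j * n + i] = clip01(W[(size_t)j * n + i] + a_plus * xtr[j], w_max_ee);
          }
          // pre event: depress outgoing E synapses by the post traces
          for (int j = 0; j < n_exc; ++j) {
            if (j == i) continue;
            W[(size_t)i * n + j] = clip01(W[(size_t)i * n + j] - a_minus * ytr[j], w_max_ee);
          }
        } else { // nearest-neighbor via last-spike registers
          for (int j = 0; j < n_exc; ++j) {
            if (j == i) continue;
            if (cur_e[j]) {
              // simultaneous spikes pair at dt = 0 (handled once per
              // ordered pair: here as post = i, pre = j)
              const double dw = window_val(0.0, a_plus, a_minus, tau_plus, tau_minus, shift);
              W[(size_t)j * n + i] = clip01(W[(size_t)j * n + i] + dw, w_max_ee);
            } else if (last_spk[j] > -1e17) {
              const double dwin = window_val(t - last_spk[j], a_plus, a_minus,
                                             tau_plus, tau_minus, shift);
              W[(size_t)j * n + i] = clip01(W[(size_t)j * n + i] + dwin, w_max_ee);
              const double dwout = window_val(last_spk[j] - t, a_plus, a_minus,
                                              tau_plus, tau_minus, shift);
              W[(size_t)i * n + j] = clip01(W[(size_t)i * n + j] + dwout, w_max_ee);
            }
          }
        }
      }
      // register/trace bumps deferred so simultaneous spikes never
      // self-pair through the current step
      for (size_t k = 0; k < cur.size(); ++k) {
        const int i = cur[k];
        if (i >= n_exc) continue;
        if (all2all) { xtr[i] += 1.0; ytr[i] += 1.0; }
        else { last_spk[i] = t; cur_e[i] = 0; }
      }
    } else {
      for (size_t k = 0; k < cur.size(); ++k)
        if (cur[k] < n_exc) last_spk[cur[k]] = t;
    }

    pending = cur;
  }
  ee_stats(w_mean[prev_win], w_var[prev_win]);
  win_end[prev_win] = t0_ms + duration_ms;

  NumericMatrix W_out(n, n);
  std::copy(W.begin(), W.end(), W_out.begin());
  List state = List::create(
      _["V"] = NumericVector(V.begin(), V.end()),
      _["syn"] = NumericVector(syn.begin(), syn.end()),
      _["xtr"] = NumericVector(xtr.begin(), xtr.end()),
      _["ytr"] = NumericVector(ytr.begin(), ytr.end()),
      _["last_spk"] = NumericVector(last_spk.begin(), last_spk.end()),
      _["pending"] = IntegerVector(pending.begin(), pending.end()),
      _["t_end_ms"] = t0_ms + duration_ms);
  return List::create(
      _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
      _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
      _["counts"] = counts,
      _["win_end_ms"] = win_end,
      _["w_mean"] = w_mean,
      _["w_var"] = w_var,
      _["W"] = W_out,
      _["state"] = state);
}

// Reduced two-neuron system: both neurons excitatory, reciprocal synapses
// w12 (neuron 1 onto neuron 2) and w21, independent compound-Poisson
// excitatory/inhibitory background plus bias and optional white noise.
// Plasticity is bookkept but frozen: per-segment accumulated drift is
// returned without modifying the weights.
// [[Rcpp::export]]
List sim_pair_cpp(double w12, double w21,
                  double mu1, double mu2, double sigma,
                  double bg_rate_e, double bg_w_e,
                  double bg_rate_i, double bg_w_i,
                  double tau_m, double v_rest, double v_thresh, double tau_s,
                  double a_plus, double a_minus,
                  double tau_plus, double tau_minus,
                  double shift, bool nearest,
                  double dt, double duration_ms, double seg_ms,
                  double seed) {
  if (dt <= 0.0 || duration_ms <= 0.0) stop("dt and duration must be positive");
  const long nsteps = (long)std::lround(duration_ms / dt);
  const int nseg = (int)std::ceil(duration_ms / seg_ms - 1e-9);

  Rng rng1, rng2;
  rng1.seed(stream_seed((uint64_t)seed, 0, 1));
  rng2.seed(stream_seed((uint64_t)seed, 0, 2));

  const double dec_s = std::exp(-dt / tau_s);
  const double dec_p = std::exp(-dt / tau_plus);
  const double dec_m = std::exp(-dt / tau_minus);
  const double noise_coef = (sigma / tau_m) * std::sqrt(dt);
  const double lam_e = bg_rate_e * dt * 1e-3;
  const double lam_i = bg_rate_i * dt * 1e-3;

  double V1 = v_rest, V2 = v_rest, syn1 = 0.0, syn2 = 0.0;
  double x1 = 0.0, y1 = 0.0, x2 = 0.0, y2 = 0.0; // all-to-all traces
  double last1 = -1e18, last2 = -1e18;           // nearest-neighbor registers
  bool pend1 = false, pend2 = false;

  NumericMatrix seg(nseg, 4); // d12, d21, n1, n2
  int prev_seg = 0;
  double d12 = 0.0, d21 = 0.0;
  long c1 = 0, c2 = 0;

  for (long step = 0; step < nsteps; ++step) {
    const double t = (step + 1) * dt;
    int sg = (int)((step * dt) / seg_ms);
    if (sg >= nseg) sg = nseg - 1;
    if (sg != prev_seg) {
      seg(prev_seg, 0) = d12; seg(prev_seg, 1) = d21;
      seg(prev_seg, 2) = (double)c1; seg(prev_seg, 3) = (double)c2;
      d12 = d21 = 0.0; c1 = c2 = 0;
      prev_seg = sg;
    }

    syn1 *= dec_s; syn2 *= dec_s;
    if (pend1) syn2 += w12;
    if (pend2) syn1 += w21;
    syn1 += rng1.poisson(lam_e) * bg_w_e - rng1.poisson(lam_i) * bg_w_i;
    syn2 += rng2.poisson(lam_e) * bg_w_e - rng2.poisson(lam_i) * bg_w_i;
    x1 *= dec_p; y1 *= dec_m; x2 *= dec_p; y2 *= dec_m;

    V1 += (dt / tau_m) * (-(V1 - v_rest) + mu1 + syn1) + noise_coef * rng1.norm();
    V2 += (dt / tau_m) * (-(V2 - v_rest) + mu2 + syn2) + noise_coef * rng2.norm();
    const bool s1 = V1 >= v_thresh, s2 = V2 >= v_thresh;
    if (s1) { V1 = v_rest; ++c1; }
    if (s2) { V2 = v_rest; ++c2; }

    if (s1 || s2) {
      if (!nearest) {
        if (s2) { d12 += a_plus * x1; d21 -= a_minus * y1; }
        if (s1) { d21 += a_plus * x2; d12 -= a_minus * y2; }
      } else {
        if (s1 && s2) {
          const double dw0 = window_val(0.0, a_plus, a_minus, tau_plus, tau_minus, shift);
          d12 += dw0; d21 += dw0;
        } else if (s2 && last1 > -1e17) {
          d12 += window_val(t - last1, a_plus, a_minus, tau_plus, tau_minus, shift);
          d21 += window_val(last1 - t, a_plus, a_minus, tau_plus, tau_minus, shift);
        } else if (s1 && last2 > -1e17) {
          d21 += window_val(t - last2, a_plus, a_minus, tau_plus, tau_minus, shift);
          d12 += window_val(last2 - t, a_plus, a_minus, tau_plus, tau_minus, shift);
        }
      }
      if (s1) { x1 += 1.0; y1 += 1.0; last1 = t; }
      if (s2) { x2 += 1.0; y2 += 1.0; last2 = t; }
    }
    pend1 = s1; pend2 = s2;
  }
  seg(prev_seg, 0) = d12; seg(prev_seg, 1) = d21;
  seg(prev_seg, 2) = (double)c1; seg(prev_seg, 3) = (double)c2;

  return List::create(_["seg"] = seg, _["seg_ms"] = seg_ms);
}

// Exact closed-walk counts trace(A^L) for L = 2..max_len using 128-bit
// integer accumulation. Entries of A^(L-1) are bounded by n^(L-2) <= 500^7,
// so products stay far below the 2^127 overflow limit at supported sizes.
// [[Rcpp::export]]
NumericVector count_loops_exact_cpp(IntegerMatrix A, int max_len) {
  const int n = A.nrow();
  if (A.ncol() != n) stop("adjacency matrix must be square");
  if (max_len < 2) stop("max_len must be >= 2");
  if (std::pow((double)n, (double)(max_len - 1)) > 1e36)
    stop("requested length exceeds the exact-arithmetic guard for this size");
  typedef __int128 bigint;
  std::vector<bigint> B((size_t)n * n), C((size_t)n * n), M((size_t)n * n);
  for (size_t k = 0; k < (size_t)n * n; ++k) {
    const int a = A[k];
    if (a != 0 && a != 1) stop("adjacency entries must be 0 or 1");
    M[k] = a; B[k] = a;
  }
  NumericVector out(max_len - 1);
  for (int L = 2; L <= max_len; ++L) {
    // C = B * M  (column-major)
    std::fill(C.begin(), C.end(), (bigint)0);
    for (int j = 0; j < n; ++j) {
      const bigint *mcol = &M[(size_t)j * n];
      bigint *ccol = &C[(size_t)j * n];
      for (int k = 0; k < n; ++k) {
        const bigint m = mcol[k];
        if (m == 0) continue;
        const bigint *bcol = &B[(size_t)k * n];
        for (int i = 0; i < n; ++i) ccol[i] += bcol[i] * m;
      }
    }
    std::swap(B, C);
    bigint tr = 0;
    for (int i = 0; i < n; ++i) tr += B[(size_t)i * n + i];
    out[L - 2] = (double)tr;
  }
  return out;
}

// Single LIF neuron with compound-Poisson background and optional periodic
// synaptic kicks. Two calls differing only in kick_on share identical
// random draws (all draws are unconditional), so the paired difference of
// their spike histograms estimates the linear response to a synaptic
// perturbation with very low variance (common random numbers).
// [[Rcpp::export]]
NumericVector sim_kick_cpp(double mu, double sigma,
                           double bg_rate_e, double bg_w_e,
                           double bg_rate_i, double bg_w_i,
                           double tau_m, double v_rest, double v_thresh,
                           double tau_s,
                           double kick_w, double kick_every_ms,
                           double kick_start_ms, bool kick_on,
                           double dt, double duration_ms, double seed) {
  if (dt <= 0.0 || duration_ms <= 0.0) stop("dt and duration must be positive");
  const long nsteps = (long)std::lround(duration_ms / dt);
  Rng rng;
  rng.seed(stream_seed((uint64_t)seed, 7, 1));
  const double dec_s = std::exp(-dt / tau_s);
  const double noise_coef = (sigma / tau_m) * std::sqrt(dt);
  const double lam_e = bg_rate_e * dt * 1e-3;
  const double lam_i = bg_rate_i * dt * 1e-3;
  double V = v_rest, syn = 0.0;
  double next_kick = kick_start_ms;
  std::vector<double> spikes;
  for (long step = 0; step < nsteps; ++step) {
    const double t = (step + 1) * dt;
    syn *= dec_s;
    syn += rng.poisson(lam_e) * bg_w_e - rng.poisson(lam_i) * bg_w_i;
    if (t >= next_kick - 0.5 * dt) {
      if (kick_on) syn += kick_w;
      next_kick += kick_every_ms;
    }
    V += (dt / tau_m) * (-(V - v_rest) + mu + syn) + noise_coef * rng.norm();
    if (V >= v_thresh) { V = v_rest; spikes.push_back(t); }
  }
  return NumericVector(spikes.begin(), spikes.end());
}
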