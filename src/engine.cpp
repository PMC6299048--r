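// Time-stepping engine. Mirrors, verbatim, the per-step semantics of the
// R primitives (read ring slot -> add background impulses -> synapse
// filter -> neuron update -> plasticity + spike delivery -> trace
// increment); the R functions define the contract, this loop is the fast
// path used by simulate(). All state is double precision.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// splitmix64 counter generator: deterministic, seedable, fast.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ^ 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on (0, 1)
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

// product-of-uniforms Poisson deviate given exp(-mean)
inline int rpois_product(Rng &rng, double expneg) {
  int k = -1;
  double p = 1.0;
  do { p *= rng.unif(); ++k; } while (p >= expneg);
  return k;
}

struct Pop {
  int n;
  double v_rest, v_thresh, v_reset, r_m;
  double em;            // exp(-dt/tau_m)
  int ref_steps;
  int syn_kind;         // 0 exp, 1 alpha
  double eds, h;        // filter decay, dt/tau_syn
  double pois_expneg;   // exp(-mean/chunks), 0 if no drive
  int pois_chunks;
  double pois_w, dc;
  double trace_decay;   // exp(-dt/tau_stdp), 0 if no trace
  int d_max, mask;
  std::vector<double> v, cur, x, trace, ring, imp;
  std::vector<int> refr;
};

struct Proj {
  int type;             // 0 ragged, 1 bitmask
  int src, tgt, n_pre, n_post, max_row;
  std::vector<int> row_length, post, delay;
  std::vector<double> weight;
  const uint8_t *bits = nullptr;
  double const_w;
  int const_d;
  bool plastic = false;
  double lam_alpha, pot_scale, mu;
  std::vector<int> col_ptr, col_pos, col_pre;
};

} // namespace

// [[Rcpp::export(name = ".run_engine")]]
List run_engine(List pops_in, List projs_in, int n_steps, double dt,
                double poisson_seed, int spike_start_step, int weight_every,
                bool record_spikes) {
  const int n_pop = pops_in.size();
  std::vector<Pop> pops(n_pop);
  for (int p = 0; p < n_pop; ++p) {
    List pl = pops_in[p];
    Pop &P = pops[p];
    P.n = as<int>(pl["n"]);
    P.v_rest = as<double>(pl["v_rest"]);
    P.v_thresh = as<double>(pl["v_thresh"]);
    P.v_reset = as<double>(pl["v_reset"]);
    P.r_m = as<double>(pl["r_m"]);
    P.em = std::exp(-dt / as<double>(pl["tau_m"]));
    P.ref_steps = (int)std::lround(as<double>(pl["tau_ref"]) / dt);
    P.syn_kind = as<int>(pl["syn_kind"]);
    double tau_syn = as<double>(pl["tau_syn"]);
    P.h = dt / tau_syn;
    P.eds = std::exp(-P.h);
    double pois_mean = as<double>(pl["poisson_rate_per_step"]);
    if (pois_mean > 0) {
      P.pois_chunks = pois_mean < 10 ? 1 : (int)std::ceil(pois_mean / 5.0);
      P.pois_expneg = std::exp(-pois_mean / P.pois_chunks);
    } else {
      P.pois_chunks = 0;
      P.pois_expneg = 0;
    }
    P.pois_w = as<double>(pl["poisson_weight"]);
    P.dc = as<double>(pl["dc"]);
    double stdp_tau = as<double>(pl["stdp_tau"]);
    P.trace_decay = stdp_tau > 0 ? std::exp(-dt / stdp_tau) : 0.0;
    P.d_max = as<int>(pl["d_max"]);
    P.mask = P.d_max - 1;
    NumericVector v0 = pl["v_init"];
    P.v.assign(v0.begin(), v0.end());
    P.cur.assign(P.n, 0.0);
    P.x.assign(P.n, 0.0);
    P.trace.assign(P.n, 0.0);
    P.refr.assign(P.n, 0);
    P.ring.assign((size_t)P.d_max * P.n, 0.0);
    P.imp.assign(P.n, 0.0);
  }

  const int n_proj = projs_in.size();
  std::vector<Proj> projs(n_proj);
  std::vector<RawVector> bit_keep;   // keep SEXPs alive
  for (int q = 0; q < n_proj; ++q) {
    List jl = projs_in[q];
    Proj &J = projs[q];
    J.type = as<int>(jl["type"]);
    J.src = as<int>(jl["src"]);
    J.tgt = as<int>(jl["tgt"]);
    J.n_pre = as<int>(jl["n_pre"]);
    J.n_post = as<int>(jl["n_post"]);
    if (J.type == 0) {
      J.max_row = as<int>(jl["max_row"]);
      IntegerVector rl = jl["row_length"], po = jl["post"], de = jl["delay"];
      NumericVector we = jl["weight"];
      J.row_length.assign(rl.begin(), rl.end());
      J.post.assign(po.begin(), po.end());
      J.delay.assign(de.begin(), de.end());
      J.weight.assign(we.begin(), we.end());
    } else {
      RawVector bits = jl["bits"];
      bit_keep.push_back(bits);
      J.bits = RAW(bits);
      J.const_w = as<double>(jl["const_w"]);
      J.const_d = as<int>(jl["const_d"]);
    }
    J.plastic = as<bool>(jl["plastic"]);
    if (J.plastic) {
      double lam = as<double>(jl["lam"]), w0 = as<double>(jl["w0"]);
      J.mu = as<double>(jl["mu"]);
      J.lam_alpha = lam * as<double>(jl["alpha"]);
      J.pot_scale = lam * std::pow(w0, 1.0 - J.mu);
      IntegerVector cp = jl["col_ptr"], cs = jl["col_pos"], cr = jl["col_pre"];
      J.col_ptr.assign(cp.begin(), cp.end());
      J.col_pos.assign(cs.begin(), cs.end());
      J.col_pre.assign(cr.begin(), cr.end());
    }
  }

  Rng rng((uint64_t)poisson_seed);
  std::vector<std::vector<int>> cur_spikes(n_pop);
  std::vector<double> spike_time;
  std::vector<int> spike_id, spike_pop;

  // per-plastic-projection weight statistics over time
  std::vector<int> plastic_idx;
  for (int q = 0; q < n_proj; ++q)
    if (projs[q].plastic) plastic_idx.push_back(q);
  std::vector<std::vector<double>> wrec_t(plastic_idx.size()),
      wrec_mean(plastic_idx.size()), wrec_sd(plastic_idx.size());

  auto record_weights = [&](int t) {
    for (size_t m = 0; m < plastic_idx.size(); ++m) {
      Proj &J = projs[plastic_idx[m]];
      double s = 0, s2 = 0;
      long cnt = 0;
      for (int i = 0; i < J.n_pre; ++i) {
        const size_t base = (size_t)i * J.max_row;
        for (int k = 0; k < J.row_length[i]; ++k) {
          double w = J.weight[base + k];
          s += w; s2 += w * w; ++cnt;
        }
      }
      double mean = cnt ? s / cnt : 0.0;
      double var = cnt ? s2 / cnt - mean * mean : 0.0;
      wrec_t[m].push_back((t + 1) * dt);
      wrec_mean[m].push_back(mean);
      wrec_sd[m].push_back(std::sqrt(var > 0 ? var : 0.0));
    }
  };

  for (int t = 0; t < n_steps; ++t) {
    if ((t & 4095) == 0) Rcpp::checkUserInterrupt();
    // neuron phase per population
    for (int p = 0; p < n_pop; ++p) {
      Pop &P = pops[p];
      double *slot = &P.ring[(size_t)(t & P.mask) * P.n];
      double *imp = P.imp.data();
      for (int j = 0; j < P.n; ++j) { imp[j] = slot[j]; slot[j] = 0.0; }
      if (P.pois_chunks > 0 && P.pois_w != 0.0) {
        for (int j = 0; j < P.n; ++j) {
          int c = 0;
          for (int m = 0; m < P.pois_chunks; ++m)
            c += rpois_product(rng, P.pois_expneg);
          imp[j] += c * P.pois_w;
        }
      }
      if (P.syn_kind == 0) {
        for (int j = 0; j < P.n; ++j) P.cur[j] = P.cur[j] * P.eds + imp[j];
      } else {
        for (int j = 0; j < P.n; ++j) {
          P.cur[j] = (P.cur[j] + P.x[j] * P.h) * P.eds;
          P.x[j] = P.x[j] * P.eds + imp[j];
        }
      }
      std::vector<int> &sp = cur_spikes[p];
      for (int j = 0; j < P.n; ++j) {
        if (P.refr[j] > 0) { --P.refr[j]; continue; }
        double v_inf = P.v_rest + P.r_m * (P.cur[j] + P.dc);
        double vn = v_inf + (P.v[j] - v_inf) * P.em;
        if (vn >= P.v_thresh) {
          sp.push_back(j);
          P.v[j] = P.v_reset;
          P.refr[j] = P.ref_steps;
          if (record_spikes && t >= spike_start_step) {
            spike_time.push_back((t + 1) * dt);
            spike_id.push_back(j + 1);
            spike_pop.push_back(p + 1);
          }
        } else {
          P.v[j] = vn;
        }
      }
    }
    // trace decay (before plasticity samples them, excluding this step's
    // spikes, which are added only after all projections are processed)
    for (int p = 0; p < n_pop; ++p) {
      Pop &P = pops[p];
      if (P.trace_decay > 0)
        for (int j = 0; j < P.n; ++j) P.trace[j] *= P.trace_decay;
    }
    // plasticity and delivery
    for (int q = 0; q < n_proj; ++q) {
      Proj &J = projs[q];
      Pop &T = pops[J.tgt];
      const std::vector<int> &sp = cur_spikes[J.src];
      if (J.type == 0) {
        const double *trace_tgt = T.trace.data();
        for (int i : sp) {
          const size_t base = (size_t)i * J.max_row;
          const int l = J.row_length[i];
          if (J.plastic) {
            for (int k = 0; k < l; ++k) {
              const size_t idx = base + k;
              const int j = J.post[idx];
              double w = J.weight[idx];
              w -= J.lam_alpha * w * trace_tgt[j];
              if (w < 0) w = 0;
              J.weight[idx] = w;
              T.ring[(size_t)((t + J.delay[idx]) & T.mask) * T.n + j] += w;
            }
          } else {
            for (int k = 0; k < l; ++k) {
              const size_t idx = base + k;
              T.ring[(size_t)((t + J.delay[idx]) & T.mask) * T.n +
                     J.post[idx]] += J.weight[idx];
            }
          }
        }
      } else {
        double *slot = &T.ring[(size_t)((t + J.const_d) & T.mask) * T.n];
        for (int i : sp) {
          const uint64_t b0 = (uint64_t)i * J.n_post;
          for (int j = 0; j < J.n_post; ++j) {
            const uint64_t b = b0 + j;
            if ((J.bits[b >> 3] >> (b & 7)) & 1) slot[j] += J.const_w;
          }
        }
      }
      if (J.plastic) {
        const double *trace_src = pops[J.src].trace.data();
        for (int j : cur_spikes[J.tgt]) {
          for (int c = J.col_ptr[j]; c < J.col_ptr[j + 1]; ++c) {
            const int pos = J.col_pos[c];
            double w = J.weight[pos];
            J.weight[pos] =
                w + J.pot_scale * std::pow(w, J.mu) * trace_src[J.col_pre[c]];
          }
        }
      }
    }
    // trace increment for this step's spikes
    for (int p = 0; p < n_pop; ++p) {
      Pop &P = pops[p];
      if (P.trace_decay > 0)
        for (int j : cur_spikes[p]) P.trace[j] += 1.0;
      cur_spikes[p].clear();
    }
    if (weight_every > 0 && (t % weight_every == weight_every - 1))
      record_weights(t);
  }
  if (weight_every > 0 &&
      (n_steps == 0 || n_steps % weight_every != 0))
    record_weights(n_steps - 1);

  // assemble outputs
  List wstats(plastic_idx.size());
  List wfinal(plastic_idx.size());
  for (size_t m = 0; m < plastic_idx.size(); ++m) {
    Proj &J = projs[plastic_idx[m]];
    wstats[m] = DataFrame::create(_["time"] = wrec_t[m],
                                  _["mean"] = wrec_mean[m],
                                  _["sd"] = wrec_sd[m]);
    std::vector<double> fw;
    for (int i = 0; i < J.n_pre; ++i)
      for (int k = 0; k < J.row_length[i]; ++k)
        fw.push_back(J.weight[(size_t)i * J.max_row + k]);
    wfinal[m] = NumericVector(fw.begin(), fw.end());
  }
  List vfinal(n_pop);
  for (int p = 0; p < n_pop; ++p)
    vfinal[p] = NumericVector(pops[p].v.begin(), pops[p].v.end());

  return List::create(
      _["spike_time"] = NumericVector(spike_time.begin(), spike_time.end()),
      _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
      _["spike_pop"] = IntegerVector(spike_pop.begin(), spike_pop.end()),
      _["weight_stats"] = wstats,
      _["final_weights"] = wfinal,
      _["final_v"] = vfinal,
      _["plastic_projections"] = IntegerVector(plastic_idx.begin(),
                                               plastic_idx.end()));
}
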