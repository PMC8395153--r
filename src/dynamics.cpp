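#include <Rcpp.h>
#include <map>
#include <string>
using namespace Rcpp;

// Ternary update engine. States are integer vectors in {-1,0,1}. The network
// arrives pre-encoded (0-based node indices) from net_encode() on the R side.
// All randomness draws from R's RNG so set.seed() governs reproducibility.

namespace {

struct Net {
  int n;
  std::vector<int> src, tgt, mode, gate, gate_val;
  std::vector<int> external;      // 0-based indices
  std::vector<int> clamp;         // length n
  std::vector<char> is_ext;       // length n
};

Net decode(const List& enc) {
  Net net;
  net.n = as<int>(enc["n"]);
  net.src = as<std::vector<int> >(enc["src"]);
  net.tgt = as<std::vector<int> >(enc["tgt"]);
  net.mode = as<std::vector<int> >(enc["mode"]);
  net.gate = as<std::vector<int> >(enc["gate"]);
  net.gate_val = as<std::vector<int> >(enc["gate_val"]);
  net.external = as<std::vector<int> >(enc["external"]);
  net.clamp = as<std::vector<int> >(enc["clamp"]);
  net.is_ext.assign(net.n, 0);
  for (size_t k = 0; k < net.external.size(); ++k)
    net.is_ext[net.external[k]] = 1;
  return net;
}

inline int sgn(int v) { return (v > 0) - (v < 0); }

// image of x under Eq.-2-style logic; conditional edges gated on current x
void image(const Net& net, const std::vector<int>& x, std::vector<int>& out) {
  const int n = net.n;
  // per-target aggregates: max over active activators / inhibitors
  std::vector<int> amax(n, -2), imax(n, -2);  // -2 = no active edge
  for (size_t e = 0; e < net.src.size(); ++e) {
    int g = net.gate[e];
    if (g >= 0 && x[g] != net.gate_val[e]) continue;  // gate closed
    int t = net.tgt[e], v = x[net.src[e]];
    if (net.mode[e] == 1) { if (v > amax[t]) amax[t] = v; }
    else                  { if (v > imax[t]) imax[t] = v; }
  }
  for (int i = 0; i < n; ++i) {
    if (net.is_ext[i]) { out[i] = x[i]; continue; }
    if (amax[i] > -2 && imax[i] > -2)      out[i] = sgn(amax[i] - imax[i]);
    else if (amax[i] > -2)                 out[i] = amax[i];
    else if (imax[i] > -2)                 out[i] = -imax[i];
    else                                   out[i] = x[i];  // no inputs
  }
}

std::string key_of(const std::vector<int>& x) {
  std::string k(x.size(), '0');
  for (size_t i = 0; i < x.size(); ++i) k[i] = (char)('1' + x[i]);
  return k;
}

// one asynchronous step among candidate (non-pinned) discrepant nodes;
// returns index updated, or -1 if none discrepant
int async_move(const Net& net, std::vector<int>& x,
               const std::vector<int>& img, const std::vector<char>& pinned) {
  std::vector<int> cand;
  for (int i = 0; i < net.n; ++i)
    if (!pinned[i] && img[i] != x[i]) cand.push_back(i);
  if (cand.empty()) return -1;
  int pick = cand[(int)std::floor(unif_rand() * cand.size()) % cand.size()];
  x[pick] += sgn(img[pick] - x[pick]);
  return pick;
}

void clamp_external(const Net& net, std::vector<int>& x) {
  for (size_t k = 0; k < net.external.size(); ++k)
    x[net.external[k]] = net.clamp[net.external[k]];
}

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_image(IntegerVector x, List enc) {
  Net net = decode(enc);
  std::vector<int> xs = as<std::vector<int> >(x), out(net.n);
  image(net, xs, out);
  return wrap(out);
}

// Simulate until fixed point or max_steps. Returns list(final, steps,
// terminated, trajectory?) ; trajectory recorded only if record is true.
// [[Rcpp::export]]
List cpp_simulate(IntegerVector start, List enc, int max_steps, bool record) {
  Net net = decode(enc);
  std::vector<int> x = as<std::vector<int> >(start), img(net.n);
  clamp_external(net, x);
  std::vector<char> pinned(net.n, 0);
  std::vector<std::vector<int> > traj;
  if (record) traj.push_back(x);
  bool terminated = false;
  int steps = 0;
  for (int t = 0; t < max_steps; ++t) {
    image(net, x, img);
    int moved = async_move(net, x, img, pinned);
    if (moved < 0) { terminated = true; break; }
    ++steps;
    if (record) traj.push_back(x);
  }
  if (!terminated) {  // cap reached; check whether we happen to sit on a FP
    image(net, x, img);
    terminated = std::equal(x.begin(), x.end(), img.begin());
  }
  List out = List::create(_["final"] = wrap(x), _["steps"] = steps,
                          _["terminated"] = terminated);
  if (record) {
    IntegerMatrix m(traj.size(), net.n);
    for (size_t r = 0; r < traj.size(); ++r)
      for (int c = 0; c < net.n; ++c) m(r, c) = traj[r][c];
    out["trajectory"] = m;
  }
  return out;
}

// Monte Carlo attractor discovery from uniform random ternary starts.
// [[Rcpp::export]]
List cpp_find_attractors(List enc, int n_starts, int max_steps) {
  Net net = decode(enc);
  std::vector<int> x(net.n), img(net.n);
  std::vector<char> pinned(net.n, 0);
  std::map<std::string, int> basins;
  std::map<std::string, std::vector<int> > reps;
  int unterminated = 0;
  for (int s = 0; s < n_starts; ++s) {
    for (int i = 0; i < net.n; ++i)
      x[i] = (int)std::floor(unif_rand() * 3.0) - 1;
    clamp_external(net, x);
    bool terminated = false;
    for (int t = 0; t < max_steps; ++t) {
      image(net, x, img);
      if (async_move(net, x, img, pinned) < 0) { terminated = true; break; }
    }
    if (!terminated) {
      image(net, x, img);
      terminated = std::equal(x.begin(), x.end(), img.begin());
    }
    if (!terminated) { ++unterminated; continue; }
    std::string k = key_of(x);
    if (basins.count(k)) ++basins[k];
    else { basins[k] = 1; reps[k] = x; }
  }
  IntegerMatrix fps(basins.size(), net.n);
  IntegerVector counts(basins.size());
  int r = 0;
  for (std::map<std::string, int>::iterator it = basins.begin();
       it != basins.end(); ++it, ++r) {
    const std::vector<int>& st = reps[it->first];
    for (int c = 0; c < net.n; ++c) fps(r, c) = st[c];
    counts[r] = it->second;
  }
  return List::create(_["fixed_points"] = fps, _["counts"] = counts,
                      _["n_unterminated"] = unterminated);
}

// Exhaustive fixed-point scan over non-external nodes (externals clamped).
// [[Rcpp::export]]
IntegerMatrix cpp_enumerate(List enc) {
  Net net = decode(enc);
  std::vector<int> free_idx;
  for (int i = 0; i < net.n; ++i) if (!net.is_ext[i]) free_idx.push_back(i);
  const int m = (int)free_idx.size();
  double total = std::pow(3.0, m);
  std::vector<int> x(net.n, 0), img(net.n);
  clamp_external(net, x);
  std::vector<std::vector<int> > found;
  std::vector<int> digit(m, 0);
  for (double c = 0; c < total; ++c) {
    for (int i = 0; i < m; ++i) x[free_idx[i]] = digit[i] - 1;
    image(net, x, img);
    if (std::equal(x.begin(), x.end(), img.begin())) found.push_back(x);
    for (int i = 0; i < m; ++i) {           // odometer
      if (++digit[i] < 3) break;
      digit[i] = 0;
    }
  }
  IntegerMatrix out(found.size(), net.n);
  for (size_t r = 0; r < found.size(); ++r)
    for (int c = 0; c < net.n; ++c) out(r, c) = found[r][c];
  return out;
}

// Timed treatment-course Monte Carlo. Interventions given as parallel vectors
// (0-based targets). Per timestep t = 1..: (1) targets of active windows are
// set to clip(x + effect) and pinned for the step; (2) one untreated node
// discrepant from the image moves one step. After the last window the run
// continues untreated until a fixed point or max_steps. Returns per-run
// final states and the count reaching `healthy`.
// [[Rcpp::export]]
List cpp_simulate_course(IntegerVector start, List enc,
                         IntegerVector target, IntegerVector effect,
                         IntegerVector t_start, IntegerVector t_stop,
                         int max_steps, int n_runs, IntegerVector healthy) {
  Net net = decode(enc);
  const int M = target.size();
  const std::vector<int> x0 = as<std::vector<int> >(start);
  const std::vector<int> h = as<std::vector<int> >(healthy);
  int last_stop = 0;
  for (int j = 0; j < M; ++j) if (t_stop[j] > last_stop) last_stop = t_stop[j];
  int n_healthy = 0, n_unterminated = 0;
  std::map<std::string, int> finals;
  std::vector<int> x(net.n), img(net.n);
  std::vector<char> pinned(net.n);
  for (int run = 0; run < n_runs; ++run) {
    x = x0;
    clamp_external(net, x);
    bool terminated = false;
    for (int t = 1; t <= max_steps; ++t) {
      std::fill(pinned.begin(), pinned.end(), 0);
      if (t <= last_stop) {
        for (int j = 0; j < M; ++j) {
          if (t >= t_start[j] && t <= t_stop[j]) {
            int v = x[target[j]] + effect[j];
            x[target[j]] = v > 1 ? 1 : (v < -1 ? -1 : v);
            pinned[target[j]] = 1;
          }
        }
      }
      image(net, x, img);
      int moved = async_move(net, x, img, pinned);
      if (moved < 0 && t > last_stop) { terminated = true; break; }
    }
    if (!terminated) {
      image(net, x, img);
      terminated = std::equal(x.begin(), x.end(), img.begin());
    }
    if (!terminated) ++n_unterminated;
    if (terminated && std::equal(x.begin(), x.end(), h.begin())) ++n_healthy;
    ++finals[key_of(x)];
  }
  IntegerMatrix fmat(finals.size(), net.n);
  IntegerVector fcnt(finals.size());
  int r = 0;
  for (std::map<std::string, int>::iterator it = finals.begin();
       it != finals.end(); ++it, ++r) {
    for (int c = 0; c < net.n; ++c) fmat(r, c) = (int)(it->first[c] - '1');
    fcnt[r] = it->second;
  }
  return List::create(_["n_healthy"] = n_healthy,
                      _["n_runs"] = n_runs,
                      _["n_unterminated"] = n_unterminated,
                      _["final_states"] = fmat,
                      _["final_counts"] = fcnt);
}
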