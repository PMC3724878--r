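// Synchronous threshold-network dynamics core.
//
// States are binary vectors over the network's nodes. One update step sets,
// for every free (non-clamped) node i,
//     s_i(t+1) = 1  iff  sum_j a_ij s_j(t) > theta_i   (strict inequality),
// reading only time-t values; clamped nodes (environment inputs, mutations,
// drug interventions) keep their clamp value. All arithmetic is integer.
//
// The network arrives as flattened per-target input lists:
//   in_ptr  (n+1) 0-based offsets into in_src/in_w for each target node
//   in_src        0-based source-node index of each incoming edge
//   in_w          signed integer strength of each incoming edge

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct Net {
  int n;
  std::vector<int> in_ptr, in_src, in_w, theta;
  std::vector<uint8_t> clamped;
  std::vector<uint8_t> clamp_val;
};

Net unpack_net(const IntegerVector& in_ptr, const IntegerVector& in_src,
               const IntegerVector& in_w, const IntegerVector& theta,
               const IntegerVector& clamp_mask, const IntegerVector& clamp_val) {
  Net net;
  net.n = theta.size();
  net.in_ptr.assign(in_ptr.begin(), in_ptr.end());
  net.in_src.assign(in_src.begin(), in_src.end());
  net.in_w.assign(in_w.begin(), in_w.end());
  net.theta.assign(theta.begin(), theta.end());
  net.clamped.resize(net.n);
  net.clamp_val.resize(net.n);
  for (int i = 0; i < net.n; ++i) {
    net.clamped[i] = static_cast<uint8_t>(clamp_mask[i]);
    net.clamp_val[i] = static_cast<uint8_t>(clamp_val[i]);
  }
  return net;
}

inline void step_state(const Net& net, const std::vector<uint8_t>& cur,
                       std::vector<uint8_t>& nxt) {
  for (int i = 0; i < net.n; ++i) {
    if (net.clamped[i]) {
      nxt[i] = net.clamp_val[i];
      continue;
    }
    int acc = 0;
    for (int e = net.in_ptr[i]; e < net.in_ptr[i + 1]; ++e)
      acc += net.in_w[e] * static_cast<int>(cur[net.in_src[e]]);
    nxt[i] = acc > net.theta[i] ? 1 : 0;
  }
}

// pack a 0/1 state into bytes, first node in the most significant bit, so
// byte-wise lexicographic order equals lexicographic order of the bit string
inline std::string pack(const std::vector<uint8_t>& s) {
  std::string out((s.size() + 7) / 8, '\0');
  for (size_t i = 0; i < s.size(); ++i)
    if (s[i]) out[i >> 3] |= static_cast<char>(1 << (7 - (i & 7)));
  return out;
}

inline std::vector<uint8_t> unpack_state(const std::string& p, int n) {
  std::vector<uint8_t> s(n);
  for (int i = 0; i < n; ++i)
    s[i] = (p[i >> 3] >> (7 - (i & 7))) & 1;
  return s;
}

std::string to_hex(const std::string& raw) {
  static const char* hx = "0123456789abcdef";
  std::string out(raw.size() * 2, '0');
  for (size_t i = 0; i < raw.size(); ++i) {
    out[2 * i] = hx[(raw[i] >> 4) & 15];
    out[2 * i + 1] = hx[raw[i] & 15];
  }
  return out;
}

// rotate the cycle so it starts at the lexicographically smallest packed state
void canonicalize(std::vector<std::string>& cycle) {
  size_t best = 0;
  for (size_t k = 1; k < cycle.size(); ++k)
    if (cycle[k] < cycle[best]) best = k;
  std::rotate(cycle.begin(), cycle.begin() + best, cycle.end());
}

struct AttractorStore {
  std::unordered_map<std::string, int> key_to_id;  // canonical key -> 1-based id
  std::vector<std::vector<std::string>> cycles;    // canonical state sequences

  int intern(std::vector<std::string> cycle) {
    canonicalize(cycle);
    std::string key;
    for (const std::string& s : cycle) key += s;
    auto it = key_to_id.find(key);
    if (it != key_to_id.end()) return it->second;
    int id = static_cast<int>(cycles.size()) + 1;
    key_to_id.emplace(std::move(key), id);
    cycles.push_back(std::move(cycle));
    return id;
  }
};

// Run one trajectory to its attractor. Returns attractor id (interned in
// store) and transient length, or id = -1 when max_steps was exhausted.
std::pair<int, int> run_one(const Net& net, std::vector<uint8_t> cur,
                            int max_steps, AttractorStore& store) {
  std::unordered_map<std::string, int> seen;
  std::vector<std::string> trace;
  std::vector<uint8_t> nxt(net.n);
  for (int t = 0; t <= max_steps; ++t) {
    std::string key = pack(cur);
    auto it = seen.find(key);
    if (it != seen.end()) {
      int t0 = it->second;
      std::vector<std::string> cycle(trace.begin() + t0, trace.end());
      return {store.intern(std::move(cycle)), t0};
    }
    seen.emplace(std::move(key), t);
    trace.push_back(pack(cur));
    step_state(net, cur, nxt);
    cur.swap(nxt);
  }
  return {-1, -1};
}

List store_to_list(const AttractorStore& store, int n) {
  int n_att = static_cast<int>(store.cycles.size());
  List states(n_att);
  IntegerVector periods(n_att);
  CharacterVector keys(n_att);
  for (int a = 0; a < n_att; ++a) {
    const std::vector<std::string>& cyc = store.cycles[a];
    int T = static_cast<int>(cyc.size());
    IntegerMatrix m(T, n);
    std::string key;
    for (int t = 0; t < T; ++t) {
      std::vector<uint8_t> s = unpack_state(cyc[t], n);
      for (int i = 0; i < n; ++i) m(t, i) = s[i];
      key += cyc[t];
    }
    periods[a] = T;
    keys[a] = to_hex(key);
    states[a] = m;
  }
  return List::create(_["period"] = periods, _["key"] = keys,
                      _["states"] = states);
}

}  // namespace

// [[Rcpp::export(name = ".tbn_step_batch")]]
IntegerMatrix tbn_step_batch(IntegerVector in_ptr, IntegerVector in_src,
                             IntegerVector in_w, IntegerVector theta,
                             IntegerVector clamp_mask, IntegerVector clamp_val,
                             IntegerMatrix states) {
  Net net = unpack_net(in_ptr, in_src, in_w, theta, clamp_mask, clamp_val);
  int ns = states.nrow();
  IntegerMatrix out(ns, net.n);
  std::vector<uint8_t> cur(net.n), nxt(net.n);
  for (int r = 0; r < ns; ++r) {
    for (int i = 0; i < net.n; ++i) cur[i] = static_cast<uint8_t>(states(r, i));
    step_state(net, cur, nxt);
    for (int i = 0; i < net.n; ++i) out(r, i) = nxt[i];
  }
  return out;
}

// [[Rcpp::export(name = ".tbn_find_attractors")]]
List tbn_find_attractors(IntegerVector in_ptr, IntegerVector in_src,
                         IntegerVector in_w, IntegerVector theta,
                         IntegerVector clamp_mask, IntegerVector clamp_val,
                         IntegerMatrix init, int max_steps) {
  Net net = unpack_net(in_ptr, in_src, in_w, theta, clamp_mask, clamp_val);
  int ns = init.nrow();
  AttractorStore store;
  IntegerVector att_id(ns), transient(ns);
  std::vector<uint8_t> s0(net.n);
  for (int r = 0; r < ns; ++r) {
    for (int i = 0; i < net.n; ++i) s0[i] = static_cast<uint8_t>(init(r, i));
    std::pair<int, int> res = run_one(net, s0, max_steps, store);
    att_id[r] = res.first;
    transient[r] = res.second;
    if (r % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  List att = store_to_list(store, net.n);
  return List::create(_["attractor_id"] = att_id, _["transient"] = transient,
                      _["attractors"] = att);
}

// Exhaustive enumeration over all configurations of the free nodes; clamped
// nodes carry their clamp values. Returns exact basin counts.
// [[Rcpp::export(name = ".tbn_enumerate")]]
List tbn_enumerate(IntegerVector in_ptr, IntegerVector in_src,
                   IntegerVector in_w, IntegerVector theta,
                   IntegerVector clamp_mask, IntegerVector clamp_val,
                   IntegerVector free_idx, int max_steps) {
  Net net = unpack_net(in_ptr, in_src, in_w, theta, clamp_mask, clamp_val);
  int k = free_idx.size();
  if (k > 24) stop("exhaustive enumeration limited to 24 free nodes, got %d", k);
  uint64_t total = 1ULL << k;
  AttractorStore store;
  std::vector<double> counts;
  std::vector<uint8_t> s0(net.n);
  for (int i = 0; i < net.n; ++i) s0[i] = net.clamped[i] ? net.clamp_val[i] : 0;
  for (uint64_t code = 0; code < total; ++code) {
    for (int b = 0; b < k; ++b)
      s0[free_idx[b]] = (code >> b) & 1;
    std::pair<int, int> res = run_one(net, s0, max_steps, store);
    if (res.first < 0) stop("no attractor found within max_steps");
    if (static_cast<size_t>(res.first) > counts.size()) counts.resize(res.first, 0.0);
    counts[res.first - 1] += 1.0;
    if ((code & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  List att = store_to_list(store, net.n);
  return List::create(_["count"] = NumericVector(counts.begin(), counts.end()),
                      _["total"] = static_cast<double>(total),
                      _["attractors"] = att);
}
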