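#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Small deterministic PRNG (xorshift64*) so partitions are reproducible
// across platforms independently of R's RNG state.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform integer in [0, n)
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
  void shuffle(std::vector<int> &v) {
    for (int i = static_cast<int>(v.size()) - 1; i > 0; --i) {
      int j = below(i + 1);
      std::swap(v[i], v[j]);
    }
  }
};

// One level of local moves on a dense weighted graph.
// w: n x n symmetric nonnegative (self-loops allowed on aggregated graphs).
// Returns community labels (0-based, compacted) and reports whether any move
// improved modularity.
static std::vector<int> local_moves(const std::vector<double> &w, int n,
                                    double gamma, double m2, XorShift &rng,
                                    bool &changed) {
  std::vector<double> k(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) k[i] += w[i + static_cast<size_t>(n) * j];

  std::vector<int> comm(n);
  std::vector<double> tot(n, 0.0);
  for (int i = 0; i < n; ++i) { comm[i] = i; tot[i] = k[i]; }

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> w_to(n, 0.0);   // weight from node i to each community
  std::vector<int> touched;
  touched.reserve(n);

  changed = false;
  bool moved = true;
  int pass = 0;
  while (moved && pass < 1000) {
    moved = false;
    ++pass;
    rng.shuffle(order);
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      int ci = comm[i];

      touched.clear();
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double wij = w[i + static_cast<size_t>(n) * j];
        if (wij != 0.0) {
          int cj = comm[j];
          if (w_to[cj] == 0.0) touched.push_back(cj);
          w_to[cj] += wij;
        }
      }
      if (w_to[ci] == 0.0) touched.push_back(ci);  // ensure own community listed

      // remove i from its community
      tot[ci] -= k[i];

      // gain of joining community c: w_to[c] - gamma * k_i * tot[c] / m2
      double best_gain = w_to[ci] - gamma * k[i] * tot[ci] / m2;
      int best_c = ci;
      for (size_t t = 0; t < touched.size(); ++t) {
        int c = touched[t];
        if (c == ci) continue;
        double gain = w_to[c] - gamma * k[i] * tot[c] / m2;
        if (gain > best_gain + 1e-12) {  // strictly positive improvement
          best_gain = gain;
          best_c = c;
        }
      }

      comm[i] = best_c;
      tot[best_c] += k[i];
      if (best_c != ci) { moved = true; changed = true; }

      for (size_t t = 0; t < touched.size(); ++t) w_to[touched[t]] = 0.0;
    }
  }

  // compact labels to 0..K-1 in order of first appearance
  std::vector<int> remap(n, -1);
  int next_label = 0;
  for (int i = 0; i < n; ++i) {
    if (remap[comm[i]] < 0) remap[comm[i]] = next_label++;
    comm[i] = remap[comm[i]];
  }
  return comm;
}

// [[Rcpp::export(name = ".louvain_cpp")]]
IntegerVector louvain_cpp(NumericMatrix W, double gamma, double seed) {
  int n = W.nrow();
  if (n == 0) return IntegerVector(0);

  std::vector<double> w(W.begin(), W.end());
  double m2 = 0.0;
  for (size_t t = 0; t < w.size(); ++t) m2 += w[t];

  IntegerVector out(n);
  if (m2 <= 0.0) {           // empty graph: every node its own module
    for (int i = 0; i < n; ++i) out[i] = i;
    return out;
  }

  XorShift rng(static_cast<uint64_t>(seed));

  std::vector<int> node2final(n);
  for (int i = 0; i < n; ++i) node2final[i] = i;

  int level_n = n;
  std::vector<double> cur = w;
  for (int level = 0; level < 100; ++level) {
    bool changed = false;
    std::vector<int> comm = local_moves(cur, level_n, gamma, m2, rng, changed);
    int K = 0;
    for (int i = 0; i < level_n; ++i) if (comm[i] + 1 > K) K = comm[i] + 1;

    // map original nodes through this level's assignment
    for (int i = 0; i < n; ++i) node2final[i] = comm[node2final[i]];
    if (!changed || K == level_n) break;

    // aggregate: community-level weights (self-loops keep internal weight)
    std::vector<double> agg(static_cast<size_t>(K) * K, 0.0);
    for (int i = 0; i < level_n; ++i)
      for (int j = 0; j < level_n; ++j)
        agg[comm[i] + static_cast<size_t>(K) * comm[j]] +=
          cur[i + static_cast<size_t>(level_n) * j];
    cur.swap(agg);
    level_n = K;
  }

  for (int i = 0; i < n; ++i) out[i] = node2final[i];
  return out;
}
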