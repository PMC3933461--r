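#include <Rcpp.h>
using namespace Rcpp;

// Seeded two-state spin-glass search.
//
// Spins take two values, "in" (the seed's community C) and "out"; the
// weighted Reichardt-Bornholdt Hamiltonian
//
//   H = - sum_{i<j} ( w_ij - gamma * s_i s_j / (2W) ) * delta(sigma_i, sigma_j)
//
// counts both in-group and out-group pairs, with w_ij the edge weight
// (0 for non-edges), s_i the strength (weighted degree) and 2W the total
// strength (configuration-model null). The sum runs over the candidate
// set (the seed's connected component); the seed's spin is pinned "in".
//
// Optimization per call (one restart; the R-level RNG is the single
// source of randomness): simulated annealing over membership flips with
// geometric cooling, then basin hopping -- greedy descent to a local
// minimum, followed by kick-perturbation / re-descent cycles keeping the
// best configuration -- to cross barriers that single flips cannot.

class SpinState {
public:
  const IntegerVector &ptr, &idx;
  const NumericVector &w, &s;
  const double twoW, gamma;
  const int seed_node;
  const IntegerVector &cand;
  std::vector<char> in;
  double s_in = 0.0, s_out = 0.0;

  SpinState(const IntegerVector& ptr_, const IntegerVector& idx_,
            const NumericVector& w_, const NumericVector& s_,
            double twoW_, double gamma_, int seed_, const IntegerVector& c_)
    : ptr(ptr_), idx(idx_), w(w_), s(s_), twoW(twoW_), gamma(gamma_),
      seed_node(seed_), cand(c_), in(s_.size(), 0) {}

  void random_init() {
    std::fill(in.begin(), in.end(), 0);
    in[seed_node] = 1;
    for (int c = 0; c < cand.size(); ++c) {
      int v = cand[c];
      if (v != seed_node && unif_rand() < 0.5) in[v] = 1;
    }
    recount();
  }
  void recount() {
    s_in = s_out = 0.0;
    for (int c = 0; c < cand.size(); ++c) {
      int v = cand[c];
      if (in[v]) s_in += s[v]; else s_out += s[v];
    }
  }
  double delta_h(int v) const {
    double link_in = 0.0, link_all = 0.0;
    for (int k = ptr[v]; k < ptr[v + 1]; ++k) {
      link_all += w[k];
      if (in[idx[k]]) link_in += w[k];
    }
    double link_out = link_all - link_in, sv = s[v];
    if (in[v])  // leaving C: lose pairs with C\{v}, gain the out-group's
      return (link_in - gamma * sv * (s_in - sv) / twoW) -
             (link_out - gamma * sv * s_out / twoW);
    return (link_out - gamma * sv * (s_out - sv) / twoW) -
           (link_in - gamma * sv * s_in / twoW);
  }
  void flip(int v) {
    double sv = s[v];
    if (in[v]) { in[v] = 0; s_in -= sv; s_out += sv; }
    else       { in[v] = 1; s_in += sv; s_out -= sv; }
  }
  void greedy_descent() {
    bool improved = true;
    while (improved) {
      improved = false;
      for (int c = 0; c < cand.size(); ++c) {
        int v = cand[c];
        if (v == seed_node) continue;
        if (delta_h(v) < -1e-12) { flip(v); improved = true; }
      }
    }
  }
  double full_h() const {
    double w_in = 0.0, w_out = 0.0, s2_in = 0.0, s2_out = 0.0;
    for (int c = 0; c < cand.size(); ++c) {
      int v = cand[c];
      double wsame = 0.0;
      for (int k = ptr[v]; k < ptr[v + 1]; ++k)
        if (in[idx[k]] == in[v]) wsame += w[k];
      if (in[v]) { w_in += wsame; s2_in += s[v] * s[v]; }
      else       { w_out += wsame; s2_out += s[v] * s[v]; }
    }
    w_in *= 0.5;  // each same-group edge visited twice
    w_out *= 0.5;
    return -(w_in - gamma * (s_in * s_in - s2_in) / 2.0 / twoW) -
           (w_out - gamma * (s_out * s_out - s2_out) / 2.0 / twoW);
  }
};

// [[Rcpp::export(name = ".spinglass_anneal_cpp")]]
List spinglass_anneal_cpp(IntegerVector adj_ptr, IntegerVector adj_idx,
                          NumericVector adj_w, NumericVector strength,
                          double twoW, int seed_node, IntegerVector candidates,
                          double gamma, double start_temp, double stop_temp,
                          double cool_fact, int sweeps, int hops,
                          double hop_frac) {
  const int ncand = candidates.size();
  SpinState st(adj_ptr, adj_idx, adj_w, strength, twoW, gamma, seed_node,
               candidates);
  st.random_init();

  const int per_temp = std::max(ncand * sweeps, 16);
  for (double temp = start_temp; temp > stop_temp; temp *= cool_fact) {
    for (int step = 0; step < per_temp; ++step) {
      int v = candidates[(int)(unif_rand() * ncand) % ncand];
      if (v == seed_node) continue;
      double dh = st.delta_h(v);
      if (dh <= 0.0 || unif_rand() < std::exp(-dh / temp)) st.flip(v);
    }
  }

  st.greedy_descent();
  std::vector<char> best_in = st.in;
  double best_h = st.full_h();
  for (int hop = 0; hop < hops; ++hop) {
    st.in = best_in;
    st.recount();
    for (int c = 0; c < ncand; ++c) {
      int v = candidates[c];
      if (v != seed_node && unif_rand() < hop_frac) st.flip(v);
    }
    st.greedy_descent();
    double h = st.full_h();
    if (h < best_h - 1e-12) { best_h = h; best_in = st.in; }
  }

  std::vector<int> members;
  for (int c = 0; c < ncand; ++c)
    if (best_in[candidates[c]]) members.push_back(candidates[c]);
  std::sort(members.begin(), members.end());
  return List::create(_["members"] = wrap(members), _["H"] = best_h);
}
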