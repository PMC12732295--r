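// Monte-Carlo core for the Random Domino Automaton on a finite 3-regular
// (or locally 3-regular) lattice. Uses R's RNG so that set.seed() makes runs
// reproducible. Draw order per step is fixed: (1) uniform cell choice,
// (2) one uniform acceptance draw r. An occupied cell's cluster (size i) is
// removed iff r < delta / i; since delta / i <= delta the cluster size
// lookup is skipped whenever r >= delta. An empty cell with t occupied
// neighbours becomes occupied iff r < c[t].
//
// Cluster bookkeeping is an incremental union-find (union by size, path
// compression): occupying a cell unions it with its occupied neighbours;
// an avalanche clears the removed cells and resets their entries, which is
// sound because no other component ever points into a different component.
// A plain BFS size computation is retained (use_union_find = false) as the
// correctness oracle: both paths consume the RNG identically and must
// produce identical trajectories.

#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

struct UnionFind {
  std::vector<int> parent, sz;
  void init(int n) {
    parent.resize(n); sz.assign(n, 1);
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int u) {
    int r = u;
    while (parent[r] != r) r = parent[r];
    while (parent[u] != r) { int nx = parent[u]; parent[u] = r; u = nx; }
    return r;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (sz[a] < sz[b]) std::swap(a, b);
    parent[b] = a; sz[a] += sz[b];
  }
  void reset(int u) { parent[u] = u; sz[u] = 1; }
};

static void bfs_cluster(const IntegerMatrix &nb, const std::vector<uint8_t> &occ,
                        int u, uint8_t target, std::vector<int> &out,
                        std::vector<int> &mark, int stamp) {
  out.clear();
  out.push_back(u);
  mark[u] = stamp;
  for (size_t head = 0; head < out.size(); ++head) {
    int v = out[head];
    for (int e = 0; e < nb.ncol(); ++e) {
      int w = nb(v, e);
      if (w < 0) continue;
      if (mark[w] != stamp && occ[w] == target) {
        mark[w] = stamp;
        out.push_back(w);
      }
    }
  }
}

struct SimState {
  std::vector<uint8_t> occ;
  UnionFind uf;
  std::vector<int> mark, scratch;
  int stamp = 0;
  bool use_uf = true;

  void init(int n, bool uuf) {
    occ.assign(n, 0);
    uf.init(n);
    mark.assign(n, 0);
    use_uf = uuf;
  }
};

// One update step; returns 0 nothing, 1 cell occupied, 2 avalanche.
static int do_step(const IntegerMatrix &nb, SimState &S, const double *cc,
                   double delta) {
  int n_cells = S.occ.size();
  int u = (int)(unif_rand() * n_cells);
  if (u == n_cells) u = n_cells - 1;
  double r = unif_rand();
  if (S.occ[u]) {
    if (r >= delta) return 0;                // mu_i = delta/i <= delta
    int size;
    if (S.use_uf) size = S.uf.sz[S.uf.find(u)];
    else {
      bfs_cluster(nb, S.occ, u, 1, S.scratch, S.mark, ++S.stamp);
      size = (int)S.scratch.size();
    }
    if (r < delta / (double)size) {
      bfs_cluster(nb, S.occ, u, 1, S.scratch, S.mark, ++S.stamp);
      for (int v : S.scratch) { S.occ[v] = 0; S.uf.reset(v); }
      return 2;
    }
    return 0;
  }
  int t = 0;
  for (int e = 0; e < nb.ncol(); ++e) {
    int w = nb(u, e);
    if (w >= 0 && S.occ[w]) ++t;
  }
  if (r < cc[t]) {
    S.occ[u] = 1;
    S.uf.reset(u);
    for (int e = 0; e < nb.ncol(); ++e) {
      int w = nb(u, e);
      if (w >= 0 && S.occ[w]) S.uf.unite(u, w);
    }
    return 1;
  }
  return 0;
}

struct SnapshotStats {
  double rho;
  int n, n0, n1_0;
  int x[4];
};

static SnapshotStats snapshot(const IntegerMatrix &nb,
                              const std::vector<uint8_t> &occ,
                              std::vector<int> &mark, int &stamp,
                              std::vector<double> &hist) {
  int n_cells = occ.size();
  SnapshotStats s{};
  int nocc = 0;
  std::vector<int> comp;
  ++stamp;
  for (int u = 0; u < n_cells; ++u) {
    if (occ[u]) {
      ++nocc;
      if (mark[u] != stamp) {
        bfs_cluster(nb, occ, u, 1, comp, mark, stamp);
        ++s.n;
        size_t sz = comp.size();
        if (sz <= hist.size()) hist[sz - 1] += 1.0;
        else hist.back() += 1.0;             // overflow bucket
      }
    } else {
      int t = 0;
      for (int e = 0; e < nb.ncol(); ++e) {
        int w = nb(u, e);
        if (w >= 0 && occ[w]) ++t;
      }
      ++s.x[t];
      if (mark[u] != stamp) {
        bfs_cluster(nb, occ, u, 0, comp, mark, stamp);
        ++s.n0;
        if (comp.size() == 1) ++s.n1_0;
      }
    }
  }
  s.rho = (double)nocc / n_cells;
  return s;
}

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(IntegerMatrix nb, LogicalVector occ0, NumericVector cvec,
                 double delta, double burn_in, int n_samples,
                 double sample_interval, bool keep_snapshots, int hist_max,
                 bool use_union_find = true) {
  int n_cells = nb.nrow();
  SimState S;
  S.init(n_cells, use_union_find);
  for (int i = 0; i < n_cells; ++i)
    if (occ0[i]) S.occ[i] = 1;
  if (use_union_find)                         // build UF for initial state
    for (int u = 0; u < n_cells; ++u)
      if (S.occ[u])
        for (int e = 0; e < nb.ncol(); ++e) {
          int w = nb(u, e);
          if (w >= 0 && S.occ[w]) S.uf.unite(u, w);
        }
  double cc[4] = {cvec[0], cvec[1], cvec[2], cvec[3]};
  std::vector<double> hist(hist_max, 0.0);

  for (double s = 0; s < burn_in; s += 1.0) {
    do_step(nb, S, cc, delta);
    if (((long long)s & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix stats(n_samples, 8);
  colnames(stats) = CharacterVector::create("rho", "n", "n0", "n1_0",
                                            "x0", "x1", "x2", "x3");
  LogicalMatrix snaps(keep_snapshots ? n_samples : 0,
                      keep_snapshots ? n_cells : 0);
  for (int k = 0; k < n_samples; ++k) {
    for (double s = 0; s < sample_interval; s += 1.0)
      do_step(nb, S, cc, delta);
    SnapshotStats st = snapshot(nb, S.occ, S.mark, S.stamp, hist);
    stats(k, 0) = st.rho;  stats(k, 1) = st.n;
    stats(k, 2) = st.n0;   stats(k, 3) = st.n1_0;
    for (int j = 0; j < 4; ++j) stats(k, 4 + j) = st.x[j];
    if (keep_snapshots)
      for (int i = 0; i < n_cells; ++i) snaps(k, i) = S.occ[i] != 0;
    Rcpp::checkUserInterrupt();
  }
  LogicalVector final_occ(n_cells);
  for (int i = 0; i < n_cells; ++i) final_occ[i] = S.occ[i] != 0;
  List out = List::create(_["stats"] = stats, _["hist"] = hist,
                          _["final_occ"] = final_occ);
  if (keep_snapshots) out["snapshots"] = snaps;
  return out;
}

// [[Rcpp::export(name = ".sim_step_cpp")]]
List sim_step_cpp(IntegerMatrix nb, LogicalVector occ0, NumericVector cvec,
                  double delta) {
  int n_cells = nb.nrow();
  SimState S;
  S.init(n_cells, false);
  for (int i = 0; i < n_cells; ++i)
    if (occ0[i]) S.occ[i] = 1;
  double cc[4] = {cvec[0], cvec[1], cvec[2], cvec[3]};
  int code = do_step(nb, S, cc, delta);
  LogicalVector out(n_cells);
  for (int i = 0; i < n_cells; ++i) out[i] = S.occ[i] != 0;
  return List::create(_["occ"] = out, _["event"] = code);
}

// [[Rcpp::export(name = ".cluster_stats_cpp")]]
List cluster_stats_cpp(IntegerMatrix nb, LogicalVector occ0) {
  int n_cells = nb.nrow();
  std::vector<uint8_t> occ(n_cells);
  for (int i = 0; i < n_cells; ++i) occ[i] = occ0[i] ? 1 : 0;
  std::vector<int> mark(n_cells, 0);
  int stamp = 0;
  std::vector<double> hist(n_cells, 0.0);
  SnapshotStats st = snapshot(nb, occ, mark, stamp, hist);
  std::vector<int> sizes;
  std::vector<int> comp;
  ++stamp;
  for (int u = 0; u < n_cells; ++u)
    if (occ[u] && mark[u] != stamp) {
      bfs_cluster(nb, occ, u, 1, comp, mark, stamp);
      sizes.push_back((int)comp.size());
    }
  return List::create(
    _["rho"] = st.rho, _["n"] = st.n, _["n0"] = st.n0, _["n1_0"] = st.n1_0,
    _["x"] = NumericVector::create(st.x[0], st.x[1], st.x[2], st.x[3]),
    _["sizes"] = wrap(sizes));
}
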