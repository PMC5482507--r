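// MRF core for metabolic network segmentation.
//
// Variables are (metabolite i, frame s) pairs with K discrete module labels.
// Factors: per-clique-per-frame neighborhood potentials
//   psi_N = exp(-lambda1 * (unique-1)/size),
// per-measured-variable Gaussian observation potentials
//   psi_O = exp(-(x-mu)^2 / (2 sigma^2)),
// and per-metabolite frame-boundary sequence potentials
//   psi_S = exp(-lambda2 * f), f = -1 if labels equal else +1.
// All computation is in the energy (negative log) domain; MAP minimizes energy.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <functional>
using namespace Rcpp;

static const double EPS = 1e-12;

struct Problem {
  int M, S, K, nvar;
  std::vector<std::vector<int>> cliques;       // 0-based metabolite ids
  std::vector<std::vector<int>> node_cliques;  // clique ids per metabolite
  std::vector<int> ea, eb;                     // edge endpoints (0-based)
  std::vector<double> eobs;                    // nvar * K observation energies
  double l1, l2;

  // connected variable subsets of size 2..max_flip with their touched factors
  struct Sub {
    std::vector<int> vars;  // variable ids i*S+s
    std::vector<int> cfs;   // clique-frame factors c*S+s
    std::vector<int> sqs;   // sequence factors i*S+s (boundary s-1 -> s), s>=1
  };
  std::vector<Sub> subs;
  std::vector<std::vector<int>> vadj;  // variable adjacency (edges + seq links)

  inline int vid(int i, int s) const { return i * S + s; }

  double clique_energy(int c, int s, const std::vector<int>& y) const {
    bool seen[8] = {false, false, false, false, false, false, false, false};
    int u = 0;
    const std::vector<int>& mem = cliques[c];
    for (size_t t = 0; t < mem.size(); ++t) {
      int k = y[vid(mem[t], s)];
      if (!seen[k]) { seen[k] = true; ++u; }
    }
    return l1 * (double)(u - 1) / (double)mem.size();
  }

  inline double seq_energy(int i, int s, const std::vector<int>& y) const {
    // boundary between frames s-1 and s
    return l2 * (y[vid(i, s - 1)] == y[vid(i, s)] ? -1.0 : 1.0);
  }

  double full_energy(const std::vector<int>& y) const {
    double e = 0.0;
    for (int s = 0; s < S; ++s)
      for (size_t c = 0; c < cliques.size(); ++c)
        e += clique_energy((int)c, s, y);
    for (int v = 0; v < nvar; ++v) e += eobs[v * K + y[v]];
    if (l2 != 0.0 || S > 1)
      for (int i = 0; i < M; ++i)
        for (int s = 1; s < S; ++s) e += seq_energy(i, s, y);
    return e;
  }

  // energy of factors touching variable (i, s)
  double local_energy(int i, int s, const std::vector<int>& y) const {
    int v = vid(i, s);
    double e = eobs[v * K + y[v]];
    const std::vector<int>& nc = node_cliques[i];
    for (size_t t = 0; t < nc.size(); ++t) e += clique_energy(nc[t], s, y);
    if (s > 0) e += seq_energy(i, s, y);
    if (s < S - 1) e += seq_energy(i, s + 1, y);
    return e;
  }

  double sub_energy(const Sub& sb, const std::vector<int>& y) const {
    double e = 0.0;
    for (size_t t = 0; t < sb.vars.size(); ++t)
      e += eobs[sb.vars[t] * K + y[sb.vars[t]]];
    for (size_t t = 0; t < sb.cfs.size(); ++t)
      e += clique_energy(sb.cfs[t] / S, sb.cfs[t] % S, y);
    for (size_t t = 0; t < sb.sqs.size(); ++t)
      e += seq_energy(sb.sqs[t] / S, sb.sqs[t] % S, y);
    return e;
  }

  void icm(std::vector<int>& y) const {
    bool changed = true;
    int guard = 0;
    while (changed && ++guard < 10000) {
      changed = false;
      for (int i = 0; i < M; ++i) {
        for (int s = 0; s < S; ++s) {
          int v = vid(i, s);
          int cur = y[v];
          int best = cur;
          double ebest = local_energy(i, s, y);
          for (int k = 0; k < K; ++k) {
            if (k == cur) continue;
            y[v] = k;
            double ek = local_energy(i, s, y);
            // strictly better, or equal-energy move to a lower label
            if (ek < ebest - EPS || (ek < ebest + EPS && k < best)) {
              ebest = ek; best = k;
            }
          }
          y[v] = best;
          if (best != cur) changed = true;
        }
      }
    }
  }

  // one pass of exhaustive flips over connected subsets; returns true if any
  // strictly improving joint reassignment was applied (ICM rerun after each)
  bool flip_pass(std::vector<int>& y) const {
    bool any = false;
    std::vector<int> cur, best;
    for (size_t q = 0; q < subs.size(); ++q) {
      const Sub& sb = subs[q];
      int n = (int)sb.vars.size();
      cur.assign(n, 0);
      for (int t = 0; t < n; ++t) cur[t] = y[sb.vars[t]];
      double ebase = sub_energy(sb, y);
      double ebest = ebase;
      best = cur;
      std::vector<int> a(n, 0);
      bool done = false;
      while (!done) {
        for (int t = 0; t < n; ++t) y[sb.vars[t]] = a[t];
        double e = sub_energy(sb, y);
        if (e < ebest - EPS) { ebest = e; best = a; }
        int t = n - 1;
        while (t >= 0) {
          if (++a[t] < K) break;
          a[t] = 0; --t;
        }
        if (t < 0) done = true;
      }
      for (int t = 0; t < n; ++t) y[sb.vars[t]] = best[t];
      if (best != cur) { any = true; icm(y); }
    }
    return any;
  }

  // one pass of whole-region relabel moves: each connected component of
  // equally labeled variables is tried at every other label (swap-move
  // style); reaches coherent module relabelings that small subset flips
  // cannot. Returns true when an improving move was applied.
  bool relabel_pass(std::vector<int>& y) const {
    bool any = false;
    std::vector<char> visited(nvar, 0);
    std::vector<int> comp, queue, cfs, sqs;
    for (int v0 = 0; v0 < nvar; ++v0) {
      if (visited[v0]) continue;
      int lab = y[v0];
      comp.clear(); queue.clear();
      queue.push_back(v0); visited[v0] = 1;
      while (!queue.empty()) {
        int v = queue.back(); queue.pop_back();
        comp.push_back(v);
        for (size_t a = 0; a < vadj[v].size(); ++a) {
          int w = vadj[v][a];
          if (!visited[w] && y[w] == lab) { visited[w] = 1; queue.push_back(w); }
        }
      }
      // factors touched by the component
      cfs.clear(); sqs.clear();
      for (size_t t = 0; t < comp.size(); ++t) {
        int i = comp[t] / S, s = comp[t] % S;
        for (size_t c = 0; c < node_cliques[i].size(); ++c)
          cfs.push_back(node_cliques[i][c] * S + s);
        if (s > 0) sqs.push_back(i * S + s);
        if (s < S - 1) sqs.push_back(i * S + s + 1);
      }
      std::sort(cfs.begin(), cfs.end());
      cfs.erase(std::unique(cfs.begin(), cfs.end()), cfs.end());
      std::sort(sqs.begin(), sqs.end());
      sqs.erase(std::unique(sqs.begin(), sqs.end()), sqs.end());
      auto comp_energy = [&](const std::vector<int>& yy) {
        double e = 0.0;
        for (size_t t = 0; t < comp.size(); ++t)
          e += eobs[comp[t] * K + yy[comp[t]]];
        for (size_t t = 0; t < cfs.size(); ++t)
          e += clique_energy(cfs[t] / S, cfs[t] % S, yy);
        for (size_t t = 0; t < sqs.size(); ++t)
          e += seq_energy(sqs[t] / S, sqs[t] % S, yy);
        return e;
      };
      double ebase = comp_energy(y);
      int bestk = lab;
      double ebest = ebase;
      for (int k = 0; k < K; ++k) {
        if (k == lab) continue;
        for (size_t t = 0; t < comp.size(); ++t) y[comp[t]] = k;
        double e = comp_energy(y);
        if (e < ebest - EPS) { ebest = e; bestk = k; }
      }
      for (size_t t = 0; t < comp.size(); ++t) y[comp[t]] = bestk;
      if (bestk != lab) { any = true; icm(y); }
    }
    return any;
  }

  void local_search(std::vector<int>& y) const {
    icm(y);
    int guard = 0;
    while (++guard < 1000) {
      bool moved = flip_pass(y);
      moved = relabel_pass(y) || moved;
      if (!moved) break;
    }
  }

  void obs_init(std::vector<int>& y) const {
    y.assign(nvar, 0);
    int mid = (K - 1) / 2;
    for (int v = 0; v < nvar; ++v) {
      const double* e = &eobs[v * K];
      bool measured = false;
      int bk = mid;
      double be = 0.0;
      for (int k = 0; k < K; ++k) {
        if (e[k] != 0.0) measured = true;
        if (k == 0 || e[k] < be - EPS) { be = e[k]; bk = k; }
      }
      y[v] = measured ? bk : mid;
    }
  }

  // deterministic multi-start: the observation-seeded basin plus one basin
  // per uniform labeling (the latter make the strong-smoothing limit exact
  // and escape the uniform trap at intermediate lambda1); best energy wins,
  // ties to the earlier start
  void solve_local(std::vector<int>& y) const {
    obs_init(y);
    local_search(y);
    double ebest = full_energy(y);
    std::vector<int> u(nvar);
    for (int k = 0; k < K; ++k) {
      std::fill(u.begin(), u.end(), k);
      local_search(u);
      double e = full_energy(u);
      if (e < ebest - EPS) { ebest = e; y = u; }
    }
  }

  void solve_exact(std::vector<int>& y) const {
    std::vector<int> a(nvar, 0);
    y = a;
    double ebest = full_energy(a);
    bool done = false;
    while (!done) {
      int t = nvar - 1;
      while (t >= 0) {
        if (++a[t] < K) break;
        a[t] = 0; --t;
      }
      if (t < 0) { done = true; break; }
      double e = full_energy(a);
      if (e < ebest - EPS) { ebest = e; y = a; }
    }
  }

  bool exact_feasible() const {
    double conf = 1.0;
    for (int v = 0; v < nvar; ++v) {
      conf *= K;
      if (conf > 262144.0) return false;  // 2^18 configurations
    }
    return true;
  }

  void solve(std::vector<int>& y, const std::string& method) const {
    if (method == "exact" || (method == "auto" && exact_feasible()))
      solve_exact(y);
    else
      solve_local(y);
  }
};

static void build_structure(Problem& P, const List& cliques,
                            const List& node_cliques,
                            const IntegerMatrix& edges, int M, int S, int K,
                            int max_flip) {
  P.M = M; P.S = S; P.K = K; P.nvar = M * S;
  P.cliques.resize(cliques.size());
  for (int c = 0; c < cliques.size(); ++c) {
    IntegerVector cc = cliques[c];
    P.cliques[c].assign(cc.begin(), cc.end());
  }
  P.node_cliques.resize(node_cliques.size());
  for (int i = 0; i < node_cliques.size(); ++i) {
    IntegerVector nc = node_cliques[i];
    P.node_cliques[i].assign(nc.begin(), nc.end());
  }
  P.ea.resize(edges.nrow());
  P.eb.resize(edges.nrow());
  for (int e = 0; e < edges.nrow(); ++e) {
    P.ea[e] = edges(e, 0);
    P.eb[e] = edges(e, 1);
  }

  // variable adjacency (within-frame edges + sequence links), then connected
  // subsets of size 2..max_flip enumerated uniquely (members >= seed, grown
  // depth-first); factor lists cached per subset
  if (max_flip < 2) max_flip = 1;
  std::vector<std::vector<int>>& adj = P.vadj;
  adj.assign(P.nvar, std::vector<int>());
  for (size_t e = 0; e < P.ea.size(); ++e)
    for (int s = 0; s < S; ++s) {
      adj[P.vid(P.ea[e], s)].push_back(P.vid(P.eb[e], s));
      adj[P.vid(P.eb[e], s)].push_back(P.vid(P.ea[e], s));
    }
  for (int i = 0; i < M; ++i)
    for (int s = 1; s < S; ++s) {
      adj[P.vid(i, s - 1)].push_back(P.vid(i, s));
      adj[P.vid(i, s)].push_back(P.vid(i, s - 1));
    }

  std::vector<int> stack;
  std::function<void(int)> grow = [&](int seed) {
    if ((int)stack.size() >= 2) {
      Problem::Sub sb;
      sb.vars = stack;
      std::sort(sb.vars.begin(), sb.vars.end());
      // touched clique-frame factors
      for (size_t t = 0; t < sb.vars.size(); ++t) {
        int i = sb.vars[t] / S, s = sb.vars[t] % S;
        for (size_t c = 0; c < P.node_cliques[i].size(); ++c) {
          int cf = P.node_cliques[i][c] * S + s;
          if (std::find(sb.cfs.begin(), sb.cfs.end(), cf) == sb.cfs.end())
            sb.cfs.push_back(cf);
        }
        if (s > 0) {
          int b = i * S + s;
          if (std::find(sb.sqs.begin(), sb.sqs.end(), b) == sb.sqs.end())
            sb.sqs.push_back(b);
        }
        if (s < S - 1) {
          int b = i * S + s + 1;
          if (std::find(sb.sqs.begin(), sb.sqs.end(), b) == sb.sqs.end())
            sb.sqs.push_back(b);
        }
      }
      P.subs.push_back(sb);
    }
    if ((int)stack.size() >= max_flip) return;
    // candidate extensions: neighbors of current subset, id > seed, not present
    std::vector<int> cand;
    for (size_t t = 0; t < stack.size(); ++t)
      for (size_t a = 0; a < adj[stack[t]].size(); ++a) {
        int w = adj[stack[t]][a];
        if (w <= seed) continue;
        if (std::find(stack.begin(), stack.end(), w) != stack.end()) continue;
        if (std::find(cand.begin(), cand.end(), w) != cand.end()) continue;
        cand.push_back(w);
      }
    std::sort(cand.begin(), cand.end());
    for (size_t t = 0; t < cand.size(); ++t) {
      // avoid duplicates: only extend with w greater than the largest var
      // already chosen after the seed? (standard ESU-style uniqueness needs
      // care; accept possible duplicates for tiny max_flip -- filtered below)
      stack.push_back(cand[t]);
      grow(seed);
      stack.pop_back();
    }
  };
  if (max_flip >= 2) {
    for (int v = 0; v < P.nvar; ++v) {
      stack.clear();
      stack.push_back(v);
      grow(v);
    }
    // dedupe subsets (the simple grower can emit one subset twice)
    std::sort(P.subs.begin(), P.subs.end(),
              [](const Problem::Sub& a, const Problem::Sub& b) {
                return a.vars < b.vars;
              });
    P.subs.erase(std::unique(P.subs.begin(), P.subs.end(),
                             [](const Problem::Sub& a, const Problem::Sub& b) {
                               return a.vars == b.vars;
                             }),
                 P.subs.end());
  }
}

static void build_eobs(Problem& P, const NumericMatrix& x,
                       const NumericVector& mu, const NumericVector& sig) {
  P.eobs.assign(P.nvar * P.K, 0.0);
  for (int i = 0; i < P.M; ++i)
    for (int s = 0; s < P.S; ++s) {
      double xv = x(i, s);
      if (ISNAN(xv)) continue;  // unmeasured: no observation factor
      for (int k = 0; k < P.K; ++k) {
        double d = xv - mu[k];
        P.eobs[P.vid(i, s) * P.K + k] = d * d / (2.0 * sig[k] * sig[k]);
      }
    }
}

// [[Rcpp::export]]
double mrf_energy_cpp(IntegerMatrix labels, NumericMatrix x, List cliques,
                      List node_cliques, IntegerMatrix edges, NumericVector mu,
                      NumericVector sig, double lambda1, double lambda2) {
  Problem P;
  build_structure(P, cliques, node_cliques, edges, x.nrow(), x.ncol(),
                  mu.size(), 1);
  build_eobs(P, x, mu, sig);
  P.l1 = lambda1; P.l2 = lambda2;
  std::vector<int> y(P.nvar);
  for (int i = 0; i < P.M; ++i)
    for (int s = 0; s < P.S; ++s) y[P.vid(i, s)] = labels(i, s);
  return P.full_energy(y);
}

// [[Rcpp::export]]
List mrf_map_cpp(NumericMatrix x, List cliques, List node_cliques,
                 IntegerMatrix edges, NumericVector mu, NumericVector sig,
                 double lambda1, double lambda2, std::string method,
                 int max_flip) {
  Problem P;
  build_structure(P, cliques, node_cliques, edges, x.nrow(), x.ncol(),
                  mu.size(), max_flip);
  build_eobs(P, x, mu, sig);
  P.l1 = lambda1; P.l2 = lambda2;
  std::vector<int> y;
  P.solve(y, method);
  IntegerMatrix lab(P.M, P.S);
  for (int i = 0; i < P.M; ++i)
    for (int s = 0; s < P.S; ++s) lab(i, s) = y[P.vid(i, s)];
  return List::create(_["labels"] = lab, _["energy"] = P.full_energy(y));
}

// Univariate lambda1 scan over B datasets (columns of xs). For each dataset
// and each grid value, MAP inference and per-edge fracture extraction;
// returns per-dataset per-edge max lambda1 and fracture counts.
// [[Rcpp::export]]
List mns_scan_cpp(NumericMatrix xs, NumericVector grid, List cliques,
                  List node_cliques, IntegerMatrix edges, NumericVector mu,
                  NumericVector sig, std::string method, int max_flip) {
  int B = xs.ncol(), E = edges.nrow();
  Problem P;
  build_structure(P, cliques, node_cliques, edges, xs.nrow(), 1, mu.size(),
                  max_flip);
  P.l2 = 0.0;
  NumericMatrix maxl1(B, E);
  IntegerMatrix nfrac(B, E);
  std::vector<int> y;
  for (int b = 0; b < B; ++b) {
    NumericMatrix xb(xs.nrow(), 1);
    for (int i = 0; i < xs.nrow(); ++i) xb(i, 0) = xs(i, b);
    build_eobs(P, xb, mu, sig);
    for (int g = 0; g < grid.size(); ++g) {
      P.l1 = grid[g];
      P.solve(y, method);
      for (int e = 0; e < E; ++e) {
        if (y[P.vid(P.ea[e], 0)] != y[P.vid(P.eb[e], 0)]) {
          nfrac(b, e) += 1;
          if (grid[g] > maxl1(b, e)) maxl1(b, e) = grid[g];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["max_lambda1"] = maxl1, _["n_fractures"] = nfrac);
}
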