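// Multi-level Louvain community detection with a weighted configuration-model
// null and resolution parameter gamma. Node visit order uses R's RNG so that
// set.seed() on the R side makes every run reproducible. Supports an initial
// partition (level-0 communities), which is what iterative fine-tuning needs.
#include <Rcpp.h>
#include <vector>
#include <utility>
#include <map>
#include <cmath>
using namespace Rcpp;

typedef std::vector<std::vector<std::pair<int, double> > > AdjList;

struct Graph {
  int n;
  AdjList adj;                  // neighbours incl. an optional self-loop entry
  std::vector<double> strength; // k_i (self-loop weight counted once)
  double m2;                    // sum_i strength_i == sum_ij A_ij
};

static Graph build_graph(int n, const std::vector<int>& ei,
                         const std::vector<int>& ej,
                         const std::vector<double>& ew) {
  Graph g;
  g.n = n;
  g.adj.assign(n, std::vector<std::pair<int, double> >());
  g.strength.assign(n, 0.0);
  for (size_t e = 0; e < ei.size(); ++e) {
    int i = ei[e], j = ej[e];
    double w = ew[e];
    if (w <= 0.0) continue;
    if (i == j) {
      g.adj[i].push_back(std::make_pair(i, w));
      g.strength[i] += w;
    } else {
      g.adj[i].push_back(std::make_pair(j, w));
      g.adj[j].push_back(std::make_pair(i, w));
      g.strength[i] += w;
      g.strength[j] += w;
    }
  }
  g.m2 = 0.0;
  for (int i = 0; i < n; ++i) g.m2 += g.strength[i];
  return g;
}

// One local-moving phase. comm is modified in place; returns true if any node
// moved. Candidate target communities are the current one, every community a
// neighbour belongs to, and (when beneficial) a fresh empty community.
static bool local_move(const Graph& g, double gamma, std::vector<int>& comm) {
  const double EPS = 1e-12;
  int n = g.n;
  std::vector<double> tot(n, 0.0);
  std::vector<int> csize(n, 0);
  for (int i = 0; i < n; ++i) {
    tot[comm[i]] += g.strength[i];
    csize[comm[i]] += 1;
  }
  std::vector<double> wlink(n, 0.0);
  std::vector<int> touched;
  touched.reserve(16);
  bool improved = false, moved = true;
  while (moved) {
    moved = false;
    IntegerVector ord = Rcpp::sample(n, n, false); // 1-based, uses R RNG
    for (int t = 0; t < n; ++t) {
      int v = ord[t] - 1;
      touched.clear();
      for (size_t a = 0; a < g.adj[v].size(); ++a) {
        int u = g.adj[v][a].first;
        if (u == v) continue;
        int c = comm[u];
        if (wlink[c] == 0.0) touched.push_back(c);
        wlink[c] += g.adj[v][a].second;
      }
      int cv = comm[v];
      tot[cv] -= g.strength[v];
      csize[cv] -= 1;
      double stay = wlink[cv] - gamma * g.strength[v] * tot[cv] / g.m2;
      int best = cv;
      double best_score = stay;
      for (size_t a = 0; a < touched.size(); ++a) {
        int c = touched[a];
        if (c == cv) continue;
        double s = wlink[c] - gamma * g.strength[v] * tot[c] / g.m2;
        if (s > best_score + EPS ||
            (best != cv && std::fabs(s - best_score) <= EPS && c < best)) {
          best_score = s;
          best = c;
        }
      }
      // a singleton community scores 0; take it if everything else is worse
      if (best_score < -EPS && csize[cv] > 0) {
        for (int c = 0; c < n; ++c) {
          if (csize[c] == 0) { best = c; best_score = 0.0; break; }
        }
      }
      comm[v] = best;
      tot[best] += g.strength[v];
      csize[best] += 1;
      if (best != cv) { moved = true; improved = true; }
      for (size_t a = 0; a < touched.size(); ++a) wlink[touched[a]] = 0.0;
    }
  }
  return improved;
}

// Relabel communities to 0..nc-1 in order of first occurrence.
static int relabel(std::vector<int>& comm) {
  std::vector<int> map(comm.size(), -1);
  int nc = 0;
  for (size_t i = 0; i < comm.size(); ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = nc++;
    comm[i] = map[comm[i]];
  }
  return nc;
}

// Collapse graph: communities become nodes, parallel edges summed, internal
// edges become self-loops carrying the full ordered-pair weight.
static void aggregate(const Graph& g, const std::vector<int>& comm, int nc,
                      std::vector<int>& ei, std::vector<int>& ej,
                      std::vector<double>& ew) {
  std::vector<std::map<int, double> > acc(nc);
  for (int v = 0; v < g.n; ++v) {
    int cv = comm[v];
    for (size_t a = 0; a < g.adj[v].size(); ++a) {
      int u = g.adj[v][a].first;
      double w = g.adj[v][a].second;
      int cu = comm[u];
      if (u == v) {
        acc[cv][cv] += w; // self-loop already carries its ordered-pair weight
      } else if (cu == cv) {
        // internal edge seen from both ends: accumulates 2w, the full
        // ordered-pair weight sum_{i,j in c} A_ij demands
        acc[cv][cv] += w;
      } else if (cu > cv) {
        acc[cv][cu] += w / 2.0; // visited from both ends; keep i<j once
      } else {
        acc[cu][cv] += w / 2.0;
      }
    }
  }
  ei.clear(); ej.clear(); ew.clear();
  for (int c = 0; c < nc; ++c) {
    for (std::map<int, double>::const_iterator it = acc[c].begin();
         it != acc[c].end(); ++it) {
      ei.push_back(c);
      ej.push_back(it->first);
      ew.push_back(it->second);
    }
  }
}

// [[Rcpp::export]]
IntegerVector louvain_cpp(int n, IntegerVector edge_i, IntegerVector edge_j,
                          NumericVector edge_w, double gamma,
                          Nullable<IntegerVector> init = R_NilValue) {
  std::vector<int> ei(edge_i.begin(), edge_i.end());
  std::vector<int> ej(edge_j.begin(), edge_j.end());
  std::vector<double> ew(edge_w.begin(), edge_w.end());
  std::vector<int> node2comm(n);
  std::vector<int> comm;
  bool use_init = init.isNotNull();
  if (use_init) {
    IntegerVector iv(init);
    comm.assign(iv.begin(), iv.end()); // 0-based labels expected
  } else {
    comm.resize(n);
    for (int i = 0; i < n; ++i) comm[i] = i;
  }
  for (int i = 0; i < n; ++i) node2comm[i] = comm[i];

  int level = 0;
  int cur_n = n;
  while (true) {
    Graph g = build_graph(cur_n, ei, ej, ew);
    if (g.m2 <= 0.0) stop("graph has no positive-weight edges");
    bool improved = local_move(g, gamma, comm);
    int nc = relabel(comm);
    // compose overall labels
    if (level == 0) {
      for (int i = 0; i < n; ++i) node2comm[i] = comm[i];
    } else {
      for (int i = 0; i < n; ++i) node2comm[i] = comm[node2comm[i]];
    }
    if (!improved && !(level == 0 && use_init)) break;
    if (nc == cur_n && !improved) break;
    if (nc == cur_n && level > 0) break;
    if (nc == cur_n && level == 0 && !use_init) break;
    // aggregate and continue
    std::vector<int> nei, nej;
    std::vector<double> new_w;
    aggregate(g, comm, nc, nei, nej, new_w);
    ei = nei; ej = nej; ew = new_w;
    cur_n = nc;
    comm.resize(cur_n);
    for (int i = 0; i < cur_n; ++i) comm[i] = i;
    ++level;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = node2comm[i] + 1;
  return out;
}
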