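// Left-right planarity test (Brandes' formulation of the de Fraysseix -
// Rosenstiehl criterion) and the greedy planar maximally filtered graph.
// The test is linear-time per call; PMFG re-tests the accepted edge set for
// every candidate insertion, which is fast enough for desk-scale networks.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct ConflictPair {
  // intervals of back-edge ids; -1 means empty endpoint
  int Llow, Lhigh, Rlow, Rhigh;
  ConflictPair() : Llow(-1), Lhigh(-1), Rlow(-1), Rhigh(-1) {}
  bool Lempty() const { return Llow == -1 && Lhigh == -1; }
  bool Rempty() const { return Rlow == -1 && Rhigh == -1; }
  void swapLR() { std::swap(Llow, Rlow); std::swap(Lhigh, Rhigh); }
};

class LRPlanarity {
public:
  int n, m;
  // undirected edges; orientation assigned in phase 1
  std::vector<int> eu, ev;        // input endpoints
  std::vector<int> esrc, etgt;    // oriented endpoints
  std::vector<char> oriented;
  std::vector<std::vector<std::pair<int,int>>> adj; // vertex -> (other, edge id)
  std::vector<int> height, parent_edge;
  std::vector<int> lowpt, lowpt2, nesting;
  std::vector<int> ref_, lowpt_edge, stack_bottom;
  std::vector<std::vector<int>> ordered_adj; // outgoing oriented edges
  std::vector<ConflictPair> S;
  bool planar_ok;

  bool run(int n_, const std::vector<int>& from, const std::vector<int>& to) {
    n = n_; m = (int)from.size();
    if (m <= 8) return true;            // smallest non-planar graphs have 9 edges
    if (n > 2 && m > 3 * n - 6) return false;
    eu = from; ev = to;
    esrc.assign(m, -1); etgt.assign(m, -1);
    oriented.assign(m, 0);
    adj.assign(n, {});
    for (int e = 0; e < m; ++e) {
      adj[eu[e]].push_back({ev[e], e});
      adj[ev[e]].push_back({eu[e], e});
    }
    height.assign(n, -1); parent_edge.assign(n, -1);
    lowpt.assign(m, 0); lowpt2.assign(m, 0); nesting.assign(m, 0);
    std::vector<int> roots;
    for (int v = 0; v < n; ++v)
      if (height[v] == -1) { height[v] = 0; roots.push_back(v); dfs1(v); }
    ordered_adj.assign(n, {});
    for (int e = 0; e < m; ++e)
      if (oriented[e]) ordered_adj[esrc[e]].push_back(e);
    for (int v = 0; v < n; ++v)
      std::sort(ordered_adj[v].begin(), ordered_adj[v].end(),
                [&](int a, int b) {
                  if (nesting[a] != nesting[b]) return nesting[a] < nesting[b];
                  return a < b;
                });
    ref_.assign(m, -1);
    lowpt_edge.assign(m, -1);
    stack_bottom.assign(m, 0);
    S.clear();
    planar_ok = true;
    for (int r : roots) { dfs2(r); if (!planar_ok) return false; }
    return true;
  }

private:
  void dfs1(int v) {
    int e = parent_edge[v];
    for (auto& pr : adj[v]) {
      int w = pr.first, ei = pr.second;
      if (oriented[ei]) continue;
      oriented[ei] = 1; esrc[ei] = v; etgt[ei] = w;
      lowpt[ei] = height[v]; lowpt2[ei] = height[v];
      if (height[w] == -1) {           // tree edge
        parent_edge[w] = ei; height[w] = height[v] + 1;
        dfs1(w);
      } else {
        lowpt[ei] = height[w];         // back edge
      }
      nesting[ei] = 2 * lowpt[ei];
      if (lowpt2[ei] < height[v]) nesting[ei] += 1;  // chordal
      if (e != -1) {
        if (lowpt[ei] < lowpt[e]) {
          lowpt2[e] = std::min(lowpt[e], lowpt2[ei]); lowpt[e] = lowpt[ei];
        } else if (lowpt[ei] > lowpt[e]) {
          lowpt2[e] = std::min(lowpt2[e], lowpt[ei]);
        } else {
          lowpt2[e] = std::min(lowpt2[e], lowpt2[ei]);
        }
      }
    }
  }

  bool conflicting(int ilow, int ihigh, int b) const {
    return !(ilow == -1 && ihigh == -1) && lowpt[ihigh] > lowpt[b];
  }
  int lowest(const ConflictPair& P) const {
    if (P.Lempty() && P.Rempty()) return -2;  // degenerate, never dropped
    if (P.Lempty()) return lowpt[P.Rlow];
    if (P.Rempty()) return lowpt[P.Llow];
    return std::min(lowpt[P.Llow], lowpt[P.Rlow]);
  }

  void dfs2(int v) {
    int e = parent_edge[v];
    bool first = true;
    for (int ei : ordered_adj[v]) {
      if (!planar_ok) return;
      int w = etgt[ei];
      stack_bottom[ei] = (int)S.size();
      if (ei == parent_edge[w]) {      // tree edge
        dfs2(w);
        if (!planar_ok) return;
      } else {                         // back edge
        lowpt_edge[ei] = ei;
        ConflictPair P; P.Rlow = ei; P.Rhigh = ei;
        S.push_back(P);
      }
      if (lowpt[ei] < height[v]) {     // ei has a return edge
        if (first) {
          lowpt_edge[e] = lowpt_edge[ei];
        } else if (!add_constraints(ei, e)) {
          planar_ok = false; return;
        }
      }
      first = false;
    }
    if (e != -1) {
      int u = esrc[e];
      trim_back_edges(u);
      if (lowpt[e] < height[u]) {      // e has a return edge
        int hl = S.back().Lhigh, hr = S.back().Rhigh;
        if (hl != -1 && (hr == -1 || lowpt[hl] > lowpt[hr])) ref_[e] = hl;
        else ref_[e] = hr;
      }
    }
  }

  bool add_constraints(int ei, int e) {
    ConflictPair P;
    // merge return edges of ei into P.R
    for (;;) {
      ConflictPair Q = S.back(); S.pop_back();
      if (!Q.Lempty()) Q.swapLR();
      if (!Q.Lempty()) return false;   // not planar
      if (Q.Rempty()) {
        if ((int)S.size() == stack_bottom[ei]) break;
        continue;
      }
      if (lowpt[Q.Rlow] > lowpt[e]) {  // merge intervals
        if (P.Rempty()) P.Rhigh = Q.Rhigh;
        else ref_[P.Rlow] = Q.Rhigh;
        P.Rlow = Q.Rlow;
      } else {                         // align
        ref_[Q.Rlow] = lowpt_edge[e];
      }
      if ((int)S.size() == stack_bottom[ei]) break;
    }
    // merge conflicting return edges of previous siblings into P.L
    while (!S.empty() &&
           (conflicting(S.back().Llow, S.back().Lhigh, ei) ||
            conflicting(S.back().Rlow, S.back().Rhigh, ei))) {
      ConflictPair Q = S.back(); S.pop_back();
      if (conflicting(Q.Rlow, Q.Rhigh, ei)) Q.swapLR();
      if (conflicting(Q.Rlow, Q.Rhigh, ei)) return false;  // not planar
      ref_[P.Rlow] = Q.Rhigh;
      if (Q.Rlow != -1) P.Rlow = Q.Rlow;
      if (P.Lempty()) P.Lhigh = Q.Lhigh;
      else ref_[P.Llow] = Q.Lhigh;
      P.Llow = Q.Llow;
    }
    if (!(P.Lempty() && P.Rempty())) S.push_back(P);
    return true;
  }

  void trim_back_edges(int u) {
    // drop entire conflict pairs ending at the parent
    while (!S.empty() && lowest(S.back()) == height[u]) S.pop_back();
    if (!S.empty()) {
      ConflictPair P = S.back(); S.pop_back();
      while (P.Lhigh != -1 && etgt[P.Lhigh] == u) P.Lhigh = ref_[P.Lhigh];
      if (P.Lhigh == -1 && P.Llow != -1) { ref_[P.Llow] = P.Rlow; P.Llow = -1; }
      while (P.Rhigh != -1 && etgt[P.Rhigh] == u) P.Rhigh = ref_[P.Rhigh];
      if (P.Rhigh == -1 && P.Rlow != -1) { ref_[P.Rlow] = P.Llow; P.Rlow = -1; }
      S.push_back(P);
    }
  }
};

} // namespace

// [[Rcpp::export]]
bool lr_is_planar(IntegerVector from, IntegerVector to, int n) {
  LRPlanarity T;
  std::vector<int> f(from.begin(), from.end()), t(to.begin(), to.end());
  return T.run(n, f, t);
}

// Greedy PMFG: candidates must arrive pre-sorted (weight descending, ties
// broken upstream); returns a keep flag per candidate. Stops once the planar
// bound 3n-6 is reached.
// [[Rcpp::export]]
LogicalVector pmfg_filter(IntegerVector from, IntegerVector to, int n,
                          int max_edges = -1) {
  int m = from.size();
  LogicalVector keep(m, false);
  int cap = (n >= 3) ? 3 * n - 6 : (n == 2 ? 1 : 0);
  if (max_edges >= 0 && max_edges < cap) cap = max_edges;
  std::vector<int> af, at;
  af.reserve(cap); at.reserve(cap);
  LRPlanarity T;
  for (int i = 0; i < m; ++i) {
    if ((int)af.size() >= cap) break;
    af.push_back(from[i]); at.push_back(to[i]);
    if (T.run(n, af, at)) {
      keep[i] = true;
    } else {
      af.pop_back(); at.pop_back();
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return keep;
}
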