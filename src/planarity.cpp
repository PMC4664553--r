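// Left-right planarity test and planar filtered network (PFN) construction.
//
// The planarity test implements the left-right criterion (Brandes' formulation
// of the de Fraysseix / Rosenstiehl characterisation): a DFS orientation is
// computed together with lowpoints and a nesting order, then return edges are
// partitioned into left/right constraint intervals on a stack of conflict
// pairs.  The graph is planar iff no constraint forces two conflicting
// same-side intervals.  Runs in O(V + E) per call.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Interval {
  int low, high;  // edge ids, -1 = empty
  Interval() : low(-1), high(-1) {}
  Interval(int l, int h) : low(l), high(h) {}
  bool empty() const { return low == -1 && high == -1; }
};

struct ConflictPair {
  Interval L, R;
  void swap_sides() { std::swap(L, R); }
};

class LRPlanarity {
public:
  // edges: m x 2 array of 0-based endpoints, simple undirected graph
  LRPlanarity(const std::vector<int>& eu, const std::vector<int>& ev, int n)
      : n_(n), m_((int)eu.size()), eu_(eu), ev_(ev) {}

  bool run() {
    if (n_ <= 2 || m_ == 0) return true;
    if (m_ > 3 * n_ - 6) return false;  // Euler bound
    adj_.assign(n_, {});
    for (int k = 0; k < m_; ++k) {
      adj_[eu_[k]].push_back(k);
      adj_[ev_[k]].push_back(k);
    }
    height_.assign(n_, -1);
    parent_edge_.assign(n_, -1);
    oriented_.assign(m_, false);
    src_.assign(m_, -1);
    dst_.assign(m_, -1);
    lowpt_.assign(m_, 0);
    lowpt2_.assign(m_, 0);
    nesting_.assign(m_, 0);
    // orientation phase (iterative DFS, robust to deep trees)
    for (int v = 0; v < n_; ++v)
      if (height_[v] == -1) { height_[v] = 0; dfs1(v); }
    // sort outgoing edges by nesting depth
    ordered_.assign(n_, {});
    for (int k = 0; k < m_; ++k) ordered_[src_[k]].push_back(k);
    for (int v = 0; v < n_; ++v)
      std::sort(ordered_[v].begin(), ordered_[v].end(),
                [&](int a, int b) { return nesting_[a] < nesting_[b]; });
    // testing phase
    ref_.assign(m_, -1);
    lowpt_edge_.assign(m_, -1);
    stack_bottom_.assign(m_, 0);
    S_.clear();
    for (int v = 0; v < n_; ++v)
      if (parent_edge_[v] == -1 && height_[v] == 0 && !visited2(v)) {
        if (!dfs2(v)) return false;
      }
    return true;
  }

private:
  int n_, m_;
  const std::vector<int>&eu_, &ev_;
  std::vector<std::vector<int>> adj_, ordered_;
  std::vector<int> height_, parent_edge_, src_, dst_, lowpt_, lowpt2_,
      nesting_, ref_, lowpt_edge_, stack_bottom_;
  std::vector<char> oriented_;
  std::vector<ConflictPair> S_;
  std::vector<char> done2_;

  bool visited2(int v) {
    if (done2_.empty()) done2_.assign(n_, 0);
    return done2_[v] != 0;
  }

  int other(int k, int v) const { return eu_[k] == v ? ev_[k] : eu_[k]; }

  void dfs1(int root) {
    // explicit stack: (vertex, adjacency cursor)
    std::vector<std::pair<int, size_t>> stk;
    stk.push_back({root, 0});
    while (!stk.empty()) {
      int v = stk.back().first;
      size_t& cur = stk.back().second;
      if (cur < adj_[v].size()) {
        int k = adj_[v][cur++];
        if (oriented_[k]) continue;
        oriented_[k] = true;
        src_[k] = v;
        dst_[k] = other(k, v);
        int w = dst_[k];
        lowpt_[k] = height_[v];
        lowpt2_[k] = height_[v];
        if (height_[w] == -1) {  // tree edge
          parent_edge_[w] = k;
          height_[w] = height_[v] + 1;
          stk.push_back({w, 0});
        } else {  // back edge
          lowpt_[k] = height_[w];
          finish_edge(k, v);
        }
      } else {
        stk.pop_back();
        // finish the tree edge into v (lowpt now final)
        int k = parent_edge_[v];
        if (k != -1) finish_edge(k, src_[k]);
      }
    }
  }

  void finish_edge(int k, int v) {
    // nesting depth and lowpoint propagation to the parent edge of v
    nesting_[k] = 2 * lowpt_[k];
    if (lowpt2_[k] < height_[v]) nesting_[k] += 1;  // chordal
    int e = parent_edge_[v];
    if (e != -1) {
      if (lowpt_[k] < lowpt_[e]) {
        lowpt2_[e] = std::min(lowpt_[e], lowpt2_[k]);
        lowpt_[e] = lowpt_[k];
      } else if (lowpt_[k] > lowpt_[e]) {
        lowpt2_[e] = std::min(lowpt2_[e], lowpt_[k]);
      } else {
        lowpt2_[e] = std::min(lowpt2_[e], lowpt2_[k]);
      }
    }
  }

  bool conflicting(const Interval& I, int b) const {
    return !I.empty() && lowpt_[I.high] > lowpt_[b];
  }

  int lowest(const ConflictPair& P) const {
    if (P.L.empty()) return lowpt_[P.R.low];
    if (P.R.empty()) return lowpt_[P.L.low];
    return std::min(lowpt_[P.L.low], lowpt_[P.R.low]);
  }

  bool add_constraints(int ei, int e) {
    ConflictPair P;
    // merge return edges of ei into P.R
    do {
      ConflictPair Q = S_.back();
      S_.pop_back();
      if (!Q.L.empty()) Q.swap_sides();
      if (!Q.L.empty()) return false;  // not planar
      if (lowpt_[Q.R.low] > lowpt_[e]) {  // merge intervals
        if (P.R.empty())
          P.R.high = Q.R.high;
        else
          ref_[P.R.low] = Q.R.high;
        P.R.low = Q.R.low;
      } else {  // align
        ref_[Q.R.low] = lowpt_edge_[e];
      }
    } while ((int)S_.size() > stack_bottom_[ei]);
    // merge conflicting return edges of earlier siblings into P.L
    while (conflicting(S_.back().L, ei) || conflicting(S_.back().R, ei)) {
      ConflictPair Q = S_.back();
      S_.pop_back();
      if (conflicting(Q.R, ei)) Q.swap_sides();
      if (conflicting(Q.R, ei)) return false;  // not planar
      // merge interval below lowpt(ei) into P.R
      if (P.R.low != -1) ref_[P.R.low] = Q.R.high;
      if (Q.R.low != -1) P.R.low = Q.R.low;
      if (P.L.empty())
        P.L.high = Q.L.high;
      else
        ref_[P.L.low] = Q.L.high;
      P.L.low = Q.L.low;
    }
    if (!(P.L.empty() && P.R.empty())) S_.push_back(P);
    return true;
  }

  void trim_back_edges(int u) {
    // drop entire conflict pairs returning only to u
    while (!S_.empty() && lowest(S_.back()) == height_[u]) S_.pop_back();
    if (!S_.empty()) {
      ConflictPair P = S_.back();
      S_.pop_back();
      while (P.L.high != -1 && dst_[P.L.high] == u) P.L.high = ref_[P.L.high];
      if (P.L.high == -1 && P.L.low != -1) {
        ref_[P.L.low] = P.R.low;
        P.L.low = -1;
      }
      while (P.R.high != -1 && dst_[P.R.high] == u) P.R.high = ref_[P.R.high];
      if (P.R.high == -1 && P.R.low != -1) {
        ref_[P.R.low] = P.L.low;
        P.R.low = -1;
      }
      S_.push_back(P);
    }
  }

  // testing DFS; explicit stack mirrors the recursive formulation
  struct Frame {
    int v;
    size_t cur;     // index into ordered_[v]
    int pending;    // edge awaiting post-recursion constraint handling, -1 none
  };

  bool dfs2(int root) {
    done2_[root] = 1;
    std::vector<Frame> stk;
    stk.push_back({root, 0, -1});
    while (!stk.empty()) {
      Frame& f = stk.back();
      int v = f.v;
      int e = parent_edge_[v];
      if (f.pending != -1) {
        int ei = f.pending;
        f.pending = -1;
        if (lowpt_[ei] < height_[v]) {  // ei has a return edge
          if (ei == ordered_[v][0]) {
            lowpt_edge_[e] = lowpt_edge_[ei];
          } else if (!add_constraints(ei, e)) {
            return false;
          }
        }
      }
      if (f.cur < ordered_[v].size()) {
        int ei = ordered_[v][f.cur++];
        stack_bottom_[ei] = (int)S_.size();
        int w = dst_[ei];
        if (ei == parent_edge_[w]) {  // tree edge: recurse, then handle ei
          f.pending = ei;
          done2_[w] = 1;
          stk.push_back({w, 0, -1});
        } else {  // back edge
          lowpt_edge_[ei] = ei;
          ConflictPair Q;
          Q.R = Interval(ei, ei);
          S_.push_back(Q);
          f.pending = ei;
        }
      } else {
        // leave v
        if (e != -1) {
          int u = src_[e];
          trim_back_edges(u);
          if (lowpt_[e] < height_[u]) {  // e has return edges
            int hl = S_.back().L.high, hr = S_.back().R.high;
            if (hl != -1 && (hr == -1 || lowpt_[hl] > lowpt_[hr]))
              ref_[e] = hl;
            else
              ref_[e] = hr;
          }
        }
        stk.pop_back();
      }
    }
    return true;
  }
};

bool lr_planar(const std::vector<int>& eu, const std::vector<int>& ev, int n) {
  LRPlanarity T(eu, ev, n);
  return T.run();
}

// ---- union-find -------------------------------------------------------

struct DSU {
  std::vector<int> parent, size_, edges_;
  explicit DSU(int n) : parent(n), size_(n, 1), edges_(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size_[a] < size_[b]) std::swap(a, b);
    parent[b] = a;
    size_[a] += size_[b];
    edges_[a] += edges_[b];
  }
};

// Helper shared by the fast constructor: test whether the component of u
// (== component of v) stays planar after adding edge (u, v).
class ComponentTester {
public:
  ComponentTester(int n) : n_(n), adj_(n), mark_(n, -1), stamp_(0) {}

  void add_edge(int u, int v) {
    adj_[u].push_back(v);
    adj_[v].push_back(u);
  }

  bool planar_with(int u, int v) {
    // collect component containing u via BFS
    ++stamp_;
    std::vector<int> comp;
    comp.push_back(u);
    mark_[u] = stamp_;
    std::vector<int> local(n_, -1);
    for (size_t h = 0; h < comp.size(); ++h) {
      int x = comp[h];
      for (int y : adj_[x])
        if (mark_[y] != stamp_) { mark_[y] = stamp_; comp.push_back(y); }
    }
    for (size_t i = 0; i < comp.size(); ++i) local[comp[i]] = (int)i;
    std::vector<int> eu, ev;
    for (int x : comp)
      for (int y : adj_[x])
        if (x < y) { eu.push_back(local[x]); ev.push_back(local[y]); }
    eu.push_back(local[u]);
    ev.push_back(local[v]);
    return lr_planar(eu, ev, (int)comp.size());
  }

private:
  int n_;
  std::vector<std::vector<int>> adj_;
  std::vector<int> mark_;
  int stamp_;
};

}  // namespace

// [[Rcpp::export(name = ".lr_planar_cpp")]]
bool lr_planar_cpp(IntegerMatrix edges, int n_nodes) {
  int m = edges.nrow();
  std::vector<int> eu(m), ev(m);
  for (int k = 0; k < m; ++k) { eu[k] = edges(k, 0); ev[k] = edges(k, 1); }
  return lr_planar(eu, ev, n_nodes);
}

// Plain serial PMFG: test every pair in rank order against the full current
// graph, no shortcuts.  Used as the reference construction.
// [[Rcpp::export(name = ".pmfg_serial_cpp")]]
IntegerVector pmfg_serial_cpp(IntegerMatrix pairs, int n_nodes) {
  int m = pairs.nrow();
  std::vector<int> eu, ev;
  std::vector<int> accepted;
  int emax = n_nodes >= 3 ? 3 * (n_nodes - 2) : (n_nodes == 2 ? 1 : 0);
  for (int k = 0; k < m; ++k) {
    if ((int)eu.size() >= emax) break;
    int u = pairs(k, 0), v = pairs(k, 1);
    eu.push_back(u);
    ev.push_back(v);
    if (lr_planar(eu, ev, n_nodes)) {
      accepted.push_back(k + 1);  // 1-based index into the pair list
    } else {
      eu.pop_back();
      ev.pop_back();
    }
  }
  return wrap(accepted);
}

// Screen candidate pairs against a fixed planar graph: candidate i passes iff
// graph + candidate_i is planar (each candidate tested independently).
// [[Rcpp::export(name = ".pcp_screen_cpp")]]
LogicalVector pcp_screen_cpp(IntegerMatrix graph_edges, int n_nodes,
                             IntegerMatrix candidates) {
  ComponentTester T(n_nodes);
  DSU dsu(n_nodes);
  int mg = graph_edges.nrow();
  for (int k = 0; k < mg; ++k) {
    int u = graph_edges(k, 0), v = graph_edges(k, 1);
    T.add_edge(u, v);
    dsu.unite(u, v);
    dsu.edges_[dsu.find(u)] += 1;
  }
  int mc = candidates.nrow();
  LogicalVector keep(mc);
  for (int k = 0; k < mc; ++k) {
    int u = candidates(k, 0), v = candidates(k, 1);
    if (dsu.find(u) != dsu.find(v)) {
      keep[k] = true;  // bridges two planar components
    } else {
      int r = dsu.find(u);
      if (dsu.size_[r] >= 3 && dsu.edges_[r] >= 3 * (dsu.size_[r] - 2))
        keep[k] = false;  // component already maximal planar
      else
        keep[k] = T.planar_with(u, v);
    }
  }
  return keep;
}

// Full PFN constructor: serial phase with component-wise planarity tests,
// optional batched screening (PCP) once the sliding-window acceptance rate
// drops below `pcp_trigger`, and early-termination rules.
//   termination codes: 0 exhausted/maximal, 1 edge-count cap, 2 reject budget
// [[Rcpp::export(name = ".fpfnc_cpp")]]
List fpfnc_cpp(IntegerMatrix pairs, int n_nodes, int max_edges,
               double reject_budget, bool use_pcp, int batch_size,
               double pcp_trigger, int window) {
  int m = pairs.nrow();
  DSU dsu(n_nodes);
  ComponentTester T(n_nodes);
  std::vector<int> accepted;
  long long n_rejected = 0, n_tested = 0, n_accepted = 0;
  int termination = 0;
  int n_batches = 0;
  // sliding window over the last `window` tested pairs
  std::vector<char> win(window > 0 ? window : 1, 0);
  int win_pos = 0, win_fill = 0, win_acc = 0;
  bool pcp_active = false;

  auto decide = [&](int u, int v) -> bool {
    // exact serial decision for the next pair, updating the graph
    bool ok;
    if (dsu.find(u) != dsu.find(v)) {
      ok = true;
    } else {
      int r = dsu.find(u);
      if (dsu.size_[r] >= 3 && dsu.edges_[r] >= 3 * (dsu.size_[r] - 2))
        ok = false;
      else
        ok = T.planar_with(u, v);
    }
    ++n_tested;
    if (ok) {
      T.add_edge(u, v);
      dsu.unite(u, v);
      dsu.edges_[dsu.find(u)] += 1;
      ++n_accepted;
    } else {
      ++n_rejected;
    }
    // update window
    if (window > 0) {
      if (win_fill == window) win_acc -= win[win_pos];
      else ++win_fill;
      win[win_pos] = ok ? 1 : 0;
      win_acc += win[win_pos];
      win_pos = (win_pos + 1) % window;
    }
    return ok;
  };

  auto terminated = [&]() -> bool {
    if (max_edges > 0 && (int)accepted.size() >= max_edges) {
      termination = 1;
      return true;
    }
    if (reject_budget > 0 && (double)n_rejected >= reject_budget) {
      termination = 2;
      return true;
    }
    return false;
  };

  int k = 0;
  while (k < m) {
    if (use_pcp && !pcp_active && win_fill == window &&
        (double)win_acc / (double)window < pcp_trigger) {
      pcp_active = true;
    }
    if (!pcp_active) {
      int u = pairs(k, 0), v = pairs(k, 1);
      if (decide(u, v)) accepted.push_back(k + 1);
      ++k;
      if (terminated()) break;
    } else {
      // screen the next batch against the frozen graph G_o, then walk the
      // batch in rank order applying the exact serial decision
      int hi = std::min(m, k + batch_size);
      ++n_batches;
      std::vector<char> pass(hi - k, 0);
      {
        // snapshot screening: candidates tested independently against G_o
        for (int j = k; j < hi; ++j) {
          int u = pairs(j, 0), v = pairs(j, 1);
          if (dsu.find(u) != dsu.find(v)) {
            pass[j - k] = 1;
          } else {
            int r = dsu.find(u);
            if (dsu.size_[r] >= 3 && dsu.edges_[r] >= 3 * (dsu.size_[r] - 2))
              pass[j - k] = 0;
            else
              pass[j - k] = T.planar_with(u, v) ? 1 : 0;
          }
        }
      }
      bool stop = false;
      for (int j = k; j < hi; ++j) {
        if (!pass[j - k]) {
          // G_o + ij nonplanar and G_o subset of current graph: certain reject
          ++n_tested;
          ++n_rejected;
          if (window > 0) {
            if (win_fill == window) win_acc -= win[win_pos];
            else ++win_fill;
            win[win_pos] = 0;
            win_pos = (win_pos + 1) % window;
          }
        } else {
          if (decide(pairs(j, 0), pairs(j, 1))) accepted.push_back(j + 1);
        }
        if (terminated()) { k = j + 1; stop = true; break; }
      }
      if (stop) break;
      k = hi;
    }
  }
  return List::create(
      _["accepted"] = wrap(accepted), _["n_tested"] = (double)n_tested,
      _["n_accepted"] = (double)n_accepted, _["n_rejected"] = (double)n_rejected,
      _["termination"] = termination, _["n_batches"] = n_batches,
      _["pcp_activated"] = pcp_active);
}
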