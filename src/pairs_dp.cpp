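#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Maximum edge-disjoint contrasting pairs on a rooted tree.
//
// Tip types encode joint (gene, trait) state:
//   1 = (1,1), 2 = (0,0)  -- class A, a pair 1-2 is "supporting"
//   3 = (1,0), 4 = (0,1)  -- class B, a pair 3-4 is "opposing"
// A pairing is a set of tip pairs, each contrasting in both states, whose
// tip-to-tip paths are edge-disjoint.  Edge-disjointness is equivalent to:
// at most one unpaired ("exposed") tip may cross any edge, and pairs formed
// at a node consume one exposed tip from each of two different children.
//
// Per node we run a DP over the signed counts of unmatched exposed tips
// (u1 = #type1 - #type2 held at the node, u2 = #type3 - #type4; at any time
// only one sign per class can be non-zero because contrasting exposures are
// matched greedily, which is optimal since same-type tips are
// interchangeable).  Value = lexicographic (pairs, +/- supporting).

struct Cell { int pairs; int supp; };
static const int NEG = INT_MIN / 4;

struct Grid {
  int lo1, hi1, lo2, hi2;           // inclusive u-ranges
  std::vector<Cell> v;
  Grid(int l1, int h1, int l2, int h2)
      : lo1(l1), hi1(h1), lo2(l2), hi2(h2),
        v((h1 - l1 + 1) * (h2 - l2 + 1), Cell{NEG, 0}) {}
  Cell &at(int u1, int u2) {
    return v[(u1 - lo1) * (hi2 - lo2 + 1) + (u2 - lo2)];
  }
};

// lexicographic improvement; sgn = +1 maximizes supp, -1 minimizes it
static inline bool better(const Cell &a, const Cell &b, int sgn) {
  if (a.pairs != b.pairs) return a.pairs > b.pairs;
  return sgn * a.supp > sgn * b.supp;
}

struct Menu {            // node summary: best value per upward exposure
  Cell e[5];             // index 0 = none, 1..4 = exposed tip type
  Menu() { for (int i = 0; i < 5; ++i) e[i] = Cell{NEG, 0}; }
};

// counts of tip types in each subtree, to bound the DP grids
static void subtree_counts(int node, const std::vector<std::vector<int> > &kids,
                           const std::vector<int> &tip_type, int ntip,
                           std::vector<std::array<int, 4> > &cnt) {
  if (node <= ntip) {
    int t = tip_type[node - 1];
    if (t >= 1) cnt[node - 1][t - 1] = 1;
    return;
  }
  for (int c : kids[node - 1]) {
    subtree_counts(c, kids, tip_type, ntip, cnt);
    for (int k = 0; k < 4; ++k) cnt[node - 1][k] += cnt[c - 1][k];
  }
}

static Menu solve(int node, const std::vector<std::vector<int> > &kids,
                  const std::vector<int> &tip_type, int ntip,
                  const std::vector<std::array<int, 4> > &cnt, int sgn) {
  Menu m;
  if (node <= ntip) {
    int t = tip_type[node - 1];
    m.e[0] = Cell{0, 0};
    if (t >= 1) m.e[t] = Cell{0, 0};
    return m;
  }
  // sequential combination of children over exposed-count state
  const std::array<int, 4> &c = cnt[node - 1];
  Grid g(-c[1], c[0], -c[3], c[2]);
  g.at(0, 0) = Cell{0, 0};
  int lo1 = 0, hi1 = 0, lo2 = 0, hi2 = 0; // reachable box so far
  for (int ci : kids[node - 1]) {
    Menu cm = solve(ci, kids, tip_type, ntip, cnt, sgn);
    const std::array<int, 4> &cc = cnt[ci - 1];
    int nlo1 = std::max(g.lo1, lo1 - cc[1]), nhi1 = std::min(g.hi1, hi1 + cc[0]);
    int nlo2 = std::max(g.lo2, lo2 - cc[3]), nhi2 = std::min(g.hi2, hi2 + cc[2]);
    Grid ng(g.lo1, g.hi1, g.lo2, g.hi2);
    for (int u1 = lo1; u1 <= hi1; ++u1)
      for (int u2 = lo2; u2 <= hi2; ++u2) {
        Cell cur = g.at(u1, u2);
        if (cur.pairs == NEG) continue;
        for (int e = 0; e < 5; ++e) {
          Cell opt = cm.e[e];
          if (opt.pairs == NEG) continue;
          int p = cur.pairs + opt.pairs, s = cur.supp + opt.supp;
          int v1 = u1, v2 = u2;
          if (e == 1) { if (u1 < 0) { ++p; ++s; } ++v1; }
          else if (e == 2) { if (u1 > 0) { ++p; ++s; } --v1; }
          else if (e == 3) { if (u2 < 0) ++p; ++v2; }
          else if (e == 4) { if (u2 > 0) ++p; --v2; }
          Cell cand{p, s};
          Cell &tgt = ng.at(v1, v2);
          if (tgt.pairs == NEG || better(cand, tgt, sgn)) tgt = cand;
        }
      }
    g.v.swap(ng.v);
    lo1 = nlo1; hi1 = nhi1; lo2 = nlo2; hi2 = nhi2;
  }
  // upward menu: discard all but at most one unmatched exposure
  for (int u1 = lo1; u1 <= hi1; ++u1)
    for (int u2 = lo2; u2 <= hi2; ++u2) {
      Cell cur = g.at(u1, u2);
      if (cur.pairs == NEG) continue;
      if (m.e[0].pairs == NEG || better(cur, m.e[0], sgn)) m.e[0] = cur;
      int ex[5] = {0, u1 > 0, u1 < 0, u2 > 0, u2 < 0};
      for (int t = 1; t <= 4; ++t)
        if (ex[t] && (m.e[t].pairs == NEG || better(cur, m.e[t], sgn)))
          m.e[t] = cur;
    }
  return m;
}

static IntegerVector dp_once(const std::vector<std::vector<int> > &kids,
                             int root, int ntip, int nnode_total,
                             const std::vector<int> &tip_type) {
  std::vector<std::array<int, 4> > cnt(nnode_total, {0, 0, 0, 0});
  subtree_counts(root, kids, tip_type, ntip, cnt);
  Menu mx = solve(root, kids, tip_type, ntip, cnt, +1);
  Menu mn = solve(root, kids, tip_type, ntip, cnt, -1);
  return IntegerVector::create(mx.e[0].pairs, mx.e[0].supp, mn.e[0].supp);
}

// [[Rcpp::export(name = ".pairs_dp_cpp")]]
IntegerVector pairs_dp_cpp(IntegerMatrix edge, int ntip,
                           IntegerVector tip_type) {
  int nnode_total = ntip + edge.nrow() + 1; // upper bound on node ids
  std::vector<std::vector<int> > kids(nnode_total);
  int maxid = 0;
  for (int i = 0; i < edge.nrow(); ++i) {
    kids[edge(i, 0) - 1].push_back(edge(i, 1));
    maxid = std::max(maxid, std::max(edge(i, 0), edge(i, 1)));
  }
  int root = ntip + 1;
  std::vector<int> tt(tip_type.begin(), tip_type.end());
  return dp_once(kids, root, ntip, maxid, tt);
}

// Batch version over many tip-type assignments (columns), e.g. label
// permutations; returns the maximum-supporting count s_max per column.
// [[Rcpp::export(name = ".pairs_dp_batch_cpp")]]
IntegerVector pairs_dp_batch_cpp(IntegerMatrix edge, int ntip,
                                 IntegerMatrix tip_types) {
  int nnode_total = ntip + edge.nrow() + 1;
  std::vector<std::vector<int> > kids(nnode_total);
  int maxid = 0;
  for (int i = 0; i < edge.nrow(); ++i) {
    kids[edge(i, 0) - 1].push_back(edge(i, 1));
    maxid = std::max(maxid, std::max(edge(i, 0), edge(i, 1)));
  }
  int root = ntip + 1;
  IntegerVector out(tip_types.ncol());
  for (int j = 0; j < tip_types.ncol(); ++j) {
    std::vector<int> tt(ntip);
    for (int i = 0; i < ntip; ++i) tt[i] = tip_types(i, j);
    std::vector<std::array<int, 4> > cnt(maxid, {0, 0, 0, 0});
    subtree_counts(root, kids, tt, ntip, cnt);
    Menu mx = solve(root, kids, tt, ntip, cnt, +1);
    out[j] = mx.e[0].supp;
  }
  return out;
}
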