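#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Two-sample Kolmogorov-Smirnov sup-statistic for pre-sorted samples.
// Ties are handled by evaluating the ECDF difference only after absorbing
// every occurrence of a pooled value.
// [[Rcpp::export]]
double cpp_ks_sorted(NumericVector a, NumericVector b) {
  const int na = a.size(), nb = b.size();
  int i = 0, j = 0;
  double d = 0.0;
  while (i < na || j < nb) {
    double v;
    if (i >= na) v = b[j];
    else if (j >= nb) v = a[i];
    else v = a[i] < b[j] ? a[i] : b[j];
    while (i < na && a[i] <= v) ++i;
    while (j < nb && b[j] <= v) ++j;
    double diff = std::fabs((double)i / na - (double)j / nb);
    if (diff > d) d = diff;
  }
  return d;
}

// ---- parsimony engine -----------------------------------------------------
// Trees are unrooted, nodes 1..ntip are tips, ntip+1.. are internal; the
// edge list is an arbitrary-order set of undirected edges.

typedef std::vector<std::array<int, 2> > EdgeVec;

// Fitch/Hartigan weighted score of a character matrix on one topology.
// Supports polytomies: at each internal node the cost contribution of a
// character is (number of children) - (max state-vote count).
static double fitch_score_edges(const EdgeVec &edges, int ntip,
                                const IntegerMatrix &tip,
                                const NumericVector &w) {
  const int nchar = tip.ncol();
  int nnode = ntip;
  for (size_t e = 0; e < edges.size(); ++e) {
    if (edges[e][0] > nnode) nnode = edges[e][0];
    if (edges[e][1] > nnode) nnode = edges[e][1];
  }
  // adjacency
  std::vector<std::vector<int> > adj(nnode + 1);
  for (size_t e = 0; e < edges.size(); ++e) {
    adj[edges[e][0]].push_back(edges[e][1]);
    adj[edges[e][1]].push_back(edges[e][0]);
  }
  int root = ntip + 1;
  // iterative postorder
  std::vector<int> order, stack, parent(nnode + 1, 0);
  stack.push_back(root);
  parent[root] = -1;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    order.push_back(v);
    for (size_t k = 0; k < adj[v].size(); ++k) {
      int u = adj[v][k];
      if (u != parent[v]) { parent[u] = v; stack.push_back(u); }
    }
  }
  // state sets as 2-bit masks per node per character
  std::vector<unsigned char> sets((size_t)(nnode + 1) * nchar, 0);
  double score = 0.0;
  for (int idx = (int)order.size() - 1; idx >= 0; --idx) {
    int v = order[idx];
    if (v <= ntip) {
      for (int k = 0; k < nchar; ++k)
        sets[(size_t)v * nchar + k] = tip(v - 1, k) ? 2 : 1;
      continue;
    }
    for (int k = 0; k < nchar; ++k) {
      int c0 = 0, c1 = 0, nch = 0;
      for (size_t q = 0; q < adj[v].size(); ++q) {
        int u = adj[v][q];
        if (u == parent[v]) continue;
        unsigned char s = sets[(size_t)u * nchar + k];
        if (s & 1) ++c0;
        if (s & 2) ++c1;
        ++nch;
      }
      int K = c0 > c1 ? c0 : c1;
      unsigned char s = 0;
      if (c0 == K) s |= 1;
      if (c1 == K) s |= 2;
      sets[(size_t)v * nchar + k] = s;
      score += w[k] * (nch - K);
    }
  }
  // gain-rooting convention: every character is absent at the origin, so a
  // character present in all taxa still costs one (root) gain event; any
  // other character already pays for at least one change
  for (int k = 0; k < nchar; ++k) {
    bool allone = true;
    for (int t = 1; t <= ntip && allone; ++t)
      if (!tip(t - 1, k)) allone = false;
    if (allone) score += w[k];
  }
  return score;
}

static EdgeVec mat_to_edges(const IntegerMatrix &edge) {
  EdgeVec ev(edge.nrow());
  for (int i = 0; i < edge.nrow(); ++i) {
    ev[i][0] = edge(i, 0);
    ev[i][1] = edge(i, 1);
  }
  return ev;
}

// [[Rcpp::export]]
double cpp_fitch_score(IntegerMatrix edge, int ntip, IntegerMatrix tip,
                       NumericVector w) {
  EdgeVec ev = mat_to_edges(edge);
  return fitch_score_edges(ev, ntip, tip, w);
}

// Random-order stepwise addition followed by best-improvement NNI
// hill-climbing. addOrder is a permutation of 1..ntip (1-based).
// [[Rcpp::export]]
List cpp_search(IntegerMatrix tip, NumericVector w, IntegerVector addOrder) {
  const int ntip = tip.nrow();
  if (ntip < 4) stop("need at least 4 taxa");
  EdgeVec edges;
  int nextInternal = ntip + 1;
  // star on first three taxa
  for (int k = 0; k < 3; ++k) {
    std::array<int, 2> e = { nextInternal, addOrder[k] };
    edges.push_back(e);
  }
  ++nextInternal;
  for (int k = 3; k < ntip; ++k) {
    int t = addOrder[k];
    double best = R_PosInf;
    size_t bestEdge = 0;
    for (size_t e = 0; e < edges.size(); ++e) {
      EdgeVec cand = edges;
      int u = cand[e][0], v = cand[e][1];
      cand[e][0] = u; cand[e][1] = nextInternal;
      std::array<int, 2> e1 = { nextInternal, v };
      std::array<int, 2> e2 = { nextInternal, t };
      cand.push_back(e1);
      cand.push_back(e2);
      double s = fitch_score_edges(cand, ntip, tip, w);
      if (s < best) { best = s; bestEdge = e; }
    }
    int u = edges[bestEdge][0], v = edges[bestEdge][1];
    edges[bestEdge][0] = u; edges[bestEdge][1] = nextInternal;
    std::array<int, 2> e1 = { nextInternal, v };
    std::array<int, 2> e2 = { nextInternal, t };
    edges.push_back(e1);
    edges.push_back(e2);
    ++nextInternal;
  }
  double score = fitch_score_edges(edges, ntip, tip, w);
  // NNI hill-climbing (binary tree by construction)
  bool improved = true;
  while (improved) {
    improved = false;
    double bestScore = score;
    EdgeVec bestTree;
    for (size_t e = 0; e < edges.size(); ++e) {
      int u = edges[e][0], v = edges[e][1];
      if (u <= ntip || v <= ntip) continue;
      // neighbours of u (excluding v) and of v (excluding u)
      std::vector<size_t> ue, ve;
      for (size_t f = 0; f < edges.size(); ++f) {
        if (f == e) continue;
        if (edges[f][0] == u || edges[f][1] == u) ue.push_back(f);
        if (edges[f][0] == v || edges[f][1] == v) ve.push_back(f);
      }
      for (size_t a = 0; a < ue.size(); ++a) {
        // swap subtree at ue[a] (u side) with each v-side subtree; swapping
        // with the first v neighbour and with the second are the two NNIs,
        // but one pair is redundant, so only a==0 x both, a==1 x first.
        for (size_t b = 0; b < ve.size(); ++b) {
          if (a == 1 && b == 1) continue;
          if (a == 1 && b == 0) continue;
          EdgeVec cand = edges;
          size_t fe = ue[a], ge = ve[b];
          int x = (cand[fe][0] == u) ? cand[fe][1] : cand[fe][0];
          int y = (cand[ge][0] == v) ? cand[ge][1] : cand[ge][0];
          cand[fe][0] = u; cand[fe][1] = y;
          cand[ge][0] = v; cand[ge][1] = x;
          double s = fitch_score_edges(cand, ntip, tip, w);
          if (s < bestScore) { bestScore = s; bestTree = cand; }
        }
      }
    }
    if (bestScore < score) {
      score = bestScore;
      edges = bestTree;
      improved = true;
    }
  }
  IntegerMatrix em(edges.size(), 2);
  for (size_t e = 0; e < edges.size(); ++e) {
    em(e, 0) = edges[e][0];
    em(e, 1) = edges[e][1];
  }
  return List::create(_["edge"] = em, _["score"] = score,
                      _["ntip"] = ntip);
}
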