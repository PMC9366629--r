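// Duplication-loss reconciliation core: LCA mapping of gene-tree nodes onto a
// rooted species tree, duplication labelling, path-stretch loss counting, and
// minimisation over all rootings of an unrooted gene tree.  This is the hot
// loop of the species-tree search, hence C++; a pure-R reference path lives in
// R/reconcile.R and the two are cross-checked in the test suite.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// Climb-to-equal-depth LCA on parent/depth arrays (1-based node ids, parent 0
// at the root).  Species trees here are small; no sparse table needed.
inline int sp_lca(int a, int b, const int* par, const int* dep) {
  while (dep[a - 1] > dep[b - 1]) a = par[a - 1];
  while (dep[b - 1] > dep[a - 1]) b = par[b - 1];
  while (a != b) { a = par[a - 1]; b = par[b - 1]; }
  return a;
}

struct FamGraph {
  int nnode;
  const int* adj;        // flat adjacency (1-based node ids)
  const int* adj_start;  // 1-based offsets into adj, length nnode + 1
  std::vector<int> tip_sp;  // species node per gene node (0 internal)
};

struct Scratch {
  std::vector<int> par, order, map;
  std::vector<char> isdup;
  // no clearing needed between rootings: every slot is written (par/map/isdup
  // along the DFS order) before it is read
  void ensure(int n) {
    if ((int)par.size() < n + 1) {
      par.resize(n + 1); map.resize(n + 1); isdup.resize(n + 1);
      order.reserve(n + 1);
    }
    order.clear();
  }
};

struct ScoreOut { long dup; long loss; };

// Score one rooted orientation.  For unrooted families the root is virtual,
// splitting edge (eu, ev): each endpoint is marked as the other's parent so
// the plain "children = neighbours except parent" DFS does the rest.  For
// rooted families pass root_node and eu = ev = 0.
ScoreOut score_rooting(const FamGraph& f, int root_node, int eu, int ev,
                       const int* sp_par, const int* sp_dep,
                       const int* pd, Scratch& sc) {
  sc.ensure(f.nnode);
  if (eu > 0) {
    sc.par[eu] = ev; sc.par[ev] = eu;
    sc.order.push_back(eu); sc.order.push_back(ev);
  } else {
    sc.par[root_node] = 0;
    sc.order.push_back(root_node);
  }
  for (size_t k = 0; k < sc.order.size(); ++k) {   // preorder via index queue
    int v = sc.order[k];
    for (int j = f.adj_start[v - 1] - 1; j < f.adj_start[v] - 1; ++j) {
      int w = f.adj[j];
      if (w != sc.par[v]) { sc.par[w] = v; sc.order.push_back(w); }
    }
  }
  long dup = 0, loss = 0;
  for (int i = (int)sc.order.size() - 1; i >= 0; --i) {  // postorder
    int v = sc.order[i];
    if (f.tip_sp[v] > 0) { sc.map[v] = f.tip_sp[v]; continue; }
    int m = 0; bool d = false;
    for (int j = f.adj_start[v - 1] - 1; j < f.adj_start[v] - 1; ++j) {
      int w = f.adj[j];
      if (w == sc.par[v]) continue;
      m = (m == 0) ? sc.map[w] : sp_lca(m, sc.map[w], sp_par, sp_dep);
    }
    for (int j = f.adj_start[v - 1] - 1; j < f.adj_start[v] - 1; ++j) {
      int w = f.adj[j];
      if (w != sc.par[v] && sc.map[w] == m) { d = true; break; }
    }
    sc.map[v] = m; sc.isdup[v] = d; if (d) ++dup;
  }
  // loss contributions of real gene edges (child side)
  for (int v : sc.order) {
    int p = sc.par[v];
    if (p == 0) continue;                     // actual root (rooted family)
    if (eu > 0 && (v == eu || v == ev)) continue;  // handled at virtual root
    loss += pd[sc.map[v] - 1] - pd[sc.map[p] - 1] - (sc.isdup[p] ? 0 : 1);
  }
  if (eu > 0) {                               // virtual root's two edges
    int root_map = sp_lca(sc.map[eu], sc.map[ev], sp_par, sp_dep);
    bool root_dup = (root_map == sc.map[eu] || root_map == sc.map[ev]);
    if (root_dup) ++dup;
    loss += pd[sc.map[eu] - 1] + pd[sc.map[ev] - 1] - 2 * pd[root_map - 1]
            - (root_dup ? 0 : 2);
  }
  ScoreOut out; out.dup = dup; out.loss = loss; return out;
}

// Pruned-depth vector: pd[v] = number of nodes on the root..v path (inclusive)
// that survive pruning the species tree to the family's taxon set (suppressing
// degree-2 nodes).  In full mode every node survives, so differences reduce to
// plain depth differences.
std::vector<int> make_pd(const IntegerVector& sp_par, const IntegerVector& sp_post,
                         const std::vector<char>& present_leaf, bool pruned) {
  int S = sp_par.size();
  std::vector<int> pd(S, 0);
  std::vector<char> inp(S, 1);
  if (pruned) {
    std::vector<int> cnt(S, 0), kidpos(S, 0);
    for (int i = 0; i < S; ++i) if (present_leaf[i]) cnt[i] = 1;
    for (int k = 0; k < S; ++k) {
      int v = sp_post[k];                    // children before parents
      if (cnt[v - 1] > 0 && sp_par[v - 1] > 0) {
        cnt[sp_par[v - 1] - 1] += cnt[v - 1];
        kidpos[sp_par[v - 1] - 1] += 1;
      }
    }
    for (int i = 0; i < S; ++i)
      inp[i] = present_leaf[i] ? 1 : (kidpos[i] >= 2 ? 1 : 0);
  }
  for (int k = S - 1; k >= 0; --k) {        // parents before children
    int v = sp_post[k];
    int p = sp_par[v - 1];
    pd[v - 1] = (p > 0 ? pd[p - 1] : 0) + (inp[v - 1] ? 1 : 0);
  }
  return pd;
}

} // namespace

// Score a batch of prepared gene families against one rooted species tree.
// Families arrive flattened (one concatenated array per field, with node ids
// local to each family) so a single call does no per-family R object access:
//   nnode      gene nodes per family
//   rooted     1 if the family tree is rooted
//   root       root node id per family (rooted families)
//   tip_flat   taxon index (1-based) per gene node, 0 at internals
//   adj_flat   flat adjacency; adjst_flat: per-family 1-based offsets
//              (length nnode + 1 each, concatenated)
//   e1/e2      edge endpoint node ids, concatenated; n_edge per family
//   eord_flat  canonical rooting order per family (edge indices, 1-based)
// sp_parent/sp_depth: per species node (1-based, parent 0 at root)
// sp_postorder: species nodes, children before parents
// taxon_sp: species leaf node id per taxon index
// [[Rcpp::export]]
List dl_score_batch_cpp(IntegerVector nnode, IntegerVector rooted,
                        IntegerVector root, IntegerVector tip_flat,
                        IntegerVector adj_flat, IntegerVector adjst_flat,
                        IntegerVector e1, IntegerVector e2,
                        IntegerVector n_edge, IntegerVector eord_flat,
                        IntegerVector sp_parent, IntegerVector sp_depth,
                        IntegerVector sp_postorder, IntegerVector taxon_sp,
                        double dup_w, double loss_w, bool pruned) {
  int nf = nnode.size();
  int S = sp_parent.size();
  NumericVector cost(nf); IntegerVector dups(nf), losses(nf), root_edge(nf);
  const int* spp = INTEGER(sp_parent);
  const int* spd = INTEGER(sp_depth);
  const int* tipf = INTEGER(tip_flat);
  const int* adjf = INTEGER(adj_flat);
  const int* adjsf = INTEGER(adjst_flat);
  const int* pe1 = INTEGER(e1);
  const int* pe2 = INTEGER(e2);
  const int* eof = INTEGER(eord_flat);
  const int* tsp = INTEGER(taxon_sp);
  std::vector<int> pd_full;
  if (!pruned) {
    std::vector<char> dummy(S, 0);
    pd_full = make_pd(sp_parent, sp_postorder, dummy, false);
  }
  Scratch sc;
  long node_off = 0, adj_off = 0, adjst_off = 0, edge_off = 0;
  for (int i = 0; i < nf; ++i) {
    int nn = nnode[i];
    int E = n_edge[i];
    FamGraph f; f.nnode = nn;
    f.adj = adjf + adj_off;          // adj_start values are per-family local
    f.adj_start = adjsf + adjst_off;
    f.tip_sp.assign(nn + 1, 0);
    for (int v = 1; v <= nn; ++v) {
      int tx = tipf[node_off + v - 1];
      if (tx > 0) {
        int sp = tsp[tx - 1];
        if (sp == NA_INTEGER || sp <= 0)
          stop("gene-tree taxon (index %d) absent from species tree", tx);
        f.tip_sp[v] = sp;
      }
    }
    std::vector<int> pd;
    const int* pdp;
    if (pruned) {
      std::vector<char> present(S, 0);
      for (int v = 1; v <= nn; ++v) if (f.tip_sp[v] > 0) present[f.tip_sp[v] - 1] = 1;
      pd = make_pd(sp_parent, sp_postorder, present, true);
      pdp = pd.data();
    } else pdp = pd_full.data();
    if (rooted[i]) {
      ScoreOut s = score_rooting(f, root[i], 0, 0, spp, spd, pdp, sc);
      dups[i] = (int)s.dup; losses[i] = (int)s.loss;
      cost[i] = dup_w * s.dup + loss_w * s.loss;
      root_edge[i] = NA_INTEGER;
    } else {
      double best = R_PosInf; long bd = 0, bl = 0; int bedge = 0;
      for (int k = 0; k < E; ++k) {
        int e = eof[edge_off + k] - 1;
        ScoreOut s = score_rooting(f, 0, pe1[edge_off + e], pe2[edge_off + e],
                                   spp, spd, pdp, sc);
        double c = dup_w * s.dup + loss_w * s.loss;
        if (c < best) { best = c; bd = s.dup; bl = s.loss; bedge = e + 1; }
      }
      dups[i] = (int)bd; losses[i] = (int)bl; cost[i] = best; root_edge[i] = bedge;
    }
    node_off += nn;
    adj_off += adjsf[adjst_off + nn] - 1;  // total neighbour entries (2E)
    adjst_off += nn + 1;
    edge_off += E;
  }
  return List::create(_["cost"] = cost, _["dups"] = dups,
                      _["losses"] = losses, _["root_edge"] = root_edge);
}
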