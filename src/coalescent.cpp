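// Structured-coalescent engine with population splits, admixture pulses and
// size changes, plus infinite-sites mutation. Time is measured backwards in
// generations; population sizes are diploid N, so the pairwise coalescence
// rate within a population of k lineages is k(k-1)/2 / (2N).
//
// Events are encoded as rows of a numeric matrix sorted by time (stable):
//   col 0: time (generations, > 0)
//   col 1: type (1 = mass move, 2 = size change)
//   col 2: population a (0-based)
//   col 3: population b (0-based; ignored for size change)
//   col 4: x (move probability for type 1; new diploid size for type 2)
//
// Randomness comes from R's RNG (RNGScope), so set.seed() on the R side
// makes every simulation reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tree {
  // nodes 0..n_leaves-1 are leaves; internal nodes appended afterwards
  std::vector<int> parent;
  std::vector<double> time;
  int n_leaves;
  int root;
};

// Simulate one coalescent tree for the sampled lineages.
Tree sim_tree(const std::vector<int> &leaf_pop, int npop,
              std::vector<double> sizes, const NumericMatrix &events) {
  const int n = static_cast<int>(leaf_pop.size());
  Tree tr;
  tr.n_leaves = n;
  tr.parent.assign(2 * n - 1, -1);
  tr.time.assign(2 * n - 1, 0.0);

  std::vector<std::vector<int>> active(npop);
  for (int i = 0; i < n; ++i) active[leaf_pop[i]].push_back(i);

  double t = 0.0;
  int next_node = n;
  int ev = 0;
  const int nev = events.nrow();
  int n_active = n;
  long guard = 0;

  std::vector<double> rate(npop);
  while (n_active > 1) {
    if (++guard > 100000000L) stop("coalescent did not complete (model leaves lineages in disconnected populations?)");
    double total = 0.0;
    for (int p = 0; p < npop; ++p) {
      const double k = static_cast<double>(active[p].size());
      rate[p] = (k > 1.0) ? k * (k - 1.0) / 2.0 / (2.0 * sizes[p]) : 0.0;
      total += rate[p];
    }
    double wait = (total > 0.0) ? exp_rand() / total : R_PosInf;
    if (ev < nev && t + wait >= events(ev, 0)) {
      t = events(ev, 0);
      const int type = static_cast<int>(events(ev, 1));
      const int a = static_cast<int>(events(ev, 2));
      if (type == 1) {
        const int b = static_cast<int>(events(ev, 3));
        const double x = events(ev, 4);
        if (x >= 1.0) {
          for (int id : active[a]) active[b].push_back(id);
          active[a].clear();
        } else {
          std::vector<int> stay;
          for (int id : active[a]) {
            if (unif_rand() < x) active[b].push_back(id); else stay.push_back(id);
          }
          active[a].swap(stay);
        }
      } else if (type == 2) {
        sizes[a] = events(ev, 4);
      } else {
        stop("unknown event type");
      }
      ++ev;
      continue;
    }
    if (!R_FINITE(wait)) stop("no coalescence possible and no events remain");
    t += wait;
    // choose population proportional to rate
    double u = unif_rand() * total;
    int p = 0;
    for (; p < npop - 1; ++p) { if (u < rate[p]) break; u -= rate[p]; }
    // choose a random pair in pop p
    std::vector<int> &A = active[p];
    const int k = static_cast<int>(A.size());
    int i = static_cast<int>(unif_rand() * k); if (i >= k) i = k - 1;
    int j = static_cast<int>(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    const int ci = A[i], cj = A[j];
    const int node = next_node++;
    tr.parent[ci] = node; tr.parent[cj] = node;
    tr.time[node] = t;
    // remove the two children, add the parent
    if (i > j) std::swap(i, j);
    A.erase(A.begin() + j); A.erase(A.begin() + i);
    A.push_back(node);
    --n_active;
  }
  tr.root = next_node - 1;
  return tr;
}

// descendant leaves of every node (post-order accumulation)
std::vector<std::vector<int>> leaf_sets(const Tree &tr) {
  const int total = 2 * tr.n_leaves - 1;
  std::vector<std::vector<int>> out(total);
  // children lists
  std::vector<std::vector<int>> child(total);
  for (int i = 0; i < total; ++i)
    if (tr.parent[i] >= 0) child[tr.parent[i]].push_back(i);
  // nodes were created in increasing time order, so ascending id is post-order
  for (int i = 0; i < tr.n_leaves; ++i) out[i].push_back(i);
  for (int i = tr.n_leaves; i < total; ++i) {
    for (int c : child[i])
      out[i].insert(out[i].end(), out[c].begin(), out[c].end());
    std::sort(out[i].begin(), out[i].end());
  }
  return out;
}

std::vector<int> expand_leaf_pops(const IntegerVector &nhap) {
  std::vector<int> leaf_pop;
  for (int p = 0; p < nhap.size(); ++p)
    for (int i = 0; i < nhap[p]; ++i) leaf_pop.push_back(p);
  return leaf_pop;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".sim_haplotypes_cpp")]]
List sim_haplotypes_cpp(IntegerVector nhap_per_pop, NumericVector pop_sizes,
                        NumericMatrix events, double mu, double locus_len,
                        int n_loci) {
  RNGScope scope;
  const int npop = nhap_per_pop.size();
  std::vector<int> leaf_pop = expand_leaf_pops(nhap_per_pop);
  const int n = static_cast<int>(leaf_pop.size());
  if (n < 2) stop("need at least two haplotypes in total");
  std::vector<double> sizes(pop_sizes.begin(), pop_sizes.end());

  List out(n_loci);
  for (int l = 0; l < n_loci; ++l) {
    Tree tr = sim_tree(leaf_pop, npop, sizes, events);
    std::vector<std::vector<int>> desc = leaf_sets(tr);
    std::vector<double> pos;
    std::vector<int> origin; // node whose branch carries the mutation
    for (int v = 0; v < 2 * n - 1; ++v) {
      if (tr.parent[v] < 0) continue;
      const double blen = tr.time[tr.parent[v]] - tr.time[v];
      const int nm = static_cast<int>(R::rpois(mu * locus_len * blen));
      for (int m = 0; m < nm; ++m) {
        pos.push_back(unif_rand() * locus_len);
        origin.push_back(v);
      }
    }
    // order sites by position
    const int ns = static_cast<int>(pos.size());
    std::vector<int> ord(ns);
    for (int i = 0; i < ns; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return pos[a] < pos[b]; });
    IntegerMatrix geno(ns, n);
    NumericVector opos(ns);
    for (int s = 0; s < ns; ++s) {
      const int src = ord[s];
      opos[s] = pos[src];
      for (int leaf : desc[origin[src]]) geno(s, leaf) = 1;
    }
    out[l] = List::create(_["pos"] = opos, _["geno"] = geno);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".sim_sfs_cpp")]]
NumericVector sim_sfs_cpp(IntegerVector nhap_per_pop, NumericVector pop_sizes,
                          NumericMatrix events, double mu, double locus_len,
                          int n_loci) {
  RNGScope scope;
  const int npop = nhap_per_pop.size();
  std::vector<int> leaf_pop = expand_leaf_pops(nhap_per_pop);
  const int n = static_cast<int>(leaf_pop.size());
  if (n < 2) stop("need at least two haplotypes in total");
  std::vector<double> sizes(pop_sizes.begin(), pop_sizes.end());

  // strides for the joint derived-count array, dims (n1+1, n2+1, ...)
  std::vector<long> stride(npop);
  long ncell = 1;
  for (int p = 0; p < npop; ++p) { stride[p] = ncell; ncell *= (nhap_per_pop[p] + 1); }
  NumericVector counts(ncell);

  std::vector<int> dpop(npop);
  for (int l = 0; l < n_loci; ++l) {
    Tree tr = sim_tree(leaf_pop, npop, sizes, events);
    std::vector<std::vector<int>> desc = leaf_sets(tr);
    for (int v = 0; v < 2 * n - 1; ++v) {
      if (tr.parent[v] < 0) continue;
      const double blen = tr.time[tr.parent[v]] - tr.time[v];
      const int nm = static_cast<int>(R::rpois(mu * locus_len * blen));
      if (nm == 0) continue;
      std::fill(dpop.begin(), dpop.end(), 0);
      for (int leaf : desc[v]) ++dpop[leaf_pop[leaf]];
      long idx = 0;
      for (int p = 0; p < npop; ++p) idx += stride[p] * dpop[p];
      counts[idx] += nm;
    }
  }
  return counts;
}
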