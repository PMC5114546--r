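// Structured coalescent on a K0 x K0 grid of demes.
//
// Backward-in-time event simulation: within-deme coalescence at rate 1 per
// lineage pair (coalescent time units), migration of each lineage at total
// rate M/2 split equally among its rook-adjacent squares with reflecting
// boundaries. One genealogy per variant; a single mutation is dropped on a
// branch chosen proportional to branch length (infinite-sites).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> parent;   // -1 for the root
  std::vector<double> time;  // node times, leaves at 0
  int n_leaves;
};

// Build one genealogy for the lineages whose starting demes are given
// (0-based deme index, row-major on the K0 x K0 grid).
Tree build_tree(const std::vector<int>& start_deme, int K0, double M) {
  const int nl = (int)start_deme.size();
  const int D = K0 * K0;
  const int n_nodes = 2 * nl - 1;

  Tree tr;
  tr.parent.assign(n_nodes, -1);
  tr.time.assign(n_nodes, 0.0);
  tr.n_leaves = nl;

  std::vector<std::vector<int>> members(D);     // active node ids per deme
  std::vector<int> deme_of(n_nodes, -1), pos_in_deme(n_nodes, -1);
  std::vector<int> act(nl), pos_in_act(n_nodes, -1);
  std::vector<int> cnt(D, 0);
  std::vector<int> hot;                         // demes that may hold >= 2
  std::vector<char> in_hot(D, 0);

  double pairs_total = 0.0;
  for (int i = 0; i < nl; ++i) {
    int d = start_deme[i];
    deme_of[i] = d;
    pos_in_deme[i] = (int)members[d].size();
    members[d].push_back(i);
    act[i] = i;
    pos_in_act[i] = i;
    pairs_total += cnt[d];
    cnt[d]++;
    if (cnt[d] >= 2 && !in_hot[d]) { in_hot[d] = 1; hot.push_back(d); }
  }

  int na = nl;
  int next_node = nl;
  double t = 0.0;
  const double mig_per_lineage = (K0 > 1) ? M / 2.0 : 0.0;

  auto remove_from_deme = [&](int node) {
    int d = deme_of[node];
    int p = pos_in_deme[node];
    int last = members[d].back();
    members[d][p] = last;
    pos_in_deme[last] = p;
    members[d].pop_back();
    cnt[d]--;
    pairs_total -= cnt[d];
  };
  auto add_to_deme = [&](int node, int d) {
    deme_of[node] = d;
    pos_in_deme[node] = (int)members[d].size();
    members[d].push_back(node);
    pairs_total += cnt[d];
    cnt[d]++;
    if (cnt[d] >= 2 && !in_hot[d]) { in_hot[d] = 1; hot.push_back(d); }
  };
  auto remove_from_act = [&](int node) {
    int p = pos_in_act[node];
    int last = act.back();
    act[p] = last;
    pos_in_act[last] = p;
    act.pop_back();
  };

  while (na > 1) {
    double mig_total = na * mig_per_lineage;
    double rate = pairs_total + mig_total;
    t += R::exp_rand() / rate;
    double u = unif_rand() * rate;
    if (u < pairs_total) {
      // coalescence: pick a deme weighted by its pair count (lazy-clean hot)
      double acc = 0.0;
      int d = -1;
      for (size_t i = 0; i < hot.size();) {
        int cd = hot[i];
        if (cnt[cd] < 2) {  // stale entry
          in_hot[cd] = 0;
          hot[i] = hot.back();
          hot.pop_back();
          continue;
        }
        acc += 0.5 * cnt[cd] * (cnt[cd] - 1);
        if (u < acc) { d = cd; break; }
        ++i;
      }
      if (d < 0) {  // floating-point edge: take any deme holding a pair
        for (int cd : hot) if (cnt[cd] >= 2) { d = cd; break; }
      }
      int c = cnt[d];
      int i1 = (int)(unif_rand() * c); if (i1 == c) i1 = c - 1;
      int i2 = (int)(unif_rand() * (c - 1)); if (i2 == c - 1) i2 = c - 2;
      if (i2 >= i1) i2++;
      int a = members[d][i1], b = members[d][i2];
      int v = next_node++;
      tr.parent[a] = v;
      tr.parent[b] = v;
      tr.time[v] = t;
      remove_from_deme(a);
      remove_from_deme(b);
      remove_from_act(a);
      remove_from_act(b);
      add_to_deme(v, d);
      act.push_back(v);
      pos_in_act[v] = na - 2;
      na--;
    } else {
      // migration of a uniformly chosen lineage to a rook neighbor
      int idx = (int)(unif_rand() * na); if (idx == na) idx = na - 1;
      int node = act[idx];
      int d = deme_of[node];
      int r = d / K0, cc = d % K0;
      int nb[4]; int nn = 0;
      if (r > 0) nb[nn++] = d - K0;
      if (r < K0 - 1) nb[nn++] = d + K0;
      if (cc > 0) nb[nn++] = d - 1;
      if (cc < K0 - 1) nb[nn++] = d + 1;
      int j = (int)(unif_rand() * nn); if (j == nn) j = nn - 1;
      remove_from_deme(node);
      add_to_deme(node, nb[j]);
    }
  }
  return tr;
}

// Drop one mutation on a branch chosen proportional to branch length;
// returns the derived-carrier indicator over leaves.
void drop_mutation_cpp(const Tree& tr, std::vector<char>& carrier,
                       int* mut_node) {
  int n_nodes = (int)tr.parent.size();
  double total = 0.0;
  for (int v = 0; v < n_nodes; ++v)
    if (tr.parent[v] >= 0) total += tr.time[tr.parent[v]] - tr.time[v];
  double target = unif_rand() * total;
  int chosen = -1;
  double acc = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    if (tr.parent[v] < 0) continue;
    acc += tr.time[tr.parent[v]] - tr.time[v];
    if (target < acc) { chosen = v; break; }
  }
  if (chosen < 0) chosen = n_nodes - 2;
  // collect leaves under 'chosen' with an explicit stack over children
  std::vector<std::vector<int>> children(n_nodes);
  for (int v = 0; v < n_nodes; ++v)
    if (tr.parent[v] >= 0) children[tr.parent[v]].push_back(v);
  carrier.assign(tr.n_leaves, 0);
  std::vector<int> stack{chosen};
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    if (v < tr.n_leaves) carrier[v] = 1;
    for (int c : children[v]) stack.push_back(c);
  }
  *mut_node = chosen;
}

}  // namespace

// [[Rcpp::export]]
List rcpp_simulate_genealogy(IntegerVector lineage_demes, int K0, double M) {
  std::vector<int> d(lineage_demes.begin(), lineage_demes.end());
  Tree tr = build_tree(d, K0, M);
  return List::create(_["parent"] = IntegerVector(tr.parent.begin(), tr.parent.end()),
                      _["time"] = NumericVector(tr.time.begin(), tr.time.end()),
                      _["n_leaves"] = tr.n_leaves);
}

// Simulate m independent variants (one genealogy each) for n diploid
// individuals placed at ind_demes (0-based). If maf_lo < maf_hi, reject and
// redraw (fresh tree + mutation) until the folded sample MAF lies in
// [maf_lo, maf_hi]. Returns an n x m genotype matrix of derived-allele
// counts folded to minor-allele counts.
// [[Rcpp::export]]
IntegerMatrix rcpp_sim_genotypes(IntegerVector ind_demes, int K0, double M,
                                 int m_variants, double maf_lo, double maf_hi,
                                 int max_tries) {
  const int n = ind_demes.size();
  const int nl = 2 * n;
  std::vector<int> lin(nl);
  for (int i = 0; i < n; ++i) lin[2 * i] = lin[2 * i + 1] = ind_demes[i];

  IntegerMatrix G(n, m_variants);
  std::vector<char> carrier;
  bool windowed = maf_lo <= maf_hi && (maf_lo > 0.0 || maf_hi < 0.5);
  if (windowed && maf_hi < 1.0 / nl)
    stop("maf window upper bound below 1/(2n); no variant can satisfy it");

  for (int j = 0; j < m_variants; ++j) {
    int tries = 0;
    for (;;) {
      if (++tries > max_tries)
        stop("maf window not met after %d genealogies (variant %d)",
             max_tries, j + 1);
      Tree tr = build_tree(lin, K0, M);
      int mut_node;
      drop_mutation_cpp(tr, carrier, &mut_node);
      int count = 0;
      for (int l = 0; l < nl; ++l) count += carrier[l];
      int mac = std::min(count, nl - count);
      double maf = (double)mac / nl;
      if (windowed && (maf < maf_lo || maf > maf_hi)) continue;
      if (!windowed && mac == 0) continue;  // fold-monomorphic; redraw
      bool flip = count > nl - count;
      for (int i = 0; i < n; ++i) {
        int g = (int)carrier[2 * i] + (int)carrier[2 * i + 1];
        G(i, j) = flip ? 2 - g : g;
      }
      break;
    }
    if (j % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return G;
}

// Derived-allele counts of variants on fresh panmictic genealogies, with
// mutations arriving as a Poisson process along branches (rate theta/2 per
// unit length), the regime in which the expected site-frequency spectrum
// is proportional to 1/i. Simulates trees until at least m_variants
// mutations have been collected.
// [[Rcpp::export]]
IntegerVector rcpp_sfs_counts(int n_lineages, int m_variants, double theta) {
  std::vector<int> lin(n_lineages, 0);
  std::vector<int> counts;
  counts.reserve(m_variants);
  std::vector<char> carrier;
  while ((int)counts.size() < m_variants) {
    Tree tr = build_tree(lin, 1, 1.0);
    double total = 0.0;
    for (size_t v = 0; v + 1 < tr.parent.size(); ++v)
      total += tr.time[tr.parent[v]] - tr.time[v];
    int nmut = (int)R::rpois(0.5 * theta * total);
    for (int s = 0; s < nmut && (int)counts.size() < m_variants; ++s) {
      int mut_node;
      drop_mutation_cpp(tr, carrier, &mut_node);
      int c = 0;
      for (int l = 0; l < n_lineages; ++l) c += carrier[l];
      counts.push_back(c);
    }
    Rcpp::checkUserInterrupt();
  }
  return IntegerVector(counts.begin(), counts.end());
}
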