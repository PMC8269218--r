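#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Stochastic "stitch" hill-climb for Barber bipartite modularity.
//
// Nodes 0..nc-1 are corals, nc..nc+np-1 phylotypes. Each stitch proposes
// either moving a node into the module of a randomly chosen neighbour, or
// merging the two endpoint modules of a randomly chosen link; a proposal is
// accepted iff Q does not decrease. Uses R's RNG so results are reproducible
// under set.seed().
//
// Q = within/F - sum_m K[m]*D[m]/F^2, where within is the total link weight
// joining same-module coral-phylotype pairs, K[m]/D[m] the coral/phylotype
// strength in module m, and F the total link weight.

// [[Rcpp::export]]
List stitch_optimize_cpp(IntegerVector ec, IntegerVector ep, NumericVector ew,
                         int nc, int np, double n_stitches,
                         IntegerVector init_mod, double merge_prob) {
  RNGScope scope;
  const int m = ec.size();
  const int n = nc + np;
  const double F = std::accumulate(ew.begin(), ew.end(), 0.0);
  const double F2 = F * F;

  // strength of each node
  std::vector<double> str(n, 0.0);
  for (int e = 0; e < m; ++e) {
    str[ec[e]] += ew[e];
    str[nc + ep[e]] += ew[e];
  }

  // CSR-style incidence: edges touching each node
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) { deg[ec[e]]++; deg[nc + ep[e]]++; }
  std::vector<int> off(n + 1, 0);
  for (int v = 0; v < n; ++v) off[v + 1] = off[v] + deg[v];
  std::vector<int> inc(off[n]);
  { std::vector<int> cur(off.begin(), off.end() - 1);
    for (int e = 0; e < m; ++e) {
      inc[cur[ec[e]]++] = e;
      inc[cur[nc + ep[e]]++] = e;
    } }

  // module state
  std::vector<int> mod(n);
  for (int v = 0; v < n; ++v) mod[v] = init_mod[v];
  std::vector<double> K(n, 0.0), D(n, 0.0);
  std::vector<std::vector<int>> members(n);
  std::vector<int> pos(n);
  for (int v = 0; v < n; ++v) {
    int g = mod[v];
    if (v < nc) K[g] += str[v]; else D[g] += str[v];
    pos[v] = members[g].size();
    members[g].push_back(v);
  }
  double within = 0.0, nullterm = 0.0;
  for (int e = 0; e < m; ++e)
    if (mod[ec[e]] == mod[nc + ep[e]]) within += ew[e];
  for (int g = 0; g < n; ++g) nullterm += K[g] * D[g];

  auto move_node = [&](int v, int from, int to) {
    // swap-pop from the old member list
    std::vector<int>& mf = members[from];
    int p = pos[v], last = mf.back();
    mf[p] = last; pos[last] = p; mf.pop_back();
    pos[v] = members[to].size();
    members[to].push_back(v);
    mod[v] = to;
  };

  // weight from node v to module g (over incident links)
  auto weight_to = [&](int v, int g) {
    double s = 0.0;
    for (int t = off[v]; t < off[v + 1]; ++t) {
      int e = inc[t];
      int partner = (v < nc) ? nc + ep[e] : ec[e];
      if (mod[partner] == g) s += ew[e];
    }
    return s;
  };

  for (double it = 0; it < n_stitches; ++it) {
    double u = R::unif_rand();
    if (u < merge_prob) {
      // merge the endpoint modules of a random link
      int e = (int)(R::unif_rand() * m); if (e >= m) e = m - 1;
      int a = mod[ec[e]], b = mod[nc + ep[e]];
      if (a == b) continue;
      // evaluate cross-weight by scanning the smaller module
      int s = (members[a].size() <= members[b].size()) ? a : b;
      int o = (s == a) ? b : a;
      double cross = 0.0;
      for (int v : members[s]) cross += weight_to(v, o);
      double dQ = cross / F - (K[a] * D[b] + K[b] * D[a]) / F2;
      if (dQ >= 0) {
        within += cross;
        nullterm += K[a] * D[b] + K[b] * D[a];
        K[o] += K[s]; D[o] += D[s];
        K[s] = 0.0; D[s] = 0.0;
        std::vector<int> mv(members[s]);  // copy: move_node mutates members[s]
        for (int v : mv) move_node(v, s, o);
      }
    } else {
      // move a node to the module of a random neighbour
      int v = (int)(R::unif_rand() * n); if (v >= n) v = n - 1;
      if (deg[v] == 0) continue;
      int t = off[v] + (int)(R::unif_rand() * deg[v]);
      if (t >= off[v + 1]) t = off[v + 1] - 1;
      int e = inc[t];
      int partner = (v < nc) ? nc + ep[e] : ec[e];
      int a = mod[v], b = mod[partner];
      if (a == b) continue;
      double wa = weight_to(v, a), wb = weight_to(v, b);
      double dQ;
      if (v < nc) dQ = (wb - wa) / F + str[v] * (D[a] - D[b]) / F2;
      else        dQ = (wb - wa) / F + str[v] * (K[a] - K[b]) / F2;
      if (dQ >= 0) {
        within += wb - wa;
        if (v < nc) { nullterm += str[v] * (D[b] - D[a]); K[a] -= str[v]; K[b] += str[v]; }
        else        { nullterm += str[v] * (K[b] - K[a]); D[a] -= str[v]; D[b] += str[v]; }
        move_node(v, a, b);
      }
    }
  }

  double Q = within / F - nullterm / F2;
  return List::create(_["membership"] = IntegerVector(mod.begin(), mod.end()),
                      _["Q"] = Q);
}
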