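#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Vietoris-Rips persistence in dimensions 0 and 1 from a dissimilarity
// matrix.  H0 by union-find over edges sorted by (length, i, j); H1 by
// column reduction of the triangle boundary matrix over GF(2).  The
// simplexwise order is (filtration value, dimension, lexicographic vertex
// tuple), which makes the output deterministic under ties.

namespace {

struct Edge {
  double w;
  int i, j;   // i < j
};

struct Tri {
  double w;
  int i, j, k;  // i < j < k
};

int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

}  // namespace

// [[Rcpp::export(name = ".rips_ph_cpp")]]
List rips_ph_cpp(NumericMatrix dm, double max_radius) {
  const int n = dm.nrow();

  std::vector<Edge> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double w = dm(i, j);
      if (w <= max_radius) edges.push_back({w, i, j});
    }
  std::sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
    if (a.w != b.w) return a.w < b.w;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  const int m = (int)edges.size();

  // --- H0: union-find ---------------------------------------------------
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::vector<double> h0_death;
  std::vector<bool> creator(m, false);  // edges not in the merge forest
  for (int e = 0; e < m; ++e) {
    int ri = uf_find(parent, edges[e].i), rj = uf_find(parent, edges[e].j);
    if (ri == rj) {
      creator[e] = true;
    } else {
      parent[ri] = rj;
      h0_death.push_back(edges[e].w);
    }
  }
  int n_components = 0;
  for (int i = 0; i < n; ++i)
    if (uf_find(parent, i) == i) ++n_components;

  // --- H1: reduce triangle columns over edge rows -----------------------
  // edge (i,j) -> its position in the sorted edge list
  std::vector<int64_t> ekey(m);
  std::vector<int> eord(m);
  for (int e = 0; e < m; ++e) {
    ekey[e] = (int64_t)edges[e].i * n + edges[e].j;
    eord[e] = e;
  }
  std::sort(eord.begin(), eord.end(),
            [&](int a, int b) { return ekey[a] < ekey[b]; });
  std::vector<int64_t> skey(m);
  for (int e = 0; e < m; ++e) skey[e] = ekey[eord[e]];
  auto edge_pos = [&](int i, int j) -> int {
    int64_t key = (int64_t)i * n + j;
    int lo = (int)(std::lower_bound(skey.begin(), skey.end(), key) -
                   skey.begin());
    return eord[lo];
  };

  std::vector<Tri> tris;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dij = dm(i, j);
      if (dij > max_radius) continue;
      for (int k = j + 1; k < n; ++k) {
        double w = std::max(dij, std::max(dm(i, k), dm(j, k)));
        if (w <= max_radius) tris.push_back({w, i, j, k});
      }
    }
  std::sort(tris.begin(), tris.end(), [](const Tri& a, const Tri& b) {
    if (a.w != b.w) return a.w < b.w;
    if (a.i != b.i) return a.i < b.i;
    if (a.j != b.j) return a.j < b.j;
    return a.k < b.k;
  });

  std::vector<int> low_to_col(m, -1);
  std::vector<std::vector<int>> cols;  // reduced, sorted ascending
  cols.reserve(tris.size());
  std::vector<double> h1_birth, h1_death;
  std::vector<int> col_store;  // column index per stored reduced column
  std::vector<int> buf;

  for (size_t t = 0; t < tris.size(); ++t) {
    std::vector<int> col = {edge_pos(tris[t].i, tris[t].j),
                            edge_pos(tris[t].i, tris[t].k),
                            edge_pos(tris[t].j, tris[t].k)};
    std::sort(col.begin(), col.end());
    while (!col.empty()) {
      int low = col.back();
      int other = low_to_col[low];
      if (other < 0) break;
      // symmetric difference with the stored column
      const std::vector<int>& oc = cols[other];
      buf.clear();
      std::set_symmetric_difference(col.begin(), col.end(), oc.begin(),
                                    oc.end(), std::back_inserter(buf));
      col.swap(buf);
    }
    if (!col.empty()) {
      int low = col.back();
      low_to_col[low] = (int)cols.size();
      double birth = edges[low].w, death = tris[t].w;
      cols.push_back(std::move(col));
      if (death > birth) {
        h1_birth.push_back(birth);
        h1_death.push_back(death);
      }
    }
  }

  // creator edges never used as a pivot generate essential H1 classes
  std::vector<double> h1_inf_birth;
  for (int e = 0; e < m; ++e)
    if (creator[e] && low_to_col[e] < 0) h1_inf_birth.push_back(edges[e].w);

  return List::create(_["h0_death"] = h0_death,
                      _["n_components"] = n_components,
                      _["h1_birth"] = h1_birth, _["h1_death"] = h1_death,
                      _["h1_inf_birth"] = h1_inf_birth);
}

// Mean log-divergence curve for the Rosenstein largest-Lyapunov estimator.
// emb: delay-embedded trajectory, one row per point.  For each reference
// point the nearest neighbour outside the Theiler window is tracked for
// n_steps steps and log distances are averaged over reference points.
// [[Rcpp::export(name = ".lyap_divergence_cpp")]]
NumericVector lyap_divergence_cpp(NumericMatrix emb, int theiler,
                                  int n_steps) {
  const int M = emb.nrow(), d = emb.ncol();
  const int last = M - 1 - n_steps;  // last usable index
  if (last < 1) stop("trajectory too short for the requested horizon");

  NumericVector sums(n_steps + 1);
  IntegerVector counts(n_steps + 1);

  for (int i = 0; i <= last; ++i) {
    int best = -1;
    double bestd = R_PosInf;
    for (int j = 0; j <= last; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = emb(i, c) - emb(j, c);
        s += diff * diff;
      }
      if (s < bestd) {
        bestd = s;
        best = j;
      }
    }
    if (best < 0) continue;
    for (int k = 0; k <= n_steps; ++k) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = emb(i + k, c) - emb(best + k, c);
        s += diff * diff;
      }
      if (s > 0.0) {
        sums[k] += 0.5 * std::log(s);
        counts[k] += 1;
      }
    }
  }

  NumericVector out(n_steps + 1);
  for (int k = 0; k <= n_steps; ++k)
    out[k] = counts[k] > 0 ? sums[k] / counts[k] : NA_REAL;
  return out;
}
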