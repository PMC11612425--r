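// Vectorized computation of the three cell-level heterogeneity scores.
// One truncated BFS per cell up to the largest requested radius yields,
// for every radius in one pass: the member type counts (local entropy,
// egophily) and the induced edge counts (local homophily), by bucketing
// members and induced edges by their hop level and accumulating.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Csr {
  std::vector<int> off;
  std::vector<int> adj;
  Csr(int n, const IntegerMatrix& edges) : off(n + 1, 0) {
    const int m = edges.nrow();
    for (int e = 0; e < m; ++e) {
      ++off[edges(e, 0) + 1];
      ++off[edges(e, 1) + 1];
    }
    for (int i = 0; i < n; ++i) off[i + 1] += off[i];
    adj.resize(off[n]);
    std::vector<int> pos(off.begin(), off.end() - 1);
    for (int e = 0; e < m; ++e) {
      const int u = edges(e, 0), w = edges(e, 1);
      adj[pos[u]++] = w;
      adj[pos[w]++] = u;
    }
  }
};

}  // namespace

// edges: 0-based undirected edge list (no duplicates, no self loops)
// labels: 0-based type codes; K: size of the full type universe
// radii: strictly positive, sorted increasing
// [[Rcpp::export]]
List cpp_local_scores(int n, IntegerMatrix edges, IntegerVector labels,
                      int K, IntegerVector radii) {
  const int nr = radii.size();
  const int rmax = nr > 0 ? radii[nr - 1] : 0;
  Csr csr(n, edges);

  NumericMatrix ent(n, nr), hom(n, nr), ego(n, nr);
  IntegerMatrix nbs(n, nr);

  std::vector<int> dist(n, -1);
  std::vector<int> order;
  order.reserve(n);
  std::vector<double> cnt(K, 0.0);
  std::vector<double> edgeTot(rmax + 1), edgeMono(rmax + 1);
  const double logK = K > 1 ? std::log(static_cast<double>(K)) : 1.0;

  for (int c = 0; c < n; ++c) {
    order.clear();
    order.push_back(c);
    dist[c] = 0;
    int maxLevel = 0;
    for (size_t qi = 0; qi < order.size(); ++qi) {
      const int u = order[qi];
      const int du = dist[u];
      if (du >= rmax) continue;
      for (int k = csr.off[u]; k < csr.off[u + 1]; ++k) {
        const int w = csr.adj[k];
        if (dist[w] < 0) {
          dist[w] = du + 1;
          maxLevel = std::max(maxLevel, du + 1);
          order.push_back(w);
        }
      }
    }
    std::fill(edgeTot.begin(), edgeTot.begin() + maxLevel + 1, 0.0);
    std::fill(edgeMono.begin(), edgeMono.begin() + maxLevel + 1, 0.0);
    for (size_t qi = 0; qi < order.size(); ++qi) {
      const int u = order[qi];
      const int du = dist[u];
      for (int k = csr.off[u]; k < csr.off[u + 1]; ++k) {
        const int w = csr.adj[k];
        const int dw = dist[w];
        if (dw < 0) continue;
        if (dw < du || (dw == du && w < u)) {
          edgeTot[du] += 1.0;
          if (labels[u] == labels[w]) edgeMono[du] += 1.0;
        }
      }
    }
    // sweep levels, snapshotting at each requested radius
    double tot = 0.0, eTot = 0.0, eMono = 0.0;
    size_t mi = 0;
    int ri = 0;
    for (int L = 0; L <= maxLevel && ri < nr; ++L) {
      while (mi < order.size() && dist[order[mi]] == L) {
        cnt[labels[order[mi]]] += 1.0;
        tot += 1.0;
        ++mi;
      }
      eTot += edgeTot[L];
      eMono += edgeMono[L];
      while (ri < nr && radii[ri] == L) {
        double H = 0.0;
        if (K > 1) {
          for (int t = 0; t < K; ++t) {
            if (cnt[t] > 0.0) {
              const double p = cnt[t] / tot;
              H -= p * std::log(p);
            }
          }
          H /= logK;
        }
        ent(c, ri) = H;
        hom(c, ri) = eTot > 0.0 ? eMono / eTot : NA_REAL;
        ego(c, ri) = cnt[labels[c]] / tot;
        nbs(c, ri) = static_cast<int>(tot);
        ++ri;
      }
      // radii between consecutive levels (none, since radii are integers
      // and levels advance by 1) -- nothing to do here
    }
    if (ri < nr) {
      // remaining radii exceed the reachable eccentricity: counts saturate
      while (mi < order.size()) {
        cnt[labels[order[mi]]] += 1.0;
        tot += 1.0;
        ++mi;
      }
      for (int L = 0; L <= maxLevel; ++L) { /* already summed below maxLevel */ }
      eTot = 0.0;
      eMono = 0.0;
      for (int L = 0; L <= maxLevel; ++L) {
        eTot += edgeTot[L];
        eMono += edgeMono[L];
      }
      double H = 0.0;
      if (K > 1) {
        for (int t = 0; t < K; ++t) {
          if (cnt[t] > 0.0) {
            const double p = cnt[t] / tot;
            H -= p * std::log(p);
          }
        }
        H /= logK;
      }
      for (; ri < nr; ++ri) {
        ent(c, ri) = H;
        hom(c, ri) = eTot > 0.0 ? eMono / eTot : NA_REAL;
        ego(c, ri) = cnt[labels[c]] / tot;
        nbs(c, ri) = static_cast<int>(tot);
      }
    }
    // reset scratch
    for (size_t qi = 0; qi < order.size(); ++qi) {
      cnt[labels[order[qi]]] = 0.0;
      dist[order[qi]] = -1;
    }
  }

  return List::create(_["entropy"] = ent, _["homophily"] = hom,
                      _["egophily"] = ego, _["size"] = nbs);
}

// Members of every r-hop neighborhood (1-based ids, BFS order from each
// center).  Used by the batch neighborhood API on small graphs.
// [[Rcpp::export]]
List cpp_khop_members(int n, IntegerMatrix edges, int r) {
  Csr csr(n, edges);
  std::vector<int> dist(n, -1);
  std::vector<int> order;
  order.reserve(n);
  List out(n);
  for (int c = 0; c < n; ++c) {
    order.clear();
    order.push_back(c);
    dist[c] = 0;
    for (size_t qi = 0; qi < order.size(); ++qi) {
      const int u = order[qi];
      if (dist[u] >= r) continue;
      for (int k = csr.off[u]; k < csr.off[u + 1]; ++k) {
        const int w = csr.adj[k];
        if (dist[w] < 0) {
          dist[w] = dist[u] + 1;
          order.push_back(w);
        }
      }
    }
    IntegerVector mem(order.size());
    for (size_t i = 0; i < order.size(); ++i) mem[i] = order[i] + 1;
    out[c] = mem;
    for (size_t i = 0; i < order.size(); ++i) dist[order[i]] = -1;
  }
  return out;
}
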