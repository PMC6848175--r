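#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static int uf_find(std::vector<int>& parent, int v) {
    while (parent[v] != v) {
        parent[v] = parent[parent[v]];
        v = parent[v];
    }
    return v;
}

// TFCE-style enhancement of an edge-wise statistic over graph components.
// For each threshold h on an equally spaced grid (dh = h_max / n_steps,
// h = dh, 2*dh, ..., h_max), edges with stat >= h (closed threshold) form a
// graph; each suprathreshold edge's extension e(h) is the number of edges in
// its connected component. The enhanced score of an edge is
//   sum_h e(h)^E * h^H * dh.
// ei/ej are 0-based node indices of each edge.
// [[Rcpp::export]]
NumericVector tfce_edge_scores_cpp(NumericVector stat, IntegerVector ei,
                                   IntegerVector ej, int n_nodes,
                                   double E, double H, int n_steps,
                                   double h_max) {
    int m = stat.size();
    NumericVector score(m);
    if (h_max <= 0.0 || n_steps < 1) return score;
    double dh = h_max / n_steps;
    // closed threshold with a relative tolerance: a statistic sitting exactly
    // on a grid point (e.g. the maximum at the top threshold) must not drop
    // out through floating-point rounding of k * dh
    double eps = 1e-12 * h_max;
    std::vector<int> parent(n_nodes);
    std::vector<int> cnt(n_nodes);
    for (int s = 1; s <= n_steps; ++s) {
        double h = s * dh;
        for (int v = 0; v < n_nodes; ++v) { parent[v] = v; cnt[v] = 0; }
        for (int e = 0; e < m; ++e) {
            if (stat[e] >= h - eps) {
                int a = uf_find(parent, ei[e]);
                int b = uf_find(parent, ej[e]);
                if (a != b) parent[a] = b;
            }
        }
        for (int e = 0; e < m; ++e)
            if (stat[e] >= h - eps) cnt[uf_find(parent, ei[e])]++;
        double hH = std::pow(h, H) * dh;
        for (int e = 0; e < m; ++e) {
            if (stat[e] >= h - eps) {
                int root = uf_find(parent, ei[e]);
                score[e] += std::pow((double)cnt[root], E) * hH;
            }
        }
    }
    return score;
}
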