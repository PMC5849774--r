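#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Compressed adjacency from a 0-based edge list.
static void build_csr(int n, const IntegerVector &from, const IntegerVector &to,
                      std::vector<int> &head, std::vector<int> &adj) {
    int m = from.size();
    head.assign(n + 1, 0);
    for (int e = 0; e < m; ++e) {
        ++head[from[e] + 1];
        ++head[to[e] + 1];
    }
    for (int v = 0; v < n; ++v) head[v + 1] += head[v];
    adj.assign(2 * m, 0);
    std::vector<int> pos(head.begin(), head.end() - 1);
    for (int e = 0; e < m; ++e) {
        adj[pos[from[e]]++] = to[e];
        adj[pos[to[e]]++] = from[e];
    }
}

// BFS order from a root; parent[] records the rooted orientation.
static void bfs_order(int n, int root, const std::vector<int> &head,
                      const std::vector<int> &adj, std::vector<int> &order,
                      std::vector<int> &parent, std::vector<int> &dist) {
    order.clear();
    order.reserve(n);
    parent.assign(n, -1);
    dist.assign(n, -1);
    dist[root] = 0;
    order.push_back(root);
    for (size_t i = 0; i < order.size(); ++i) {
        int v = order[i];
        for (int k = head[v]; k < head[v + 1]; ++k) {
            int w = adj[k];
            if (dist[w] < 0) {
                dist[w] = dist[v] + 1;
                parent[w] = v;
                order.push_back(w);
            }
        }
    }
}

//' @noRd
// [[Rcpp::export(name = ".cpp_tree_alpha")]]
int cpp_tree_alpha(int n, IntegerVector from, IntegerVector to) {
    // Independence number of a tree by the classic two-state DP:
    // incl[v] = best size of an independent set in v's subtree using v,
    // excl[v] = best size not using v.  Processing vertices in reverse
    // BFS order visits every child before its parent.
    if (n == 1) return 1;
    std::vector<int> head, adj, order, parent, dist;
    build_csr(n, from, to, head, adj);
    bfs_order(n, 0, head, adj, order, parent, dist);
    std::vector<int> incl(n, 1), excl(n, 0);
    for (int i = n - 1; i >= 1; --i) {
        int v = order[i], p = parent[v];
        incl[p] += std::max(0, excl[v]);
        excl[p] += std::max(incl[v], excl[v]);
    }
    int r = order[0];
    return std::max(incl[r], excl[r]);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_tree_diameter")]]
int cpp_tree_diameter(int n, IntegerVector from, IntegerVector to) {
    // Double-sweep BFS: exact for trees.
    if (n == 1) return 0;
    std::vector<int> head, adj, order, parent, dist;
    build_csr(n, from, to, head, adj);
    bfs_order(n, 0, head, adj, order, parent, dist);
    int far = 0;
    for (int v = 0; v < n; ++v)
        if (dist[v] > dist[far]) far = v;
    bfs_order(n, far, head, adj, order, parent, dist);
    int d = 0;
    for (int v = 0; v < n; ++v)
        if (dist[v] > d) d = dist[v];
    return d;
}
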