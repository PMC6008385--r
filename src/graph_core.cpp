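// Core graph primitives for binary undirected networks.
// Hot loops of the pipeline: BFS distances, Brandes betweenness,
// Maslov-Sneppen degree-preserving rewiring, and the random-network
// null ensemble used for small-world normalization. All stochastic
// routines draw from R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <stack>
using namespace Rcpp;

typedef std::vector< std::vector<int> > AdjList;

static AdjList as_adjlist(const IntegerMatrix& A) {
    int n = A.nrow();
    AdjList adj(n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
            if (i != j && A(i, j) != 0) adj[i].push_back(j);
    return adj;
}

// BFS from src; dist filled with -1 for unreachable.
static void bfs(const AdjList& adj, int src, std::vector<int>& dist) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[src] = 0;
    std::queue<int> q;
    q.push(src);
    while (!q.empty()) {
        int u = q.front(); q.pop();
        for (size_t k = 0; k < adj[u].size(); ++k) {
            int v = adj[u][k];
            if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
        }
    }
}

// [[Rcpp::export]]
IntegerMatrix cpp_bfs_distances(IntegerMatrix A) {
    int n = A.nrow();
    AdjList adj = as_adjlist(A);
    IntegerMatrix D(n, n);
    std::vector<int> dist(n);
    for (int s = 0; s < n; ++s) {
        bfs(adj, s, dist);
        for (int j = 0; j < n; ++j) D(s, j) = dist[j];
    }
    return D;
}

// Local clustering coefficient; nodes of degree < 2 get 0.
// [[Rcpp::export]]
NumericVector cpp_clustering(IntegerMatrix A) {
    int n = A.nrow();
    AdjList adj = as_adjlist(A);
    NumericVector ci(n);
    for (int i = 0; i < n; ++i) {
        int k = (int) adj[i].size();
        if (k < 2) { ci[i] = 0.0; continue; }
        int links = 0;
        for (int a = 0; a < k; ++a)
            for (int b = a + 1; b < k; ++b)
                if (A(adj[i][a], adj[i][b]) != 0) ++links;
        ci[i] = 2.0 * links / ((double) k * (k - 1));
    }
    return ci;
}

// Sum over ordered pairs i != j of 1/d_ij, with 1/infinity = 0.
// Harmonic-mean path length and global efficiency both derive from it.
// [[Rcpp::export]]
double cpp_inv_dist_sum(IntegerMatrix A) {
    int n = A.nrow();
    AdjList adj = as_adjlist(A);
    std::vector<int> dist(n);
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
        bfs(adj, i, dist);
        for (int j = 0; j < n; ++j)
            if (j != i && dist[j] > 0) s += 1.0 / dist[j];
    }
    return s;
}

// Brandes betweenness, undirected unweighted, unnormalized:
// b_i = sum over unordered pairs {s,t}, s,t != i, of the fraction of
// shortest s-t paths passing through i.
// [[Rcpp::export]]
NumericVector cpp_betweenness(IntegerMatrix A) {
    int n = A.nrow();
    AdjList adj = as_adjlist(A);
    NumericVector cb(n);
    std::vector<double> sigma(n), delta(n);
    std::vector<int> dist(n);
    std::vector< std::vector<int> > pred(n);
    for (int s = 0; s < n; ++s) {
        std::stack<int> S;
        for (int i = 0; i < n; ++i) { pred[i].clear(); sigma[i] = 0.0; dist[i] = -1; }
        sigma[s] = 1.0; dist[s] = 0;
        std::queue<int> q;
        q.push(s);
        while (!q.empty()) {
            int v = q.front(); q.pop();
            S.push(v);
            for (size_t k = 0; k < adj[v].size(); ++k) {
                int w = adj[v][k];
                if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
                if (dist[w] == dist[v] + 1) { sigma[w] += sigma[v]; pred[w].push_back(v); }
            }
        }
        std::fill(delta.begin(), delta.end(), 0.0);
        while (!S.empty()) {
            int w = S.top(); S.pop();
            for (size_t k = 0; k < pred[w].size(); ++k) {
                int v = pred[w][k];
                delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
            }
            if (w != s) cb[w] += delta[w];
        }
    }
    for (int i = 0; i < n; ++i) cb[i] /= 2.0;  // each unordered pair counted twice
    return cb;
}

// Local efficiency: mean over nodes of the global efficiency of the
// neighbor-induced subgraph (0 for neighbor sets smaller than 2).
// [[Rcpp::export]]
double cpp_local_efficiency(IntegerMatrix A) {
    int n = A.nrow();
    AdjList adj = as_adjlist(A);
    double total = 0.0;
    std::vector<int> nb, dist;
    std::vector< std::vector<int> > sub;
    for (int i = 0; i < n; ++i) {
        nb = adj[i];
        int m = (int) nb.size();
        if (m < 2) continue;
        sub.assign(m, std::vector<int>());
        for (int a = 0; a < m; ++a)
            for (int b = 0; b < m; ++b)
                if (a != b && A(nb[a], nb[b]) != 0) sub[a].push_back(b);
        dist.assign(m, -1);
        double s = 0.0;
        for (int src = 0; src < m; ++src) {
            bfs(sub, src, dist);
            for (int j = 0; j < m; ++j)
                if (j != src && dist[j] > 0) s += 1.0 / dist[j];
        }
        total += s / ((double) m * (m - 1));
    }
    return total / n;
}

struct EdgeList {
    std::vector<int> u, v;
};

static EdgeList edges_of(const IntegerMatrix& A) {
    EdgeList e;
    int n = A.nrow();
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
            if (A(i, j) != 0) { e.u.push_back(i); e.v.push_back(j); }
    return e;
}

static int runif_int(int n) {  // uniform on 0..n-1 via R's RNG
    int k = (int) (unif_rand() * n);
    return k >= n ? n - 1 : k;
}

// Maslov-Sneppen double-edge swap on a copy of A. `attempts` candidate
// swaps are drawn; those that would create a self-loop or multi-edge are
// rejected. Degree sequence is invariant.
static void rewire_inplace(IntegerMatrix& B, EdgeList& e, int attempts) {
    int m = (int) e.u.size();
    if (m < 2) return;
    for (int it = 0; it < attempts; ++it) {
        int a = runif_int(m), b = runif_int(m);
        if (a == b) continue;
        int u1 = e.u[a], v1 = e.v[a], u2 = e.u[b], v2 = e.v[b];
        // swap orientation of second edge half the time: (u1-v1),(u2-v2) -> (u1-u2),(v1-v2) or (u1-v2),(v1-u2)
        if (unif_rand() < 0.5) { int tmp = u2; u2 = v2; v2 = tmp; }
        if (u1 == u2 || u1 == v2 || v1 == u2 || v1 == v2) continue;   // would self-loop / share node
        if (B(u1, u2) != 0 || B(v1, v2) != 0) continue;               // would multi-edge
        B(u1, v1) = B(v1, u1) = 0;
        B(u2, v2) = B(v2, u2) = 0;
        B(u1, u2) = B(u2, u1) = 1;
        B(v1, v2) = B(v2, v1) = 1;
        e.u[a] = u1 < u2 ? u1 : u2; e.v[a] = u1 < u2 ? u2 : u1;
        e.u[b] = v1 < v2 ? v1 : v2; e.v[b] = v1 < v2 ? v2 : v1;
    }
}

// [[Rcpp::export]]
IntegerMatrix cpp_rewire(IntegerMatrix A, int attempts) {
    IntegerMatrix B = clone(A);
    EdgeList e = edges_of(B);
    rewire_inplace(B, e, attempts);
    return B;
}

// Small fast RNG (xorshift128+) seeded from R's RNG: deterministic
// under set.seed() while keeping the rewiring loop cheap.
struct XRng {
    uint64_t s0, s1;
    explicit XRng() {
        uint64_t seed = (uint64_t) (unif_rand() * 4294967296.0);
        seed ^= ((uint64_t) (unif_rand() * 4294967296.0)) << 32;
        // splitmix64 expansion
        for (int i = 0; i < 2; ++i) {
            seed += 0x9E3779B97F4A7C15ULL;
            uint64_t z = seed;
            z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
            z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
            z ^= z >> 31;
            if (i == 0) s0 = z; else s1 = z;
        }
        if (s0 == 0 && s1 == 0) s1 = 1;
    }
    inline uint64_t next64() {
        uint64_t x = s0, y = s1;
        s0 = y;
        x ^= x << 23;
        s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
        return s1 + y;
    }
    inline double unif() { return (next64() >> 11) * (1.0 / 9007199254740992.0); }
    inline int below(int n) { int k = (int) (unif() * n); return k >= n ? n - 1 : k; }
};

// All global (and optionally nodal) metric curves for one subject in a
// single call: edges are supplied ranked strongest-first, the adjacency
// grows incrementally along the nondecreasing edge-count grid `ks`, and
// the rewiring null ensemble runs at every level.
// Returns per level: cp, lp, eglob, eloc, largest component, ensemble
// mean cp_rand / lp_rand, and optionally per-node metric matrices.
// [[Rcpp::export]]
List cpp_metric_curves(IntegerVector eu, IntegerVector ev, int n,
                       IntegerVector ks, int n_random,
                       double swaps_per_edge, bool nodal) {
    int nlev = ks.size();
    int m_all = eu.size();
    NumericMatrix glob(nlev, 7);
    colnames(glob) = CharacterVector::create("cp", "lp", "eglob", "eloc",
                                             "largest_component",
                                             "cp_rand", "lp_rand");
    NumericMatrix nod_deg, nod_btw, nod_eff, nod_ci;
    if (nodal) {
        nod_deg = NumericMatrix(nlev, n);
        nod_btw = NumericMatrix(nlev, n);
        nod_eff = NumericMatrix(nlev, n);
        nod_ci = NumericMatrix(nlev, n);
    }
    XRng rng;
    IntegerMatrix A(n, n);
    AdjList adj(n);
    std::vector<int> dist(n), q(n);
    std::vector<char> B, base((size_t) n * n, 0);
    std::vector<int> u, v;
    int k_prev = 0;
    for (int g = 0; g < nlev; ++g) {
        int k = ks[g];
        if (k > m_all) stop("edge count exceeds available edges");
        for (int e = k_prev; e < k; ++e) {
            A(eu[e], ev[e]) = A(ev[e], eu[e]) = 1;
            adj[eu[e]].push_back(ev[e]);
            adj[ev[e]].push_back(eu[e]);
            base[(size_t) eu[e] * n + ev[e]] = base[(size_t) ev[e] * n + eu[e]] = 1;
        }
        k_prev = k;
        // real-graph metrics
        NumericVector ci = cpp_clustering(A);
        glob(g, 0) = mean(ci);
        double s = 0.0;
        int comp_max = 0;
        for (int src = 0; src < n; ++src) {
            bfs(adj, src, dist);
            int reach = 0;
            for (int j = 0; j < n; ++j) {
                if (dist[j] >= 0) ++reach;
                if (j != src && dist[j] > 0) s += 1.0 / dist[j];
            }
            if (reach > comp_max) comp_max = reach;
            if (nodal) {
                double si = 0.0;
                for (int j = 0; j < n; ++j)
                    if (j != src && dist[j] > 0) si += 1.0 / dist[j];
                nod_eff(g, src) = si / (n - 1);
            }
        }
        glob(g, 1) = s > 0 ? (double) n * (n - 1) / s : NA_REAL;
        glob(g, 2) = s / ((double) n * (n - 1));
        glob(g, 3) = cpp_local_efficiency(A);
        glob(g, 4) = comp_max;
        if (nodal) {
            NumericVector btw = cpp_betweenness(A);
            for (int i = 0; i < n; ++i) {
                nod_deg(g, i) = (double) adj[i].size();
                nod_btw(g, i) = btw[i];
                nod_ci(g, i) = ci[i];
            }
        }
        // null ensemble
        if (n_random > 0) {
            u.assign(eu.begin(), eu.begin() + k);
            v.assign(ev.begin(), ev.begin() + k);
            std::vector<int> u0 = u, v0 = v;
            int attempts = (int) (swaps_per_edge * k + 0.5);
            double cp_sum = 0.0, lp_sum = 0.0;
            int lp_cnt = 0;
            std::vector< std::vector<int> > radj(n);
            for (int r = 0; r < n_random; ++r) {
                B = base; u = u0; v = v0;
                if (k >= 2) for (int it = 0; it < attempts; ++it) {
                    int a = rng.below(k), b = rng.below(k);
                    if (a == b) continue;
                    int u1 = u[a], v1 = v[a], u2 = u[b], v2 = v[b];
                    if (rng.unif() < 0.5) { int tmp = u2; u2 = v2; v2 = tmp; }
                    if (u1 == u2 || u1 == v2 || v1 == u2 || v1 == v2) continue;
                    if (B[(size_t) u1 * n + u2] || B[(size_t) v1 * n + v2]) continue;
                    B[(size_t) u1 * n + v1] = B[(size_t) v1 * n + u1] = 0;
                    B[(size_t) u2 * n + v2] = B[(size_t) v2 * n + u2] = 0;
                    B[(size_t) u1 * n + u2] = B[(size_t) u2 * n + u1] = 1;
                    B[(size_t) v1 * n + v2] = B[(size_t) v2 * n + v1] = 1;
                    u[a] = u1; v[a] = u2;
                    u[b] = v1; v[b] = v2;
                }
                for (int i = 0; i < n; ++i) radj[i].clear();
                for (int e = 0; e < k; ++e) {
                    radj[u[e]].push_back(v[e]);
                    radj[v[e]].push_back(u[e]);
                }
                double cps = 0.0;
                for (int i = 0; i < n; ++i) {
                    int kk = (int) radj[i].size();
                    if (kk < 2) continue;
                    int links = 0;
                    for (int a = 0; a < kk; ++a)
                        for (int b = a + 1; b < kk; ++b)
                            if (B[(size_t) radj[i][a] * n + radj[i][b]]) ++links;
                    cps += 2.0 * links / ((double) kk * (kk - 1));
                }
                cp_sum += cps / n;
                double rs = 0.0;
                for (int src = 0; src < n; ++src) {
                    bfs(radj, src, dist);
                    for (int j = 0; j < n; ++j)
                        if (j != src && dist[j] > 0) rs += 1.0 / dist[j];
                }
                if (rs > 0) { lp_sum += (double) n * (n - 1) / rs; ++lp_cnt; }
            }
            glob(g, 5) = cp_sum / n_random;
            glob(g, 6) = lp_cnt > 0 ? lp_sum / lp_cnt : NA_REAL;
        } else {
            glob(g, 5) = NA_REAL;
            glob(g, 6) = NA_REAL;
        }
    }
    List out = List::create(_["global"] = glob);
    if (nodal) {
        out["degree"] = nod_deg;
        out["betweenness"] = nod_btw;
        out["efficiency"] = nod_eff;
        out["clustering"] = nod_ci;
    }
    return out;
}

// Null ensemble for small-world normalization: n_random independent
// degree-preserving rewirings of A; returns per-network Cp (col 1) and
// harmonic Lp (col 2). Flat-array implementation: this is the hottest
// loop of the cohort-scale analysis.
// [[Rcpp::export]]
NumericMatrix cpp_smallworld_ensemble(IntegerMatrix A, int n_random, int attempts) {
    int n = A.nrow();
    std::vector<char> base((size_t) n * n, 0);
    std::vector<int> eu, ev;
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
            if (A(i, j) != 0) {
                eu.push_back(i); ev.push_back(j);
                base[(size_t) i * n + j] = base[(size_t) j * n + i] = 1;
            }
    int m = (int) eu.size();
    NumericMatrix out(n_random, 2);
    std::vector<char> B;
    std::vector<int> u, v, dist(n), q(n);
    std::vector< std::vector<int> > adj(n);
    for (int r = 0; r < n_random; ++r) {
        B = base; u = eu; v = ev;
        if (m >= 2) for (int it = 0; it < attempts; ++it) {
            int a = runif_int(m), b = runif_int(m);
            if (a == b) continue;
            int u1 = u[a], v1 = v[a], u2 = u[b], v2 = v[b];
            if (unif_rand() < 0.5) { int tmp = u2; u2 = v2; v2 = tmp; }
            if (u1 == u2 || u1 == v2 || v1 == u2 || v1 == v2) continue;
            if (B[(size_t) u1 * n + u2] || B[(size_t) v1 * n + v2]) continue;
            B[(size_t) u1 * n + v1] = B[(size_t) v1 * n + u1] = 0;
            B[(size_t) u2 * n + v2] = B[(size_t) v2 * n + u2] = 0;
            B[(size_t) u1 * n + u2] = B[(size_t) u2 * n + u1] = 1;
            B[(size_t) v1 * n + v2] = B[(size_t) v2 * n + v1] = 1;
            u[a] = u1; v[a] = u2;
            u[b] = v1; v[b] = v2;
        }
        for (int i = 0; i < n; ++i) adj[i].clear();
        for (int e = 0; e < m; ++e) {
            adj[u[e]].push_back(v[e]);
            adj[v[e]].push_back(u[e]);
        }
        double cpsum = 0.0;
        for (int i = 0; i < n; ++i) {
            int k = (int) adj[i].size();
            if (k < 2) continue;
            int links = 0;
            for (int a = 0; a < k; ++a)
                for (int b = a + 1; b < k; ++b)
                    if (B[(size_t) adj[i][a] * n + adj[i][b]]) ++links;
            cpsum += 2.0 * links / ((double) k * (k - 1));
        }
        double s = 0.0;
        for (int src = 0; src < n; ++src) {
            std::fill(dist.begin(), dist.end(), -1);
            dist[src] = 0;
            int head = 0, tail = 0;
            q[tail++] = src;
            while (head < tail) {
                int x = q[head++];
                for (size_t kk = 0; kk < adj[x].size(); ++kk) {
                    int y = adj[x][kk];
                    if (dist[y] < 0) { dist[y] = dist[x] + 1; q[tail++] = y; }
                }
            }
            for (int j = 0; j < n; ++j)
                if (j != src && dist[j] > 0) s += 1.0 / dist[j];
        }
        out(r, 0) = cpsum / n;
        out(r, 1) = s > 0 ? (double) n * (n - 1) / s : NA_REAL;
    }
    return out;
}
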