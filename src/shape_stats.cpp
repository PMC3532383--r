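#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Truncated-geometric likelihood-ratio statistic for a single nodal split.
//
// Under homogeneous equal-rates-Markov (ERM) growth the ingroup split size i
// of a clade of n tips is uniform on 1..n-1.  Under a one-shift two-rate
// model the split law is truncated geometric P(i | n, r) = r^i / sum_j r^j.
// The statistic is ln[ sup_r P(i|n,r) / (1/(n-1)) ].
//
// The supremum is found by solving E_r[j] = i for theta = ln r (the mean of
// the truncated geometric is strictly increasing in theta), using closed
// forms for log S(theta) = log sum_{j=1}^m e^{j theta} that stay stable for
// theta near 0 and for large |theta| m.
// ---------------------------------------------------------------------------

static double logS(double th, int m) {
    if (std::fabs(th) < 1e-12) return std::log((double)m);
    if (th > 0.0)
        return m * th + std::log1p(-std::exp(-m * th)) - std::log1p(-std::exp(-th));
    return th + std::log1p(-std::exp(m * th)) - std::log1p(-std::exp(th));
}

// mean of j under the truncated geometric with parameter theta on 1..m
static double meanJ(double th, int m) {
    if (std::fabs(th) < 1e-9) {
        // series about theta = 0: (m+1)/2 + theta * Var_unif(1..m)
        return (m + 1) / 2.0 + th * ((double)m * m - 1.0) / 12.0;
    }
    if (th > 0.0) {
        double emt = std::exp(-m * th), et = std::exp(-th);
        return m + m * emt / (1.0 - emt) - et / (1.0 - et);
    }
    double emt = std::exp(m * th), et = std::exp(th);
    return 1.0 - m * emt / (1.0 - emt) + et / (1.0 - et);
}

static std::unordered_map<uint64_t, double> loglr_memo;

// ln sup_r P(i|n,r) - ln(1/(n-1)); n >= 2, 1 <= i <= n-1
static double shift_loglr1(int n, int i) {
    int m = n - 1;
    if (m == 1) return 0.0;
    if (i == 1 || i == m) return std::log((double)m); // supremum at r -> 0 / inf
    int ic = std::min(i, n - i);                      // reflection symmetry
    uint64_t key = ((uint64_t)n << 32) | (uint64_t)ic;
    auto it = loglr_memo.find(key);
    if (it != loglr_memo.end()) return it->second;

    // bisection for E(theta) = ic, E increasing from 1 to m
    double lo = -60.0, hi = 0.0; // ic < (m+1)/2 after canonicalization
    if (2 * ic == n) { lo = -1e-12; hi = 1e-12; }
    for (int it2 = 0; it2 < 200 && hi - lo > 1e-13 * (1.0 + std::fabs(lo)); ++it2) {
        double mid = 0.5 * (lo + hi);
        if (meanJ(mid, m) < ic) lo = mid; else hi = mid;
    }
    double th = 0.5 * (lo + hi);
    double val = ic * th - logS(th, m) + std::log((double)m);
    if (val < 0.0) val = 0.0; // guard: supremum cannot beat r = 1 from below
    loglr_memo[key] = val;
    return val;
}

// [[Rcpp::export]]
NumericVector shift_loglr_cpp(IntegerVector n, IntegerVector i) {
    R_xlen_t len = n.size();
    if (i.size() != len) stop("n and i must have equal length");
    NumericVector out(len);
    for (R_xlen_t k = 0; k < len; ++k) {
        int nn = n[k], ii = i[k];
        if (nn < 2) stop("n must be >= 2");
        if (ii < 1 || ii > nn - 1) stop("i out of range 1..n-1");
        out[k] = shift_loglr1(nn, ii);
    }
    return out;
}

// ---------------------------------------------------------------------------
// ERM (equal-rates Markov) clade growth, simulated on split sizes only.
// Each clade of size n splits into (i, n-i) with i uniform on 1..n-1,
// which is the ERM uniform-split law.  Whole-tree symmetry indices and the
// pooled delta-1 null are accumulated without ever materializing tips.
// ---------------------------------------------------------------------------

static int unif_split(int n) {
    int i = 1 + (int)(unif_rand() * (n - 1));
    if (i > n - 1) i = n - 1;
    return i;
}

struct ShapeAcc {
    double ic = 0.0, sum = 0.0, ss = 0.0, b1 = 0.0;
    int k = 0;
};

// returns max edge-count depth of the clade; accumulates IC, log-prob stats
// and 1/M terms (root's term removed by the caller)
static int gen_shape(int n, ShapeAcc &a) {
    if (n == 1) return 0;
    int i = unif_split(n);
    int Ml = gen_shape(i, a);
    int Mr = gen_shape(n - i, a);
    int M = 1 + (Ml > Mr ? Ml : Mr);
    a.ic += std::abs(n - 2 * i);
    if (n >= 3) {
        double p = (2 * i == n) ? 1.0 / (n - 1) : 2.0 / (n - 1);
        double lp = std::log(p);
        a.sum += lp;
        a.ss += lp * lp;
        a.k += 1;
    }
    a.b1 += 1.0 / M;
    return M;
}

// [[Rcpp::export]]
NumericMatrix erm_shape_stats_cpp(int n_tips, int reps) {
    if (n_tips < 2) stop("n_tips must be >= 2");
    if (reps < 1) stop("reps must be >= 1");
    NumericMatrix out(reps, 4);
    for (int r = 0; r < reps; ++r) {
        if (r % 256 == 0) checkUserInterrupt();
        ShapeAcc a;
        int Mroot = gen_shape(n_tips, a);
        double b1 = a.b1 - 1.0 / Mroot;
        double mpi = a.k > 0 ? a.sum / a.k : 0.0;
        double var = a.k > 0 ? a.ss / a.k - mpi * mpi : 0.0;
        if (var < 0.0) var = 0.0;
        out(r, 0) = a.ic;
        out(r, 1) = mpi;
        out(r, 2) = std::sqrt(var);
        out(r, 3) = b1;
    }
    return out;
}

// recursion for the pooled delta-1 null; returns this clade's own split size
static int gen_delta1(int n, std::vector<double> &pool) {
    if (n < 2) return 0;
    int i = unif_split(n);
    int jl = gen_delta1(i, pool);
    int jr = gen_delta1(n - i, pool);
    if (i >= 2)
        pool.push_back(shift_loglr1(n, i) - shift_loglr1(i, jl));
    if (n - i >= 2)
        pool.push_back(shift_loglr1(n, n - i) - shift_loglr1(n - i, jr));
    return i;
}

// [[Rcpp::export]]
NumericVector erm_delta1_pool_cpp(int n_tips, int reps) {
    if (n_tips < 3) stop("n_tips must be >= 3");
    if (reps < 1) stop("reps must be >= 1");
    std::vector<double> pool;
    pool.reserve((size_t)reps * (size_t)(n_tips > 4 ? n_tips / 2 : 2));
    for (int r = 0; r < reps; ++r) {
        if (r % 64 == 0) checkUserInterrupt();
        gen_delta1(n_tips, pool);
    }
    return NumericVector(pool.begin(), pool.end());
}

// size-conditional delta-1 null: condition on the parent clade size n,
// draw an eligible split (i >= 2) and the child's nodal split uniformly
// [[Rcpp::export]]
NumericVector erm_delta1_conditional_cpp(int n, int reps) {
    if (n < 3) stop("parent clade size must be >= 3");
    if (reps < 1) stop("reps must be >= 1");
    NumericVector out(reps);
    for (int r = 0; r < reps; ++r) {
        if (r % 4096 == 0) checkUserInterrupt();
        int i;
        do { i = unif_split(n); } while (i < 2);
        int j = unif_split(i);
        out[r] = shift_loglr1(n, i) - shift_loglr1(i, j);
    }
    return out;
}

// ---------------------------------------------------------------------------
// Shape indices for an observed strictly bifurcating tree given its ape
// edge matrix.  Also returns per-node descendant tip counts and max depths
// (used by the per-branch triplet scan).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List tree_shape_cpp(IntegerMatrix edge, int n_tip) {
    int n_edge = edge.nrow();
    int n_node_total = n_tip;
    for (int e = 0; e < n_edge; ++e) {
        if (edge(e, 0) > n_node_total) n_node_total = edge(e, 0);
        if (edge(e, 1) > n_node_total) n_node_total = edge(e, 1);
    }
    std::vector<std::vector<int> > kids(n_node_total + 1);
    std::vector<int> parent(n_node_total + 1, 0);
    for (int e = 0; e < n_edge; ++e) {
        kids[edge(e, 0)].push_back(edge(e, 1));
        parent[edge(e, 1)] = edge(e, 0);
    }
    int root = 0;
    for (int v = n_tip + 1; v <= n_node_total; ++v)
        if (parent[v] == 0) { root = v; break; }
    if (root == 0) stop("could not locate root");

    bool binary = true;
    for (int v = n_tip + 1; v <= n_node_total; ++v)
        if (kids[v].size() != 2) binary = false;

    // iterative post-order
    std::vector<int> tipc(n_node_total + 1, 0), mdep(n_node_total + 1, 0);
    std::vector<int> stack, order;
    stack.push_back(root);
    while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        order.push_back(v);
        for (size_t c = 0; c < kids[v].size(); ++c) stack.push_back(kids[v][c]);
    }
    for (int t = (int)order.size() - 1; t >= 0; --t) {
        int v = order[t];
        if (kids[v].empty()) { tipc[v] = 1; mdep[v] = 0; continue; }
        int tc = 0, md = 0;
        for (size_t c = 0; c < kids[v].size(); ++c) {
            tc += tipc[kids[v][c]];
            if (mdep[kids[v][c]] > md) md = mdep[kids[v][c]];
        }
        tipc[v] = tc;
        mdep[v] = md + 1;
    }

    double ic = NA_REAL, mpi = NA_REAL, msig = NA_REAL, b1 = NA_REAL;
    if (binary) {
        double icx = 0.0, s = 0.0, ss = 0.0, b = 0.0;
        int k = 0;
        for (int v = n_tip + 1; v <= n_node_total; ++v) {
            int l = tipc[kids[v][0]], r = tipc[kids[v][1]], n = l + r;
            icx += std::abs(l - r);
            if (n >= 3) {
                double p = (l == r) ? 1.0 / (n - 1) : 2.0 / (n - 1);
                double lp = std::log(p);
                s += lp; ss += lp * lp; ++k;
            }
            if (v != root) b += 1.0 / mdep[v];
        }
        ic = icx;
        mpi = k > 0 ? s / k : 0.0;
        double var = k > 0 ? ss / k - mpi * mpi : 0.0;
        if (var < 0.0) var = 0.0;
        msig = std::sqrt(var);
        b1 = b;
    }

    return List::create(
        _["binary"] = binary,
        _["root"] = root,
        _["tip_counts"] = IntegerVector(tipc.begin() + 1, tipc.end()),
        _["max_depth"] = IntegerVector(mdep.begin() + 1, mdep.end()),
        _["ic"] = ic, _["mpi"] = mpi, _["msig"] = msig, _["b1"] = b1);
}
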