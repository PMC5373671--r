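#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Joint Bernoulli segmentation of a heterozygosity profile.
// Columns (SNPs) are summarised by pooled counts over lines:
// h[j] = heterozygous cells, m[j] = non-missing cells.  A segment's
// maximised log-likelihood uses the pooled MLE p = H/M, so its cost
// (negative log-likelihood) is
//   -(H log(H/M) + (M-H) log(1-H/M)) = -(xlx(H) + xlx(M-H) - xlx(M))
// with xlx(x) = x log x and xlx(0) = 0.  Because the pooled counts are
// integers, xlx is tabulated once per chromosome, making the inner DP
// loop pure table lookups.
//
// The suffix dynamic program
//   E(k, i) = min cost of splitting columns i..n into k segments
// gives -E(K, 1) as the optimal K-segment log-likelihood and lets the
// leftmost-tie-break segmentation be reconstructed front to back.
// The split-point monotonicity (Monge) shortcut does NOT hold for this
// cost with heterogeneous per-column m, so the DP is exact O(K n^2).

static const double INF = std::numeric_limits<double>::infinity();

struct Cost {
    std::vector<double> ch, cm, xlx;
    Cost(const IntegerVector& h, const IntegerVector& m) {
        int n = h.size();
        ch.assign(n + 1, 0.0);
        cm.assign(n + 1, 0.0);
        for (int j = 0; j < n; ++j) {
            ch[j + 1] = ch[j] + h[j];
            cm[j + 1] = cm[j] + m[j];
        }
        int tot = (int) cm[n];
        xlx.assign(tot + 1, 0.0);
        for (int x = 2; x <= tot; ++x) xlx[x] = x * std::log((double) x);
    }
    // cost of segment [i, j], 1-based inclusive
    inline double operator()(int i, int j) const {
        int H = (int) (ch[j] - ch[i - 1]);
        int M = (int) (cm[j] - cm[i - 1]);
        return -(xlx[H] + xlx[M - H] - xlx[M]);
    }
};

// Exact O(kmax * n^2) suffix DP; returns the kmax x (n+1) matrix E with
// E(k-1, i-1) = E(k, i) (INF where a k-split of i..n is infeasible).
// [[Rcpp::export]]
NumericMatrix dp_suffix_exact(IntegerVector h, IntegerVector m, int kmax) {
    int n = h.size();
    Cost cost(h, m);
    NumericMatrix E(kmax, n + 1);
    std::fill(E.begin(), E.end(), INF);
    for (int i = 1; i <= n; ++i) E(0, i - 1) = cost(i, n);
    std::vector<double> prev(n + 2), cur(n + 2);
    for (int i = 1; i <= n + 1; ++i) prev[i] = (i <= n) ? E(0, i - 1) : INF;
    for (int k = 2; k <= kmax; ++k) {
        std::fill(cur.begin(), cur.end(), INF);
        for (int i = 1; i <= n - k + 1; ++i) {
            double chi = cost.ch[i - 1], cmi = cost.cm[i - 1];
            double best = INF;
            const double* xlx = cost.xlx.data();
            for (int t = i; t <= n - k + 1; ++t) {
                int H = (int) (cost.ch[t] - chi);
                int M = (int) (cost.cm[t] - cmi);
                double v = -(xlx[H] + xlx[M - H] - xlx[M]) + prev[t + 1];
                if (v < best) best = v;
            }
            cur[i] = best;
            E(k - 1, i - 1) = best;
        }
        std::swap(prev, cur);
    }
    return E;
}

// Vector of segment costs cost(i, t) for fixed i and t in [i, n]; used
// by the R-side reconstruction of leftmost-tie-break breakpoints.
// [[Rcpp::export]]
NumericVector seg_cost_row(IntegerVector h, IntegerVector m, int i) {
    int n = h.size();
    Cost cost(h, m);
    NumericVector out(n - i + 1);
    for (int t = i; t <= n; ++t) out[t - i] = cost(i, t);
    return out;
}

// Vector of segment costs cost(i, j) for fixed j and i in [1, j]; used
// by the R-side reconstruction on the prefix DP.
// [[Rcpp::export]]
NumericVector seg_cost_col(IntegerVector h, IntegerVector m, int j) {
    Cost cost(h, m);
    NumericVector out(j);
    for (int i = 1; i <= j; ++i) out[i - 1] = cost(i, j);
    return out;
}

// Exact prefix DP with PELT-style candidate pruning.
//   D(k, j) = min cost of splitting columns 1..j into k segments
//           = min_t D(k-1, t) + cost(t+1, j).
// Because splitting a segment never increases its cost
// (cost(a, b) >= cost(a, c) + cost(c+1, b)), a candidate t with
//   D(k-1, t) + cost(t+1, j) >= D(k-1, j)
// is dominated by candidate j for every j' > j and can be discarded
// without changing the optimum.  Returns the kmax x n matrix D with
// D(k-1, j-1) = D(k, j); -D(K, n) is the optimal log-likelihood.
// [[Rcpp::export]]
NumericMatrix dp_prefix_pruned(IntegerVector h, IntegerVector m, int kmax) {
    int n = h.size();
    Cost cost(h, m);
    NumericMatrix D(kmax, n);
    std::fill(D.begin(), D.end(), INF);
    for (int j = 1; j <= n; ++j) D(0, j - 1) = cost(1, j);
    std::vector<double> prev(n + 1), cur(n + 1);
    for (int j = 1; j <= n; ++j) prev[j] = D(0, j - 1);
    std::vector<int> cand, keep;
    cand.reserve(n); keep.reserve(n);
    for (int k = 2; k <= kmax; ++k) {
        cand.clear();
        for (int j = k; j <= n; ++j) {
            cand.push_back(j - 1);  // a (k-1)-split can end at j-1
            double best = INF;
            keep.clear();
            double ref = prev[j];
            for (size_t c = 0; c < cand.size(); ++c) {
                int t = cand[c];
                double v = prev[t] + cost(t + 1, j);
                if (v < best) best = v;
                if (v < ref) keep.push_back(t);
            }
            cand.swap(keep);
            cur[j] = best;
            D(k - 1, j - 1) = best;
        }
        std::swap(prev, cur);
    }
    return D;
}
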