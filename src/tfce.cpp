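#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimal union-find over node ids.
struct UF {
    std::vector<int> parent, size;
    void init(int n) {
        parent.resize(n); size.assign(n, 1);
        for (int i = 0; i < n; ++i) parent[i] = i;
    }
    int find(int a) {
        while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
        return a;
    }
    void unite(int a, int b) {
        a = find(a); b = find(b);
        if (a == b) return;
        if (size[a] < size[b]) std::swap(a, b);
        parent[b] = a; size[a] += size[b];
    }
};

// One-sided TFCE accumulation for v >= 0 parts of `stat` into `enh`.
static void tfce_one_side(const std::vector<double>& stat,
                          const IntegerVector& e0, const IntegerVector& e1,
                          double E, double H, double dh,
                          std::vector<double>& enh, double sign) {
    int n = (int)stat.size();
    double hmax = 0.0;
    for (int i = 0; i < n; ++i) if (stat[i] > hmax) hmax = stat[i];
    if (hmax <= 0.0) return;
    // extreme statistics (e.g. from the zero-variance guard) would need
    // an absurd number of threshold steps; coarsen dh beyond 2000 steps
    if (hmax / dh > 2000.0) dh = hmax / 2000.0;
    UF uf;
    std::vector<char> member(n);
    // midpoint threshold grid: h = (k - 1/2) dh while h <= hmax
    for (double h = 0.5 * dh; h <= hmax; h += dh) {
        uf.init(n);
        int nmem = 0;
        for (int i = 0; i < n; ++i) {
            member[i] = stat[i] >= h;
            nmem += member[i];
        }
        if (!nmem) break;
        for (int k = 0; k < e0.size(); ++k)
            if (member[e0[k]] && member[e1[k]]) uf.unite(e0[k], e1[k]);
        double hh = std::pow(h, H) * dh;
        for (int i = 0; i < n; ++i)
            if (member[i])
                enh[i] += sign * std::pow((double)uf.size[uf.find(i)], E) * hh;
    }
}

// Threshold-free cluster enhancement of a signed statistic map over a
// graph given by 0-based edge endpoints e0, e1. Negative values are
// enhanced symmetrically on the negated map and returned negative.
// [[Rcpp::export]]
NumericVector tfce_cpp(const NumericVector& stat, const IntegerVector& e0,
                       const IntegerVector& e1, double E, double H,
                       double dh) {
    int n = stat.size();
    std::vector<double> pos(n), neg(n), enh(n, 0.0);
    for (int i = 0; i < n; ++i) {
        if (!R_finite(stat[i])) stop("non-finite statistic in TFCE input");
        pos[i] = stat[i] > 0 ? stat[i] : 0.0;
        neg[i] = stat[i] < 0 ? -stat[i] : 0.0;
    }
    tfce_one_side(pos, e0, e1, E, H, dh, enh, +1.0);
    tfce_one_side(neg, e0, e1, E, H, dh, enh, -1.0);
    return NumericVector(enh.begin(), enh.end());
}

// Row-wise TFCE of a permutation x source matrix; returns max |enhanced|
// per row (the permutation max-statistic).
// [[Rcpp::export]]
NumericVector tfce_max_batch_cpp(const NumericMatrix& stats,
                                 const IntegerVector& e0,
                                 const IntegerVector& e1, double E,
                                 double H, double dh) {
    int np = stats.nrow(), n = stats.ncol();
    NumericVector out(np);
    std::vector<double> pos(n), neg(n), enh(n);
    for (int r = 0; r < np; ++r) {
        std::fill(enh.begin(), enh.end(), 0.0);
        for (int i = 0; i < n; ++i) {
            double v = stats(r, i);
            pos[i] = v > 0 ? v : 0.0;
            neg[i] = v < 0 ? -v : 0.0;
        }
        tfce_one_side(pos, e0, e1, E, H, dh, enh, +1.0);
        tfce_one_side(neg, e0, e1, E, H, dh, enh, -1.0);
        double m = 0.0;
        for (int i = 0; i < n; ++i)
            if (std::fabs(enh[i]) > m) m = std::fabs(enh[i]);
        out[r] = m;
    }
    return out;
}

// Label spatiotemporal clusters of a source x time statistic matrix.
// Cells with t > thr (and, separately, t < -thr) form clusters connected
// through spatial edges (same time) and adjacent time points (same
// source). Returns integer labels (0 = background) and per-cluster summed
// statistic (mass).
// [[Rcpp::export]]
List label_clusters_cpp(const NumericMatrix& stat, double thr,
                        const IntegerVector& e0, const IntegerVector& e1) {
    int ns = stat.nrow(), nt = stat.ncol(), n = ns * nt;
    std::vector<int> side(n, 0);  // +1, -1, 0
    for (int t = 0; t < nt; ++t)
        for (int s = 0; s < ns; ++s) {
            double v = stat(s, t);
            side[t * ns + s] = v > thr ? 1 : (v < -thr ? -1 : 0);
        }
    UF uf; uf.init(n);
    for (int t = 0; t < nt; ++t) {
        int b = t * ns;
        for (int k = 0; k < e0.size(); ++k)
            if (side[b + e0[k]] && side[b + e0[k]] == side[b + e1[k]])
                uf.unite(b + e0[k], b + e1[k]);
        if (t + 1 < nt)
            for (int s = 0; s < ns; ++s)
                if (side[b + s] && side[b + s] == side[b + ns + s])
                    uf.unite(b + s, b + ns + s);
    }
    std::vector<int> label(n, 0);
    std::vector<double> mass;
    std::vector<int> root2lab(n, -1);
    int nl = 0;
    for (int i = 0; i < n; ++i) {
        if (!side[i]) continue;
        int r = uf.find(i);
        if (root2lab[r] < 0) { root2lab[r] = nl++; mass.push_back(0.0); }
        label[i] = root2lab[r] + 1;
        mass[root2lab[r]] += stat(i % ns, i / ns);
    }
    IntegerMatrix lab(ns, nt);
    for (int t = 0; t < nt; ++t)
        for (int s = 0; s < ns; ++s) lab(s, t) = label[t * ns + s];
    return List::create(_["labels"] = lab,
                        _["mass"] = NumericVector(mass.begin(), mass.end()));
}

// Max |cluster mass| of a source x time map (for permutation nulls).
// [[Rcpp::export]]
double max_cluster_mass_cpp(const NumericMatrix& stat, double thr,
                            const IntegerVector& e0,
                            const IntegerVector& e1) {
    List res = label_clusters_cpp(stat, thr, e0, e1);
    NumericVector mass = res["mass"];
    double m = 0.0;
    for (int i = 0; i < mass.size(); ++i)
        if (std::fabs(mass[i]) > m) m = std::fabs(mass[i]);
    return m;
}
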