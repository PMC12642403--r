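#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Boosting works on Z_ij(t) = U_i(t - c_j): the predictor convolved with
// the basis window (segment-local, zero padded), shifted by the basis
// element's center c_j. U is precomputed per (used segment, predictor),
// both dense (O(1) lookup) and as a nonzero list (iteration).
struct SegConv {
    int lo;                    // time index of u[0]
    std::vector<double> u;     // dense values
    std::vector<int> nz;       // indices into u with u != 0
    std::vector<double> nzv;   // matching values
};

static SegConv make_segconv(const NumericMatrix& X, int pred,
                            int s0, int s1,
                            const NumericVector& win, int off) {
    SegConv sc;
    int L = win.size();
    sc.lo = s0 - off;
    int n = (s1 - s0) + L - 1;
    sc.u.assign(n, 0.0);
    for (int t = s0; t < s1; ++t) {
        double x = X(t, pred);
        if (x == 0.0) continue;
        int base = t - s0;  // contributes to u[base .. base+L-1]
        for (int m = 0; m < L; ++m) sc.u[base + m] += win[m] * x;
    }
    for (int q = 0; q < n; ++q)
        if (sc.u[q] != 0.0) { sc.nz.push_back(q); sc.nzv.push_back(sc.u[q]); }
    return sc;
}

static double l1_over(const std::vector<double>& r, int s0, int s1) {
    double e = 0.0;
    for (int t = s0; t < s1; ++t) e += std::fabs(r[t]);
    return e;
}

static inline double sgn(double v) { return v > 0 ? 1.0 : (v < 0 ? -1.0 : 0.0); }

struct Cand {
    double lb;   // lower bound on the l1 error change
    int i, j;    // predictor, basis element
    double sign; // +1 / -1 step
};

// Boosting run: steepest l1 coordinate descent with validation freezing.
// Selection is exact: a linear lower bound -delta * sum(sign(r) z) on the
// error change of every coordinate is computed from the residual-sign
// correlation G, candidates are scanned in ascending bound order, and the
// exact +/-delta error change is evaluated until the bound exceeds the
// best exact change found (ties resolve to the lowest predictor, earliest
// lag, positive sign). G is maintained incrementally under residual sign
// flips and refreshed periodically.
// [[Rcpp::export]]
List boost_run_cpp(const NumericMatrix& X, const NumericVector& y,
                   const IntegerVector& seg_start,
                   const IntegerVector& seg_end,
                   const IntegerVector& train_ids, int val_id,
                   const IntegerVector& centers, const NumericVector& win,
                   int off, double delta, int max_iter) {
    int n = X.nrow(), p = X.ncol(), nb = centers.size();
    int ntr = train_ids.size();
    std::vector<int> used;
    for (int s = 0; s < ntr; ++s) used.push_back(train_ids[s]);
    used.push_back(val_id);
    int nused = (int)used.size();

    std::vector<double> r(n, 0.0);
    for (int s = 0; s < nused; ++s)
        for (int t = seg_start[used[s]]; t < seg_end[used[s]]; ++t)
            r[t] = y[t];

    std::vector<std::vector<SegConv> > conv(nused);
    for (int s = 0; s < nused; ++s) {
        conv[s].reserve(p);
        for (int i = 0; i < p; ++i)
            conv[s].push_back(make_segconv(X, i, seg_start[used[s]],
                                           seg_end[used[s]], win, off));
    }

    // residual sign over training segments (0 elsewhere)
    std::vector<double> sign_r(n, 0.0);
    std::vector<int> seg_of(n, -1);  // training segment index at t
    for (int s = 0; s < ntr; ++s)
        for (int t = seg_start[used[s]]; t < seg_end[used[s]]; ++t) {
            sign_r[t] = sgn(r[t]);
            seg_of[t] = s;
        }

    // G[i][j] = sum over training samples of sign(r_t) * Z_ij(t)
    std::vector<std::vector<double> > G(p, std::vector<double>(nb, 0.0));
    int cmin = centers[0], cmax = centers[0];
    for (int j = 0; j < nb; ++j) {
        cmin = std::min(cmin, (int)centers[j]);
        cmax = std::max(cmax, (int)centers[j]);
    }
    std::vector<double> sbuf;  // per-segment sign buffer with padding
    int pad = std::max(std::abs(cmin), std::abs(cmax)) + win.size() + 4;

    auto full_G = [&]() {
        for (int i = 0; i < p; ++i)
            std::fill(G[i].begin(), G[i].end(), 0.0);
        sbuf.assign(n + 2 * pad, 0.0);
        for (int s = 0; s < ntr; ++s) {
            int s0 = seg_start[used[s]], s1 = seg_end[used[s]];
            for (int t = s0; t < s1; ++t) sbuf[pad + t] = sign_r[t];
            for (int i = 0; i < p; ++i) {
                const SegConv& sc = conv[s][i];
                size_t nnz = sc.nz.size();
                for (size_t q = 0; q < nnz; ++q) {
                    double v = sc.nzv[q];
                    int base = pad + sc.lo + sc.nz[q];
                    double* g = G[i].data();
                    const double* sb = sbuf.data() + base;
                    for (int j = 0; j < nb; ++j) g[j] += v * sb[centers[j]];
                }
            }
            for (int t = s0; t < s1; ++t) sbuf[pad + t] = 0.0;
        }
    };
    full_G();

    // exact l1 error change on the training segments for step d at (i, c)
    auto exact_delta = [&](int i, int c, double d) {
        double e = 0.0;
        for (int s = 0; s < ntr; ++s) {
            const SegConv& sc = conv[s][i];
            int s0 = seg_start[used[s]], s1 = seg_end[used[s]];
            size_t nnz = sc.nz.size();
            for (size_t q = 0; q < nnz; ++q) {
                int t = sc.lo + c + sc.nz[q];
                if (t < s0 || t >= s1) continue;
                double rt = r[t];
                e += std::fabs(rt - d * sc.nzv[q]) - std::fabs(rt);
            }
        }
        return e;
    };

    NumericMatrix coef(p, nb);
    std::vector<bool> frozen(p, false);
    int n_frozen = 0;
    double val_err = l1_over(r, seg_start[val_id], seg_end[val_id]);

    std::vector<Cand> cands;
    cands.reserve(2 * p * nb);
    std::vector<int> flip_t;
    std::vector<double> flip_ds;
    std::vector<double> saved;
    std::vector<int> saved_ix;

    std::vector<int> log_iter, log_pred, log_basis, log_acc;
    std::vector<double> log_sign, log_train, log_val;
    int iter = 0;
    bool g_dirty = false;
    while (n_frozen < p && iter < max_iter) {
        ++iter;
        if (g_dirty || iter % 256 == 0) { full_G(); g_dirty = false; }

        cands.clear();
        for (int i = 0; i < p; ++i) {
            if (frozen[i]) continue;
            for (int j = 0; j < nb; ++j) {
                double lin = delta * G[i][j];
                cands.push_back(Cand{-lin, i, j, +1.0});
                cands.push_back(Cand{lin, i, j, -1.0});
            }
        }
        std::sort(cands.begin(), cands.end(),
                  [](const Cand& a, const Cand& b) {
                      if (a.lb != b.lb) return a.lb < b.lb;
                      if (a.i != b.i) return a.i < b.i;
                      if (a.j != b.j) return a.j < b.j;
                      return a.sign > b.sign;
                  });
        double best = 0.0;
        int bi = -1, bj = -1;
        double bsign = 0.0;
        const double margin = 1e-9;
        for (size_t kk = 0; kk < cands.size(); ++kk) {
            const Cand& cd = cands[kk];
            if (cd.lb > best + margin) break;
            double ex = exact_delta(cd.i, centers[cd.j], cd.sign * delta);
            bool take;
            if (ex < best) take = true;
            else if (bi >= 0 && ex == best) {
                take = (cd.i < bi) || (cd.i == bi && cd.j < bj) ||
                       (cd.i == bi && cd.j == bj && cd.sign > bsign);
            } else take = false;
            if (take) { best = ex; bi = cd.i; bj = cd.j; bsign = cd.sign; }
        }
        if (bi < 0 || best >= 0) {  // no coordinate reduces training error
            for (int i = 0; i < p; ++i)
                if (!frozen[i]) { frozen[i] = true; ++n_frozen; }
            break;
        }

        // apply the step on all used segments; track validation samples
        // for exact revert and training sign flips for G maintenance
        double d = bsign * delta;
        int c = centers[bj];
        saved.clear(); saved_ix.clear();
        flip_t.clear(); flip_ds.clear();
        for (int s = 0; s < nused; ++s) {
            const SegConv& sc = conv[s][bi];
            int s0 = seg_start[used[s]], s1 = seg_end[used[s]];
            bool is_train = s < ntr;
            size_t nnz = sc.nz.size();
            for (size_t q = 0; q < nnz; ++q) {
                int t = sc.lo + c + sc.nz[q];
                if (t < s0 || t >= s1) continue;
                if (!is_train) { saved.push_back(r[t]); saved_ix.push_back(t); }
                r[t] -= d * sc.nzv[q];
                if (is_train) {
                    double ns = sgn(r[t]);
                    if (ns != sign_r[t]) {
                        flip_t.push_back(t);
                        flip_ds.push_back(ns - sign_r[t]);
                        sign_r[t] = ns;
                    }
                }
            }
        }
        // incremental G update for flipped signs; a refresh is cheaper
        // when many signs flipped at once
        if ((long)flip_t.size() * p > n) {
            g_dirty = true;
        } else {
            for (size_t f = 0; f < flip_t.size(); ++f) {
                int t = flip_t[f];
                double ds = flip_ds[f];
                int s = seg_of[t];
                for (int i = 0; i < p; ++i) {
                    const SegConv& sc = conv[s][i];
                    int qbase = t - sc.lo;
                    int ulen = (int)sc.u.size();
                    double* g = G[i].data();
                    for (int j = 0; j < nb; ++j) {
                        int q = qbase - centers[j];
                        if (q >= 0 && q < ulen && sc.u[q] != 0.0)
                            g[j] += ds * sc.u[q];
                    }
                }
            }
        }

        double new_val = l1_over(r, seg_start[val_id], seg_end[val_id]);
        int accepted;
        if (new_val > val_err) {
            // revert: validation samples exactly, training via the step
            for (size_t q = 0; q < saved_ix.size(); ++q)
                r[saved_ix[q]] = saved[q];
            for (int s = 0; s < ntr; ++s) {
                const SegConv& sc = conv[s][bi];
                int s0 = seg_start[used[s]], s1 = seg_end[used[s]];
                size_t nnz = sc.nz.size();
                for (size_t q = 0; q < nnz; ++q) {
                    int t = sc.lo + c + sc.nz[q];
                    if (t < s0 || t >= s1) continue;
                    r[t] += d * sc.nzv[q];
                }
            }
            // undo the sign flips and their G contributions
            for (size_t f = 0; f < flip_t.size(); ++f) {
                int t = flip_t[f];
                sign_r[t] = sgn(r[t]);
            }
            if (!g_dirty) {
                for (size_t f = 0; f < flip_t.size(); ++f) {
                    int t = flip_t[f];
                    double ds = -flip_ds[f];
                    int s = seg_of[t];
                    for (int i = 0; i < p; ++i) {
                        const SegConv& sc = conv[s][i];
                        int qbase = t - sc.lo;
                        int ulen = (int)sc.u.size();
                        double* g = G[i].data();
                        for (int j = 0; j < nb; ++j) {
                            int q = qbase - centers[j];
                            if (q >= 0 && q < ulen && sc.u[q] != 0.0)
                                g[j] += ds * sc.u[q];
                        }
                    }
                }
            }
            frozen[bi] = true;
            ++n_frozen;
            accepted = 0;
        } else {
            coef(bi, bj) += d;
            val_err = new_val;
            accepted = 1;
        }
        double tr_err = 0.0;
        for (int s = 0; s < ntr; ++s)
            tr_err += l1_over(r, seg_start[used[s]], seg_end[used[s]]);
        log_iter.push_back(iter); log_pred.push_back(bi + 1);
        log_basis.push_back(bj + 1); log_sign.push_back(bsign);
        log_acc.push_back(accepted);
        log_train.push_back(tr_err); log_val.push_back(val_err);
    }
    return List::create(
        _["coef"] = coef,
        _["n_iter"] = iter,
        _["log"] = DataFrame::create(
            _["iter"] = log_iter, _["predictor"] = log_pred,
            _["basis"] = log_basis, _["sign"] = log_sign,
            _["accepted"] = log_acc, _["train_err"] = log_train,
            _["val_err"] = log_val),
        _["val_err"] = val_err);
}

// Predicted response from basis coefficients, segment-local convolution
// (zero padding at segment edges).
// [[Rcpp::export]]
NumericVector predict_mtrf_cpp(const NumericMatrix& X,
                               const NumericMatrix& coef,
                               const IntegerVector& centers,
                               const NumericVector& win, int off,
                               const IntegerVector& seg_start,
                               const IntegerVector& seg_end) {
    int n = X.nrow(), p = X.ncol();
    NumericVector yhat(n);
    for (int s = 0; s < seg_start.size(); ++s) {
        int s0 = seg_start[s], s1 = seg_end[s];
        for (int i = 0; i < p; ++i) {
            SegConv sc = make_segconv(X, i, s0, s1, win, off);
            for (int j = 0; j < centers.size(); ++j) {
                double cf = coef(i, j);
                if (cf == 0.0) continue;
                int c = centers[j];
                size_t nnz = sc.nz.size();
                for (size_t q = 0; q < nnz; ++q) {
                    int t = sc.lo + c + sc.nz[q];
                    if (t < s0 || t >= s1) continue;
                    yhat[t] += cf * sc.nzv[q];
                }
            }
        }
    }
    return yhat;
}
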