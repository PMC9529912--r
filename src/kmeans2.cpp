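#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double sqdist_row(const NumericMatrix& X, int i,
                                const std::vector<double>& c) {
    double s = 0.0;
    const int d = X.ncol();
    for (int j = 0; j < d; ++j) {
        const double v = X(i, j) - c[j];
        s += v * v;
    }
    return s;
}

// k = 2 Lloyd iterations from n_init k-means++ seedings; the labeling with
// the smallest within-cluster sum of squares wins. Uses R's RNG stream so a
// set.seed() in R makes the result reproducible.
// [[Rcpp::export]]
List kmeans2_cpp(NumericMatrix X, int n_init, int max_iter, double tol) {
    const int n = X.nrow(), d = X.ncol();
    std::vector<int> best_lab(n, 1);
    double best_wss = R_PosInf;
    std::vector<double> dist2(n);

    for (int init = 0; init < n_init; ++init) {
        std::vector< std::vector<double> > cent(2, std::vector<double>(d, 0.0));
        // k-means++: first center uniform, second weighted by squared distance
        int first = (int)std::floor(unif_rand() * n);
        if (first >= n) first = n - 1;
        for (int j = 0; j < d; ++j) cent[0][j] = X(first, j);
        double tot = 0.0;
        for (int i = 0; i < n; ++i) {
            dist2[i] = sqdist_row(X, i, cent[0]);
            tot += dist2[i];
        }
        int second;
        if (tot <= 0.0) {
            second = (first + 1) % n;
        } else {
            const double u = unif_rand() * tot;
            double acc = 0.0;
            second = n - 1;
            for (int i = 0; i < n; ++i) {
                acc += dist2[i];
                if (u <= acc) { second = i; break; }
            }
        }
        for (int j = 0; j < d; ++j) cent[1][j] = X(second, j);

        std::vector<int> lab(n, -1);
        int cnt[2] = {0, 0};
        for (int iter = 0; iter < max_iter; ++iter) {
            bool changed = false;
            for (int i = 0; i < n; ++i) {
                const double d0 = sqdist_row(X, i, cent[0]);
                const double d1 = sqdist_row(X, i, cent[1]);
                const int l = (d1 < d0) ? 1 : 0;   // ties go to cluster 1
                if (l != lab[i]) { lab[i] = l; changed = true; }
            }
            cnt[0] = cnt[1] = 0;
            for (int i = 0; i < n; ++i) ++cnt[lab[i]];
            for (int c = 0; c < 2; ++c) {
                if (cnt[c] == 0) {
                    // empty cluster: seize the point farthest from the other center
                    int far = 0;
                    double fmax = -1.0;
                    for (int i = 0; i < n; ++i) {
                        const double dd = sqdist_row(X, i, cent[1 - c]);
                        if (dd > fmax) { fmax = dd; far = i; }
                    }
                    lab[far] = c;
                    cnt[c] = 1;
                    --cnt[1 - c];
                    changed = true;
                }
            }
            double shift = 0.0;
            for (int c = 0; c < 2; ++c) {
                std::vector<double> nc(d, 0.0);
                for (int i = 0; i < n; ++i)
                    if (lab[i] == c)
                        for (int j = 0; j < d; ++j) nc[j] += X(i, j);
                for (int j = 0; j < d; ++j) {
                    nc[j] /= cnt[c];
                    const double df = nc[j] - cent[c][j];
                    shift += df * df;
                    cent[c][j] = nc[j];
                }
            }
            if (!changed || shift < tol) break;
        }
        double wss = 0.0;
        for (int i = 0; i < n; ++i) wss += sqdist_row(X, i, cent[lab[i]]);
        if (wss < best_wss) {
            best_wss = wss;
            for (int i = 0; i < n; ++i) best_lab[i] = lab[i] + 1;
        }
    }
    return List::create(_["labels"] = IntegerVector(best_lab.begin(), best_lab.end()),
                        _["inertia"] = best_wss);
}
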