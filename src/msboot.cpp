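#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Agglomerative clustering (average = UPGMA, otherwise complete linkage)
// over n <= 30 items from a condensed distance matrix d (n x n, symmetric).
// Appends the bitmask of every internal node's member set to `out`.
// Ties are broken deterministically by scan order (smallest indices first).
static void cladeMasks(std::vector<double>& d, int n, bool average,
                       std::vector<unsigned int>& out) {
    std::vector<bool> active(n, true);
    std::vector<int> size(n, 1);
    std::vector<unsigned int> mask(n);
    for (int i = 0; i < n; ++i) mask[i] = 1u << i;
    for (int step = 0; step < n - 1; ++step) {
        int bi = -1, bj = -1;
        double best = R_PosInf;
        for (int i = 0; i < n; ++i) {
            if (!active[i]) continue;
            for (int j = i + 1; j < n; ++j) {
                if (!active[j]) continue;
                double v = d[i * n + j];
                if (v < best) { best = v; bi = i; bj = j; }
            }
        }
        // merge bj into bi
        for (int k = 0; k < n; ++k) {
            if (!active[k] || k == bi || k == bj) continue;
            double dik = d[bi * n + k], djk = d[bj * n + k];
            double v = average
                ? (size[bi] * dik + size[bj] * djk) / (size[bi] + size[bj])
                : (dik > djk ? dik : djk);
            d[bi * n + k] = v; d[k * n + bi] = v;
        }
        active[bj] = false;
        size[bi] += size[bj];
        mask[bi] |= mask[bj];
        out.push_back(mask[bi]);
    }
}

// Multiscale bootstrap clade counts. X is probes x samples (column-major);
// for each scale, nBoot feature resamples of the given size are drawn with
// replacement, samples are reclustered (1 - Pearson correlation or
// Euclidean distance; average or complete linkage), and for every observed
// clade bitmask the number of resampled trees containing it is counted.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix msBootCounts(NumericMatrix X, IntegerVector sizes, int nBoot,
                           IntegerVector obsMasks, bool correlation,
                           bool average) {
    const int P = X.nrow(), n = X.ncol();
    if (n > 30) stop("at most 30 samples are supported");
    const int nScale = sizes.size(), nNode = obsMasks.size();
    IntegerMatrix counts(nNode, nScale);
    std::vector<int> w(P);
    std::vector<double> s1(n), S2(n * n), dmat(n * n);
    std::vector<unsigned int> masks;

    // row-major copy of X: probe i's profile is contiguous
    std::vector<double> xr((size_t)P * n);
    for (int j = 0; j < n; ++j)
        for (int i = 0; i < P; ++i)
            xr[(size_t)i * n + j] = X(i, j);

    std::vector<double> wx(n);
    for (int s = 0; s < nScale; ++s) {
        const int m = sizes[s];
        if (m < 2) stop("resample size must be >= 2");
        for (int b = 0; b < nBoot; ++b) {
            std::fill(w.begin(), w.end(), 0);
            for (int t = 0; t < m; ++t) {
                int i = (int)(unif_rand() * P);
                if (i >= P) i = P - 1;
                ++w[i];
            }
            std::fill(s1.begin(), s1.end(), 0.0);
            std::fill(S2.begin(), S2.end(), 0.0);
            for (int i = 0; i < P; ++i) {
                if (!w[i]) continue;
                const double wi = (double)w[i];
                const double* xi = &xr[(size_t)i * n];
                for (int j = 0; j < n; ++j) {
                    wx[j] = wi * xi[j];
                    s1[j] += wx[j];
                }
                for (int j = 0; j < n; ++j) {
                    const double wxj = wx[j];
                    double* S2j = &S2[j * n];
                    for (int k = j; k < n; ++k)
                        S2j[k] += wxj * xi[k];
                }
            }
            for (int j = 0; j < n; ++j)
                for (int k = j; k < n; ++k) {
                    double v;
                    if (correlation) {
                        const double cjk = S2[j * n + k] / m -
                            (s1[j] / m) * (s1[k] / m);
                        const double cjj = S2[j * n + j] / m -
                            (s1[j] / m) * (s1[j] / m);
                        const double ckk = S2[k * n + k] / m -
                            (s1[k] / m) * (s1[k] / m);
                        const double den = std::sqrt(cjj * ckk);
                        v = (den > 0.0) ? 1.0 - cjk / den : 1.0;
                        if (j == k) v = 0.0;
                    } else {
                        v = std::sqrt(std::max(0.0,
                            S2[j * n + j] + S2[k * n + k] -
                            2.0 * S2[j * n + k]));
                    }
                    dmat[j * n + k] = v; dmat[k * n + j] = v;
                }
            masks.clear();
            cladeMasks(dmat, n, average, masks);
            for (int q = 0; q < nNode; ++q) {
                const unsigned int om = (unsigned int)obsMasks[q];
                for (size_t z = 0; z < masks.size(); ++z)
                    if (masks[z] == om) { ++counts(q, s); break; }
            }
        }
    }
    return counts;
}
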