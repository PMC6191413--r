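#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-class soft-margin linear C-SVC, solved in the dual by SMO on a
// precomputed Gram matrix (the searchlight trains thousands of tiny SVMs,
// so the solver works on n <= n_items samples and never forms w explicitly).
//
// Solves: min 1/2 a' Q a - e'a   s.t. 0 <= a_i <= C, sum a_i y_i = 0,
// with Q_ij = y_i y_j K_ij.  Working-set selection is the maximal violating
// pair; convergence when the KKT gap drops below eps.  Decisions are
// f(x) = sum_i a_i y_i K(x, x_i) + b, ties (f == 0) resolved to class +1.

struct SvcFit {
    std::vector<double> alpha;
    double b;
};

static SvcFit smo_solve(const std::vector<double> &K, int n,
                        const std::vector<int> &y, double C,
                        double eps = 1e-8, int max_iter = 100000) {
    std::vector<double> alpha(n, 0.0);
    std::vector<double> f(n, 0.0); // f_i = sum_k alpha_k y_k K_ik (no b)
    int iter = 0;
    while (iter++ < max_iter) {
        // maximal violating pair
        double m_up = -1e300, m_low = 1e300;
        int i = -1, j = -1;
        for (int k = 0; k < n; ++k) {
            double viol = y[k] - f[k]; // -E_k
            bool in_up  = (y[k] == 1 && alpha[k] < C) || (y[k] == -1 && alpha[k] > 0);
            bool in_low = (y[k] == 1 && alpha[k] > 0) || (y[k] == -1 && alpha[k] < C);
            if (in_up && viol > m_up)  { m_up = viol;  i = k; }
            if (in_low && viol < m_low) { m_low = viol; j = k; }
        }
        if (i < 0 || j < 0 || m_up - m_low < eps) break;

        // feasible descent direction: alpha_i += y_i t, alpha_j -= y_j t,
        // t > 0; unconstrained step (m_up - m_low)/eta, clipped by the box
        double eta = K[i * n + i] + K[j * n + j] - 2.0 * K[i * n + j];
        double t = (eta > 1e-12) ? (m_up - m_low) / eta : 1e12;
        double cap_i = (y[i] == 1) ? C - alpha[i] : alpha[i];
        double cap_j = (y[j] == 1) ? alpha[j] : C - alpha[j];
        if (t > cap_i) t = cap_i;
        if (t > cap_j) t = cap_j;
        if (t <= 0) break; // cannot happen for a violating pair; guard
        alpha[i] += y[i] * t;
        alpha[j] -= y[j] * t;
        alpha[i] = std::min(C, std::max(0.0, alpha[i]));
        alpha[j] = std::min(C, std::max(0.0, alpha[j]));
        for (int k = 0; k < n; ++k)
            f[k] += t * (K[i * n + k] - K[j * n + k]);
    }
    // offset b: mean over free SVs, else midpoint of the feasible interval
    double bsum = 0.0;
    int nfree = 0;
    for (int k = 0; k < n; ++k)
        if (alpha[k] > 1e-10 && alpha[k] < C - 1e-10) { bsum += y[k] - f[k]; ++nfree; }
    double b;
    if (nfree > 0) {
        b = bsum / nfree;
    } else {
        double up = -1e300, low = 1e300;
        for (int k = 0; k < n; ++k) {
            double v = y[k] - f[k];
            bool in_up  = (y[k] == 1 && alpha[k] < C) || (y[k] == -1 && alpha[k] > 0);
            bool in_low = (y[k] == 1 && alpha[k] > 0) || (y[k] == -1 && alpha[k] < C);
            if (in_up && v > up) up = v;
            if (in_low && v < low) low = v;
        }
        b = (up > -1e299 && low < 1e299) ? (up + low) / 2.0 : 0.0;
    }
    SvcFit out;
    out.alpha = alpha;
    out.b = b;
    return out;
}

// Leave-one-run-out decoding given the full-item Gram matrix.
// G: n_items x n_items (row-major flat), y in {+1,-1}, run id per item.
// Fills decisions (test decision value per item) and returns accuracy.
static double cv_from_gram(const std::vector<double> &G, int n,
                           const std::vector<int> &y,
                           const std::vector<int> &run, double C,
                           std::vector<double> &decisions) {
    // unique runs in order of first appearance
    std::vector<int> runs;
    for (int i = 0; i < n; ++i) {
        bool seen = false;
        for (size_t r = 0; r < runs.size(); ++r)
            if (runs[r] == run[i]) { seen = true; break; }
        if (!seen) runs.push_back(run[i]);
    }
    int correct = 0;
    for (size_t r = 0; r < runs.size(); ++r) {
        std::vector<int> tr, te;
        for (int i = 0; i < n; ++i)
            (run[i] == runs[r] ? te : tr).push_back(i);
        int nt = (int)tr.size();
        std::vector<double> Ktr(nt * nt);
        std::vector<int> ytr(nt);
        for (int a = 0; a < nt; ++a) {
            ytr[a] = y[tr[a]];
            for (int b = 0; b < nt; ++b)
                Ktr[a * nt + b] = G[tr[a] * n + tr[b]];
        }
        SvcFit fit = smo_solve(Ktr, nt, ytr, C);
        for (size_t t = 0; t < te.size(); ++t) {
            double f = fit.b;
            for (int a = 0; a < nt; ++a)
                f += fit.alpha[a] * ytr[a] * G[te[t] * n + tr[a]];
            decisions[te[t]] = f;
            int pred = (f >= 0.0) ? 1 : -1; // tie -> class +1 (first level)
            if (pred == y[te[t]]) ++correct;
        }
    }
    return (double)correct / n;
}

// [[Rcpp::export]]
List decode_cv_cpp(NumericMatrix X, IntegerVector y, IntegerVector run, double cost) {
    int n = X.nrow(), p = X.ncol();
    std::vector<double> G(n * n);
    for (int i = 0; i < n; ++i)
        for (int j = i; j < n; ++j) {
            double s = 0.0;
            for (int k = 0; k < p; ++k) s += X(i, k) * X(j, k);
            G[i * n + j] = s;
            G[j * n + i] = s;
        }
    std::vector<int> yv(y.begin(), y.end()), rv(run.begin(), run.end());
    std::vector<double> dec(n, 0.0);
    double acc = cv_from_gram(G, n, yv, rv, cost, dec);
    return List::create(_["accuracy"] = acc,
                        _["decision"] = NumericVector(dec.begin(), dec.end()));
}

// Searchlight driver.  B: n_items x n_voxels beta matrix (columns are voxels
// in mask order); neighbours: per mask voxel, 1-based column indices of the
// voxels inside its (mask-truncated) sphere; y/run as above.
// [[Rcpp::export]]
NumericVector searchlight_cpp(NumericMatrix B, List neighbours,
                              IntegerVector y, IntegerVector run, double cost) {
    int n = B.nrow();
    int nvox = neighbours.size();
    std::vector<int> yv(y.begin(), y.end()), rv(run.begin(), run.end());
    NumericVector acc(nvox);
    std::vector<double> G(n * n), dec(n);
    for (int v = 0; v < nvox; ++v) {
        IntegerVector nb = neighbours[v];
        int p = nb.size();
        // Gram over the neighbourhood's features
        for (int i = 0; i < n; ++i)
            for (int j = i; j < n; ++j) {
                double s = 0.0;
                for (int k = 0; k < p; ++k) {
                    int c = nb[k] - 1;
                    s += B(i, c) * B(j, c);
                }
                G[i * n + j] = s;
                G[j * n + i] = s;
            }
        acc[v] = cv_from_gram(G, n, yv, rv, cost, dec);
    }
    return acc;
}
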