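#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Non-negative AR(1) deconvolution (pool-merging algorithm, no sparsity
// penalty): finds c minimizing ||c - y||^2 subject to
//   s_1 = c_1 >= 0,  s_t = c_t - gamma * c_{t-1} >= 0  (t >= 2).
// Pools represent maximal runs where the constraint is active
// (c follows v * gamma^k); merging is the weighted projection. The
// non-negativity of c_1 is encoded as a virtual zero pool: a pool whose
// fitted value would be negative while it is the leading pool collapses
// onto zero, exactly as the KKT conditions require.
struct Pool {
    double v;      // fitted value at pool start
    double w;      // sum of gamma^{2k} over the pool
    int t;         // start index
    int l;         // length in frames
    bool zero;     // leading zero pool (c == 0 throughout)
};

// [[Rcpp::export(name = ".oasisAR1")]]
List oasisAR1(NumericVector y, double gamma) {
    int n = y.size();
    std::vector<Pool> pools;
    pools.reserve(n);
    // precompute powers lazily via pow(); pool lengths can be large
    for (int t = 0; t < n; ++t) {
        Pool p = {y[t], 1.0, t, 1, false};
        pools.push_back(p);
        while (pools.size() > 1) {
            Pool &cur = pools.back();
            Pool &prev = pools[pools.size() - 2];
            double boundary = prev.zero ? 0.0
                : prev.v * std::pow(gamma, prev.l);
            if (cur.v >= boundary) break;
            if (prev.zero) {
                // absorbing into the zero region keeps c at 0
                prev.l += cur.l;
                pools.pop_back();
            } else {
                double g = std::pow(gamma, prev.l);
                double num = prev.v * prev.w + cur.v * g * cur.w;
                double den = prev.w + g * g * cur.w;
                prev.v = num / den;
                prev.w = den;
                prev.l += cur.l;
                pools.pop_back();
            }
        }
        // the leading pool must satisfy c_1 >= 0
        if (pools.size() == 1 && pools[0].v < 0) {
            pools[0].v = 0.0;
            pools[0].zero = true;
        }
    }
    NumericVector c(n);
    for (size_t i = 0; i < pools.size(); ++i) {
        const Pool &p = pools[i];
        double val = p.zero ? 0.0 : p.v;
        for (int k = 0; k < p.l; ++k) {
            c[p.t + k] = val;
            val *= gamma;
        }
    }
    NumericVector s(n);
    s[0] = c[0];
    for (int t = 1; t < n; ++t) {
        double st = c[t] - gamma * c[t - 1];
        s[t] = (st > 0) ? st : 0.0;
    }
    return List::create(_["s"] = s, _["c"] = c);
}
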