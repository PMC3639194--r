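#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Base-pair weight of the stacking-energy proxy, in -kcal/mol units:
// GC/CG = 3, AT/TA = 2, GT/TG = 1 (G:U wobble; internal alphabet is DNA),
// anything else 0 (not pairable). Positive weights are maximized; the
// reported energy is the negated optimum.
static inline int pair_weight(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
    if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
    if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
    return 0;
}

static const int MIN_LOOP = 3; // >=3 unpaired nt enclosed by the closing pair

// Maximum-weight pseudoknot-free pairing (weighted Nussinov).
// [[Rcpp::export(name = ".fold_proxy_cpp")]]
List fold_proxy_cpp(std::string seq) {
    const int n = (int) seq.size();
    if (n == 0) return List::create(_["structure"] = "", _["energy"] = 0.0,
                                    _["pairs"] = IntegerVector(0));
    std::vector<std::vector<int>> W(n, std::vector<int>(n, 0));
    for (int span = MIN_LOOP + 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            int j = i + span;
            int best = W[i + 1][j]; // i unpaired
            for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
                int w = pair_weight(seq[i], seq[k]);
                if (!w) continue;
                int cand = w + (k - i >= 2 ? W[i + 1][k - 1] : 0)
                             + (k < j ? W[k + 1][j] : 0);
                if (cand > best) best = cand;
            }
            W[i][j] = best;
        }
    }
    // deterministic traceback: among co-optimal choices prefer pairing i
    // with its outermost admissible partner (yields canonical rod-like
    // stems for hairpins), falling back to "i unpaired"
    std::vector<int> partner(n, -1);
    std::vector<std::pair<int,int>> stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (i >= j || j - i <= MIN_LOOP) continue;
        bool paired = false;
        for (int k = j; k >= i + MIN_LOOP + 1; --k) {
            int w = pair_weight(seq[i], seq[k]);
            if (!w) continue;
            int cand = w + (k - i >= 2 ? W[i + 1][k - 1] : 0)
                         + (k < j ? W[k + 1][j] : 0);
            if (cand == W[i][j]) {
                partner[i] = k;
                partner[k] = i;
                if (k - i >= 2) stack.push_back(std::make_pair(i + 1, k - 1));
                if (k < j) stack.push_back(std::make_pair(k + 1, j));
                paired = true;
                break;
            }
        }
        if (!paired) stack.push_back(std::make_pair(i + 1, j));
    }
    std::string db(n, '.');
    IntegerVector pairs(n, 0);
    for (int i = 0; i < n; ++i) {
        if (partner[i] >= 0) {
            db[i] = (partner[i] > i) ? '(' : ')';
            pairs[i] = partner[i] + 1; // 1-based partner, 0 = unpaired
        }
    }
    return List::create(_["structure"] = db,
                        _["energy"] = -(double) W[0][n - 1],
                        _["pairs"] = pairs);
}
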