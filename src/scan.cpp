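#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Penalty of putting miRNA base mc opposite target base tc (both DNA):
// Watson-Crick 0, G:U wobble 0.5, otherwise 1.0. Doubled when the miRNA
// position lies in the seed-extended region 2..13.
static inline double base_pen(char mc, char tc) {
    if ((mc == 'A' && tc == 'T') || (mc == 'T' && tc == 'A') ||
        (mc == 'G' && tc == 'C') || (mc == 'C' && tc == 'G')) return 0.0;
    if ((mc == 'G' && tc == 'T') || (mc == 'T' && tc == 'G')) return 0.5;
    return 1.0;
}

static inline double pos_weight(int i) { return (i >= 2 && i <= 13) ? 2.0 : 1.0; }

// Exhaustive complementarity scan of one transcript with one miRNA.
// Windows of widths L-1, L, L+1 at every start; at most one single-nt gap
// (gapped miRNA position for width L-1, bulged target base for width L+1).
// Coordinates are 1-based inclusive on the transcript sense strand.
// [[Rcpp::export(name = ".scan_duplex_cpp")]]
DataFrame scan_duplex_cpp(std::string mirna, std::string tx, double max_score) {
    const int L = (int) mirna.size();
    const int n = (int) tx.size();
    std::vector<int> starts, ends, widths, gap_types, gap_pos, p10s, p11s;
    std::vector<double> scores;

    for (int w = L - 1; w <= L + 1; ++w) {
        if (w < 1) continue;
        for (int s = 1; s + w - 1 <= n; ++s) {
            // reversed window: r[k] = tx[s + w - k] (1-based)
            double best = R_PosInf;
            int best_gt = 0, best_gp = 0, bp10 = 0, bp11 = 0;
            if (w == L) {
                double sc = 0.0;
                for (int i = 1; i <= L; ++i)
                    sc += base_pen(mirna[i - 1], tx[s + w - i - 1]) * pos_weight(i);
                best = sc; best_gt = 0; best_gp = 0;
                bp10 = s + L - 10; bp11 = s + L - 11;
            } else if (w == L - 1) {
                for (int g = 1; g <= L; ++g) { // miRNA position g opposite a gap
                    double sc = pos_weight(g); // gap penalty 1.0 x weight
                    for (int i = 1; i < g; ++i)
                        sc += base_pen(mirna[i - 1], tx[s + w - i - 1]) * pos_weight(i);
                    for (int i = g + 1; i <= L; ++i)
                        sc += base_pen(mirna[i - 1], tx[s + w - (i - 1) - 1]) * pos_weight(i);
                    if (sc < best) {
                        best = sc; best_gt = 1; best_gp = g;
                        bp10 = (10 < g) ? s + L - 1 - 10 : (10 > g ? s + L - 10 : 0);
                        bp11 = (11 < g) ? s + L - 1 - 11 : (11 > g ? s + L - 11 : 0);
                    }
                }
            } else { // w == L + 1: reversed-window index g is bulged out
                for (int g = 1; g <= w; ++g) {
                    double sc = pos_weight(g > L ? L : g); // bulge inherits flanking weight
                    for (int i = 1; i < g && i <= L; ++i)
                        sc += base_pen(mirna[i - 1], tx[s + w - i - 1]) * pos_weight(i);
                    for (int i = (g > L ? L + 1 : g); i <= L; ++i)
                        sc += base_pen(mirna[i - 1], tx[s + w - (i + 1) - 1]) * pos_weight(i);
                    if (sc < best) {
                        best = sc; best_gt = 2; best_gp = g;
                        bp10 = (10 < g) ? s + L + 1 - 10 : s + L - 10;
                        bp11 = (11 < g) ? s + L + 1 - 11 : s + L - 11;
                    }
                }
            }
            if (best <= max_score) {
                starts.push_back(s);
                ends.push_back(s + w - 1);
                widths.push_back(w);
                scores.push_back(best);
                gap_types.push_back(best_gt);
                gap_pos.push_back(best_gp);
                p10s.push_back(bp10);
                p11s.push_back(bp11);
            }
        }
    }
    return DataFrame::create(_["start"] = starts, _["end"] = ends,
                             _["width"] = widths, _["score"] = scores,
                             _["gap_type"] = gap_types, _["gap_pos"] = gap_pos,
                             _["pos10"] = p10s, _["pos11"] = p11s);
}
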