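#include <Rcpp.h>
#include "residue.h"

using namespace Rcpp;

// Sliding-window dot matrix (dotter style): for every pair of window centers
// (i in A, j in B) count positional matches of the two length-w windows and
// emit the pair when the count reaches the threshold. Reverse points compare
// A's window with the reverse complement of B's window. Stride is fixed at 1.
// Self mode emits canonical points only: forward i < j (main diagonal
// suppressed), reverse i <= j (a window can pair with its own revcomp).

// [[Rcpp::export]]
DataFrame cpp_window_dotmatrix(std::string a, std::string b, bool nucleotide,
                               int window, int threshold,
                               bool search_reverse, bool self_mode) {
    const int m = (int)a.size(), n = (int)b.size();
    const int h = (window - 1) / 2;
    std::vector<int> v_x, v_y, v_sc;
    std::vector<std::string> v_ori;

    for (int i = h + 1; i <= m - h; ++i) {
        for (int j = h + 1; j <= n - h; ++j) {
            if (self_mode && j <= i) continue;
            int sc = 0;
            for (int k = -h; k <= h; ++k)
                if (res_match(a[i + k - 1], b[j + k - 1], nucleotide)) ++sc;
            if (sc >= threshold) {
                v_x.push_back(i); v_y.push_back(j);
                v_sc.push_back(sc); v_ori.push_back("forward");
            }
        }
    }

    if (search_reverse) {
        for (int i = h + 1; i <= m - h; ++i) {
            for (int j = h + 1; j <= n - h; ++j) {
                if (self_mode && j < i) continue;
                int sc = 0;
                for (int k = -h; k <= h; ++k)
                    if (res_match(a[i + k - 1], comp_base(b[j - k - 1]),
                                  nucleotide)) ++sc;
                if (sc >= threshold) {
                    v_x.push_back(i); v_y.push_back(j);
                    v_sc.push_back(sc); v_ori.push_back("reverse");
                }
            }
        }
    }

    return DataFrame::create(
        Named("x") = v_x, Named("y") = v_y, Named("score") = v_sc,
        Named("orientation") = v_ori, Named("stringsAsFactors") = false);
}
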