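#include <Rcpp.h>
#include "residue.h"

using namespace Rcpp;

// Maximal exact repeats by per-diagonal match-run scanning, O(L^2).
//
// Forward: for every diagonal offset d >= 1, maximal runs of positions i with
// s[i] == s[i+d] are maximal exact repeats (start1=i_run, start2=i_run+d);
// overlapping copies (d < length) are reported, matching repeat-match.
//
// Reverse: runs on the diagonals of s vs revcomp(s). A cell (i, j) pairs
// forward-strand positions i and p = L - j + 1; only cells with i < p
// (first copy strictly before the second) are kept, which drops mirror
// duplicates and splits palindromic runs at their center into two disjoint
// copies. Ambiguity codes never match (see residue.h).

// [[Rcpp::export]]
DataFrame cpp_exact_repeats(std::string s, bool nucleotide, int min_len,
                            bool search_reverse) {
    const int m = (int)s.size();
    std::vector<int> v_s1, v_s2, v_len;
    std::vector<std::string> v_ori;

    for (int d = 1; d <= m - 1; ++d) {
        int run = 0;
        for (int i = 1; i <= m - d + 1; ++i) {
            bool ok = (i <= m - d) && res_match(s[i - 1], s[i - 1 + d], nucleotide);
            if (ok) {
                ++run;
            } else if (run > 0) {
                if (run >= min_len) {
                    v_s1.push_back(i - run);
                    v_s2.push_back(i - run + d);
                    v_len.push_back(run);
                    v_ori.push_back("forward");
                }
                run = 0;
            }
        }
    }

    if (search_reverse) {
        std::string b = revcomp_str(s);
        for (int c = -(m - 1); c <= m - 1; ++c) {
            int ilo = std::max(1, 1 - c), ihi = std::min(m, m - c);
            int run = 0;
            for (int i = ilo; i <= ihi + 1; ++i) {
                bool ok = (i <= ihi) && res_match(s[i - 1], b[i + c - 1], nucleotide);
                if (ok) {
                    ++run;
                } else if (run > 0) {
                    int i1 = i - run, i2 = i - 1;        // cell run [i1..i2]
                    // keep cells with i + j <= m, j = i + c
                    int ik = std::min(i2, (m - c) / 2);
                    int len = ik - i1 + 1;
                    if (len >= min_len) {
                        int start2 = m - (ik + c) + 1;
                        v_s1.push_back(i1);
                        v_s2.push_back(start2);
                        v_len.push_back(len);
                        v_ori.push_back("reverse");
                    }
                    run = 0;
                }
            }
        }
    }

    return DataFrame::create(
        Named("start1") = v_s1, Named("start2") = v_s2,
        Named("length") = v_len, Named("orientation") = v_ori,
        Named("stringsAsFactors") = false);
}
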