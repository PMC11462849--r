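#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include "residue.h"

using namespace Rcpp;

// Iterated Smith-Waterman (Gotoh affine-gap) extraction of local alignments.
//
// mode 0: cross comparison, no cell restrictions.
// mode 1: self forward. Cells with j - i < band (band = min_len) are
//         forbidden: excludes the identity diagonal and near-diagonal
//         self-overlap while keeping tandem copies >= min_len apart, and
//         makes every alignment canonical (start1 < start2).
// mode 2: self reverse (a vs revcomp(a), equal lengths). Cells with
//         i + j > L are forbidden, i.e. the first copy must lie strictly
//         before the second copy on the forward strand. This removes mirror
//         duplicates and splits palindromic self-alignments at their center.
//
// After each accepted (or rejected-by-threshold) best alignment, every cell
// on its traceback path plus a 1-cell neighborhood is masked and the DP is
// rerun, until the best remaining score drops below min_score or max_pairs
// alignments have been recorded. Residues are never masked: a residue may
// take part in many repeat pairs.

namespace {

const double NEG = -1e15;
const double EPS = 1e-9;

struct DPResult {
    double score;
    int a_start, a_end, b_start, b_end;
    std::string aln_a, aln_b;
    int matches, columns;
};

inline bool feq(double x, double y) { return std::fabs(x - y) < EPS; }

} // namespace

// [[Rcpp::export]]
List cpp_extract_all(std::string a, std::string b, bool nucleotide,
                     double match, double mismatch,
                     double gap_open, double gap_extend,
                     int min_len, double min_identity, double min_score,
                     int max_pairs, int mode, double trim_tau) {
    const int m = (int)a.size(), n = (int)b.size();
    const size_t W = (size_t)n + 1;
    std::vector<double> H((size_t)(m + 1) * W, 0.0),
                        E((size_t)(m + 1) * W, NEG),
                        F((size_t)(m + 1) * W, NEG);
    std::vector<uint8_t> maskv((size_t)m * n, 0);
    const int band = min_len;

    auto forbidden = [&](int i, int j) -> bool {
        if (maskv[(size_t)(i - 1) * n + (j - 1)]) return true;
        if (mode == 1 && j - i < band) return true;
        if (mode == 2 && i + j > n) return true;
        return false;
    };

    std::vector<DPResult> kept;
    bool truncated = false;
    const long iter_cap = std::max(1000L, 10L * (long)max_pairs);
    long iter = 0;

    while ((int)kept.size() < max_pairs) {
        if (++iter > iter_cap) { truncated = true; break; }
        // full DP pass
        double best = 0.0; int bi = 0, bj = 0;
        for (int i = 1; i <= m; ++i) {
            const size_t r = (size_t)i * W, rp = (size_t)(i - 1) * W;
            for (int j = 1; j <= n; ++j) {
                if (forbidden(i, j)) {
                    H[r + j] = 0.0; E[r + j] = NEG; F[r + j] = NEG;
                    continue;
                }
                double e = std::max(H[r + j - 1] + gap_open,
                                    E[r + j - 1] + gap_extend);
                double f = std::max(H[rp + j] + gap_open,
                                    F[rp + j] + gap_extend);
                double s = res_match(a[i - 1], b[j - 1], nucleotide)
                               ? match : mismatch;
                double h = H[rp + j - 1] + s;
                if (e > h) h = e;
                if (f > h) h = f;
                if (h < 0.0) h = 0.0;
                H[r + j] = h; E[r + j] = e; F[r + j] = f;
                // ties go to the later end cell in row-major order, which
                // prefers the longest of equal-scoring alignments
                if (h > best - EPS && h > EPS) { best = h; bi = i; bj = j; }
            }
        }
        if (best < min_score - EPS || bi == 0) break;

        // traceback from (bi, bj)
        int i = bi, j = bj, state = 0; // 0=H, 1=E (gap in a), 2=F (gap in b)
        std::string ra, rb;            // reversed alignment strings
        std::vector<std::pair<int, int> > path;
        for (;;) {
            const size_t r = (size_t)i * W, rp = (size_t)(i - 1) * W;
            if (state == 0) {
                if (H[r + j] <= EPS) break;
                double s = res_match(a[i - 1], b[j - 1], nucleotide)
                               ? match : mismatch;
                if (i >= 1 && j >= 1 && feq(H[r + j], H[rp + j - 1] + s)) {
                    ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
                    path.push_back(std::make_pair(i, j));
                    --i; --j;
                } else if (feq(H[r + j], E[r + j])) {
                    state = 1;
                } else if (feq(H[r + j], F[r + j])) {
                    state = 2;
                } else {
                    break; // numerically unreachable
                }
            } else if (state == 1) {
                ra.push_back('-'); rb.push_back(b[j - 1]);
                path.push_back(std::make_pair(i, j));
                if (feq(E[r + j], H[r + j - 1] + gap_open)) state = 0;
                --j;
            } else {
                ra.push_back(a[i - 1]); rb.push_back('-');
                path.push_back(std::make_pair(i, j));
                if (feq(F[r + j], H[rp + j] + gap_open)) state = 0;
                --i;
            }
        }

        std::reverse(ra.begin(), ra.end());
        std::reverse(rb.begin(), rb.end());
        const int C = (int)ra.size();

        // Per-column scores of the alignment (gap runs pay open once,
        // extend afterwards; switching gap side reopens).
        std::vector<double> col(C);
        int gap_side = 0;
        for (int k = 0; k < C; ++k) {
            if (ra[k] == '-' || rb[k] == '-') {
                int side = (ra[k] == '-') ? 1 : 2;
                col[k] = (gap_side == side) ? gap_extend : gap_open;
                gap_side = side;
            } else {
                gap_side = 0;
                col[k] = res_match(ra[k], rb[k], nucleotide) ? match : mismatch;
            }
        }

        // End trimming: maximum-sum subarray of (col - trim_tau) strips
        // terminal segments whose mean column score is below the trim
        // level, i.e. chance extension of the local alignment beyond the
        // repeat core. trim_tau <= 0 disables trimming. Ties: earliest
        // start, then earliest end. Boundaries always land on match
        // columns because only match columns are positive after the shift.
        int u = 0, v = C - 1;
        if (trim_tau > 0.0) {
            double run = 0.0, bsum = -1.0;
            int rstart = 0;
            u = -1;
            for (int k = 0; k < C; ++k) {
                if (run <= 0.0) { run = 0.0; rstart = k; }
                run += col[k] - trim_tau;
                if (run > bsum + EPS) { bsum = run; u = rstart; v = k; }
            }
        }

        if (u >= 0) {
            DPResult res;
            res.aln_a = ra.substr(u, v - u + 1);
            res.aln_b = rb.substr(u, v - u + 1);
            res.columns = v - u + 1;
            double sc = 0.0;
            int nm = 0;
            for (int k = u; k <= v; ++k) sc += col[k];
            for (int k = u; k <= v; ++k)
                if (ra[k] != '-' && rb[k] != '-' &&
                    res_match(ra[k], rb[k], nucleotide)) ++nm;
            res.matches = nm;
            res.score = sc;
            // span starts shift by the residues trimmed off the front
            int askip = 0, bskip = 0, atail = 0, btail = 0;
            for (int k = 0; k < u; ++k) {
                if (ra[k] != '-') ++askip;
                if (rb[k] != '-') ++bskip;
            }
            for (int k = v + 1; k < C; ++k) {
                if (ra[k] != '-') ++atail;
                if (rb[k] != '-') ++btail;
            }
            res.a_start = i + 1 + askip; res.a_end = bi - atail;
            res.b_start = j + 1 + bskip; res.b_end = bj - btail;

            if (res.columns >= min_len &&
                (double)nm / res.columns >= min_identity - 1e-12 &&
                res.score >= min_score - EPS)
                kept.push_back(res);
        }

        // mask path cells + 1-cell neighborhood
        for (size_t k = 0; k < path.size(); ++k) {
            for (int di = -1; di <= 1; ++di) {
                for (int dj = -1; dj <= 1; ++dj) {
                    int pi = path[k].first + di, pj = path[k].second + dj;
                    if (pi >= 1 && pi <= m && pj >= 1 && pj <= n)
                        maskv[(size_t)(pi - 1) * n + (pj - 1)] = 1;
                }
            }
        }
        if ((int)kept.size() == max_pairs) { truncated = true; break; }
    }

    const int np = (int)kept.size();
    NumericVector score(np);
    IntegerVector a_start(np), a_end(np), b_start(np), b_end(np),
                  matches(np), columns(np);
    CharacterVector aln_a(np), aln_b(np);
    for (int k = 0; k < np; ++k) {
        score[k] = kept[k].score;
        a_start[k] = kept[k].a_start; a_end[k] = kept[k].a_end;
        b_start[k] = kept[k].b_start; b_end[k] = kept[k].b_end;
        matches[k] = kept[k].matches; columns[k] = kept[k].columns;
        aln_a[k] = kept[k].aln_a; aln_b[k] = kept[k].aln_b;
    }
    return List::create(
        Named("score") = score,
        Named("a_start") = a_start, Named("a_end") = a_end,
        Named("b_start") = b_start, Named("b_end") = b_end,
        Named("matches") = matches, Named("columns") = columns,
        Named("aligned_a") = aln_a, Named("aligned_b") = aln_b,
        Named("truncated") = truncated,
        Named("iterations") = (double)iter);
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp_str(s); }
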