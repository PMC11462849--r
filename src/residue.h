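#ifndef INTRAREP_RESIDUE_H
#define INTRAREP_RESIDUE_H

#include <string>

// Residues are uppercase on entry (enforced by the R layer).
// Ambiguity codes never match anything, including themselves: N/IUPAC codes
// for nucleotides, X/B/Z/* for proteins. U is treated as T for matching.

inline bool nuc_unambiguous(char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T' || c == 'U';
}

inline char nuc_norm(char c) { return c == 'U' ? 'T' : c; }

inline bool prot_unambiguous(char c) {
    return c != 'X' && c != 'B' && c != 'Z' && c != '*';
}

inline bool res_match(char x, char y, bool nucleotide) {
    if (nucleotide) {
        if (!nuc_unambiguous(x) || !nuc_unambiguous(y)) return false;
        return nuc_norm(x) == nuc_norm(y);
    }
    return prot_unambiguous(x) && x == y;
}

inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T'; case 'T': return 'A'; case 'U': return 'A';
    case 'C': return 'G'; case 'G': return 'C';
    case 'R': return 'Y'; case 'Y': return 'R';
    case 'S': return 'S'; case 'W': return 'W';
    case 'K': return 'M'; case 'M': return 'K';
    case 'B': return 'V'; case 'V': return 'B';
    case 'D': return 'H'; case 'H': return 'D';
    default:  return 'N';
    }
}

inline std::string revcomp_str(const std::string &s) {
    std::string out(s.rbegin(), s.rend());
    for (size_t i = 0; i < out.size(); ++i) out[i] = comp_base(out[i]);
    return out;
}

#endif
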