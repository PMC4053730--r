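#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// IUPAC nucleotide codes as base bitmasks: A=1, C=2, G=4, T=8.
static int iupac_mask(char c) {
    switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'R': return 1|4; case 'Y': return 2|8; case 'S': return 2|4;
    case 'W': return 1|8; case 'K': return 4|8; case 'M': return 1|2;
    case 'B': return 2|4|8; case 'D': return 1|4|8; case 'H': return 1|2|8;
    case 'V': return 1|2|4; case 'N': return 1|2|4|8;
    default: return -1;
    }
}

// Semi-global alignment with unit costs: the pattern is aligned
// end-to-end, the subject has free leading/trailing ends. Exact
// character comparison (sequences are expected uppercase).
//
// Tie-breaks are fixed so results are deterministic: the alignment end
// is the smallest subject position reaching the optimum, and traceback
// prefers diagonal moves (match/mismatch) over pattern-consuming gaps
// over subject-consuming gaps.
//
// Returns [edit_distance, alignment_columns, sstart, send] (1-based
// subject span; sstart > send denotes an empty span when the subject is
// skipped entirely).
// [[Rcpp::export]]
IntegerVector cpp_semiglobal_align(std::string pattern, std::string subject) {
    const int m = pattern.size(), n = subject.size();
    std::vector<std::vector<int> > D(m + 1, std::vector<int>(n + 1));
    for (int j = 0; j <= n; ++j) D[0][j] = 0;
    for (int i = 1; i <= m; ++i) D[i][0] = i;
    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            int sub = D[i-1][j-1] + (pattern[i-1] == subject[j-1] ? 0 : 1);
            int del = D[i-1][j] + 1;  // pattern char vs gap
            int ins = D[i][j-1] + 1;  // subject char vs gap
            int best = sub;
            if (del < best) best = del;
            if (ins < best) best = ins;
            D[i][j] = best;
        }
    }
    int jend = 0, dist = D[m][0];
    for (int j = 1; j <= n; ++j)
        if (D[m][j] < dist) { dist = D[m][j]; jend = j; }
    // traceback to count alignment columns and locate the subject start
    int i = m, j = jend, cols = 0;
    while (i > 0) {
        if (j > 0 &&
            D[i][j] == D[i-1][j-1] + (pattern[i-1] == subject[j-1] ? 0 : 1)) {
            --i; --j;
        } else if (D[i][j] == D[i-1][j] + 1) {
            --i;
        } else {
            --j;
        }
        ++cols;
    }
    return IntegerVector::create(dist, cols, j + 1, jend);
}

// Minimum semi-global edit distance of an IUPAC primer against a plain
// ACGT target: substitution costs 0 when the target base belongs to the
// primer symbol's base set, 1 otherwise; indels cost 1; the primer is
// aligned end-to-end, the target locally. With hamming = true, indels
// are disallowed and the minimum mismatch count over all full-length
// target windows is returned instead.
// [[Rcpp::export]]
int cpp_primer_distance(std::string primer, std::string target,
                        bool hamming) {
    const int m = primer.size(), n = target.size();
    if (m == 0) stop("primer must be non-empty");
    std::vector<int> pmask(m);
    for (int i = 0; i < m; ++i) {
        pmask[i] = iupac_mask(primer[i]);
        if (pmask[i] < 0)
            stop("unknown IUPAC symbol in primer: '%s'",
                 std::string(1, primer[i]).c_str());
    }
    std::vector<int> tmask(n);
    for (int j = 0; j < n; ++j) {
        char c = target[j];
        if (c == 'A') tmask[j] = 1;
        else if (c == 'C') tmask[j] = 2;
        else if (c == 'G') tmask[j] = 4;
        else if (c == 'T' || c == 'U') tmask[j] = 8;
        else stop("target bases must be A, C, G or T; found '%s'",
                  std::string(1, c).c_str());
    }
    if (hamming) {
        if (n < m)
            stop("hamming mode requires the target to be at least as long "
                 "as the primer");
        int best = m;
        for (int s = 0; s + m <= n; ++s) {
            int d = 0;
            for (int i = 0; i < m && d < best; ++i)
                if (!(pmask[i] & tmask[s + i])) ++d;
            if (d < best) best = d;
        }
        return best;
    }
    std::vector<int> prev(n + 1), cur(n + 1);
    for (int j = 0; j <= n; ++j) prev[j] = 0;
    for (int i = 1; i <= m; ++i) {
        cur[0] = i;
        for (int j = 1; j <= n; ++j) {
            int sub = prev[j-1] + ((pmask[i-1] & tmask[j-1]) ? 0 : 1);
            int del = prev[j] + 1;
            int ins = cur[j-1] + 1;
            int best = sub;
            if (del < best) best = del;
            if (ins < best) best = ins;
            cur[j] = best;
        }
        std::swap(prev, cur);
    }
    int dist = prev[0];
    for (int j = 1; j <= n; ++j) if (prev[j] < dist) dist = prev[j];
    return dist;
}
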