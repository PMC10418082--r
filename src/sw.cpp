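#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps, Gotoh recurrences.
// A gap of length L costs gap_open + gap_extend * (L - 1); the opening
// penalty includes the first gapped base. Columns whose *reference* base is
// 'N' score n_score regardless of the query base and are recorded as 'N'
// operations so downstream code can keep masked columns out of mismatch
// statistics. Query 'N's against a non-N reference base score `mismatch`.
//
// Op alphabet: '=' match, 'X' mismatch, 'N' masked reference column,
// 'I' insertion (query base absent from reference), 'D' deletion
// (reference base absent from query).

static inline int col_score(char q, char r, int match, int mismatch, int n_score) {
    if (r == 'N') return n_score;
    return (q == r && q != 'N') ? match : mismatch;
}

struct SwResult {
    int score;
    int qstart, qend;   // 0-based half-open on query
    int rstart, rend;   // 0-based half-open on reference
    std::string ops;
};

// Score-only pass, O(m) memory per reference.
static int sw_score_only(const std::string& q, const std::string& r,
                         int match, int mismatch, int n_score,
                         int gap_open, int gap_extend) {
    const int n = q.size(), m = r.size();
    const int NEG = INT_MIN / 4;
    std::vector<int> H(m + 1, 0), F(m + 1, NEG); // F: vertical (gap in reference)
    int best = 0;
    for (int i = 1; i <= n; ++i) {
        int Hdiag = 0;  // H[i-1][j-1]
        int Hleft = 0;  // H[i][j-1]
        int E = NEG;    // horizontal (gap in query, consumes reference)
        for (int j = 1; j <= m; ++j) {
            E = std::max(Hleft - gap_open, E - gap_extend);
            F[j] = std::max(H[j] - gap_open, F[j] - gap_extend);
            int h = Hdiag + col_score(q[i - 1], r[j - 1], match, mismatch, n_score);
            h = std::max(h, E);
            h = std::max(h, F[j]);
            h = std::max(h, 0);
            Hdiag = H[j];
            H[j] = h;
            Hleft = h;
            if (h > best) best = h;
        }
    }
    return best;
}

// Full DP with traceback; O(nm) memory, fine for tRNA-length sequences.
static SwResult sw_traceback(const std::string& q, const std::string& r,
                             int match, int mismatch, int n_score,
                             int gap_open, int gap_extend) {
    const int n = q.size(), m = r.size();
    const int NEG = INT_MIN / 4;
    std::vector<std::vector<int>> H(n + 1, std::vector<int>(m + 1, 0));
    std::vector<std::vector<int>> E(n + 1, std::vector<int>(m + 1, NEG));
    std::vector<std::vector<int>> F(n + 1, std::vector<int>(m + 1, NEG));
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            E[i][j] = std::max(H[i][j - 1] - gap_open, E[i][j - 1] - gap_extend);
            F[i][j] = std::max(H[i - 1][j] - gap_open, F[i - 1][j] - gap_extend);
            int h = H[i - 1][j - 1] + col_score(q[i - 1], r[j - 1], match, mismatch, n_score);
            h = std::max(h, E[i][j]);
            h = std::max(h, F[i][j]);
            h = std::max(h, 0);
            H[i][j] = h;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }
    SwResult res;
    res.score = best;
    std::string ops;
    int i = bi, j = bj;
    // state 0 = H, 1 = E (deletion run), 2 = F (insertion run)
    int state = 0;
    while (i > 0 && j > 0) {
        if (state == 0) {
            if (H[i][j] == 0) break;
            int diag = H[i - 1][j - 1] + col_score(q[i - 1], r[j - 1], match, mismatch, n_score);
            // deterministic tie-break: diagonal > deletion > insertion
            if (H[i][j] == diag) {
                char rb = r[j - 1];
                ops.push_back(rb == 'N' ? 'N' : ((q[i - 1] == rb && q[i - 1] != 'N') ? '=' : 'X'));
                --i; --j;
            } else if (H[i][j] == E[i][j]) {
                state = 1;
            } else {
                state = 2;
            }
        } else if (state == 1) {
            ops.push_back('D');
            // did this deletion run open here?
            if (E[i][j] == H[i][j - 1] - gap_open) { --j; state = 0; }
            else { --j; }                             // extend: E[i][j-1] - gap_extend
        } else {
            ops.push_back('I');
            if (F[i][j] == H[i - 1][j] - gap_open) { --i; state = 0; }
            else { --i; }
        }
    }
    std::reverse(ops.begin(), ops.end());
    res.ops = ops;
    res.qstart = i; res.qend = bi;
    res.rstart = j; res.rend = bj;
    return res;
}

//' @noRd
// [[Rcpp::export(name = ".sw_score_matrix")]]
IntegerMatrix sw_score_matrix(CharacterVector queries, CharacterVector refs,
                              int match, int mismatch, int n_score,
                              int gap_open, int gap_extend) {
    const int nq = queries.size(), nr = refs.size();
    std::vector<std::string> rs(nr);
    for (int k = 0; k < nr; ++k) rs[k] = as<std::string>(refs[k]);
    IntegerMatrix out(nq, nr);
    for (int i = 0; i < nq; ++i) {
        std::string q = as<std::string>(queries[i]);
        for (int k = 0; k < nr; ++k)
            out(i, k) = sw_score_only(q, rs[k], match, mismatch, n_score,
                                      gap_open, gap_extend);
    }
    return out;
}

//' @noRd
// [[Rcpp::export(name = ".sw_align_pairs")]]
List sw_align_pairs(CharacterVector queries, CharacterVector refs,
                    int match, int mismatch, int n_score,
                    int gap_open, int gap_extend) {
    const int n = queries.size();
    if (refs.size() != n) stop("queries and refs must have equal length");
    IntegerVector score(n), qstart(n), qend(n), rstart(n), rend(n);
    CharacterVector ops(n);
    for (int i = 0; i < n; ++i) {
        SwResult res = sw_traceback(as<std::string>(queries[i]),
                                    as<std::string>(refs[i]),
                                    match, mismatch, n_score,
                                    gap_open, gap_extend);
        score[i] = res.score;
        qstart[i] = res.qstart; qend[i] = res.qend;
        rstart[i] = res.rstart; rend[i] = res.rend;
        ops[i] = res.ops;
    }
    return List::create(_["score"] = score,
                        _["qstart"] = qstart, _["qend"] = qend,
                        _["rstart"] = rstart, _["rend"] = rend,
                        _["ops"] = ops);
}
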