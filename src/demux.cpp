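#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Batch adapter-barcode matcher. For each read, finds per adapter the
// 3'-most substring within the last (pattern length + window_slack) bases
// whose Hamming distance to the pattern (barcode + splint context) is
// minimal. A read is assigned when exactly one adapter achieves distance
// <= 1; two or more such adapters make it ambiguous.
// Returns: n_hits (adapters within distance 1), adapter (1-based index of
// the unique hit, 0 otherwise), match_start (1-based start of that hit).

//' @noRd
// [[Rcpp::export(name = ".barcode_match")]]
List barcode_match(CharacterVector reads, CharacterVector patterns,
                   int window_slack) {
    const int n = reads.size(), na = patterns.size();
    std::vector<std::string> pats(na);
    for (int k = 0; k < na; ++k) pats[k] = as<std::string>(patterns[k]);
    IntegerVector n_hits(n), adapter(n), match_start(n);
    for (int i = 0; i < n; ++i) {
        const std::string s = as<std::string>(reads[i]);
        const int sl = s.size();
        int hits = 0, hit_k = -1, hit_start = -1;
        for (int k = 0; k < na; ++k) {
            const std::string& p = pats[k];
            const int pl = p.size();
            if (pl > sl) continue;
            const int window = pl + window_slack;
            const int from = std::max(0, sl - window);
            int best = INT_MAX, best_start = -1;
            for (int st = from; st + pl <= sl; ++st) {
                int d = 0;
                for (int j = 0; j < pl && d <= best; ++j)
                    if (s[st + j] != p[j]) ++d;
                if (d <= best) { best = d; best_start = st; } // 3'-most on ties
            }
            if (best <= 1) { ++hits; hit_k = k; hit_start = best_start; }
        }
        n_hits[i] = hits;
        adapter[i] = (hits == 1) ? hit_k + 1 : 0;
        match_start[i] = (hits == 1) ? hit_start + 1 : NA_INTEGER;
    }
    return List::create(_["n_hits"] = n_hits, _["adapter"] = adapter,
                        _["match_start"] = match_start);
}
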