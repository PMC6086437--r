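#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Smith-Waterman local alignment with match/mismatch scoring and a linear gap
// penalty. Returns the maximal local score, one optimal span pair and traceback
// statistics. Ties on the optimal cell are broken toward the smallest
// (q_end, s_end) pair; traceback prefers diagonal, then gap-in-subject, then
// gap-in-query, so the reported span is deterministic.
// [[Rcpp::export]]
List sw_align_cpp(std::string q, std::string s, double match, double mismatch,
                  double gap) {
    const int n = (int)q.size();
    const int m = (int)s.size();
    if (n == 0 || m == 0) {
        return List::create(_["score"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
                            _["s_start"] = 0, _["s_end"] = 0,
                            _["align_length"] = 0, _["matches"] = 0,
                            _["gaps"] = 0);
    }
    std::vector<double> H((size_t)(n + 1) * (m + 1), 0.0);
    const int W = m + 1;
    double best = 0.0;
    int bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
            double h = H[(size_t)(i - 1) * W + (j - 1)] + sub;
            double up = H[(size_t)(i - 1) * W + j] + gap;
            double left = H[(size_t)i * W + (j - 1)] + gap;
            if (up > h) h = up;
            if (left > h) h = left;
            if (h < 0.0) h = 0.0;
            H[(size_t)i * W + j] = h;
            if (h > best) {  // strict > keeps the first (smallest i, then j)
                best = h;
                bi = i;
                bj = j;
            }
        }
    }
    if (best <= 0.0) {
        return List::create(_["score"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
                            _["s_start"] = 0, _["s_end"] = 0,
                            _["align_length"] = 0, _["matches"] = 0,
                            _["gaps"] = 0);
    }
    // traceback
    int i = bi, j = bj;
    int alen = 0, nmatch = 0, ngap = 0;
    while (i > 0 && j > 0 && H[(size_t)i * W + j] > 0.0) {
        double h = H[(size_t)i * W + j];
        double sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
        if (H[(size_t)(i - 1) * W + (j - 1)] + sub == h) {
            if (q[i - 1] == s[j - 1]) ++nmatch;
            ++alen;
            --i;
            --j;
        } else if (H[(size_t)(i - 1) * W + j] + gap == h) {
            ++alen;
            ++ngap;
            --i;
        } else {
            ++alen;
            ++ngap;
            --j;
        }
    }
    return List::create(_["score"] = best, _["q_start"] = i + 1,
                        _["q_end"] = bi, _["s_start"] = j + 1, _["s_end"] = bj,
                        _["align_length"] = alen, _["matches"] = nmatch,
                        _["gaps"] = ngap);
}
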