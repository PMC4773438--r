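#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <vector>
#include <string>

using namespace Rcpp;

// Semi-global (glocal) affine-gap alignment of a read against an amplicon
// reference, augmented with a flat-cost long-deletion state so that one
// deletion of 100-400 bp outscores fragmented representations.
//
// The query is consumed end to end; reference overhangs at either end are
// free. States follow Gotoh: M (diagonal), X (insertion in the query,
// consumes query), Y (deletion, consumes reference). A fourth transition
// "jump" deletes >= min_jump reference bases for a single flat cost,
// implemented with a per-row running prefix maximum so the DP stays
// O(n * m).
//
// Tie-breaking in the traceback prefers M over Y over X over jump, which
// pushes indels to the leftmost equivalent placement; callers additionally
// left-normalize extracted indels.

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
List align_semiglobal_cpp(const std::string& q, const std::string& r,
                          int match, int mismatch,
                          int gap_open, int gap_ext,
                          int jump_cost, int min_jump) {
    const int n = (int) q.size();
    const int m = (int) r.size();
    if (n == 0 || m == 0) stop("empty query or reference");

    const size_t W = (size_t) m + 1;
    std::vector<int> M((size_t)(n + 1) * W, NEG);
    std::vector<int> X((size_t)(n + 1) * W, NEG);
    std::vector<int> Y((size_t)(n + 1) * W, NEG);
    std::vector<int> H((size_t)(n + 1) * W, NEG);
    // source column of the best jump into (i, j); -1 when no jump possible
    std::vector<int> Jsrc((size_t)(n + 1) * W, -1);
    std::vector<int> Jval((size_t)(n + 1) * W, NEG);

#define AT(i, j) ((size_t)(i) * W + (size_t)(j))

    // free leading reference gap
    for (int j = 0; j <= m; ++j) H[AT(0, j)] = 0;
    // query bases before the reference starts must be insertions
    for (int i = 1; i <= n; ++i) {
        X[AT(i, 0)] = -(gap_open + i * gap_ext);
        H[AT(i, 0)] = X[AT(i, 0)];
    }

    for (int i = 1; i <= n; ++i) {
        int rowbest = NEG, rowbestcol = -1;
        for (int j = 1; j <= m; ++j) {
            // columns <= j - min_jump become eligible jump sources
            int src = j - min_jump;
            if (src >= 0 && H[AT(i, src)] > rowbest) {
                rowbest = H[AT(i, src)];
                rowbestcol = src;
            }

            int sub = (q[(size_t) i - 1] == r[(size_t) j - 1]) ? match : mismatch;
            int mm = H[AT(i - 1, j - 1)] + sub;
            M[AT(i, j)] = mm;

            int xo = H[AT(i - 1, j)];
            int xopen = (xo <= NEG / 2) ? NEG : xo - gap_open - gap_ext;
            int xext  = (X[AT(i - 1, j)] <= NEG / 2) ? NEG : X[AT(i - 1, j)] - gap_ext;
            X[AT(i, j)] = std::max(xopen, xext);

            int yo = H[AT(i, j - 1)];
            int yopen = (yo <= NEG / 2) ? NEG : yo - gap_open - gap_ext;
            int yext  = (Y[AT(i, j - 1)] <= NEG / 2) ? NEG : Y[AT(i, j - 1)] - gap_ext;
            Y[AT(i, j)] = std::max(yopen, yext);

            if (rowbestcol >= 0) {
                Jval[AT(i, j)] = rowbest - jump_cost;
                Jsrc[AT(i, j)] = rowbestcol;
            }

            int h = M[AT(i, j)];
            if (Y[AT(i, j)] > h) h = Y[AT(i, j)];
            if (X[AT(i, j)] > h) h = X[AT(i, j)];
            if (Jval[AT(i, j)] > h) h = Jval[AT(i, j)];
            H[AT(i, j)] = h;
        }
    }

    // free trailing reference gap: best score anywhere on the last row
    int best = NEG, bestj = 0;
    for (int j = 0; j <= m; ++j) {
        if (H[AT(n, j)] > best) { best = H[AT(n, j)]; bestj = j; }
    }

    // traceback; preference M > Y > X > jump at ties
    std::string ops;
    ops.reserve((size_t) n + 32);
    int i = n, j = bestj;
    // state codes: 0 = H (choose), 1 = X, 2 = Y
    int state = 0;
    while (i > 0) {
        if (state == 0) {
            int h = H[AT(i, j)];
            if (j > 0 && M[AT(i, j)] == h) {
                ops.push_back(q[(size_t) i - 1] == r[(size_t) j - 1] ? '=' : 'X');
                --i; --j;
                state = 0;
            } else if (j > 0 && Y[AT(i, j)] == h) {
                state = 2;
            } else if (X[AT(i, j)] == h) {
                state = 1;
            } else if (j > 0 && Jval[AT(i, j)] == h) {
                int src = Jsrc[AT(i, j)];
                for (int t = 0; t < j - src; ++t) ops.push_back('D');
                j = src;
                state = 0;
            } else {
                stop("traceback failure (inconsistent DP matrices)");
            }
        } else if (state == 1) { // insertion in query
            ops.push_back('I');
            // was this an opening or an extension?
            int open = (H[AT(i - 1, j)] <= NEG / 2) ? NEG : H[AT(i - 1, j)] - gap_open - gap_ext;
            int ext  = (X[AT(i - 1, j)] <= NEG / 2) ? NEG : X[AT(i - 1, j)] - gap_ext;
            int cur = X[AT(i, j)];
            --i;
            if (ext == cur && i > 0) state = 1; else state = 0;
            if (open != cur && ext != cur) stop("traceback failure in X state");
        } else { // deletion
            ops.push_back('D');
            int open = (H[AT(i, j - 1)] <= NEG / 2) ? NEG : H[AT(i, j - 1)] - gap_open - gap_ext;
            int ext  = (Y[AT(i, j - 1)] <= NEG / 2) ? NEG : Y[AT(i, j - 1)] - gap_ext;
            int cur = Y[AT(i, j)];
            --j;
            if (ext == cur) state = 2; else state = 0;
            if (open != cur && ext != cur) stop("traceback failure in Y state");
        }
    }
#undef AT

    std::reverse(ops.begin(), ops.end());

    return List::create(_["score"] = best,
                        _["ref_start"] = j,
                        _["ops"] = ops);
}
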