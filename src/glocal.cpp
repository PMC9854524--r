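#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Glocal (global-in-query, local-in-target) affine-gap alignment.
//
// Three-state affine DP over query i = 1..n (rows) and target j = 1..m:
//   M(i,j): query[i] aligned to target[j]
//   X(i,j): query[i] aligned to a gap (gap in target)
//   Y(i,j): target[j] aligned to a gap (gap in query)
// A gap run of length L costs gapOpen + (L-1) * gapExtend (penalties are
// negative integers; FastA convention). The target prefix and suffix are
// free: row 0 scores 0 at every j, and the optimum is taken over all
// (n, j) cells that do not end in a gap-in-query column (trailing target
// residues are simply left out of the local window instead).
//
// Traceback ties prefer diagonal (M), then gap-in-target (X), then
// gap-in-query (Y); among equal-scoring end columns the smallest target
// end coordinate wins. This makes the reported alignment deterministic.

static const int NEG = std::numeric_limits<int>::min() / 4;

// [[Rcpp::export(name = ".glocal_align_cpp")]]
List glocal_align_cpp(IntegerVector qIdx, IntegerVector tIdx,
                      IntegerMatrix sub, int gapOpen, int gapExtend) {
    const int n = qIdx.size(), m = tIdx.size();
    if (n == 0 || m == 0) stop("empty query or target");

    std::vector<std::vector<int>> M(n + 1, std::vector<int>(m + 1, NEG));
    std::vector<std::vector<int>> X(n + 1, std::vector<int>(m + 1, NEG));
    std::vector<std::vector<int>> Y(n + 1, std::vector<int>(m + 1, NEG));

    // row 0: free start anywhere in the target
    for (int j = 0; j <= m; ++j) M[0][j] = 0;
    // column 0: query consumed entirely against gaps before any target
    for (int i = 1; i <= n; ++i) X[i][0] = gapOpen + (i - 1) * gapExtend;

    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            const int s = sub(qIdx[i - 1], tIdx[j - 1]);
            int dM = M[i - 1][j - 1], dX = X[i - 1][j - 1], dY = Y[i - 1][j - 1];
            int best = dM;
            if (dX > best) best = dX;
            if (dY > best) best = dY;
            if (best > NEG) M[i][j] = best + s;

            int xo = (M[i - 1][j] > Y[i - 1][j]) ? M[i - 1][j] : Y[i - 1][j];
            int xb = NEG;
            if (xo > NEG) xb = xo + gapOpen;
            if (X[i - 1][j] > NEG && X[i - 1][j] + gapExtend > xb)
                xb = X[i - 1][j] + gapExtend;
            X[i][j] = xb;

            int yo = (M[i][j - 1] > X[i][j - 1]) ? M[i][j - 1] : X[i][j - 1];
            int yb = NEG;
            if (yo > NEG) yb = yo + gapOpen;
            if (Y[i][j - 1] > NEG && Y[i][j - 1] + gapExtend > yb)
                yb = Y[i][j - 1] + gapExtend;
            Y[i][j] = yb;
        }
    }

    // final: max over j of M/X in row n (Y excluded: trailing gap-in-query
    // columns are dominated by shortening the local window)
    int bestScore = NEG, bestJ = 0, bestState = 1; // 1=M, 2=X
    // j = 0: whole query against gaps (degenerate but legal)
    if (X[n][0] > bestScore) { bestScore = X[n][0]; bestJ = 0; bestState = 2; }
    for (int j = 0; j <= m; ++j) {
        if (M[n][j] > bestScore) { bestScore = M[n][j]; bestJ = j; bestState = 1; }
        if (X[n][j] > bestScore) { bestScore = X[n][j]; bestJ = j; bestState = 2; }
    }

    // traceback
    std::string qa, ta;
    std::vector<int> qcol, tcol; // indices, 0 for gap
    int i = n, j = bestJ, state = bestState;
    while (i > 0) {
        if (state == 1) { // M: consumes q[i], t[j]
            const int s = sub(qIdx[i - 1], tIdx[j - 1]);
            qcol.push_back(i); tcol.push_back(j);
            int prev = M[i][j] - s;
            if (M[i - 1][j - 1] == prev) state = 1;
            else if (X[i - 1][j - 1] == prev) state = 2;
            else state = 3;
            --i; --j;
        } else if (state == 2) { // X: consumes q[i], gap in target
            qcol.push_back(i); tcol.push_back(0);
            if (j == 0) {
                state = 2; --i; continue;
            }
            if (M[i - 1][j] > NEG && M[i - 1][j] + gapOpen == X[i][j]) state = 1;
            else if (X[i - 1][j] > NEG && X[i - 1][j] + gapExtend == X[i][j]) state = 2;
            else state = 3;
            --i;
        } else { // Y: consumes t[j], gap in query
            qcol.push_back(0); tcol.push_back(j);
            if (M[i][j - 1] > NEG && M[i][j - 1] + gapOpen == Y[i][j]) state = 1;
            else if (X[i][j - 1] > NEG && X[i][j - 1] + gapOpen == Y[i][j]) state = 2;
            else state = 3;
            --j;
        }
        if (i == 0 && state == 3) stop("traceback error"); // leading Y impossible
    }

    int tStart = 0, tEnd = 0;
    for (int k = (int)qcol.size() - 1; k >= 0; --k) {
        if (tcol[k] > 0) {
            if (tStart == 0) tStart = tcol[k];
            tEnd = tcol[k];
        }
    }
    // columns were collected back-to-front
    std::reverse(qcol.begin(), qcol.end());
    std::reverse(tcol.begin(), tcol.end());

    return List::create(
        _["score"] = bestScore,
        _["qcol"] = IntegerVector(qcol.begin(), qcol.end()),
        _["tcol"] = IntegerVector(tcol.begin(), tcol.end()),
        _["targetStart"] = tStart == 0 ? NA_INTEGER : tStart,
        _["targetEnd"] = tEnd == 0 ? NA_INTEGER : tEnd);
}

// Exhaustive enumeration oracle: recursively walks every gapped alignment
// of the whole query against every contiguous target substring, scoring
// affine gap runs incrementally, and returns the maximum score found.
// Deliberately has no memoisation and shares nothing with the DP above.
struct Enum {
    const IntegerVector &q, &t;
    const IntegerMatrix &sub;
    int open, ext, n, m, best;

    Enum(const IntegerVector &q_, const IntegerVector &t_,
         const IntegerMatrix &sub_, int open_, int ext_)
        : q(q_), t(t_), sub(sub_), open(open_), ext(ext_),
          n(q_.size()), m(t_.size()), best(NEG) {}

    // i, j: next query/target indices to consume (0-based); lastGap:
    // 0 none, 1 gap-in-target run, 2 gap-in-query run; jEndLimit: target
    // consumption beyond j is allowed until the substring closes.
    void walk(int i, int j, int lastGap, int score) {
        if (i == n) { // query consumed; substring may end here
            if (score > best) best = score;
            return;
        }
        if (j < m) { // align q[i] with t[j]
            walk(i + 1, j + 1, 0, score + sub(q[i], t[j]));
        }
        // q[i] against a gap
        walk(i + 1, j, 1, score + (lastGap == 1 ? ext : open));
        if (j < m && i > 0) { // t[j] against a gap (internal only)
            walk(i, j + 1, 2, score + (lastGap == 2 ? ext : open));
        }
    }
};

// [[Rcpp::export(name = ".glocal_enum_cpp")]]
int glocal_enum_cpp(IntegerVector qIdx, IntegerVector tIdx,
                    IntegerMatrix sub, int gapOpen, int gapExtend) {
    const int m = tIdx.size();
    int best = NEG;
    // empty substring: whole query in one gap run
    int allGap = gapOpen + (qIdx.size() - 1) * gapExtend;
    if (allGap > best) best = allGap;
    for (int a = 0; a < m; ++a) {
        // substrings starting at a: the walk consumes target residues
        // from t[a] onward and may stop at any point once the query is
        // exhausted, so every end coordinate b >= a is covered
        IntegerVector subT(tIdx.begin() + a, tIdx.end());
        Enum e(qIdx, subT, sub, gapOpen, gapExtend);
        e.walk(0, 0, 0, 0);
        if (e.best > best) best = e.best;
    }
    return best;
}
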