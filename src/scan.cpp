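#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment of profile match columns against a query.
//
// scores: 21 x L matrix (rows = 20 residues + zero-scoring ambiguity row),
// query: 1-based residue codes into the score rows,
// mask:  query positions already claimed by a previous hit; an alignment can
//        neither match nor span a masked residue.
//
// States: M (match column j consumes query residue i), X (query insertion,
// consumes i only), Y (column deletion, consumes j only). Insertions carry
// gap costs but no emission score. Returns the single best local hit with
// its traceback column map; repeated calls with updated masks implement
// greedy best-first extraction of non-overlapping hits.
//
// Tie-breaking: cells are examined with ascending end position and the
// maximum is replaced only on strict improvement, so equal-scoring hits
// resolve to the earliest end (and thus smallest start for equal lengths);
// traceback prefers M over X over Y for determinism.

// [[Rcpp::export(name = ".sw_best_hit")]]
List sw_best_hit(IntegerVector query, NumericMatrix scores,
                 double gapOpen, double gapExtend, LogicalVector mask) {
  const int n = query.size();
  const int L = scores.ncol();
  const double NEG = -1e30;
  if (n == 0 || L == 0)
    return List::create(_["score"] = 0.0, _["start"] = NA_INTEGER,
                        _["end"] = NA_INTEGER,
                        _["col_map"] = IntegerVector(L, NA_INTEGER));

  std::vector<double> M((n + 1) * (L + 1), 0.0), X(M), Y(M);
  for (size_t k = 0; k < M.size(); ++k) { X[k] = NEG; Y[k] = NEG; }
  auto at = [L](int i, int j) { return i * (L + 1) + j; };

  double best = 0.0; int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    const bool blocked = mask[i - 1];
    const int q = query[i - 1] - 1;  // 0-based row
    for (int j = 1; j <= L; ++j) {
      double m, x;
      if (blocked) { m = NEG; x = NEG; }
      else {
        double prev = 0.0;
        double v = M[at(i - 1, j - 1)]; if (v > prev) prev = v;
        v = X[at(i - 1, j - 1)]; if (v > prev) prev = v;
        v = Y[at(i - 1, j - 1)]; if (v > prev) prev = v;
        m = scores(q, j - 1) + prev;
        double xo = M[at(i - 1, j)] + gapOpen;
        double xe = X[at(i - 1, j)] + gapExtend;
        x = xo >= xe ? xo : xe;
      }
      double yo = M[at(i, j - 1)] + gapOpen;
      double ye = Y[at(i, j - 1)] + gapExtend;
      double y = yo >= ye ? yo : ye;
      M[at(i, j)] = m; X[at(i, j)] = x; Y[at(i, j)] = y;
      if (m > best) { best = m; bi = i; bj = j; }
    }
  }

  IntegerVector colMap(L, NA_INTEGER);
  int start = NA_INTEGER, end = NA_INTEGER;
  if (bi > 0) {
    end = bi;
    int i = bi, j = bj, state = 0;  // 0 = M, 1 = X, 2 = Y
    while (true) {
      if (state == 0) {
        colMap[j - 1] = i;
        start = i;
        double prev = M[at(i, j)] - scores(query[i - 1] - 1, j - 1);
        int pi = i - 1, pj = j - 1;
        if (prev <= 0.0 || pi == 0 || pj == 0) break;
        double dm = M[at(pi, pj)], dx = X[at(pi, pj)], dy = Y[at(pi, pj)];
        if (dm >= dx && dm >= dy) { i = pi; j = pj; state = 0; }
        else if (dx >= dy) { i = pi; j = pj; state = 1; }
        else { i = pi; j = pj; state = 2; }
      } else if (state == 1) {
        if (M[at(i - 1, j)] + gapOpen >= X[at(i - 1, j)] + gapExtend)
          state = 0;
        i -= 1;
      } else {
        if (M[at(i, j - 1)] + gapOpen >= Y[at(i, j - 1)] + gapExtend)
          state = 0;
        j -= 1;
      }
    }
  }
  return List::create(_["score"] = best, _["start"] = start, _["end"] = end,
                      _["col_map"] = colMap);
}
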