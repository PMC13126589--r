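#include <Rcpp.h>
using namespace Rcpp;

// Cross-validated testing balanced accuracy for every candidate locus
// tuple at once. `cells` holds, per record (row) and tuple (column), the
// flattened genotype-cell index in 0..n_cells-1 (-1 when any genotype is
// missing). `y` is 1 for responders, 0 for non-responders; `fold` in
// 1..n_folds. For each tuple and fold the training counts are the totals
// minus the held-out fold's counts; a cell is favorable when
// r_cell / n_cell >= R / N (training responder/non-responder totals),
// evaluated by exact cross-multiplication so integer ties are handled
// without floating error. Empty training cells are indeterminate; test
// records falling in them (or with missing genotypes) are excluded from
// the balanced-accuracy terms. A fold whose evaluable test set lacks one
// class yields NA.
// [[Rcpp::export]]
NumericMatrix mdr_cv_ba(const IntegerMatrix& cells, const IntegerVector& y,
                        const IntegerVector& fold, int n_folds,
                        int n_cells) {
  const int n = cells.nrow(), P = cells.ncol();
  if (y.size() != n || fold.size() != n)
    stop("length mismatch between cells, y and fold");
  NumericMatrix ba(P, n_folds);
  std::vector<int> rc((size_t)n_cells * n_folds), nc((size_t)n_cells * n_folds);
  std::vector<int> rtot(n_cells), ntot(n_cells);
  for (int p = 0; p < P; ++p) {
    std::fill(rc.begin(), rc.end(), 0);
    std::fill(nc.begin(), nc.end(), 0);
    std::fill(rtot.begin(), rtot.end(), 0);
    std::fill(ntot.begin(), ntot.end(), 0);
    for (int i = 0; i < n; ++i) {
      int c = cells(i, p);
      if (c < 0) continue;
      if (c >= n_cells) stop("cell index out of range");
      int f = fold[i] - 1;
      if (f < 0 || f >= n_folds) stop("fold index out of range");
      if (y[i] == 1) { ++rc[(size_t)c * n_folds + f]; ++rtot[c]; }
      else           { ++nc[(size_t)c * n_folds + f]; ++ntot[c]; }
    }
    for (int f = 0; f < n_folds; ++f) {
      long long trR = 0, trN = 0;
      for (int c = 0; c < n_cells; ++c) {
        trR += rtot[c] - rc[(size_t)c * n_folds + f];
        trN += ntot[c] - nc[(size_t)c * n_folds + f];
      }
      double TP = 0, FN = 0, TN = 0, FP = 0;
      for (int c = 0; c < n_cells; ++c) {
        int teR = rc[(size_t)c * n_folds + f];
        int teN = nc[(size_t)c * n_folds + f];
        if (teR == 0 && teN == 0) continue;
        long long tr = rtot[c] - teR, tn = ntot[c] - teN;
        if (tr == 0 && tn == 0) continue;  // indeterminate cell
        bool fav = tr * trN >= trR * tn;
        if (fav) { TP += teR; FP += teN; }
        else     { FN += teR; TN += teN; }
      }
      bool haveR = (TP + FN) > 0, haveN = (TN + FP) > 0;
      ba(p, f) = (haveR && haveN)
        ? 0.5 * (TP / (TP + FN) + TN / (TN + FP))
        : NA_REAL;
    }
  }
  return ba;
}
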