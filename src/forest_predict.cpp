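#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Bulk vote-fraction prediction for a fitted randomForest classification
// forest, reading the forest arrays directly (treemap, nodestatus, bestvar,
// xbestsplit, nodepred). Returns, per row of X, the fraction of trees voting
// for each class (identical to predict(rf, type = "prob")).
//
// Conventions of the randomForest C code: nodestatus == -1 marks a terminal
// node; numeric splits send x <= xbestsplit to the left daughter.
//
// Rows are processed in blocks that are transposed into a contiguous
// feature buffer, and trees are walked per block, so both the feature
// matrix and the tree arrays are read cache-coherently on multi-megapixel
// inputs.
// [[Rcpp::export(name = ".forest_votes_cpp")]]
NumericMatrix forest_votes_cpp(const NumericMatrix& X,
                               const IntegerVector& ldaughter,
                               const IntegerVector& rdaughter,
                               const IntegerMatrix& nodestatus,
                               const IntegerMatrix& bestvar,
                               const NumericMatrix& xbestsplit,
                               const IntegerMatrix& nodepred,
                               const int nclass) {
  const int n = X.nrow();
  const int p = X.ncol();
  const int ntree = nodestatus.ncol();
  const int nrnodes = nodestatus.nrow();
  const int block = 4096;
  NumericMatrix votes(n, nclass);
  std::vector<double> buf((size_t)block * p);

  for (int b0 = 0; b0 < n; b0 += block) {
    const int bn = (b0 + block < n) ? block : n - b0;
    // transpose the block: buf[i * p + j] = X(b0 + i, j)
    for (int j = 0; j < p; ++j) {
      const double* xj = &X(0, j);
      for (int i = 0; i < bn; ++i) buf[(size_t)i * p + j] = xj[b0 + i];
    }
    for (int t = 0; t < ntree; ++t) {
      const int* ld = &ldaughter[(R_xlen_t)t * nrnodes];
      const int* rd = &rdaughter[(R_xlen_t)t * nrnodes];
      const int* st = &nodestatus(0, t);
      const int* bv = &bestvar(0, t);
      const double* sp = &xbestsplit(0, t);
      const int* np = &nodepred(0, t);
      for (int i = 0; i < bn; ++i) {
        const double* x = &buf[(size_t)i * p];
        int k = 0;
        while (st[k] != -1) {
          k = (x[bv[k] - 1] <= sp[k]) ? (ld[k] - 1) : (rd[k] - 1);
        }
        votes(b0 + i, np[k] - 1) += 1.0;
      }
    }
  }
  const double inv = 1.0 / ntree;
  for (int j = 0; j < nclass; ++j) {
    double* vj = &votes(0, j);
    for (int i = 0; i < n; ++i) vj[i] *= inv;
  }
  return votes;
}
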