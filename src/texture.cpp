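#include <Rcpp.h>
using namespace Rcpp;

// Symmetric grey-level co-occurrence counts for one 2-D slice.
// `levels` codes voxels 1..nlevels inside the mask and 0 outside; a pair
// contributes only when both ends are inside. Counts are accumulated in
// both orders, so the matrix is symmetric by construction.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_counts(IntegerMatrix levels, int nlevels,
                              int dr, int dc) {
  const int nr = levels.nrow(), nc = levels.ncol();
  NumericMatrix out(nlevels, nlevels);
  const int* lev = INTEGER(levels);
  double* o = REAL(out);
  const int i_lo = std::max(0, -dr), i_hi = std::min(nr, nr - dr);
  const int j_lo = std::max(0, -dc), j_hi = std::min(nc, nc - dc);
  for (int j = j_lo; j < j_hi; ++j) {
    const int* ca = lev + (R_xlen_t)j * nr;
    const int* cb = lev + (R_xlen_t)(j + dc) * nr + dr;
    for (int i = i_lo; i < i_hi; ++i) {
      const int a = ca[i], b = cb[i];
      if (a > 0 && b > 0) {
        o[(R_xlen_t)(b - 1) * nlevels + (a - 1)] += 1.0;
        o[(R_xlen_t)(a - 1) * nlevels + (b - 1)] += 1.0;
      }
    }
  }
  return out;
}

// Grey-level run-length counts along direction (dr, dc) for one 2-D slice:
// maximal runs of constant level fully inside the mask. Out-of-mask voxels
// (level 0) break runs. Each run is counted once (a direction and its
// opposite describe the same runs).
// [[Rcpp::export]]
NumericMatrix cpp_glrlm_counts(IntegerMatrix levels, int nlevels,
                               int dr, int dc) {
  const int nr = levels.nrow(), nc = levels.ncol();
  const int maxlen = nr > nc ? nr : nc;
  NumericMatrix out(nlevels, maxlen);
  const int* lev = INTEGER(levels);
  double* o = REAL(out);
  for (int j = 0; j < nc; ++j) {
    const int* cj = lev + (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      const int v = cj[i];
      if (v <= 0) continue;
      const int pi = i - dr, pj = j - dc;
      const bool is_start = pi < 0 || pi >= nr || pj < 0 || pj >= nc ||
        lev[(R_xlen_t)pj * nr + pi] != v;
      if (!is_start) continue;
      int len = 1, ci = i + dr, cj2 = j + dc;
      while (ci >= 0 && ci < nr && cj2 >= 0 && cj2 < nc &&
             lev[(R_xlen_t)cj2 * nr + ci] == v) {
        ++len; ci += dr; cj2 += dc;
      }
      o[(R_xlen_t)(len - 1) * nlevels + (v - 1)] += 1.0;
    }
  }
  return out;
}
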