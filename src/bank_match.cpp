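#include <Rcpp.h>
using namespace Rcpp;

// Exact nearest bank entry in the (centroid, spread) plane.
// Returns 1-based indices; ties resolve to the first (lowest-index) entry,
// which with a (mode, width)-ordered bank means the smaller mode, then the
// smaller width. NA queries yield NA.
// [[Rcpp::export]]
IntegerVector nearest_cs(NumericVector C, NumericVector S,
                         NumericVector Cb, NumericVector Sb) {
  const R_xlen_t n = C.size(), m = Cb.size();
  if (S.size() != n || Sb.size() != m)
    stop("nearest_cs: inconsistent input lengths");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double ci = C[i], si = S[i];
    if (!R_finite(ci) || !R_finite(si)) {
      out[i] = NA_INTEGER;
      continue;
    }
    double best = R_PosInf;
    R_xlen_t besti = 0;
    for (R_xlen_t j = 0; j < m; ++j) {
      const double dc = ci - Cb[j], ds = si - Sb[j];
      const double d2 = dc * dc + ds * ds;
      if (d2 < best) {
        best = d2;
        besti = j;
      }
    }
    out[i] = static_cast<int>(besti + 1);
  }
  return out;
}
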