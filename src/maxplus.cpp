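#include <Rcpp.h>
using namespace Rcpp;

// Maximum of G12(i,j) + G13t(k,i) + G23t(k,j) over all index triples.
// Used to join per-pair objective surfaces in exhaustive grid searches over
// three blocks (the transposed arguments make the inner loop contiguous).
// [[Rcpp::export(rng = false)]]
double maxplus3_max(NumericMatrix G12, NumericMatrix G13t, NumericMatrix G23t) {
  const int m = G12.nrow();
  double best = R_NegInf;
  for (int i = 0; i < m; ++i) {
    const double *c13 = &G13t(0, i);
    for (int j = 0; j < m; ++j) {
      const double *c23 = &G23t(0, j);
      double bi = R_NegInf;
      for (int k = 0; k < m; ++k) {
        const double v = c13[k] + c23[k];
        if (v > bi) bi = v;
      }
      const double tot = G12(i, j) + bi;
      if (tot > best) best = tot;
    }
  }
  return best;
}
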