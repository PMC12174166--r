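#include <Rcpp.h>
using namespace Rcpp;

// Best-match-average (FunSimAvg) over all disease pairs.
//
// termIdx: per-disease 0-based indices into the term-similarity matrix S.
// weights: per-disease term weights (already rescaled to [0,1] when
//          weighted = true; ignored otherwise).
// Score(i,j) = 0.5 * (wmean_t max_u s'(t,u) + wmean_u max_t s'(t,u))
// with s'(t,u) = S(t,u) * sqrt(w_t * w_u) (or arithmetic mean coupling),
// and wmean the weight-weighted mean; unweighted reduces to plain BMA.
// [[Rcpp::export(name = ".bmaPairwise")]]
NumericMatrix bmaPairwise(List termIdx, List weights, NumericMatrix S,
                          bool weighted, bool geometric) {
  int n = termIdx.size();
  NumericMatrix out(n, n);
  std::vector<IntegerVector> idx(n);
  std::vector<NumericVector> wts(n);
  for (int i = 0; i < n; ++i) {
    idx[i] = termIdx[i];
    wts[i] = weights[i];
  }
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      const IntegerVector &ti = idx[i], &tj = idx[j];
      const NumericVector &wi = wts[i], &wj = wts[j];
      int ni = ti.size(), nj = tj.size();
      std::vector<double> colMax(nj, R_NegInf);
      double num1 = 0.0, den1 = 0.0;
      for (int a = 0; a < ni; ++a) {
        double rowMax = R_NegInf;
        for (int b = 0; b < nj; ++b) {
          double s = S(ti[a], tj[b]);
          if (weighted) {
            double g = geometric ? std::sqrt(wi[a] * wj[b])
                                 : 0.5 * (wi[a] + wj[b]);
            s *= g;
          }
          if (s > rowMax) rowMax = s;
          if (s > colMax[b]) colMax[b] = s;
        }
        double w = weighted ? wi[a] : 1.0;
        num1 += w * rowMax;
        den1 += w;
      }
      double num2 = 0.0, den2 = 0.0;
      for (int b = 0; b < nj; ++b) {
        double w = weighted ? wj[b] : 1.0;
        num2 += w * colMax[b];
        den2 += w;
      }
      double score = 0.0;
      if (den1 > 0 && den2 > 0)
        score = 0.5 * (num1 / den1 + num2 / den2);
      out(i, j) = score;
      out(j, i) = score;
    }
  }
  return out;
}
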