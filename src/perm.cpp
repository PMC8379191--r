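#include <Rcpp.h>
using namespace Rcpp;

// Conditional permutation null for the self-excluded Getis-Ord ratio.
// For each cell i, x_i is held fixed and the remaining n-1 values are
// permuted over the remaining cells; G_i under one permutation is the
// sum of W_i values drawn without replacement from the others, divided
// by their (fixed) total. Returns per cell: mean, variance, z-score of
// the observed G_i, and the upper-tail empirical p-value with the
// add-one correction.
//
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix permNullCpp(NumericVector x, List nbr, int nPerm) {
  int n = x.size();
  NumericMatrix out(n, 4);
  std::fill(out.begin(), out.end(), NA_REAL);
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += x[i];
  std::vector<double> others(n - 1);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double denom = total - x[i];
    if (denom <= 0.0) continue;
    IntegerVector nb = nbr[i];
    int k = nb.size();
    // observed numerator
    double numObs = 0.0;
    for (int j = 0; j < k; ++j) numObs += x[nb[j] - 1];
    double gObs = numObs / denom;
    if (k == 0) { out(i, 0) = 0.0; out(i, 1) = 0.0; out(i, 3) = 1.0; continue; }
    int m = 0;
    for (int j = 0; j < n; ++j) if (j != i) others[m++] = x[j];
    double sum = 0.0, sumsq = 0.0;
    int ge = 0;
    for (int b = 0; b < nPerm; ++b) {
      // partial Fisher-Yates: first k entries become a uniform draw
      // without replacement
      double s = 0.0;
      for (int t = 0; t < k; ++t) {
        int j = t + (int)(unif_rand() * (m - t));
        if (j >= m) j = m - 1;
        std::swap(others[t], others[j]);
        s += others[t];
      }
      double g = s / denom;
      sum += g; sumsq += g * g;
      if (g >= gObs - 1e-12) ++ge;
    }
    double mu = sum / nPerm;
    double vv = sumsq / nPerm - mu * mu;
    if (vv < 0) vv = 0;
    out(i, 0) = mu;
    out(i, 1) = vv;
    out(i, 2) = vv > 0 ? (gObs - mu) / std::sqrt(vv) : 0.0;
    out(i, 3) = (ge + 1.0) / (nPerm + 1.0);
  }
  return out;
}
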