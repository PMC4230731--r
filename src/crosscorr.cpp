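#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pearson correlation of the overlapping segments of x and y at a lag:
// lag >= 0 pairs x[t] with y[t + lag] (x leads y).
static double pearson_at_lag(const double *x, const double *y, int n,
                             int lag) {
  const double *a = x, *b = y + lag;
  int m = n - lag;
  double sa = 0, sb = 0;
  for (int t = 0; t < m; ++t) { sa += a[t]; sb += b[t]; }
  double ma = sa / m, mb = sb / m;
  double saa = 0, sbb = 0, sab = 0;
  for (int t = 0; t < m; ++t) {
    double da = a[t] - ma, db = b[t] - mb;
    saa += da * da; sbb += db * db; sab += da * db;
  }
  double den = std::sqrt(saa * sbb);
  if (den <= 0) return NA_REAL;
  return sab / den;
}

// [[Rcpp::export(name = ".crosscorr_lags")]]
NumericVector crosscorr_lags(NumericVector x, NumericVector y, int max_lag) {
  int n = x.size();
  if (y.size() != n) stop("series lengths differ");
  NumericVector out(2 * max_lag + 1);  // lags -max_lag .. max_lag
  for (int lag = -max_lag; lag <= max_lag; ++lag) {
    double r = (lag >= 0)
      ? pearson_at_lag(REAL(x), REAL(y), n, lag)
      : pearson_at_lag(REAL(y), REAL(x), n, -lag);
    out[lag + max_lag] = r;
  }
  return out;
}
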