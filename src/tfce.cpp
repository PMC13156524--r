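#include <Rcpp.h>
using namespace Rcpp;

// Threshold-free cluster enhancement over a (lag x channel) t map with
// adjacency along the lag axis within each channel. Positive and negative
// values are enhanced separately; the returned map holds the nonnegative
// enhancement magnitude (a point only ever has one sign of t).

static void tfce_column(const double* t, int n, double sign, double E, double H,
                        double dh, double* out) {
  double tmax = 0.0;
  for (int i = 0; i < n; ++i) {
    double v = sign * t[i];
    if (v > tmax) tmax = v;
  }
  if (tmax <= 0.0) return;
  for (double h = dh; h <= tmax + 1e-12; h += dh) {
    const double hw = std::pow(h, H) * dh;
    int i = 0;
    while (i < n) {
      if (sign * t[i] >= h) {
        int j = i;
        while (j < n && sign * t[j] >= h) ++j;
        const double add = std::pow((double)(j - i), E) * hw;
        for (int k = i; k < j; ++k) out[k] += add;
        i = j;
      } else {
        ++i;
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix tfce_cpp(NumericMatrix t, double E, double H, double dh) {
  const int n = t.nrow(), m = t.ncol();
  if (dh <= 0) stop("dh must be positive");
  NumericMatrix out(n, m);
  for (int c = 0; c < m; ++c) {
    tfce_column(&t(0, c), n, 1.0, E, H, dh, &out(0, c));
    tfce_column(&t(0, c), n, -1.0, E, H, dh, &out(0, c));
  }
  return out;
}

// Max TFCE statistic for a batch of flattened permutation t maps.
// Each column of `tmaps` is one (nlag x nch) map, column-major in lag.

// [[Rcpp::export]]
NumericVector tfce_max_cpp(NumericMatrix tmaps, int nlag, double E, double H,
                           double dh) {
  const int npts = tmaps.nrow(), nperm = tmaps.ncol();
  if (npts % nlag != 0) stop("map size not a multiple of nlag");
  const int nch = npts / nlag;
  NumericVector out(nperm);
  std::vector<double> buf(npts);
  for (int q = 0; q < nperm; ++q) {
    std::fill(buf.begin(), buf.end(), 0.0);
    const double* tq = &tmaps(0, q);
    for (int c = 0; c < nch; ++c) {
      tfce_column(tq + c * nlag, nlag, 1.0, E, H, dh, buf.data() + c * nlag);
      tfce_column(tq + c * nlag, nlag, -1.0, E, H, dh, buf.data() + c * nlag);
    }
    double mx = 0.0;
    for (int i = 0; i < npts; ++i)
      if (buf[i] > mx) mx = buf[i];
    out[q] = mx;
  }
  return out;
}
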