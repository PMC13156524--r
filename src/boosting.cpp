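#include <Rcpp.h>
using namespace Rcpp;

// Greedy coordinate boosting for TRF estimation with MAE objective.
//
// The model is y_hat(k) = sum_{c,p} w[c,p] * S(k - shifts[p], c), where S holds
// the basis-smoothed input channels (so each weight corresponds to one basis
// function on one input channel) and shifts are lags in samples, already
// sign-adjusted for model direction. Shifted reads never cross segment
// boundaries (zero outside the segment holding k).
//
// Each step adds +/-delta to the single weight giving the largest reduction of
// the training mean absolute error. Validation MAE (samples in
// [val_start, val_end)) is monitored; the returned weights are the snapshot at
// the validation minimum ("selective stopping"), so the returned kernel never
// has higher validation MAE than any accepted intermediate. Weights never
// touched remain exactly zero.

// [[Rcpp::export]]
List boost_fit_cpp(NumericMatrix S, NumericVector y, IntegerVector shifts,
                   IntegerVector seg_starts, int val_start, int val_end,
                   double delta, int patience, int max_steps) {
  const int N = S.nrow(), C = S.ncol(), P = shifts.size();
  const int nseg = seg_starts.size();
  if (y.size() != N) stop("input/target length mismatch");
  if (val_start < 0 || val_end > N || val_start >= val_end)
    stop("invalid validation range");

  // segment bounds
  std::vector<int> seg_a(nseg), seg_b(nseg);
  for (int s = 0; s < nseg; ++s) {
    seg_a[s] = seg_starts[s];
    seg_b[s] = (s + 1 < nseg) ? seg_starts[s + 1] : N;
  }

  std::vector<double> e(N);
  for (int k = 0; k < N; ++k) e[k] = y[k];

  const int n_val = val_end - val_start;
  const int n_train = N - n_val;

  double base = 0.0;  // training sum |e|
  for (int k = 0; k < val_start; ++k) base += std::fabs(e[k]);
  for (int k = val_end; k < N; ++k) base += std::fabs(e[k]);

  double val_sum = 0.0;
  for (int k = val_start; k < val_end; ++k) val_sum += std::fabs(e[k]);

  NumericMatrix W(C, P), bestW(C, P);
  double best_val = val_sum;
  int pat_ctr = 0, steps = 0;

  // train ranges (complement of validation range)
  const int tr0a = 0, tr0b = val_start, tr1a = val_end, tr1b = N;

  for (steps = 0; steps < max_steps; ++steps) {
    double best_d = -1e-12;  // require strict improvement
    int best_c = -1, best_p = -1;
    double best_sign = 0.0;

    for (int c = 0; c < C; ++c) {
      const double* sc = &S(0, c);
      for (int p = 0; p < P; ++p) {
        const int l = shifts[p];
        double d_plus = 0.0, d_minus = 0.0;
        for (int s = 0; s < nseg; ++s) {
          int k0 = seg_a[s] + (l > 0 ? l : 0);
          int k1 = seg_b[s] + (l < 0 ? l : 0);
          if (k0 >= k1) continue;
          // intersect with the two training ranges
          for (int r = 0; r < 2; ++r) {
            int a = (r == 0) ? std::max(k0, tr0a) : std::max(k0, tr1a);
            int b = (r == 0) ? std::min(k1, tr0b) : std::min(k1, tr1b);
            for (int k = a; k < b; ++k) {
              const double sv = delta * sc[k - l];
              const double ek = e[k], ab = std::fabs(ek);
              d_plus += std::fabs(ek - sv) - ab;
              d_minus += std::fabs(ek + sv) - ab;
            }
          }
        }
        if (d_plus < best_d) { best_d = d_plus; best_c = c; best_p = p; best_sign = 1.0; }
        if (d_minus < best_d) { best_d = d_minus; best_c = c; best_p = p; best_sign = -1.0; }
      }
    }

    if (best_c < 0) break;  // no step reduces training MAE

    // apply the step and update residual over the full timeline
    const double d = best_sign * delta;
    W(best_c, best_p) += d;
    const int l = shifts[best_p];
    const double* sc = &S(0, best_c);
    for (int s = 0; s < nseg; ++s) {
      int k0 = seg_a[s] + (l > 0 ? l : 0);
      int k1 = seg_b[s] + (l < 0 ? l : 0);
      for (int k = std::max(k0, 0); k < std::min(k1, N); ++k)
        e[k] -= d * sc[k - l];
    }
    base += best_d;

    val_sum = 0.0;
    for (int k = val_start; k < val_end; ++k) val_sum += std::fabs(e[k]);

    if (val_sum < best_val - 1e-15) {
      best_val = val_sum;
      for (int c = 0; c < C; ++c)
        for (int p = 0; p < P; ++p) bestW(c, p) = W(c, p);
      pat_ctr = 0;
    } else if (++pat_ctr >= patience) {
      ++steps;
      break;
    }
  }

  return List::create(_["weights"] = bestW, _["steps"] = steps,
                      _["val_mae"] = best_val / n_val,
                      _["train_mae"] = base / n_train);
}
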