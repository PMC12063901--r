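#include <Rcpp.h>
using namespace Rcpp;

// Online margin-perceptron with nonnegative-orthant projection after every
// update. Patterns are visited cyclically in data order; each violating
// pattern (y * (w.x - theta) <= margin) triggers
//   w <- max(w + eta * y * x, 0),  theta <- theta - eta * y.
// Success = all patterns strictly correct at the end of an epoch.

// [[Rcpp::export]]
List cpp_train_perceptron(const NumericMatrix& X, const NumericVector& y,
                          NumericVector w, double theta,
                          double margin, double eta, int max_epochs) {
  const int P = X.nrow(), N = X.ncol();
  bool success = false;
  int epochs_used = 0;
  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    int violations = 0;
    for (int mu = 0; mu < P; ++mu) {
      double z = 0.0;
      for (int i = 0; i < N; ++i) z += X(mu, i) * w[i];
      if (y[mu] * (z - theta) <= margin) {
        ++violations;
        for (int i = 0; i < N; ++i) {
          w[i] += eta * y[mu] * X(mu, i);
          if (w[i] < 0.0) w[i] = 0.0;
        }
        theta -= eta * y[mu];
      }
    }
    epochs_used = epoch;
    if (violations == 0) break;
  }
  // strict-correctness check (margin may be zero: ties are failures)
  success = true;
  for (int mu = 0; mu < P && success; ++mu) {
    double z = 0.0;
    for (int i = 0; i < N; ++i) z += X(mu, i) * w[i];
    if (!(y[mu] * (z - theta) > 0.0)) success = false;
  }
  return List::create(_["weights"] = w, _["theta"] = theta,
                      _["success"] = success, _["epochs_used"] = epochs_used);
}
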