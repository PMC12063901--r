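#include <Rcpp.h>
using namespace Rcpp;

// Full-batch hinge-loss training loop for the restricted parallel-synapse
// neuron. Mirrors the R reference loop (gradient_step + resurrect_synapses)
// exactly: same update algebra, same accumulation order (mu ascending within
// each (i, j) synapse, synapses in column-major order), and resurrection
// draws taken from R's RNG stream so R and C++ trajectories coincide.
// The per-synapse sigmoid values are computed once per epoch and reused by
// the gradient pass.

static inline double sigm(double u) { return 1.0 / (1.0 + std::exp(-u)); }

// [[Rcpp::export]]
List cpp_train_restricted(const NumericMatrix& X, const NumericVector& y,
                          NumericMatrix amp, NumericMatrix slope,
                          NumericMatrix thr, double theta,
                          bool tanh_form, double margin,
                          const NumericVector& etas,
                          int max_epochs, int resur_period, double amp_floor,
                          double range_lo, double range_hi) {
  const int P = X.nrow(), N = X.ncol(), M = amp.ncol();
  const double eta_a = etas[0], eta_s = etas[1], eta_t = etas[2],
               eta_th = etas[3];
  std::vector<double> z(P);
  std::vector<int> omega;
  omega.reserve(P);
  NumericMatrix amp_new(N, M), slope_new(N, M), thr_new(N, M);
  // sigmoid cache, P x (N*M); ~6 MB at P = 100, N*M = 75 scales
  const bool cache_ok = (double)P * N * M <= 4e6;
  std::vector<double> sig_cache(cache_ok ? (size_t)P * N * M : 0);

  bool success = false;
  int epochs_used = 0;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::fill(z.begin(), z.end(), 0.0);
    for (int j = 0; j < M; ++j) {
      for (int i = 0; i < N; ++i) {
        const double a2 = amp(i, j) * amp(i, j);
        const double s = slope(i, j), t = thr(i, j);
        double* cache = cache_ok ? &sig_cache[((size_t)j * N + i) * P] : nullptr;
        if (tanh_form) {
          for (int mu = 0; mu < P; ++mu) {
            const double sg = sigm(2.0 * s * (X(mu, i) - t));
            if (cache) cache[mu] = sg;
            z[mu] += 2.0 * a2 * sg - a2;
          }
        } else {
          for (int mu = 0; mu < P; ++mu) {
            const double sg = sigm(s * (X(mu, i) - t));
            if (cache) cache[mu] = sg;
            z[mu] += a2 * sg;
          }
        }
      }
    }

    bool all_correct = true;
    for (int mu = 0; mu < P; ++mu) {
      if (!((z[mu] - theta) * y[mu] > 0.0)) { all_correct = false; break; }
    }
    if (all_correct) { success = true; break; }

    omega.clear();
    for (int mu = 0; mu < P; ++mu) {
      if (margin - (z[mu] - theta) * y[mu] > 0.0) omega.push_back(mu);
    }
    // no violators yet not all strictly correct: parameters have gone
    // non-finite (diverged) or are stuck on a zero-margin tie; stop early
    if (omega.empty()) break;

    double sum_y = 0.0;
    for (size_t k = 0; k < omega.size(); ++k) sum_y += y[omega[k]];

    for (int j = 0; j < M; ++j) {
      for (int i = 0; i < N; ++i) {
        const double a = amp(i, j), s = slope(i, j), t = thr(i, j);
        const double* cache = cache_ok ? &sig_cache[((size_t)j * N + i) * P] : nullptr;
        double S1 = 0.0, S2 = 0.0, S3 = 0.0;
        if (tanh_form) {
          for (size_t k = 0; k < omega.size(); ++k) {
            const int mu = omega[k];
            const double dx = X(mu, i) - t;
            const double sg = cache ? cache[mu] : sigm(2.0 * s * dx);
            S1 += y[mu] * (2.0 * sg - 1.0);
            S2 += y[mu] * sg * (1.0 - sg) * dx;
            S3 += y[mu] * sg * (1.0 - sg);
          }
          amp_new(i, j) = a + eta_a * 2.0 * a * S1;
          double sn = s + eta_s * 4.0 * a * a * S2;
          slope_new(i, j) = sn < 0.0 ? 0.0 : sn;
          thr_new(i, j) = t - eta_t * 4.0 * a * a * s * S3;
        } else {
          for (size_t k = 0; k < omega.size(); ++k) {
            const int mu = omega[k];
            const double dx = X(mu, i) - t;
            const double sg = cache ? cache[mu] : sigm(s * dx);
            S1 += y[mu] * sg;
            S2 += y[mu] * sg * (1.0 - sg) * dx;
            S3 += y[mu] * sg * (1.0 - sg);
          }
          amp_new(i, j) = a + eta_a * 2.0 * a * S1;
          double sn = s + eta_s * a * a * S2;
          slope_new(i, j) = sn < 0.0 ? 0.0 : sn;
          thr_new(i, j) = t - eta_t * a * a * s * S3;
        }
      }
    }
    theta -= eta_th * sum_y;
    std::copy(amp_new.begin(), amp_new.end(), amp.begin());
    std::copy(slope_new.begin(), slope_new.end(), slope.begin());
    std::copy(thr_new.begin(), thr_new.end(), thr.begin());
    epochs_used = epoch;

    if (epoch % resur_period == 0) {
      // column-major sweep matches which() order in the R reference
      for (int j = 0; j < M; ++j) {
        for (int i = 0; i < N; ++i) {
          if (amp(i, j) * amp(i, j) < amp_floor) {
            amp(i, j) = std::sqrt(amp_floor);
            thr(i, j) = range_lo +
              (range_hi - range_lo) * R::rbeta(0.5, 0.5);
          }
        }
      }
    }
  }

  if (!success) {
    std::fill(z.begin(), z.end(), 0.0);
    for (int j = 0; j < M; ++j) {
      for (int i = 0; i < N; ++i) {
        const double a2 = amp(i, j) * amp(i, j);
        const double s = slope(i, j), t = thr(i, j);
        for (int mu = 0; mu < P; ++mu) {
          const double u = tanh_form ? 2.0 * s * (X(mu, i) - t)
                                     : s * (X(mu, i) - t);
          z[mu] += tanh_form ? 2.0 * a2 * sigm(u) - a2 : a2 * sigm(u);
        }
      }
    }
    success = true;
    for (int mu = 0; mu < P; ++mu) {
      if (!((z[mu] - theta) * y[mu] > 0.0)) { success = false; break; }
    }
  }

  return List::create(
    _["amp_root"] = amp, _["slope"] = slope, _["threshold"] = thr,
    _["theta"] = theta, _["success"] = success,
    _["epochs_used"] = epochs_used);
}
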