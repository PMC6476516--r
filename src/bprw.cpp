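#include <Rcpp.h>
using namespace Rcpp;

// Biased persistent random walk sampling.
//
// Step-angle density: b*cos(theta) + exp(p*cos(theta - prev))/(2 pi I0(p)).
// The persistence term is evaluated with the exponentially scaled Bessel
// function, exp(p*(cos(.) - 1)) / (2 pi I0(p) e^{-p}), so large p does not
// overflow. Sampling is rejection against a constant envelope equal to the
// density supremum b + e^p/(2 pi I0(p)).

namespace {

struct AngleSampler {
  double b, p, inv2piI0e; // 1/(2 pi I0(p) e^{-p})
  double sup;             // envelope constant

  AngleSampler(double b_, double p_) : b(b_), p(p_) {
    double i0e = R::bessel_i(p, 0.0, 2.0); // scaled: I0(p) * exp(-p)
    inv2piI0e = 1.0 / (2.0 * M_PI * i0e);
    sup = b + inv2piI0e; // persistence term max is at theta = prev
  }

  double density(double theta, double prev) const {
    return b * std::cos(theta) +
           std::exp(p * (std::cos(theta - prev) - 1.0)) * inv2piI0e;
  }

  // uniform density in place of the persistence term (first step: no prev)
  double density_first(double theta) const {
    return b * std::cos(theta) + 1.0 / (2.0 * M_PI);
  }

  double draw(double prev) const {
    for (;;) {
      double theta = (2.0 * unif_rand() - 1.0) * M_PI;
      if (unif_rand() * sup <= density(theta, prev)) return theta;
    }
  }

  double draw_first() const {
    double sup1 = b + 1.0 / (2.0 * M_PI);
    for (;;) {
      double theta = (2.0 * unif_rand() - 1.0) * M_PI;
      if (unif_rand() * sup1 <= density_first(theta)) return theta;
    }
  }
};

} // namespace

// [[Rcpp::export]]
NumericVector bprw_sample_angles_cpp(int n, double theta_prev, double b,
                                     double p) {
  AngleSampler s(b, p);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = s.draw(theta_prev);
  return out;
}

// [[Rcpp::export]]
NumericMatrix bprw_trajectory_cpp(int M, double b, double p) {
  AngleSampler s(b, p);
  NumericMatrix pos(M + 1, 2);
  double x = 0.0, y = 0.0, theta = 0.0;
  for (int k = 0; k < M; ++k) {
    theta = (k == 0) ? s.draw_first() : s.draw(theta);
    double len = R::exp_rand(); // exponential, mean 1
    x += len * std::cos(theta);
    y += len * std::sin(theta);
    pos(k + 1, 0) = x;
    pos(k + 1, 1) = y;
  }
  return pos;
}

// Fixed-time ensemble: the velocity-jump reading of the walk. Unit speed,
// unit-mean exponential runs, initial direction uniform (bias-free), the
// walk observed at elapsed time t_total with the last run truncated. This
// is the process whose displacement moments the closed forms describe;
// path length is exactly t_total.
// [[Rcpp::export]]
NumericMatrix bprw_ensemble_time_cpp(int n_traj, double t_total, double b,
                                     double p) {
  AngleSampler s(b, p);
  NumericMatrix out(n_traj, 3);
  for (int t = 0; t < n_traj; ++t) {
    double x = 0.0, y = 0.0, remaining = t_total;
    double theta = (2.0 * unif_rand() - 1.0) * M_PI;
    bool first = true;
    while (remaining > 0.0) {
      if (!first) theta = s.draw(theta);
      first = false;
      double len = R::exp_rand();
      if (len > remaining) len = remaining;
      x += len * std::cos(theta);
      y += len * std::sin(theta);
      remaining -= len;
    }
    out(t, 0) = x;
    out(t, 1) = y;
    out(t, 2) = t_total;
  }
  return out;
}

// Per-trajectory endpoint summaries: net x, net y, path length.
// [[Rcpp::export]]
NumericMatrix bprw_ensemble_cpp(int n_traj, int M, double b, double p) {
  AngleSampler s(b, p);
  NumericMatrix out(n_traj, 3);
  for (int t = 0; t < n_traj; ++t) {
    double x = 0.0, y = 0.0, path = 0.0, theta = 0.0;
    for (int k = 0; k < M; ++k) {
      theta = (k == 0) ? s.draw_first() : s.draw(theta);
      double len = R::exp_rand();
      x += len * std::cos(theta);
      y += len * std::sin(theta);
      path += len;
    }
    out(t, 0) = x;
    out(t, 1) = y;
    out(t, 2) = path;
  }
  return out;
}
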