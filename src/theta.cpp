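#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of a network of theta neurons coupled through
// a nonnegative weight matrix C (C(j, i) = weight of connection j -> i).
// Node i obeys  dtheta_i = [1 - cos(theta_i) + g(theta_i) * I_i] dt
//               + g(theta_i) * Inoise * sqrt(dt) * dW
// with I_i = I0 + omega/N * sum_j C(j,i) * (1 - cos(theta_j - theta_star)),
// g(theta) = 1 + cos(theta) in the standard form (classic_form = false) or
// 1 - cos(theta) for the degenerate literal variant. With noise_per_step,
// the noise term enters the current without sqrt(dt) scaling instead.
// A removed node is frozen at theta_star and emits no pulse; the coupling
// sum stays normalized by N.
// A node is "active" at a step if it spiked (upward pi-crossing) within the
// trailing window of active_window time units.
// [[Rcpp::export]]
List theta_simulate_cpp(NumericMatrix C, double I0, double Inoise,
                        double omega, double dt, double n_steps_d,
                        double active_window, int removed,
                        bool classic_form, bool noise_per_step,
                        bool return_spikes) {
  long n_steps = (long)n_steps_d;
  int n = C.nrow();
  double theta_star = (I0 < 0) ? -2.0 * std::atan(std::sqrt(-I0)) : 0.0;
  std::vector<double> theta(n, theta_star), pulse(n), last_spike(n, R_NegInf);
  std::vector<long> active_count(n, 0), spike_count(n, 0);
  std::vector< std::vector<double> > spikes(return_spikes ? n : 0);
  double sdt = std::sqrt(dt);
  GetRNGstate();
  for (long t = 0; t < n_steps; ++t) {
    double now = (t + 1) * dt;
    for (int j = 0; j < n; ++j)
      pulse[j] = (j == removed) ? 0.0
                                : (1.0 - std::cos(theta[j] - theta_star));
    for (int i = 0; i < n; ++i) {
      if (i == removed) continue;
      double coup = 0.0;
      for (int j = 0; j < n; ++j) coup += C(j, i) * pulse[j];
      double Idet = I0 + omega * coup / n;
      double ct = std::cos(theta[i]);
      double g = classic_form ? (1.0 - ct) : (1.0 + ct);
      double xi = norm_rand();
      double dth;
      if (noise_per_step)
        dth = dt * (1.0 - ct + g * (Idet + Inoise * xi));
      else
        dth = dt * (1.0 - ct + g * Idet) + g * Inoise * sdt * xi;
      theta[i] += dth;
      if (theta[i] > M_PI) {
        theta[i] -= 2.0 * M_PI;
        last_spike[i] = now;
        spike_count[i]++;
        if (return_spikes) spikes[i].push_back(now);
      }
      if (now - last_spike[i] <= active_window) active_count[i]++;
    }
  }
  PutRNGstate();
  NumericVector active(n);
  IntegerVector nsp(n);
  for (int i = 0; i < n; ++i) {
    active[i] = (i == removed) ? NA_REAL : (double)active_count[i] / n_steps;
    nsp[i] = (i == removed) ? NA_INTEGER : (int)spike_count[i];
  }
  List out = List::create(_["active"] = active, _["n_spikes"] = nsp,
                          _["theta_star"] = theta_star);
  if (return_spikes) {
    List sp(n);
    for (int i = 0; i < n; ++i) sp[i] = wrap(spikes[i]);
    out["spike_times"] = sp;
  }
  return out;
}
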