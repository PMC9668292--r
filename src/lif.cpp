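#include <Rcpp.h>
using namespace Rcpp;

// Leaky integrate-and-fire pool with a common sinusoidal drive and
// independent Gaussian noise per neuron. Euler-Maruyama at step dt; the
// noise term is scaled so that `noise_sd` equals the stationary standard
// deviation of the free membrane potential. Draws come from R's RNG so
// that set.seed() at the R level makes the simulation reproducible. One
// rnorm(n) block is consumed every step regardless of spiking, which
// keeps the stream alignment independent of the trajectory.
// [[Rcpp::export]]
List lif_pool_core(NumericVector offsets, double duration, double dt,
                   double tau, double threshold, double reset,
                   double refractory, double sine_freq, double sine_amp,
                   double noise_sd) {
  const int n = offsets.size();
  const int K = (int)std::round(duration / dt);
  const int refr_steps = (int)std::round(refractory / dt);
  const double a = dt / tau;
  const double nscale = noise_sd * std::sqrt(2.0 * dt / tau);
  const double w = 2.0 * M_PI * sine_freq;

  std::vector<std::vector<double>> spikes(n);
  std::vector<double> v(n, reset);
  std::vector<int> refr(n, 0);

  for (int k = 0; k < K; ++k) {
    const double common = sine_amp * std::sin(w * k * dt);
    NumericVector eta = rnorm(n);
    for (int i = 0; i < n; ++i) {
      if (refr[i] > 0) {
        --refr[i];
        continue;
      }
      v[i] += a * (offsets[i] + common - v[i]) + nscale * eta[i];
      if (v[i] >= threshold) {
        spikes[i].push_back(k * dt);
        v[i] = reset;
        refr[i] = refr_steps;
      }
    }
  }

  List out(n);
  for (int i = 0; i < n; ++i) out[i] = wrap(spikes[i]);
  return out;
}
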