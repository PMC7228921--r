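#include <Rcpp.h>
using namespace Rcpp;

// Explicit-Euler integration of the volatile memristor state equation
//   dw/dt = lambda * sinh(eta * V) - w / tau,  w clamped to [0, 1]
// with the device current evaluated at the end of each step:
//   I = w^p * gamma * sinh(delta * V)
//     + (1 - w^p) * sign(V) * alpha * (1 - exp(-beta * |V|)).
// Times in ms, voltages in mV, currents in nA.
// [[Rcpp::export(name = ".euler_sim")]]
List euler_sim(NumericVector v, double dt, double w0,
               double lambda, double eta, double tau,
               double gamma, double delta, double alpha, double beta,
               double p) {
  const int n = v.size();
  NumericVector w_out(n), i_out(n);
  double w = w0;
  for (int k = 0; k < n; ++k) {
    const double V = v[k];
    w += dt * (lambda * std::sinh(eta * V) - w / tau);
    if (w < 0.0) w = 0.0;
    if (w > 1.0) w = 1.0;
    const double g = std::pow(w, p);
    const double sgn = (V > 0.0) - (V < 0.0);
    i_out[k] = g * gamma * std::sinh(delta * V)
             + (1.0 - g) * sgn * alpha * (1.0 - std::exp(-beta * std::fabs(V)));
    w_out[k] = w;
  }
  return List::create(_["w"] = w_out, _["i"] = i_out);
}
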