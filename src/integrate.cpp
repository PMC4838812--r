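#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

namespace {

struct Pars {
  double A, B, G, a, b, g;
  double C1, C2, C3, C4, C5, C6, C7;
  double v0, e0, r;
};

Pars unpack(const List& pars) {
  Pars P;
  P.A  = as<double>(pars["A"]);
  P.B  = as<double>(pars["B"]);
  P.G  = as<double>(pars["G"]);
  P.a  = as<double>(pars["a"]);
  P.b  = as<double>(pars["b"]);
  P.g  = as<double>(pars["g"]);
  P.C1 = as<double>(pars["C1"]);
  P.C2 = as<double>(pars["C2"]);
  P.C3 = as<double>(pars["C3"]);
  P.C4 = as<double>(pars["C4"]);
  P.C5 = as<double>(pars["C5"]);
  P.C6 = as<double>(pars["C6"]);
  P.C7 = as<double>(pars["C7"]);
  P.v0 = as<double>(pars["v0"]);
  P.e0 = as<double>(pars["e0"]);
  P.r  = as<double>(pars["r"]);
  return P;
}

// wave-to-pulse sigmoid; exp overflow gives Inf -> S = 0, no NaN
inline double sig(const Pars& P, double v) {
  return 2.0 * P.e0 / (1.0 + std::exp(P.r * (P.v0 - v)));
}

// Full 10-equation drift, original variable indexing.  The stochastic
// input enters only the y6 equation; here it is the fixed number p for
// one evaluation.
inline void drift_full(const Pars& P, const double* y, double p, double* dy) {
  dy[0] = y[5];
  dy[1] = y[6];
  dy[2] = y[7];
  dy[3] = y[8];
  dy[4] = y[9];
  dy[5] = P.A * P.a * sig(P, y[1] - y[2] - y[3]) - 2.0 * P.a * y[5] - P.a * P.a * y[0];
  dy[6] = P.A * P.a * (p + P.C2 * sig(P, P.C1 * y[0])) - 2.0 * P.a * y[6] - P.a * P.a * y[1];
  dy[7] = P.B * P.b * P.C4 * sig(P, P.C3 * y[0]) - 2.0 * P.b * y[7] - P.b * P.b * y[2];
  dy[8] = P.G * P.g * P.C7 * sig(P, P.C5 * y[0] - P.C6 * y[4]) - 2.0 * P.g * y[8] - P.g * P.g * y[3];
  dy[9] = P.B * P.b * sig(P, P.C3 * y[0]) - 2.0 * P.b * y[9] - P.b * P.b * y[4];
}

// Reduced 8-equation drift.  State: z0..z3 PSP outputs (z2 is the former
// y4), z4..z7 their derivatives.  The fast-inhibition drive couples to
// the slow-inhibition PSP z2.
inline void drift_reduced(const Pars& P, const double* z, double p, double* dz) {
  dz[0] = z[4];
  dz[1] = z[5];
  dz[2] = z[6];
  dz[3] = z[7];
  dz[4] = P.A * P.a * sig(P, z[1] - P.C4 * z[2] - z[3]) - 2.0 * P.a * z[4] - P.a * P.a * z[0];
  dz[5] = P.A * P.a * (p + P.C2 * sig(P, P.C1 * z[0])) - 2.0 * P.a * z[5] - P.a * P.a * z[1];
  dz[6] = P.B * P.b * sig(P, P.C3 * z[0]) - 2.0 * P.b * z[6] - P.b * P.b * z[2];
  dz[7] = P.G * P.g * P.C7 * sig(P, P.C5 * z[0] - P.C6 * z[2]) - 2.0 * P.g * z[7] - P.g * P.g * z[3];
}

} // namespace

//' @name integrate_nmm_cpp
//' @title Fixed-step integration loop (internal)
//' @description Internal C++ integration kernel; use simulate() instead.
//' @keywords internal
// [[Rcpp::export]]
List integrate_nmm_cpp(NumericVector init, List pars, double h, int nsteps,
                       int scheme, NumericVector noise, bool reduced,
                       bool record_states, double reference_h,
                       double input_mean, double input_sd) {
  const Pars P = unpack(pars);
  const int dim = reduced ? 8 : 10;
  if (init.size() != dim)
    stop("initial state must have %d components", dim);
  if (noise.size() < nsteps)
    stop("noise stream shorter than the number of steps");

  double y[10], k1[10], k2[10], k3[10], k4[10], tmp[10];
  for (int i = 0; i < dim; ++i) y[i] = init[i];

  NumericVector yout(nsteps + 1);
  NumericMatrix states;
  if (record_states) states = NumericMatrix(nsteps + 1, dim);

  // index of the derivative state receiving the noise increment
  const int noise_idx = reduced ? 5 : 6;
  // Wiener-consistent increment scale of the corrected scheme
  const double sde_scale =
      P.A * P.a * std::sqrt(input_sd * input_sd * reference_h * h);

  auto out = [&](const double* s) {
    return reduced ? s[1] - P.C4 * s[2] - s[3] : s[1] - s[2] - s[3];
  };
  auto f = [&](const double* s, double p, double* ds) {
    if (reduced) drift_reduced(P, s, p, ds); else drift_full(P, s, p, ds);
  };

  yout[0] = out(y);
  if (record_states)
    for (int i = 0; i < dim; ++i) states(0, i) = y[i];

  for (int n = 0; n < nsteps; ++n) {
    if (scheme == 0) {            // classical forward Euler, noisy input x h
      const double p = input_mean + input_sd * noise[n];
      f(y, p, k1);
      for (int i = 0; i < dim; ++i) y[i] += h * k1[i];
    } else if (scheme == 1) {     // classical RK4, one draw held over stages
      const double p = input_mean + input_sd * noise[n];
      f(y, p, k1);
      for (int i = 0; i < dim; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
      f(tmp, p, k2);
      for (int i = 0; i < dim; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
      f(tmp, p, k3);
      for (int i = 0; i < dim; ++i) tmp[i] = y[i] + h * k3[i];
      f(tmp, p, k4);
      for (int i = 0; i < dim; ++i)
        y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    } else {                      // stochastic forward Euler
      f(y, input_mean, k1);
      for (int i = 0; i < dim; ++i) y[i] += h * k1[i];
      y[noise_idx] += sde_scale * noise[n];
    }

    for (int i = 0; i < dim; ++i)
      if (!std::isfinite(y[i]))
        stop("integration diverged: non-finite state at step %d (t = %g s)",
             n + 1, (n + 1) * h);

    yout[n + 1] = out(y);
    if (record_states)
      for (int i = 0; i < dim; ++i) states(n + 1, i) = y[i];
  }

  NumericVector final_state(dim);
  for (int i = 0; i < dim; ++i) final_state[i] = y[i];

  List res = List::create(_["y_out"] = yout, _["final_state"] = final_state);
  if (record_states) res["states"] = states;
  return res;
}
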