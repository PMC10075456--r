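#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// State layout: he, hi, Iee, Jee, Iei, Jei, Iie, Jie, Iii, Jii.
// Parameter layout follows the canonical order of liley_param_names().

static inline double sig(double h, double smax, double mu, double sigma,
                         double c) {
  return smax / (1.0 + std::exp(-c * (h - mu) / sigma));
}

// Fixed-step Euler-Maruyama integration of the 10-dimensional Liley system.
// noise_mode: 0 = off, 1 = white noise increment on J_ee,
//             2 = per-step Gaussian resampling of the input rate p(t).
// noise holds pre-drawn N(0,1) deviates (length >= n_steps) for modes 1/2.
// Returns the state component `obs` (0 = h_e, 1 = h_i) at every step
// (length n_steps + 1, including t = 0) with an attribute "divergent" set
// when |h_e| exceeds 1e4 mV or goes non-finite.
// [[Rcpp::export]]
NumericVector liley_integrate_cpp(NumericVector params, double c_sig,
                                  double dt, int n_steps,
                                  NumericVector noise, int noise_mode,
                                  NumericVector init, int obs) {
  const double he_rest = params[0], hi_rest = params[1];
  const double N_ee = params[2], N_ei = params[3], N_ie = params[4],
               N_ii = params[5];
  const double G_e = params[6], G_i = params[7];
  const double g_e = params[8], g_i = params[9];
  const double tau_e = params[10], tau_i = params[11];
  const double Se_max = params[12], Si_max = params[13];
  const double mu_e = params[14], mu_i = params[15];
  const double s_e = params[16], s_i = params[17];
  const double he_eq = params[18], hi_eq = params[19];
  const double p_ee = params[20], p_ei = params[21];
  const double xi = params[22];

  const double wden_ee = std::fabs(he_eq - he_rest);
  const double wden_ie = std::fabs(hi_eq - he_rest);
  const double wden_ei = std::fabs(he_eq - hi_rest);
  const double wden_ii = std::fabs(hi_eq - hi_rest);
  const double e1 = std::exp(1.0);
  const double Ae = G_e * g_e * e1;  // drive scale of excitatory synapses
  const double Ai = G_i * g_i * e1;
  const double sqdt = std::sqrt(dt);

  double s[10];
  for (int k = 0; k < 10; ++k) s[k] = init[k];

  NumericVector he_out(n_steps + 1);
  he_out[0] = s[obs];
  bool divergent = false;
  int last = n_steps;

  for (int n = 0; n < n_steps; ++n) {
    const double he = s[0], hi = s[1];
    const double Se = sig(he, Se_max, mu_e, s_e, c_sig);
    const double Si = sig(hi, Si_max, mu_i, s_i, c_sig);

    double p_in = p_ee;
    if (noise_mode == 2) p_in = p_ee + xi * noise[n];

    const double d_he = (he_rest - he + (he_eq - he) / wden_ee * s[2] +
                         (hi_eq - he) / wden_ie * s[6]) / tau_e;
    const double d_hi = (hi_rest - hi + (he_eq - hi) / wden_ei * s[4] +
                         (hi_eq - hi) / wden_ii * s[8]) / tau_i;
    const double d_Iee = s[3];
    const double d_Jee = Ae * (N_ee * Se + p_in) - 2.0 * g_e * s[3] -
                         g_e * g_e * s[2];
    const double d_Iei = s[5];
    const double d_Jei = Ae * (N_ei * Se + p_ei) - 2.0 * g_e * s[5] -
                         g_e * g_e * s[4];
    const double d_Iie = s[7];
    const double d_Jie = Ai * (N_ie * Si) - 2.0 * g_i * s[7] - g_i * g_i * s[6];
    const double d_Iii = s[9];
    const double d_Jii = Ai * (N_ii * Si) - 2.0 * g_i * s[9] - g_i * g_i * s[8];

    s[0] += dt * d_he;
    s[1] += dt * d_hi;
    s[2] += dt * d_Iee;
    s[3] += dt * d_Jee;
    s[4] += dt * d_Iei;
    s[5] += dt * d_Jei;
    s[6] += dt * d_Iie;
    s[7] += dt * d_Jie;
    s[8] += dt * d_Iii;
    s[9] += dt * d_Jii;

    if (noise_mode == 1)
      s[3] += Ae * xi * sqdt * noise[n];  // diffusion on J_ee only

    he_out[n + 1] = s[obs];
    if (!std::isfinite(s[0]) || std::fabs(s[0]) > 1e4) {
      divergent = true;
      last = n + 1;
      break;
    }
  }
  if (divergent)
    for (int n = last + 1; n <= n_steps; ++n) he_out[n] = NA_REAL;

  he_out.attr("divergent") = divergent;
  return he_out;
}

// Weighted horizontal visibility graph by the standard monotone-stack sweep.
// Nodes i < j are linked iff every intermediate sample is strictly below both
// endpoints; the edge weight is x[j] - x[i] (later minus earlier). Returns
// 1-based endpoint indices, weights, and per-node signed strength sums.
// [[Rcpp::export]]
List whvg_cpp(NumericVector x) {
  const int n = x.size();
  std::vector<int> from, to;
  std::vector<double> w;
  from.reserve(2 * n);
  to.reserve(2 * n);
  w.reserve(2 * n);
  NumericVector strength(n);

  std::vector<int> stack;
  stack.reserve(n);
  stack.push_back(0);
  for (int j = 1; j < n; ++j) {
    // every popped element is visible from j and blocked afterwards
    while (!stack.empty() && x[stack.back()] < x[j]) {
      int i = stack.back();
      stack.pop_back();
      from.push_back(i + 1);
      to.push_back(j + 1);
      double wij = x[j] - x[i];
      w.push_back(wij);
      strength[i] += wij;
      strength[j] += wij;
    }
    if (!stack.empty()) {
      int i = stack.back();
      from.push_back(i + 1);
      to.push_back(j + 1);
      double wij = x[j] - x[i];
      w.push_back(wij);
      strength[i] += wij;
      strength[j] += wij;
      if (x[i] == x[j]) stack.pop_back();  // equal heights block past j
    }
    stack.push_back(j);
  }

  return List::create(_["from"] = wrap(from), _["to"] = wrap(to),
                      _["weight"] = wrap(w), _["strength"] = strength);
}
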