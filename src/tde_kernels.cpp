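#include <Rcpp.h>
using namespace Rcpp;

// Surrogate derivative of the Heaviside spike function: 1 / (1 + beta*|x|)^2.
// Peaked at 0, strictly positive, decays polynomially (fast-sigmoid family).
static inline double surr_grad(double x, double beta) {
  double d = 1.0 + beta * std::fabs(x);
  return 1.0 / (d * d);
}

// Batched discrete-time TDE dynamics.
//
// Per example b and timestep t (states start at zero):
//   i[t] = a_i * i[t-1] + g[t-1] * Tr[t]            (trigger reads *previous* gain)
//   g[t] = (a_g * g[t-1] + w_g * Fac[t])            (TDE-2)
//   g[t] = (a_g * g[t-1] + w_g * Fac[t]) * (1-Inh[t])  (TDE-3)
//   u[t] = a_v * v[t-1] + i[t]                       (pre-reset membrane voltage)
//   s[t] = H(u[t] - theta)
//   v[t] = (1 - s[t]) * u[t]                         (reset to 0 on spike)
//
// Inputs fac/tr/inh are B x T (binary); returns full state traces needed by
// the adjoint pass.
// [[Rcpp::export]]
List tde_forward_cpp(NumericMatrix fac, NumericMatrix tr, NumericMatrix inh,
                     double a_g, double a_i, double a_v,
                     double w_g, double theta, bool tde3) {
  int B = fac.nrow(), T = fac.ncol();
  NumericMatrix g(B, T), cur(B, T), u(B, T), s(B, T);
  for (int b = 0; b < B; ++b) {
    double gm1 = 0.0, im1 = 0.0, vm1 = 0.0;
    for (int t = 0; t < T; ++t) {
      double it = a_i * im1 + gm1 * tr(b, t);
      double A  = a_g * gm1 + w_g * fac(b, t);
      double gt = tde3 ? A * (1.0 - inh(b, t)) : A;
      double ut = a_v * vm1 + it;
      double st = (ut - theta >= 0.0) ? 1.0 : 0.0;
      cur(b, t) = it; g(b, t) = gt; u(b, t) = ut; s(b, t) = st;
      gm1 = gt; im1 = it; vm1 = (1.0 - st) * ut;
    }
  }
  return List::create(_["g"] = g, _["i"] = cur, _["u"] = u, _["s"] = s);
}

// Adjoint (reverse-mode) pass of tde_forward_cpp under the surrogate-gradient
// convention: dH/du is replaced by surr_grad(u - theta, beta) everywhere the
// binary spike enters downstream computation (loss term ds_ext, and the
// voltage reset). di_ext carries gradients arriving directly at the current
// trace (e.g. through the onset indicator of the decoders).
//
// Returns parameter gradients (in multiplier space: a_g, a_i, a_v, w_g) and
// gradients w.r.t. the three binary input streams (used for STCF threshold
// training).
// [[Rcpp::export]]
List tde_backward_cpp(NumericMatrix fac, NumericMatrix tr, NumericMatrix inh,
                      NumericMatrix g, NumericMatrix cur, NumericMatrix u,
                      NumericMatrix s,
                      NumericMatrix ds_ext, NumericMatrix di_ext,
                      double a_g, double a_i, double a_v,
                      double w_g, double theta, bool tde3, double beta) {
  int B = fac.nrow(), T = fac.ncol();
  NumericMatrix dfac(B, T), dtr(B, T), dinh(B, T);
  double d_ag = 0.0, d_ai = 0.0, d_av = 0.0, d_wg = 0.0;
  for (int b = 0; b < B; ++b) {
    double dg_c = 0.0, di_c = 0.0, dv_c = 0.0;
    for (int t = T - 1; t >= 0; --t) {
      double gm1 = (t > 0) ? g(b, t - 1) : 0.0;
      double im1 = (t > 0) ? cur(b, t - 1) : 0.0;
      double vm1 = (t > 0) ? (1.0 - s(b, t - 1)) * u(b, t - 1) : 0.0;
      double dv = dv_c;
      double ds = ds_ext(b, t) - dv * u(b, t);
      double sgp = surr_grad(u(b, t) - theta, beta);
      double du = dv * (1.0 - s(b, t)) + ds * sgp;
      double di = du + di_c + di_ext(b, t);
      double dg = dg_c;
      double inh_t = tde3 ? inh(b, t) : 0.0;
      double A = a_g * gm1 + w_g * fac(b, t);
      double dA = dg * (1.0 - inh_t);
      if (tde3) dinh(b, t) = -dg * A;
      d_ag += dA * gm1;
      d_wg += dA * fac(b, t);
      dfac(b, t) = dA * w_g;
      d_ai += di * im1;
      dtr(b, t) = di * gm1;
      d_av += du * vm1;
      dg_c = dA * a_g + di * tr(b, t);
      di_c = di * a_i;
      dv_c = du * a_v;
    }
  }
  return List::create(_["d_ag"] = d_ag, _["d_ai"] = d_ai, _["d_av"] = d_av,
                      _["d_wg"] = d_wg, _["dfac"] = dfac, _["dtr"] = dtr,
                      _["dinh"] = dinh);
}
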