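#include <Rcpp.h>
using namespace Rcpp;

// Time-stepping core shared by the QLV, AQLV and ANLV simulators.
//
// Each of the seven viscoelastic processes is a first-order state x_i driven
// by u_i(t) (precomputed in R as a N x 7 matrix; it never depends on the
// attenuation state).  Over one step of size dt the drive is taken to vary
// linearly between its sampled endpoint values, for which the state update
// is exact:
//
//   x_i <- x_i * E + u_k * tau_i * (1 - E) + (u_{k+1} - u_k) * (tau_i - tau_i^2 (1 - E)/dt)
//
// with E = exp(-dt/tau_i).  For piecewise-constant drive segments (ramps,
// holds) this coincides with the frozen-drive exponential update and incurs
// no time-stepping error at all; for smooth drives it is second order.
//
// The structural parameter lambda obeys d(lambda)/dt = -a * lambda with
// instantaneous breakdown rate a = k_d * v^n / (1 + k_f * F), v and F frozen
// at their start-of-step values (F from the previous assembled total force),
// giving the positivity-preserving update lambda <- lambda * exp(-a * dt).
// lambda is clipped at 1 only where it enters the per-process gains
// beta_i = 1 - gamma_i * (1 - min(lambda, 1)).
//
// f_passive[k] = static length-tension force + pure viscous force at sample k
// (neither is attenuated).  reset_idx are 1-based sample indices at which
// lambda is restored to lambda0 (before the output at that sample is formed).
//
// [[Rcpp::export]]
List sim_core(NumericMatrix drive, NumericVector tau, NumericVector f_passive,
              NumericVector v, double dt, bool attenuate,
              NumericVector gamma, double k_d, double n_exp, double lambda0,
              double k_f, IntegerVector reset_idx,
              NumericVector x0, double lam_init) {
  const int N = drive.nrow();
  const int P = drive.ncol();
  if ((int)tau.size() != P) stop("tau length must match drive columns");

  NumericVector decay(P), gain0(P), gain1(P);
  for (int i = 0; i < P; ++i) {
    decay[i] = std::exp(-dt / tau[i]);
    double g = tau[i] * (1.0 - decay[i]);      // response to constant drive
    double h = tau[i] - tau[i] * g / dt;       // extra response to the ramp part
    gain0[i] = g - h;                          // weight of the start value
    gain1[i] = h;                              // weight of the end value
  }

  NumericMatrix x(N, P);
  NumericVector lam(N), F(N);
  std::vector<bool> is_reset(N + 1, false);
  for (int r = 0; r < reset_idx.size(); ++r) {
    int k = reset_idx[r];
    if (k >= 1 && k <= N) is_reset[k] = true;
  }

  std::vector<double> xs(P);
  for (int i = 0; i < P; ++i) xs[i] = (x0.size() == P) ? x0[i] : 0.0;
  double lambda = attenuate ? lam_init : 1.0;

  const double* dp = REAL(drive);       // column-major, N rows
  const double* vp = REAL(v);
  const double* fp = REAL(f_passive);
  const double* gp = REAL(gamma);
  double* xp = REAL(x);
  double* lp = REAL(lam);
  double* Fp = REAL(F);
  double v_prev = -1.0, pow_prev = 0.0;  // cache v^n across equal-speed steps

  for (int k = 0; k < N; ++k) {
    if (k > 0) {
      // advance from sample k-1 to k (drive linear between the samples)
      for (int i = 0; i < P; ++i)
        xs[i] = xs[i] * decay[i] + dp[(size_t)i * N + (k - 1)] * gain0[i]
                                 + dp[(size_t)i * N + k] * gain1[i];
      if (attenuate) {
        double vk = vp[k - 1];
        if (vk > 0.0) {
          if (vk != v_prev) { v_prev = vk; pow_prev = std::pow(vk, n_exp); }
          double Fk = Fp[k - 1] > 0.0 ? Fp[k - 1] : 0.0;
          double a = k_d * pow_prev / (1.0 + k_f * Fk);
          lambda *= std::exp(-a * dt);
        }
      }
    }
    if (attenuate && is_reset[k + 1]) lambda = lambda0;

    double lam_eff = lambda < 1.0 ? lambda : 1.0;
    double visco = 0.0;
    for (int i = 0; i < P; ++i) {
      double beta = attenuate ? 1.0 - gp[i] * (1.0 - lam_eff) : 1.0;
      visco += beta * xs[i];
      xp[(size_t)i * N + k] = xs[i];
    }
    lp[k] = attenuate ? lambda : 1.0;
    Fp[k] = fp[k] + visco;
  }

  return List::create(_["x"] = x, _["lam"] = lam, _["F_total"] = F);
}
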