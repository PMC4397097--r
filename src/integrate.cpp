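#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integration of delay-coupled oscillators.
//
// The Stuart-Landau node state is integrated in Cartesian (complex)
// coordinates: the polar form has a removable singularity at r = 0 which an
// explicit polar integrator cannot cross once additive amplitude noise is
// strong enough to drive r through zero.  The deterministic drift is
//   dz_j/dt = (lambda + i*omega_j - |z_j|^2) z_j
//             + (S/g_j^gamma) * sum_k K_jk z_k(t - tau_jk)
// which is the complex-state equivalent of the separated amplitude/phase
// equations.  Noise is applied per step either in polar coordinates
// (independent increments on modulus and angle, the default) or as a
// complex additive increment; both use the sqrt(dt) diffusion scaling.
//
// Delays are handled with a ring buffer of past states at the fine
// (substepped) resolution; lags are given per directed edge in fine steps.
// History before t = 0 is the initial state held constant.

static inline double wrap_pm_pi(double d) {
  // wrap to (-pi, pi] without fmod
  double w = d - 2.0 * M_PI * std::floor(d / (2.0 * M_PI));  // [0, 2pi)
  if (w > M_PI) w -= 2.0 * M_PI;
  return w;
}

// [[Rcpp::export]]
List sim_oscillators_cpp(IntegerVector nbr_ptr,    // CSR row pointers, length n+1 (0-based)
                         IntegerVector nbr_idx,    // neighbour ids per directed edge (0-based)
                         IntegerVector lag_fine,   // delay per directed edge, in fine steps
                         NumericVector pref,       // per-node coupling prefactor S / g^gamma
                         NumericVector omega,      // natural frequencies, rad/s
                         double lambda,
                         double noise_sd,
                         double dt,                // output sampling interval, s
                         int n_out,                // number of output samples (incl. initial)
                         int substeps,             // integration substeps per output sample
                         NumericVector r0,
                         NumericVector theta0,
                         int model,                // 0 stuart_landau, 1 kuramoto
                         int noise_mode) {         // 0 polar, 1 complex
  const int n = nbr_ptr.size() - 1;
  const double dtf = dt / substeps;
  const double sq = noise_sd * std::sqrt(dtf);

  int max_lag = 0;
  for (int e = 0; e < lag_fine.size(); ++e)
    if (lag_fine[e] > max_lag) max_lag = lag_fine[e];
  const int buf_len = max_lag + 1;

  NumericMatrix r_out(n, n_out), theta_out(n, n_out);

  // ring buffers of past states (x, y) or theta at fine resolution
  std::vector<double> bx((size_t)n * buf_len), by((size_t)n * buf_len);
  std::vector<double> x(n), y(n), thu(n), rr(n);

  for (int j = 0; j < n; ++j) {
    rr[j] = r0[j];
    thu[j] = theta0[j];
    x[j] = r0[j] * std::cos(theta0[j]);
    y[j] = r0[j] * std::sin(theta0[j]);
    for (int b = 0; b < buf_len; ++b) {
      bx[(size_t)j * buf_len + b] = (model == 1) ? theta0[j] : x[j];
      by[(size_t)j * buf_len + b] = y[j];
    }
    r_out(j, 0) = (model == 1) ? 1.0 : r0[j];
    theta_out(j, 0) = theta0[j];
  }

  int head = 0;  // buffer slot holding the current state
  std::vector<double> nx(n), ny(n);
  GetRNGstate();

  for (int s = 1; s < n_out; ++s) {
    for (int sub = 0; sub < substeps; ++sub) {
      if (model == 1) {  // Kuramoto: theta only, r == 1
        for (int j = 0; j < n; ++j) {
          double acc = 0.0;
          for (int e = nbr_ptr[j]; e < nbr_ptr[j + 1]; ++e) {
            int b = head - lag_fine[e];
            if (b < 0) b += buf_len;
            acc += std::sin(bx[(size_t)nbr_idx[e] * buf_len + b] - thu[j]);
          }
          nx[j] = thu[j] + dtf * (omega[j] + pref[j] * acc) + sq * norm_rand();
        }
        head = (head + 1) % buf_len;
        for (int j = 0; j < n; ++j) {
          thu[j] = nx[j];
          bx[(size_t)j * buf_len + head] = thu[j];
        }
      } else {  // Stuart-Landau in Cartesian coordinates
        // The natural rotation exp(i omega dt) is applied exactly
        // (integrating factor); a plain Euler step on the rotation would
        // inflate the limit-cycle radius by O((omega dt)^2) per step.
        for (int j = 0; j < n; ++j) {
          double cx = 0.0, cy = 0.0;
          for (int e = nbr_ptr[j]; e < nbr_ptr[j + 1]; ++e) {
            int b = head - lag_fine[e];
            if (b < 0) b += buf_len;
            size_t k = (size_t)nbr_idx[e] * buf_len + b;
            cx += bx[k];
            cy += by[k];
          }
          double rc = std::cos(omega[j] * dtf), rs = std::sin(omega[j] * dtf);
          double x1 = x[j] * rc - y[j] * rs;
          double y1 = x[j] * rs + y[j] * rc;
          double r2 = x1 * x1 + y1 * y1;
          nx[j] = x1 + dtf * ((lambda - r2) * x1 + pref[j] * cx);
          ny[j] = y1 + dtf * ((lambda - r2) * y1 + pref[j] * cy);
        }
        head = (head + 1) % buf_len;
        for (int j = 0; j < n; ++j) {
          double rn, an;
          if (noise_mode == 0) {  // polar noise
            rn = std::sqrt(nx[j] * nx[j] + ny[j] * ny[j]);
            an = (rn > 0.0) ? std::atan2(ny[j], nx[j]) : thu[j];
            rn += sq * norm_rand();
            if (rn < 0.0) rn = 0.0;
            an += sq * norm_rand();
            x[j] = rn * std::cos(an);
            y[j] = rn * std::sin(an);
          } else {  // complex additive noise
            x[j] = nx[j] + sq * norm_rand();
            y[j] = ny[j] + sq * norm_rand();
            rn = std::sqrt(x[j] * x[j] + y[j] * y[j]);
            an = (rn > 0.0) ? std::atan2(y[j], x[j]) : thu[j];
          }
          rr[j] = rn;
          thu[j] += wrap_pm_pi(an - wrap_pm_pi(thu[j]));
          bx[(size_t)j * buf_len + head] = x[j];
          by[(size_t)j * buf_len + head] = y[j];
        }
      }
    }
    for (int j = 0; j < n; ++j) {
      double rv = (model == 1) ? 1.0 : rr[j];
      if (!std::isfinite(rv) || !std::isfinite(thu[j])) {
        PutRNGstate();
        stop("integration failure: non-finite state at node %d, sample %d",
             j + 1, s + 1);
      }
      r_out(j, s) = rv;
      theta_out(j, s) = thu[j];
    }
  }
  PutRNGstate();

  return List::create(_["r"] = r_out, _["theta"] = theta_out);
}

// Pairwise phase statistics over a sample window [from, to] (1-based,
// inclusive): mean phase coherence PC_jk = |<exp(i dtheta)>| and the
// directed phase lag index dPLI_jk = <sign(dtheta wrapped to (-pi, pi])>.
// Wrapped differences with |d| < tie_tol count as ties (sign 0).

// [[Rcpp::export]]
List phase_pair_stats_cpp(NumericMatrix theta, int from, int to,
                          double tie_tol, bool do_pc) {
  const int n = theta.nrow();
  const int T = to - from + 1;
  NumericMatrix pc(n, n), dpli(n, n);

  for (int i = 0; i < n; ++i) {
    pc(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double sc = 0.0, ss = 0.0;
      long tally = 0;
      for (int t = from - 1; t < to; ++t) {
        double w = wrap_pm_pi(theta(i, t) - theta(j, t));
        if (do_pc) {
          sc += std::cos(w);
          ss += std::sin(w);
        }
        if (w > tie_tol) ++tally;
        else if (w < -tie_tol) --tally;
      }
      double d = (double)tally / T;
      dpli(i, j) = d;
      dpli(j, i) = -d;
      if (do_pc) {
        double p = std::sqrt(sc * sc + ss * ss) / T;
        pc(i, j) = p;
        pc(j, i) = p;
      }
    }
  }
  return List::create(_["pc"] = pc, _["dpli"] = dpli);
}
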