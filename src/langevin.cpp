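#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Euler-Maruyama integration of a single tracer in a sum of
// inverted Gaussian wells under periodic boundaries.  Energies are in k_BT,
// lengths in nm, times in ps.  With potential U in k_BT the overdamped update
// is x += -D0 * grad(U) * dt + sqrt(2 D0 dt) xi, where the free diffusion
// coefficient D0 = 1/friction (nm^2/ps) also plays the role of the mobility.
// Well depths may be modulated sinusoidally in time (one shared timescale,
// independent random phases) to emulate the slow reorganization of the
// surrounding organic matrix; `frozen` evaluates the potential at a fixed
// phase, mimicking a matrix held rigid while the tracer explores it.

static inline double minimg(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// [[Rcpp::export]]
List langevin_cpp(NumericMatrix centers, NumericVector depths, NumericVector widths,
                  double amp, double ts_ps, NumericVector phases,
                  double friction, bool noise, double dt, double n_steps_d,
                  int thin, NumericVector box, NumericVector x0,
                  bool frozen, double t_freeze) {
  const long long n_steps = (long long)n_steps_d;
  const int K = centers.nrow();
  const double D0 = 1.0 / friction;
  const double sig = noise ? std::sqrt(2.0 * D0 * dt) : 0.0;
  const double TWO_PI = 2.0 * M_PI;

  const long long n_frames = n_steps / thin + 1;
  NumericMatrix un((int)n_frames, 3);
  NumericVector times((int)n_frames);

  double x[3] = {x0[0], x0[1], x0[2]};
  double L[3] = {box[0], box[1], box[2]};
  double maxmove = 0.5 * std::min(L[0], std::min(L[1], L[2]));

  long long fr = 0;
  for (long long s = 0; s <= n_steps; ++s) {
    if (s % thin == 0 && fr < n_frames) {
      un(fr, 0) = x[0]; un(fr, 1) = x[1]; un(fr, 2) = x[2];
      times[fr] = s * dt;
      ++fr;
    }
    if (s == n_steps) break;

    double tmod = frozen ? t_freeze : s * dt;
    double g[3] = {0.0, 0.0, 0.0};
    for (int kk = 0; kk < K; ++kk) {
      double d0 = depths[kk];
      if (amp != 0.0) d0 += amp * std::sin(TWO_PI * tmod / ts_ps + phases[kk]);
      double dx[3], r2 = 0.0;
      for (int a = 0; a < 3; ++a) {
        dx[a] = minimg(x[a] - centers(kk, a), L[a]);
        r2 += dx[a] * dx[a];
      }
      double w2 = widths[kk] * widths[kk];
      double e = d0 * std::exp(-0.5 * r2 / w2) / w2;  // dU/dx = d*exp(..)*dx/w^2
      for (int a = 0; a < 3; ++a) g[a] += e * dx[a];
    }

    // instability guard on the deterministic drift only: the Gaussian kick
    // can legitimately be large at high D0, but a drift move beyond box/2
    // means the force integration has blown up.
    double driftmax = 0.0;
    for (int a = 0; a < 3; ++a) {
      double drift = -D0 * g[a] * dt;
      if (std::abs(drift) > driftmax) driftmax = std::abs(drift);
      x[a] += drift + (noise ? sig * norm_rand() : 0.0);
    }
    if (driftmax > maxmove || !R_finite(x[0] + x[1] + x[2]))
      stop("langevin integrator unstable: |drift step| = %g nm > box/2 at step %g; reduce dt",
           driftmax, (double)s);
  }

  return List::create(_["unwrapped"] = un, _["times"] = times);
}

// Potential energy (k_BT) of the static well landscape at given positions;
// used as the closed-form oracle for Boltzmann-inversion checks.
// [[Rcpp::export]]
NumericVector cavity_potential_cpp(NumericMatrix X, NumericMatrix centers,
                                   NumericVector depths, NumericVector widths,
                                   NumericVector box) {
  const int n = X.nrow(), K = centers.nrow();
  NumericVector U(n);
  for (int i = 0; i < n; ++i) {
    double u = 0.0;
    for (int kk = 0; kk < K; ++kk) {
      double r2 = 0.0;
      for (int a = 0; a < 3; ++a) {
        double d = minimg(X(i, a) - centers(kk, a), box[a]);
        r2 += d * d;
      }
      double w2 = widths[kk] * widths[kk];
      u -= depths[kk] * std::exp(-0.5 * r2 / w2);
    }
    U[i] = u;
  }
  return U;
}
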