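#include <Rcpp.h>
using namespace Rcpp;

// Spherical-shell Fickian water transport in an aqueous-organic droplet.
// Shells hold fixed solute mass; water moves between shells down the radial
// concentration gradient with a diffusivity evaluated at the interface water
// activity.  The droplet surface is held at instantaneous equilibrium with
// the gas phase (Dirichlet condition at r = R imposed through a half-cell
// flux into the outermost shell; no gas-side resistance).
//
// Units: SI throughout (kg, m, s).  log10 D(a_w) is a polynomial in a_w.
// Activity model: a_w(w) = w * exp(A * (1 - w)^2) with w the water mass
// fraction; strictly increasing for A < 2, a_w(0)=0, a_w(1)=1.

static double polyval(const NumericVector& c, double x) {
  double y = 0.0;
  for (int k = c.size() - 1; k >= 0; --k) y = y * x + c[k];
  return y;
}

static double activity_of_w(double w, double A) {
  double om = 1.0 - w;
  return w * std::exp(A * om * om);
}

// invert a_w(w) = a by bisection (map is strictly increasing on [0,1])
static double w_of_activity(double a, double A) {
  if (a <= 0.0) return 0.0;
  if (a >= 1.0) return 1.0;
  double lo = 0.0, hi = 1.0;
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    if (activity_of_w(mid, A) < a) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

static double density_of_w(double w, double rho_w, double rho_s) {
  return 1.0 / (w / rho_w + (1.0 - w) / rho_s);   // ideal volume additivity
}

// [[Rcpp::export]]
List shell_solve_cpp(NumericVector m_s, NumericVector m_w0, NumericVector dcoef,
                     double act_A, double rho_w, double rho_s,
                     double a_surf, NumericVector out_times,
                     double safety, double max_steps) {
  const int N = m_s.size();
  const int M = out_times.size();
  const double PI4 = 4.0 * M_PI;
  const double C43 = 4.0 * M_PI / 3.0;

  std::vector<double> m_w(m_w0.begin(), m_w0.end());
  std::vector<double> w(N), aw(N), V(N), rb(N + 1), rc(N), conc(N), k(N),
      m_new(N);

  const double w_surf = w_of_activity(a_surf, act_A);
  const double c_surf = w_surf * density_of_w(w_surf, rho_w, rho_s);

  NumericVector out_R(M), out_Mw(M);
  double t = 0.0;
  double prev_t = 0.0, prev_R = 0.0, prev_Mw = 0.0;
  int next_out = 0;
  long long steps = 0;
  double M0 = 0.0;
  for (int i = 0; i < N; ++i) M0 += m_w[i];
  double cum_flux = 0.0;   // net water into the droplet through the surface

  while (true) {
    // geometry and thermodynamic state
    double cumV = 0.0;
    for (int i = 0; i < N; ++i) {
      double mt = m_s[i] + m_w[i];
      w[i] = m_w[i] / mt;
      aw[i] = activity_of_w(w[i], act_A);
      V[i] = mt / density_of_w(w[i], rho_w, rho_s);
      conc[i] = m_w[i] / V[i];
      cumV += V[i];
      rb[i + 1] = std::cbrt(cumV / C43);
    }
    rb[0] = 0.0;
    for (int i = 0; i < N; ++i) rc[i] = 0.5 * (rb[i] + rb[i + 1]);

    const double R = rb[N];
    double Mw = 0.0;
    for (int i = 0; i < N; ++i) Mw += m_w[i];
    if (steps == 0) { prev_t = 0.0; prev_R = R; prev_Mw = Mw; }

    // emit outputs up to current t (linear interpolation between steps)
    while (next_out < M && out_times[next_out] <= t + 1e-300) {
      double to = out_times[next_out];
      double f = (t > prev_t) ? (to - prev_t) / (t - prev_t) : 1.0;
      if (to <= prev_t) f = 0.0;
      out_R[next_out] = prev_R + f * (R - prev_R);
      out_Mw[next_out] = prev_Mw + f * (Mw - prev_Mw);
      ++next_out;
    }
    if (next_out >= M) break;

    // transfer coefficients (m^3/s): k[j] couples shells j | j+1 for
    // j < N-1; k[N-1] couples the outermost shell to the surface node.
    for (int j = 0; j < N - 1; ++j) {
      double ai = 0.5 * (aw[j] + aw[j + 1]);
      double D = std::pow(10.0, polyval(dcoef, ai));
      k[j] = D * PI4 * rb[j + 1] * rb[j + 1] / (rc[j + 1] - rc[j]);
    }
    {
      double ai = 0.5 * (aw[N - 1] + a_surf);
      double D = std::pow(10.0, polyval(dcoef, ai));
      k[N - 1] = D * PI4 * R * R / (R - rc[N - 1]);
    }
    double smax = 0.0;
    for (int i = 0; i < N; ++i) {
      double s = ((i > 0 ? k[i - 1] : 0.0) + k[i]) / V[i];
      if (s > smax) smax = s;
    }
    if (smax <= 0.0 || !R_finite(smax)) break;   // degenerate; hold below

    double grad_any = 0.0;
    for (int j = 0; j < N - 1; ++j) grad_any += std::abs(conc[j + 1] - conc[j]);
    grad_any += std::abs(c_surf - conc[N - 1]);
    if (grad_any < 1e-12 * (std::abs(c_surf) + 1e-300)) {
      for (; next_out < M; ++next_out) { out_R[next_out] = R; out_Mw[next_out] = Mw; }
      break;
    }

    double dt = safety / smax;
    double t_last = out_times[M - 1];
    if (t + dt > t_last) dt = t_last - t + 1e-9 * (t_last + 1e-300);

    // explicit flux update with negative-mass auto-refinement
    double loc = 1.0;
    for (int attempt = 0; ; ++attempt) {
      double dtt = dt * loc;
      for (int i = 0; i < N; ++i) m_new[i] = m_w[i];
      for (int j = 0; j < N - 1; ++j) {
        double f = dtt * k[j] * (conc[j + 1] - conc[j]);  // into shell j
        m_new[j] += f;
        m_new[j + 1] -= f;
      }
      double f_surf = dtt * k[N - 1] * (c_surf - conc[N - 1]);
      m_new[N - 1] += f_surf;
      bool ok = true;
      for (int i = 0; i < N; ++i) if (m_new[i] < 0.0) { ok = false; break; }
      if (ok) {
        cum_flux += f_surf;
        for (int i = 0; i < N; ++i) m_w[i] = m_new[i];
        prev_t = t; prev_R = R; prev_Mw = Mw;
        t += dtt;
        break;
      }
      loc *= 0.5;
      if (attempt >= 40)
        stop("shell solver: negative water mass persists after dt refinement (t=%g s, dt=%g s)", t, dtt);
    }

    if (++steps > (long long)max_steps)
      stop("shell solver: step budget exceeded (%g steps, reached t=%g of %g s)",
           (double)steps, t, out_times[M - 1]);
  }

  double M1 = 0.0;
  for (int i = 0; i < N; ++i) M1 += m_w[i];
  double denom = std::max(std::abs(cum_flux), 1e-300);
  double audit = std::abs((M1 - M0) - cum_flux) / denom;

  return List::create(_["radius"] = out_R, _["water_mass"] = out_Mw,
                      _["m_w_final"] = NumericVector(m_w.begin(), m_w.end()),
                      _["n_steps"] = (double)steps,
                      _["mass_audit"] = audit,
                      _["w_surf"] = w_surf);
}

// [[Rcpp::export]]
double activity_forward_cpp(double w, double A) { return activity_of_w(w, A); }

// [[Rcpp::export]]
double activity_inverse_cpp(double a, double A) { return w_of_activity(a, A); }
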