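// Calcium-response ODE core: right-hand side and adaptive Dormand-Prince RK45.
//
// Four states: ip3 (uM), plc (a.u.), ca (uM cytosolic free), h (IP3R fraction
// not calcium-inactivated). Seventeen free kinetic parameters, natural scale.
// The ER leak conductance is not free: it is closed once per simulation so
// that leak balances SERCA pumping exactly at the pre-stimulus rest state.
//
// No stiff solver is available in the target environment; the embedded RK45
// with tight tolerances handles the mildly stiff gating dynamics, and draws
// extreme enough to defeat it are reported as failures (the sampler treats a
// failure as a rejection, never an exception).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// frozen parameter order; must match calci_param_names() on the R side
enum par {
  D1, D5, DINH, A2, V_IP3R, V_SERCA, K_SERCA, K_PLC, K_R, K_PLC_DEG,
  V_IP3_PROD, K_PLC_HALF, N_HILL, K_IP3_DEG, C_ER, CA_TOT, BETA_BUF,
  NPAR
};

static inline double hill_up(double x, double k, double n) {
  // x^n / (k^n + x^n), computed as 1/(1+(k/x)^n) for overflow safety
  if (x <= 0.0) return 0.0;
  return 1.0 / (1.0 + std::pow(k / x, n));
}

static void rhs_core(double t, const double *y, double *dy,
                     const double *p, double L, double t_on, double k_leak) {
  const double ip3 = y[0], plc = y[1], ca = y[2], h = y[3];
  const double u = (t >= t_on) ? L * std::exp(-p[K_R] * (t - t_on)) : 0.0;
  dy[1] = p[K_PLC] * u - p[K_PLC_DEG] * plc;
  dy[0] = p[V_IP3_PROD] * hill_up(plc, p[K_PLC_HALF], p[N_HILL])
          - p[K_IP3_DEG] * ip3;
  const double ca_er = (p[CA_TOT] - ca) / p[C_ER];
  const double act = ip3 / (ip3 + p[D1]) * ca / (ca + p[D5]) * h;
  const double popen = act * act * act;
  const double j_rel = p[C_ER] * (p[V_IP3R] * popen + k_leak) * (ca_er - ca);
  const double j_serca = p[V_SERCA] * ca * ca
                         / (p[K_SERCA] * p[K_SERCA] + ca * ca);
  dy[2] = p[BETA_BUF] * (j_rel - j_serca);
  dy[3] = p[A2] * (p[DINH] * (1.0 - h) - ca * h);
}

// leak closure; returns negative value on inadmissible rest state
static double leak_coef(const double *p, double ca0) {
  const double ca_er0 = (p[CA_TOT] - ca0) / p[C_ER];
  if (!(ca_er0 > ca0)) return -1.0;
  const double j0 = p[V_SERCA] * ca0 * ca0
                    / (p[K_SERCA] * p[K_SERCA] + ca0 * ca0);
  return j0 / (p[C_ER] * (ca_er0 - ca0));
}

// [[Rcpp::export]]
NumericVector calci_rhs_cpp(NumericVector state, double t, NumericVector params,
                            double atp, double t_on, double ca0) {
  if (state.size() != 4) stop("state must have length 4");
  if (params.size() != NPAR) stop("params must have length 17");
  const double kl = leak_coef(REAL(params), ca0);
  if (kl < 0) stop("inadmissible rest state: ER calcium not above cytosolic");
  NumericVector dy(4);
  rhs_core(t, REAL(state), REAL(dy), REAL(params), atp, t_on, kl);
  return dy;
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0/5, c3 = 3.0/10, c4 = 4.0/5, c5 = 8.0/9;
static const double a21 = 1.0/5;
static const double a31 = 3.0/40, a32 = 9.0/40;
static const double a41 = 44.0/45, a42 = -56.0/15, a43 = 32.0/9;
static const double a51 = 19372.0/6561, a52 = -25360.0/2187,
                    a53 = 64448.0/6561, a54 = -212.0/729;
static const double a61 = 9017.0/3168, a62 = -355.0/33, a63 = 46732.0/5247,
                    a64 = 49.0/176, a65 = -5103.0/18656;
static const double b1 = 35.0/384, b3 = 500.0/1113, b4 = 125.0/192,
                    b5 = -2187.0/6784, b6 = 11.0/84;
static const double e1 = 71.0/57600, e3 = -71.0/16695, e4 = 71.0/1920,
                    e5 = -17253.0/339200, e6 = 22.0/525, e7 = -1.0/40;

struct Integrator {
  const double *p;
  double L, t_on, k_leak, rtol, atol;
  long max_steps, steps_used = 0;

  // advance y from t0 to t1; returns false on failure
  bool leg(double t0, double t1, double *y) {
    if (t1 <= t0) return true;
    double t = t0, hstep = std::min(1.0, t1 - t0);
    double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], k7[4], ytmp[4], ynew[4];
    rhs_core(t, y, k1, p, L, t_on, k_leak);
    while (t < t1) {
      if (++steps_used > max_steps) return false;
      if (hstep < 1e-10 * (std::fabs(t) + 1.0)) return false;
      if (t + hstep > t1) hstep = t1 - t;
      for (int i = 0; i < 4; ++i) ytmp[i] = y[i] + hstep * a21 * k1[i];
      rhs_core(t + c2*hstep, ytmp, k2, p, L, t_on, k_leak);
      for (int i = 0; i < 4; ++i)
        ytmp[i] = y[i] + hstep * (a31*k1[i] + a32*k2[i]);
      rhs_core(t + c3*hstep, ytmp, k3, p, L, t_on, k_leak);
      for (int i = 0; i < 4; ++i)
        ytmp[i] = y[i] + hstep * (a41*k1[i] + a42*k2[i] + a43*k3[i]);
      rhs_core(t + c4*hstep, ytmp, k4, p, L, t_on, k_leak);
      for (int i = 0; i < 4; ++i)
        ytmp[i] = y[i] + hstep * (a51*k1[i] + a52*k2[i] + a53*k3[i] + a54*k4[i]);
      rhs_core(t + c5*hstep, ytmp, k5, p, L, t_on, k_leak);
      for (int i = 0; i < 4; ++i)
        ytmp[i] = y[i] + hstep * (a61*k1[i] + a62*k2[i] + a63*k3[i]
                                  + a64*k4[i] + a65*k5[i]);
      rhs_core(t + hstep, ytmp, k6, p, L, t_on, k_leak);
      for (int i = 0; i < 4; ++i)
        ynew[i] = y[i] + hstep * (b1*k1[i] + b3*k3[i] + b4*k4[i]
                                  + b5*k5[i] + b6*k6[i]);
      rhs_core(t + hstep, ynew, k7, p, L, t_on, k_leak);
      double errnorm = 0.0;
      for (int i = 0; i < 4; ++i) {
        const double err = hstep * (e1*k1[i] + e3*k3[i] + e4*k4[i]
                                    + e5*k5[i] + e6*k6[i] + e7*k7[i]);
        const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                                 std::fabs(ynew[i]));
        const double r = err / sc;
        errnorm += r * r;
      }
      errnorm = std::sqrt(errnorm / 4.0);
      if (!std::isfinite(errnorm)) return false;
      if (errnorm <= 1.0) {           // accept
        t += hstep;
        for (int i = 0; i < 4; ++i) { y[i] = ynew[i]; k1[i] = k7[i]; }
        if (!std::isfinite(y[0]) || !std::isfinite(y[2])) return false;
        // conservation guard: implied ER calcium must stay nonnegative
        if (y[2] < -1e-9 || y[2] > p[CA_TOT] + 1e-9) return false;
      }
      double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
      fac = std::min(5.0, std::max(0.2, fac));
      hstep *= fac;
    }
    return true;
  }
};

// Simulate the model on an output grid 0, dt_out, ..., <= duration.
// Returns list(status, times, states [n x 4]); status 0 = ok, 1 = failed.
// [[Rcpp::export]]
List calci_simulate_cpp(NumericVector params, double atp, double t_on,
                        double duration, double dt_out, double ca0,
                        double rtol, double atol, double max_steps) {
  if (params.size() != NPAR) stop("params must have length 17");
  const double *p = REAL(params);
  for (int i = 0; i < NPAR; ++i)
    if (!(p[i] > 0.0) || !std::isfinite(p[i]))
      return List::create(_["status"] = 1, _["times"] = R_NilValue,
                          _["states"] = R_NilValue);
  const double kl = leak_coef(p, ca0);
  if (kl < 0)
    return List::create(_["status"] = 1, _["times"] = R_NilValue,
                        _["states"] = R_NilValue);
  const int n = (int)std::floor(duration / dt_out + 1e-9) + 1;
  NumericVector times(n);
  NumericMatrix states(n, 4);
  double y[4] = {0.0, 0.0, ca0, p[DINH] / (p[DINH] + ca0)};

  Integrator ig;
  ig.p = p; ig.L = atp; ig.t_on = t_on; ig.k_leak = kl;
  ig.rtol = rtol; ig.atol = atol; ig.max_steps = (long)max_steps;

  double t_prev = 0.0;
  bool crossed = false;
  times[0] = 0.0;
  for (int j = 0; j < 4; ++j) states(0, j) = y[j];
  for (int i = 1; i < n; ++i) {
    const double t_next = i * dt_out;
    bool ok = true;
    // never step across the stimulus discontinuity
    if (!crossed && t_prev < t_on && t_next > t_on) {
      ok = ig.leg(t_prev, t_on, y) && ig.leg(t_on, t_next, y);
      crossed = true;
    } else {
      ok = ig.leg(t_prev, t_next, y);
      if (t_next >= t_on) crossed = true;
    }
    if (!ok)
      return List::create(_["status"] = 1, _["times"] = R_NilValue,
                          _["states"] = R_NilValue);
    times[i] = t_next;
    for (int j = 0; j < 4; ++j) states(i, j) = y[j];
    t_prev = t_next;
  }
  return List::create(_["status"] = 0, _["times"] = times,
                      _["states"] = states);
}
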