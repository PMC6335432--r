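// Population-dynamics right-hand sides and an adaptive Dormand-Prince RK45
// integrator. Kept in C++ because scenario generation integrates thousands
// of trajectories per dataset.
//
// Dynamics kinds:
//   0  two-population logistic mutualism family (structural flags in par)
//   1  complex-pair surrogate (competition, partner-dependent cost,
//      high-Hill saturating benefit, asymmetric function forms)
//   2  N-mutualist: benefit saturates in the sum of partner densities
//   3  oscillatory forcing of the model-21 pair (square-wave signal
//      modulating delta and beta)
//   4  complex pair embedded in a bystander community with random
//      Lotka-Volterra cross-interactions

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// positive remainder; avoids std::fmod, whose symbol version is newer than
// some host glibc runtimes
static inline double mod_pos(double x, double T) {
  double m = x - std::floor(x / T) * T;
  if (m < 0) m += T;
  if (m >= T) m -= T;
  return m;
}

static inline double hillf(double x, double K, double h) {
  if (x <= 0.0) return 0.0;
  double xh = std::pow(x, h), Kh = std::pow(K, h);
  return xh / (Kh + xh);
}

// complex-pair surrogate constants (see scenarios module docs)
static const double CP_R = 1.0, CP_A = 0.2, CP_C = 0.1;
static const double CP_K1 = 0.30, CP_H1 = 4.0;  // population 1 forms
static const double CP_K2 = 0.35, CP_H2 = 6.0;  // population 2 forms

static void rhs_complex_pair(const double* p, const double* x, double* dx,
                             double extra1, double extra2) {
  // p = [delta1, delta2, beta1, beta2]; extra_i: additive per-capita terms
  double X1 = x[0], X2 = x[1];
  double s1 = hillf(X2, CP_K1, CP_H1);  // saturation seen by population 1
  double s2 = hillf(X1, CP_K2, CP_H2);
  double phi1 = CP_R * (1.0 - X1 - CP_A * X2) - CP_C * s1 -
                p[0] / (1.0 + p[2] * s1) + extra1;
  double phi2 = CP_R * (1.0 - X2 - CP_A * X1) - CP_C * s2 -
                p[1] / (1.0 + p[3] * s2) + extra2;
  dx[0] = X1 * phi1;
  dx[1] = X2 * phi2;
}

static void rhs(int kind, const double* p, const double* x, int n, double t,
                double* dx) {
  switch (kind) {
  case 0: {
    // p = [bt, cf, bsat, layer, beta1, beta2, eps1, eps2, delta1, delta2,
    //      a, d, hill, Kb, Kc]
    int bt = (int)p[0], cf = (int)p[1], bsat = (int)p[2], layer = (int)p[3];
    double beta[2] = {p[4], p[5]}, eps[2] = {p[6], p[7]}, del[2] = {p[8], p[9]};
    double a = p[10], dtn = p[11], h = p[12], Kb = p[13], Kc = p[14];
    if (layer == 2) {  // structural asymmetry layer: fixed multipliers
      beta[1] *= 0.8;
      eps[1] *= 1.25;
    }
    for (int i = 0; i < 2; i++) {
      int j = 1 - i;
      double Xi = x[i], Xj = x[j];
      double g;
      if (bt == 2) g = beta[i] * Xj;  // relief saturates through 1/(1+g)
      else g = bsat ? beta[i] * hillf(Xj, Kb, h) : beta[i] * Xj;
      double cm;
      if (cf == 0) cm = 1.0 / eps[i];
      else if (cf == 1) cm = 1.0 / (1.0 + eps[i] * Xi);
      else cm = 1.0 / (1.0 + eps[i] * Xi / (Xi + Kc));
      double crowd = (layer == 1) ? Xi + a * Xj : Xi;
      double phi;
      if (bt == 0) phi = cm * (1.0 + g) * (1.0 - crowd) - del[i];
      else if (bt == 1) phi = cm * (1.0 - crowd / (1.0 + g)) - del[i];
      else phi = cm * (1.0 - crowd) - del[i] / (1.0 + g);
      if (layer == 3) phi -= dtn;
      dx[i] = Xi * phi;
    }
    break;
  }
  case 1:
    rhs_complex_pair(p, x, dx, 0.0, 0.0);
    break;
  case 2: {
    // p = [n, r, h, K, delta_1..n, beta_1..n]
    int nm = (int)p[0];
    double r = p[1], h = p[2], K = p[3];
    double S = 0.0;
    for (int i = 0; i < nm; i++) S += x[i];
    for (int i = 0; i < nm; i++) {
      double Si = S - x[i];
      double sat = hillf(Si, K, h);
      double phi = r * (1.0 - x[i]) - p[4 + i] / (1.0 + p[4 + nm + i] * sat);
      dx[i] = x[i] * phi;
    }
    break;
  }
  case 3: {
    // p = [beta0, eps, delta0, I, L, T]; square wave s(t) on for
    // (t mod T) < L
    double beta0 = p[0], eps = p[1], delta0 = p[2], I = p[3], L = p[4],
           T = p[5];
    double tm = mod_pos(t, T);
    double s = (tm < L) ? 1.0 : 0.0;
    double beta = beta0 * (1.0 - 0.5 * s);
    double del = delta0 * (1.0 + I * s);
    for (int i = 0; i < 2; i++) {
      int j = 1 - i;
      double phi = (1.0 / eps) * (1.0 - x[i]) - del / (1.0 + beta * x[j]);
      dx[i] = x[i] * phi;
    }
    break;
  }
  case 4: {
    // p = [nb, delta1, delta2, beta1, beta2, rb, db, W (m*m row-major)]
    int nb = (int)p[0];
    int m = 2 + nb;
    double rb = p[5], db = p[6];
    const double* W = p + 7;
    double e1 = 0.0, e2 = 0.0;
    for (int k = 2; k < m; k++) {
      e1 += W[0 * m + k] * x[k];
      e2 += W[1 * m + k] * x[k];
    }
    rhs_complex_pair(p + 1, x, dx, e1, e2);
    for (int b = 2; b < m; b++) {
      double inter = 0.0;
      for (int k = 0; k < m; k++)
        if (k != b) inter += W[b * m + k] * x[k];
      dx[b] = x[b] * (rb * (1.0 - x[b]) - db + inter);
    }
    break;
  }
  default:
    stop("unknown dynamics kind");
  }
}

// [[Rcpp::export]]
NumericVector ode_rhs(int kind, NumericVector par, NumericVector x,
                      double t = 0.0) {
  int n = x.size();
  NumericVector dx(n);
  rhs(kind, par.begin(), x.begin(), n, t, dx.begin());
  return dx;
}

// Dormand-Prince 5(4) coefficients
static const double C2 = 1.0 / 5, C3 = 3.0 / 10, C4 = 4.0 / 5, C5 = 8.0 / 9;
static const double A21 = 1.0 / 5;
static const double A31 = 3.0 / 40, A32 = 9.0 / 40;
static const double A41 = 44.0 / 45, A42 = -56.0 / 15, A43 = 32.0 / 9;
static const double A51 = 19372.0 / 6561, A52 = -25360.0 / 2187,
                    A53 = 64448.0 / 6561, A54 = -212.0 / 729;
static const double A61 = 9017.0 / 3168, A62 = -355.0 / 33,
                    A63 = 46732.0 / 5247, A64 = 49.0 / 176,
                    A65 = -5103.0 / 18656;
static const double B1 = 35.0 / 384, B3 = 500.0 / 1113, B4 = 125.0 / 192,
                    B5 = -2187.0 / 6784, B6 = 11.0 / 84;
static const double E1 = 71.0 / 57600, E3 = -71.0 / 16695, E4 = 71.0 / 1920,
                    E5 = -17253.0 / 339200, E6 = 22.0 / 525, E7 = -1.0 / 40;

// Integrate from t = 0 to t_end. Stops early (steady = TRUE) when the
// derivative max-norm falls below steady_tol (autonomous kinds only).
// For kind 3 the step is clipped so it never straddles a square-wave switch,
// and componentwise minima / time-averages are accumulated for
// t >= window_start (pass < 0 to disable).
// [[Rcpp::export]]
List ode_solve(int kind, NumericVector par, NumericVector x0, double t_end,
               double rtol = 1e-8, double atol = 1e-10,
               double steady_tol = 1e-6, bool record = false,
               double window_start = -1.0, int max_steps = 2000000) {
  int n = x0.size();
  bool autonomous = (kind != 3);
  std::vector<double> y(x0.begin(), x0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n),
      ytmp(n), y5(n);
  std::vector<double> wmin(n, R_PosInf), wsum(n, 0.0);
  double wtime = 0.0;
  bool have_window = window_start >= 0.0;

  std::vector<double> rec_t;
  std::vector<double> rec_y;
  double t = 0.0;
  if (record) {
    rec_t.push_back(t);
    for (int i = 0; i < n; i++) rec_y.push_back(y[i]);
  }

  rhs(kind, par.begin(), y.data(), n, t, k1.data());
  double h = std::min(1e-2, t_end / 100.0);
  if (h <= 0) stop("horizon must be positive");
  bool steady = false;
  int step = 0;

  while (t < t_end && step < max_steps) {
    step++;
    if (h > t_end - t) h = t_end - t;
    if (kind == 3) {  // clip at square-wave discontinuities
      double T = par[5], L = par[4];
      double tm = mod_pos(t, T);
      double tnext = (tm < L) ? (L - tm) : (T - tm);
      if (tnext < 1e-9) tnext = 1e-9;
      if (h > tnext) h = tnext;
    }

    for (int i = 0; i < n; i++) ytmp[i] = y[i] + h * A21 * k1[i];
    rhs(kind, par.begin(), ytmp.data(), n, t + C2 * h, k2.data());
    for (int i = 0; i < n; i++)
      ytmp[i] = y[i] + h * (A31 * k1[i] + A32 * k2[i]);
    rhs(kind, par.begin(), ytmp.data(), n, t + C3 * h, k3.data());
    for (int i = 0; i < n; i++)
      ytmp[i] = y[i] + h * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
    rhs(kind, par.begin(), ytmp.data(), n, t + C4 * h, k4.data());
    for (int i = 0; i < n; i++)
      ytmp[i] = y[i] + h * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] +
                            A54 * k4[i]);
    rhs(kind, par.begin(), ytmp.data(), n, t + C5 * h, k5.data());
    for (int i = 0; i < n; i++)
      ytmp[i] = y[i] + h * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i] +
                            A64 * k4[i] + A65 * k5[i]);
    rhs(kind, par.begin(), ytmp.data(), n, t + h, k6.data());
    for (int i = 0; i < n; i++)
      y5[i] = y[i] + h * (B1 * k1[i] + B3 * k3[i] + B4 * k4[i] + B5 * k5[i] +
                          B6 * k6[i]);
    rhs(kind, par.begin(), y5.data(), n, t + h, k7.data());

    double err = 0.0;
    for (int i = 0; i < n; i++) {
      double e = h * (E1 * k1[i] + E3 * k3[i] + E4 * k4[i] + E5 * k5[i] +
                      E6 * k6[i] + E7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double r = e / sc;
      err += r * r;
    }
    err = std::sqrt(err / n);

    if (err <= 1.0 || h <= 1e-12) {
      // accept
      double t_new = t + h;
      for (int i = 0; i < n; i++) {
        double v = y5[i];
        if (v < 0.0) v = (v > -1e-8) ? 0.0 : v;  // numerical undershoot
        if (v < 0.0) v = 0.0;  // dynamics are non-negative by construction
        y[i] = v;
      }
      if (have_window) {
        double lo = std::max(t, window_start);
        if (t_new > window_start) {
          double w = t_new - lo;
          for (int i = 0; i < n; i++) {
            if (y[i] < wmin[i]) wmin[i] = y[i];
            wsum[i] += w * y[i];
          }
          wtime += w;
        }
      }
      t = t_new;
      if (record) {
        rec_t.push_back(t);
        for (int i = 0; i < n; i++) rec_y.push_back(y[i]);
      }
      rhs(kind, par.begin(), y.data(), n, t, k1.data());  // FSAL restart
      if (autonomous) {
        double dmax = 0.0;
        for (int i = 0; i < n; i++)
          dmax = std::max(dmax, std::fabs(k1[i]));
        if (dmax < steady_tol) {
          steady = true;
          break;
        }
      }
    }
    double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < 1e-12) h = 1e-12;
  }
  if (step >= max_steps)
    stop("integration exceeded max_steps (diagnostics: t=%f, h=%g)", t, h);

  NumericVector fin(n);
  for (int i = 0; i < n; i++) fin[i] = y[i];
  List out = List::create(
      _["final_state"] = fin, _["t_final"] = t, _["steady"] = steady,
      _["n_steps"] = step);
  if (record) {
    int m = rec_t.size();
    NumericVector tv(m);
    NumericMatrix ym(m, n);
    for (int r = 0; r < m; r++) {
      tv[r] = rec_t[r];
      for (int i = 0; i < n; i++) ym(r, i) = rec_y[(size_t)r * n + i];
    }
    out["times"] = tv;
    out["states"] = ym;
  }
  if (have_window) {
    NumericVector mn(n), mean(n);
    for (int i = 0; i < n; i++) {
      mn[i] = wmin[i];
      mean[i] = (wtime > 0) ? wsum[i] / wtime : NA_REAL;
    }
    out["window_min"] = mn;
    out["window_mean"] = mean;
  }
  return out;
}
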