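#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State layout: eIF4E, 4E-BP, eIF4G (free forms), eIF4E:4E-BP, eIF4E:eIF4G,
// accumulated protein. Parameter layout: k_on1, k_off1, k_on2, k_off2,
// k_cat_4ebp, k_lys_4ebp, k_cat_protein. Concentrations in uM, time in s,
// second-order rates in uM^-1 s^-1.
static const int NS = 6;
static const int NP = 7;

// Fraction of the linear parameter ramp completed at time t.
static inline double ramp_frac(double t, double t_start, double duration) {
  if (t <= t_start) return 0.0;
  if (duration <= 0.0 || t >= t_start + duration) return 1.0;
  return (t - t_start) / duration;
}

static inline void deriv(double t, const double* y, double* dy,
                         const double* p0, const double* fold,
                         double t_start, double duration) {
  const double s = ramp_frac(t, t_start, duration);
  double p[NP];
  for (int i = 0; i < NP; ++i) p[i] = p0[i] * (1.0 + (fold[i] - 1.0) * s);
  const double E = y[0], B = y[1], G = y[2], C1 = y[3], C2 = y[4];
  const double a1 = p[0] * E * B;   // eIF4E + 4E-BP association flux
  const double d1 = p[1] * C1;      // eIF4E:4E-BP dissociation flux
  const double a2 = p[2] * E * G;   // eIF4E + eIF4G association flux
  const double d2 = p[3] * C2;      // eIF4E:eIF4G dissociation flux
  dy[0] = d1 + d2 - a1 - a2;
  dy[1] = d1 + p[4] * C2 - p[5] * B - a1;
  dy[2] = d2 - a2;
  dy[3] = a1 - d1;
  dy[4] = a2 - d2;
  dy[5] = p[6] * C2;
}

// Dormand-Prince 5(4) coefficients (FSAL).
static const double C2 = 1.0 / 5.0, C3 = 3.0 / 10.0, C4 = 4.0 / 5.0,
                    C5 = 8.0 / 9.0;
static const double A21 = 1.0 / 5.0;
static const double A31 = 3.0 / 40.0, A32 = 9.0 / 40.0;
static const double A41 = 44.0 / 45.0, A42 = -56.0 / 15.0, A43 = 32.0 / 9.0;
static const double A51 = 19372.0 / 6561.0, A52 = -25360.0 / 2187.0,
                    A53 = 64448.0 / 6561.0, A54 = -212.0 / 729.0;
static const double A61 = 9017.0 / 3168.0, A62 = -355.0 / 33.0,
                    A63 = 46732.0 / 5247.0, A64 = 49.0 / 176.0,
                    A65 = -5103.0 / 18656.0;
static const double B1 = 35.0 / 384.0, B3 = 500.0 / 1113.0,
                    B4 = 125.0 / 192.0, B5 = -2187.0 / 6784.0,
                    B6 = 11.0 / 84.0;
// b - bhat (embedded 4th-order error coefficients)
static const double E1 = 71.0 / 57600.0, E3 = -71.0 / 16695.0,
                    E4 = 71.0 / 1920.0, E5 = -17253.0 / 339200.0,
                    E6 = 22.0 / 525.0, E7 = -1.0 / 40.0;

// Integrate from t = 0, writing all NS species at each requested output
// time into out (row-major n_out x NS). Returns 0 on success, 1 if a
// species went more negative than -100*abs_tol, 2 on step-size underflow,
// 3 if the step budget was exhausted.
static int integrate_path(const double* y0, const double* p0,
                          const double* fold, double t_start, double duration,
                          const double* t_out, int n_out, double rel_tol,
                          double abs_tol, double* out) {
  double y[NS], ynew[NS];
  double k1[NS], k2[NS], k3[NS], k4[NS], k5[NS], k6[NS], k7[NS], ytmp[NS];
  for (int i = 0; i < NS; ++i) y[i] = y0[i];
  double t = 0.0;
  int iout = 0;
  while (iout < n_out && t_out[iout] <= t + 1e-14) {
    for (int i = 0; i < NS; ++i) out[iout * NS + i] = y[i];
    ++iout;
  }
  if (iout >= n_out) return 0;

  const double t_end = t_out[n_out - 1];
  double h = std::min(1.0, t_end > 0 ? t_end : 1.0);
  const double neg_floor = -100.0 * abs_tol;
  long max_steps = 50000000L;
  deriv(t, y, k1, p0, fold, t_start, duration);

  while (iout < n_out) {
    if (--max_steps <= 0) return 3;
    double target = t_out[iout];
    if (h > target - t) h = target - t;
    if (h < 1e-13) {
      // degenerate leftover interval; snap to target
      t = target;
      for (int i = 0; i < NS; ++i) out[iout * NS + i] = y[i];
      ++iout;
      h = 1.0;
      continue;
    }

    for (int i = 0; i < NS; ++i) ytmp[i] = y[i] + h * A21 * k1[i];
    deriv(t + C2 * h, ytmp, k2, p0, fold, t_start, duration);
    for (int i = 0; i < NS; ++i)
      ytmp[i] = y[i] + h * (A31 * k1[i] + A32 * k2[i]);
    deriv(t + C3 * h, ytmp, k3, p0, fold, t_start, duration);
    for (int i = 0; i < NS; ++i)
      ytmp[i] = y[i] + h * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
    deriv(t + C4 * h, ytmp, k4, p0, fold, t_start, duration);
    for (int i = 0; i < NS; ++i)
      ytmp[i] = y[i] +
                h * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] + A54 * k4[i]);
    deriv(t + C5 * h, ytmp, k5, p0, fold, t_start, duration);
    for (int i = 0; i < NS; ++i)
      ytmp[i] = y[i] + h * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i] +
                            A64 * k4[i] + A65 * k5[i]);
    deriv(t + h, ytmp, k6, p0, fold, t_start, duration);
    for (int i = 0; i < NS; ++i)
      ynew[i] = y[i] + h * (B1 * k1[i] + B3 * k3[i] + B4 * k4[i] +
                            B5 * k5[i] + B6 * k6[i]);
    deriv(t + h, ynew, k7, p0, fold, t_start, duration);

    double err = 0.0;
    for (int i = 0; i < NS; ++i) {
      double e = h * (E1 * k1[i] + E3 * k3[i] + E4 * k4[i] + E5 * k5[i] +
                      E6 * k6[i] + E7 * k7[i]);
      double sc = abs_tol +
                  rel_tol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = e / sc;
      err += r * r;
    }
    err = std::sqrt(err / NS);

    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < NS; ++i) {
        y[i] = ynew[i];
        k1[i] = k7[i];  // FSAL
        if (y[i] < neg_floor) return 1;
      }
      while (iout < n_out && t_out[iout] <= t + 1e-10) {
        for (int i = 0; i < NS; ++i) out[iout * NS + i] = y[i];
        ++iout;
      }
    }
    double fac = err > 0.0 ? 0.9 * std::pow(err, -0.2) : 5.0;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < 1e-12) return 2;
  }
  return 0;
}

static void check_status(int status) {
  if (status == 1)
    stop("integration error: a species concentration became negative "
         "beyond tolerance");
  if (status == 2) stop("integration error: step size underflow");
  if (status == 3) stop("integration error: step budget exhausted");
}

// [[Rcpp::export]]
NumericMatrix ode_simulate_cpp(NumericVector y0, NumericVector params,
                               NumericVector fold, double t_start,
                               double duration, NumericVector t_out,
                               double rel_tol, double abs_tol) {
  if (y0.size() != NS) stop("state vector must have %d components", NS);
  if (params.size() != NP || fold.size() != NP)
    stop("parameter and fold vectors must have %d components", NP);
  const int n = t_out.size();
  if (n < 1) stop("empty output time grid");
  for (int j = 0; j < n; ++j) {
    if (t_out[j] < 0) stop("output times must be >= 0");
    if (j > 0 && t_out[j] <= t_out[j - 1])
      stop("output times must be strictly increasing");
  }
  std::vector<double> buf(static_cast<size_t>(n) * NS);
  int status = integrate_path(REAL(y0), REAL(params), REAL(fold), t_start,
                              duration, REAL(t_out), n, rel_tol, abs_tol,
                              buf.data());
  check_status(status);
  NumericMatrix out(n, NS);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < NS; ++i)
      out(j, i) = buf[j * NS + i] < 0.0 ? 0.0 : buf[j * NS + i];  // clip for reporting
  return out;
}

// Batch SSR of simulated total 4E-BP (% of its initial value) against pooled
// observations, one value per row of `folds`. obs_idx is a 0-based index
// into t_uniq for each observation.
// [[Rcpp::export]]
NumericVector grid_ssr_cpp(NumericVector y0, NumericVector params,
                           NumericMatrix folds, NumericVector durations,
                           double t_start, NumericVector t_uniq,
                           IntegerVector obs_idx, NumericVector obs_val,
                           double rel_tol, double abs_tol) {
  if (y0.size() != NS) stop("state vector must have %d components", NS);
  if (params.size() != NP || folds.ncol() != NP)
    stop("parameter/fold dimensions must be %d", NP);
  const int ng = folds.nrow();
  if (durations.size() != ng) stop("durations must match fold rows");
  const int nt = t_uniq.size();
  const int nobs = obs_idx.size();
  if (obs_val.size() != nobs) stop("obs_idx/obs_val length mismatch");
  for (int k = 0; k < nobs; ++k)
    if (obs_idx[k] < 0 || obs_idx[k] >= nt) stop("obs_idx out of range");

  const double tot0 = y0[1] + y0[3];  // initial total 4E-BP
  if (tot0 <= 0) stop("initial total 4E-BP must be positive");
  std::vector<double> buf(static_cast<size_t>(nt) * NS);
  std::vector<double> fold(NP), pred(nt);
  NumericVector ssr(ng);

  for (int g = 0; g < ng; ++g) {
    for (int i = 0; i < NP; ++i) fold[i] = folds(g, i);
    int status = integrate_path(REAL(y0), REAL(params), fold.data(), t_start,
                                durations[g], REAL(t_uniq), nt, rel_tol,
                                abs_tol, buf.data());
    check_status(status);
    for (int j = 0; j < nt; ++j)
      pred[j] = 100.0 * (buf[j * NS + 1] + buf[j * NS + 3]) / tot0;
    double s = 0.0;
    for (int k = 0; k < nobs; ++k) {
      double r = obs_val[k] - pred[obs_idx[k]];
      s += r * r;
    }
    ssr[g] = s;
    if (g % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return ssr;
}
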