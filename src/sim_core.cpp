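#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 integrator for the five-state gastric-emptying /
// glucose-insulin delay system.
//
// States: AcS (mg), AcP (mg), GlS (mmol), GlP (mmol), InP (ug), plus a
// sixth bookkeeping state accumulating the exogenous glucose appearance
// flux (cumulative PGl_ex, mmol) so hexose mass balance can be checked at
// integrator accuracy.
//
// Delays are fixed time lags. PGl_ex(t) replays the gastric glucose
// outflow flux from t - T_lag_SP (zero before the lag has elapsed); since
// the stomach glucose pool depends only on the Z-schedule, that flux is
// evaluated exactly from its piecewise-exponential closed form. The
// insulin signal Is(t) = cInP(t - T_lag_IS) (basal iIs before the lag) is
// served from a history buffer recorded at every integration step with
// linear interpolation; when the lag is shorter than the step the lookup
// falls back to the current stage value.
//
// Parameter vector layout (see .sim_param_vector() on the R side):
//  0 BW, 1 iAcS, 2 iAcP, 3 iGlS, 4 iGlP, 5 iInP, 6 iIs,
//  7 kSP2, 8 kSP3, 9 kAcUAc, 10 kGlUGl, 11 kIsUGl, 12 iPGlend,
// 13 TlagSP, 14 TlagIS, 15 VPIn, 16 KGlPIn, 17 expPIn, 18 kInUIn,
// 19 vdAc, 20 vdGlIn

struct ZLookup {
  const double *bp;
  const int *val;
  int n;     // number of intervals (length of val); bp has n + 1 entries
  int cache;
  ZLookup(const NumericVector &breaks, const IntegerVector &codes)
      : bp(breaks.begin()), val(codes.begin()), n(codes.size()), cache(0) {}
  // half-open intervals [bp[i], bp[i+1}); beyond the last breakpoint the
  // last code applies
  int code(double t) {
    if (t >= bp[n]) return val[n - 1];
    if (t < bp[0]) return val[0];
    int i = cache;
    if (i >= n) i = n - 1;
    while (i > 0 && t < bp[i]) --i;
    while (i < n - 1 && t >= bp[i + 1]) ++i;
    cache = i;
    return val[i];
  }
};

struct Hist {
  std::vector<double> v;
  double dt;
  int filled; // highest valid index (values known at i * dt for i <= filled)
  Hist(int n, double dt_) : v(n, 0.0), dt(dt_), filled(0) {}
  // value at time s, falling back to `current` beyond the recorded range
  double at(double s, double current) const {
    double x = s / dt;
    int i = (int)std::floor(x);
    if (i < 0) return v[0];
    if (i >= filled) return current;
    double f = x - i;
    return v[i] * (1.0 - f) + v[i + 1] * f;
  }
};

struct Model {
  double BW, iIs, kSP2, kSP3, kAcUAc, kGlUGl, kIsUGl, iPGlend;
  double TlagSP, TlagIS, VPIn, KGlPIn, expPIn, kInUIn, vdAc, vdGlIn;
  double volGI;
  bool lagOutflux;
  ZLookup *z;
  Hist *hCin;
  // stomach glucose at every schedule breakpoint (chained piecewise
  // exponentials): the lagged outflow flux is evaluated exactly from this
  // closed form, so the transport delay introduces no interpolation error
  std::vector<double> glsBP;

  double ksp(int code) const {
    return code == 0 ? 0.0 : (code == 1 ? kSP2 : kSP3);
  }

  double hill(double cGl) const {
    if (cGl <= 0.0) return 0.0;
    return VPIn / (1.0 + std::pow(KGlPIn / cGl, expPIn));
  }

  void init_gls_breakpoints(double iGlS) {
    int n = z->n;
    glsBP.assign(n + 1, iGlS);
    for (int i = 0; i < n; ++i)
      glsBP[i + 1] =
          glsBP[i] * std::exp(-ksp(z->val[i]) * (z->bp[i + 1] - z->bp[i]));
  }

  // closed-form Gl_S on the branch of interval i (extends smoothly past
  // the interval edges, giving the one-sided limit a Runge-Kutta stage
  // sitting exactly on a switch boundary needs)
  double gls_branch(int i, double s) const {
    return glsBP[i] * std::exp(-ksp(z->val[i]) * (s - z->bp[i]));
  }

  int interval_of(double s) const {
    int n = z->n;
    if (s >= z->bp[n]) return n - 1;
    if (s <= z->bp[0]) return 0;
    int lo = 0, hi = n;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (z->bp[mid] <= s) lo = mid; else hi = mid;
    }
    return lo;
  }

  // exogenous glucose appearance at stage time t: the outflow flux one
  // lag earlier, with the analytic branch selected at the *step midpoint*
  // (tmid) so that every stage of a step stays on one smooth branch and
  // switch times land exactly on step boundaries
  double pglex(double t, double tmid) const {
    double s = t - TlagSP, smid = tmid - TlagSP;
    if (smid < 0.0 || s < 0.0) return 0.0;
    int i = interval_of(smid);
    if (lagOutflux)
      return ksp(z->val[i]) * gls_branch(i, s);
    // alternative convention: current-time rate, lagged stomach mass
    return step_k * gls_branch(i, s);
  }

  // emptying rate for the current integration step; one lookup per step at
  // the step midpoint so a breakpoint coinciding with a step boundary
  // never mixes the two intervals' rates within one RK4 step (keeps the
  // numeric solution on the analytic piecewise trajectory)
  double step_k;

  // dy for state y at time t (tmid = midpoint of the current step);
  // stage-local values supply the fallback for sub-step lags
  void deriv(double t, double tmid, const double *y, double *dy) {
    double k = step_k;
    double cGl = y[3] / volGI;
    double cIn = y[4] / volGI;

    dy[0] = -k * y[0];
    dy[1] = k * y[0] - kAcUAc * y[1];
    dy[2] = -k * y[2];

    double pg = pglex(t, tmid);

    double sIS = t - TlagIS;
    double Is = (sIS < 0.0) ? iIs : hCin->at(sIS, cIn);

    double UGl = kGlUGl * cGl + kIsUGl * Is * cGl;
    dy[3] = pg + iPGlend - UGl;
    dy[4] = hill(cGl) - kInUIn * cIn;
    dy[5] = pg;
  }
};

// [[Rcpp::export(name = ".sim_core_cpp")]]
List sim_core_cpp(NumericVector par, NumericVector z_breaks,
                  IntegerVector z_codes, double horizon, double dt,
                  double report_every, bool lag_outflux) {
  if (dt <= 0) stop("dt must be > 0");
  if (horizon < 0) stop("horizon must be >= 0");
  int nsteps = (int)std::llround(horizon / dt);
  if (std::fabs(nsteps * dt - horizon) > 1e-9 * std::max(1.0, horizon))
    nsteps = (int)std::ceil(horizon / dt - 1e-12);
  int stride = std::max(1, (int)std::llround(report_every / dt));

  ZLookup z(z_breaks, z_codes);
  Hist hCin(nsteps + 1, dt);

  Model m;
  m.BW = par[0];
  m.iIs = par[6];
  m.kSP2 = par[7];
  m.kSP3 = par[8];
  m.kAcUAc = par[9];
  m.kGlUGl = par[10];
  m.kIsUGl = par[11];
  m.iPGlend = par[12];
  m.TlagSP = par[13];
  m.TlagIS = par[14];
  m.VPIn = par[15];
  m.KGlPIn = par[16];
  m.expPIn = par[17];
  m.kInUIn = par[18];
  m.vdAc = par[19];
  m.vdGlIn = par[20];
  m.volGI = m.vdGlIn * m.BW;
  m.lagOutflux = lag_outflux;
  m.z = &z;
  m.hCin = &hCin;
  m.init_gls_breakpoints(par[3]);

  double y[6] = {par[1], par[2], par[3], par[4], par[5], 0.0};

  int nrep = nsteps / stride + 1;
  NumericMatrix out(nrep, 15);
  int status = 0;
  double fail_t = NA_REAL;

  auto record_hist = [&](int i) {
    hCin.v[i] = y[4] / m.volGI;
    hCin.filled = i;
  };

  auto report = [&](int row, double t) {
    m.step_k = m.ksp(z.code(t));
    double cAc = y[1] / (m.vdAc * m.BW);
    double cGl = y[3] / m.volGI;
    double cIn = y[4] / m.volGI;
    double sIS = t - m.TlagIS;
    double Is = (sIS < 0.0) ? m.iIs : hCin.at(sIS, cIn);
    double pglex = m.pglex(t, t);
    out(row, 0) = t;
    out(row, 1) = y[0];
    out(row, 2) = y[1];
    out(row, 3) = y[2];
    out(row, 4) = y[3];
    out(row, 5) = y[4];
    out(row, 6) = cAc;
    out(row, 7) = cGl;
    out(row, 8) = cIn;
    out(row, 9) = pglex;
    out(row, 10) = m.kGlUGl * cGl + m.kIsUGl * Is * cGl;
    out(row, 11) = m.hill(cGl);
    out(row, 12) = m.kInUIn * cIn;
    out(row, 13) = Is;
    out(row, 14) = y[5];
  };

  record_hist(0);
  report(0, 0.0);
  int row = 1;

  double k1[6], k2[6], k3[6], k4[6], ytmp[6];
  for (int n = 0; n < nsteps; ++n) {
    double t = n * dt;
    double tmid = t + 0.5 * dt;
    m.step_k = m.ksp(z.code(tmid));
    m.deriv(t, tmid, y, k1);
    for (int j = 0; j < 6; ++j) ytmp[j] = y[j] + 0.5 * dt * k1[j];
    m.deriv(tmid, tmid, ytmp, k2);
    for (int j = 0; j < 6; ++j) ytmp[j] = y[j] + 0.5 * dt * k2[j];
    m.deriv(tmid, tmid, ytmp, k3);
    for (int j = 0; j < 6; ++j) ytmp[j] = y[j] + dt * k3[j];
    m.deriv(t + dt, tmid, ytmp, k4);
    for (int j = 0; j < 6; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);

    bool bad = false;
    for (int j = 0; j < 6; ++j)
      if (!std::isfinite(y[j])) bad = true;
    // masses must stay non-negative; tolerate only roundoff-scale dips
    if (y[0] < -1e-9 || y[1] < -1e-9 || y[2] < -1e-9 || y[3] < -1e-9 ||
        y[4] < -1e-9)
      bad = true;
    if (bad) {
      status = 1;
      fail_t = t + dt;
      break;
    }

    record_hist(n + 1);
    if ((n + 1) % stride == 0) report(row++, (n + 1) * dt);
  }

  if (status == 1 && row < nrep) {
    NumericMatrix trimmed(row, 15);
    for (int i = 0; i < row; ++i)
      for (int j = 0; j < 15; ++j) trimmed(i, j) = out(i, j);
    out = trimmed;
  }

  return List::create(_["mat"] = out, _["status"] = status,
                      _["fail_time"] = fail_t);
}
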