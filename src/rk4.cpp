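#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Double-exponential LTP transient (normalised so the bump peaks at C + A).
static inline double anorm(double tau1, double tau2) {
  double r = tau2 / tau1;
  return std::pow(r, tau1 / (tau1 - tau2)) - std::pow(r, tau2 / (tau1 - tau2));
}

static inline double pulse(double t, double C, double A,
                           double tau2, double tau1, double an) {
  if (t < 0.0 || A == 0.0) return C;
  return C + A * (std::exp(-t / tau2) - std::exp(-t / tau1)) / an;
}

static inline double sphere_area(double V) {
  // A = (36 pi)^(1/3) V^(2/3) for a sphere of volume V
  return std::cbrt(36.0 * M_PI) * std::cbrt(V * V);
}

struct SpineModel {
  // trafficking
  double kExo0, SExo0, kIn, kOut, kEndo, kBU, kUB0, P, VSpine0;
  // protocol flags
  bool ltp, noexo, coop, sltp;
  // pulses (exocytosis event rate, binding rate)
  double AExo, tExo1, tExo2, anExo;
  double AUB, tUB1, tUB2, anUB;
  // mean-field cooperativity coefficients evaluated at this P
  double mP, lambdaP, betaP;
  // sLTP
  double dVLong, tauS1, tauS2, anS, tauL1, tauL2, anL, shortAmp;
  double kInRE, kOutRE;
  bool instArea;

  double vspine(double t) const {
    if (!(sltp && ltp)) return VSpine0;
    double s = pulse(t, 1.0, 1.0 + shortAmp * dVLong, tauS2, tauS1, anS);
    double l = pulse(t, 0.0, dVLong, tauL2, tauL1, anL);
    return VSpine0 * (s + l);
  }

  void rhs(double t, const double *y, double *dy) const {
    double U = y[0] > 0.0 ? y[0] : 0.0;
    double B = y[1] > 0.0 ? y[1] : 0.0;
    double S = y[2] > 0.0 ? y[2] : 0.0;
    double V = vspine(t);
    double A = instArea ? sphere_area(V) : sphere_area(VSpine0);
    double ke = noexo ? 0.0
      : kExo0 * (ltp ? pulse(t, 1.0, AExo, tExo2, tExo1, anExo) : 1.0);
    double kub = kUB0 * (ltp ? pulse(t, 1.0, AUB, tUB2, tUB1, anUB) : 1.0);
    double gU = 1.0, gB = 1.0;
    if (coop) {
      gU = mP * std::pow(B, 0.8) + 1.0;
      gB = lambdaP / (betaP + B - 0.5);
    }
    double bind = kub * gU * (P - B) * U / A;
    double unbind = kBU * gB * B;
    dy[0] = ke * S + kIn + unbind - (kEndo + kOut) * U / A - bind;
    dy[1] = bind - unbind;
    dy[2] = sltp ? (kInRE - kOutRE * S / V) : 0.0;
  }
};

static SpineModel build_model(const List &pars) {
  SpineModel m;
  m.kExo0 = pars["kExo0"]; m.SExo0 = pars["SExo0"];
  m.kIn = pars["kIn"]; m.kOut = pars["kOut"]; m.kEndo = pars["kEndo"];
  m.kBU = pars["kBU"]; m.kUB0 = pars["kUB0"];
  m.P = pars["P"]; m.VSpine0 = pars["VSpine0"];
  m.ltp = pars["ltp"]; m.noexo = pars["noexo"];
  m.coop = pars["coop"]; m.sltp = pars["sltp"];
  m.AExo = pars["AExo"]; m.tExo1 = pars["tExo1"]; m.tExo2 = pars["tExo2"];
  m.AUB = pars["AUB"]; m.tUB1 = pars["tUB1"]; m.tUB2 = pars["tUB2"];
  m.anExo = anorm(m.tExo1, m.tExo2);
  m.anUB = anorm(m.tUB1, m.tUB2);
  m.mP = pars["mP"]; m.lambdaP = pars["lambdaP"]; m.betaP = pars["betaP"];
  m.dVLong = pars["dVLong"];
  m.tauS1 = pars["tauS1"]; m.tauS2 = pars["tauS2"];
  m.tauL1 = pars["tauL1"]; m.tauL2 = pars["tauL2"];
  m.anS = anorm(m.tauS1, m.tauS2);
  m.anL = anorm(m.tauL1, m.tauL2);
  m.shortAmp = pars["shortAmp"];
  m.kInRE = pars["kInRE"]; m.kOutRE = pars["kOutRE"];
  m.instArea = pars["instArea"];
  return m;
}

// [[Rcpp::export(name = ".rk4_spine")]]
List rk4_spine(List pars, NumericVector y0, double tEnd, double dt,
               double outDt) {
  SpineModel m = build_model(pars);
  const int n = (int)std::lround(tEnd / dt);
  const int keep = std::max(1, (int)std::lround(outDt / dt));
  const int nout = n / keep + 1;
  NumericMatrix out(nout, 6);
  double y[3] = { y0[0], y0[1], y0[2] };
  double k1[3], k2[3], k3[3], k4[3], yt[3];
  int clips = 0, j = 0;

  auto record = [&](int row, double t) {
    double V = m.vspine(t);
    out(row, 0) = t; out(row, 1) = y[0]; out(row, 2) = y[1];
    out(row, 3) = V; out(row, 4) = y[2];
    out(row, 5) = m.instArea ? sphere_area(V) : sphere_area(m.VSpine0);
  };
  record(j++, 0.0);

  for (int i = 0; i < n; i++) {
    double t = i * dt;
    m.rhs(t, y, k1);
    for (int s = 0; s < 3; s++) yt[s] = y[s] + 0.5 * dt * k1[s];
    m.rhs(t + 0.5 * dt, yt, k2);
    for (int s = 0; s < 3; s++) yt[s] = y[s] + 0.5 * dt * k2[s];
    m.rhs(t + 0.5 * dt, yt, k3);
    for (int s = 0; s < 3; s++) yt[s] = y[s] + dt * k3[s];
    m.rhs(t + dt, yt, k4);
    for (int s = 0; s < 3; s++) {
      y[s] += dt / 6.0 * (k1[s] + 2.0 * k2[s] + 2.0 * k3[s] + k4[s]);
      if (y[s] < 0.0) { y[s] = 0.0; clips++; }
      if (!std::isfinite(y[s]))
        stop("integration failure (non-finite state) at step %d (t = %g s)",
             i + 1, t + dt);
    }
    if ((i + 1) % keep == 0) record(j++, (i + 1) * dt);
  }
  colnames(out) = CharacterVector::create("t", "U", "B", "VSpine", "SExo",
                                          "ASpine");
  return List::create(_["trajectory"] = out, _["nClipped"] = clips);
}
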