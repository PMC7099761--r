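// NPZD water-column integrator: explicit biological step with demand capping,
// implicit vertical diffusion (flux-form tridiagonal), upwind sinking,
// deep-reservoir restoring and surface boundary sources. Nitrogen currency with
// a parallel phosphorus ledger per organic pool so variable uptake
// stoichiometry stays mass-conservative.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// state column layout (per layer)
enum {
  iP1 = 0, iP2, iP3,      // phytoplankton N (diatom, flagellate, cyanobacteria)
  iQ1, iQ2, iQ3,          // phytoplankton internal P
  iZN, iZP,               // zooplankton N, P
  iDN, iDP,               // detritus N, P
  iNO3, iNH4, iPO4,
  NSTATE
};

struct Pars {
  int mode;                       // 0 = redfield, 1 = lof
  double pToN, lofSlope, lofIntercept, nToC;
  double muMax[3], alpha[3], ih[3], wsink[3], mort[3];
  int fixes[3];
  int fixationOn;
  double gmax, kg, beta, zExcr, zMortQ;
  double rdn, rdp, nitrif;
  double q10, tref;
  double kw, kchl, chlToN;
  double wdet;
  double kzHigh, kzBg, restoreDepth, restoreTau, deepNO3, deepPO4;
  double boundNO3, boundPO4;
  double tempDeep, thermoclineScale;
};

static Pars unpack(const List& p) {
  Pars P;
  P.mode = as<int>(p["mode"]);
  P.pToN = as<double>(p["pToN"]);
  P.lofSlope = as<double>(p["lofSlope"]);
  P.lofIntercept = as<double>(p["lofIntercept"]);
  P.nToC = as<double>(p["nToC"]);
  NumericVector mu = p["muMax"], al = p["alpha"], ih = p["ih"],
                ws = p["wsink"], mo = p["mort"];
  IntegerVector fx = p["fixes"];
  for (int i = 0; i < 3; ++i) {
    P.muMax[i] = mu[i]; P.alpha[i] = al[i]; P.ih[i] = ih[i];
    P.wsink[i] = ws[i]; P.mort[i] = mo[i]; P.fixes[i] = fx[i];
  }
  P.fixationOn = as<int>(p["fixationOn"]);
  P.gmax = as<double>(p["gmax"]); P.kg = as<double>(p["kg"]);
  P.beta = as<double>(p["beta"]); P.zExcr = as<double>(p["zExcr"]);
  P.zMortQ = as<double>(p["zMortQ"]);
  P.rdn = as<double>(p["rdn"]); P.rdp = as<double>(p["rdp"]);
  P.nitrif = as<double>(p["nitrif"]);
  P.q10 = as<double>(p["q10"]); P.tref = as<double>(p["tref"]);
  P.kw = as<double>(p["kw"]); P.kchl = as<double>(p["kchl"]);
  P.chlToN = as<double>(p["chlToN"]);
  P.wdet = as<double>(p["wdet"]);
  P.kzHigh = as<double>(p["kzHigh"]); P.kzBg = as<double>(p["kzBg"]);
  P.restoreDepth = as<double>(p["restoreDepth"]);
  P.restoreTau = as<double>(p["restoreTau"]);
  P.deepNO3 = as<double>(p["deepNO3"]); P.deepPO4 = as<double>(p["deepPO4"]);
  P.boundNO3 = as<double>(p["boundNO3"]); P.boundPO4 = as<double>(p["boundPO4"]);
  P.tempDeep = as<double>(p["tempDeep"]);
  P.thermoclineScale = as<double>(p["thermoclineScale"]);
  return P;
}

// linear interpolation of a daily-sampled series at time t (days)
static inline double interp(const NumericVector& v, double t) {
  int n = v.size();
  if (t <= 0.0) return v[0];
  if (t >= n - 1.0) return v[n - 1];
  int i = (int)std::floor(t);
  double f = t - i;
  return v[i] * (1.0 - f) + v[i + 1] * f;
}

static inline double irfr_of(const Pars& P, double po4) {
  return P.mode == 0 ? P.pToN : (P.lofSlope * po4 + P.lofIntercept) / P.nToC;
}

struct BioFlux {
  double g[3], fix, upNH4, upNO3, upP;
  double grazN[3], grazP[3], morN[3], morP[3];
  double zExN, zExP, zMoN, zMoP, remN, remP, nit, irfr;
  int nCaps;
};

// One-layer biological fluxes over an interval dt (amounts, mmol m^-3).
// All sinks of every pool are demand-capped so no pool can go negative.
static BioFlux bio_layer(const double* s, double I, double T, double dt,
                         const Pars& P) {
  BioFlux F;
  F.nCaps = 0;
  const double fT = std::pow(P.q10, (T - P.tref) / 10.0);
  const double no3 = s[iNO3], nh4 = s[iNH4], po4 = s[iPO4];
  const double D = no3 + nh4;
  const double irfr = irfr_of(P, po4);
  F.irfr = irfr;

  // growth demands
  bool ledger[3];
  double gsum = 0.0, gDIN = 0.0;
  for (int i = 0; i < 3; ++i) {
    double nl = D * D / (P.alpha[i] * P.alpha[i] + D * D);
    double ha = irfr * P.alpha[i];
    double pl = po4 * po4 / (ha * ha + po4 * po4);
    double ll = I / (I + P.ih[i]);
    bool fixNow = P.fixes[i] && P.fixationOn && nl < std::min(pl, ll);
    double lim = fixNow ? std::min(pl, ll) : std::min(nl, std::min(pl, ll));
    F.g[i] = P.muMax[i] * fT * lim * s[iP1 + i] * dt;
    ledger[i] = fixNow;
    gsum += F.g[i];
    if (!fixNow) gDIN += F.g[i];
  }
  // cap by available phosphate (uniform) and DIN (DIN consumers only)
  double pDem = irfr * gsum;
  double sP = (pDem > po4 && pDem > 0.0) ? po4 / pDem : 1.0;
  double sN = (gDIN > D && gDIN > 0.0) ? D / gDIN : 1.0;
  if (sP < 1.0 || sN < 1.0) F.nCaps++;
  double upDIN = 0.0, upP = 0.0;
  F.fix = 0.0;
  for (int i = 0; i < 3; ++i) {
    double sc = ledger[i] ? sP : std::min(sP, sN);
    F.g[i] *= sc;
    upP += F.g[i] * irfr;
    if (ledger[i]) F.fix += F.g[i]; else upDIN += F.g[i];
  }
  F.upP = upP;
  F.upNH4 = std::min(nh4, upDIN);       // ammonium preference
  F.upNO3 = upDIN - F.upNH4;

  // grazing: Holling III on total phytoplankton N, prey-proportional
  double PT = s[iP1] + s[iP2] + s[iP3];
  double G = 0.0;
  if (PT > 0.0 && s[iZN] > 0.0) {
    G = P.gmax * fT * PT * PT / (P.kg * P.kg + PT * PT) * s[iZN] * dt;
    if (G > PT) { G = PT; F.nCaps++; }
  }
  // per-PFT phytoplankton sinks: grazing share + mortality, jointly capped
  for (int i = 0; i < 3; ++i) {
    double p = s[iP1 + i];
    double gr = (PT > 0.0) ? G * p / PT : 0.0;
    double mo = P.mort[i] * p * dt;
    double sink = gr + mo;
    if (sink > p && sink > 0.0) {
      double sc = p / sink; gr *= sc; mo *= sc; F.nCaps++;
    }
    double ratio = (p > 0.0) ? s[iQ1 + i] / p : 0.0;
    F.grazN[i] = gr; F.grazP[i] = gr * ratio;
    F.morN[i] = mo;  F.morP[i] = mo * ratio;
  }

  // zooplankton: linear excretion to NH4/PO4, quadratic mortality to detritus
  {
    double zn = s[iZN], zp = s[iZP];
    double ex = P.zExcr * fT * zn * dt;
    double mo = P.zMortQ * zn * zn * dt;
    double sink = ex + mo;
    if (sink > zn && sink > 0.0) {
      double sc = zn / sink; ex *= sc; mo *= sc; F.nCaps++;
    }
    double ratio = (zn > 0.0) ? zp / zn : 0.0;
    F.zExN = ex; F.zExP = ex * ratio;
    F.zMoN = mo; F.zMoP = mo * ratio;
  }

  // detritus remineralization (separate first-order N and P rates);
  // nitrification acts on the ammonium left after uptake (uptake priority)
  F.remN = std::min(s[iDN], P.rdn * fT * s[iDN] * dt);
  F.remP = std::min(s[iDP], P.rdp * fT * s[iDP] * dt);
  F.nit = std::min(nh4 - F.upNH4, P.nitrif * fT * (nh4 - F.upNH4) * dt);
  return F;
}

static inline void apply_bio(double* s, const BioFlux& F, double beta) {
  double sGrN = 0, sGrP = 0, sMoN = 0, sMoP = 0;
  for (int i = 0; i < 3; ++i) {
    s[iP1 + i] += F.g[i] - F.grazN[i] - F.morN[i];
    s[iQ1 + i] += F.g[i] * F.irfr - F.grazP[i] - F.morP[i];
    sGrN += F.grazN[i]; sGrP += F.grazP[i];
    sMoN += F.morN[i];  sMoP += F.morP[i];
  }
  s[iZN] += beta * sGrN - F.zExN - F.zMoN;
  s[iZP] += beta * sGrP - F.zExP - F.zMoP;
  s[iDN] += (1.0 - beta) * sGrN + sMoN + F.zMoN - F.remN;
  s[iDP] += (1.0 - beta) * sGrP + sMoP + F.zMoP - F.remP;
  s[iNO3] += F.nit - F.upNO3;
  s[iNH4] += F.remN + F.zExN - F.upNH4 - F.nit;
  s[iPO4] += F.remP + F.zExP - F.upP;
  // absorb sub-roundoff negatives from exact demand capping
  for (int k = 0; k < NSTATE; ++k)
    if (s[k] < 0.0 && s[k] > -1e-10) s[k] = 0.0;
}

// light and temperature profiles at one time
static void profiles(const NumericVector& h, double par0, double sst,
                     double mld, const double* chl, const Pars& P,
                     std::vector<double>& I, std::vector<double>& T) {
  int n = h.size();
  double atten = 0.0, z = 0.0;
  for (int j = 0; j < n; ++j) {
    double k = P.kw + P.kchl * chl[j];
    I[j] = par0 * std::exp(-(atten + k * h[j] / 2.0));
    atten += k * h[j];
    double zc = z + h[j] / 2.0;
    T[j] = (zc <= mld)
      ? sst
      : P.tempDeep + (sst - P.tempDeep) * std::exp(-(zc - mld) / P.thermoclineScale);
    z += h[j];
  }
}

// Thomas solve of (I - dt*Adiff) x = rhs, flux-form => exactly conservative
static void diffuse(std::vector<double>& x, const std::vector<double>& a,
                    const std::vector<double>& b, const std::vector<double>& c,
                    std::vector<double>& cp, std::vector<double>& dp) {
  int n = x.size();
  cp[0] = c[0] / b[0];
  dp[0] = x[0] / b[0];
  for (int j = 1; j < n; ++j) {
    double m = b[j] - a[j] * cp[j - 1];
    cp[j] = c[j] / m;
    dp[j] = (x[j] - a[j] * dp[j - 1]) / m;
  }
  x[n - 1] = dp[n - 1];
  for (int j = n - 2; j >= 0; --j) x[j] = dp[j] - cp[j] * x[j + 1];
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix init, NumericVector h, bool column,
             double dt, int nsteps, int saveEvery,
             NumericVector mldF, NumericVector parF, NumericVector sstF,
             List pars) {
  const Pars P = unpack(pars);
  const int n = init.nrow();
  if (init.ncol() != NSTATE) stop("state matrix must have %d columns", NSTATE);
  // working state, row-major per layer
  std::vector<double> S(n * NSTATE);
  for (int j = 0; j < n; ++j)
    for (int k = 0; k < NSTATE; ++k) S[j * NSTATE + k] = init(j, k);

  // geometry
  std::vector<double> zc(n), ze(n + 1, 0.0);
  for (int j = 0; j < n; ++j) { ze[j + 1] = ze[j] + h[j]; zc[j] = ze[j] + h[j] / 2.0; }

  // CFL for upwind sinking
  double wmax = P.wdet;
  for (int i = 0; i < 3; ++i) wmax = std::max(wmax, P.wsink[i]);
  for (int j = 0; j < n; ++j)
    if (column && wmax * dt > h[j])
      stop("sinking CFL violated: w*dt = %g m exceeds layer thickness %g m",
           wmax * dt, (double)h[j]);

  const int nsave = nsteps / saveEvery;
  List out(NSTATE + 1);
  std::vector<NumericMatrix> saved;
  for (int k = 0; k < NSTATE + 1; ++k) saved.push_back(NumericMatrix(n, nsave));
  NumericVector times(nsave);
  NumericMatrix ledg(nsave, 5); // fixedN, boundN, boundP, restN, restP (mmol m^-2, cumulative)
  double ledFix = 0, ledBN = 0, ledBP = 0, ledRN = 0, ledRP = 0;
  long nCaps = 0;

  std::vector<double> I(n), T(n), chl(n);
  std::vector<double> a(n), b(n), c(n), cp(n), dp(n), x(n);

  for (int s = 1; s <= nsteps; ++s) {
    double t = (s - 1) * dt;
    double mld = interp(mldF, t), par0 = interp(parF, t), sst = interp(sstF, t);

    for (int j = 0; j < n; ++j)
      chl[j] = P.chlToN * (S[j * NSTATE + iP1] + S[j * NSTATE + iP2] + S[j * NSTATE + iP3]);
    profiles(h, par0, sst, mld, chl.data(), P, I, T);

    // biology (explicit, capped)
    for (int j = 0; j < n; ++j) {
      double* sj = &S[j * NSTATE];
      BioFlux F = bio_layer(sj, I[j], T[j], dt, P);
      apply_bio(sj, F, P.beta);
      ledFix += F.fix * h[j];
      nCaps += F.nCaps;
    }

    if (column && n > 1) {
      // upwind sinking (no export through the sea floor)
      for (int tr = 0; tr < 2 + 6; ++tr) {
        int k; double w;
        if (tr < 6) { k = tr; w = P.wsink[tr % 3]; }       // iP1..iQ3
        else if (tr == 6) { k = iDN; w = P.wdet; }
        else { k = iDP; w = P.wdet; }
        if (w <= 0.0) continue;
        for (int j = n - 2; j >= 0; --j) {
          double amt = w * dt * S[j * NSTATE + k];          // mmol m^-2
          S[j * NSTATE + k] -= amt / h[j];
          S[(j + 1) * NSTATE + k] += amt / h[j + 1];
        }
      }
      // implicit diffusion, kz from mixed-layer depth at interfaces
      for (int j = 0; j < n; ++j) { a[j] = 0; c[j] = 0; b[j] = 1; }
      for (int j = 0; j < n - 1; ++j) {
        double kz = (ze[j + 1] < mld) ? P.kzHigh : P.kzBg;
        double dzc = zc[j + 1] - zc[j];
        double fl = dt * kz / dzc;
        c[j] -= fl / h[j];
        a[j + 1] -= fl / h[j + 1];
        b[j] += fl / h[j];
        b[j + 1] += fl / h[j + 1];
      }
      for (int k = 0; k < NSTATE; ++k) {
        for (int j = 0; j < n; ++j) x[j] = S[j * NSTATE + k];
        diffuse(x, a, b, c, cp, dp);
        for (int j = 0; j < n; ++j) S[j * NSTATE + k] = x[j];
      }
      // deep-reservoir restoring (nutrients only)
      if (P.restoreTau > 0.0) {
        for (int j = 0; j < n; ++j) {
          if (zc[j] < P.restoreDepth) continue;
          double dn3 = dt * (P.deepNO3 - S[j * NSTATE + iNO3]) / P.restoreTau;
          double dp4 = dt * (P.deepPO4 - S[j * NSTATE + iPO4]) / P.restoreTau;
          S[j * NSTATE + iNO3] += dn3;
          S[j * NSTATE + iPO4] += dp4;
          ledRN += dn3 * h[j];
          ledRP += dp4 * h[j];
        }
      }
      // surface boundary source (river-like)
      if (P.boundNO3 > 0.0 || P.boundPO4 > 0.0) {
        S[iNO3] += dt * P.boundNO3 / h[0];
        S[iPO4] += dt * P.boundPO4 / h[0];
        ledBN += dt * P.boundNO3;
        ledBP += dt * P.boundPO4;
      }
    }

    if (s % saveEvery == 0) {
      int m = s / saveEvery - 1;
      times[m] = s * dt;
      for (int j = 0; j < n; ++j) {
        for (int k = 0; k < NSTATE; ++k) {
          double v = S[j * NSTATE + k];
          if (!R_finite(v))
            stop("non-finite state (field %d, layer %d) at step %d (t = %g d)",
                 k + 1, j + 1, s, s * dt);
          saved[k](j, m) = v;
        }
        saved[NSTATE](j, m) =
          P.chlToN * (S[j * NSTATE + iP1] + S[j * NSTATE + iP2] + S[j * NSTATE + iP3]);
      }
      ledg(m, 0) = ledFix; ledg(m, 1) = ledBN; ledg(m, 2) = ledBP;
      ledg(m, 3) = ledRN; ledg(m, 4) = ledRP;
    }
  }

  NumericMatrix fin(n, NSTATE);
  for (int j = 0; j < n; ++j)
    for (int k = 0; k < NSTATE; ++k) fin(j, k) = S[j * NSTATE + k];

  for (int k = 0; k < NSTATE + 1; ++k) out[k] = saved[k];
  return List::create(_["fields"] = out, _["times"] = times,
                      _["ledgers"] = ledg, _["final"] = fin,
                      _["nCaps"] = (double)nCaps);
}

// Single biological step with full flux accounting, for process-level tests.
// [[Rcpp::export]]
List cpp_bio_fluxes(NumericMatrix state, NumericVector light,
                    NumericVector temp, double dt, List pars) {
  const Pars P = unpack(pars);
  int n = state.nrow();
  if (state.ncol() != NSTATE) stop("state matrix must have %d columns", NSTATE);
  NumericMatrix out(clone(state));
  NumericMatrix growth(n, 3), grazN(n, 3), grazP(n, 3), morN(n, 3), morP(n, 3);
  NumericVector fix(n), upNH4(n), upNO3(n), upP(n), zExN(n), zExP(n),
                zMoN(n), zMoP(n), remN(n), remP(n), nit(n), irfr(n);
  for (int j = 0; j < n; ++j) {
    std::vector<double> s(NSTATE);
    for (int k = 0; k < NSTATE; ++k) s[k] = state(j, k);
    BioFlux F = bio_layer(s.data(), light[j], temp[j], dt, P);
    apply_bio(s.data(), F, P.beta);
    for (int k = 0; k < NSTATE; ++k) out(j, k) = s[k];
    for (int i = 0; i < 3; ++i) {
      growth(j, i) = F.g[i]; grazN(j, i) = F.grazN[i]; grazP(j, i) = F.grazP[i];
      morN(j, i) = F.morN[i]; morP(j, i) = F.morP[i];
    }
    fix[j] = F.fix; upNH4[j] = F.upNH4; upNO3[j] = F.upNO3; upP[j] = F.upP;
    zExN[j] = F.zExN; zExP[j] = F.zExP; zMoN[j] = F.zMoN; zMoP[j] = F.zMoP;
    remN[j] = F.remN; remP[j] = F.remP; nit[j] = F.nit; irfr[j] = F.irfr;
  }
  return List::create(
    _["state"] = out, _["growth"] = growth, _["fixation"] = fix,
    _["uptakeNH4"] = upNH4, _["uptakeNO3"] = upNO3, _["uptakeP"] = upP,
    _["grazingN"] = grazN, _["grazingP"] = grazP,
    _["mortalityN"] = morN, _["mortalityP"] = morP,
    _["zooExcretionN"] = zExN, _["zooExcretionP"] = zExP,
    _["zooMortalityN"] = zMoN, _["zooMortalityP"] = zMoP,
    _["reminN"] = remN, _["reminP"] = remP, _["nitrification"] = nit,
    _["iRfr"] = irfr);
}
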