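/* Right-hand side of the 22-state guinea-pig ventricular cell model and of the
 * monodomain fiber assembled from it.
 *
 * Unit system: mV, ms, nA, uS, nF, mM (so uS * mV = nA and nF * mV/ms = nA).
 * Internally rates are evaluated per second (the reference model's native
 * form) and the whole derivative vector is scaled by 1e-3 at the end.
 *
 * State layout per cell (cell-major flattening, 22 doubles per cell):
 *   0 V    1 m    2 h    3 d    4 f    5 f2   6 f2ds 7 s    8 r
 *   9 xr1 10 xr2 11 xs  12 ActFrac 13 ProdFrac
 *  14 Nai 15 Ki  16 Cai 17 Cads 18 Caup 19 Carel 20 CaCalmod 21 CaTrop
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define NSTATE 22

/* gas constant (mJ mol^-1 K^-1) and Faraday constant (C mol^-1) */
static const double RGAS = 8314.472;
static const double FARADAY = 96485.3415;

/* parameter vector layout; must match .paramOrder in R/constants.R */
enum {
  P_GK1, P_GNA, P_KMK1, P_KO, P_CM, P_TEMP, P_NAO, P_CAO,
  P_GKR1, P_GKR2, P_GKS, P_GTO, P_GTOS, P_GPNA, P_GBNA, P_GBCA,
  P_INAKMAX, P_KMK, P_KMNA,
  P_KNACA, P_GAMMA, P_NNACA, P_DNACA, P_FRANACA,
  P_FRICA, P_PCAL, P_PCAK, P_PCANA,
  P_SPEEDD, P_SPEEDF,
  P_KMF2, P_RF2, P_KMF2DS, P_RF2DS,
  P_KMCACYT, P_KMCADS, P_KMREL, P_KLEAK, P_ACTMAX, P_INACTBASE, P_INACTCA,
  P_SRELSLOW, P_VSREL,
  P_AUP, P_BUP, P_KCYCA, P_KXCS, P_KSRCA, P_KTRANS,
  P_RADIUS, P_LENGTH, P_VIRATIO, P_VDSRATIO, P_VRELRATIO, P_VUPRATIO,
  P_KDECAYDS,
  P_ACALMOD, P_BCALMOD, P_CALMODTOT, P_ATROP, P_BTROP, P_TROPTOT,
  P_PKNA, P_NARATIOMH, P_RECTK1,
  NPAR
};

/* exp with clamped argument: stimulus amplitudes probed near the
 * inexcitability cap drive stimulated cells far outside the
 * physiological voltage range; clamping keeps the RHS finite there
 * without affecting any physiological state */
static double sexp(double x)
{
  return exp(x > 330.0 ? 330.0 : (x < -330.0 ? -330.0 : x));
}

/* derivatives of one cell; iext is total external current (nA, inward
 * negative, outward positive: stimulus and/or gap-junction load) entering
 * the membrane-charge balance as Cm dV/dt = -(Iion + iext). */
static void cell_rhs(const double *y, const double *p, double iext,
                     double *dy)
{
  const double V = y[0], m = y[1], h = y[2], d = y[3], f = y[4],
    f2 = y[5], f2ds = y[6], s = y[7], r = y[8], xr1 = y[9], xr2 = y[10],
    xs = y[11], act = y[12], prod = y[13], Nai = y[14], Ki = y[15],
    Cai = y[16], Cads = y[17], Caup = y[18], Carel = y[19],
    CaCalmod = y[20], CaTrop = y[21];

  const double RTF = RGAS * p[P_TEMP] / FARADAY;   /* ~26.71 mV at 310 K */
  const double Ko = p[P_KO], Nao = p[P_NAO], Cao = p[P_CAO];

  /* the two small calcium pools sit close to the solver's absolute
   * tolerance and can be driven through zero by extreme stimuli; a
   * positivity floor inside the rate expressions keeps the RHS away from
   * the poles at Cads = -Km while the decay terms restore positivity */
  const double CaiS = Cai > 1e-12 ? Cai : 1e-12;
  const double CadsS = Cads > 1e-12 ? Cads : 1e-12;

  const double EK  = RTF * log(Ko / Ki);
  const double ENa = RTF * log(Nao / Nai);
  const double ECa = 0.5 * RTF * log(Cao / CaiS);
  const double EKs = RTF * log((Ko + p[P_PKNA] * Nao) /
                               (Ki + p[P_PKNA] * Nai));
  const double Emh = RTF * log((Nao + p[P_NARATIOMH] * Ko) /
                               (Nai + p[P_NARATIOMH] * Ki));

  /* --- membrane currents (nA, outward positive) --- */

  /* inward rectifier: rectification exponent (V - EK - 10)/(RT/kF) */
  const double iK1 = p[P_GK1] * (Ko / (Ko + p[P_KMK1])) * (V - EK) /
    (1.0 + sexp((V - EK - 10.0) * p[P_RECTK1] / RTF));

  /* fast sodium */
  const double iNa = p[P_GNA] * m * m * m * h * (V - Emh);

  /* persistent sodium */
  const double ipNa = p[P_GPNA] / (1.0 + sexp(-(V + 52.0) / 8.0)) * (V - ENa);

  /* rapid and slow delayed rectifiers */
  const double iKr = (p[P_GKR1] * xr1 + p[P_GKR2] * xr2) *
    (V - EK) / (1.0 + sexp((V + 9.0) / 22.4));
  const double iKs = p[P_GKS] * xs * xs * (V - EKs);

  /* transient outward */
  const double ito = p[P_GTO] * (p[P_GTOS] + s * (1.0 - p[P_GTOS])) * r *
    (V - EK);

  /* L-type calcium current, constant-field form, split between bulk
   * cytosol and the diadic subspace by FrICa */
  const double FrICa = p[P_FRICA];
  const double vfac = (V - 50.0) / RTF;
  /* guard the removable singularity at V = 50 mV */
  const double den2 = 1.0 - sexp(-2.0 * vfac);
  const double den1 = 1.0 - sexp(-vfac);
  const double gd2 = (fabs(den2) < 1e-9) ? 0.5 : vfac / den2;
  const double gd1 = (fabs(den1) < 1e-9) ? 1.0 : vfac / den1;

  const double caTermCyt = CaiS * sexp(100.0 / RTF) - Cao * sexp(-2.0 * vfac);
  const double kTerm  = Ki  * sexp(50.0 / RTF) - Ko  * sexp(-vfac);
  const double naTerm = Nai * sexp(50.0 / RTF) - Nao * sexp(-vfac);

  const double dff   = d * f;
  const double PCaL  = p[P_PCAL];
  const double iCaLCaCyt = (1.0 - FrICa) * 4.0 * PCaL * dff * f2 * gd2 *
    caTermCyt;
  const double iCaLCaDs  = FrICa * 4.0 * PCaL * dff * f2ds * gd2 * caTermCyt;
  const double iCaLKCyt  = (1.0 - FrICa) * p[P_PCAK] * PCaL * dff * f2 *
    gd1 * kTerm;
  const double iCaLKDs   = FrICa * p[P_PCAK] * PCaL * dff * f2ds * gd1 * kTerm;
  const double iCaLNaCyt = (1.0 - FrICa) * p[P_PCANA] * PCaL * dff * f2 *
    gd1 * naTerm;
  const double iCaLNaDs  = FrICa * p[P_PCANA] * PCaL * dff * f2ds * gd1 *
    naTerm;

  /* backgrounds */
  const double ibNa = p[P_GBNA] * (V - ENa);
  const double ibCa = p[P_GBCA] * (V - ECa);

  /* Na/K pump */
  const double iNaK = p[P_INAKMAX] * (Ko / (p[P_KMK] + Ko)) *
    (Nai / (p[P_KMNA] + Nai));

  /* Na/Ca exchanger (cytosolic and diadic-space fractions).  The
   * exchanger voltage dependence is clamped at +-427 mV: outside the
   * model's credible voltage range its exponential growth only serves to
   * wreck the implicit solver when near-cap stimulus amplitudes are
   * probed; every physiological state is unaffected. */
  const double Vx = V > 427.0 ? 427.0 : (V < -427.0 ? -427.0 : V);
  const double gamma = p[P_GAMMA], nnaca = p[P_NNACA];
  const double e1 = sexp(gamma * (nnaca - 2.0) * Vx / RTF);
  const double e2 = sexp((gamma - 1.0) * (nnaca - 2.0) * Vx / RTF);
  const double nai_n = pow(Nai, nnaca), nao_n = pow(Nao, nnaca);
  const double iNaCaCyt = (1.0 - p[P_FRANACA]) * p[P_KNACA] *
    (e1 * nai_n * Cao - e2 * nao_n * CaiS) /
    ((1.0 + p[P_DNACA] * (CaiS * nao_n + Cao * nai_n)) *
     (1.0 + CaiS / 0.0069));
  const double iNaCaDs = p[P_FRANACA] * p[P_KNACA] *
    (e1 * nai_n * Cao - e2 * nao_n * CadsS) /
    ((1.0 + p[P_DNACA] * (CadsS * nao_n + Cao * nai_n)) *
     (1.0 + CadsS / 0.0069));

  const double iIon = iK1 + iNa + ipNa + iKr + iKs + ito +
    iCaLCaCyt + iCaLCaDs + iCaLKCyt + iCaLKDs + iCaLNaCyt + iCaLNaDs +
    ibNa + ibCa + iNaK + iNaCaCyt + iNaCaDs;

  /* --- gating kinetics (rates per second) --- */

  double E0, am, bm, ah, bh, ad, bd, af, bf;

  E0 = V + 41.0;
  am = (fabs(E0) < 1e-5) ? 2000.0 : 200.0 * E0 / (1.0 - sexp(-0.1 * E0));
  bm = 8000.0 * sexp(-0.056 * (V + 66.0));
  ah = 20.0 * sexp(-0.125 * (V + 75.0));
  bh = 2000.0 / (1.0 + 320.0 * sexp(-0.1 * (V + 75.0)));

  E0 = V + 19.0;
  ad = (fabs(E0) < 1e-4) ? 360.0 : 90.0 * E0 / (1.0 - sexp(-E0 / 4.0));
  bd = (fabs(E0) < 1e-4) ? 360.0 : 36.0 * E0 / (sexp(E0 / 10.0) - 1.0);

  E0 = V + 34.0;
  af = (fabs(E0) < 1e-4) ? 25.0 : 6.25 * E0 / (sexp(E0 / 4.0) - 1.0);
  bf = 12.0 / (1.0 + sexp(-E0 / 4.0));

  const double as = 0.033 * sexp(-V / 17.0);
  const double bs = 33.0 / (1.0 + sexp(-0.125 * (V + 10.0)));
  const double rinf = 1.0 / (1.0 + sexp(-(V + 4.0) / 5.0));

  const double axr = 50.0 / (1.0 + sexp(-(V - 5.0) / 9.0));
  const double bxr1 = 0.05 * sexp(-(V - 20.0) / 15.0);
  const double t3 = (V + 30.0) / 30.0;
  const double bxr2 = 0.4 * sexp(-t3 * t3 * t3);
  const double axs = 14.0 / (1.0 + sexp(-(V - 40.0) / 9.0));
  const double bxs = sexp(-V / 45.0);

  /* --- sarcoplasmic-reticulum calcium handling (fluxes in mM/s) --- */

  const double caiReg = CaiS / (CaiS + p[P_KMCACYT]);
  const double cadsReg = CadsS / (CadsS + p[P_KMCADS]);
  const double regBind = caiReg + (1.0 - caiReg) * cadsReg;
  const double actRate = p[P_ACTMAX] * regBind * regBind;
  const double inactRate = p[P_INACTBASE] + p[P_INACTCA] * regBind * regBind;
  /* steep logistic blend of the voltage-dependent release speed; a hard
   * switch at V = -50 mV stalls the implicit solver when cells linger
   * at the switch potential (decremental responses near the
   * excitability boundary) */
  const double speedRel = 1.0 + (p[P_SRELSLOW] - 1.0) /
    (1.0 + sexp((V - p[P_VSREL]) / 0.25));
  const double precFrac = 1.0 - act - prod;

  const double frel = act / (act + 0.25);
  const double irel = (frel * frel * p[P_KMREL] + p[P_KLEAK]) * Carel;

  const double K1 = p[P_KCYCA] * p[P_KXCS] / p[P_KSRCA];
  const double K2 = CaiS + Caup * K1 + p[P_KCYCA] * p[P_KXCS] + p[P_KCYCA];
  const double iup = p[P_AUP] * CaiS / K2 - p[P_BUP] * Caup * K1 / K2;
  const double itrans = p[P_KTRANS] * (Caup - Carel);

  /* cell volumes (mm^3 == uL) */
  const double vCell = M_PI * p[P_RADIUS] * p[P_RADIUS] * p[P_LENGTH];
  const double vi = vCell * p[P_VIRATIO];
  const double vds = vi * p[P_VDSRATIO];
  const double viF = vi * FARADAY;

  /* buffering fluxes */
  const double dCalmod = p[P_ACALMOD] * CaiS * (p[P_CALMODTOT] - CaCalmod) -
    p[P_BCALMOD] * CaCalmod;
  const double dTrop = p[P_ATROP] * CaiS * (p[P_TROPTOT] - CaTrop) -
    p[P_BTROP] * CaTrop;

  /* --- assemble derivatives (per second) --- */

  dy[0]  = -(iIon + iext) / p[P_CM] * 1000.0;  /* nA/nF = mV/ms -> mV/s */
  dy[1]  = am * (1.0 - m) - bm * m;
  dy[2]  = ah * (1.0 - h) - bh * h;
  dy[3]  = p[P_SPEEDD] * (ad * (1.0 - d) - bd * d);
  dy[4]  = p[P_SPEEDF] * (af * (1.0 - f) - bf * f);
  dy[5]  = p[P_RF2] * (1.0 - (CaiS / (p[P_KMF2] + CaiS) + f2));
  dy[6]  = p[P_RF2DS] * (1.0 - (CadsS / (p[P_KMF2DS] + CadsS) + f2ds));
  dy[7]  = as * (1.0 - s) - bs * s;
  dy[8]  = 333.0 * (rinf - r);
  dy[9]  = axr * (1.0 - xr1) - bxr1 * xr1;
  dy[10] = axr * (1.0 - xr2) - bxr2 * xr2;
  dy[11] = axs * (1.0 - xs) - bxs * xs;
  dy[12] = precFrac * speedRel * actRate - act * speedRel * inactRate;
  dy[13] = act * speedRel * inactRate - speedRel * prod;

  dy[14] = -(iNa + ipNa + ibNa + 3.0 * iNaK +
             3.0 * (iNaCaCyt + iNaCaDs) + iCaLNaCyt + iCaLNaDs) / viF;
  dy[15] = -(iK1 + iKr + iKs + ito + iCaLKCyt + iCaLKDs - 2.0 * iNaK) / viF;
  dy[16] = -(iCaLCaCyt + ibCa - 2.0 * (iNaCaCyt + iNaCaDs)) / (2.0 * viF) +
    Cads * p[P_VDSRATIO] * p[P_KDECAYDS] +
    irel * (p[P_VRELRATIO] / p[P_VIRATIO]) - iup - dCalmod - dTrop;
  dy[17] = -iCaLCaDs / (2.0 * vds * FARADAY) - Cads * p[P_KDECAYDS];
  dy[18] = (p[P_VIRATIO] / p[P_VUPRATIO]) * iup - itrans;
  dy[19] = (p[P_VUPRATIO] / p[P_VRELRATIO]) * itrans - irel;
  dy[20] = dCalmod;
  dy[21] = dTrop;

  /* per second -> per millisecond */
  for (int k = 0; k < NSTATE; k++) dy[k] *= 1e-3;
}

/* passive (linearised-membrane) cell: Iion = gm (V - Erest); all
 * non-voltage states frozen.  Same 22-slot layout for interface parity. */
static void passive_rhs(const double *y, double gm, double erest, double cm,
                        double iext, double *dy)
{
  dy[0] = -(gm * (y[0] - erest) + iext) / cm;   /* mV/ms directly */
  for (int k = 1; k < NSTATE; k++) dy[k] = 0.0;
}

/* Fiber RHS.
 *   y     : ncell*22 state vector, cell-major
 *   p     : NPAR parameter vector (active model) -- always supplied
 *   ggj   : scalar coupling conductance (uS)
 *   stim  : per-cell external stimulus current (nA, inward negative)
 *   passive: 0/1; pas = c(gm, erest, cm) used when passive != 0
 */
SEXP C_fiber_rhs(SEXP ySEXP, SEXP pSEXP, SEXP ggjSEXP, SEXP stimSEXP,
                 SEXP passiveSEXP, SEXP pasSEXP)
{
  const double *y = REAL(ySEXP);
  const double *p = REAL(pSEXP);
  const double ggj = asReal(ggjSEXP);
  const double *stim = REAL(stimSEXP);
  const int passive = asInteger(passiveSEXP);
  const double *pas = REAL(pasSEXP);

  const int n = LENGTH(ySEXP);
  if (n % NSTATE != 0)
    error("state vector length %d is not a multiple of %d", n, NSTATE);
  const int ncell = n / NSTATE;
  if (LENGTH(stimSEXP) != ncell)
    error("stimulus vector length %d does not match %d cells",
          LENGTH(stimSEXP), ncell);
  if (!passive && LENGTH(pSEXP) != NPAR)
    error("parameter vector must have length %d", NPAR);

  SEXP out = PROTECT(allocVector(REALSXP, n));
  double *dy = REAL(out);

  for (int i = 0; i < ncell; i++) {
    const double Vi = y[i * NSTATE];
    /* sealed ends: no flux past the first and last cells */
    double icouple = 0.0;  /* nA leaving the cell through gap junctions */
    if (ncell > 1) {
      if (i > 0)         icouple += ggj * (Vi - y[(i - 1) * NSTATE]);
      if (i < ncell - 1) icouple += ggj * (Vi - y[(i + 1) * NSTATE]);
    }
    const double iext = stim[i] + icouple;
    if (passive)
      passive_rhs(y + i * NSTATE, pas[0], pas[1], pas[2], iext,
                  dy + i * NSTATE);
    else
      cell_rhs(y + i * NSTATE, p, iext, dy + i * NSTATE);
  }

  UNPROTECT(1);
  return out;
}

static const R_CallMethodDef callMethods[] = {
  {"C_fiber_rhs", (DL_FUNC) &C_fiber_rhs, 6},
  {NULL, NULL, 0}
};

void R_init_fiberAP(DllInfo *info)
{
  R_registerRoutines(info, NULL, callMethods, NULL, NULL);
  R_useDynamicSymbols(info, FALSE);
}
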