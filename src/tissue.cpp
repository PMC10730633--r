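// 2D monodomain engine: explicit 5-point-stencil diffusion with no-flux
// boundaries, Strang operator splitting around a per-node reaction substep,
// global-illumination protocols (open-loop pulse train / resonant feedback),
// rectangular stimulus windows, sensor traces, voltage snapshots and
// quiescence detection.
//
// Two reaction schemes:
//   scheme 0 ("split"): tabulated rates, exponential-Euler Markov updates,
//     Rush-Larsen HH gates.  Fast path used for long runs.
//   scheme 1 ("rk4"): full RK4 on the coupled per-node ODEs, bitwise
//     identical to the single-cell integrator when D = 0.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "bondarenko.h"
using namespace Rcpp;

static const double ksatT = 0.1, etaT = 0.35;

// ---------------- rate lookup table ----------------------------------------

enum {
  cANA11, cANA12, cANA13, cBNA11, cBNA12, cBNA13, cANA3, cBNA3, cANA2, cBNA2,
  cACA, cBCA, cKPCF,
  cAA0, cBA0, cAA1, cBA1, cAI, cBI,
  cAF_INF, cAF_RL, cIF_INF, cIF_RL, cASS, cAS_RL, cISS, cITOS_RL,
  cN_INF, cN_RL, cIUR_RL, cAKSS_RL,
  cOCLCA, cE0896, cENAK1, cENAKV, cEETA, cEETAM,
  cGD1, cGR, cGFUN, cPRYR, NCOL
};

struct RateTable {
  double vmin, vmax, dv;
  int n;
  std::vector<double> tab;   // row-major: bin * NCOL + col
  void build(double dt) {
    vmin = -150.0; vmax = 100.0; dv = 0.05;
    n = (int)((vmax - vmin) / dv) + 2;
    tab.assign((size_t)n * NCOL, 0.0);
    VRates r;
    for (int i = 0; i < n; i++) {
      double V = vmin + i * dv;
      vrates_eval(V, r);
      double* row = &tab[(size_t)i * NCOL];
      row[cANA11]=r.aNa11; row[cANA12]=r.aNa12; row[cANA13]=r.aNa13;
      row[cBNA11]=r.bNa11; row[cBNA12]=r.bNa12; row[cBNA13]=r.bNa13;
      row[cANA3]=r.aNa3; row[cBNA3]=r.bNa3; row[cANA2]=r.aNa2; row[cBNA2]=r.bNa2;
      row[cACA]=r.aCa; row[cBCA]=r.bCa; row[cKPCF]=r.Kpcf;
      row[cAA0]=r.aa0; row[cBA0]=r.ba0; row[cAA1]=r.aa1; row[cBA1]=r.ba1;
      row[cAI]=r.ai; row[cBI]=r.bi;
      double sa = r.atof_a + r.atof_b;
      row[cAF_INF] = r.atof_a / sa;   row[cAF_RL] = 1.0 - exp(-dt * sa);
      double si = r.itof_a + r.itof_b;
      row[cIF_INF] = r.itof_a / si;   row[cIF_RL] = 1.0 - exp(-dt * si);
      row[cASS] = r.ass;              row[cAS_RL] = 1.0 - exp(-dt / r.tau_tas);
      row[cISS] = r.iss;              row[cITOS_RL] = 1.0 - exp(-dt / r.tau_tis);
      double sn = r.an + r.bn;
      row[cN_INF] = r.an / sn;        row[cN_RL] = 1.0 - exp(-dt * sn);
      row[cIUR_RL]  = 1.0 - exp(-dt / r.tau_iur);
      row[cAKSS_RL] = 1.0 - exp(-dt / r.tau_aKss);
      row[cOCLCA] = r.OClCa;
      row[cE0896] = exp(0.0896 * V);
      row[cENAK1] = exp(-0.1 * V / RTF);
      row[cENAKV] = exp(-V / RTF);
      row[cEETA]  = exp(etaT * V / RTF);
      row[cEETAM] = exp((etaT - 1.0) * V / RTF);
      row[cGD1] = r.Gd1; row[cGR] = r.Gr; row[cGFUN] = r.Gfun;
      row[cPRYR] = r.pryr_gauss;
    }
  }
};

// cheap monotone approximation of exp(-x) for x >= 0 (exact enough for the
// exponential-Euler substeps; validated by self-convergence tests)
static inline double fexpneg(double x) {
  return 1.0 / (1.0 + x * (1.0 + x * (0.5 + x * (1.0 / 6.0))));
}
// exponential-Euler update toward quasi-steady state A/B
static inline double eeup(double x, double A, double B, double dt) {
  double bx = B * dt;
  if (bx < 1e-10) return x + dt * (A - B * x);
  double e = fexpneg(bx);
  return x * e + (A / B) * (1.0 - e);
}

// per-node reversal-potential cache
struct RevCache {
  std::vector<double> ENa, EK, EKr, ECaN, eK1;
  void resize(int n) { ENa.resize(n); EK.resize(n); EKr.resize(n);
                       ECaN.resize(n); eK1.resize(n); }
  void update(int node, const double* s, const double* p) {
    double Nai = s[26], Ki = s[27], Cai = s[1];
    double Ko = p[pKO], Nao = p[pNAO], Cao = p[pCAO];
    ENa[node] = RTF * log((0.9 * Nao + 0.1 * Ko) / (0.9 * Nai + 0.1 * Ki));
    EK[node]  = RTF * log(Ko / Ki);
    EKr[node] = RTF * log((0.98 * Ko + 0.02 * Nao) / (0.98 * Ki + 0.02 * Nai));
    ECaN[node] = 0.5 * RTF * log(Cao / Cai);
    eK1[node] = exp(-0.0896 * EK[node]);
  }
};

// fixed model constants shared with model.cpp (kept in sync)
static const double CMDNtot = 50.0, KmCMDN = 0.238;
static const double CSQNtot = 15000.0, KmCSQN = 800.0;
static const double LTRPNtot = 70.0, HTRPNtot = 140.0;
static const double kp_htrpn = 0.00237, km_htrpn = 3.2e-5;
static const double kp_ltrpn = 0.0327,  km_ltrpn = 0.0196;
static const double ka_p = 0.006075, ka_m = 0.07125;
static const double kb_p = 0.00405,  kb_m = 0.965;
static const double kc_p = 0.009,    kc_m = 0.0008;
static const double ECaL = 63.0, KmpCa = 0.5;
static const double KmNaiNaK = 21000.0, KmKoNaK = 1500.0;
static const double KmNaNCX = 87500.0, KmCaNCX = 1380.0;
static const double KmClCa = 10.0, ICaLmax = 7.0;

// fast reaction substep for one node; returns new V (not yet stored)
static inline double node_step_fast(double* s, double Iapp, double dt,
                                    const double* p, const double* q,
                                    const RateTable& T, const RevCache& R,
                                    int node, double k1, double k2,
                                    double e12, double e21, double sigmaNaK) {
  const double V = s[0];
  double vi = (V - T.vmin) / T.dv;
  if (vi < 0) vi = 0;
  if (vi > T.n - 2) vi = T.n - 2;
  int i0 = (int)vi;
  double w = vi - i0;
  const double* r0 = &T.tab[(size_t)i0 * NCOL];
  const double* r1 = r0 + NCOL;
#define L(c) (r0[c] + w * (r1[c] - r0[c]))

  const double Cai = s[1], Cass = s[2], CaJSR = s[3], CaNSR = s[4];
  const double LT = s[5], HT = s[6], PRyR = s[7];
  const double PO1 = s[8], PO2 = s[9], PC2 = s[10];
  const double O = s[11], C2 = s[12], C3 = s[13], C4 = s[14];
  const double I1 = s[15], I2 = s[16], I3 = s[17];
  const double CNa2 = s[18], CNa1 = s[19], ONa = s[20], IFNa = s[21];
  const double I1Na = s[22], I2Na = s[23], ICNa2 = s[24], ICNa3 = s[25];
  const double Nai = s[26], Ki = s[27];
  const double cO1 = s[42], cO2 = s[43];

  const double ENa = R.ENa[node], EK = R.EK[node], EKr = R.EKr[node];
  const double ECaN = R.ECaN[node];

  // currents
  const double INa  = p[pGNA] * ONa * (V - ENa);
  const double ICaL = p[pGCAL] * O * (V - ECaL);
  const double IpCa = p[pIPCA] * Cai * Cai / (KmpCa * KmpCa + Cai * Cai);
  const double IKtof = p[pGKTOF] * s[28] * s[28] * s[28] * s[29] * (V - EK);
  const double IKtos = p[pGKTOS] * s[30] * s[31] * (V - EK);
  const double IK1 = p[pGK1] * (p[pKO] / (p[pKO] + 210.0)) * (V - EK) /
                     (1.0 + L(cE0896) * R.eK1[node]);
  const double IKs  = p[pGKS] * s[32] * s[32] * (V - EK);
  const double IKur = p[pGKUR] * s[33] * s[34] * (V - EK);
  const double IKss = p[pGKSS] * s[35] * s[36] * (V - EK);
  const double IKr  = p[pGKR] * s[39] * (V - EKr);
  const double fNaK = 1.0 / (1.0 + 0.1245 * L(cENAK1)
                                 + 0.0365 * sigmaNaK * L(cENAKV));
  const double INaK = p[pINAK] * fNaK * (p[pKO] / (p[pKO] + KmKoNaK)) /
                      (1.0 + pow(KmNaiNaK / Nai, 1.5));
  const double Nai3 = Nai * Nai * Nai;
  const double Nao = p[pNAO], Cao = p[pCAO];
  const double Nao3 = Nao * Nao * Nao;
  const double eEta = L(cEETA), eEtam = L(cEETAM);
  const double INaCa = p[pKNACA] / (KmNaNCX * KmNaNCX * KmNaNCX + Nao3) /
                       (KmCaNCX + Cao) / (1.0 + ksatT * eEtam) *
                       (eEta * Nai3 * Cao - eEtam * Nao3 * Cai);
  const double IClCa = p[pGCLCA] * L(cOCLCA) * (V - p[pECL]) * Cai / (Cai + KmClCa);
  const double ICab = p[pGCAB] * (V - ECaN);
  const double INab = p[pGNAB] * (V - ENa);
  const double IChR2 = q[qGCHR2] * L(cGFUN) * (cO1 + q[qGAMMA] * cO2);

  const double Iion = INa + ICaL + IpCa + IKtof + IKtos + IKr + IKur + IKss +
                      IK1 + IKs + INaCa + INaK + IClCa + ICab + INab;
  const double Vnew = V - dt * (Iion + IChR2 + Iapp) / p[pCM];

  // calcium handling (Cass, PO1 via exponential-Euler: they are stiff)
  const double Bi   = 1.0 / (1.0 + CMDNtot * KmCMDN / ((KmCMDN + Cai) * (KmCMDN + Cai)));
  const double Bss  = 1.0 / (1.0 + CMDNtot * KmCMDN / ((KmCMDN + Cass) * (KmCMDN + Cass)));
  const double BJSR = 1.0 / (1.0 + CSQNtot * KmCSQN / ((KmCSQN + CaJSR) * (KmCSQN + CaJSR)));
  const double Prel = p[pV1] * (PO1 + PO2) * PRyR;
  const double Jrel  = Prel * (CaJSR - Cass);
  const double Jtr   = (CaNSR - CaJSR) / p[pTAUTR];
  const double Jxfer = (Cass - Cai) / p[pTAUXFER];
  const double Jleak = p[pV2] * (CaNSR - Cai);
  const double Jup   = p[pV3] * Cai * Cai / (p[pKMUP] * p[pKMUP] + Cai * Cai);
  const double dLT = kp_ltrpn * Cai * (LTRPNtot - LT) - km_ltrpn * LT;
  const double dHT = kp_htrpn * Cai * (HTRPNtot - HT) - km_htrpn * HT;
  const double convI  = p[pACAP] * p[pCM] / (2.0 * p[pVMYO] * Farad);
  const double convSS = p[pACAP] * p[pCM] / (2.0 * p[pVSS] * Farad);
  const double rJSRSS = p[pVJSR] / p[pVSS], rMYOSS = p[pVMYO] / p[pVSS];

  s[1] = Cai + dt * Bi * (Jleak + Jxfer - Jup - (dLT + dHT)
                          - (ICab - 2.0 * INaCa + IpCa) * convI);
  {
    double A = Bss * (Prel * rJSRSS * CaJSR + rMYOSS * Cai / p[pTAUXFER]
                      - ICaL * convSS);
    double B = Bss * (Prel * rJSRSS + rMYOSS / p[pTAUXFER]);
    s[2] = eeup(Cass, A, B, dt);
  }
  s[3] = CaJSR + dt * BJSR * (Jtr - Jrel);
  s[4] = CaNSR + dt * ((Jup - Jleak) * p[pVMYO] / p[pVNSR]
                       - Jtr * p[pVJSR] / p[pVNSR]);
  s[5] = LT + dt * dLT;
  s[6] = HT + dt * dHT;
  s[7] = PRyR + dt * (-0.04 * PRyR - 0.1 * (ICaL / ICaLmax) * L(cPRYR));

  // RyR Markov: backward Euler on the reduced 3-state linear system (the
  // PO1<->PO2 rates scale as Cass^3..Cass^4 and are very stiff during the
  // subspace Ca transient)
  const double Cass3 = Cass * Cass * Cass, Cass4 = Cass3 * Cass;
  {
    const double a = ka_p * Cass4, b = kb_p * Cass3;
    // x' solves (I - dt J) x' = x + dt c with PC1 eliminated
    const double m11 = 1.0 + dt * (a + ka_m + b + kc_p);
    const double m12 = -dt * (kb_m - a), m13 = -dt * (kc_m - a);
    const double m21 = -dt * b, m22 = 1.0 + dt * kb_m;
    const double m31 = -dt * kc_p, m33 = 1.0 + dt * kc_m;
    const double r1 = PO1 + dt * a, r2 = PO2, r3 = PC2;
    const double det = m11 * m22 * m33 - m12 * m21 * m33 - m13 * m22 * m31;
    s[8]  = (r1 * m22 * m33 - m12 * r2 * m33 - m13 * m22 * r3) / det;
    s[9]  = (r2 - m21 * s[8]) / m22;
    s[10] = (r3 - m31 * s[8]) / m33;
  }

  // L-type Ca Markov (exponential-Euler, Jacobi style on old values)
  {
    const double aCa = L(cACA), bCa = L(cBCA), Kpcf = L(cKPCF), Kpcb = 0.0005;
    const double gCa = 0.23324 * Cass / (20.0 + Cass);
    const double C1L = 1.0 - (O + C2 + C3 + C4 + I1 + I2 + I3);
    s[11] = eeup(O, aCa * C4 + Kpcb * I1 + 0.001 * aCa * I2,
                 4.0 * bCa + gCa + 0.001 * Kpcf, dt);
    s[12] = eeup(C2, 4.0 * aCa * C1L + 2.0 * bCa * C3, bCa + 3.0 * aCa, dt);
    s[13] = eeup(C3, 3.0 * aCa * C2 + 3.0 * bCa * C4, 2.0 * bCa + 2.0 * aCa, dt);
    s[14] = eeup(C4, 2.0 * aCa * C3 + 4.0 * bCa * O
                     + 0.04 * Kpcb * bCa * I1 + 0.008 * bCa * I2
                     + 4.0 * bCa * Kpcb * I3,
                 3.0 * bCa + aCa + 0.01 * aCa * gCa + 0.002 * Kpcf
                     + gCa * Kpcf, dt);
    s[15] = eeup(I1, gCa * O + 0.001 * aCa * I3 + 0.01 * aCa * gCa * C4,
                 Kpcb + 0.001 * Kpcf + 0.04 * bCa * Kpcb, dt);
    s[16] = eeup(I2, 0.001 * Kpcf * O + Kpcb * I3 + 0.002 * Kpcf * C4,
                 0.001 * aCa + gCa + 0.008 * bCa, dt);
    s[17] = eeup(I3, 0.001 * Kpcf * I1 + gCa * I2 + gCa * Kpcf * C4,
                 0.001 * aCa + Kpcb + 4.0 * bCa * Kpcb, dt);
  }

  // fast Na Markov
  {
    const double aNa11 = L(cANA11), aNa12 = L(cANA12), aNa13 = L(cANA13);
    const double bNa11 = L(cBNA11), bNa12 = L(cBNA12), bNa13 = L(cBNA13);
    const double aNa3 = L(cANA3), bNa3 = L(cBNA3), aNa2 = L(cANA2), bNa2 = L(cBNA2);
    const double aNa4 = aNa2 / 1000.0, bNa4 = aNa3;
    const double aNa5 = aNa2 / 95000.0, bNa5 = aNa3 / 50.0;
    const double CNa3 = 1.0 - (CNa2 + CNa1 + ONa + IFNa + I1Na + I2Na + ICNa2 + ICNa3);
    s[18] = eeup(CNa2, aNa11 * CNa3 + bNa12 * CNa1 + aNa3 * ICNa2,
                 bNa11 + aNa12 + bNa3, dt);
    s[19] = eeup(CNa1, aNa12 * CNa2 + bNa13 * ONa + aNa3 * IFNa,
                 bNa12 + aNa13 + bNa3, dt);
    s[20] = eeup(ONa, aNa13 * CNa1 + bNa2 * IFNa, bNa13 + aNa2, dt);
    s[21] = eeup(IFNa, aNa2 * ONa + bNa3 * CNa1 + bNa4 * I1Na + aNa12 * ICNa2,
                 bNa2 + aNa3 + aNa4 + bNa12, dt);
    s[22] = eeup(I1Na, aNa4 * IFNa + bNa5 * I2Na, bNa4 + aNa5, dt);
    s[23] = eeup(I2Na, aNa5 * I1Na, bNa5, dt);
    s[24] = eeup(ICNa2, aNa11 * ICNa3 + bNa12 * IFNa + bNa3 * CNa2,
                 bNa11 + aNa12 + aNa3, dt);
    s[25] = eeup(ICNa3, bNa11 * ICNa2 + bNa3 * CNa3, aNa11 + aNa3, dt);
  }

  const double convV = p[pACAP] * p[pCM] / (p[pVMYO] * Farad);
  s[26] = Nai + dt * (-(INa + INab + 3.0 * INaCa + 3.0 * INaK) * convV);
  s[27] = Ki + dt * (-(IKtof + IKtos + IK1 + IKs + IKss + IKur + IKr
                       - 2.0 * INaK) * convV);

  // HH gates, Rush-Larsen
  s[28] += (L(cAF_INF) - s[28]) * L(cAF_RL);
  s[29] += (L(cIF_INF) - s[29]) * L(cIF_RL);
  s[30] += (L(cASS)    - s[30]) * L(cAS_RL);
  s[31] += (L(cISS)    - s[31]) * L(cITOS_RL);
  s[32] += (L(cN_INF)  - s[32]) * L(cN_RL);
  s[33] += (L(cASS)    - s[33]) * L(cAS_RL);
  s[34] += (L(cISS)    - s[34]) * L(cIUR_RL);
  s[35] += (L(cASS)    - s[35]) * L(cAKSS_RL);
  // s[36] iKss constant

  // IKr Markov
  {
    const double aa0 = L(cAA0), ba0 = L(cBA0), aa1 = L(cAA1), ba1 = L(cBA1);
    const double ai = L(cAI), bi = L(cBI), kf = 0.023761, kb = 0.036778;
    const double CK1 = s[37], CK2 = s[38], OK = s[39], IK = s[40];
    const double CK0 = 1.0 - (CK1 + CK2 + OK + IK);
    s[37] = eeup(CK1, aa0 * CK0 + kb * CK2, ba0 + kf, dt);
    s[38] = eeup(CK2, kf * CK1 + ba1 * OK, kb + aa1, dt);
    s[39] = eeup(OK, aa1 * CK2 + bi * IK, ba1 + ai, dt);
    s[40] = eeup(IK, ai * OK, bi, dt);
  }

  // ChR2 (plain Euler keeps the occupancy sum exactly conserved)
  {
    const double Gd1 = L(cGD1), Gr = L(cGR), Gd2 = q[qGD2];
    const double cC1 = s[41], cO1o = s[42], cO2o = s[43], cC2o = s[44];
    s[41] = cC1 + dt * (Gr * cC2o + Gd1 * cO1o - k1 * cC1);
    s[42] = cO1o + dt * (k1 * cC1 - (Gd1 + e12) * cO1o + e21 * cO2o);
    s[43] = cO2o + dt * (k2 * cC2o + e12 * cO1o - (Gd2 + e21) * cO2o);
    s[44] = cC2o + dt * (Gd2 * cO2o - (k2 + Gr) * cC2o);
  }
#undef L
  return Vnew;
}

// ---------------- diffusion ------------------------------------------------

static void laplace5(const double* V, double* lap, int nx, int ny, double inv_dx2) {
  // no-flux boundaries: ghost nodes mirror across the domain face (ghost =
  // boundary node), the conservative convention -- the spatial mean of V is
  // invariant under pure diffusion to machine precision
  for (int j = 0; j < ny; j++) {
    int jm = (j == 0) ? 0 : j - 1;
    int jp = (j == ny - 1) ? ny - 1 : j + 1;
    for (int i = 0; i < nx; i++) {
      int im = (i == 0) ? 0 : i - 1;
      int ip = (i == nx - 1) ? nx - 1 : i + 1;
      lap[j * nx + i] = (V[j * nx + im] + V[j * nx + ip] +
                         V[jm * nx + i] + V[jp * nx + i] -
                         4.0 * V[j * nx + i]) * inv_dx2;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix laplacian5_cpp(NumericMatrix V, double dx) {
  int ny = V.nrow(), nx = V.ncol();   // R matrix: rows = y, cols = x
  if (nx < 3 || ny < 3) stop("field must be at least 3 x 3");
  // transposed copy into x-fastest layout
  std::vector<double> v((size_t)nx * ny), l((size_t)nx * ny);
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) v[j * nx + i] = V(j, i);
  laplace5(v.data(), l.data(), nx, ny, 1.0 / (dx * dx));
  NumericMatrix out(ny, nx);
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) out(j, i) = l[j * nx + i];
  return out;
}

// ---------------- full tissue run ------------------------------------------

// [[Rcpp::export]]
List tissue_run_cpp(NumericVector states, int nx, int ny, double dx, double D,
                    double dt, int n_steps, double t0,
                    NumericVector p, NumericVector q, int scheme,
                    List protocol, NumericMatrix stims, IntegerMatrix sensors,
                    int trace_every, int snap_every,
                    bool stop_on_quiescence, double quiet_thresh,
                    double quiet_thresh_lit, double quiet_window,
                    int rev_every) {
  const int nn = nx * ny;
  if (states.size() != (R_xlen_t)nn * NS)
    stop("states must have nx*ny*%d elements", NS);
  if (dt <= 0) stop("dt must be positive");
  const double cfl = dx * dx / (4.0 * D);
  if (D > 0 && dt >= cfl)
    stop("diffusion stability violated: dt = %g ms >= dx^2/(4 D) = %g ms", dt, cfl);

  NumericVector st = clone(states);
  double* S = REAL(st);
  std::vector<double> V(nn), lap(nn);
  for (int k = 0; k < nn; k++) V[k] = S[(size_t)k * NS];

  RateTable T;
  if (scheme == 0) T.build(dt);
  RevCache R;
  R.resize(nn);
  for (int k = 0; k < nn; k++) R.update(k, &S[(size_t)k * NS], REAL(p));
  const double sigmaNaK = (exp(p[pNAO] / 67300.0) - 1.0) / 7.0;

  // protocol
  const std::string mode = as<std::string>(protocol["mode"]);
  const int pm = (mode == "open_loop") ? 1 : (mode == "feedback" ? 2 : 0);
  double pl_start = 0, pl_period = 1e300, pl_width = 0, pl_Ee = 0;
  int pl_nmax = INT_MAX;
  int fb_node = -1; double fb_Vc = -40.0;
  bool fb_armed = true;
  double fb_active_until = -1e300;
  int pulses_fired = 0;
  if (pm == 1) {
    pl_start = as<double>(protocol["t_start"]);
    pl_period = as<double>(protocol["period"]);
    pl_width = as<double>(protocol["width"]);
    pl_Ee = as<double>(protocol["Ee_on"]);
    if (protocol.containsElementNamed("n_max")) {
      double nm = as<double>(protocol["n_max"]);
      if (R_finite(nm)) pl_nmax = (int)nm;
    }
    if (pl_width > pl_period)
      stop("pulse width %g ms exceeds pacing period %g ms", pl_width, pl_period);
  } else if (pm == 2) {
    int ei = as<int>(protocol["elec_i"]), ej = as<int>(protocol["elec_j"]);
    if (ei < 0 || ei >= nx || ej < 0 || ej >= ny)
      stop("feedback electrode outside the grid");
    fb_node = ej * nx + ei;
    fb_Vc = as<double>(protocol["Vc"]);
    pl_width = as<double>(protocol["width"]);
    pl_Ee = as<double>(protocol["Ee_on"]);
    fb_armed = V[fb_node] < fb_Vc;
  }

  // recording
  const int nrec = n_steps / trace_every + 1;
  const int nsens = sensors.nrow();
  NumericVector trace_t(nrec), trace_Ee(nrec), trace_vmax(nrec);
  NumericMatrix traces(nrec, nsens);
  std::vector<int> sens_node(nsens);
  for (int ss = 0; ss < nsens; ss++) {
    int i = sensors(ss, 0), j = sensors(ss, 1);
    if (i < 0 || i >= nx || j < 0 || j >= ny) stop("sensor outside the grid");
    sens_node[ss] = j * nx + i;
  }
  int nsnap = (snap_every > 0) ? n_steps / snap_every + 1 : 0;
  NumericVector snaps(nsnap > 0 ? (R_xlen_t)nsnap * nn : 0);
  NumericVector snap_t(nsnap > 0 ? nsnap : 0);
  std::vector<double> ev_on, ev_off, ev_trig;

  const double difc = D / (dx * dx);
  double vmax_cur = -1e300;
  for (int k = 0; k < nn; k++) if (V[k] > vmax_cur) vmax_cur = V[k];
  double quiet_ms = 0.0;
  bool terminated = false;
  double t_term = NA_REAL;
  int last_ol_pulse = -1;
  int ri = 0, si = 0;

  // rk4 scratch
  double k1v[NS], k2v[NS], k3v[NS], k4v[NS], tmpv[NS];

  for (int n = 0; n <= n_steps; n++) {
    const double t = t0 + n * dt;

    // irradiance for this step
    double Ee = 0.0;
    int new_pulse_trigger = -1;
    if (pm == 1 && t >= pl_start - 1e-12) {
      int kp = (int)floor((t - pl_start) / pl_period + 1e-12);
      double phase = t - pl_start - kp * pl_period;
      if (kp < pl_nmax && phase < pl_width - 1e-12) {
        Ee = pl_Ee;
        if (kp > last_ol_pulse) { last_ol_pulse = kp; new_pulse_trigger = 0; }
      }
    } else if (pm == 2) {
      if (t < fb_active_until - 1e-12) Ee = pl_Ee;
    }
    if (new_pulse_trigger == 0) {
      ev_on.push_back(t); ev_off.push_back(t + pl_width); ev_trig.push_back(0);
      pulses_fired++;
    }

    // recording
    if (n % trace_every == 0 && ri < nrec) {
      trace_t[ri] = t; trace_Ee[ri] = Ee; trace_vmax[ri] = vmax_cur;
      for (int ss = 0; ss < nsens; ss++) traces(ri, ss) = V[sens_node[ss]];
      ri++;
    }
    if (snap_every > 0 && n % snap_every == 0 && si < nsnap) {
      std::copy(V.begin(), V.end(), &snaps[(R_xlen_t)si * nn]);
      snap_t[si] = t;
      si++;
    }

    // quiescence bookkeeping; sub-threshold light holds resting tissue a few
    // mV depolarized, so lit samples use a relaxed threshold
    if ((Ee == 0.0 && vmax_cur < quiet_thresh) ||
        (Ee > 0.0 && vmax_cur < quiet_thresh_lit)) {
      quiet_ms += dt;
      if (!terminated && quiet_ms >= quiet_window) {
        terminated = true;
        t_term = t;
        if (stop_on_quiescence) break;
      }
    } else quiet_ms = 0.0;

    if (n == n_steps) break;

    // active stimuli this step
    int act[16]; int nact = 0;
    for (int sr = 0; sr < stims.nrow() && nact < 16; sr++)
      if (t >= stims(sr, 0) - 1e-12 && t < stims(sr, 0) + stims(sr, 1) - 1e-12)
        act[nact++] = sr;

    // Strang splitting: half diffusion, reaction, half diffusion
    if (D > 0) {
      laplace5(V.data(), lap.data(), nx, ny, 1.0);
      for (int k = 0; k < nn; k++) V[k] += 0.5 * dt * difc * lap[k];
    }

    if (rev_every > 0 && n % rev_every == 0)
      for (int k = 0; k < nn; k++) R.update(k, &S[(size_t)k * NS], REAL(p));

    double chk1 = 0, chk2 = 0, che12 = 0, che21 = 0;
    chk1 = q[qKC1] * Ee; chk2 = q[qKC2] * Ee;
    che12 = q[qE12D] + q[qE12C] * log(1.0 + Ee / q[qEEREF]);
    che21 = q[qE21D] + q[qE21C] * log(1.0 + Ee / q[qEEREF]);

    double vmax_new = -1e300;
    for (int j = 0; j < ny; j++) {
      for (int i = 0; i < nx; i++) {
        const int k = j * nx + i;
        double* s = &S[(size_t)k * NS];
        s[0] = V[k];
        double Iapp = 0.0;
        for (int a = 0; a < nact; a++) {
          const int sr = act[a];
          if (i >= (int)stims(sr, 3) && i <= (int)stims(sr, 4) &&
              j >= (int)stims(sr, 5) && j <= (int)stims(sr, 6))
            Iapp += stims(sr, 2);
        }
        double Vn;
        if (scheme == 0) {
          Vn = node_step_fast(s, Iapp, dt, REAL(p), REAL(q), T, R, k,
                              chk1, chk2, che12, che21, sigmaNaK);
        } else {
          bond_rk4_step(s, Iapp, Ee, dt, REAL(p), REAL(q),
                        k1v, k2v, k3v, k4v, tmpv);
          Vn = s[0];
        }
        if (!std::isfinite(Vn))
          stop("non-finite voltage at node (i=%d, j=%d), t = %g ms", i + 1, j + 1, t);
        V[k] = Vn;
        if (Vn > vmax_new) vmax_new = Vn;
      }
    }

    if (D > 0) {
      laplace5(V.data(), lap.data(), nx, ny, 1.0);
      for (int k = 0; k < nn; k++) V[k] += 0.5 * dt * difc * lap[k];
      vmax_new = -1e300;
      for (int k = 0; k < nn; k++) if (V[k] > vmax_new) vmax_new = V[k];
    }
    vmax_cur = vmax_new;

    // feedback sensing after the step (value at t + dt)
    if (pm == 2) {
      const double Vs = V[fb_node];
      const double tn = t + dt;
      if (fb_armed && Vs >= fb_Vc && tn >= fb_active_until) {
        fb_active_until = tn + pl_width;
        fb_armed = false;
        pulses_fired++;
        ev_on.push_back(tn); ev_off.push_back(tn + pl_width); ev_trig.push_back(1);
      } else if (!fb_armed && Vs < fb_Vc) {
        fb_armed = true;
      }
    }
  }

  for (int k = 0; k < nn; k++) S[(size_t)k * NS] = V[k];

  const int nev = ev_on.size();
  NumericMatrix events(nev, 3);
  for (int e = 0; e < nev; e++) {
    events(e, 0) = ev_on[e]; events(e, 1) = ev_off[e]; events(e, 2) = ev_trig[e];
  }
  colnames(events) = CharacterVector::create("t_on", "t_off", "trigger");

  // trim recordings when the run stopped early
  if (ri < nrec) {
    trace_t = head(trace_t, ri); trace_Ee = head(trace_Ee, ri);
    trace_vmax = head(trace_vmax, ri);
    NumericMatrix tr2(ri, nsens);
    for (int a = 0; a < ri; a++)
      for (int b = 0; b < nsens; b++) tr2(a, b) = traces(a, b);
    traces = tr2;
  }
  List snapout;
  if (nsnap > 0) {
    if (si < nsnap) {
      NumericVector s2((R_xlen_t)si * nn);
      std::copy(snaps.begin(), snaps.begin() + (R_xlen_t)si * nn, s2.begin());
      snaps = s2; snap_t = head(snap_t, si);
      nsnap = si;
    }
    snaps.attr("dim") = IntegerVector::create(nn, nsnap);
  }

  return List::create(
    _["states"] = st, _["t_end"] = t0 + (terminated && stop_on_quiescence
                       ? (t_term - t0) : n_steps * dt),
    _["trace_t"] = trace_t, _["traces"] = traces, _["trace_Ee"] = trace_Ee,
    _["trace_vmax"] = trace_vmax,
    _["snapshots"] = (nsnap > 0 ? (SEXP)snaps : R_NilValue),
    _["snap_t"] = (nsnap > 0 ? (SEXP)snap_t : R_NilValue),
    _["events"] = events, _["pulses_fired"] = pulses_fired,
    _["terminated"] = terminated, _["t_terminated"] = t_term,
    _["fb_armed"] = fb_armed, _["fb_active_until"] = fb_active_until);
}
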