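#ifndef OPTOSPIRAL_BONDARENKO_H
#define OPTOSPIRAL_BONDARENKO_H

#include <cmath>

static const int NS = 45;   // states per node (41 ionic + 4 ChR2)

// cell parameter vector indices
enum {
  pGNA, pGCAL, pGKTOF, pGKTOS, pGKUR, pGKSS, pGKR, pGKS, pGK1, pKNACA,
  pINAK, pIPCA, pGCAB, pGNAB, pGCLCA, pCM, pKO, pNAO, pCAO, pACAP,
  pVMYO, pVJSR, pVNSR, pVSS, pV1, pV2, pV3, pKMUP, pTAUTR, pTAUXFER,
  pECL, NPAR
};
// ChR2 parameter vector indices
enum {
  qGCHR2, qGAMMA, qECHR2, qKC1, qKC2, qE12D, qE12C, qE21D, qE21C, qGD2,
  qEEREF, NQPAR
};

static const double Rgas = 8.314, Temp = 298.0, Farad = 96.5;
static const double RTF = Rgas * Temp / Farad;

struct VRates {
  double aNa11, aNa12, aNa13, bNa11, bNa12, bNa13, aNa3, bNa3, aNa2, bNa2;
  double aCa, bCa, Kpcf;
  double aa0, ba0, aa1, ba1, ai, bi;
  double atof_a, atof_b, itof_a, itof_b;
  double ass, tau_tas, iss, tau_tis, an, bn, tau_iur, tau_aKss;
  double OClCa, pryr_gauss;
  double Gd1, Gr, Gfun;
};

void vrates_eval(double V, VRates& r);
void bond_rhs(const double* s, double Iapp, double Ee,
              const double* p, const double* q, double* d, double* cur);

// classical RK4 update of one cell state in place; k1..k4/tmp are NS scratch
inline void bond_rk4_step(double* s, double Iapp, double Ee, double dt,
                          const double* p, const double* q,
                          double* k1, double* k2, double* k3, double* k4,
                          double* tmp) {
  bond_rhs(s, Iapp, Ee, p, q, k1, 0);
  for (int i = 0; i < NS; i++) tmp[i] = s[i] + 0.5 * dt * k1[i];
  bond_rhs(tmp, Iapp, Ee, p, q, k2, 0);
  for (int i = 0; i < NS; i++) tmp[i] = s[i] + 0.5 * dt * k2[i];
  bond_rhs(tmp, Iapp, Ee, p, q, k3, 0);
  for (int i = 0; i < NS; i++) tmp[i] = s[i] + dt * k3[i];
  bond_rhs(tmp, Iapp, Ee, p, q, k4, 0);
  for (int i = 0; i < NS; i++)
    s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

#endif
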