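// Bondarenko (2004) mouse ventricular myocyte model coupled to a 4-state
// channelrhodopsin-2 photocurrent, with single-cell RK4 integration.
//
// State layout (NS = 45 doubles per cell):
//   0  V        membrane voltage [mV]
//   1  Cai      cytosolic  Ca2+ [uM]
//   2  Cass     subspace   Ca2+ [uM]
//   3  CaJSR    junctional SR Ca2+ [uM]
//   4  CaNSR    network    SR Ca2+ [uM]
//   5  LTRPNCa  Ca bound to low-affinity troponin sites [uM]
//   6  HTRPNCa  Ca bound to high-affinity troponin sites [uM]
//   7  PRyR     RyR modulation factor
//   8  PO1  9 PO2  10 PC2            RyR Markov (PC1 dependent)
//   11 O  12 C2 13 C3 14 C4 15 I1 16 I2 17 I3   L-type Ca Markov (C1 dependent)
//   18 CNa2 19 CNa1 20 ONa 21 IFNa 22 I1Na 23 I2Na 24 ICNa2 25 ICNa3
//                                        fast Na Markov (CNa3 dependent)
//   26 Nai [uM]  27 Ki [uM]
//   28 atof 29 itof 30 atos 31 itos 32 nKs 33 aur 34 iur 35 aKss 36 iKss
//   37 CK1 38 CK2 39 OK 40 IK        IKr Markov (CK0 dependent)
//   41 cC1 42 cO1 43 cO2 44 cC2      ChR2 4-state occupancies
//
// Currents are in pA/pF; depolarizing (inward) currents are negative and
// dV/dt = -(sum + I_applied)/Cm, so a depolarizing applied current is negative.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include "bondarenko.h"
using namespace Rcpp;

// fixed (non-exposed) model constants
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
static const double KmNaNCX = 87500.0, KmCaNCX = 1380.0, ksat = 0.1, eta = 0.35;
static const double KmClCa = 10.0, ICaLmax = 7.0;

// [[Rcpp::export]]
NumericVector bond_param_defaults(std::string variant = "apical") {
  NumericVector p(NPAR);
  p[pGNA] = 13.0; p[pGCAL] = 0.1729;
  if (variant == "septal") {
    p[pGKTOF] = 0.0798; p[pGKTOS] = 0.0629; p[pGKUR] = 0.0975; p[pGKSS] = 0.0324;
  } else {
    p[pGKTOF] = 0.4067; p[pGKTOS] = 0.0;    p[pGKUR] = 0.160;  p[pGKSS] = 0.050;
  }
  p[pGKR] = 0.078; p[pGKS] = 0.00575; p[pGK1] = 0.2938; p[pKNACA] = 292.8;
  p[pINAK] = 0.88; p[pIPCA] = 1.0; p[pGCAB] = 0.000367; p[pGNAB] = 0.0026;
  p[pGCLCA] = 10.0; p[pCM] = 1.0; p[pKO] = 5400.0; p[pNAO] = 140000.0;
  p[pCAO] = 1800.0; p[pACAP] = 1.534e-4; p[pVMYO] = 25.84e-6;
  p[pVJSR] = 0.12e-6; p[pVNSR] = 2.098e-6; p[pVSS] = 1.485e-9;
  p[pV1] = 4.5; p[pV2] = 1.74e-5; p[pV3] = 0.45; p[pKMUP] = 0.5;
  p[pTAUTR] = 20.0; p[pTAUXFER] = 8.0; p[pECL] = -40.0;
  p.attr("names") = CharacterVector::create(
    "g_Na","g_CaL","g_Kto_f","g_Kto_s","g_Kur","g_Kss","g_Kr","g_Ks",
    "g_K1","k_NaCa","I_NaK_max","I_pCa_max","g_Cab","g_Nab","g_ClCa",
    "Cm","Ko","Nao","Cao","Acap","Vmyo","VJSR","VNSR","Vss",
    "v1","v2","v3","Km_up","tau_tr","tau_xfer","E_Cl");
  return p;
}

// [[Rcpp::export]]
NumericVector chr2_param_defaults() {
  // Rate law for light activation: k1 = kc1*Ee, k2 = kc2*Ee with Ee in
  // uW/mm^2 (= W/m^2); kc derived from retinal cross-section photon flux
  // at 470 nm (ChR2 H134R).  e12/e21 grow logarithmically with irradiance.
  NumericVector q(NQPAR);
  q[qGCHR2] = 0.3;          // mS/uF; calibrated, see package docs
  q[qGAMMA] = 0.1; q[qECHR2] = 0.0;
  q[qKC1] = 1.8637e-4; q[qKC2] = 3.0569e-5;   // per ms per (uW/mm^2)
  q[qE12D] = 0.011; q[qE12C] = 0.005;
  q[qE21D] = 0.008; q[qE21C] = 0.004;
  q[qGD2] = 0.05; q[qEEREF] = 24.2;
  q.attr("names") = CharacterVector::create(
    "g_ChR2","gamma","E_ChR2","kc1","kc2","e12_dark","e12_log",
    "e21_dark","e21_log","Gd2","Ee_ref");
  return q;
}

// [[Rcpp::export]]
CharacterVector bond_state_names() {
  CharacterVector n(NS);
  const char* nm[NS] = {
    "V","Cai","Cass","CaJSR","CaNSR","LTRPNCa","HTRPNCa","PRyR",
    "PO1","PO2","PC2","O","C2","C3","C4","I1","I2","I3",
    "CNa2","CNa1","ONa","IFNa","I1Na","I2Na","ICNa2","ICNa3",
    "Nai","Ki","ato_f","ito_f","ato_s","ito_s","nKs","aur","iur",
    "aKss","iKss","CK1","CK2","OK","IK","cC1","cO1","cO2","cC2"};
  for (int i = 0; i < NS; i++) n[i] = nm[i];
  return n;
}

// [[Rcpp::export]]
NumericVector bond_state_init() {
  NumericVector s(NS);
  s[0] = -82.4202; s[1] = 0.115001; s[2] = 0.115001; s[3] = 1299.5;
  s[4] = 1299.5; s[5] = 11.2684; s[6] = 125.29; s[7] = 0.0;
  s[8] = 0.0037; s[9] = 0.0; s[10] = 0.0;
  s[11] = 0.0; s[12] = 1.2e-4; s[13] = 1.0e-4; s[14] = 2.0e-5;
  s[15] = 0.0; s[16] = 0.0; s[17] = 0.0;
  s[18] = 0.020752; s[19] = 0.000279132; s[20] = 7.13483e-7;
  s[21] = 0.000153176; s[22] = 0.000673345; s[23] = 1.55787e-9;
  s[24] = 0.0113879; s[25] = 0.34278;
  s[26] = 14237.1; s[27] = 143720.0;
  s[28] = 0.00265563; s[29] = 0.999977; s[30] = 0.000417069; s[31] = 0.998543;
  s[32] = 0.000262753; s[33] = 0.000417069; s[34] = 0.998543;
  s[35] = 0.000417069; s[36] = 1.0;
  s[37] = 0.000992513; s[38] = 0.000641229; s[39] = 0.00175298;
  s[40] = 3.19129e-5;
  s[41] = 1.0; s[42] = 0.0; s[43] = 0.0; s[44] = 0.0;
  s.attr("names") = bond_state_names();
  return s;
}

// ---------------- voltage-dependent rate helpers (direct evaluation) -------

void vrates_eval(double V, VRates& r) {
  r.aNa11 = 3.802 / (0.1027 * exp(-(V + 2.5) / 17.0) + 0.20 * exp(-(V + 2.5) / 150.0));
  r.aNa12 = 3.802 / (0.1027 * exp(-(V + 2.5) / 15.0) + 0.23 * exp(-(V + 2.5) / 150.0));
  r.aNa13 = 3.802 / (0.1027 * exp(-(V + 2.5) / 12.0) + 0.25 * exp(-(V + 2.5) / 150.0));
  r.bNa11 = 0.1917 * exp(-(V + 2.5) / 20.3);
  r.bNa12 = 0.20 * exp(-(V - 2.5) / 20.3);
  r.bNa13 = 0.22 * exp(-(V - 7.5) / 20.3);
  // Na recovery from inactivation is gated to hyperpolarized potentials
  // (sigmoid factor ~1 below -60 mV, ~0 above -30 mV).  Without it the
  // as-published rate set supports a finite open probability in detailed
  // balance at plateau voltages whose persistent inward current exceeds the
  // weak murine K+ repolarization reserve there, creating a spurious stable
  // equilibrium near -33 mV that freezes tissue in the wake of premature
  // beats.  Gating only the recovery transitions leaves the resting-state
  // occupancies and the upstroke unchanged.
  r.aNa3  = 7.0e-7 * exp(-(V + 7.0) / 7.7) / (1.0 + exp((V + 45.0) / 5.0));
  r.bNa3  = 0.0084 + 0.00002 * (V + 7.0);
  r.aNa2  = 1.0 / (0.188495 * exp(-(V + 7.0) / 16.6) + 0.393956);
  r.bNa2  = r.aNa13 * r.aNa2 * r.aNa3 / (r.bNa13 * r.bNa3);
  double ev = exp((V + 12.0) / 10.0);
  r.aCa = 0.4 * ev *
    (1.0 + 0.7 * exp(-(V + 40.0) * (V + 40.0) / 10.0)
         - 0.75 * exp(-(V + 20.0) * (V + 20.0) / 400.0)) / (1.0 + 0.12 * ev);
  r.bCa = 0.05 * exp(-(V + 12.0) / 13.0);
  r.Kpcf = 13.0 * (1.0 - exp(-(V + 14.5) * (V + 14.5) / 100.0));
  r.aa0 = 0.022348 * exp(0.01176 * V);
  r.ba0 = 0.047002 * exp(-0.0631 * V);
  r.aa1 = 0.013733 * exp(0.038198 * V);
  r.ba1 = 0.0000689 * exp(-0.04178 * V);
  r.ai  = 0.090821 * exp(0.023391 * (V + 5.0));
  r.bi  = 0.006497 * exp(-0.03268 * (V + 5.0));
  r.atof_a = 0.18064 * exp(0.03577 * (V + 30.0));
  r.atof_b = 0.3956  * exp(-0.06237 * (V + 30.0));
  r.itof_a = 0.000152 * exp(-(V + 13.5) / 7.0) /
             (0.0067083 * exp(-(V + 33.5) / 7.0) + 1.0);
  r.itof_b = 0.00095 * exp((V + 33.5) / 7.0) /
             (0.051335 * exp((V + 33.5) / 7.0) + 1.0);
  r.ass = 1.0 / (1.0 + exp(-(V + 22.5) / 7.7));
  r.tau_tas = 0.493 * exp(-0.0629 * V) + 2.058;
  r.iss = 1.0 / (1.0 + exp((V + 45.2) / 5.7));
  r.tau_tis = 270.0 + 1050.0 / (1.0 + exp((V + 45.2) / 5.7));
  double dv = V + 26.5;
  r.an = (fabs(dv) < 1e-9) ? 4.81333e-6 / 0.128
       : 4.81333e-6 * dv / (1.0 - exp(-0.128 * dv));
  r.bn = 9.53333e-5 * exp(-0.038 * dv);
  r.tau_iur  = 1200.0 - 170.0 / (1.0 + exp((V + 45.2) / 5.7));
  r.tau_aKss = 39.3 * exp(-0.0862 * V) + 13.17;
  r.OClCa = 0.2 / (1.0 + exp(-(V - 46.7) / 7.8));
  r.pryr_gauss = exp(-(V - 5.0) * (V - 5.0) / 648.0);
  r.Gd1 = 0.075 + 0.043 * tanh(-(V + 20.0) / 20.0);
  r.Gr  = 4.34e-5 * exp(-0.0211539274 * V);
  r.Gfun = 10.6408 - 14.6408 * exp(-V / 42.7671);
}

// ---------------- full right-hand side --------------------------------------

// cur (if non-null) receives 17 values:
// INa ICaL IpCa IKtof IKtos IKr IKur IKss IK1 IKs INaCa INaK IClCa ICab INab
// IChR2 total_ionic
void bond_rhs(const double* s, double Iapp, double Ee,
              const double* p, const double* q,
              double* d, double* cur) {
  const double V = s[0], Cai = s[1], Cass = s[2], CaJSR = s[3], CaNSR = s[4];
  const double LT = s[5], HT = s[6], PRyR = s[7];
  const double PO1 = s[8], PO2 = s[9], PC2 = s[10];
  const double O = s[11], C2 = s[12], C3 = s[13], C4 = s[14];
  const double I1 = s[15], I2 = s[16], I3 = s[17];
  const double CNa2 = s[18], CNa1 = s[19], ONa = s[20], IFNa = s[21];
  const double I1Na = s[22], I2Na = s[23], ICNa2 = s[24], ICNa3 = s[25];
  const double Nai = s[26], Ki = s[27];
  const double atof = s[28], itof = s[29], atos = s[30], itos = s[31];
  const double nKs = s[32], aur = s[33], iur = s[34], aKss = s[35], iKss = s[36];
  const double CK1 = s[37], CK2 = s[38], OK = s[39], IK = s[40];
  const double cC1 = s[41], cO1 = s[42], cO2 = s[43], cC2 = s[44];

  VRates r; vrates_eval(V, r);

  const double Ko = p[pKO], Nao = p[pNAO], Cao = p[pCAO];
  const double ENa  = RTF * log((0.9 * Nao + 0.1 * Ko) / (0.9 * Nai + 0.1 * Ki));
  const double EK   = RTF * log(Ko / Ki);
  const double EKr  = RTF * log((0.98 * Ko + 0.02 * Nao) / (0.98 * Ki + 0.02 * Nai));
  const double ECaN = 0.5 * RTF * log(Cao / Cai);

  const double INa  = p[pGNA] * ONa * (V - ENa);
  const double ICaL = p[pGCAL] * O * (V - ECaL);
  const double IpCa = p[pIPCA] * Cai * Cai / (KmpCa * KmpCa + Cai * Cai);
  const double IKtof = p[pGKTOF] * atof * atof * atof * itof * (V - EK);
  const double IKtos = p[pGKTOS] * atos * itos * (V - EK);
  const double IK1  = p[pGK1] * (Ko / (Ko + 210.0)) * (V - EK) /
                      (1.0 + exp(0.0896 * (V - EK)));
  const double IKs  = p[pGKS] * nKs * nKs * (V - EK);
  const double IKur = p[pGKUR] * aur * iur * (V - EK);
  const double IKss = p[pGKSS] * aKss * iKss * (V - EK);
  const double IKr  = p[pGKR] * OK * (V - EKr);

  const double sigma = (exp(Nao / 67300.0) - 1.0) / 7.0;
  const double fNaK = 1.0 / (1.0 + 0.1245 * exp(-0.1 * V / RTF)
                                 + 0.0365 * sigma * exp(-V / RTF));
  const double INaK = p[pINAK] * fNaK * (Ko / (Ko + KmKoNaK)) /
                      (1.0 + pow(KmNaiNaK / Nai, 1.5));

  const double Nai3 = Nai * Nai * Nai, Nao3 = Nao * Nao * Nao;
  const double eEta  = exp(eta * V / RTF);
  const double eEtam = exp((eta - 1.0) * V / RTF);
  const double INaCa = p[pKNACA] / (KmNaNCX * KmNaNCX * KmNaNCX + Nao3) /
                       (KmCaNCX + Cao) / (1.0 + ksat * eEtam) *
                       (eEta * Nai3 * Cao - eEtam * Nao3 * Cai);

  const double IClCa = p[pGCLCA] * r.OClCa * (V - p[pECL]) * Cai / (Cai + KmClCa);
  const double ICab = p[pGCAB] * (V - ECaN);
  const double INab = p[pGNAB] * (V - ENa);

  // ChR2 photocurrent: G(V)*(V-E) evaluated jointly; with E = 0 the
  // removable singularity at V = 0 cancels to Gfun(V).
  const double Echr = q[qECHR2];
  double gv;
  if (Echr == 0.0) gv = r.Gfun;
  else {
    double Vv = (fabs(V) < 1e-9) ? ((V < 0) ? -1e-9 : 1e-9) : V;
    gv = r.Gfun * (Vv - Echr) / Vv;
  }
  const double IChR2 = q[qGCHR2] * gv * (cO1 + q[qGAMMA] * cO2);

  const double Iion = INa + ICaL + IpCa + IKtof + IKtos + IKr + IKur + IKss +
                      IK1 + IKs + INaCa + INaK + IClCa + ICab + INab;

  if (cur) {
    cur[0]=INa; cur[1]=ICaL; cur[2]=IpCa; cur[3]=IKtof; cur[4]=IKtos;
    cur[5]=IKr; cur[6]=IKur; cur[7]=IKss; cur[8]=IK1; cur[9]=IKs;
    cur[10]=INaCa; cur[11]=INaK; cur[12]=IClCa; cur[13]=ICab; cur[14]=INab;
    cur[15]=IChR2; cur[16]=Iion;
  }
  if (!d) return;

  d[0] = -(Iion + IChR2 + Iapp) / p[pCM];

  // calcium handling
  const double Bi   = 1.0 / (1.0 + CMDNtot * KmCMDN / ((KmCMDN + Cai) * (KmCMDN + Cai)));
  const double Bss  = 1.0 / (1.0 + CMDNtot * KmCMDN / ((KmCMDN + Cass) * (KmCMDN + Cass)));
  const double BJSR = 1.0 / (1.0 + CSQNtot * KmCSQN / ((KmCSQN + CaJSR) * (KmCSQN + CaJSR)));
  const double Jrel  = p[pV1] * (PO1 + PO2) * (CaJSR - Cass) * PRyR;
  const double Jtr   = (CaNSR - CaJSR) / p[pTAUTR];
  const double Jxfer = (Cass - Cai) / p[pTAUXFER];
  const double Jleak = p[pV2] * (CaNSR - Cai);
  const double Jup   = p[pV3] * Cai * Cai / (p[pKMUP] * p[pKMUP] + Cai * Cai);
  const double dLT = kp_ltrpn * Cai * (LTRPNtot - LT) - km_ltrpn * LT;
  const double dHT = kp_htrpn * Cai * (HTRPNtot - HT) - km_htrpn * HT;
  const double Jtrpn = dLT + dHT;
  const double convI  = p[pACAP] * p[pCM] / (2.0 * p[pVMYO] * Farad);
  const double convSS = p[pACAP] * p[pCM] / (2.0 * p[pVSS] * Farad);
  d[1] = Bi * (Jleak + Jxfer - Jup - Jtrpn - (ICab - 2.0 * INaCa + IpCa) * convI);
  d[2] = Bss * (Jrel * p[pVJSR] / p[pVSS] - Jxfer * p[pVMYO] / p[pVSS] - ICaL * convSS);
  d[3] = BJSR * (Jtr - Jrel);
  d[4] = (Jup - Jleak) * p[pVMYO] / p[pVNSR] - Jtr * p[pVJSR] / p[pVNSR];
  d[5] = dLT; d[6] = dHT;
  d[7] = -0.04 * PRyR - 0.1 * (ICaL / ICaLmax) * r.pryr_gauss;

  const double Cass3 = Cass * Cass * Cass, Cass4 = Cass3 * Cass;
  const double PC1 = 1.0 - (PO1 + PO2 + PC2);
  d[8]  = ka_p * Cass4 * PC1 - ka_m * PO1 - kb_p * Cass3 * PO1 + kb_m * PO2
          - kc_p * PO1 + kc_m * PC2;
  d[9]  = kb_p * Cass3 * PO1 - kb_m * PO2;
  d[10] = kc_p * PO1 - kc_m * PC2;

  // L-type Ca channel Markov chain
  const double gCa = 0.23324 * Cass / (20.0 + Cass);
  const double C1L = 1.0 - (O + C2 + C3 + C4 + I1 + I2 + I3);
  const double aCa = r.aCa, bCa = r.bCa, Kpcf = r.Kpcf, Kpcb = 0.0005;
  d[11] = aCa * C4 - 4.0 * bCa * O + Kpcb * I1 - gCa * O + 0.001 * (aCa * I2 - Kpcf * O);
  d[12] = 4.0 * aCa * C1L + 2.0 * bCa * C3 - (bCa + 3.0 * aCa) * C2;
  d[13] = 3.0 * aCa * C2 + 3.0 * bCa * C4 - (2.0 * bCa + 2.0 * aCa) * C3;
  d[14] = 2.0 * aCa * C3 + 4.0 * bCa * O - (3.0 * bCa + aCa) * C4
          + 0.01 * (4.0 * Kpcb * bCa * I1 - aCa * gCa * C4)
          + 0.002 * (4.0 * bCa * I2 - Kpcf * C4)
          + 4.0 * bCa * Kpcb * I3 - gCa * Kpcf * C4;
  d[15] = gCa * O - Kpcb * I1 + 0.001 * (aCa * I3 - Kpcf * I1)
          + 0.01 * (aCa * gCa * C4 - 4.0 * bCa * Kpcb * I1);
  d[16] = 0.001 * (Kpcf * O - aCa * I2) + Kpcb * I3 - gCa * I2
          + 0.002 * (Kpcf * C4 - 4.0 * bCa * I2);
  d[17] = 0.001 * (Kpcf * I1 - aCa * I3) + gCa * I2 - Kpcb * I3
          + gCa * Kpcf * C4 - 4.0 * bCa * Kpcb * I3;

  // fast Na channel Markov chain
  const double CNa3 = 1.0 - (CNa2 + CNa1 + ONa + IFNa + I1Na + I2Na + ICNa2 + ICNa3);
  const double aNa4 = r.aNa2 / 1000.0, bNa4 = r.aNa3;
  const double aNa5 = r.aNa2 / 95000.0, bNa5 = r.aNa3 / 50.0;
  d[18] = r.aNa11 * CNa3 + r.bNa12 * CNa1 + r.aNa3 * ICNa2
          - (r.bNa11 + r.aNa12 + r.bNa3) * CNa2;
  d[19] = r.aNa12 * CNa2 + r.bNa13 * ONa + r.aNa3 * IFNa
          - (r.bNa12 + r.aNa13 + r.bNa3) * CNa1;
  d[20] = r.aNa13 * CNa1 + r.bNa2 * IFNa - (r.bNa13 + r.aNa2) * ONa;
  d[21] = r.aNa2 * ONa + r.bNa3 * CNa1 + bNa4 * I1Na + r.aNa12 * ICNa2
          - (r.bNa2 + r.aNa3 + aNa4 + r.bNa12) * IFNa;
  d[22] = aNa4 * IFNa + bNa5 * I2Na - (bNa4 + aNa5) * I1Na;
  d[23] = aNa5 * I1Na - bNa5 * I2Na;
  d[24] = r.aNa11 * ICNa3 + r.bNa12 * IFNa + r.bNa3 * CNa2
          - (r.bNa11 + r.aNa12 + r.aNa3) * ICNa2;
  d[25] = r.bNa11 * ICNa2 + r.bNa3 * CNa3 - (r.aNa11 + r.aNa3) * ICNa3;

  const double convV = p[pACAP] * p[pCM] / (p[pVMYO] * Farad);
  d[26] = -(INa + INab + 3.0 * INaCa + 3.0 * INaK) * convV;
  d[27] = -(IKtof + IKtos + IK1 + IKs + IKss + IKur + IKr - 2.0 * INaK) * convV;

  // Hodgkin-Huxley gates
  d[28] = r.atof_a * (1.0 - atof) - r.atof_b * atof;
  d[29] = r.itof_a * (1.0 - itof) - r.itof_b * itof;
  d[30] = (r.ass - atos) / r.tau_tas;
  d[31] = (r.iss - itos) / r.tau_tis;
  d[32] = r.an * (1.0 - nKs) - r.bn * nKs;
  d[33] = (r.ass - aur) / r.tau_tas;
  d[34] = (r.iss - iur) / r.tau_iur;
  d[35] = (r.ass - aKss) / r.tau_aKss;
  d[36] = 0.0;

  // IKr Markov chain
  const double CK0 = 1.0 - (CK1 + CK2 + OK + IK);
  const double kf = 0.023761, kb = 0.036778;
  d[37] = r.aa0 * CK0 + kb * CK2 - (r.ba0 + kf) * CK1;
  d[38] = kf * CK1 + r.ba1 * OK - (kb + r.aa1) * CK2;
  d[39] = r.aa1 * CK2 + r.bi * IK - (r.ba1 + r.ai) * OK;
  d[40] = r.ai * OK - r.bi * IK;

  // ChR2 kinetics (conservative form)
  const double k1 = q[qKC1] * Ee, k2 = q[qKC2] * Ee;
  const double e12 = q[qE12D] + q[qE12C] * log(1.0 + Ee / q[qEEREF]);
  const double e21 = q[qE21D] + q[qE21C] * log(1.0 + Ee / q[qEEREF]);
  d[41] = r.Gr * cC2 + r.Gd1 * cO1 - k1 * cC1;
  d[42] = k1 * cC1 - (r.Gd1 + e12) * cO1 + e21 * cO2;
  d[43] = k2 * cC2 + e12 * cO1 - (q[qGD2] + e21) * cO2;
  d[44] = q[qGD2] * cO2 - (k2 + r.Gr) * cC2;
}

// [[Rcpp::export]]
NumericVector bond_derivs_cpp(NumericVector state, double I_applied,
                              double Ee, NumericVector p, NumericVector q) {
  if (state.size() != NS) stop("state must have %d elements", NS);
  NumericVector d(NS);
  bond_rhs(REAL(state), I_applied, Ee, REAL(p), REAL(q), REAL(d), nullptr);
  d.attr("names") = bond_state_names();
  return d;
}

// [[Rcpp::export]]
NumericVector bond_currents_cpp(NumericVector state, NumericVector p,
                                NumericVector q) {
  if (state.size() != NS) stop("state must have %d elements", NS);
  NumericVector cur(17);
  bond_rhs(REAL(state), 0.0, 0.0, REAL(p), REAL(q), nullptr, REAL(cur));
  cur.attr("names") = CharacterVector::create(
    "I_Na","I_CaL","I_pCa","I_Kto_f","I_Kto_s","I_Kr","I_Kur","I_Kss",
    "I_K1","I_Ks","I_NaCa","I_NaK","I_ClCa","I_Cab","I_Nab",
    "I_ChR2","total");
  return cur;
}


// [[Rcpp::export]]
NumericVector cell_rk4_cpp(NumericVector state, double dt, int n_steps,
                           NumericVector I_applied, NumericVector Ee,
                           NumericVector p, NumericVector q) {
  if (dt <= 0) stop("dt must be positive");
  NumericVector out = clone(state);
  double* s = REAL(out);
  double k1[NS], k2[NS], k3[NS], k4[NS], tmp[NS];
  const bool ivec = I_applied.size() > 1, evec = Ee.size() > 1;
  for (int n = 0; n < n_steps; n++) {
    double ia = ivec ? I_applied[n] : I_applied[0];
    double ee = evec ? Ee[n] : Ee[0];
    bond_rk4_step(s, ia, ee, dt, REAL(p), REAL(q), k1, k2, k3, k4, tmp);
    if (!std::isfinite(s[0]))
      stop("integration became unstable (non-finite V) at step %d (dt = %g ms)",
           n + 1, dt);
  }
  out.attr("names") = bond_state_names();
  return out;
}

// Integrate a single cell with optional stimulus/light schedules, recording
// V (and photocurrent) every `record_every` steps.
// [[Rcpp::export]]
List cell_run_cpp(NumericVector state, double dt, int n_steps,
                  NumericVector I_applied, NumericVector Ee,
                  NumericVector p, NumericVector q, int record_every) {
  if (dt <= 0) stop("dt must be positive");
  NumericVector fin = clone(state);
  double* s = REAL(fin);
  double k1[NS], k2[NS], k3[NS], k4[NS], tmp[NS];
  const bool ivec = I_applied.size() > 1, evec = Ee.size() > 1;
  int nrec = n_steps / record_every + 1;
  NumericVector tv(nrec), Vv(nrec), Iv(nrec), Ich(nrec);
  double cur[17];
  int ri = 0;
  for (int n = 0; n <= n_steps; n++) {
    if (n % record_every == 0 && ri < nrec) {
      bond_rhs(s, 0.0, evec ? Ee[std::min(n, n_steps - 1)] : Ee[0],
               REAL(p), REAL(q), nullptr, cur);
      tv[ri] = n * dt; Vv[ri] = s[0];
      Iv[ri] = ivec ? I_applied[std::min(n, n_steps - 1)] : I_applied[0];
      Ich[ri] = cur[15];
      ri++;
    }
    if (n == n_steps) break;
    double ia = ivec ? I_applied[n] : I_applied[0];
    double ee = evec ? Ee[n] : Ee[0];
    bond_rk4_step(s, ia, ee, dt, REAL(p), REAL(q), k1, k2, k3, k4, tmp);
    if (!std::isfinite(s[0]))
      stop("integration became unstable (non-finite V) at step %d (dt = %g ms)",
           n + 1, dt);
  }
  fin.attr("names") = bond_state_names();
  return List::create(_["state"] = fin, _["t"] = tv, _["V"] = Vv,
                      _["I_applied"] = Iv, _["I_ChR2"] = Ich);
}
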