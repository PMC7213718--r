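// O'Hara-Rudy (2011) human ventricular myocyte model, endocardial variant,
// with multiplicative scaling of 13 conductances/fluxes, an adaptive
// Rush-Larsen integrator and a 1D cable of diffusively coupled cells.
//
// State layout (41 components, see ord_state_names_cpp):
//   0 v, 1 nai, 2 nass, 3 ki, 4 kss, 5 cai, 6 cass, 7 cansr, 8 cajsr,
//   9..39 gating-type variables updated by Rush-Larsen, 40 CaMKt (Euler).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NSTATE = 41;
static const int IDX_V = 0;

// physical constants and geometry (ORd 2011)
static const double nao = 140.0, cao = 1.8, ko = 5.4;
static const double Rgas = 8314.0, Temp = 310.0, Frdy = 96485.0;
static const double Lcell = 0.01, rad = 0.0011;
static const double vcell = 1000.0 * 3.14 * rad * rad * Lcell;
static const double Ageo = 2.0 * 3.14 * rad * rad + 2.0 * 3.14 * rad * Lcell;
static const double Acap = 2.0 * Ageo;
static const double vmyo = 0.68 * vcell;
static const double vnsr = 0.0552 * vcell;
static const double vjsr = 0.0048 * vcell;
static const double vss = 0.02 * vcell;

// scaling vector order (fixed contract with the R side)
// 0 gNa, 1 gKr, 2 gK1, 3 gKs, 4 PCaL, 5 gto, 6 gNaK, 7 gNCX, 8 gpCa,
// 9 Jrel, 10 Jup, 11 CMDN, 12 CaMKII
static const int NSCALE = 13;

struct Derivs {
  double dx[NSTATE];    // explicit derivatives (valid for Euler states)
  double xinf[NSTATE];  // steady state for RL states
  double xtau[NSTATE];  // time constant for RL states
  bool rl[NSTATE];      // which states use Rush-Larsen
};

// evaluates all currents and derivatives at one state.
// Istim in A/F. currents written to cur (14 entries) if not NULL.
static void ord_eval(const double *x, const double *s, double Istim,
                     Derivs &d, double *cur) {
  for (int i = 0; i < NSTATE; ++i) { d.rl[i] = false; d.dx[i] = 0.0; }

  double v = x[0];
  if (std::fabs(v) < 1e-4) v = 1e-4;  // avoid 0/0 in GHK fluxes
  const double nai = x[1], nass = x[2], ki = x[3], kss = x[4];
  const double cai = x[5], cass = x[6], cansr = x[7], cajsr = x[8];
  const double m = x[9], hf = x[10], hs = x[11], j = x[12], hsp = x[13],
               jp = x[14], mL = x[15], hL = x[16], hLp = x[17], a = x[18],
               iF = x[19], iS = x[20], ap = x[21], iFp = x[22], iSp = x[23],
               dgate = x[24], ff = x[25], fs = x[26], fcaf = x[27],
               fcas = x[28], jca = x[29], nca = x[30], ffp = x[31],
               fcafp = x[32], xrf = x[33], xrs = x[34], xs1 = x[35],
               xs2 = x[36], xk1 = x[37], Jrelnp = x[38], Jrelp = x[39],
               CaMKt = x[40];

  // CaMKII (total CaMK pool scaled by the CaMKII multiplier)
  const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068;
  const double CaMKo = 0.05 * s[12], KmCaM = 0.0015;
  const double CaMKb = CaMKo * (1.0 - CaMKt) / (1.0 + KmCaM / cass);
  const double CaMKa = CaMKb + CaMKt;
  d.dx[40] = aCaMK * CaMKb * (CaMKb + CaMKt) - bCaMK * CaMKt;
  const double fphos = 1.0 / (1.0 + KmCaMK / CaMKa);

  const double ENa = (Rgas * Temp / Frdy) * std::log(nao / nai);
  const double EK = (Rgas * Temp / Frdy) * std::log(ko / ki);
  const double PKNa = 0.01833;
  const double EKs =
      (Rgas * Temp / Frdy) * std::log((ko + PKNa * nao) / (ki + PKNa * nai));
  const double vffrt = v * Frdy * Frdy / (Rgas * Temp);
  const double vfrt = v * Frdy / (Rgas * Temp);

  // INa (fast)
  d.rl[9] = true;
  d.xinf[9] = 1.0 / (1.0 + std::exp(-(v + 39.57) / 9.871));
  d.xtau[9] = 1.0 / (6.765 * std::exp((v + 11.64) / 34.77) +
                     8.552 * std::exp(-(v + 77.42) / 5.955));
  const double hss = 1.0 / (1.0 + std::exp((v + 82.90) / 6.086));
  const double thf = 1.0 / (1.432e-5 * std::exp(-(v + 1.196) / 6.285) +
                            6.149 * std::exp((v + 0.5096) / 20.27));
  const double ths = 1.0 / (0.009794 * std::exp(-(v + 17.95) / 28.05) +
                            0.3343 * std::exp((v + 5.730) / 56.66));
  d.rl[10] = true; d.xinf[10] = hss; d.xtau[10] = thf;
  d.rl[11] = true; d.xinf[11] = hss; d.xtau[11] = ths;
  const double Ahf = 0.99, Ahs = 1.0 - Ahf;
  const double h = Ahf * hf + Ahs * hs;
  const double jss = hss;
  const double tj = 2.038 + 1.0 / (0.02136 * std::exp(-(v + 100.6) / 8.281) +
                                   0.3052 * std::exp((v + 0.9941) / 38.45));
  d.rl[12] = true; d.xinf[12] = jss; d.xtau[12] = tj;
  const double hssp = 1.0 / (1.0 + std::exp((v + 89.1) / 6.086));
  d.rl[13] = true; d.xinf[13] = hssp; d.xtau[13] = 3.0 * ths;
  const double hp = Ahf * hf + Ahs * hsp;
  d.rl[14] = true; d.xinf[14] = jss; d.xtau[14] = 1.46 * tj;
  const double GNa = 75.0 * s[0];
  const double INa = GNa * (v - ENa) * m * m * m *
                     ((1.0 - fphos) * h * j + fphos * hp * jp);

  // INaL (also carried by Nav1.5, scaled with gNa)
  d.rl[15] = true;
  d.xinf[15] = 1.0 / (1.0 + std::exp(-(v + 42.85) / 5.264));
  d.xtau[15] = d.xtau[9];
  const double thL = 200.0;
  d.rl[16] = true;
  d.xinf[16] = 1.0 / (1.0 + std::exp((v + 87.61) / 7.488));
  d.xtau[16] = thL;
  d.rl[17] = true;
  d.xinf[17] = 1.0 / (1.0 + std::exp((v + 93.81) / 7.488));
  d.xtau[17] = 3.0 * thL;
  const double GNaL = 0.0075 * s[0];
  const double INaL =
      GNaL * (v - ENa) * mL * ((1.0 - fphos) * hL + fphos * hLp);

  // Ito
  const double ass = 1.0 / (1.0 + std::exp(-(v - 14.34) / 14.82));
  const double ta =
      1.0515 / (1.0 / (1.2089 * (1.0 + std::exp(-(v - 18.4099) / 29.3814))) +
                3.5 / (1.0 + std::exp((v + 100.0) / 29.3814)));
  d.rl[18] = true; d.xinf[18] = ass; d.xtau[18] = ta;
  const double iss = 1.0 / (1.0 + std::exp((v + 43.94) / 5.711));
  const double delta_epi = 1.0;  // endocardial
  const double tiF =
      (4.562 + 1.0 / (0.3933 * std::exp(-(v + 100.0) / 100.0) +
                      0.08004 * std::exp((v + 50.0) / 16.59))) * delta_epi;
  const double tiS =
      (23.62 + 1.0 / (0.001416 * std::exp(-(v + 96.52) / 59.05) +
                      1.780e-8 * std::exp((v + 114.1) / 8.079))) * delta_epi;
  d.rl[19] = true; d.xinf[19] = iss; d.xtau[19] = tiF;
  d.rl[20] = true; d.xinf[20] = iss; d.xtau[20] = tiS;
  const double AiF = 1.0 / (1.0 + std::exp((v - 213.6) / 151.2));
  const double AiS = 1.0 - AiF;
  const double igate = AiF * iF + AiS * iS;
  const double assp = 1.0 / (1.0 + std::exp(-(v - 24.34) / 14.82));
  d.rl[21] = true; d.xinf[21] = assp; d.xtau[21] = ta;
  const double dti_develop =
      1.354 + 1.0e-4 / (std::exp((v - 167.4) / 15.89) +
                        std::exp(-(v - 12.23) / 0.2154));
  const double dti_recover = 1.0 - 0.5 / (1.0 + std::exp((v + 70.0) / 20.0));
  d.rl[22] = true; d.xinf[22] = iss; d.xtau[22] = dti_develop * dti_recover * tiF;
  d.rl[23] = true; d.xinf[23] = iss; d.xtau[23] = dti_develop * dti_recover * tiS;
  const double ipgate = AiF * iFp + AiS * iSp;
  const double Gto = 0.02 * s[5];
  const double Ito = Gto * (v - EK) *
                     ((1.0 - fphos) * a * igate + fphos * ap * ipgate);

  // ICaL / ICaNa / ICaK
  d.rl[24] = true;
  d.xinf[24] = 1.0 / (1.0 + std::exp(-(v + 3.940) / 4.230));
  d.xtau[24] = 0.6 + 1.0 / (std::exp(-0.05 * (v + 6.0)) +
                            std::exp(0.09 * (v + 14.0)));
  const double fss = 1.0 / (1.0 + std::exp((v + 19.58) / 3.696));
  const double tff = 7.0 + 1.0 / (0.0045 * std::exp(-(v + 20.0) / 10.0) +
                                  0.0045 * std::exp((v + 20.0) / 10.0));
  const double tfs = 1000.0 + 1.0 / (0.000035 * std::exp(-(v + 5.0) / 4.0) +
                                     0.000035 * std::exp((v + 5.0) / 6.0));
  d.rl[25] = true; d.xinf[25] = fss; d.xtau[25] = tff;
  d.rl[26] = true; d.xinf[26] = fss; d.xtau[26] = tfs;
  const double Aff = 0.6, Afs = 1.0 - Aff;
  const double f = Aff * ff + Afs * fs;
  const double fcass = fss;
  const double tfcaf = 7.0 + 1.0 / (0.04 * std::exp(-(v - 4.0) / 7.0) +
                                    0.04 * std::exp((v - 4.0) / 7.0));
  const double tfcas = 100.0 + 1.0 / (0.00012 * std::exp(-v / 3.0) +
                                      0.00012 * std::exp(v / 7.0));
  const double Afcaf = 0.3 + 0.6 / (1.0 + std::exp((v - 10.0) / 10.0));
  const double Afcas = 1.0 - Afcaf;
  d.rl[27] = true; d.xinf[27] = fcass; d.xtau[27] = tfcaf;
  d.rl[28] = true; d.xinf[28] = fcass; d.xtau[28] = tfcas;
  const double fca = Afcaf * fcaf + Afcas * fcas;
  d.rl[29] = true; d.xinf[29] = fcass; d.xtau[29] = 75.0;
  d.rl[31] = true; d.xinf[31] = fss; d.xtau[31] = 2.5 * tff;
  const double fp = Aff * ffp + Afs * fs;
  d.rl[32] = true; d.xinf[32] = fcass; d.xtau[32] = 2.5 * tfcaf;
  const double fcap = Afcaf * fcafp + Afcas * fcas;
  const double Kmn = 0.002, k2n = 1000.0;
  const double km2n = jca * 1.0;
  const double km_ratio = 1.0 + Kmn / cass;
  const double anca = 1.0 / (k2n / km2n + km_ratio * km_ratio * km_ratio * km_ratio);
  d.rl[30] = true; d.xinf[30] = anca * k2n / km2n; d.xtau[30] = 1.0 / km2n;
  const double PhiCaL = 4.0 * vffrt *
      (cass * std::exp(2.0 * vfrt) - 0.341 * cao) / (std::exp(2.0 * vfrt) - 1.0);
  const double PhiCaNa = 1.0 * vffrt *
      (0.75 * nass * std::exp(vfrt) - 0.75 * nao) / (std::exp(vfrt) - 1.0);
  const double PhiCaK = 1.0 * vffrt *
      (0.75 * kss * std::exp(vfrt) - 0.75 * ko) / (std::exp(vfrt) - 1.0);
  const double PCa = 0.0001 * s[4];
  const double PCap = 1.1 * PCa;
  const double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
  const double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
  const double gl = dgate * (f * (1.0 - nca) + jca * fca * nca);
  const double glp = dgate * (fp * (1.0 - nca) + jca * fcap * nca);
  const double ICaL = (1.0 - fphos) * PCa * PhiCaL * gl +
                      fphos * PCap * PhiCaL * glp;
  const double ICaNa = (1.0 - fphos) * PCaNa * PhiCaNa * gl +
                       fphos * PCaNap * PhiCaNa * glp;
  const double ICaK = (1.0 - fphos) * PCaK * PhiCaK * gl +
                      fphos * PCaKp * PhiCaK * glp;

  // IKr
  const double xrss = 1.0 / (1.0 + std::exp(-(v + 8.337) / 6.789));
  d.rl[33] = true; d.xinf[33] = xrss;
  d.xtau[33] = 12.98 + 1.0 / (0.3652 * std::exp((v - 31.66) / 3.869) +
                              4.123e-5 * std::exp(-(v - 47.78) / 20.38));
  d.rl[34] = true; d.xinf[34] = xrss;
  d.xtau[34] = 1.865 + 1.0 / (0.06629 * std::exp((v - 34.70) / 7.355) +
                              1.128e-5 * std::exp(-(v - 29.74) / 25.94));
  const double Axrf = 1.0 / (1.0 + std::exp((v + 54.81) / 38.21));
  const double Axrs = 1.0 - Axrf;
  const double xr = Axrf * xrf + Axrs * xrs;
  const double rkr = 1.0 / (1.0 + std::exp((v + 55.0) / 75.0)) *
                     1.0 / (1.0 + std::exp((v - 10.0) / 30.0));
  const double GKr = 0.046 * s[1];
  const double IKr = GKr * std::sqrt(ko / 5.4) * xr * rkr * (v - EK);

  // IKs
  const double xs1ss = 1.0 / (1.0 + std::exp(-(v + 11.60) / 8.932));
  d.rl[35] = true; d.xinf[35] = xs1ss;
  d.xtau[35] = 817.3 + 1.0 / (2.326e-4 * std::exp((v + 48.28) / 17.80) +
                              0.001292 * std::exp(-(v + 210.0) / 230.0));
  d.rl[36] = true; d.xinf[36] = xs1ss;
  d.xtau[36] = 1.0 / (0.01 * std::exp((v - 50.0) / 20.0) +
                      0.0193 * std::exp(-(v + 66.54) / 31.0));
  const double KsCa = 1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / cai, 1.4));
  const double GKs = 0.0034 * s[3];
  const double IKs = GKs * KsCa * xs1 * xs2 * (v - EKs);

  // IK1
  const double xk1ss = 1.0 / (1.0 + std::exp(-(v + 2.5538 * ko + 144.59) /
                                             (1.5692 * ko + 3.8115)));
  d.rl[37] = true; d.xinf[37] = xk1ss;
  d.xtau[37] = 122.2 / (std::exp(-(v + 127.2) / 20.36) +
                        std::exp((v + 236.8) / 69.33));
  const double rk1 = 1.0 / (1.0 + std::exp((v + 105.8 - 2.6 * ko) / 9.493));
  const double GK1 = 0.1908 * s[2];
  const double IK1 = GK1 * std::sqrt(ko) * rk1 * xk1 * (v - EK);

  // INaCa (myoplasmic and subspace components)
  const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
  const double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
  const double kcaon = 1.5e6, kcaoff = 5.0e3;
  const double qna = 0.5224, qca = 0.1670;
  const double hca = std::exp(qca * vfrt), hna = std::exp(qna * vfrt);
  const double zca = 2.0, zna = 1.0, zk = 1.0;
  const double Gncx = 0.0008 * s[7];
  const double KmCaAct = 150.0e-6;
  double INaCa_i, INaCa_ss;
  {
    const double h1 = 1.0 + nai / kna3 * (1.0 + hna);
    const double h2 = (nai * hna) / (kna3 * h1);
    const double h3 = 1.0 / h1;
    const double h4 = 1.0 + nai / kna1 * (1.0 + nai / kna2);
    const double h5 = nai * nai / (h4 * kna1 * kna2);
    const double h6 = 1.0 / h4;
    const double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    const double h8 = nao / (kna3 * hna * h7);
    const double h9 = 1.0 / h7;
    const double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    const double h11 = nao * nao / (h10 * kna1 * kna2);
    const double h12 = 1.0 / h10;
    const double k1 = h12 * cao * kcaon, k2 = kcaoff;
    const double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
    const double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
    const double k5 = kcaoff, k6 = h6 * cai * kcaon;
    const double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
    const double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    const double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    const double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    const double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    const double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
    const double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
    const double allo = 1.0 / (1.0 + (KmCaAct / cai) * (KmCaAct / cai));
    const double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    const double JncxCa = E2 * k2 - E1 * k1;
    INaCa_i = 0.8 * Gncx * allo * (zna * JncxNa + zca * JncxCa);
  }
  {
    const double h1 = 1.0 + nass / kna3 * (1.0 + hna);
    const double h2 = (nass * hna) / (kna3 * h1);
    const double h3 = 1.0 / h1;
    const double h4 = 1.0 + nass / kna1 * (1.0 + nass / kna2);
    const double h5 = nass * nass / (h4 * kna1 * kna2);
    const double h6 = 1.0 / h4;
    const double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    const double h8 = nao / (kna3 * hna * h7);
    const double h9 = 1.0 / h7;
    const double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    const double h11 = nao * nao / (h10 * kna1 * kna2);
    const double h12 = 1.0 / h10;
    const double k1 = h12 * cao * kcaon, k2 = kcaoff;
    const double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
    const double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
    const double k5 = kcaoff, k6 = h6 * cass * kcaon;
    const double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
    const double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    const double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    const double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    const double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    const double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
    const double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
    const double allo = 1.0 / (1.0 + (KmCaAct / cass) * (KmCaAct / cass));
    const double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    const double JncxCa = E2 * k2 - E1 * k1;
    INaCa_ss = 0.2 * Gncx * allo * (zna * JncxNa + zca * JncxCa);
  }

  // INaK
  double INaK;
  {
    const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
    const double k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
    const double Knai0 = 9.073, Knao0 = 27.78, delta = -0.1550;
    const double Knai = Knai0 * std::exp(delta * vfrt / 3.0);
    const double Knao = Knao0 * std::exp((1.0 - delta) * vfrt / 3.0);
    const double Kki = 0.5, Kko = 0.3582;
    const double MgADP = 0.05, MgATP = 9.8, Kmgatp = 1.698e-7;
    const double H = 1.0e-7, eP = 4.2, Khp = 1.698e-7;
    const double Knap = 224.0, Kxkur = 292.0;
    const double P = eP / (1.0 + H / Khp + nai / Knap + ki / Kxkur);
    const double na_i = nai / Knai, na_o = nao / Knao;
    const double a1 = (k1p * na_i * na_i * na_i) /
        (std::pow(1.0 + na_i, 3.0) + std::pow(1.0 + ki / Kki, 2.0) - 1.0);
    const double b1 = k1m * MgADP;
    const double a2 = k2p;
    const double b2 = (k2m * na_o * na_o * na_o) /
        (std::pow(1.0 + na_o, 3.0) + std::pow(1.0 + ko / Kko, 2.0) - 1.0);
    const double a3 = (k3p * (ko / Kko) * (ko / Kko)) /
        (std::pow(1.0 + na_o, 3.0) + std::pow(1.0 + ko / Kko, 2.0) - 1.0);
    const double b3 = (k3m * P * H) / (1.0 + MgATP / Kmgatp);
    const double a4 = (k4p * MgATP / Kmgatp) / (1.0 + MgATP / Kmgatp);
    const double b4 = (k4m * (ki / Kki) * (ki / Kki)) /
        (std::pow(1.0 + na_i, 3.0) + std::pow(1.0 + ki / Kki, 2.0) - 1.0);
    const double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
    const double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
    const double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
    const double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1;
    const double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
    const double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
    const double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
    const double JnakK = 2.0 * (E4 * b1 - E3 * a1);
    const double Pnak = 30.0 * s[6];
    INaK = Pnak * (zna * JnakNa + zk * JnakK);
  }

  // background and pump currents
  const double xkb = 1.0 / (1.0 + std::exp(-(v - 14.48) / 18.34));
  const double GKb = 0.003;
  const double IKb = GKb * xkb * (v - EK);
  const double PNab = 3.75e-10;
  const double INab = PNab * vffrt * (nai * std::exp(vfrt) - nao) /
                      (std::exp(vfrt) - 1.0);
  const double PCab = 2.5e-8;
  const double ICab = PCab * 4.0 * vffrt *
      (cai * std::exp(2.0 * vfrt) - 0.341 * cao) / (std::exp(2.0 * vfrt) - 1.0);
  const double GpCa = 0.0005 * s[8];
  const double IpCa = GpCa * cai / (0.0005 + cai);

  // diffusion fluxes between subspace and myoplasm
  const double JdiffNa = (nass - nai) / 2.0;
  const double JdiffK = (kss - ki) / 2.0;
  const double Jdiff = (cass - cai) / 0.2;

  // SR release (Jrel multiplier scales the driven release flux)
  const double bt = 4.75, a_rel = 0.5 * bt;
  double Jrel_inf = s[9] * a_rel * (-ICaL) / (1.0 + std::pow(1.5 / cajsr, 8.0));
  double tau_rel = bt / (1.0 + 0.0123 / cajsr);
  if (tau_rel < 0.001) tau_rel = 0.001;
  d.rl[38] = true; d.xinf[38] = Jrel_inf; d.xtau[38] = tau_rel;
  const double btp = 1.25 * bt, a_relp = 0.5 * btp;
  double Jrel_infp = s[9] * a_relp * (-ICaL) / (1.0 + std::pow(1.5 / cajsr, 8.0));
  double tau_relp = btp / (1.0 + 0.0123 / cajsr);
  if (tau_relp < 0.001) tau_relp = 0.001;
  d.rl[39] = true; d.xinf[39] = Jrel_infp; d.xtau[39] = tau_relp;
  const double Jrel = (1.0 - fphos) * Jrelnp + fphos * Jrelp;

  // SERCA uptake (Jup multiplier scales the pump, not the leak)
  const double Jupnp = s[10] * 0.004375 * cai / (cai + 0.00092);
  const double Jupp = s[10] * 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
  const double Jleak = 0.0039375 * cansr / 15.0;
  const double Jup = (1.0 - fphos) * Jupnp + fphos * Jupp - Jleak;
  const double Jtr = (cansr - cajsr) / 100.0;

  // buffers (CMDN multiplier scales calmodulin capacity)
  const double cmdnmax = 0.05 * s[11], kmcmdn = 0.00238;
  const double trpnmax = 0.07, kmtrpn = 0.0005;
  const double BSRmax = 0.047, KmBSR = 0.00087;
  const double BSLmax = 1.124, KmBSL = 0.0087;
  const double csqnmax = 10.0, kmcsqn = 0.8;

  d.dx[1] = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab) * Acap /
                (Frdy * vmyo) + JdiffNa * vss / vmyo;
  d.dx[2] = -(ICaNa + 3.0 * INaCa_ss) * Acap / (Frdy * vss) - JdiffNa;
  d.dx[3] = -(Ito + IKr + IKs + IK1 + IKb + Istim - 2.0 * INaK) * Acap /
                (Frdy * vmyo) + JdiffK * vss / vmyo;
  d.dx[4] = -ICaK * Acap / (Frdy * vss) - JdiffK;
  const double Bcai = 1.0 /
      (1.0 + cmdnmax * kmcmdn / ((kmcmdn + cai) * (kmcmdn + cai)) +
       trpnmax * kmtrpn / ((kmtrpn + cai) * (kmtrpn + cai)));
  d.dx[5] = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) * Acap / (2.0 * Frdy * vmyo) -
                    Jup * vnsr / vmyo + Jdiff * vss / vmyo);
  const double Bcass = 1.0 /
      (1.0 + BSRmax * KmBSR / ((KmBSR + cass) * (KmBSR + cass)) +
       BSLmax * KmBSL / ((KmBSL + cass) * (KmBSL + cass)));
  d.dx[6] = Bcass * (-(ICaL - 2.0 * INaCa_ss) * Acap / (2.0 * Frdy * vss) +
                     Jrel * vjsr / vss - Jdiff);
  d.dx[7] = Jup - Jtr * vjsr / vnsr;
  const double Bcajsr = 1.0 /
      (1.0 + csqnmax * kmcsqn / ((kmcsqn + cajsr) * (kmcsqn + cajsr)));
  d.dx[8] = Bcajsr * (Jtr - Jrel);

  d.dx[0] = -(INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
              INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab + Istim);

  if (cur) {
    cur[0] = INa; cur[1] = INaL; cur[2] = Ito; cur[3] = ICaL; cur[4] = ICaNa;
    cur[5] = ICaK; cur[6] = IKr; cur[7] = IKs; cur[8] = IK1;
    cur[9] = INaCa_i + INaCa_ss; cur[10] = INaK; cur[11] = IKb;
    cur[12] = INab; cur[13] = ICab; cur[14] = IpCa; cur[15] = Jrel;
    cur[16] = Jup;
  }
}

// [[Rcpp::export]]
CharacterVector ord_state_names_cpp() {
  return CharacterVector::create(
      "v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
      "m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp",
      "a", "iF", "iS", "ap", "iFp", "iSp",
      "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
      "xrf", "xrs", "xs1", "xs2", "xk1", "Jrelnp", "Jrelp", "CaMKt");
}

// [[Rcpp::export]]
NumericVector ord_initial_state_cpp() {
  NumericVector x = NumericVector::create(
      -87.5, 7.268, 7.268, 144.65, 144.65, 8.6e-5, 8.49e-5, 1.61, 1.56,
      0.0074621, 0.692591, 0.692574, 0.692477, 0.448501, 0.692413,
      0.000194015, 0.496116, 0.265885,
      0.00101185, 0.999542, 0.589579, 0.000515567, 0.999542, 0.641861,
      2.43015e-9, 1.0, 0.910671, 1.0, 0.99982, 0.999977, 0.00267171, 1.0, 1.0,
      8.26608e-6, 0.453268, 0.270492, 0.0001963, 0.996801,
      2.53943e-5, 3.17262e-7, 0.0124065);
  x.names() = ord_state_names_cpp();
  return x;
}

// [[Rcpp::export]]
List ord_rhs_cpp(NumericVector state, NumericVector scaling, double istim) {
  if (state.size() != NSTATE) stop("state must have %d components", NSTATE);
  if (scaling.size() != NSCALE) stop("scaling must have %d components", NSCALE);
  for (int i = 0; i < NSTATE; ++i)
    if (!std::isfinite(state[i]))
      stop("non-finite state component '%s'",
           std::string(as<CharacterVector>(ord_state_names_cpp())[i]));
  Derivs d;
  double cur[17];
  ord_eval(REAL(state), REAL(scaling), istim, d, cur);
  NumericVector dx(NSTATE);
  for (int i = 0; i < NSTATE; ++i) {
    if (d.rl[i]) dx[i] = (d.xinf[i] - state[i]) / d.xtau[i];
    else dx[i] = d.dx[i];
  }
  dx.names() = ord_state_names_cpp();
  NumericVector currents = NumericVector::create(
      _["INa"] = cur[0], _["INaL"] = cur[1], _["Ito"] = cur[2],
      _["ICaL"] = cur[3], _["ICaNa"] = cur[4], _["ICaK"] = cur[5],
      _["IKr"] = cur[6], _["IKs"] = cur[7], _["IK1"] = cur[8],
      _["INaCa"] = cur[9], _["INaK"] = cur[10], _["IKb"] = cur[11],
      _["INab"] = cur[12], _["ICab"] = cur[13], _["IpCa"] = cur[14],
      _["Jrel"] = cur[15], _["Jup"] = cur[16]);
  return List::create(_["deriv"] = dx, _["currents"] = currents);
}

// advance one cell by dt given precomputed Derivs (Rush-Larsen + Euler)
static inline void apply_step(double *x, const Derivs &d, double dt,
                              double dv_extra) {
  x[0] += dt * (d.dx[0] + dv_extra);
  for (int i = 1; i < NSTATE; ++i) {
    if (d.rl[i]) {
      x[i] = d.xinf[i] + (x[i] - d.xinf[i]) * std::exp(-dt / d.xtau[i]);
    } else if (i >= 1 && i <= 8) {
      // concentrations: keep positive; when an Euler step would cross zero
      // use the first-order-consistent multiplicative update instead
      double xn = x[i] + dt * d.dx[i];
      if (xn <= 0.0) xn = x[i] * std::exp(dt * d.dx[i] / x[i]);
      x[i] = (xn > 1e-10) ? xn : 1e-10;
    } else {
      x[i] += dt * d.dx[i];
    }
  }
}

static inline bool state_bad(const double *x) {
  if (!std::isfinite(x[0]) || std::fabs(x[0]) > 200.0) return true;
  for (int i = 1; i < 9; ++i)
    if (!std::isfinite(x[i]) || x[i] <= 0.0) return true;
  return false;
}

// shared driver for a cable of n >= 1 cells (n = 1 is the single cell).
// stim_times are onsets (ms); stimulated cells get stim_amp for stim_dur.
// Records V of record_cell on a uniform dt_out grid from record_from.
// Activation times: first upward crossing of -20 mV at or after act_from.
static List run_cable(NumericMatrix states, NumericVector scaling,
                      double duration, NumericVector stim_times,
                      double stim_amp, double stim_dur,
                      IntegerVector stim_cells, double coupling,
                      double dt_min, double dt_max, double dt_out,
                      double record_from, int record_cell, double act_from) {
  const int ncell = states.nrow();
  if (states.ncol() != NSTATE) stop("state matrix must have %d columns", NSTATE);
  if (record_cell < 0 || record_cell >= ncell) stop("bad recording cell index");
  std::vector<double> x(ncell * NSTATE);
  for (int c = 0; c < ncell; ++c)
    for (int i = 0; i < NSTATE; ++i) x[c * NSTATE + i] = states(c, i);
  std::vector<bool> is_stim(ncell, false);
  for (int k = 0; k < stim_cells.size(); ++k) {
    int c = stim_cells[k];
    if (c < 0 || c >= ncell) stop("stimulated cell index out of range");
    is_stim[c] = true;
  }
  // explicit diffusion stability cap
  double dt_cap = dt_max;
  if (ncell > 1) {
    double lim = 0.9 / (4.0 * coupling);
    if (lim < dt_cap) dt_cap = lim;
  }

  const int nout = (int)std::floor((duration - record_from) / dt_out) + 1;
  NumericVector t_out(nout), v_out(nout);
  for (int k = 0; k < nout; ++k) t_out[k] = record_from + k * dt_out;
  int next_out = 0;
  double v_prev_rec = x[record_cell * NSTATE + 0];
  NumericVector act(ncell, NA_REAL);
  std::vector<double> v_prev(ncell);

  std::vector<Derivs> dv(ncell);
  const double *s = REAL(scaling);
  double t = 0.0;
  int next_stim = 0;
  const int nstim = stim_times.size();
  bool ok = true;

  while (t < duration - 1e-9) {
    // stimulus current active now?
    while (next_stim < nstim && t >= stim_times[next_stim] + stim_dur - 1e-12)
      ++next_stim;
    bool in_stim = next_stim < nstim && t >= stim_times[next_stim] - 1e-12 &&
                   t < stim_times[next_stim] + stim_dur - 1e-12;
    double istim = in_stim ? stim_amp : 0.0;

    double max_dv = 0.0;
    for (int c = 0; c < ncell; ++c) {
      v_prev[c] = x[c * NSTATE + 0];
      ord_eval(&x[c * NSTATE], s, is_stim[c] ? istim : 0.0, dv[c], nullptr);
    }
    std::vector<double> dv_extra(ncell, 0.0);
    if (ncell > 1) {
      for (int c = 0; c < ncell; ++c) {
        double vl = (c > 0) ? x[(c - 1) * NSTATE] : x[c * NSTATE];
        double vr = (c < ncell - 1) ? x[(c + 1) * NSTATE] : x[c * NSTATE];
        dv_extra[c] = coupling * (vl - 2.0 * x[c * NSTATE] + vr);
      }
    }
    for (int c = 0; c < ncell; ++c) {
      double adv = std::fabs(dv[c].dx[0] + dv_extra[c]);
      if (adv > max_dv) max_dv = adv;
    }
    // target voltage change per step: 0.2 mV
    double dt = (max_dv > 0.0) ? 0.2 / max_dv : dt_cap;
    // and at most 3% relative change of the calcium pools per step
    for (int c = 0; c < ncell; ++c) {
      const double *xc = &x[c * NSTATE];
      static const int ca_idx[4] = {5, 6, 7, 8};  // cai, cass, cansr, cajsr
      for (int k = 0; k < 4; ++k) {
        int i = ca_idx[k];
        double rate = std::fabs(dv[c].dx[i]);
        if (rate > 0) {
          double lim = 0.03 * xc[i] / rate;
          if (lim < dt) dt = lim;
        }
      }
    }
    if (dt > dt_cap) dt = dt_cap;
    if (dt < dt_min) dt = dt_min;
    // do not step across stimulus onset/offset or the end of the run
    if (next_stim < nstim) {
      double on = stim_times[next_stim];
      if (t < on - 1e-12 && t + dt > on) dt = on - t;
      double off = on + stim_dur;
      if (in_stim && t + dt > off) dt = off - t;
    }
    if (t + dt > duration) dt = duration - t;

    for (int c = 0; c < ncell; ++c)
      apply_step(&x[c * NSTATE], dv[c], dt, dv_extra[c]);
    t += dt;

    for (int c = 0; c < ncell; ++c) {
      if (state_bad(&x[c * NSTATE])) { ok = false; break; }
      double vc = x[c * NSTATE];
      if (t >= act_from && R_IsNA(act[c]) && v_prev[c] < -20.0 && vc >= -20.0) {
        // linear interpolation of the -20 mV crossing
        double frac = (-20.0 - v_prev[c]) / (vc - v_prev[c]);
        act[c] = t - dt + frac * dt;
      }
    }
    if (!ok) break;

    double v_rec = x[record_cell * NSTATE];
    while (next_out < nout && t_out[next_out] <= t + 1e-9) {
      double tt = t_out[next_out];
      double frac = (dt > 0) ? (tt - (t - dt)) / dt : 0.0;
      if (frac < 0) frac = 0;
      if (frac > 1) frac = 1;
      v_out[next_out] = v_prev_rec + frac * (v_rec - v_prev_rec);
      ++next_out;
    }
    v_prev_rec = v_rec;
  }
  if (ok && next_out < nout) {
    for (int k = next_out; k < nout; ++k) v_out[k] = v_prev_rec;
  }
  NumericMatrix final_states(ncell, NSTATE);
  for (int c = 0; c < ncell; ++c)
    for (int i = 0; i < NSTATE; ++i) final_states(c, i) = x[c * NSTATE + i];
  colnames(final_states) = ord_state_names_cpp();
  return List::create(_["time"] = t_out, _["v"] = v_out,
                      _["final_states"] = final_states,
                      _["activation"] = act, _["ok"] = ok);
}

// [[Rcpp::export]]
List ord_run_cpp(NumericVector state, NumericVector scaling, double duration,
                 NumericVector stim_times, double stim_amp, double stim_dur,
                 double dt_min, double dt_max, double dt_out,
                 double record_from) {
  if (state.size() != NSTATE) stop("state must have %d components", NSTATE);
  NumericMatrix m(1, NSTATE);
  for (int i = 0; i < NSTATE; ++i) m(0, i) = state[i];
  IntegerVector sc = IntegerVector::create(0);
  List res = run_cable(m, scaling, duration, stim_times, stim_amp, stim_dur,
                       sc, 0.0, dt_min, dt_max, dt_out, record_from, 0,
                       record_from);
  NumericMatrix fs = res["final_states"];
  NumericVector out(NSTATE);
  for (int i = 0; i < NSTATE; ++i) out[i] = fs(0, i);
  out.names() = ord_state_names_cpp();
  return List::create(_["time"] = res["time"], _["v"] = res["v"],
                      _["final_state"] = out, _["ok"] = res["ok"]);
}

// [[Rcpp::export]]
List cable_run_cpp(NumericMatrix states, NumericVector scaling,
                   double duration, NumericVector stim_times, double stim_amp,
                   double stim_dur, IntegerVector stim_cells, double coupling,
                   double dt_min, double dt_max, double dt_out,
                   double record_from, int record_cell, double act_from) {
  return run_cable(states, scaling, duration, stim_times, stim_amp, stim_dur,
                   stim_cells, coupling, dt_min, dt_max, dt_out, record_from,
                   record_cell, act_from);
}
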