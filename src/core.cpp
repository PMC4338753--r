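// Core integration engine: branched-cable backward-Euler voltage solve
// (Hines elimination over the tree), Hodgkin-Huxley gate updates by
// exponential Euler, Markov schemes by implicit Euler on the master
// equation, and submembrane calcium shells with diffusible buffers and a
// generic extrusion pump.  Units throughout: mV, ms, nA, uS, nF, mM, um.
#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// channel type codes (kept in step with pc_channel_names() on the R side)
// ---------------------------------------------------------------------------
enum {
  CH_NAV16 = 0, CH_KV11, CH_KV15, CH_KV33, CH_KV34, CH_KV43, CH_KIR2,
  CH_KCA11, CH_KCA22, CH_KCA31, CH_CAV21, CH_CAV31, CH_CAV32, CH_CAV33,
  CH_HCN1, CH_TRP, N_TYPES
};

static const char *TYPE_NAMES[N_TYPES] = {
  "Nav1.6", "Kv1.1", "Kv1.5", "Kv3.3", "Kv3.4", "Kv4.3", "Kir2.x",
  "KCa1.1", "KCa2.2", "KCa3.1", "Cav2.1", "Cav3.1", "Cav3.2", "Cav3.3",
  "HCN1", "TRP"
};

// experimental temperature of the source kinetics (degC); rates are scaled
// to the simulation temperature with Q10 = 3 (except where the source model
// carries its own factor, handled inside the rate functions)
static const double TYPE_TEXP[N_TYPES] = {
  22, 22, 37, 22, 22, 25.5, 20, 22, 23, 37, 23, 21, 24, 28, 37, 37
};

static const int HH_NGATES[N_TYPES] = {
  0, 1, 3, 1, 2, 2, 1, 3, 0, 1, 1, 2, 2, 2, 1, 0
};
static const int HH_EXPO[N_TYPES][3] = {
  {0,0,0}, {4,0,0}, {3,1,1}, {4,0,0}, {3,1,0}, {3,1,0}, {1,0,0},
  {3,2,1}, {0,0,0}, {1,0,0}, {1,0,0}, {2,1,0}, {2,1,0}, {2,1,0},
  {1,0,0}, {0,0,0}
};
// gates whose kinetics depend on intracellular calcium (recomputed each step)
static const int HH_CADEP[N_TYPES][3] = {
  {0,0,0}, {0,0,0}, {0,0,0}, {0,0,0}, {0,0,0}, {0,0,0}, {0,0,0},
  {0,1,0}, {0,0,0}, {1,0,0}, {0,0,0}, {0,0,0}, {0,0,0}, {0,0,0},
  {0,0,0}, {0,0,0}
};
static const bool TYPE_ISCA[N_TYPES] = {
  false, false, false, false, false, false, false, false, false, false,
  true, true, true, true, false, false
};
static const int MARKOV_NSTATES[N_TYPES] = {
  13, 0, 0, 0, 0, 0, 0, 0, 6, 0, 0, 0, 0, 0, 0, 0
};

static inline double q10_3(double tsim, double texp) {
  return std::pow(3.0, (tsim - texp) / 10.0);
}

// GHK constant-field calcium flux: current in nA per unit (cm^3/s) of
// open permeability-area product, concentrations in mM, v in mV
static inline double ghk_flux(double v, double ci, double co, double rt) {
  const double F = 96485.332;
  double xi = 2.0 * F * v * 1e-3 / rt;
  if (std::fabs(xi) < 1e-6) xi = (xi >= 0) ? 1e-6 : -1e-6;
  double ef = std::exp(-xi);
  double ratio = (ci - co * ef) / (1.0 - ef); // mol/m^3
  double vv = xi * rt / (2.0 * F);            // volts, consistent with xi
  return 1e3 * (4.0 * F * F * vv / rt) * ratio; // nA per cm^3/s
}

// ---------------------------------------------------------------------------
// Hodgkin-Huxley rate functions: fill inf[] and tau[] (ms) per gate
// ---------------------------------------------------------------------------
static void hh_inf_tau(int type, double v, double cai, double celsius,
                       double *inf, double *tau) {
  const double TAU_MIN = 1e-4;
  switch (type) {
  case CH_KV11: { // n^4 delayed rectifier, low threshold
    double qt = q10_3(celsius, 22.0);
    double a = 0.12889 * std::exp((v + 45.0) / 33.90877);
    double b = 0.12889 * std::exp(-(v + 45.0) / 12.42101);
    inf[0] = a / (a + b);
    tau[0] = 1.0 / ((a + b) * qt);
    break;
  }
  case CH_KV15: { // m^3 n u ultrarapid delayed rectifier (atrial kinetics)
    double a = 0.65 / (std::exp(-(v + 10.0) / 8.5) + std::exp(-(v - 30.0) / 59.0));
    double b = 0.65 / (2.5 + std::exp((v + 82.0) / 17.0));
    inf[0] = 1.0 / (1.0 + std::exp(-(v + 30.3) / 9.6));
    tau[0] = 1.0 / ((a + b) * 3.0);
    double an = 0.001 / (2.4 + 10.9 * std::exp(-(v + 90.0) / 78.0));
    double bn = 0.001 * std::exp((v - 168.0) / 16.0);
    inf[1] = 0.25 + 1.0 / (1.35 + std::exp((v + 7.0) / 14.0));
    tau[1] = 1.0 / ((an + bn) * 3.0);
    inf[2] = 0.1 + 1.0 / (1.1 + std::exp((v + 7.0) / 14.0));
    tau[2] = 6800.0;
    break;
  }
  case CH_KV33: { // n^4 high-threshold delayed rectifier
    double qt = q10_3(celsius, 22.0);
    double a = 0.22 * std::exp((v + 16.0) / 26.5);
    double b = 0.22 * std::exp(-(v + 16.0) / 26.5);
    inf[0] = a / (a + b);
    tau[0] = 1.0 / ((a + b) * qt);
    break;
  }
  case CH_KV34: { // m^3 h fast TEA-sensitive K current (Purkinje)
    double qt = q10_3(celsius, 22.0);
    inf[0] = 1.0 / (1.0 + std::exp(-(v + 24.0) / 15.4));
    double mt;
    if (v < -35.0)
      mt = (3.4225e-5 + 4.98e-3 * std::exp(v / 28.29)) * 3.0;
    else
      mt = 1.2851e-4 + 1.0 / (std::exp((v + 100.7) / 12.9) +
                              std::exp(-(v - 56.0) / 23.1));
    tau[0] = 1000.0 * mt / qt;
    inf[1] = 0.31 + 0.69 / (1.0 + std::exp((v + 5.802) / 11.2));
    double ht;
    if (v > 0.0)
      ht = 0.0012 + 0.0023 * std::exp(-0.141 * v);
    else {
      double z = (v + 56.3) / 49.62;
      ht = 1.2202e-5 + 0.012 * std::exp(-z * z);
    }
    tau[1] = 1000.0 * ht / qt;
    break;
  }
  case CH_KV43: { // a^3 b A-type (granule-cell kinetics)
    double qt = q10_3(celsius, 25.5);
    double aa = 0.8147 / (std::exp((v + 9.17203) / -23.32708) + 1.0);
    double ba = 0.1655 * std::exp(-(v + 18.27914) / 19.47175);
    inf[0] = aa / (aa + ba);
    tau[0] = 1.0 / ((aa + ba) * qt);
    double ab = 0.0368 / (std::exp((v + 111.33209) / 12.8433) + 1.0);
    double bb = 0.0345 / (std::exp((v + 49.9537) / -8.90123) + 1.0);
    inf[1] = ab / (ab + bb);
    tau[1] = 1.0 / ((ab + bb) * qt);
    break;
  }
  case CH_KIR2: { // d inward rectifier
    double qt = q10_3(celsius, 20.0);
    double a = 0.13289 * std::exp(-(v + 83.94) / 24.3902);
    double b = 0.16994 * std::exp((v + 83.94) / 35.714);
    inf[0] = a / (a + b);
    tau[0] = 1.0 / ((a + b) * qt);
    break;
  }
  case CH_KCA11: { // BK: m^3 z^2 h, z is Ca-gated
    double qt = q10_3(celsius, 22.0);
    inf[0] = 1.0 / (1.0 + std::exp(-(v + 28.9) / 6.2));
    tau[0] = 1000.0 * (0.000505 + 1.0 / (std::exp((v + 86.4) / 10.1) +
                                         std::exp((-33.3 - v) / 10.0))) / qt;
    inf[1] = 1.0 / (1.0 + 0.001 / std::max(cai, 1e-9));
    tau[1] = 1.0; // Ca-binding step, temperature factor not applied (source)
    inf[2] = 0.085 + 0.915 / (1.0 + std::exp((v + 32.0) / 5.8));
    tau[2] = 1000.0 * (0.0019 + 1.0 / (std::exp((v + 48.5) / 5.2) +
                                       std::exp((-54.2 - v) / 12.9))) / qt;
    break;
  }
  case CH_KCA31: { // single Y gate, joint V/Ca activation (mitral kinetics)
    double vdep = std::exp((v + 70.0) / 27.0);
    double cdep;
    if (cai < 0.01) {
      double x = 0.015 - cai;
      cdep = 500.0 * x / (std::exp(x / 0.0013) - 1.0);
    } else {
      cdep = 500.0 * 0.005 / (std::exp(0.005 / 0.0013) - 1.0);
    }
    double a = vdep * cdep;
    double b = 0.05;
    inf[0] = a / (a + b);
    tau[0] = 1.0 / (a + b);
    break;
  }
  case CH_CAV21: { // P-type HVA, activation gates (room-temp kinetics)
    double qt = q10_3(celsius, 23.0);
    inf[0] = 1.0 / (1.0 + std::exp((v + 29.5) / -8.5));
    if (v >= -40.0) {
      double z = v + 26.798;
      tau[0] = (0.2702 + 1.1622 * std::exp(-z * z / 164.19)) / qt;
    } else {
      tau[0] = 0.6923 * std::exp(v / 1089.372) / qt;
    }
    break;
  }
  case CH_CAV31: { // T-type m^2 h (room-temp kinetics)
    double qt = q10_3(celsius, 21.0);
    inf[0] = 1.0 / (1.0 + std::exp(-(v + 52.0) / 5.0));
    tau[0] = (1.0 + 1.0 / (std::exp((v + 40.0) / 9.0) +
                           std::exp(-(v + 102.0) / 18.0))) / qt;
    inf[1] = 1.0 / (1.0 + std::exp((v + 72.0) / 7.0));
    tau[1] = (15.0 + std::exp(-(v + 32.0) / 7.0)) / qt;
    break;
  }
  case CH_CAV32: { // T-type m^2 h (thalamic kinetics), 2 mV screening shift
    double shift = 2.0, vs = v + shift;
    double phim = std::pow(5.0, (celsius - 24.0) / 10.0);
    double phih = std::pow(3.0, (celsius - 24.0) / 10.0);
    inf[0] = 1.0 / (1.0 + std::exp(-(vs + 54.8) / 7.4));
    tau[0] = (1.9 + 1.0 / (std::exp((vs + 37.0) / 11.9) +
                           std::exp(-(vs + 131.6) / 21.0))) / phim;
    inf[1] = 1.0 / (1.0 + std::exp((vs + 85.5) / 7.18));
    tau[1] = (13.7 + (1942.0 + std::exp(-(vs + 164.0) / 9.2)) /
                         (1.0 + std::exp((vs + 89.3) / 3.73))) / phih;
    break;
  }
  case CH_CAV33: { // T-type n^2 l (CA3 kinetics)
    double qt = std::pow(2.3, (celsius - 28.0) / 10.0);
    inf[0] = 1.0 / (1.0 + std::exp(-(v + 41.5) / 6.2));
    inf[1] = 1.0 / (1.0 + std::exp((v + 69.8) / 6.1));
    if (v > -60.0) {
      tau[0] = (7.2 + 0.02 * std::exp(-v / 14.7)) / qt;
      tau[1] = (79.5 + 2.0 * std::exp(-v / 9.3)) / qt;
    } else {
      tau[0] = (0.875 * std::exp((v + 120.0) / 41.0)) / qt;
      tau[1] = 260.0 / qt;
    }
    break;
  }
  case CH_HCN1: { // single activation gate, opens on hyperpolarization
    inf[0] = 1.0 / (1.0 + std::exp((v + 90.3) / 9.67));
    tau[0] = 1.0 / (0.0018 * (std::exp(-(v + 58.7) / 22.0) +
                              std::exp((v + 58.7) / 7.14)));
    break;
  }
  default:
    break;
  }
  for (int g = 0; g < HH_NGATES[type]; ++g) {
    if (tau[g] < TAU_MIN) tau[g] = TAU_MIN;
    // clamp to the probability range (some printed steady-state forms
    // slightly exceed 1 at extreme voltages)
    if (inf[g] < 0.0) inf[g] = 0.0;
    if (inf[g] > 1.0) inf[g] = 1.0;
  }
}

// ---------------------------------------------------------------------------
// Markov schemes: rate matrix Q (Q[i][j] = transition rate i -> j, 1/ms)
// ---------------------------------------------------------------------------

// 13-state resurgent Na channel: C1-C5, O, B(locked), I1-I6
static void nav16_Q(double v, double celsius, double Q[13][13]) {
  const double qt = q10_3(celsius, 22.0);
  const double alpha = 150.0, beta = 3.0, gamma = 150.0, delta = 40.0;
  const double eps = 1.75, zeta = 0.03;
  const double x1 = 20.0, x2 = -20.0, x6 = -25.0;
  const double Con = 0.005, Coff = 0.5, Oon = 0.75, Ooff = 0.005;
  const double alfac = std::pow(Oon / Con, 0.25);   // 3.4996
  const double btfac = std::pow(Ooff / Coff, 0.25); // 0.3162
  const double ev1 = std::exp(v / x1), ev2 = std::exp(v / x2);
  const double ev6 = std::exp(v / x6);
  std::memset(Q, 0, sizeof(double) * 13 * 13);
  // indices: 0..4 C1..C5, 5 O, 6 B, 7..11 I1..I5, 12 I6
  for (int i = 0; i < 4; ++i) {
    Q[i][i + 1] = (4 - i) * alpha * ev1 * qt;          // C_i -> C_{i+1}
    Q[i + 1][i] = (i + 1) * beta * ev2 * qt;           // back
    Q[7 + i][8 + i] = (4 - i) * alpha * alfac * ev1 * qt; // I chain forward
    Q[8 + i][7 + i] = (i + 1) * beta * btfac * ev2 * qt;
  }
  Q[4][5] = gamma * qt;  Q[5][4] = delta * qt;   // C5 <-> O
  Q[5][6] = eps * qt;    Q[6][5] = zeta * ev6 * qt; // O <-> B (open block)
  Q[11][12] = gamma * qt; Q[12][11] = delta * qt; // I5 <-> I6
  for (int i = 0; i < 5; ++i) {
    Q[i][7 + i] = Con * std::pow(alfac, i) * qt;   // C_i -> I_i
    Q[7 + i][i] = Coff * std::pow(btfac, i) * qt;  // I_i -> C_i
  }
  Q[5][12] = Oon * qt;  Q[12][5] = Ooff * qt;     // O <-> I6
}

// 6-state SK2 channel: c1-c4, o1, o2; Ca-dependent forward binding
static void kca22_Q(double cai, double celsius, double Q[6][6]) {
  const double qt = q10_3(celsius, 23.0);
  const double invc1 = 80e-3, invc2 = 80e-3, invc3 = 200e-3;
  const double invo1 = 1.0, invo2 = 100e-3;
  const double diro1 = 160e-3, diro2 = 1.2;
  const double dirc2 = 200.0, dirc3 = 160.0, dirc4 = 80.0; // 1/(mM ms)
  std::memset(Q, 0, sizeof(double) * 6 * 6);
  Q[0][1] = dirc2 * cai * qt; Q[1][0] = invc1 * qt;
  Q[1][2] = dirc3 * cai * qt; Q[2][1] = invc2 * qt;
  Q[2][3] = dirc4 * cai * qt; Q[3][2] = invc3 * qt;
  Q[2][4] = diro1 * qt;       Q[4][2] = invo1 * qt;
  Q[3][5] = diro2 * qt;       Q[5][3] = invo2 * qt;
}

static void markov_Q(int type, double v, double cai, double celsius,
                     std::vector<double> &Q) {
  if (type == CH_NAV16) {
    double q[13][13];
    nav16_Q(v, celsius, q);
    Q.assign(&q[0][0], &q[0][0] + 169);
  } else if (type == CH_KCA22) {
    double q[6][6];
    kca22_Q(cai, celsius, q);
    Q.assign(&q[0][0], &q[0][0] + 36);
  } else {
    stop("not a Markov channel type");
  }
}

static void markov_conducting(int type, std::vector<int> &cond) {
  if (type == CH_NAV16) cond = {5};
  else cond = {4, 5};
}

// dense solve A x = b (in place, partial pivoting); n <= 13
static void dense_solve(int n, double *A, double *b) {
  for (int k = 0; k < n; ++k) {
    int piv = k;
    double amax = std::fabs(A[k * n + k]);
    for (int i = k + 1; i < n; ++i) {
      double a = std::fabs(A[i * n + k]);
      if (a > amax) { amax = a; piv = i; }
    }
    if (piv != k) {
      for (int j = k; j < n; ++j) std::swap(A[k * n + j], A[piv * n + j]);
      std::swap(b[k], b[piv]);
    }
    double d = A[k * n + k];
    for (int i = k + 1; i < n; ++i) {
      double f = A[i * n + k] / d;
      if (f == 0.0) continue;
      for (int j = k; j < n; ++j) A[i * n + j] -= f * A[k * n + j];
      b[i] -= f * b[k];
    }
  }
  for (int k = n - 1; k >= 0; --k) {
    double s = b[k];
    for (int j = k + 1; j < n; ++j) s -= A[k * n + j] * b[j];
    b[k] = s / A[k * n + k];
  }
}

// implicit (backward Euler) step of the master equation, then renormalize
static void markov_be_step(int n, const std::vector<double> &Q, double *p,
                           double dt, double *scratchA, double *scratchB) {
  // A = I - dt * Q^T
  for (int i = 0; i < n; ++i) {
    double qout = 0.0;
    for (int j = 0; j < n; ++j) qout += Q[i * n + j];
    for (int j = 0; j < n; ++j)
      scratchA[i * n + j] = -dt * Q[j * n + i];
    // diagonal of Q is -sum of row; fold it in via Q^T structure:
    scratchA[i * n + i] = 1.0 + dt * qout;
  }
  std::memcpy(scratchB, p, sizeof(double) * n);
  dense_solve(n, scratchA, scratchB);
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    if (scratchB[i] < 0.0) scratchB[i] = 0.0;
    s += scratchB[i];
  }
  for (int i = 0; i < n; ++i) p[i] = scratchB[i] / s;
}

// ---------------------------------------------------------------------------
// R-facing kinetics utilities
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector cpp_channel_names() {
  CharacterVector out(N_TYPES);
  for (int i = 0; i < N_TYPES; ++i) out[i] = TYPE_NAMES[i];
  return out;
}

// [[Rcpp::export]]
List cpp_channel_info(int type) {
  if (type < 0 || type >= N_TYPES) stop("bad channel type code");
  bool markov = MARKOV_NSTATES[type] > 0;
  IntegerVector expo(HH_NGATES[type]);
  LogicalVector cadep(HH_NGATES[type]);
  for (int g = 0; g < HH_NGATES[type]; ++g) {
    expo[g] = HH_EXPO[type][g];
    cadep[g] = HH_CADEP[type][g] != 0;
  }
  return List::create(
    _["name"] = TYPE_NAMES[type], _["kind"] = markov ? "markov" : "hh",
    _["n_gates"] = HH_NGATES[type], _["exponents"] = expo,
    _["ca_dependent"] = cadep, _["n_states"] = MARKOV_NSTATES[type],
    _["t_exp"] = TYPE_TEXP[type], _["is_ca_ion"] = TYPE_ISCA[type]);
}

// [[Rcpp::export]]
List cpp_hh_inf_tau(int type, NumericVector v, double cai, double celsius) {
  int ng = HH_NGATES[type];
  if (ng == 0) stop("channel has no HH gates");
  NumericMatrix inf(v.size(), ng), tau(v.size(), ng);
  double fi[3], ft[3];
  for (int i = 0; i < v.size(); ++i) {
    hh_inf_tau(type, v[i], cai, celsius, fi, ft);
    for (int g = 0; g < ng; ++g) { inf(i, g) = fi[g]; tau(i, g) = ft[g]; }
  }
  return List::create(_["inf"] = inf, _["tau"] = tau);
}

// [[Rcpp::export]]
NumericMatrix cpp_markov_rate_matrix(int type, double v, double cai,
                                     double celsius) {
  int n = MARKOV_NSTATES[type];
  if (n == 0) stop("not a Markov channel type");
  std::vector<double> Q;
  markov_Q(type, v, cai, celsius, Q);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    double qout = 0.0;
    for (int j = 0; j < n; ++j)
      if (j != i) { out(i, j) = Q[i * n + j]; qout += Q[i * n + j]; }
    out(i, i) = -qout;
  }
  std::vector<int> cond;
  markov_conducting(type, cond);
  out.attr("conducting") = IntegerVector(cond.begin(), cond.end());
  return out;
}

// integrate a single channel under a voltage-clamp waveform; returns the
// open fraction and the full state trajectory
// [[Rcpp::export]]
List cpp_clamp_channel(int type, NumericVector v, NumericVector cai,
                       double dt, double celsius, double v_init,
                       double cai_init) {
  int nt = v.size();
  if (cai.size() != nt) stop("v and cai must have equal length");
  int nm = MARKOV_NSTATES[type];
  NumericVector open(nt);
  if (nm > 0) {
    std::vector<double> p(nm, 0.0), Q, A(nm * nm), b(nm);
    std::vector<int> cond;
    markov_conducting(type, cond);
    // settle to steady state at the holding potential
    p[0] = 1.0;
    markov_Q(type, v_init, cai_init, celsius, Q);
    for (int k = 0; k < 4000; ++k)
      markov_be_step(nm, Q, p.data(), 2.5, A.data(), b.data());
    NumericMatrix states(nt, nm);
    for (int i = 0; i < nt; ++i) {
      markov_Q(type, v[i], cai[i], celsius, Q);
      markov_be_step(nm, Q, p.data(), dt, A.data(), b.data());
      double o = 0.0;
      for (int c : cond) o += p[c];
      open[i] = o;
      for (int s = 0; s < nm; ++s) states(i, s) = p[s];
    }
    return List::create(_["open"] = open, _["states"] = states);
  }
  int ng = HH_NGATES[type];
  double x[3], fi[3], ft[3];
  hh_inf_tau(type, v_init, cai_init, celsius, fi, ft);
  for (int g = 0; g < ng; ++g) x[g] = fi[g];
  NumericMatrix states(nt, std::max(ng, 1));
  for (int i = 0; i < nt; ++i) {
    hh_inf_tau(type, v[i], cai[i], celsius, fi, ft);
    double o = 1.0;
    for (int g = 0; g < ng; ++g) {
      x[g] = fi[g] + (x[g] - fi[g]) * std::exp(-dt / ft[g]);
      for (int e = 0; e < HH_EXPO[type][g]; ++e) o *= x[g];
      states(i, g) = x[g];
    }
    open[i] = (ng > 0) ? o : 1.0;
  }
  return List::create(_["open"] = open, _["states"] = states);
}

// ---------------------------------------------------------------------------
// simulation engine
// ---------------------------------------------------------------------------

struct Stim {
  int comp;
  int kind; // 0 step, 1 piecewise linear
  std::vector<double> t, a;
  double amp, t0, t1;
  double current(double time) const {
    if (kind == 0) return (time >= t0 && time < t1) ? amp : 0.0;
    int n = (int)t.size();
    if (time <= t[0] || time >= t[n - 1]) return 0.0;
    int lo = 0;
    while (lo + 1 < n && t[lo + 1] < time) ++lo;
    double f = (time - t[lo]) / (t[lo + 1] - t[lo]);
    return a[lo] + f * (a[lo + 1] - a[lo]);
  }
};

struct HHTable {
  // per gate: inf and exp(-dt/tau) on a voltage grid
  static constexpr double VMIN = -150.0, VMAX = 100.0, DV = 0.05;
  int np = 0, ng = 0;
  std::vector<double> inf, edt; // np x ng, column-major by gate
  void build(int type, double celsius, double dt) {
    ng = HH_NGATES[type];
    np = (int)std::floor((VMAX - VMIN) / DV) + 1;
    inf.resize((size_t)np * ng);
    edt.resize((size_t)np * ng);
    double fi[3], ft[3];
    for (int i = 0; i < np; ++i) {
      double v = VMIN + i * DV;
      hh_inf_tau(type, v, 1e-4, celsius, fi, ft);
      for (int g = 0; g < ng; ++g) {
        inf[(size_t)g * np + i] = fi[g];
        edt[(size_t)g * np + i] = std::exp(-dt / ft[g]);
      }
    }
  }
  inline void at(double v, int g, double &xi, double &xe) const {
    double u = (v - VMIN) / DV;
    if (u < 0.0) u = 0.0;
    if (u > np - 1.001) u = np - 1.001;
    int i0 = (int)u;
    double f = u - i0;
    const double *ci = &inf[(size_t)g * np];
    const double *ce = &edt[(size_t)g * np];
    xi = ci[i0] + f * (ci[i0 + 1] - ci[i0]);
    xe = ce[i0] + f * (ce[i0 + 1] - ce[i0]);
  }
};

struct ChanInst {
  int type;
  bool markov, isca;
  int ng, nstate;
  double erev; // fixed reversal (ignored for Ca-carrying channels)
  std::vector<int> comp;
  std::vector<double> gbar; // uS
  std::vector<double> state; // gates (ncomp x ng) or occupancies
  HHTable tab;
  bool any_cadep = false;
};

struct CaComp {
  int comp;
  int ns;
  std::vector<double> vol;   // um^3 per shell (0 = outermost)
  std::vector<double> gd;    // diffusion geometry A/dr (um) between shells
  double pump_vmax;          // mM um^3 / ms at saturation
  double jleak;              // constant influx balancing the pump at rest
  std::vector<double> free_ca;          // mM
  std::vector<std::vector<double>> bnd; // per buffer, mM bound
};

// [[Rcpp::export]]
List cpp_sim_run(List sys, double dt, double duration, List stims,
                 IntegerVector rec_comp, double record_from, int rec_every,
                 bool record_ca, double v_init, double celsius,
                 Nullable<List> vclamp_) {
  IntegerVector parent = sys["parent"];
  NumericVector cm = sys["cm"], gleak = sys["gleak"], eleak = sys["eleak"],
                gax = sys["gax"];
  const int n = parent.size();
  List chan = sys["chan"];
  double cao = sys["cao"];
  double carest = sys["carest"];
  const double ghk_coef = 1000.0 * 8.31446 * (celsius + 273.15) /
                          (2.0 * 96485.332); // mV
  const double RT = 8.31446 * (celsius + 273.15);
  const double KCAF = 1e6 / (2.0 * 96485.332); // mM um^3 / (nA ms)
  const double KPUMP = sys.containsElementNamed("pump_kd") ?
      (double)as<double>(sys["pump_kd"]) : 5e-4; // mM, pump half-saturation
  // calcium permeation: 1 = GHK constant-field flux (gbar = P*A, cm^3/s),
  // 0 = ohmic with GHK-updated reversal (gbar in uS)
  const int ca_ghk = sys.containsElementNamed("ca_ghk") ?
      (int)as<int>(sys["ca_ghk"]) : 1;

  // --- channels ---
  std::vector<ChanInst> ch;
  for (int k = 0; k < chan.size(); ++k) {
    List e = chan[k];
    ChanInst ci;
    ci.type = e["type"];
    ci.erev = e["erev"];
    ci.comp = as<std::vector<int>>(e["comp"]);
    ci.gbar = as<std::vector<double>>(e["gbar"]);
    ci.markov = MARKOV_NSTATES[ci.type] > 0;
    ci.isca = TYPE_ISCA[ci.type];
    ci.ng = HH_NGATES[ci.type];
    ci.nstate = MARKOV_NSTATES[ci.type];
    if (!ci.markov && ci.ng > 0) {
      ci.tab.build(ci.type, celsius, dt);
      for (int g = 0; g < ci.ng; ++g)
        if (HH_CADEP[ci.type][g]) ci.any_cadep = true;
    }
    ch.push_back(std::move(ci));
  }

  // --- calcium compartments ---
  List calist = sys["ca"];
  List bufs = sys["buffers"];
  NumericVector btot = bufs["btot"], kon = bufs["kon"], koff = bufs["koff"],
                bdif = bufs["dif"];
  double dca = bufs["dca"];
  int nbuf = btot.size();
  int nsub = sys.containsElementNamed("ca_substeps") ?
             (int)as<int>(sys["ca_substeps"]) : 2;
  std::vector<CaComp> cac;
  std::vector<int> ca_index(n, -1); // comp -> index into cac
  for (int k = 0; k < calist.size(); ++k) {
    List e = calist[k];
    CaComp cc;
    cc.comp = e["comp"];
    cc.vol = as<std::vector<double>>(e["vol"]);
    cc.gd = as<std::vector<double>>(e["gd"]);
    cc.pump_vmax = e["pump_vmax"];
    cc.ns = (int)cc.vol.size();
    cc.jleak = cc.pump_vmax * carest / (carest + KPUMP);
    cc.free_ca.assign(cc.ns, carest);
    cc.bnd.resize(nbuf);
    for (int b = 0; b < nbuf; ++b) {
      double kd = koff[b] / kon[b];
      cc.bnd[b].assign(cc.ns, btot[b] * carest / (carest + kd));
    }
    ca_index[cc.comp] = (int)cac.size();
    cac.push_back(std::move(cc));
  }

  // --- stimuli ---
  std::vector<Stim> stim;
  for (int k = 0; k < stims.size(); ++k) {
    List e = stims[k];
    Stim s;
    s.comp = e["comp"];
    s.kind = e["kind"];
    if (s.kind == 0) {
      s.t0 = e["t0"]; s.t1 = e["t1"]; s.amp = e["amp"];
    } else {
      s.t = as<std::vector<double>>(e["t"]);
      s.a = as<std::vector<double>>(e["a"]);
    }
    stim.push_back(std::move(s));
  }

  // --- voltage clamp (optional) ---
  bool has_clamp = false;
  Stim clampw;
  int clamp_comp = -1;
  if (vclamp_.isNotNull()) {
    List vc(vclamp_);
    clamp_comp = vc["comp"];
    clampw.comp = clamp_comp;
    clampw.kind = 1;
    clampw.t = as<std::vector<double>>(vc["t"]);
    clampw.a = as<std::vector<double>>(vc["a"]);
    has_clamp = true;
  }

  // --- state init ---
  std::vector<double> V(n, v_init);
  std::vector<double> eca(n, ghk_coef * std::log(cao / carest));
  {
    double fi[3], ft[3];
    for (auto &ci : ch) {
      if (ci.markov) {
        ci.state.assign((size_t)ci.comp.size() * ci.nstate, 0.0);
        std::vector<double> p(ci.nstate, 0.0), Q, A(ci.nstate * ci.nstate),
            b(ci.nstate);
        p[0] = 1.0;
        markov_Q(ci.type, v_init, carest, celsius, Q);
        for (int k = 0; k < 4000; ++k)
          markov_be_step(ci.nstate, Q, p.data(), 2.5, A.data(), b.data());
        for (size_t k = 0; k < ci.comp.size(); ++k)
          for (int s = 0; s < ci.nstate; ++s)
            ci.state[k * ci.nstate + s] = p[s];
      } else if (ci.ng > 0) {
        ci.state.assign((size_t)ci.comp.size() * ci.ng, 0.0);
        hh_inf_tau(ci.type, v_init, carest, celsius, fi, ft);
        for (size_t k = 0; k < ci.comp.size(); ++k)
          for (int g = 0; g < ci.ng; ++g) ci.state[k * ci.ng + g] = fi[g];
      }
    }
  }

  // --- recording setup ---
  long nsteps = (long)std::llround(duration / dt);
  std::vector<long> rec_steps;
  for (long s = 1; s <= nsteps; ++s) {
    double t = s * dt;
    if (t >= record_from - 1e-9 && (s % rec_every == 0)) rec_steps.push_back(s);
  }
  int nrec = (int)rec_steps.size(), nsite = rec_comp.size();
  NumericVector time_out(nrec);
  NumericMatrix v_out(nrec, nsite);
  NumericMatrix ca_out(record_ca ? nrec : 0, record_ca ? nsite : 0);
  size_t rec_ptr = 0;

  // --- work arrays ---
  std::vector<double> gsum(n), gesum(n), gca(n), istim(n), pca(n);
  std::vector<double> diag(n), rhs(n);
  std::vector<double> QA(13 * 13), Qb(13), Qm;
  std::vector<double> caflux; // scratch

  std::vector<double> inst_i(ch.size(), 0.0), inst_g(ch.size(), 0.0);
  for (long s = 1; s <= nsteps; ++s) {
    double t_new = s * dt;
    std::fill(inst_i.begin(), inst_i.end(), 0.0);
    std::fill(inst_g.begin(), inst_g.end(), 0.0);
    std::fill(gsum.begin(), gsum.end(), 0.0);
    std::fill(gesum.begin(), gesum.end(), 0.0);
    std::fill(gca.begin(), gca.end(), 0.0);
    std::fill(istim.begin(), istim.end(), 0.0);
    std::fill(pca.begin(), pca.end(), 0.0);

    // 1. channel state update + conductance assembly (rates at V_t)
    for (auto &ci : ch) {
      const int nc = (int)ci.comp.size();
      if (ci.markov) {
        for (int k = 0; k < nc; ++k) {
          int c = ci.comp[k];
          double cai = (ca_index[c] >= 0) ? cac[ca_index[c]].free_ca[0] : carest;
          markov_Q(ci.type, V[c], cai, celsius, Qm);
          markov_be_step(ci.nstate, Qm, &ci.state[(size_t)k * ci.nstate], dt,
                         QA.data(), Qb.data());
          double open = 0.0;
          if (ci.type == CH_NAV16) open = ci.state[(size_t)k * ci.nstate + 5];
          else open = ci.state[(size_t)k * ci.nstate + 4] +
                      ci.state[(size_t)k * ci.nstate + 5];
          double g = ci.gbar[k] * open;
          if (ci.isca) {
            double cai2 = (ca_index[c] >= 0) ? cac[ca_index[c]].free_ca[0]
                                             : carest;
            if (ca_ghk) {
              pca[c] += g;
              inst_i[&ci - &ch[0]] += g * ghk_flux(V[c], cai2, cao, RT);
            } else {
              gsum[c] += g;
              gesum[c] += g * eca[c];
              gca[c] += g;
              inst_i[&ci - &ch[0]] += g * (V[c] - eca[c]);
            }
            inst_g[&ci - &ch[0]] += g;
          } else {
            gsum[c] += g;
            gesum[c] += g * ci.erev;
            inst_i[&ci - &ch[0]] += g * (V[c] - ci.erev);
            inst_g[&ci - &ch[0]] += g;
          }
        }
      } else {
        double erev = ci.erev;
        if (ci.ng == 0) { // ungated leak-like channel (TRP)
          for (int k = 0; k < nc; ++k) {
            int c = ci.comp[k];
            gsum[c] += ci.gbar[k];
            gesum[c] += ci.gbar[k] * erev;
          }
          continue;
        }
        double fi[3], ft[3];
        for (int k = 0; k < nc; ++k) {
          int c = ci.comp[k];
          double v = V[c];
          double open = 1.0;
          bool need_ca = ci.any_cadep;
          double cai = 0.0;
          if (need_ca)
            cai = (ca_index[c] >= 0) ? cac[ca_index[c]].free_ca[0] : carest;
          for (int g = 0; g < ci.ng; ++g) {
            double xi, xe;
            if (HH_CADEP[ci.type][g]) {
              hh_inf_tau(ci.type, v, cai, celsius, fi, ft);
              xi = fi[g];
              xe = std::exp(-dt / ft[g]);
            } else {
              ci.tab.at(v, g, xi, xe);
            }
            double &x = ci.state[(size_t)k * ci.ng + g];
            x = xi + (x - xi) * xe;
            for (int e2 = 0; e2 < HH_EXPO[ci.type][g]; ++e2) open *= x;
          }
          double g = ci.gbar[k] * open;
          if (ci.isca) {
            double cai2 = (ca_index[c] >= 0) ? cac[ca_index[c]].free_ca[0]
                                             : carest;
            if (ca_ghk) {
              pca[c] += g;
              inst_i[&ci - &ch[0]] += g * ghk_flux(V[c], cai2, cao, RT);
            } else {
              gsum[c] += g;
              gesum[c] += g * eca[c];
              gca[c] += g;
              inst_i[&ci - &ch[0]] += g * (V[c] - eca[c]);
            }
            inst_g[&ci - &ch[0]] += g;
          } else {
            gsum[c] += g;
            gesum[c] += g * erev;
            inst_i[&ci - &ch[0]] += g * (V[c] - erev);
            inst_g[&ci - &ch[0]] += g;
          }
        }
      }
    }

    // 2. stimuli
    for (auto &st : stim) istim[st.comp] += st.current(t_new);

    // 3. implicit voltage solve over the tree (Hines elimination)
    for (int i = 0; i < n; ++i) {
      diag[i] = cm[i] / dt + gleak[i] + gsum[i];
      rhs[i] = cm[i] / dt * V[i] + gleak[i] * eleak[i] + gesum[i] + istim[i];
      if (pca[i] > 0.0) {
        double cai2 = (ca_index[i] >= 0) ? cac[ca_index[i]].free_ca[0] : carest;
        rhs[i] -= pca[i] * ghk_flux(V[i], cai2, cao, RT);
      }
    }
    for (int i = 1; i < n; ++i) {
      diag[i] += gax[i];
      diag[parent[i]] += gax[i];
    }
    if (has_clamp) {
      double vc = clampw.current(t_new);
      diag[clamp_comp] += 1e6;
      rhs[clamp_comp] += 1e6 * vc;
    }
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = gax[i] / diag[i];
      diag[p] -= gax[i] * f;
      rhs[p] += rhs[i] * f;
    }
    V[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i)
      V[i] = (rhs[i] + gax[i] * V[parent[i]]) / diag[i];

    // 4. divergence guard
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(V[i]) || std::fabs(V[i]) >= 200.0)
        stop("voltage diverged (|V| >= 200 mV) at t = %.3f ms, compartment %d; "
             "reduce dt or check the model", t_new, i + 1);
    }

    // 5. calcium update (influx at new V, diffusion, buffering, pump)
    double dtc = dt / nsub;
    for (auto &cc : cac) {
      int c = cc.comp;
      double ica = pca[c] * ghk_flux(V[c], cc.free_ca[0], cao, RT);
      ica += gca[c] * (V[c] - eca[c]); // nA, negative = inward
      for (int sub = 0; sub < nsub; ++sub) {
        double ca0 = cc.free_ca[0];
        double influx = -ica * KCAF + cc.jleak -
                        cc.pump_vmax * ca0 / (ca0 + KPUMP); // mM um^3/ms
        cc.free_ca[0] += dtc * influx / cc.vol[0];
        // radial diffusion (free Ca and bound buffer)
        for (int j = 0; j + 1 < cc.ns; ++j) {
          double fl = dca * cc.gd[j] * (cc.free_ca[j] - cc.free_ca[j + 1]);
          cc.free_ca[j] -= dtc * fl / cc.vol[j];
          cc.free_ca[j + 1] += dtc * fl / cc.vol[j + 1];
          for (int b = 0; b < nbuf; ++b) {
            double fb = bdif[b] * cc.gd[j] * (cc.bnd[b][j] - cc.bnd[b][j + 1]);
            cc.bnd[b][j] -= dtc * fb / cc.vol[j];
            cc.bnd[b][j + 1] += dtc * fb / cc.vol[j + 1];
          }
        }
        // buffer kinetics
        for (int j = 0; j < cc.ns; ++j) {
          for (int b = 0; b < nbuf; ++b) {
            double freeb = btot[b] - cc.bnd[b][j];
            double r = kon[b] * cc.free_ca[j] * freeb - koff[b] * cc.bnd[b][j];
            double d = dtc * r;
            if (d > cc.free_ca[j]) d = cc.free_ca[j]; // guard
            cc.bnd[b][j] += d;
            cc.free_ca[j] -= d;
          }
          if (!std::isfinite(cc.free_ca[j]) || cc.free_ca[j] < -1e-3)
            stop("negative calcium concentration at t = %.3f ms: "
                 "time step too large", t_new);
          if (cc.free_ca[j] < 1e-9) cc.free_ca[j] = 1e-9;
        }
      }
      eca[c] = ghk_coef * std::log(cao / cc.free_ca[0]);
    }

    // 6. recording
    if (rec_ptr < rec_steps.size() && rec_steps[rec_ptr] == s) {
      time_out[rec_ptr] = t_new;
      for (int j = 0; j < nsite; ++j) {
        int c = rec_comp[j];
        v_out(rec_ptr, j) = V[c];
        if (record_ca)
          ca_out(rec_ptr, j) =
              (ca_index[c] >= 0) ? cac[ca_index[c]].free_ca[0] : NA_REAL;
      }
      ++rec_ptr;
    }
  }

  List out = List::create(
      _["time"] = time_out, _["v"] = v_out,
      _["ca"] = record_ca ? (SEXP)ca_out : R_NilValue,
      _["v_final"] = NumericVector(V.begin(), V.end()),
      _["i_chan_final"] = NumericVector(inst_i.begin(), inst_i.end()),
      _["g_chan_final"] = NumericVector(inst_g.begin(), inst_g.end()));
  return out;
}
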