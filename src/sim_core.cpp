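// Fixed-step Euler-Maruyama integrator for the SAC wave model.
// One cell = 9 ODE states + an exactly-discretised OU noise state;
// lattice cells share the ACh/GABA fields through a biased 5-point
// exchange operator advanced with a Crank-Nicolson substep.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <map>
#include <string>
#include <vector>
using namespace Rcpp;

namespace {

struct Pars {
  double V1, V2, V3, V4, V0e, Vse, V0i, Vsi;
  double V7, V8, V9, V10, V11, V12, V13, V14, V15, V16, V17, V18;
  double Cm, gLeak, gCa, gK, gNa, gTREK, gACh, gGABA;
  double ELeak, ECa, EK, ENa, EACh, ECl, sigma, tauW;
  double tauN, tauA, tauB, tauC, tauACh, tauGABA;
  double C0, lambda, delta, alpha, beta, rho_e, rho_i;
  double Kd, De, Di;
  double dXeL, dXeR, dYeU, dYeD, dXiL, dXiR, dYiU, dYiD;
  double Iapp;
  double noise_gain; // sigma scaled to the unit-diffusion OU state
};

Pars unpack(const NumericVector& v) {
  Pars p;
  CharacterVector nm = v.names();
  std::map<std::string, double> m;
  for (int i = 0; i < v.size(); ++i) m[as<std::string>(nm[i])] = v[i];
  auto g = [&](const char* k) {
    auto it = m.find(k);
    if (it == m.end()) stop("parameter vector is missing '%s'", k);
    return it->second;
  };
  p.V1 = g("V1"); p.V2 = g("V2"); p.V3 = g("V3"); p.V4 = g("V4");
  p.V0e = g("V0e"); p.Vse = g("Vse"); p.V0i = g("V0i"); p.Vsi = g("Vsi");
  p.V7 = g("V7"); p.V8 = g("V8"); p.V9 = g("V9"); p.V10 = g("V10");
  p.V11 = g("V11"); p.V12 = g("V12"); p.V13 = g("V13"); p.V14 = g("V14");
  p.V15 = g("V15"); p.V16 = g("V16"); p.V17 = g("V17"); p.V18 = g("V18");
  p.Cm = g("Cm"); p.gLeak = g("gLeak"); p.gCa = g("gCa"); p.gK = g("gK");
  p.gNa = g("gNa"); p.gTREK = g("gTREK"); p.gACh = g("gACh"); p.gGABA = g("gGABA");
  p.ELeak = g("ELeak"); p.ECa = g("ECa"); p.EK = g("EK"); p.ENa = g("ENa");
  p.EACh = g("EACh"); p.ECl = g("ECl"); p.sigma = g("sigma"); p.tauW = g("tauW");
  p.tauN = g("tauN"); p.tauA = g("tauA"); p.tauB = g("tauB"); p.tauC = g("tauC");
  p.tauACh = g("tauACh"); p.tauGABA = g("tauGABA");
  p.C0 = g("C0"); p.lambda = g("lambda"); p.delta = g("delta");
  p.alpha = g("alpha"); p.beta = g("beta");
  p.rho_e = g("rho_e"); p.rho_i = g("rho_i");
  p.Kd = g("Kd"); p.De = g("De"); p.Di = g("Di");
  p.dXeL = g("dXeL"); p.dXeR = g("dXeR"); p.dYeU = g("dYeU"); p.dYeD = g("dYeD");
  p.dXiL = g("dXiL"); p.dXiR = g("dXiR"); p.dYiU = g("dYiU"); p.dYiD = g("dYiD");
  p.Iapp = g("Iapp");
  // sigma is the stationary noise-current amplitude (pA); W has
  // stationary SD sqrt(tauW/2)
  p.noise_gain = p.sigma / std::sqrt(p.tauW / 2.0);
  return p;
}

inline uint64_t splitmix64(uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// xorshift128+ with a Box-Muller normal; one stream per cell so results
// are reproducible under any iteration order
struct CellRng {
  uint64_t s0, s1;
  bool has;
  double cache;
  void seed(uint64_t s) {
    uint64_t x = s;
    s0 = splitmix64(x);
    s1 = splitmix64(x);
    if (s0 == 0 && s1 == 0) s1 = 1;
    has = false;
    cache = 0;
  }
  inline double unif() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    uint64_t r = s1 + y;
    return ((r >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (has) { has = false; return cache; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double t = 6.283185307179586 * u2;
    cache = r * std::sin(t);
    has = true;
    return r * std::cos(t);
  }
};

struct Drift {
  double dV, dN, dM, dH, dC, dA, dB, dE, dI, dW, ITREK;
};

inline Drift rhs_one(const Pars& p, double V, double N, double M, double H,
                     double C, double A, double B, double E, double I,
                     double W, double lapE, double lapI) {
  const double minf = 0.5 * (1.0 + std::tanh((V - p.V1) / p.V2));
  const double ninf = 0.5 * (1.0 + std::tanh((V - p.V3) / p.V4));
  const double lam = std::cosh((V - p.V3) / (2.0 * p.V4));
  const double x = V - p.V8;
  const double am = (std::fabs(x) < 1e-7)
      ? p.V9 / p.V7
      : -x / (p.V7 * (std::exp(-x / p.V9) - 1.0));
  const double bm = p.V10 * std::exp(-(V - p.V11) / p.V12);
  const double ah = p.V13 * std::exp(-(V - p.V14) / p.V15);
  const double bh = 1.0 / (p.V16 * std::exp(-(V - p.V17) / p.V18) + 1.0);
  const double hE = E * E / (E * E + p.Kd);
  const double hI = I * I / (I * I + p.Kd);
  const double Ileak = -p.gLeak * (V - p.ELeak);
  const double ICa = -p.gCa * minf * (V - p.ECa);
  const double IK = -p.gK * N * (V - p.EK);
  const double ITREK = -p.gTREK * B * (V - p.EK);
  const double INa = -p.gNa * M * M * M * H * (V - p.ENa);
  const double IACh = -p.gACh * hE * (V - p.EACh);
  const double IGABA = -p.gGABA * hI * (V - p.ECl);
  const double Inoise = p.noise_gain * W;
  const double phiE = 1.0 / (1.0 + std::exp(-p.Vse * (V - p.V0e)));
  const double phiI = 1.0 / (1.0 + std::exp(-p.Vsi * (V - p.V0i)));
  Drift d;
  d.dV = (Ileak + ICa + IK + ITREK + INa + IACh + IGABA + Inoise + p.Iapp) / p.Cm;
  d.dN = lam * (ninf - N) / p.tauN;
  d.dM = am * (1.0 - M) - bm * M;
  d.dH = ah * (1.0 - H) - bh * H;
  d.dC = (p.C0 + p.delta * ICa - p.lambda * C) / p.tauC;
  const double C2 = C * C, A2 = A * A;
  d.dA = (p.alpha * C2 * C2 * (1.0 - A) - A) / p.tauA;
  d.dB = (p.beta * A2 * A2 * (1.0 - B) - B) / p.tauB;
  d.dE = p.De * lapE + (p.rho_e * phiE - E) / p.tauACh;
  d.dI = p.Di * lapI + (p.rho_i * phiI - I) / p.tauGABA;
  d.dW = -W / p.tauW;
  d.ITREK = ITREK;
  return d;
}

inline double clamp01(double x) { return x < 0 ? 0 : (x > 1 ? 1 : x); }
inline double clamp0(double x) { return x < 0 ? 0 : x; }

// flux-form biased exchange operator; weights are transport rates per
// direction of motion, edges are no-flux
void apply_lap(const std::vector<double>& f, std::vector<double>& out,
               int nx, int ny, double wL, double wR, double wU, double wD) {
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      const int i = iy * nx + ix;
      double in = 0, send = 0;
      if (iy > 0)      { in += wU * f[i - nx]; send += wD; }
      if (iy < ny - 1) { in += wD * f[i + nx]; send += wU; }
      if (ix > 0)      { in += wR * f[i - 1];  send += wL; }
      if (ix < nx - 1) { in += wL * f[i + 1];  send += wR; }
      out[i] = in - send * f[i];
    }
  }
}

// one Crank-Nicolson diffusion substep, implicit half solved by
// fixed-point iteration (D*dt << 1 so a few sweeps reach machine precision)
void cn_diffuse(std::vector<double>& f, std::vector<double>& rhs,
                std::vector<double>& tmp, std::vector<double>& lap,
                int nx, int ny, double half,
                double wL, double wR, double wU, double wD) {
  const int n = nx * ny;
  apply_lap(f, lap, nx, ny, wL, wR, wU, wD);
  for (int i = 0; i < n; ++i) rhs[i] = f[i] + half * lap[i];
  tmp = f;
  for (int it = 0; it < 3; ++it) {
    apply_lap(tmp, lap, nx, ny, wL, wR, wU, wD);
    for (int i = 0; i < n; ++i) tmp[i] = rhs[i] + half * lap[i];
  }
  for (int i = 0; i < n; ++i) f[i] = clamp0(tmp[i]);
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_rhs(NumericVector state, NumericVector par,
                      double lapE = 0, double lapI = 0) {
  Pars p = unpack(par);
  Drift d = rhs_one(p, state[0], state[1], state[2], state[3], state[4],
                    state[5], state[6], state[7], state[8], state[9],
                    lapE, lapI);
  NumericVector out = NumericVector::create(
    _["V"] = d.dV, _["N"] = d.dN, _["M"] = d.dM, _["H"] = d.dH,
    _["C"] = d.dC, _["A"] = d.dA, _["B"] = d.dB, _["E"] = d.dE,
    _["I"] = d.dI, _["W"] = d.dW);
  return out;
}

// [[Rcpp::export]]
List cpp_simulate(NumericVector par, NumericMatrix init, int nx, int ny,
                  double t_end, double dt, double save_every, double seed,
                  bool coupled, bool save_fields, bool full_trace) {
  const Pars p = unpack(par);
  const int ncell = nx * ny;
  if (init.nrow() != ncell || init.ncol() != 10)
    stop("init must be a %d x 10 matrix", ncell);
  if (dt <= 0 || t_end <= 0) stop("dt and t_end must be positive");
  const int sstride = (int)std::lround(save_every / dt);
  if (sstride < 1 || std::fabs(sstride * dt - save_every) > 1e-9)
    stop("save_every must be a positive multiple of dt");
  const long nsteps = std::lround(t_end / dt);
  const int nsave = (int)(nsteps / sstride) + 1;
  if (full_trace && ncell != 1) stop("full_trace requires a single cell");

  std::vector<double> V(ncell), N(ncell), M(ncell), H(ncell), C(ncell),
      A(ncell), B(ncell), E(ncell), I(ncell), W(ncell);
  for (int i = 0; i < ncell; ++i) {
    V[i] = init(i, 0); N[i] = init(i, 1); M[i] = init(i, 2); H[i] = init(i, 3);
    C[i] = init(i, 4); A[i] = init(i, 5); B[i] = init(i, 6); E[i] = init(i, 7);
    I[i] = init(i, 8); W[i] = init(i, 9);
  }

  std::vector<CellRng> rng(ncell);
  const uint64_t master = (uint64_t)std::llround(seed);
  for (int i = 0; i < ncell; ++i) {
    uint64_t s = master * 0x100000001B3ULL ^
                 (uint64_t)(i + 1) * 0x9E3779B97F4A7C15ULL;
    rng[i].seed(s);
  }

  const double ou_a = std::exp(-dt / p.tauW);
  const double ou_b = std::sqrt(p.tauW / 2.0 * (1.0 - ou_a * ou_a));
  const bool diffuse = coupled && ncell > 1;

  NumericMatrix traceV, traceE, traceI, full;
  if (full_trace) full = NumericMatrix(nsave, 10);
  else {
    traceV = NumericMatrix(ncell, nsave);
    if (save_fields) {
      traceE = NumericMatrix(ncell, nsave);
      traceI = NumericMatrix(ncell, nsave);
    }
  }

  std::vector<double> rhsE, tmpE, lapE;
  if (diffuse) { rhsE.resize(ncell); tmpE.resize(ncell); lapE.resize(ncell); }

  auto save_at = [&](int isave) {
    if (full_trace) {
      full(isave, 0) = V[0]; full(isave, 1) = N[0]; full(isave, 2) = M[0];
      full(isave, 3) = H[0]; full(isave, 4) = C[0]; full(isave, 5) = A[0];
      full(isave, 6) = B[0]; full(isave, 7) = E[0]; full(isave, 8) = I[0];
      full(isave, 9) = W[0];
    } else {
      for (int i = 0; i < ncell; ++i) traceV(i, isave) = V[i];
      if (save_fields)
        for (int i = 0; i < ncell; ++i) {
          traceE(i, isave) = E[i];
          traceI(i, isave) = I[i];
        }
    }
  };
  save_at(0);

  for (long k = 1; k <= nsteps; ++k) {
    // local (reaction) update of every cell, Euler-Maruyama with exact OU
    for (int i = 0; i < ncell; ++i) {
      Drift d = rhs_one(p, V[i], N[i], M[i], H[i], C[i], A[i], B[i],
                        E[i], I[i], W[i], 0.0, 0.0);
      V[i] += dt * d.dV;
      N[i] = clamp01(N[i] + dt * d.dN);
      M[i] = clamp01(M[i] + dt * d.dM);
      H[i] = clamp01(H[i] + dt * d.dH);
      C[i] = clamp0(C[i] + dt * d.dC);
      A[i] = clamp01(A[i] + dt * d.dA);
      B[i] = clamp01(B[i] + dt * d.dB);
      E[i] = clamp0(E[i] + dt * d.dE);
      I[i] = clamp0(I[i] + dt * d.dI);
      W[i] = ou_a * W[i] + ou_b * rng[i].norm();
    }
    // shared-field diffusion substep (Crank-Nicolson)
    if (diffuse) {
      cn_diffuse(E, rhsE, tmpE, lapE, nx, ny, p.De * dt / 2.0,
                 p.dXeL, p.dXeR, p.dYeU, p.dYeD);
      cn_diffuse(I, rhsE, tmpE, lapE, nx, ny, p.Di * dt / 2.0,
                 p.dXiL, p.dXiR, p.dYiU, p.dYiD);
    }
    if (k % sstride == 0) {
      const int isave = (int)(k / sstride);
      for (int i = 0; i < ncell; ++i)
        if (!std::isfinite(V[i]))
          stop("non-finite state at t = %.3f ms (cell %d); reduce dt",
               k * dt, i + 1);
      save_at(isave);
      if (isave % 50000 == 0) Rcpp::checkUserInterrupt();
    }
  }

  NumericVector t(nsave);
  for (int i = 0; i < nsave; ++i) t[i] = i * save_every;
  if (full_trace) return List::create(_["t"] = t, _["trace"] = full);
  List out = List::create(_["t"] = t, _["V"] = traceV);
  if (save_fields) { out["E"] = traceE; out["I"] = traceI; }
  return out;
}
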