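// Finite-volume core for the extended Keller-Segel model.
//
// Conservative flux form on a uniform cell-centered grid (Cartesian or
// axisymmetric radial), zero total flux at both boundaries, minmod
// slope-limited upwinding of the drift term, Heun (explicit RK2) stepping
// under a CFL-style bound recomputed every step. Mirrors the R reference
// implementation in R/pde.R; an equivalence test keeps the two in step.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

namespace {

struct Pars {
  double N, H, K_S, eta, omega, n, delta0, zeta, K_chi;
  bool growth_on;
  bool const_speed;
  double s;           // uniform speed in constant_speed mode
  double omega_n;     // cached omega^n
  bool n_integer;
  int n_int;
};

// x^n for n >= 0; fast path for integer exponents (the Hill exponents of
// interest, n = 1..40, are integers)
inline double pow_n(double x, const Pars& p) {
  if (p.n_integer) {
    double r = 1.0, b = x;
    int e = p.n_int;
    while (e > 0) {
      if (e & 1) r *= b;
      b *= b;
      e >>= 1;
    }
    return r;
  }
  return std::pow(x, p.n);
}

inline double vspeed(double C, const Pars& p) {
  if (p.const_speed) return p.s;
  double Cn = pow_n(C, p);
  return 1.0 + p.eta * Cn / (Cn + p.omega_n);
}

// dV/dC = n eta omega^n C^(n-1) / (C^n + omega^n)^2
inline double vsens(double C, const Pars& p) {
  if (p.const_speed || p.eta == 0.0) return 0.0;
  double Cn = pow_n(C, p);
  double Cnm1;
  if (p.n_integer && p.n_int >= 1) {
    Cnm1 = (p.n_int == 1) ? 1.0 : ((C > 0.0) ? Cn / C : 0.0);
  } else {
    Cnm1 = std::pow(C, p.n - 1.0);
  }
  double den = Cn + p.omega_n;
  return p.n * p.eta * p.omega_n * Cnm1 / (den * den);
}

Pars unpack(const List& par) {
  Pars p;
  p.N = as<double>(par["N"]);
  p.H = as<double>(par["H"]);
  p.K_S = as<double>(par["K_S"]);
  p.eta = as<double>(par["eta"]);
  p.omega = as<double>(par["omega"]);
  p.n = as<double>(par["n_hill"]);
  p.delta0 = as<double>(par["delta0"]);
  p.zeta = as<double>(par["zeta"]);
  p.K_chi = as<double>(par["K_chi"]);
  p.growth_on = as<bool>(par["growth_on"]);
  p.const_speed = as<std::string>(par["mode"]) == "constant_speed";
  p.s = as<double>(par["speed_factor"]);
  p.omega_n = std::pow(p.omega, p.n);
  p.n_int = static_cast<int>(p.n);
  p.n_integer = (p.n == static_cast<double>(p.n_int)) && p.n_int >= 1 &&
                p.n_int <= 1024;
  return p;
}

// c_mode: 0 frozen, 1 dynamic, 2 analytic pulse (C prescribed)
struct Engine {
  int M;
  double dx;
  bool axi;
  std::vector<double> w;       // divergence weights (dx or r_c*dx)
  std::vector<double> inv_w;
  std::vector<double> a;       // face areas (1 or r_f)
  Pars p;
  int c_mode;
  double pS, pN;               // analytic-pulse content and diffusivity
  std::vector<double> rc;

  // scratch
  std::vector<double> V, dCdT_an, slope;
  // frozen-C cache: with a static attractant the face diffusivity and
  // drift never change, so the flux operator is linear in B
  bool frozen_cached = false;
  std::vector<double> cDface, cdrift;
  double cmaxV2 = 0.0, cmaxdrift = 0.0;

  void pulse_fields(double T, std::vector<double>& C,
                    std::vector<double>& dCdT) {
    double pref = pS / (4.0 * M_PI * pN * T);
    for (int i = 0; i < M; ++i) {
      double r2 = rc[i] * rc[i];
      double e = std::exp(-r2 / (4.0 * pN * T));
      C[i] = pref * e;
      dCdT[i] = C[i] * (r2 / (4.0 * pN * T * T) - 1.0 / T);
    }
  }

  // dB, dC at (B, C, T); also report max V^2 and max |drift| for dt control
  void rhs(const std::vector<double>& B, const std::vector<double>& C,
           double T, std::vector<double>& dB, std::vector<double>& dC,
           double& maxV2, double& maxdrift) {
    const std::vector<double>* Cp = &C;
    std::vector<double> Cpulse;
    const double* dCdT_chi = nullptr;

    if (c_mode == 2) {
      Cpulse.resize(M);
      dCdT_an.resize(M);
      pulse_fields(T, Cpulse, dCdT_an);
      Cp = &Cpulse;
      dCdT_chi = dCdT_an.data();
      std::fill(dC.begin(), dC.end(), 0.0);
    } else if (c_mode == 1) {
      // dC = N lap(C) - H B g(C); Laplacian assembled via faces so the
      // diffusive part conserves attractant content exactly
      std::fill(dC.begin(), dC.end(), 0.0);
      for (int f = 1; f < M; ++f) {
        double flux = a[f] * p.N * (C[f] - C[f - 1]) / dx;
        dC[f - 1] += flux * inv_w[f - 1];
        dC[f] -= flux * inv_w[f];
      }
      for (int i = 0; i < M; ++i) {
        double g = C[i] / (C[i] + p.K_S);
        dC[i] -= p.H * B[i] * g;
      }
      dCdT_chi = dC.data();
    } else {
      std::fill(dC.begin(), dC.end(), 0.0);
      dCdT_chi = dC.data();
    }

    const std::vector<double>& Cu = *Cp;
    const bool cacheable = (c_mode == 0);
    if (!cacheable || !frozen_cached) {
      const double inv_dx = 1.0 / dx;
      V.resize(M);
      double mv2 = 0.0;
      for (int i = 0; i < M; ++i) {
        V[i] = vspeed(Cu[i], p);
        double v2 = V[i] * V[i];
        if (v2 > mv2) mv2 = v2;
      }
      cDface.resize(M - 1);
      cdrift.resize(M - 1);
      double mdrift = 0.0;
      for (int f = 1; f < M; ++f) {
        int l = f - 1, r = f;
        cDface[l] = 0.5 * (V[l] * V[l] + V[r] * V[r]);
        double gradC = (Cu[r] - Cu[l]) * inv_dx;
        double Cf = 0.5 * (Cu[l] + Cu[r]);
        double dCdTf = 0.5 * (dCdT_chi[l] + dCdT_chi[r]);
        double Vf = vspeed(Cf, p);
        double Vk = -Vf * vsens(Cf, p) * gradC;
        double kk = Cf + p.K_chi;
        double Vchi = Vf * Vf * p.delta0 * p.K_chi / (kk * kk) *
                      (gradC + p.zeta / Vf * dCdTf);
        cdrift[l] = Vk + Vchi;
        double ad = std::fabs(cdrift[l]);
        if (ad > mdrift) mdrift = ad;
      }
      cmaxV2 = mv2;
      cmaxdrift = mdrift;
      if (cacheable) frozen_cached = true;
    }
    maxV2 = cmaxV2;
    maxdrift = cmaxdrift;

    // minmod-limited slopes of B for second-order upwinding; the limited
    // face values stay within the range of the adjacent cells, so the
    // scheme remains positivity-preserving under the CFL bound
    slope.resize(M);
    slope[0] = slope[M - 1] = 0.0;
    for (int i = 1; i < M - 1; ++i) {
      double dl = B[i] - B[i - 1], dr = B[i + 1] - B[i];
      slope[i] = (dl * dr <= 0.0) ? 0.0
                 : (std::fabs(dl) < std::fabs(dr) ? dl : dr);
    }

    std::fill(dB.begin(), dB.end(), 0.0);
    const double inv_dx = 1.0 / dx;
    for (int f = 1; f < M; ++f) {
      int l = f - 1, r = f;
      double gradB = (B[r] - B[l]) * inv_dx;
      double drift = cdrift[l];
      double Bup = (drift > 0.0) ? B[l] + 0.5 * slope[l]
                                 : B[r] - 0.5 * slope[r];
      double J = -cDface[l] * gradB + drift * Bup;
      double aJ = a[f] * J;
      dB[l] -= aJ * inv_w[l];
      dB[r] += aJ * inv_w[r];
    }
    if (p.growth_on) {
      for (int i = 0; i < M; ++i) {
        double g = Cu[i] / (Cu[i] + p.K_S);
        dB[i] += B[i] * g * (1.0 - B[i]);
      }
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_advance(NumericVector B0, NumericVector C0, double T0,
                 NumericVector tout, double dx, int geometry,
                 NumericVector r_cell, NumericVector r_face, List par,
                 int c_mode, double pulse_S, double pulse_N,
                 double safety, double dt_min) {
  const int M = B0.size();
  const int nt = tout.size();

  Engine e;
  e.M = M;
  e.dx = dx;
  e.axi = geometry == 1;
  e.p = unpack(par);
  e.c_mode = c_mode;
  e.pS = pulse_S;
  e.pN = pulse_N;
  e.rc.assign(r_cell.begin(), r_cell.end());
  e.w.resize(M);
  e.inv_w.resize(M);
  e.a.resize(M + 1);
  for (int i = 0; i < M; ++i) {
    e.w[i] = e.axi ? r_cell[i] * dx : dx;
    e.inv_w[i] = 1.0 / e.w[i];
  }
  for (int f = 0; f <= M; ++f)
    e.a[f] = e.axi ? r_face[f] : 1.0;

  std::vector<double> B(B0.begin(), B0.end());
  std::vector<double> C(C0.begin(), C0.end());
  if (c_mode == 2) {
    std::vector<double> d(M);
    e.pulse_fields(T0, C, d);
  }
  std::vector<double> dB1(M), dC1(M), dB2(M), dC2(M), Bp(M), Cp(M);

  NumericMatrix Bout(M, nt), Cout(M, nt);
  double T = T0;
  double clipped_B = 0.0, clipped_C = 0.0;
  long long n_steps = 0;
  double dt = 0.0;
  const double inf = std::numeric_limits<double>::infinity();

  for (int k = 0; k < nt; ++k) {
    const double tnext = tout[k];
    while (T < tnext) {
      double maxV2, maxdrift;
      e.rhs(B, C, T, dB1, dC1, maxV2, maxdrift);

      double lim = inf;
      if (maxV2 > 0.0) lim = std::min(lim, dx * dx / (2.0 * maxV2));
      if (c_mode == 1 && e.p.N > 0.0)
        lim = std::min(lim, dx * dx / (2.0 * e.p.N));
      if (maxdrift > 0.0) lim = std::min(lim, dx / maxdrift);
      dt = safety * lim;
      if (!(dt > 0.0) || !std::isfinite(dt))
        stop("time-step computation failed (non-finite fields?)");
      bool landing = false;
      if (T + dt >= tnext) {
        dt = tnext - T;
        landing = true;
      }
      if (!landing && dt < dt_min)
        stop("step-size collapse: dt = %g < dt_min = %g at T = %g",
             dt, dt_min, T);

      // predictor (Euler)
      for (int i = 0; i < M; ++i) {
        Bp[i] = B[i] + dt * dB1[i];
        if (Bp[i] < 0.0) Bp[i] = 0.0;
        Cp[i] = C[i] + dt * dC1[i];
        if (Cp[i] < 0.0) Cp[i] = 0.0;
      }
      if (c_mode == 2) {
        std::vector<double> d(M);
        e.pulse_fields(T + dt, Cp, d);
      }
      double mv2, md;
      e.rhs(Bp, Cp, T + dt, dB2, dC2, mv2, md);

      // corrector; clip round-off negatives, account for the mass added
      for (int i = 0; i < M; ++i) {
        B[i] += 0.5 * dt * (dB1[i] + dB2[i]);
        if (B[i] < 0.0) {
          clipped_B += -B[i] * e.w[i];
          B[i] = 0.0;
        }
        if (c_mode == 1) {
          C[i] += 0.5 * dt * (dC1[i] + dC2[i]);
          if (C[i] < 0.0) {
            clipped_C += -C[i] * e.w[i];
            C[i] = 0.0;
          }
        }
      }
      T += dt;
      if (c_mode == 2) {
        std::vector<double> d(M);
        e.pulse_fields(T, C, d);
      }
      ++n_steps;
      if ((n_steps & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    }
    for (int i = 0; i < M; ++i) {
      Bout(i, k) = B[i];
      Cout(i, k) = C[i];
    }
  }

  return List::create(
      _["B"] = Bout, _["C"] = Cout, _["n_steps"] = (double)n_steps,
      _["dt_last"] = dt, _["clipped_B"] = clipped_B,
      _["clipped_C"] = clipped_C);
}

// Single right-hand-side evaluation, exposed for the equivalence test
// against the R reference implementation (pde_rhs).
// [[Rcpp::export]]
List cpp_rhs(NumericVector B0, NumericVector C0, double T0, double dx,
             int geometry, NumericVector r_cell, NumericVector r_face,
             List par, int c_mode, double pulse_S, double pulse_N) {
  const int M = B0.size();
  Engine e;
  e.M = M;
  e.dx = dx;
  e.axi = geometry == 1;
  e.p = unpack(par);
  e.c_mode = c_mode;
  e.pS = pulse_S;
  e.pN = pulse_N;
  e.rc.assign(r_cell.begin(), r_cell.end());
  e.w.resize(M);
  e.inv_w.resize(M);
  e.a.resize(M + 1);
  for (int i = 0; i < M; ++i) {
    e.w[i] = e.axi ? r_cell[i] * dx : dx;
    e.inv_w[i] = 1.0 / e.w[i];
  }
  for (int f = 0; f <= M; ++f)
    e.a[f] = e.axi ? r_face[f] : 1.0;
  std::vector<double> B(B0.begin(), B0.end());
  std::vector<double> C(C0.begin(), C0.end());
  std::vector<double> dB(M), dC(M);
  double mv2, md;
  e.rhs(B, C, T0, dB, dC, mv2, md);
  return List::create(_["dB"] = NumericVector(dB.begin(), dB.end()),
                      _["dC"] = NumericVector(dC.begin(), dC.end()),
                      _["max_V2"] = mv2, _["max_drift"] = md);
}
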