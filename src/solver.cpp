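// Compiled kernels: complex Bessel-function ratio for the Womersley factor,
// and the two-step Lax-Wendroff driver for the proximal arterial-venous
// network with characteristic boundary closures and convolution bed coupling.
#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;
typedef std::complex<double> cplx;

// J1(z)/J0(z) by backward (Miller-type) recurrence on t_n = J_n / J_{n-1}:
// t_n = 1 / (2n/z - t_{n+1}), started well above |z| where the continued
// fraction has converged. Valid off the real axis (J0 has only real zeros).
// [[Rcpp::export]]
ComplexVector bessel_j_ratio(ComplexVector z) {
  int n = z.size();
  ComplexVector out(n);
  for (int i = 0; i < n; ++i) {
    cplx zz(z[i].r, z[i].i);
    double az = std::abs(zz);
    if (az == 0.0) { out[i] = Rcomplex{0.0, 0.0}; continue; }
    int M = (int)std::ceil(1.3 * az) + 30;
    cplx t(0.0, 0.0);
    for (int k = M; k >= 1; --k) {
      t = 1.0 / (2.0 * (double)k / zz - t);
    }
    out[i] = Rcomplex{t.real(), t.imag()};
  }
  return out;
}

// ---------------------------------------------------------------------------
// 1D pulse-wave network solver
// ---------------------------------------------------------------------------
// State per vessel: A (area, cm^2) and q (flow, cm^3/s) on a uniform grid.
// Wall law p = f (sqrt(A/A0) - 1), f = (4/3) K; c(A) = c0 (A/A0)^{1/4},
// c0^2 = f / (2 rho). Riemann invariants W+/- = u +/- 4c.

struct Vessel {
  int nx;
  int off;       // node offset into the global arrays
  double dx, A0, f, c0, L;
};

struct SolverError {
  std::string msg;
};

static inline double wall_p(double A, double A0, double f) {
  return f * (std::sqrt(A / A0) - 1.0);
}
static inline double wall_dpdA(double A, double A0, double f) {
  return f / (2.0 * std::sqrt(A * A0));
}
static inline double wave_c(double A, double A0, double c0) {
  return c0 * std::sqrt(std::sqrt(A / A0));  // c0 (A/A0)^{1/4}
}

class Network {
public:
  std::vector<Vessel> ves;
  std::vector<double> A, q, Aold, qold;
  double rho, nu, gamma, delta, visc_coef;
  double dt;
  // boundary bookkeeping
  int inlet;                               // vessel index with prescribed q at x=0
  IntegerMatrix jdiv, jconv;               // diverging: (p,d1,d2); converging: (d1,d2,c)
  IntegerVector vein_out;                  // vessels with prescribed p at x=L
  IntegerVector nonrefl_out;               // vessels with non-reflecting outlet
  IntegerMatrix bed_idx;                   // (artery, vein) vessel indices
  std::vector<NumericMatrix> kernels;      // per bed: N x 4 (y11,y12,y21,y22)

  Network() : inlet(-1) {}

  inline int endL(int v) const { return ves[v].off + ves[v].nx - 1; }
  inline int beg(int v) const { return ves[v].off; }

  // characteristic invariants at boundaries, traced from the OLD state with
  // the friction source dW/dt = -2 pi nu (gamma+2) u / A along the path
  double Wplus_at_L(int v) const {
    const Vessel& V = ves[v];
    int iL = endL(v), iL1 = iL - 1;
    double u1 = qold[iL] / Aold[iL];
    double c1 = wave_c(Aold[iL], V.A0, V.c0);
    double th = (u1 + c1) * dt / V.dx;
    if (th < 0.0) th = 0.0; if (th > 1.0) th = 1.0;
    double u2 = qold[iL1] / Aold[iL1];
    double c2 = wave_c(Aold[iL1], V.A0, V.c0);
    double uf = (1.0 - th) * u1 + th * u2;
    double cf = (1.0 - th) * c1 + th * c2;
    double Af = (1.0 - th) * Aold[iL] + th * Aold[iL1];
    return uf + 4.0 * cf - dt * visc_coef * uf / Af;
  }
  double Wminus_at_0(int v) const {
    const Vessel& V = ves[v];
    int i0 = beg(v), i1 = i0 + 1;
    double u1 = qold[i0] / Aold[i0];
    double c1 = wave_c(Aold[i0], V.A0, V.c0);
    double th = (c1 - u1) * dt / V.dx;
    if (th < 0.0) th = 0.0; if (th > 1.0) th = 1.0;
    double u2 = qold[i1] / Aold[i1];
    double c2 = wave_c(Aold[i1], V.A0, V.c0);
    double uf = (1.0 - th) * u1 + th * u2;
    double cf = (1.0 - th) * c1 + th * c2;
    double Af = (1.0 - th) * Aold[i0] + th * Aold[i1];
    return uf - 4.0 * cf - dt * visc_coef * uf / Af;
  }

  std::vector<double> Ah_buf, qh_buf;  // preallocated half-step scratch

  // interior two-step Lax-Wendroff update; returns max CFL number seen
  double step_interior() {
    double cfl_max = 0.0;
    for (size_t v = 0; v < ves.size(); ++v) {
      const Vessel& V = ves[v];
      int n = V.nx, o = V.off;
      double dxl = V.dx;
      double lam = dt / dxl;
      // half-step values at j+1/2 for j = 0..n-2
      double* Ah = Ah_buf.data();
      double* qh = qh_buf.data();
      for (int j = 0; j < n - 1; ++j) {
        double A1 = Aold[o + j], A2 = Aold[o + j + 1];
        double q1 = qold[o + j], q2 = qold[o + j + 1];
        double F1a = q1, F2a = q2;
        double F1b = delta * q1 * q1 / A1 + bflux(A1, V);
        double F2b = delta * q2 * q2 / A2 + bflux(A2, V);
        double S1 = -visc_coef * q1 / A1;
        double S2 = -visc_coef * q2 / A2;
        Ah[j] = 0.5 * (A1 + A2) - 0.5 * lam * (F2a - F1a);
        qh[j] = 0.5 * (q1 + q2) - 0.5 * lam * (F2b - F1b) + 0.25 * dt * (S1 + S2);
        if (Ah[j] <= 0.0) throw SolverError{"negative area (half step), vessel " + std::to_string(v)};
      }
      // full step for interior nodes j = 1..n-2
      for (int j = 1; j < n - 1; ++j) {
        double FL = qh[j - 1], FR = qh[j];
        double GL = delta * qh[j - 1] * qh[j - 1] / Ah[j - 1] + bflux(Ah[j - 1], V);
        double GR = delta * qh[j] * qh[j] / Ah[j] + bflux(Ah[j], V);
        double SL = -visc_coef * qh[j - 1] / Ah[j - 1];
        double SR = -visc_coef * qh[j] / Ah[j];
        A[o + j] = Aold[o + j] - lam * (FR - FL);
        q[o + j] = qold[o + j] - lam * (GR - GL) + 0.5 * dt * (SL + SR);
        if (A[o + j] <= 0.0) throw SolverError{"negative area, vessel " + std::to_string(v)};
      }
      // CFL over old state
      for (int j = 0; j < n; ++j) {
        double u = std::fabs(qold[o + j] / Aold[o + j]);
        double c = wave_c(Aold[o + j], V.A0, V.c0);
        double cfl = (u + c) * lam;
        if (cfl > cfl_max) cfl_max = cfl;
      }
    }
    return cfl_max;
  }

  inline double bflux(double A, const Vessel& V) const {
    // B(A) with dB/dA = (A/rho) dp/dA
    return V.f * A * std::sqrt(A) / (3.0 * rho * std::sqrt(V.A0));
  }

  // ---- boundary solves (write into new state) ----
  void bc_inlet(double qin) {
    const Vessel& V = ves[inlet];
    int i0 = beg(inlet);
    double W2 = Wminus_at_0(inlet);
    double Ax = Aold[i0];
    for (int it = 0; it < 60; ++it) {
      double c = wave_c(Ax, V.A0, V.c0);
      double Fr = qin / Ax - 4.0 * c - W2;
      double dF = -qin / (Ax * Ax) - c / Ax;
      double dA = -Fr / dF;
      if (dA < -0.5 * Ax) dA = -0.5 * Ax;
      Ax += dA;
      if (std::fabs(dA) < 1e-14 * V.A0) break;
    }
    if (!(Ax > 0.0)) throw SolverError{"inlet area went nonpositive"};
    A[i0] = Ax;
    q[i0] = qin;
  }

  void bc_vein_outlet(int v, double pla) {
    const Vessel& V = ves[v];
    int iL = endL(v);
    double s = 1.0 + pla / V.f;
    if (s <= 0.0) throw SolverError{"vein collapse at prescribed pressure"};
    double Ax = V.A0 * s * s;
    double W1 = Wplus_at_L(v);
    double u = W1 - 4.0 * wave_c(Ax, V.A0, V.c0);
    A[iL] = Ax;
    q[iL] = u * Ax;
  }

  void bc_nonreflecting(int v) {
    const Vessel& V = ves[v];
    int iL = endL(v);
    double W1 = Wplus_at_L(v);
    double W2ref = -4.0 * V.c0;  // incoming invariant frozen at rest value
    double u = 0.5 * (W1 + W2ref);
    double c = 0.125 * (W1 - W2ref);
    double Ax = V.A0 * std::pow(c / V.c0, 4.0);
    A[iL] = Ax;
    q[iL] = u * Ax;
  }

  // diverging junction: parent at x=L feeds d1, d2 at x=0
  void bc_junction_div(int p, int d1, int d2) {
    const Vessel& P = ves[p]; const Vessel& D1 = ves[d1]; const Vessel& D2 = ves[d2];
    double W1p = Wplus_at_L(p);
    double W21 = Wminus_at_0(d1);
    double W22 = Wminus_at_0(d2);
    double Ap = Aold[endL(p)], A1 = Aold[beg(d1)], A2 = Aold[beg(d2)];
    double scf = 1.0 / P.f, scq = 1.0 / (P.A0 * P.c0);
    for (int it = 0; it < 60; ++it) {
      double cp = wave_c(Ap, P.A0, P.c0), c1 = wave_c(A1, D1.A0, D1.c0),
             c2 = wave_c(A2, D2.A0, D2.c0);
      double up = W1p - 4.0 * cp, u1 = W21 + 4.0 * c1, u2 = W22 + 4.0 * c2;
      double F1 = Ap * up - A1 * u1 - A2 * u2;
      double F2 = wall_p(Ap, P.A0, P.f) - wall_p(A1, D1.A0, D1.f);
      double F3 = wall_p(Ap, P.A0, P.f) - wall_p(A2, D2.A0, D2.f);
      if (std::fabs(F1) * scq + (std::fabs(F2) + std::fabs(F3)) * scf < 1e-12 && it > 0) break;
      double J11 = up - cp, J12 = -(u1 + c1), J13 = -(u2 + c2);
      double dpp = wall_dpdA(Ap, P.A0, P.f);
      double J21 = dpp, J22 = -wall_dpdA(A1, D1.A0, D1.f), J23 = 0.0;
      double J31 = dpp, J32 = 0.0, J33 = -wall_dpdA(A2, D2.A0, D2.f);
      // solve 3x3
      double det = J11 * (J22 * J33 - J23 * J32) - J12 * (J21 * J33 - J23 * J31)
                 + J13 * (J21 * J32 - J22 * J31);
      if (det == 0.0) throw SolverError{"singular junction Jacobian"};
      double b1 = -F1, b2 = -F2, b3 = -F3;
      double dAp = (b1 * (J22 * J33 - J23 * J32) - J12 * (b2 * J33 - J23 * b3)
                  + J13 * (b2 * J32 - J22 * b3)) / det;
      double dA1 = (J11 * (b2 * J33 - J23 * b3) - b1 * (J21 * J33 - J23 * J31)
                  + J13 * (J21 * b3 - b2 * J31)) / det;
      double dA2 = (J11 * (J22 * b3 - b2 * J32) - J12 * (J21 * b3 - b2 * J31)
                  + b1 * (J21 * J32 - J22 * J31)) / det;
      clampd(dAp, Ap); clampd(dA1, A1); clampd(dA2, A2);
      Ap += dAp; A1 += dA1; A2 += dA2;
      if (it == 59) throw SolverError{"junction Newton did not converge"};
    }
    double cp = wave_c(Ap, P.A0, P.c0), c1 = wave_c(A1, D1.A0, D1.c0),
           c2 = wave_c(A2, D2.A0, D2.c0);
    A[endL(p)] = Ap;  q[endL(p)] = Ap * (W1p - 4.0 * cp);
    A[beg(d1)] = A1;  q[beg(d1)] = A1 * (W21 + 4.0 * c1);
    A[beg(d2)] = A2;  q[beg(d2)] = A2 * (W22 + 4.0 * c2);
  }

  // converging junction: d1, d2 at x=L merge into c at x=0
  void bc_junction_conv(int d1, int d2, int cv) {
    const Vessel& D1 = ves[d1]; const Vessel& D2 = ves[d2]; const Vessel& C = ves[cv];
    double W11 = Wplus_at_L(d1);
    double W12 = Wplus_at_L(d2);
    double W2c = Wminus_at_0(cv);
    double A1 = Aold[endL(d1)], A2 = Aold[endL(d2)], Ac = Aold[beg(cv)];
    double scf = 1.0 / C.f, scq = 1.0 / (C.A0 * C.c0);
    for (int it = 0; it < 60; ++it) {
      double c1 = wave_c(A1, D1.A0, D1.c0), c2 = wave_c(A2, D2.A0, D2.c0),
             cc = wave_c(Ac, C.A0, C.c0);
      double u1 = W11 - 4.0 * c1, u2 = W12 - 4.0 * c2, uc = W2c + 4.0 * cc;
      double F1 = A1 * u1 + A2 * u2 - Ac * uc;
      double F2 = wall_p(A1, D1.A0, D1.f) - wall_p(Ac, C.A0, C.f);
      double F3 = wall_p(A2, D2.A0, D2.f) - wall_p(Ac, C.A0, C.f);
      if (std::fabs(F1) * scq + (std::fabs(F2) + std::fabs(F3)) * scf < 1e-12 && it > 0) break;
      double J11 = u1 - c1, J12 = u2 - c2, J13 = -(uc + cc);
      double J21 = wall_dpdA(A1, D1.A0, D1.f), J22 = 0.0,
             J23 = -wall_dpdA(Ac, C.A0, C.f);
      double J31 = 0.0, J32 = wall_dpdA(A2, D2.A0, D2.f), J33 = J23;
      double det = J11 * (J22 * J33 - J23 * J32) - J12 * (J21 * J33 - J23 * J31)
                 + J13 * (J21 * J32 - J22 * J31);
      if (det == 0.0) throw SolverError{"singular junction Jacobian"};
      double b1 = -F1, b2 = -F2, b3 = -F3;
      double dA1 = (b1 * (J22 * J33 - J23 * J32) - J12 * (b2 * J33 - J23 * b3)
                  + J13 * (b2 * J32 - J22 * b3)) / det;
      double dA2 = (J11 * (b2 * J33 - J23 * b3) - b1 * (J21 * J33 - J23 * J31)
                  + J13 * (J21 * b3 - b2 * J31)) / det;
      double dAc = (J11 * (J22 * b3 - b2 * J32) - J12 * (J21 * b3 - b2 * J31)
                  + b1 * (J21 * J32 - J22 * J31)) / det;
      clampd(dA1, A1); clampd(dA2, A2); clampd(dAc, Ac);
      A1 += dA1; A2 += dA2; Ac += dAc;
      if (it == 59) throw SolverError{"junction Newton did not converge"};
    }
    double c1 = wave_c(A1, D1.A0, D1.c0), c2 = wave_c(A2, D2.A0, D2.c0),
           cc = wave_c(Ac, C.A0, C.c0);
    A[endL(d1)] = A1; q[endL(d1)] = A1 * (W11 - 4.0 * c1);
    A[endL(d2)] = A2; q[endL(d2)] = A2 * (W12 - 4.0 * c2);
    A[beg(cv)] = Ac;  q[beg(cv)] = Ac * (W2c + 4.0 * cc);
  }

  // bed coupling: terminal artery x=L and paired vein x=0, convolution BC.
  // Kernels are in the symmetric into-port convention, so the +x vein flow is
  // minus the port-2 flow. k0* are the lag-0 kernel coefficients (implicit),
  // H1/H2 the explicit history sums.
  void bc_bed(int ia, int iv, double k011, double k012, double k021,
              double k022, double H1, double H2, int bed_id) {
    const Vessel& VA = ves[ia]; const Vessel& VV = ves[iv];
    double W1A = Wplus_at_L(ia);
    double W2V = Wminus_at_0(iv);
    double AA = Aold[endL(ia)], AV = Aold[beg(iv)];
    double scq = 1.0 / (VA.A0 * VA.c0);
    for (int it = 0; it < 80; ++it) {
      double cA = wave_c(AA, VA.A0, VA.c0), cV = wave_c(AV, VV.A0, VV.c0);
      double uA = W1A - 4.0 * cA, uV = W2V + 4.0 * cV;
      double pA = wall_p(AA, VA.A0, VA.f), pV = wall_p(AV, VV.A0, VV.f);
      double F1 = AA * uA - (k011 * pA + k012 * pV + H1);
      double F2 = AV * uV + (k021 * pA + k022 * pV + H2);
      if ((std::fabs(F1) + std::fabs(F2)) * scq < 1e-12 && it > 0) break;
      double dpA = wall_dpdA(AA, VA.A0, VA.f), dpV = wall_dpdA(AV, VV.A0, VV.f);
      double J11 = uA - cA - k011 * dpA;
      double J12 = -k012 * dpV;
      double J21 = k021 * dpA;
      double J22 = uV + cV + k022 * dpV;
      double det = J11 * J22 - J12 * J21;
      if (det == 0.0) throw SolverError{"singular bed Jacobian, bed " + std::to_string(bed_id)};
      double dAA = (-F1 * J22 + F2 * J12) / det;
      double dAV = (-J11 * F2 + J21 * F1) / det;
      clampd(dAA, AA); clampd(dAV, AV);
      AA += dAA; AV += dAV;
      if (it == 79) throw SolverError{"bed coupling iteration diverged, bed " + std::to_string(bed_id)};
    }
    double cA = wave_c(AA, VA.A0, VA.c0), cV = wave_c(AV, VV.A0, VV.c0);
    A[endL(ia)] = AA; q[endL(ia)] = AA * (W1A - 4.0 * cA);
    A[beg(iv)] = AV;  q[beg(iv)] = AV * (W2V + 4.0 * cV);
  }

  static inline void clampd(double& dA, double Acur) {
    if (dA > 0.5 * Acur) dA = 0.5 * Acur;
    if (dA < -0.5 * Acur) dA = -0.5 * Acur;
  }
};

// [[Rcpp::export]]
List lw_run(List vessels, List topo, List bcs, List numerics) {
  Network net;
  // vessels
  IntegerVector nx = vessels["nx"];
  NumericVector dxv = vessels["dx"], A0v = vessels["A0"], fv = vessels["f"],
                Lv = vessels["L"];
  int nv = nx.size(), off = 0;
  NumericVector pars = numerics["pars"];
  // pars: rho, nu, gamma, T, dt, n_store, substeps, max_cycles, tol, cfl_limit
  net.rho = pars[0]; net.nu = pars[1]; net.gamma = pars[2];
  double T = pars[3];
  int n_store = (int)pars[5], substeps = (int)pars[6],
      max_cycles = (int)pars[7];
  double tol = pars[8], cfl_limit = pars[9];
  net.dt = T / ((double)n_store * substeps);
  net.delta = (net.gamma + 2.0) / (net.gamma + 1.0);
  net.visc_coef = 2.0 * M_PI * net.nu * (net.gamma + 2.0);

  for (int v = 0; v < nv; ++v) {
    Vessel V;
    V.nx = nx[v]; V.off = off; V.dx = dxv[v]; V.A0 = A0v[v]; V.f = fv[v];
    V.L = Lv[v];
    V.c0 = std::sqrt(V.f / (2.0 * net.rho));
    net.ves.push_back(V);
    off += V.nx;
  }
  int NT = off;
  int nx_max = 0;
  for (int v = 0; v < nv; ++v) nx_max = std::max(nx_max, (int)nx[v]);
  net.Ah_buf.assign(nx_max, 0.0); net.qh_buf.assign(nx_max, 0.0);
  net.A.assign(NT, 0.0); net.q.assign(NT, 0.0);
  for (int v = 0; v < nv; ++v)
    for (int j = 0; j < net.ves[v].nx; ++j) net.A[net.ves[v].off + j] = net.ves[v].A0;
  net.Aold = net.A; net.qold = net.q;

  net.inlet = as<int>(topo["inlet"]);
  net.jdiv = as<IntegerMatrix>(topo["jdiv"]);
  net.jconv = as<IntegerMatrix>(topo["jconv"]);
  net.vein_out = as<IntegerVector>(topo["vein_out"]);
  net.nonrefl_out = as<IntegerVector>(topo["nonrefl_out"]);
  net.bed_idx = as<IntegerMatrix>(topo["bed_idx"]);
  List klist = topo["kernels"];
  int nbed = net.bed_idx.nrow();
  for (int b = 0; b < nbed; ++b) net.kernels.push_back(as<NumericMatrix>(klist[b]));

  NumericVector qin = bcs["q_inlet"];   // length n_store*substeps, value at each new substep time
  NumericVector pla = bcs["p_la"];
  int nsub_tot = n_store * substeps;

  // storage of final fields (periodically overwritten each cycle)
  NumericMatrix Astore(NT, n_store), qstore(NT, n_store);
  // bed pressure history ring buffers at storage resolution
  NumericMatrix pAh(n_store, std::max(nbed, 1)), pVh(n_store, std::max(nbed, 1));
  std::fill(pAh.begin(), pAh.end(), 0.0);
  std::fill(pVh.begin(), pVh.end(), 0.0);

  // previous-cycle midpoint traces for convergence checks
  NumericMatrix pmid_prev(n_store, nv), qmid_prev(n_store, nv);
  NumericMatrix pmid(n_store, nv), qmid(n_store, nv);
  std::vector<double> conv_hist;
  bool converged = false;
  int cycles_done = 0;
  double cfl_seen = 0.0;
  std::string err = "";

  std::vector<double> H1(nbed), H2(nbed), k011(nbed), k012(nbed), k021(nbed), k022(nbed);
  for (int b = 0; b < nbed; ++b) {
    k011[b] = net.kernels[b](0, 0);
    k012[b] = net.kernels[b](0, 1);
    k021[b] = net.kernels[b](0, 2);
    k022[b] = net.kernels[b](0, 3);
  }

  try {
    for (int cyc = 0; cyc < max_cycles && !converged; ++cyc) {
      for (int m = 0; m < n_store; ++m) {
        // explicit history sums for the upcoming storage sample m+1
        for (int b = 0; b < nbed; ++b) {
          const NumericMatrix& K = net.kernels[b];
          double h1 = 0.0, h2 = 0.0;
          int base = m + 1;
          for (int l = 1; l < n_store; ++l) {
            int idx = base - l; idx %= n_store; if (idx < 0) idx += n_store;
            double pa = pAh(idx, b), pv = pVh(idx, b);
            h1 += K(l, 0) * pa + K(l, 1) * pv;
            h2 += K(l, 2) * pa + K(l, 3) * pv;
          }
          H1[b] = h1; H2[b] = h2;
        }
        for (int sub = 0; sub < substeps; ++sub) {
          int nglob = (m * substeps + sub + 1) % nsub_tot; // index of the NEW time level
          net.Aold = net.A; net.qold = net.q;
          double cfl = net.step_interior();
          if (cfl > cfl_seen) cfl_seen = cfl;
          if (cfl > cfl_limit) {
            throw SolverError{"CFL violation (" + std::to_string(cfl) + ")"};
          }
          net.bc_inlet(qin[nglob]);
          for (int jj = 0; jj < net.jdiv.nrow(); ++jj)
            net.bc_junction_div(net.jdiv(jj, 0), net.jdiv(jj, 1), net.jdiv(jj, 2));
          for (int jj = 0; jj < net.jconv.nrow(); ++jj)
            net.bc_junction_conv(net.jconv(jj, 0), net.jconv(jj, 1), net.jconv(jj, 2));
          for (int b = 0; b < nbed; ++b)
            net.bc_bed(net.bed_idx(b, 0), net.bed_idx(b, 1), k011[b], k012[b],
                       k021[b], k022[b], H1[b], H2[b], b);
          for (int jj = 0; jj < net.vein_out.size(); ++jj)
            net.bc_vein_outlet(net.vein_out[jj], pla[nglob]);
          for (int jj = 0; jj < net.nonrefl_out.size(); ++jj)
            net.bc_nonreflecting(net.nonrefl_out[jj]);
        }
        // record storage sample (m+1) mod n_store
        int ms = (m + 1) % n_store;
        for (int v = 0; v < nv; ++v) {
          const Vessel& V = net.ves[v];
          for (int j = 0; j < V.nx; ++j) {
            Astore(V.off + j, ms) = net.A[V.off + j];
            qstore(V.off + j, ms) = net.q[V.off + j];
          }
          int jm = V.off + V.nx / 2;
          pmid(ms, v) = wall_p(net.A[jm], V.A0, V.f);
          qmid(ms, v) = net.q[jm];
        }
        for (int b = 0; b < nbed; ++b) {
          int ia = net.bed_idx(b, 0), iv = net.bed_idx(b, 1);
          pAh(ms, b) = wall_p(net.A[net.endL(ia)], net.ves[ia].A0, net.ves[ia].f);
          pVh(ms, b) = wall_p(net.A[net.beg(iv)], net.ves[iv].A0, net.ves[iv].f);
        }
      }
      cycles_done = cyc + 1;
      if (cyc >= 1) {
        double worst = 0.0;
        for (int v = 0; v < nv; ++v) {
          double dp = 0.0, dq = 0.0, sp = 0.0, sq = 0.0;
          for (int m2 = 0; m2 < n_store; ++m2) {
            dp = std::max(dp, std::fabs(pmid(m2, v) - pmid_prev(m2, v)));
            dq = std::max(dq, std::fabs(qmid(m2, v) - qmid_prev(m2, v)));
            sp = std::max(sp, std::fabs(pmid_prev(m2, v)));
            sq = std::max(sq, std::fabs(qmid_prev(m2, v)));
          }
          worst = std::max(worst, dp / (sp + 1e-30));
          worst = std::max(worst, dq / (sq + 1e-3));
        }
        conv_hist.push_back(worst);
        if (worst < tol) converged = true;
      }
      pmid_prev = clone(pmid);
      qmid_prev = clone(qmid);
    }
  } catch (SolverError& e) {
    err = e.msg;
  }

  return List::create(
    _["A"] = Astore, _["q"] = qstore,
    _["cycles"] = cycles_done, _["converged"] = converged,
    _["conv_history"] = NumericVector(conv_hist.begin(), conv_hist.end()),
    _["cfl_max"] = cfl_seen,
    _["pA_bed"] = pAh, _["pV_bed"] = pVh,
    _["error"] = err
  );
}
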