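#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Small dense linear solve (Gaussian elimination, partial pivoting).
// n is the number of species (<= a handful), called once per axial cell.
static void solve_small(std::vector<double>& M, std::vector<double>& b, int n) {
  for (int c = 0; c < n; ++c) {
    int piv = c;
    double best = std::fabs(M[c * n + c]);
    for (int r = c + 1; r < n; ++r) {
      double v = std::fabs(M[r * n + c]);
      if (v > best) { best = v; piv = r; }
    }
    if (piv != c) {
      for (int j = 0; j < n; ++j) std::swap(M[c * n + j], M[piv * n + j]);
      std::swap(b[c], b[piv]);
    }
    double d = M[c * n + c];
    for (int r = c + 1; r < n; ++r) {
      double f = M[r * n + c] / d;
      if (f == 0.0) continue;
      for (int j = c; j < n; ++j) M[r * n + j] -= f * M[c * n + j];
      b[r] -= f * b[c];
    }
  }
  for (int r = n - 1; r >= 0; --r) {
    double s = b[r];
    for (int j = r + 1; j < n; ++j) s -= M[r * n + j] * b[j];
    b[r] = s / M[r * n + r];
  }
}

// Right-hand side of the method-of-lines lumped-pore column model.
//
// State layout: y[k*2n + i] = C_i (mobile) in cell k, y[k*2n + n + i] = C_f,i
// (stagnant). Finite volumes with donor-cell (upwind) convection, central
// dispersion, Danckwerts flux inlet (total inlet flux = v*C_in) and
// zero-diffusive-flux outlet. The stagnant phase assumes local equilibrium
// with the multi-component Langmuir isotherm: the accumulation term
// [eps_p I + (1-eps_p) dq/dC_f] dC_f/dt = A k_eff (C - C_f) is solved per
// cell with the analytic isotherm Jacobian, including the salt column for
// salt-dependent parameters.
// [[Rcpp::export]]
NumericVector column_rhs_cpp(double t, NumericVector y, List p) {
  const int N = as<int>(p["N"]);
  const int n = as<int>(p["n"]);
  const double dz = as<double>(p["dz"]);
  const double eps_b = as<double>(p["eps_b"]);
  const double eps_p = as<double>(p["eps_p"]);
  NumericVector keffA = p["keffA"];
  IntegerVector iso_type = p["iso_type"];
  NumericVector qmax_fix = p["qmax_fix"];
  NumericVector Keq_fix = p["Keq_fix"];
  NumericVector a1 = p["a1"], a2 = p["a2"], b1 = p["b1"], b2 = p["b2"];
  const int salt_idx = as<int>(p["salt_idx"]);  // 1-based, 0 = none
  NumericVector seg_t = p["seg_t"];
  NumericVector seg_v = p["seg_v"];
  NumericMatrix seg_dax = p["seg_dax"];  // nseg x n
  NumericVector inlet_t = p["inlet_t"];
  NumericMatrix inlet_C = p["inlet_C"]; // length(inlet_t) x n

  // active program segment (piecewise-constant flow)
  int s = 0;
  for (int k = (int)seg_t.size() - 1; k >= 0; --k)
    if (t >= seg_t[k]) { s = k; break; }
  const double v = seg_v[s];

  // inlet concentrations by linear interpolation
  std::vector<double> cin(n);
  {
    const int m = inlet_t.size();
    double tc = t;
    if (tc <= inlet_t[0]) {
      for (int i = 0; i < n; ++i) cin[i] = inlet_C(0, i);
    } else if (tc >= inlet_t[m - 1]) {
      for (int i = 0; i < n; ++i) cin[i] = inlet_C(m - 1, i);
    } else {
      int lo = 0, hi = m - 1;
      while (hi - lo > 1) { int mid = (lo + hi) / 2; if (inlet_t[mid] <= tc) lo = mid; else hi = mid; }
      double w = (tc - inlet_t[lo]) / (inlet_t[hi] - inlet_t[lo]);
      for (int i = 0; i < n; ++i)
        cin[i] = (1.0 - w) * inlet_C(lo, i) + w * inlet_C(hi, i);
    }
  }

  NumericVector dy(2 * n * N);
  const double phi_m = 1.0 / eps_b;          // mobile-phase sink prefactor: keffA/eps_b
  const double phi_f = 1.0 / (1.0 - eps_b);  // stagnant source: A*k_eff = keffA/(1-eps_b)

  // --- mobile phase: convection + dispersion + exchange -------------------
  for (int i = 0; i < n; ++i) {
    const double D = seg_dax(s, i);
    double f_prev = v * cin[i];  // Danckwerts: total inlet flux
    for (int k = 0; k < N; ++k) {
      const double C = y[k * 2 * n + i];
      double f_next;
      if (k < N - 1) {
        const double Cnext = y[(k + 1) * 2 * n + i];
        f_next = v * C - D * (Cnext - C) / dz;
      } else {
        f_next = v * C;  // zero-gradient outlet
      }
      const double Cf = y[k * 2 * n + n + i];
      dy[k * 2 * n + i] = (f_prev - f_next) / dz
        - phi_m * keffA[i] * (C - Cf);
      f_prev = f_next;
    }
  }

  // --- stagnant phase: local-equilibrium closure per cell -----------------
  std::vector<double> M(n * n), rhs(n), Cf(n), Cfc(n);
  std::vector<double> K(n), qm(n), Kp(n);  // local Keq, qmax, dKeq/dc_salt
  std::vector<bool> bind(n);
  for (int k = 0; k < N; ++k) {
    const int base = k * 2 * n;
    double csalt = 0.0;
    if (salt_idx > 0) {
      csalt = y[base + n + (salt_idx - 1)];
      if (csalt < 0.0) csalt = 0.0;
    }
    double S = 1.0, dSdc = 0.0;
    for (int i = 0; i < n; ++i) {
      Cf[i] = y[base + n + i];
      Cfc[i] = Cf[i] > 0.0 ? Cf[i] : 0.0;  // clamp for isotherm evaluation
      bind[i] = iso_type[i] != 0;
      K[i] = 0.0; qm[i] = 0.0; Kp[i] = 0.0;
      if (iso_type[i] == 1) {
        K[i] = Keq_fix[i]; qm[i] = qmax_fix[i];
      } else if (iso_type[i] == 2) {
        double q = a1[i] * csalt + a2[i];
        qm[i] = q > 0.0 ? q : 0.0;  // floor beyond calibrated salt range
        K[i] = b1[i] * std::exp(-b2[i] * csalt);
        Kp[i] = -b2[i] * K[i];
        if (bind[i]) { S += K[i] * Cfc[i]; dSdc += Kp[i] * Cfc[i]; }
        continue;
      }
      if (bind[i]) S += K[i] * Cfc[i];
    }
    const double S2 = S * S;
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) M[i * n + j] = 0.0;
      M[i * n + i] = eps_p;
      if (bind[i]) {
        const double kq = K[i] * qm[i];
        for (int j = 0; j < n; ++j) {
          if (!bind[j]) continue;
          double Jij = kq * (((i == j) ? S : 0.0) - Cfc[i] * K[j]) / S2;
          M[i * n + j] += (1.0 - eps_p) * Jij;
        }
        if (salt_idx > 0 && iso_type[i] >= 1) {
          // d q_i / d c_salt: parameter drift plus denominator drift
          double dpar = 0.0;
          if (iso_type[i] == 2) {
            double da1 = (a1[i] * csalt + a2[i]) > 0.0 ? a1[i] : 0.0;
            dpar = (Kp[i] * qm[i] + K[i] * da1) * Cfc[i] / S;
          }
          double Jic = dpar - kq * Cfc[i] * dSdc / S2;
          M[i * n + (salt_idx - 1)] += (1.0 - eps_p) * Jic;
        }
      }
      rhs[i] = phi_f * keffA[i] * (y[base + i] - Cf[i]);
    }
    solve_small(M, rhs, n);
    for (int i = 0; i < n; ++i) dy[base + n + i] = rhs[i];
  }
  return dy;
}
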