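// Cyclic-coordinate-descent ring closure inner loop.
//
// Operates on the flat N/CA/C chain matrix built in R (3L + 3 rows: the
// backbone chain plus a virtual copy of residue 1's N/CA/C continued past
// residue L). Each CCD step rotates one adjustable torsion by the
// (step-capped) angle that best superposes the virtual atoms onto the
// real residue-1 atoms.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

static inline void getrow(const NumericMatrix& A, int i, double* out) {
  out[0] = A(i, 0); out[1] = A(i, 1); out[2] = A(i, 2);
}

static double angle_deg(const double* a, const double* b, const double* c) {
  double u[3], v[3];
  for (int k = 0; k < 3; ++k) { u[k] = a[k] - b[k]; v[k] = c[k] - b[k]; }
  double cosang = dot3(u, v) / (norm3(u) * norm3(v));
  if (cosang > 1.0) cosang = 1.0;
  if (cosang < -1.0) cosang = -1.0;
  return std::acos(cosang) * 180.0 / M_PI;
}

static double dihedral_deg(const double* p1, const double* p2,
                           const double* p3, const double* p4) {
  double b1[3], b2[3], b3[3], n1[3], n2[3], m1[3], u2[3];
  for (int k = 0; k < 3; ++k) {
    b1[k] = p2[k] - p1[k];
    b2[k] = p3[k] - p2[k];
    b3[k] = p4[k] - p3[k];
  }
  cross3(b1, b2, n1);
  cross3(b2, b3, n2);
  double nb2 = norm3(b2);
  for (int k = 0; k < 3; ++k) u2[k] = b2[k] / nb2;
  cross3(n1, u2, m1);
  return std::atan2(dot3(m1, n2), dot3(n1, n2)) * 180.0 / M_PI;
}

static double wrap_deg(double x) {
  double w = x - 360.0 * std::floor((x + 180.0) / 360.0);
  if (w == -180.0) w = 180.0;
  return w;
}

// Residual of the head-to-tail bond measured on the chain matrix.
static void residual(const NumericMatrix& A, int L, double c_n,
                     double ca_c_n, double c_n_ca,
                     double* bond_dev, double* angle_dev, double* omega_dev) {
  double CL[3], N1[3], CA1[3], CAL[3], d[3];
  getrow(A, 3 * L - 1, CL);
  getrow(A, 0, N1);
  getrow(A, 1, CA1);
  getrow(A, 3 * L - 2, CAL);
  for (int k = 0; k < 3; ++k) d[k] = CL[k] - N1[k];
  *bond_dev = std::fabs(norm3(d) - c_n);
  double a1 = std::fabs(angle_deg(CAL, CL, N1) - ca_c_n);
  double a2 = std::fabs(angle_deg(CL, N1, CA1) - c_n_ca);
  *angle_dev = a1 > a2 ? a1 : a2;
  *omega_dev = std::fabs(wrap_deg(dihedral_deg(CAL, CL, N1, CA1) - 180.0));
}

// One CCD sweep over the adjustable torsions; returns nothing, mutates
// `chain` in place.
static void ccd_sweep(NumericMatrix& chain, int n,
                      const IntegerVector& torsion_res,
                      const IntegerVector& torsion_ang, double max_step) {
  for (int t = 0; t < torsion_res.size(); ++t) {
    int p = torsion_res[t];
    int ang = torsion_ang[t];
    int i0 = (p - 1) * 3 + (ang == 0 ? 0 : 1);
    int i1 = i0 + 1;
    double origin[3], axis[3];
    getrow(chain, i1, origin);
    for (int k = 0; k < 3; ++k) axis[k] = chain(i1, k) - chain(i0, k);
    double an = norm3(axis);
    for (int k = 0; k < 3; ++k) axis[k] /= an;
    double a = 0.0, b = 0.0;
    for (int m = n - 3; m < n; ++m) {
      double mrel[3], f[3], kxr[3], r[3], tgt[3];
      for (int k = 0; k < 3; ++k) mrel[k] = chain(m, k) - origin[k];
      double proj = dot3(mrel, axis);
      for (int k = 0; k < 3; ++k) r[k] = mrel[k] - proj * axis[k];
      getrow(chain, m - (n - 3), tgt);
      for (int k = 0; k < 3; ++k) f[k] = tgt[k] - origin[k];
      double fproj = dot3(f, axis);
      for (int k = 0; k < 3; ++k) f[k] -= fproj * axis[k];
      cross3(axis, r, kxr);
      a += dot3(f, r);
      b += dot3(f, kxr);
    }
    double theta = std::atan2(b, a);
    if (theta > max_step) theta = max_step;
    if (theta < -max_step) theta = -max_step;
    if (std::fabs(theta) < 1e-12) continue;
    double ct = std::cos(theta), st = std::sin(theta);
    for (int m = i1 + 1; m < n; ++m) {
      double v[3], kxv[3];
      for (int k = 0; k < 3; ++k) v[k] = chain(m, k) - origin[k];
      double kv = dot3(axis, v);
      cross3(axis, v, kxv);
      for (int k = 0; k < 3; ++k) {
        chain(m, k) = origin[k] + v[k] * ct + kxv[k] * st +
          axis[k] * kv * (1.0 - ct);
      }
    }
  }
}

// Rotate a single torsion by `theta` (radians), mutating `chain`.
static void rotate_torsion(NumericMatrix& chain, int n, int p, int ang,
                           double theta) {
  int i0 = (p - 1) * 3 + (ang == 0 ? 0 : 1);
  int i1 = i0 + 1;
  double origin[3], axis[3];
  getrow(chain, i1, origin);
  for (int k = 0; k < 3; ++k) axis[k] = chain(i1, k) - chain(i0, k);
  double an = norm3(axis);
  for (int k = 0; k < 3; ++k) axis[k] /= an;
  double ct = std::cos(theta), st = std::sin(theta);
  for (int m = i1 + 1; m < n; ++m) {
    double v[3], kxv[3];
    for (int k = 0; k < 3; ++k) v[k] = chain(m, k) - origin[k];
    double kv = dot3(axis, v);
    cross3(axis, v, kxv);
    for (int k = 0; k < 3; ++k) {
      chain(m, k) = origin[k] + v[k] * ct + kxv[k] * st +
        axis[k] * kv * (1.0 - ct);
    }
  }
}

// Measure phi(p) / psi(p) from the chain (virtual row used for psi(L)).
static double measure_torsion(const NumericMatrix& chain, int p, int ang) {
  double p1[3], p2[3], p3[3], p4[3];
  int k = (p - 1) * 3;
  if (ang == 0) {  // phi: C(p-1), N(p), CA(p), C(p); only p >= 2
    getrow(chain, k - 1, p1);
    getrow(chain, k, p2);
    getrow(chain, k + 1, p3);
    getrow(chain, k + 2, p4);
  } else {  // psi: N(p), CA(p), C(p), N(p+1)
    getrow(chain, k, p1);
    getrow(chain, k + 1, p2);
    getrow(chain, k + 2, p3);
    getrow(chain, k + 3, p4);
  }
  return dihedral_deg(p1, p2, p3, p4);
}

// Wrapped-normal factor (one wrap either side), matching the R density.
static double wnorm(double x, double mu, double sigma) {
  double d = wrap_deg(x - mu);
  const double c = 1.0 / (sigma * std::sqrt(2.0 * M_PI));
  return c * (std::exp(-0.5 * d * d / (sigma * sigma)) +
              std::exp(-0.5 * (d + 360.0) * (d + 360.0) / (sigma * sigma)) +
              std::exp(-0.5 * (d - 360.0) * (d - 360.0) / (sigma * sigma)));
}

// torsion_res / torsion_ang describe the adjustable torsions:
// torsion_ang = 0 for phi (axis N->CA), 1 for psi (axis CA->C);
// residue indices are 1-based.
// [[Rcpp::export(name = ".ccd_close_cpp")]]
List ccd_close_cpp(NumericMatrix A, int L,
                   IntegerVector torsion_res, IntegerVector torsion_ang,
                   double tol_b, double tol_a, int max_sweeps,
                   double max_step,
                   double c_n, double ca_c_n, double c_n_ca) {
  NumericMatrix chain = clone(A);
  int n = chain.nrow();
  double bond_dev, angle_dev, omega_dev;
  residual(chain, L, c_n, ca_c_n, c_n_ca, &bond_dev, &angle_dev, &omega_dev);
  int sweeps = 0;
  while (!(bond_dev <= tol_b && angle_dev <= tol_a) && sweeps < max_sweeps) {
    ++sweeps;
    ccd_sweep(chain, n, torsion_res, torsion_ang, max_step);
    residual(chain, L, c_n, ca_c_n, c_n_ca, &bond_dev, &angle_dev, &omega_dev);
  }
  return List::create(
    _["chain"] = chain, _["sweeps"] = sweeps,
    _["bond_dev"] = bond_dev, _["angle_dev"] = angle_dev,
    _["omega_dev"] = omega_dev,
    _["success"] = (bond_dev <= tol_b && angle_dev <= tol_a)
  );
}

// Ramachandran-restrained ring closure by projected gradient descent on
// the closed-ring manifold.
//
// DOFs are the open chain's torsions (virtual wrap phi included) plus the
// backbone bond angles (C-N-CA, N-CA-C, CA-C-N), each tethered to its
// target: torsions to the center of the residue's assigned Ramachandran
// basin (spread = basin sigma), bond angles to ideal geometry with a
// tight spread, mirroring the small angular strain real macrocycles
// carry. The closure constraint c(theta) in R^9 stacks the residuals of
// the three virtual end atoms against the real residue-1 triad. Each
// iteration Newton-restores closure (step -J^T (JJ^T)^-1 c), then takes a
// capped Gauss-Newton step on the tether objective projected onto the
// null space of J, so the ring stays closed while sliding toward the
// assigned basins. The tether is barrier-free, so convergence failures
// mean the assignment is geometrically infeasible, not optimiser
// misfortune; infeasible assignments are rejected by the caller.

// solve (M + lambda I) x = b for symmetric 9x9 M, Gauss with partial pivot
static bool solve9(double M[9][9], double b[9], double x[9], double lambda) {
  double a[9][10];
  for (int i = 0; i < 9; ++i) {
    for (int j = 0; j < 9; ++j) a[i][j] = M[i][j] + (i == j ? lambda : 0.0);
    a[i][9] = b[i];
  }
  for (int col = 0; col < 9; ++col) {
    int piv = col;
    for (int i = col + 1; i < 9; ++i)
      if (std::fabs(a[i][col]) > std::fabs(a[piv][col])) piv = i;
    if (std::fabs(a[piv][col]) < 1e-14) return false;
    if (piv != col) for (int j = 0; j < 10; ++j) std::swap(a[piv][j], a[col][j]);
    for (int i = 0; i < 9; ++i) {
      if (i == col) continue;
      double f = a[i][col] / a[col][col];
      for (int j = col; j < 10; ++j) a[i][j] -= f * a[col][j];
    }
  }
  for (int i = 0; i < 9; ++i) x[i] = a[i][9] / a[i][i];
  return true;
}

// [[Rcpp::export(name = ".ring_relax_cpp")]]
List ring_relax_cpp(NumericMatrix A, int L,
                    double tol_b, double tol_a,
                    int max_iter, double step_cap_deg,
                    NumericMatrix basins, IntegerVector assign,
                    double p_max, double e_target, double sigma_angle,
                    int stall_limit,
                    double n_ca_c, double ca_c_n, double c_n_ca,
                    double c_n, double ca_c_nn, double c_n_caa) {
  NumericMatrix chain = clone(A);
  int n = chain.nrow();
  int nb = basins.nrow();
  double bond_dev, angle_dev, omega_dev;

  // DOF table. kind: 0 phi (p >= 2), 1 psi, 2 virtual wrap phi,
  // 3 angle at N(p) (C(p-1)-N-CA, p >= 2), 4 angle at CA(p) (N-CA-C),
  // 5 angle at C(p) (CA-C-N(p+1))
  std::vector<int> dof_p, dof_k;
  std::vector<double> tether, sig;
  dof_k.push_back(2); dof_p.push_back(1);
  dof_k.push_back(1); dof_p.push_back(1);
  for (int p = 2; p <= L; ++p) {
    dof_k.push_back(0); dof_p.push_back(p);
    dof_k.push_back(1); dof_p.push_back(p);
  }
  for (int p = 1; p <= L; ++p) {
    if (p >= 2) { dof_k.push_back(3); dof_p.push_back(p); }
    dof_k.push_back(4); dof_p.push_back(p);
    dof_k.push_back(5); dof_p.push_back(p);
  }
  int nd = (int)dof_p.size();
  std::vector<int> cur_assign(L);
  for (int r = 0; r < L; ++r) cur_assign[r] = assign[r] - 1;
  tether.resize(nd);
  sig.resize(nd);
  for (int d = 0; d < nd; ++d) {
    int p = dof_p[d], kk = dof_k[d];
    if (kk <= 2) {
      int b = assign[p - 1] - 1;
      tether[d] = (kk == 1) ? basins(b, 1) : basins(b, 0);
      sig[d] = basins(b, 2);
    } else {
      tether[d] = (kk == 3) ? c_n_ca : (kk == 4 ? n_ca_c : ca_c_n);
      sig[d] = sigma_angle;
    }
  }

  // axis, origin and first moving row of a DOF; rotation by +theta about
  // the axis DECREASES the measured value (torsion or bond angle)
  auto axis_of = [&](int d, double* origin, double* axis, int* mv_first) {
    int p = dof_p[d], kk = dof_k[d];
    if (kk == 2) {
      getrow(chain, n - 2, origin);
      double a0[3];
      getrow(chain, n - 3, a0);
      for (int k = 0; k < 3; ++k) axis[k] = origin[k] - a0[k];
      *mv_first = n - 1;
    } else if (kk <= 1) {
      int i0 = (p - 1) * 3 + (kk == 0 ? 0 : 1);
      getrow(chain, i0 + 1, origin);
      double a0[3];
      getrow(chain, i0, a0);
      for (int k = 0; k < 3; ++k) axis[k] = origin[k] - a0[k];
      *mv_first = i0 + 2;
    } else {
      int vtx = (p - 1) * 3 + (kk - 3);  // N, CA or C row
      double prev[3], nxt[3], u[3], v[3];
      getrow(chain, vtx, origin);
      getrow(chain, vtx - 1, prev);
      getrow(chain, vtx + 1, nxt);
      for (int k = 0; k < 3; ++k) { u[k] = origin[k] - prev[k]; v[k] = nxt[k] - origin[k]; }
      cross3(u, v, axis);
      *mv_first = vtx + 1;
    }
    double an = norm3(axis);
    for (int k = 0; k < 3; ++k) axis[k] /= an;
  };

  auto res_pair = [&](int r, double* phi, double* psi) {
    if (r == 1) {
      double p1[3], p2[3], p3[3], p4[3];
      getrow(chain, 3 * L - 1, p1);
      getrow(chain, n - 3, p2);
      getrow(chain, n - 2, p3);
      getrow(chain, n - 1, p4);
      *phi = dihedral_deg(p1, p2, p3, p4);
    } else {
      *phi = measure_torsion(chain, r, 0);
    }
    *psi = measure_torsion(chain, r, 1);
  };

  auto energy_at = [&](double phi, double psi) {
    double dens = 0.0;
    for (int k = 0; k < nb; ++k) {
      dens += basins(k, 3) * wnorm(phi, basins(k, 0), basins(k, 2)) *
        wnorm(psi, basins(k, 1), basins(k, 2));
    }
    double e = -std::log(dens / p_max);
    return e < 0.0 ? 0.0 : e;
  };

  // energy with analytic d/dphi, d/dpsi (wrapped-normal mixture)
  auto energy_grad_at = [&](double phi, double psi, double* e,
                            double* dphi, double* dpsi) {
    double dens = 0.0, gp = 0.0, gq = 0.0;
    for (int k = 0; k < nb; ++k) {
      double sg = basins(k, 2), s2 = sg * sg;
      double dp = wrap_deg(phi - basins(k, 0));
      double dq = wrap_deg(psi - basins(k, 1));
      double fp = 0.0, fq = 0.0, fpd = 0.0, fqd = 0.0;
      const double c = 1.0 / (sg * std::sqrt(2.0 * M_PI));
      for (int w = -1; w <= 1; ++w) {
        double xp = dp + 360.0 * w, xq = dq + 360.0 * w;
        double tp = c * std::exp(-0.5 * xp * xp / s2);
        double tq = c * std::exp(-0.5 * xq * xq / s2);
        fp += tp;
        fq += tq;
        fpd += -xp / s2 * tp;
        fqd += -xq / s2 * tq;
      }
      double wk = basins(k, 3);
      dens += wk * fp * fq;
      gp += wk * fpd * fq;
      gq += wk * fp * fqd;
    }
    double ee = -std::log(dens / p_max);
    *e = ee < 0.0 ? 0.0 : ee;
    *dphi = -gp / dens;
    *dpsi = -gq / dens;
  };

  // current value of a DOF (degrees): torsion or bond angle
  auto dof_value = [&](int d) {
    int p = dof_p[d], kk = dof_k[d];
    if (kk == 2) {
      double p1[3], p2[3], p3[3], p4[3];
      getrow(chain, 3 * L - 1, p1);
      getrow(chain, n - 3, p2);
      getrow(chain, n - 2, p3);
      getrow(chain, n - 1, p4);
      return dihedral_deg(p1, p2, p3, p4);
    }
    if (kk <= 1) return measure_torsion(chain, p, kk);
    int vtx = (p - 1) * 3 + (kk - 3);
    double prev[3], o[3], nxt[3];
    getrow(chain, vtx - 1, prev);
    getrow(chain, vtx, o);
    getrow(chain, vtx + 1, nxt);
    return angle_deg(prev, o, nxt);
  };

  auto closure_vec = [&](double* c) {
    for (int m = 0; m < 3; ++m) {
      double v[3], t[3];
      getrow(chain, n - 3 + m, v);
      getrow(chain, m, t);
      for (int k = 0; k < 3; ++k) c[3 * m + k] = v[k] - t[k];
    }
  };

  // Jacobian of the closure vector w.r.t. each DOF in its own degree
  // units (torsions: value decreases under +theta rotation)
  std::vector<double> J(9 * nd);
  auto jacobian = [&]() {
    for (int d = 0; d < nd; ++d) {
      double f = -M_PI / 180.0;  // +theta rotation decreases every DOF value
      double origin[3], axis[3];
      int mv_first;
      axis_of(d, origin, axis, &mv_first);
      for (int m = 0; m < 3; ++m) {
        int row = n - 3 + m;
        double der[3] = {0, 0, 0};
        if (row >= mv_first) {
          double v[3];
          for (int k = 0; k < 3; ++k) v[k] = chain(row, k) - origin[k];
          cross3(axis, v, der);
          for (int k = 0; k < 3; ++k) der[k] *= f;
        }
        for (int k = 0; k < 3; ++k) J[(3 * m + k) * nd + d] = der[k];
      }
    }
  };

  auto apply_steps = [&](const std::vector<double>& dv) {
    for (int d = 0; d < nd; ++d) {
      if (std::fabs(dv[d]) < 2e-3) continue;  // negligible rotation
      double origin[3], axis[3];
      int mv_first;
      axis_of(d, origin, axis, &mv_first);
      double th = -dv[d] * M_PI / 180.0;
      double ct = std::cos(th), st = std::sin(th);
      for (int m = mv_first; m < n; ++m) {
        double v[3], kxv[3];
        for (int k = 0; k < 3; ++k) v[k] = chain(m, k) - origin[k];
        double kv = dot3(axis, v);
        cross3(axis, v, kxv);
        for (int k = 0; k < 3; ++k) {
          chain(m, k) = origin[k] + v[k] * ct + kxv[k] * st +
            axis[k] * kv * (1.0 - ct);
        }
      }
    }
  };

  // DOF metric: tether variances; stiff DOFs (bond angles) move less
  std::vector<double> W(nd);
  for (int d = 0; d < nd; ++d) W[d] = sig[d] * sig[d];

  // solve (J W J^T + eps) mu = rhs
  auto solve_normal = [&](const double* rhs9, double* mu) {
    double M[9][9];
    for (int i = 0; i < 9; ++i)
      for (int j = 0; j < 9; ++j) {
        double s = 0.0;
        for (int d = 0; d < nd; ++d) s += W[d] * J[i * nd + d] * J[j * nd + d];
        M[i][j] = s;
      }
    double b[9];
    for (int i = 0; i < 9; ++i) b[i] = rhs9[i];
    return solve9(M, b, mu, 1e-9);
  };

  // restoration uses torsion DOFs only (angle columns zeroed): cheaper,
  // and keeps closure corrections out of the stiff angle DOFs entirely
  auto restore = [&](int iters) {
    for (int it = 0; it < iters; ++it) {
      double c[9];
      closure_vec(c);
      double nrm = 0.0;
      for (int k = 0; k < 9; ++k) nrm += c[k] * c[k];
      if (nrm < 1e-6) break;
      if (it == 0 || nrm > 1e-2) jacobian();  // reuse J for small corrections
      double mu[9];
      if (!solve_normal(c, mu)) break;
      std::vector<double> dv(nd);
      for (int d = 0; d < nd; ++d) {
        if (dof_k[d] > 2) { dv[d] = 0.0; continue; }
        double s = 0.0;
        for (int k = 0; k < 9; ++k) s += J[k * nd + d] * mu[k];
        dv[d] = -W[d] * s;
        if (dv[d] > 15.0) dv[d] = 15.0;
        if (dv[d] < -15.0) dv[d] = -15.0;
      }
      apply_steps(dv);
    }
  };

  auto closed_ok = [&]() {
    residual(chain, L, c_n, ca_c_nn, c_n_caa, &bond_dev, &angle_dev, &omega_dev);
    return bond_dev <= tol_b && angle_dev <= tol_a;
  };

  restore(40);
  int iters = 0;
  int kicks_left = 1;
  int stall = 0;
  double best_worst = 1e300;
  bool success = false;
  GetRNGstate();
  for (int it = 0; it < max_iter; ++it) {
    ++iters;
    restore(it == 0 ? 3 : 2);
    bool ok = closed_ok();
    double worst = 0.0;
    for (int r = 1; r <= L; ++r) {
      double phi, psi;
      res_pair(r, &phi, &psi);
      double e = energy_at(phi, psi);
      if (e > worst) worst = e;
    }
    if (ok && worst <= e_target) { success = true; break; }
    // stall detection: give up when the worst residue stops improving
    if (worst < best_worst - 0.01) { best_worst = worst; stall = 0; }
    else if (++stall > stall_limit) break;
    // gradient: torsions descend the hinge penalty on the mixture energy
    // (any basin satisfies the filter); bond angles stay tethered to
    // ideal geometry
    std::vector<double> gphi(L + 1), gpsi(L + 1);
    for (int r = 1; r <= L; ++r) {
      double phi, psi, e, dp, dq;
      res_pair(r, &phi, &psi);
      energy_grad_at(phi, psi, &e, &dp, &dq);
      // d/dv of the hinge penalty max(0, E - 0.75 e_target)^2
      double hp = e > 0.75 * e_target ? 2.0 * (e - 0.75 * e_target) : 0.0;
      gphi[r] = hp * dp;
      gpsi[r] = hp * dq;
    }
    std::vector<double> g(nd);
    for (int d = 0; d < nd; ++d) {
      if (dof_k[d] <= 2) {
        int r = (dof_k[d] == 2) ? 1 : dof_p[d];
        g[d] = (dof_k[d] == 1) ? gpsi[r] : gphi[r];
      } else {
        g[d] = (dof_value(d) - tether[d]) / (sig[d] * sig[d]);
      }
    }
    jacobian();
    double Jg[9], mu[9];
    for (int i = 0; i < 9; ++i) {
      double s = 0.0;
      for (int d = 0; d < nd; ++d) s += W[d] * J[i * nd + d] * g[d];
      Jg[i] = s;
    }
    if (!solve_normal(Jg, mu)) break;
    // W-metric steepest descent of the tether, tangent to the manifold
    std::vector<double> dv(nd);
    double dmax = 0.0;
    for (int d = 0; d < nd; ++d) {
      double s = 0.0;
      for (int k = 0; k < 9; ++k) s += J[k * nd + d] * mu[k];
      dv[d] = -0.5 * W[d] * (g[d] - s);
      double cap = dof_k[d] <= 2 ? step_cap_deg : 1.0;
      if (dv[d] > cap) dv[d] = cap;
      if (dv[d] < -cap) dv[d] = -cap;
      if (std::fabs(dv[d]) > dmax) dmax = std::fabs(dv[d]);
    }
    if (dmax < 0.01) {
      // stalled at an infeasible stationary point: random tangent-space
      // kick (basin hopping on the closure manifold), then keep going
      if (kicks_left-- <= 0) break;
      std::vector<double> xi(nd);
      for (int d = 0; d < nd; ++d)
        xi[d] = (dof_k[d] <= 2) ? (unif_rand() * 2.0 - 1.0) / W[d] : 0.0;
      double Jxi[9], muk[9];
      for (int i = 0; i < 9; ++i) {
        double s = 0.0;
        for (int d = 0; d < nd; ++d) s += W[d] * J[i * nd + d] * xi[d];
        Jxi[i] = s;
      }
      if (!solve_normal(Jxi, muk)) break;
      for (int d = 0; d < nd; ++d) {
        double s = 0.0;
        for (int k = 0; k < 9; ++k) s += J[k * nd + d] * muk[k];
        double step = 40.0 * W[d] * (xi[d] - s);  // ~40 deg torsion kicks
        if (step > 60.0) step = 60.0;
        if (step < -60.0) step = -60.0;
        dv[d] = step;
      }
      apply_steps(dv);
      restore(10);
      continue;
    }
    apply_steps(dv);
  }
  PutRNGstate();
  restore(5);
  residual(chain, L, c_n, ca_c_nn, c_n_caa, &bond_dev, &angle_dev, &omega_dev);
  double worst_e = 0.0;
  NumericVector phi_out(L), psi_out(L);
  for (int r = 1; r <= L; ++r) {
    double phi, psi;
    res_pair(r, &phi, &psi);
    phi_out[r - 1] = phi;
    psi_out[r - 1] = psi;
    double e = energy_at(phi, psi);
    if (e > worst_e) worst_e = e;
  }
  double max_angle_strain = 0.0;
  for (int d = 0; d < nd; ++d) {
    if (dof_k[d] <= 2) continue;
    double s = std::fabs(dof_value(d) - tether[d]);
    if (s > max_angle_strain) max_angle_strain = s;
  }
  if (success) {
    bool ok = (bond_dev <= tol_b && angle_dev <= tol_a);
    for (int r = 1; r <= L && ok; ++r) {
      double phi, psi;
      res_pair(r, &phi, &psi);
      ok = energy_at(phi, psi) <= e_target;
    }
    success = ok;
  }
  return List::create(
    _["chain"] = chain, _["sweeps"] = iters,
    _["bond_dev"] = bond_dev, _["angle_dev"] = angle_dev,
    _["omega_dev"] = omega_dev, _["angle_strain"] = max_angle_strain,
    _["worst_e"] = worst_e, _["phi"] = phi_out, _["psi"] = psi_out,
    _["success"] = success
  );
}


// NeRF chain building: N/CA/C for residues 1..L plus the virtual closure
// triad, from torsions under ideal geometry. Mirrors the R builder
// (rotation by +theta decreases the measured dihedral, hence -tor).
static void nerf_place(const double* a, const double* b, const double* c,
                       double bond, double angle_deg_v, double tor_deg,
                       double* out) {
  double ang = angle_deg_v * M_PI / 180.0;
  double tor = tor_deg * M_PI / 180.0;
  double d2[3] = {-bond * std::cos(ang),
                  bond * std::sin(ang) * std::cos(tor),
                  -bond * std::sin(ang) * std::sin(tor)};
  double bc[3], ab[3], n[3], m1[3];
  for (int k = 0; k < 3; ++k) { bc[k] = c[k] - b[k]; ab[k] = b[k] - a[k]; }
  double nb = norm3(bc);
  for (int k = 0; k < 3; ++k) bc[k] /= nb;
  cross3(ab, bc, n);
  double nn = norm3(n);
  for (int k = 0; k < 3; ++k) n[k] /= nn;
  cross3(n, bc, m1);
  for (int k = 0; k < 3; ++k) {
    out[k] = bc[k] * d2[0] + m1[k] * d2[1] + n[k] * d2[2] + c[k];
  }
}

// [[Rcpp::export(name = ".build_chain_cpp")]]
NumericMatrix build_chain_cpp(NumericVector phi, NumericVector psi,
                              NumericVector omega,
                              double n_ca, double ca_c, double c_n,
                              double n_ca_c, double ca_c_n, double c_n_ca) {
  int L = phi.size();
  NumericMatrix A(3 * L + 3, 3);
  double th = n_ca_c * M_PI / 180.0;
  A(0, 0) = 0; A(0, 1) = 0; A(0, 2) = 0;
  A(1, 0) = n_ca; A(1, 1) = 0; A(1, 2) = 0;
  A(2, 0) = n_ca - ca_c * std::cos(th);
  A(2, 1) = ca_c * std::sin(th);
  A(2, 2) = 0;
  for (int i = 0; i < L; ++i) {
    int k = 3 * i;
    double p1[3], p2[3], p3[3], out[3];
    double phi_next = (i + 1 < L) ? phi[i + 1] : phi[0];
    getrow(A, k, p1); getrow(A, k + 1, p2); getrow(A, k + 2, p3);
    nerf_place(p1, p2, p3, c_n, ca_c_n, psi[i], out);
    for (int q = 0; q < 3; ++q) A(k + 3, q) = out[q];
    getrow(A, k + 1, p1); getrow(A, k + 2, p2); getrow(A, k + 3, p3);
    nerf_place(p1, p2, p3, n_ca, c_n_ca, omega[i], out);
    for (int q = 0; q < 3; ++q) A(k + 4, q) = out[q];
    getrow(A, k + 2, p1); getrow(A, k + 3, p2); getrow(A, k + 4, p3);
    nerf_place(p1, p2, p3, ca_c, n_ca_c, phi_next, out);
    for (int q = 0; q < 3; ++q) A(k + 5, q) = out[q];
  }
  return A;
}
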