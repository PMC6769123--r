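// Coupled displacement/potential hex8 element and global assembly.
//
// Total-Lagrangian weak form, backward-Euler in time for the potential and
// the quadrature-point internal variables (recovery r, active tension T).
// The element Jacobian carries all four coupling blocks:
//   dRu/du (material + geometric + active), dRu/dPhi (active tension),
//   dRphi/dPhi (capacity + conduction + reaction), dRphi/du (deformed
//   conductivity + stretch-activated current).
// Optional selective reduced integration (single center point) of the
// volumetric penalty term mitigates locking of the nearly incompressible
// models on coarse hexahedral meshes.

#include "cem.h"
using namespace arma;

static const double GP1 = 0.5773502691896257645091488;

static void hex8_shape(double xi, double eta, double zeta,
                       double N[8], double dN[8][3]) {
  static const double sg[8][3] = {
    {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
    {-1, -1, 1},  {1, -1, 1},  {1, 1, 1},  {-1, 1, 1}};
  for (int a = 0; a < 8; ++a) {
    double sx = sg[a][0], sy = sg[a][1], sz = sg[a][2];
    N[a] = 0.125 * (1 + sx * xi) * (1 + sy * eta) * (1 + sz * zeta);
    dN[a][0] = 0.125 * sx * (1 + sy * eta) * (1 + sz * zeta);
    dN[a][1] = 0.125 * sy * (1 + sx * xi) * (1 + sz * zeta);
    dN[a][2] = 0.125 * sz * (1 + sx * xi) * (1 + sy * eta);
  }
}

struct GpGeom {
  double N[8];
  double dNdX[8][3];
  double detJ;
};

// geometry of one quadrature point; returns false on non-positive mapping
static bool gp_geometry(const mat &Xe, double xi, double eta, double zeta,
                        GpGeom &g) {
  double dN[8][3];
  hex8_shape(xi, eta, zeta, g.N, dN);
  mat33 Jm(fill::zeros);
  for (int a = 0; a < 8; ++a)
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) Jm(i, j) += Xe(a, i) * dN[a][j];
  g.detJ = det(Jm);
  if (!(g.detJ > 0.0)) return false;
  mat33 Ji = inv(Jm);
  for (int a = 0; a < 8; ++a)
    for (int j = 0; j < 3; ++j) {
      g.dNdX[a][j] = 0.0;
      for (int k = 0; k < 3; ++k) g.dNdX[a][j] += dN[a][k] * Ji(k, j);
    }
  return true;
}

// [[Rcpp::export(name = ".cem_ref_jacobians")]]
Rcpp::NumericMatrix cem_ref_jacobians(const Rcpp::NumericMatrix &nodes,
                                      const Rcpp::IntegerMatrix &elems) {
  int m = elems.nrow();
  Rcpp::NumericMatrix out(m, 8);
  for (int e = 0; e < m; ++e) {
    mat Xe(8, 3);
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) Xe(a, i) = nodes(elems(e, a) - 1, i);
    int q = 0;
    for (int kz = 0; kz < 2; ++kz)
      for (int ky = 0; ky < 2; ++ky)
        for (int kx = 0; kx < 2; ++kx) {
          GpGeom g;
          bool ok = gp_geometry(Xe, (2 * kx - 1) * GP1, (2 * ky - 1) * GP1,
                                (2 * kz - 1) * GP1, g);
          out(e, q++) = ok ? g.detJ : -1.0;
        }
  }
  return out;
}

// [[Rcpp::export(name = ".cem_assemble")]]
Rcpp::List cem_assemble(const Rcpp::NumericMatrix &nodes,
                        const Rcpp::IntegerMatrix &elems,
                        const Rcpp::NumericMatrix &f0m,
                        const Rcpp::NumericMatrix &s0m,
                        const Rcpp::NumericVector &uvec,
                        const Rcpp::NumericVector &Phi,
                        const Rcpp::NumericVector &Phi_n,
                        const Rcpp::NumericMatrix &r_n,
                        const Rcpp::NumericMatrix &T_n,
                        double dt, double time,
                        const Rcpp::List &material, const Rcpp::List &electro,
                        const Rcpp::List &active,
                        bool vol_sri = false, double sri_frac = 0.05,
                        bool want_matrix = true, bool want_pattern = true) {
  const int n = nodes.nrow(), m = elems.nrow();
  const int ndof = 4 * n;
  MatPar mp = as_matpar(material);
  EpPar ep = as_eppar(electro);
  ActPar ap = as_actpar(active);
  const bool sri = vol_sri && mp.model != MODEL_TIC;
  // stabilized selective integration: sri_frac of the penalty stays on the
  // full quadrature (keeps the system away from singularity for very soft
  // deviatoric responses), the rest moves to the element center
  MatPar mp_gp = mp, mp_c = mp;
  if (sri) {
    mp_gp.kappa = sri_frac * mp.kappa;
    mp_c.kappa = (1.0 - sri_frac) * mp.kappa;
  }
  const double dtbar = dt / ep.kt;
  const double src_scale = ep.kphi / ep.kt;

  Rcpp::NumericVector res(ndof);
  Rcpp::IntegerVector ti, tj;
  Rcpp::NumericVector tx;
  if (want_matrix) {
    tx = Rcpp::NumericVector(m * 1024);
    if (want_pattern) {
      ti = Rcpp::IntegerVector(m * 1024);
      tj = Rcpp::IntegerVector(m * 1024);
    }
  }
  Rcpp::NumericMatrix r_new(m, 8), T_new(m, 8);
  Rcpp::NumericVector lam_c(m), J_c(m), Tact_c(m);
  double psi_tot = 0.0;

  std::vector<double> gpx(8), gpy(8), gpz(8);
  {
    int q = 0;
    for (int kz = 0; kz < 2; ++kz)
      for (int ky = 0; ky < 2; ++ky)
        for (int kx = 0; kx < 2; ++kx) {
          gpx[q] = (2 * kx - 1) * GP1; gpy[q] = (2 * ky - 1) * GP1;
          gpz[q] = (2 * kz - 1) * GP1; ++q;
        }
  }

  mat Ke(32, 32);
  vec Re(32);

  for (int e = 0; e < m; ++e) {
    mat Xe(8, 3), ue(8, 3);
    vec Phie(8), Phine(8);
    int gid[8];
    for (int a = 0; a < 8; ++a) {
      int nd = elems(e, a) - 1;
      gid[a] = nd;
      for (int i = 0; i < 3; ++i) {
        Xe(a, i) = nodes(nd, i);
        ue(a, i) = uvec[3 * nd + i];
      }
      Phie[a] = Phi[nd];
      Phine[a] = Phi_n[nd];
    }
    vec3 f0 = {f0m(e, 0), f0m(e, 1), f0m(e, 2)};
    vec3 s0 = {s0m(e, 0), s0m(e, 1), s0m(e, 2)};
    mat33 ff = f0 * f0.t();

    Ke.zeros();
    Re.zeros();

    for (int q = 0; q < 8; ++q) {
      GpGeom g;
      if (!gp_geometry(Xe, gpx[q], gpy[q], gpz[q], g))
        Rcpp::stop("element %d: non-positive reference Jacobian at quadrature point %d",
                   e + 1, q + 1);
      // deformation gradient
      mat33 F(fill::eye);
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) F(i, j) += ue(a, i) * g.dNdX[a][j];
      double Jdef = det(F);
      if (!(Jdef > 0.0))
        Rcpp::stop("element %d inverted (det F = %g) at t = %g ms, quadrature point %d",
                   e + 1, Jdef, time, q + 1);

      // fields at the point
      double Phig = 0.0, Phing = 0.0;
      vec3 gradPhi(fill::zeros);
      for (int a = 0; a < 8; ++a) {
        Phig += g.N[a] * Phie[a];
        Phing += g.N[a] * Phine[a];
        for (int j = 0; j < 3; ++j) gradPhi[j] += g.dNdX[a][j] * Phie[a];
      }
      double phig = (Phig + ep.dphi) / ep.kphi;

      // internal variable updates (local backward Euler, consistent)
      double rnew, drdphi, Tnew, dTdPhi;
      recovery_update_point(phig, r_n(e, q), dtbar, ep, rnew, drdphi);
      active_update_point(Phig, T_n(e, q), dt, ap, Tnew, dTdPhi);
      r_new(e, q) = rnew;
      T_new(e, q) = Tnew;

      // stress and tangent (deviatoric/full part; volumetric split off under SRI)
      mat33 S; T4 CC; double psi, lam, Jk;
      pk2_point(F, f0, s0, mp_gp, Tnew, want_matrix, true, false, S, CC, psi, lam, Jk);

      double I4f = lam * lam;
      T4 dDdC;
      mat33 Dcond = conductivity_point(F, f0, ep, want_matrix, dDdC);

      double fe = fe_point(phig, rnew, ep);
      double fm = fm_point(lam, phig, ep);
      double w = g.detJ;
      psi_tot += psi * w;

      // residuals
      mat33 FS = F * S;
      vec3 Q = Dcond * gradPhi;
      double cap = (Phig - Phing) / dt;
      double src = src_scale * (fe + fm);
      for (int a = 0; a < 8; ++a) {
        for (int i = 0; i < 3; ++i) {
          double v = 0.0;
          for (int j = 0; j < 3; ++j) v += FS(i, j) * g.dNdX[a][j];
          Re[4 * a + i] += v * w;
        }
        double vphi = g.N[a] * cap - g.N[a] * src;
        for (int j = 0; j < 3; ++j) vphi += g.dNdX[a][j] * Q[j];
        Re[4 * a + 3] += vphi * w;
      }

      if (!want_matrix) continue;

      // mechanics tangent
      mat33 SA = S; // includes active part
      // per-dof dE and dC structures
      // K_uu
      for (int b = 0; b < 8; ++b) {
        for (int k = 0; k < 3; ++k) {
          // dE_mn = 1/2 (F_km H_bn + F_kn H_bm); dC = 2 dE
          mat33 dE;
          for (int mm = 0; mm < 3; ++mm)
            for (int nn = 0; nn < 3; ++nn)
              dE(mm, nn) = 0.5 * (F(k, mm) * g.dNdX[b][nn] +
                                  F(k, nn) * g.dNdX[b][mm]);
          // dS = CC : dE
          mat33 dS(fill::zeros);
          for (int i2 = 0; i2 < 3; ++i2)
            for (int j2 = 0; j2 < 3; ++j2) {
              double sv = 0.0;
              for (int mm = 0; mm < 3; ++mm)
                for (int nn = 0; nn < 3; ++nn)
                  sv += CC.v[i2][j2][mm][nn] * dE(mm, nn);
              dS(i2, j2) = sv;
            }
          mat33 FdS = F * dS;
          for (int a = 0; a < 8; ++a) {
            for (int i = 0; i < 3; ++i) {
              double v = 0.0;
              for (int j = 0; j < 3; ++j) v += FdS(i, j) * g.dNdX[a][j];
              Ke(4 * a + i, 4 * b + k) += v * w;
            }
          }
          // dRphi/du: conductivity + stretch-current sensitivities (dC = 2 dE)
          mat33 dC = 2.0 * dE;
          vec3 dQ(fill::zeros);
          for (int i2 = 0; i2 < 3; ++i2)
            for (int j2 = 0; j2 < 3; ++j2) {
              double sv = 0.0;
              for (int mm = 0; mm < 3; ++mm)
                for (int nn = 0; nn < 3; ++nn)
                  sv += dDdC.v[i2][j2][mm][nn] * dC(mm, nn);
              dQ[i2] += sv * gradPhi[j2];
            }
          double dfm = 0.0;
          if (ep.mef_on && lam > 1.0) {
            // dlam/dC = ff/(2 lam)
            double dlam = 0.0;
            for (int mm = 0; mm < 3; ++mm)
              for (int nn = 0; nn < 3; ++nn)
                dlam += ff(mm, nn) / (2.0 * lam) * dC(mm, nn);
            dfm = ep.Gs * (ep.phis - phig) * dlam;
          }
          for (int a = 0; a < 8; ++a) {
            double v = -g.N[a] * src_scale * dfm;
            for (int j = 0; j < 3; ++j) v += g.dNdX[a][j] * dQ[j];
            Ke(4 * a + 3, 4 * b + k) += v * w;
          }
        }
      }
      // geometric stiffness
      for (int a = 0; a < 8; ++a)
        for (int b = 0; b < 8; ++b) {
          double gg = 0.0;
          for (int j = 0; j < 3; ++j)
            for (int l = 0; l < 3; ++l)
              gg += g.dNdX[a][j] * SA(l, j) * g.dNdX[b][l];
          for (int i = 0; i < 3; ++i) Ke(4 * a + i, 4 * b + i) += gg * w;
        }
      // K_uPhi via active tension, dS_act/dPhi = dT/dPhi ff
      {
        mat33 dSdPhi = dTdPhi * ff;
        mat33 FdS = F * dSdPhi;
        for (int a = 0; a < 8; ++a)
          for (int i = 0; i < 3; ++i) {
            double v = 0.0;
            for (int j = 0; j < 3; ++j) v += FdS(i, j) * g.dNdX[a][j];
            for (int b = 0; b < 8; ++b)
              Ke(4 * a + i, 4 * b + 3) += v * g.N[b] * w;
          }
      }
      // K_PhiPhi
      {
        double dfe = fe_dphi(phig, rnew, ep) + (-phig) * drdphi;
        double dfmphi = (ep.mef_on && lam > 1.0) ? -ep.Gs * (lam - 1.0) : 0.0;
        double react = (dfe + dfmphi) / ep.kt; // d src / d Phi
        for (int a = 0; a < 8; ++a)
          for (int b = 0; b < 8; ++b) {
            double v = g.N[a] * g.N[b] * (1.0 / dt - react);
            for (int j = 0; j < 3; ++j)
              for (int l = 0; l < 3; ++l)
                v += g.dNdX[a][j] * Dcond(j, l) * g.dNdX[b][l];
            Ke(4 * a + 3, 4 * b + 3) += v * w;
          }
      }
    } // gp loop

    // selective reduced integration of the volumetric penalty: one center point
    if (sri) {
      GpGeom g;
      if (!gp_geometry(Xe, 0.0, 0.0, 0.0, g))
        Rcpp::stop("element %d: non-positive reference Jacobian at element center", e + 1);
      mat33 F(fill::eye);
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) F(i, j) += ue(a, i) * g.dNdX[a][j];
      if (!(det(F) > 0.0))
        Rcpp::stop("element %d inverted (det F = %g) at t = %g ms (center point)",
                   e + 1, det(F), time);
      mat33 S; T4 CC; double psi, lam, Jk;
      pk2_point(F, f0, s0, mp_c, 0.0, want_matrix, false, true, S, CC, psi, lam, Jk);
      double w = 8.0 * g.detJ;
      psi_tot += psi * w;
      mat33 FS = F * S;
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          double v = 0.0;
          for (int j = 0; j < 3; ++j) v += FS(i, j) * g.dNdX[a][j];
          Re[4 * a + i] += v * w;
        }
      if (want_matrix) {
        for (int b = 0; b < 8; ++b)
          for (int k = 0; k < 3; ++k) {
            mat33 dE;
            for (int mm = 0; mm < 3; ++mm)
              for (int nn = 0; nn < 3; ++nn)
                dE(mm, nn) = 0.5 * (F(k, mm) * g.dNdX[b][nn] +
                                    F(k, nn) * g.dNdX[b][mm]);
            mat33 dS(fill::zeros);
            for (int i2 = 0; i2 < 3; ++i2)
              for (int j2 = 0; j2 < 3; ++j2) {
                double sv = 0.0;
                for (int mm = 0; mm < 3; ++mm)
                  for (int nn = 0; nn < 3; ++nn)
                    sv += CC.v[i2][j2][mm][nn] * dE(mm, nn);
                dS(i2, j2) = sv;
              }
            mat33 FdS = F * dS;
            for (int a = 0; a < 8; ++a)
              for (int i = 0; i < 3; ++i) {
                double v = 0.0;
                for (int j = 0; j < 3; ++j) v += FdS(i, j) * g.dNdX[a][j];
                Ke(4 * a + i, 4 * b + k) += v * w;
              }
          }
        for (int a = 0; a < 8; ++a)
          for (int b = 0; b < 8; ++b) {
            double gg = 0.0;
            for (int j = 0; j < 3; ++j)
              for (int l = 0; l < 3; ++l)
                gg += g.dNdX[a][j] * S(l, j) * g.dNdX[b][l];
            for (int i = 0; i < 3; ++i) Ke(4 * a + i, 4 * b + i) += gg * w;
          }
      }
    }

    // element center fields
    {
      GpGeom g;
      gp_geometry(Xe, 0.0, 0.0, 0.0, g);
      mat33 F(fill::eye);
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) F(i, j) += ue(a, i) * g.dNdX[a][j];
      mat33 C = F.t() * F;
      lam_c[e] = std::sqrt(as_scalar(f0.t() * C * f0));
      J_c[e] = det(F);
      double Tm = 0.0;
      for (int q = 0; q < 8; ++q) Tm += T_new(e, q);
      Tact_c[e] = Tm / 8.0;
    }

    // scatter
    for (int a = 0; a < 8; ++a) {
      for (int p = 0; p < 4; ++p) {
        int gr = 4 * gid[a] + p;
        res[gr] += Re[4 * a + p];
      }
    }
    if (want_matrix) {
      int base = e * 1024, q2 = 0;
      for (int a = 0; a < 8; ++a)
        for (int p = 0; p < 4; ++p) {
          int gr = 4 * gid[a] + p + 1;
          for (int b = 0; b < 8; ++b)
            for (int pc = 0; pc < 4; ++pc) {
              if (want_pattern) {
                ti[base + q2] = gr;
                tj[base + q2] = 4 * gid[b] + pc + 1;
              }
              tx[base + q2] = Ke(4 * a + p, 4 * b + pc);
              ++q2;
            }
        }
    }
  } // element loop

  return Rcpp::List::create(
      Rcpp::Named("res") = res,
      Rcpp::Named("i") = ti, Rcpp::Named("j") = tj, Rcpp::Named("x") = tx,
      Rcpp::Named("r_new") = r_new, Rcpp::Named("T_new") = T_new,
      Rcpp::Named("lambda") = lam_c, Rcpp::Named("J") = J_c,
      Rcpp::Named("T_act") = Tact_c, Rcpp::Named("psi") = psi_tot);
}

// accumulate element triplets into a fixed sparsity pattern
// [[Rcpp::export(name = ".cem_accum")]]
Rcpp::NumericVector cem_accum(const Rcpp::IntegerVector &map,
                              const Rcpp::NumericVector &x, int nnz) {
  Rcpp::NumericVector out(nnz);
  const int n = map.size();
  for (int q = 0; q < n; ++q) out[map[q] - 1] += x[q];
  return out;
}
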