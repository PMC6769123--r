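// Pointwise constitutive kernels: passive strain energies, second
// Piola-Kirchhoff stress and consistent material tangents for the three
// passive myocardium models (TIC, TII, HO), the active fiber stress,
// deformation-dependent conduction and the Aliev-Panfilov / stretch-current
// point kinetics.  All tensors live in the material frame.

#include "cem.h"
using namespace arma;

MatPar as_matpar(const Rcpp::List &l) {
  MatPar p;
  std::string m = Rcpp::as<std::string>(l["model"]);
  if (m == "TIC") p.model = MODEL_TIC;
  else if (m == "TII") p.model = MODEL_TII;
  else if (m == "HO") p.model = MODEL_HO;
  else Rcpp::stop("unknown material model '%s'", m.c_str());
  auto g = [&](const char *k, double d) {
    return l.containsElementNamed(k) ? Rcpp::as<double>(l[k]) : d;
  };
  p.Lambda = g("Lambda", 0); p.mu = g("mu", 0); p.eta = g("eta", 0);
  p.kappa = g("kappa", 0);
  p.a = g("a", 0); p.b = g("b", 1);
  p.af = g("a_f", 0); p.bf = g("b_f", 1);
  p.as_ = g("a_s", 0); p.bs = g("b_s", 1);
  p.afs = g("a_fs", 0); p.bfs = g("b_fs", 1);
  p.exp_cap = g("exp_cap", 50.0);
  return p;
}

EpPar as_eppar(const Rcpp::List &l) {
  EpPar p;
  auto g = [&](const char *k, double d) {
    return l.containsElementNamed(k) ? Rcpp::as<double>(l[k]) : d;
  };
  p.alpha = g("alpha", 0.01); p.c = g("c", 8.0); p.Iext = g("I_ext", 0.0);
  p.gamma = g("gamma", 0.012); p.mu1 = g("mu1", 0.2); p.mu2 = g("mu2", 0.3);
  p.brec = g("b_rec", 0.15);
  p.kphi = g("k_phi", 100.0); p.dphi = g("delta_phi", 80.0); p.kt = g("k_t", 12.9);
  p.diso = g("d_iso", 0.1); p.dani = g("d_ani", 0.3);
  p.Gs = g("G_s", 0.0); p.phis = g("phi_s", 0.6);
  p.mef_on = l.containsElementNamed("mef_on") ? Rcpp::as<bool>(l["mef_on"]) : true;
  return p;
}

ActPar as_actpar(const Rcpp::List &l) {
  ActPar p;
  auto g = [&](const char *k, double d) {
    return l.containsElementNamed(k) ? Rcpp::as<double>(l[k]) : d;
  };
  p.kT = g("k_T", 0.49); p.Phir = g("Phi_r", -80.0);
  p.eps0 = g("eps_0", 0.1); p.epsinf = g("eps_inf", 1.0);
  p.xi = g("xi", 0.1); p.Phibar = g("Phi_bar", 0.0);
  return p;
}

// ---- invariant derivative helpers -------------------------------------

// (A odot A)_ijkl = 1/2 (A_ik A_jl + A_il A_jk)
static void add_odot(T4 &out, const mat33 &A, double w) {
  for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j)
    for (int k = 0; k < 3; ++k) for (int l = 0; l < 3; ++l)
      out.v[i][j][k][l] += w * 0.5 * (A(i, k) * A(j, l) + A(i, l) * A(j, k));
}

static void add_dyad(T4 &out, const mat33 &A, const mat33 &B, double w) {
  for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j)
    for (int k = 0; k < 3; ++k) for (int l = 0; l < 3; ++l)
      out.v[i][j][k][l] += w * A(i, j) * B(k, l);
}

// first/second derivative of J wrt C
static void dJ(const mat33 &Ci, double J, mat33 &D1, T4 *D2) {
  D1 = 0.5 * J * Ci;
  if (D2) {
    add_dyad(*D2, Ci, Ci, 0.25 * J);
    add_odot(*D2, Ci, -0.5 * J);
  }
}

// derivative of an isochoric invariant Ibar = J^{-2/3} A, where A has the
// constant structural derivative G = dA/dC
static void dIbar(const mat33 &G, double A, const mat33 &Ci, double J23,
                  mat33 &D1, T4 *D2) {
  D1 = J23 * (G - (A / 3.0) * Ci);
  if (D2) {
    add_dyad(*D2, G, Ci, -J23 / 3.0);
    add_dyad(*D2, Ci, G, -J23 / 3.0);
    add_dyad(*D2, Ci, Ci, J23 * A / 9.0);
    add_odot(*D2, Ci, J23 * A / 3.0);
  }
}

void pk2_point(const mat33 &F, const vec3 &f0, const vec3 &s0,
               const MatPar &mp, double Tact,
               bool want_tan, bool include_vol, bool vol_only,
               mat33 &S, T4 &CC, double &psi, double &lam, double &J) {
  J = det(F);
  if (!(J > 0.0)) Rcpp::stop("degenerate deformation state: det(F) = %g <= 0", J);
  mat33 C = F.t() * F;
  mat33 Ci = inv_sympd(symmatu(C));
  mat33 Id = eye<mat>(3, 3);
  mat33 ff = f0 * f0.t();
  mat33 ss = s0 * s0.t();
  mat33 fs = 0.5 * (f0 * s0.t() + s0 * f0.t());

  double I1 = trace(C);
  double I4f = as_scalar(f0.t() * C * f0);
  double I4s = as_scalar(s0.t() * C * s0);
  double I8  = as_scalar(f0.t() * C * s0);
  double J23 = std::pow(J, -2.0 / 3.0);
  double Ib1 = J23 * I1, Ib4f = J23 * I4f, Ib4s = J23 * I4s, Ib8 = J23 * I8;
  lam = std::sqrt(I4f);

  psi = 0.0;
  double lnJ = std::log(J);

  S.zeros();
  if (want_tan) CC.zero();
  // accumulate one energy term: S += 2 w1 dA/dC, and
  // CC += 4 w2 (dA/dC x dA/dC) + 4 w1 d2A/dC2
  auto add_term = [&](const mat33 &D1, const T4 *D2, double w1, double w2) {
    S += 2.0 * w1 * D1;
    if (!want_tan) return;
    if (w2 != 0.0) add_dyad(CC, D1, D1, 4.0 * w2);
    if (D2)
      for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j)
        for (int k = 0; k < 3; ++k) for (int l = 0; l < 3; ++l)
          CC.v[i][j][k][l] += 4.0 * w1 * D2->v[i][j][k][l];
  };

  bool volumetric_model = (mp.model != MODEL_TIC);

  if (!vol_only) {
    if (mp.model == MODEL_TIC) {
      // Psi = Lambda/2 ln^2 J + mu/2 (I1 - 3 - 2 lnJ) + theta eta/2 (I4f-1)^2
      bool th = (lam > 1.0);
      psi += 0.5 * mp.Lambda * lnJ * lnJ + 0.5 * mp.mu * (I1 - 3.0 - 2.0 * lnJ);
      if (th) psi += 0.5 * mp.eta * (I4f - 1.0) * (I4f - 1.0);
      add_term(Id, nullptr, 0.5 * mp.mu, 0.0);
      {
        mat33 D1; T4 D2; dJ(Ci, J, D1, want_tan ? &D2 : nullptr);
        double w1 = (mp.Lambda * lnJ - mp.mu) / J;
        double w2 = (mp.Lambda * (1.0 - lnJ) + mp.mu) / (J * J);
        add_term(D1, want_tan ? &D2 : nullptr, w1, w2);
      }
      if (th) add_term(ff, nullptr, mp.eta * (I4f - 1.0), mp.eta);
    } else if (mp.model == MODEL_TII) {
      // Psi = mu/2 (Ib1 - 3) + theta eta/2 (Ib4f - 1)^2 [+ kappa (J-1)^2]
      bool th = (std::sqrt(Ib4f) > 1.0);
      psi += 0.5 * mp.mu * (Ib1 - 3.0);
      if (th) psi += 0.5 * mp.eta * (Ib4f - 1.0) * (Ib4f - 1.0);
      {
        mat33 D1; T4 D2; dIbar(Id, I1, Ci, J23, D1, want_tan ? &D2 : nullptr);
        add_term(D1, want_tan ? &D2 : nullptr, 0.5 * mp.mu, 0.0);
      }
      if (th) {
        mat33 D1; T4 D2; dIbar(ff, I4f, Ci, J23, D1, want_tan ? &D2 : nullptr);
        add_term(D1, want_tan ? &D2 : nullptr, mp.eta * (Ib4f - 1.0), mp.eta);
      }
    } else { // HO
      double arg1 = mp.b * (Ib1 - 3.0);
      double argf = mp.bf * (Ib4f - 1.0) * (Ib4f - 1.0);
      double args = mp.bs * (Ib4s - 1.0) * (Ib4s - 1.0);
      double argfs = mp.bfs * Ib8 * Ib8;
      if (arg1 > mp.exp_cap || argf > mp.exp_cap || args > mp.exp_cap ||
          argfs > mp.exp_cap)
        Rcpp::stop("HO energy: exponent argument exceeds cap %g (nonphysical strain)",
                   mp.exp_cap);
      bool thf = (Ib4f > 1.0), ths = (Ib4s > 1.0);
      psi += mp.a / (2.0 * mp.b) * std::exp(arg1);
      if (thf) psi += mp.af / (2.0 * mp.bf) * (std::exp(argf) - 1.0);
      if (ths) psi += mp.as_ / (2.0 * mp.bs) * (std::exp(args) - 1.0);
      psi += mp.afs / (2.0 * mp.bfs) * (std::exp(argfs) - 1.0);
      {
        mat33 D1; T4 D2; dIbar(Id, I1, Ci, J23, D1, want_tan ? &D2 : nullptr);
        double e = std::exp(arg1);
        add_term(D1, want_tan ? &D2 : nullptr, 0.5 * mp.a * e, 0.5 * mp.a * mp.b * e);
      }
      if (thf) {
        mat33 D1; T4 D2; dIbar(ff, I4f, Ci, J23, D1, want_tan ? &D2 : nullptr);
        double e = std::exp(argf), x = Ib4f - 1.0;
        add_term(D1, want_tan ? &D2 : nullptr, mp.af * x * e,
                 mp.af * e * (1.0 + 2.0 * mp.bf * x * x));
      }
      if (ths) {
        mat33 D1; T4 D2; dIbar(ss, I4s, Ci, J23, D1, want_tan ? &D2 : nullptr);
        double e = std::exp(args), x = Ib4s - 1.0;
        add_term(D1, want_tan ? &D2 : nullptr, mp.as_ * x * e,
                 mp.as_ * e * (1.0 + 2.0 * mp.bs * x * x));
      }
      {
        mat33 D1; T4 D2; dIbar(fs, I8, Ci, J23, D1, want_tan ? &D2 : nullptr);
        double e = std::exp(argfs);
        add_term(D1, want_tan ? &D2 : nullptr, mp.afs * Ib8 * e,
                 mp.afs * e * (1.0 + 2.0 * mp.bfs * Ib8 * Ib8));
      }
    }

    // active fiber stress S_act = Tact f0 x f0 (second Piola-Kirchhoff);
    // the associated Cauchy fiber stress Tact I4f / J falls off with fiber
    // shortening, which makes the contraction self-limiting
    if (Tact != 0.0) {
      add_term(ff, nullptr, 0.5 * Tact, 0.0);
    }
  }

  // volumetric penalty kappa (J-1)^2 for the nearly incompressible models
  if (volumetric_model && (include_vol || vol_only)) {
    psi += mp.kappa * (J - 1.0) * (J - 1.0);
    mat33 D1; T4 D2; dJ(Ci, J, D1, want_tan ? &D2 : nullptr);
    add_term(D1, want_tan ? &D2 : nullptr, 2.0 * mp.kappa * (J - 1.0), 2.0 * mp.kappa);
  }

}

// conductivity D = J d_iso C^-1 + J d_ani f0xf0 / I4f and (optionally) dD/dC
mat33 conductivity_point(const mat33 &F, const vec3 &f0, const EpPar &ep,
                         bool want_dD, T4 &dDdC) {
  double J = det(F);
  if (!(J > 0.0)) Rcpp::stop("degenerate deformation state: det(F) = %g <= 0", J);
  mat33 C = F.t() * F;
  mat33 Ci = inv_sympd(symmatu(C));
  mat33 ff = f0 * f0.t();
  double I4f = as_scalar(f0.t() * C * f0);
  mat33 D = J * ep.diso * Ci + J * ep.dani * ff / I4f;
  if (want_dD) {
    dDdC.zero();
    add_dyad(dDdC, Ci, Ci, 0.5 * J * ep.diso);
    add_odot(dDdC, Ci, -J * ep.diso);
    add_dyad(dDdC, ff, Ci, 0.5 * J * ep.dani / I4f);
    add_dyad(dDdC, ff, ff, -J * ep.dani / (I4f * I4f));
  }
  return D;
}

// ---- Aliev-Panfilov point kinetics ------------------------------------

double fe_point(double phi, double r, const EpPar &ep) {
  return ep.c * phi * (phi - ep.alpha) * (1.0 - phi) - r * phi + ep.Iext;
}

double fe_dphi(double phi, double r, const EpPar &ep) {
  return ep.c * ((phi - ep.alpha) * (1.0 - phi) + phi * (1.0 - phi)
                 - phi * (phi - ep.alpha)) - r;
}

// recovery ODE  dr/dtbar = [gamma + mu1 r/(mu2 + phi)] [-r - c phi (phi - b - 1)]
double recovery_rhs_point(double phi, double r, const EpPar &ep) {
  return (ep.gamma + ep.mu1 * r / (ep.mu2 + phi)) *
         (-r - ep.c * phi * (phi - ep.brec - 1.0));
}

static double recovery_dr(double phi, double r, const EpPar &ep) {
  double q = -r - ep.c * phi * (phi - ep.brec - 1.0);
  return (ep.mu1 / (ep.mu2 + phi)) * q -
         (ep.gamma + ep.mu1 * r / (ep.mu2 + phi));
}

static double recovery_dphi(double phi, double r, const EpPar &ep) {
  double q = -r - ep.c * phi * (phi - ep.brec - 1.0);
  return (-ep.mu1 * r / ((ep.mu2 + phi) * (ep.mu2 + phi))) * q +
         (ep.gamma + ep.mu1 * r / (ep.mu2 + phi)) *
         (-ep.c * (2.0 * phi - ep.brec - 1.0));
}

// local backward-Euler update of r with consistent sensitivity dr/dphi
void recovery_update_point(double phi, double rn, double dtbar, const EpPar &ep,
                           double &rnew, double &drdphi) {
  double r = rn;
  for (int it = 0; it < 50; ++it) {
    double h = r - rn - dtbar * recovery_rhs_point(phi, r, ep);
    double hp = 1.0 - dtbar * recovery_dr(phi, r, ep);
    double dr = -h / hp;
    r += dr;
    if (std::abs(dr) < 1e-14) break;
  }
  rnew = r;
  drdphi = dtbar * recovery_dphi(phi, r, ep) /
           (1.0 - dtbar * recovery_dr(phi, r, ep));
}

double fm_point(double lam, double phi, const EpPar &ep) {
  if (!ep.mef_on || lam <= 1.0) return 0.0;
  return ep.Gs * (lam - 1.0) * (ep.phis - phi);
}

// activation rate: slow at rest, fast when depolarized
static double eps_fun(double Phi, const ActPar &ap, double *deps) {
  double z = std::exp(-ap.xi * (Phi - ap.Phibar));
  double e = std::exp(-z);
  if (deps) *deps = (ap.epsinf - ap.eps0) * e * z * ap.xi;
  return ap.eps0 + (ap.epsinf - ap.eps0) * e;
}

// backward-Euler update of dT/dt = eps(Phi) [kT (Phi - Phir) - T]
void active_update_point(double Phi, double Tn, double dt, const ActPar &ap,
                         double &Tnew, double &dTdPhi) {
  double de;
  double e = eps_fun(Phi, ap, &de);
  double src = ap.kT * (Phi - ap.Phir);
  double B = 1.0 + dt * e;
  Tnew = (Tn + dt * e * src) / B;
  dTdPhi = (dt * (de * src + e * ap.kT)) / B - (Tn + dt * e * src) * dt * de / (B * B);
}

// ---- exported single-point wrappers -----------------------------------

static T4 dummyT4;

// [[Rcpp::export(name = ".cem_kinematics")]]
Rcpp::List cem_kinematics_cpp(const arma::mat &F, const arma::vec &f0,
                              const arma::vec &s0) {
  double J = det(F);
  if (!(J > 0.0)) Rcpp::stop("degenerate deformation state: det(F) = %g <= 0", J);
  mat33 Fm = F;
  mat33 C = Fm.t() * Fm;
  vec3 f = f0, s = s0;
  double I1 = trace(C);
  double I4f = as_scalar(f.t() * C * f);
  double I4s = as_scalar(s.t() * C * s);
  double I8 = as_scalar(f.t() * C * s);
  double J23 = std::pow(J, -2.0 / 3.0);
  return Rcpp::List::create(
      Rcpp::Named("C") = C, Rcpp::Named("J") = J,
      Rcpp::Named("I1") = I1, Rcpp::Named("I4f") = I4f,
      Rcpp::Named("I4s") = I4s, Rcpp::Named("I8fs") = I8,
      Rcpp::Named("Ib1") = J23 * I1, Rcpp::Named("Ib4f") = J23 * I4f,
      Rcpp::Named("Ib4s") = J23 * I4s, Rcpp::Named("Ib8fs") = J23 * I8,
      Rcpp::Named("lambda") = std::sqrt(I4f));
}

// [[Rcpp::export(name = ".cem_psi")]]
double cem_psi_cpp(const arma::mat &F, const arma::vec &f0, const arma::vec &s0,
                   const Rcpp::List &mat, double Tact = 0.0,
                   bool include_vol = true) {
  MatPar mp = as_matpar(mat);
  mat33 S; double psi, lam, J;
  mat33 Fm = F;
  pk2_point(Fm, vec3(f0), vec3(s0), mp, Tact, false, include_vol, false,
            S, dummyT4, psi, lam, J);
  return psi;
}

// [[Rcpp::export(name = ".cem_pk2")]]
arma::mat cem_pk2_cpp(const arma::mat &F, const arma::vec &f0, const arma::vec &s0,
                      const Rcpp::List &mat, double Tact = 0.0,
                      bool include_vol = true) {
  MatPar mp = as_matpar(mat);
  mat33 S; double psi, lam, J;
  mat33 Fm = F;
  pk2_point(Fm, vec3(f0), vec3(s0), mp, Tact, false, include_vol, false,
            S, dummyT4, psi, lam, J);
  return S;
}

// [[Rcpp::export(name = ".cem_tangent")]]
Rcpp::NumericVector cem_tangent_cpp(const arma::mat &F, const arma::vec &f0,
                                    const arma::vec &s0, const Rcpp::List &mat,
                                    double Tact = 0.0, bool include_vol = true) {
  MatPar mp = as_matpar(mat);
  mat33 S; T4 CC; double psi, lam, J;
  mat33 Fm = F;
  pk2_point(Fm, vec3(f0), vec3(s0), mp, Tact, true, include_vol, false,
            S, CC, psi, lam, J);
  Rcpp::NumericVector out(81);
  int q = 0; // column-major R array [i,j,k,l]
  for (int l = 0; l < 3; ++l) for (int k = 0; k < 3; ++k)
    for (int j = 0; j < 3; ++j) for (int i = 0; i < 3; ++i)
      out[q++] = CC.v[i][j][k][l];
  out.attr("dim") = Rcpp::IntegerVector::create(3, 3, 3, 3);
  return out;
}

// [[Rcpp::export(name = ".cem_conductivity")]]
arma::mat cem_conductivity_cpp(const arma::mat &F, const arma::vec &f0,
                               const Rcpp::List &electro) {
  EpPar ep = as_eppar(electro);
  T4 d;
  mat33 Fm = F;
  return conductivity_point(Fm, vec3(f0), ep, false, d);
}

// [[Rcpp::export(name = ".cem_fe")]]
double cem_fe_cpp(double phi, double r, const Rcpp::List &electro) {
  return fe_point(phi, r, as_eppar(electro));
}

// [[Rcpp::export(name = ".cem_recovery_rhs")]]
double cem_recovery_rhs_cpp(double phi, double r, const Rcpp::List &electro) {
  return recovery_rhs_point(phi, r, as_eppar(electro));
}

// [[Rcpp::export(name = ".cem_recovery_update")]]
Rcpp::List cem_recovery_update_cpp(double phi, double rn, double dtbar,
                                   const Rcpp::List &electro) {
  EpPar ep = as_eppar(electro);
  double rnew, drdphi;
  recovery_update_point(phi, rn, dtbar, ep, rnew, drdphi);
  return Rcpp::List::create(Rcpp::Named("r") = rnew,
                            Rcpp::Named("dr_dphi") = drdphi);
}

// [[Rcpp::export(name = ".cem_fm")]]
double cem_fm_cpp(double lam, double phi, const Rcpp::List &electro) {
  return fm_point(lam, phi, as_eppar(electro));
}

// [[Rcpp::export(name = ".cem_active_update")]]
Rcpp::List cem_active_update_cpp(double Phi, double Tn, double dt,
                                 const Rcpp::List &active) {
  ActPar ap = as_actpar(active);
  double Tnew, dTdPhi;
  active_update_point(Phi, Tn, dt, ap, Tnew, dTdPhi);
  return Rcpp::List::create(Rcpp::Named("T_act") = Tnew,
                            Rcpp::Named("dT_dPhi") = dTdPhi);
}

// single-cell integration of the coupled (phi, r, T) point model under a
// prescribed external stimulus current; RK4 on (phi, r), exact-sampled T
// [[Rcpp::export(name = ".cem_cell_trace")]]
Rcpp::List cem_cell_trace_cpp(double phi0, double r0, double dt, double t_end,
                              const Rcpp::List &electro, const Rcpp::List &active,
                              Rcpp::NumericVector I_t) {
  // I_t: per-step external dimensionless current (recycled if length 1)
  EpPar ep = as_eppar(electro);
  ActPar ap = as_actpar(active);
  int n = (int)std::ceil(t_end / dt - 1e-9);
  Rcpp::NumericVector t(n + 1), phi(n + 1), r(n + 1), Phi(n + 1), Tact(n + 1);
  double ph = phi0, rr = r0, T = 0.0;
  phi[0] = ph; r[0] = rr; t[0] = 0.0;
  Phi[0] = ep.kphi * ph - ep.dphi; Tact[0] = 0.0;
  double dtbar = dt / ep.kt;
  for (int s = 0; s < n; ++s) {
    double I = I_t.size() == 1 ? I_t[0] : I_t[std::min(s, (int)I_t.size() - 1)];
    EpPar e2 = ep; e2.Iext = ep.Iext + I;
    auto fphi = [&](double p, double q) { return fe_point(p, q, e2); };
    auto fr = [&](double p, double q) { return recovery_rhs_point(p, q, e2); };
    double k1p = fphi(ph, rr), k1r = fr(ph, rr);
    double k2p = fphi(ph + 0.5 * dtbar * k1p, rr + 0.5 * dtbar * k1r);
    double k2r = fr(ph + 0.5 * dtbar * k1p, rr + 0.5 * dtbar * k1r);
    double k3p = fphi(ph + 0.5 * dtbar * k2p, rr + 0.5 * dtbar * k2r);
    double k3r = fr(ph + 0.5 * dtbar * k2p, rr + 0.5 * dtbar * k2r);
    double k4p = fphi(ph + dtbar * k3p, rr + dtbar * k3r);
    double k4r = fr(ph + dtbar * k3p, rr + dtbar * k3r);
    ph += dtbar / 6.0 * (k1p + 2 * k2p + 2 * k3p + k4p);
    rr += dtbar / 6.0 * (k1r + 2 * k2r + 2 * k3r + k4r);
    double PhiPhys = ep.kphi * ph - ep.dphi, dT;
    active_update_point(PhiPhys, T, dt, ap, T, dT);
    t[s + 1] = (s + 1) * dt; phi[s + 1] = ph; r[s + 1] = rr;
    Phi[s + 1] = PhiPhys; Tact[s + 1] = T;
  }
  return Rcpp::List::create(Rcpp::Named("t") = t, Rcpp::Named("phi") = phi,
                            Rcpp::Named("r") = r, Rcpp::Named("Phi") = Phi,
                            Rcpp::Named("T_act") = Tact);
}
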