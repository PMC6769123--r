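#ifndef CEM_H
#define CEM_H

#include <RcppArmadillo.h>

// Units used throughout: mm, ms, kPa, mV.  Force = kPa*mm^2 = mN.

enum ModelId { MODEL_TIC = 0, MODEL_TII = 1, MODEL_HO = 2 };

struct MatPar {
  int model;
  // TIC / TII
  double Lambda, mu, eta;
  // volumetric penalty (TII, HO)
  double kappa;
  // HO
  double a, b, af, bf, as_, bs, afs, bfs;
  double exp_cap;   // cap on exponent arguments (HO); above -> error
};

struct EpPar {
  double alpha, c, Iext;          // Aliev-Panfilov kinetics
  double gamma, mu1, mu2, brec;   // recovery ODE constants
  double kphi, dphi, kt;          // dimensional conversion
  double diso, dani;              // conduction, mm^2/ms
  double Gs, phis;                // stretch-activated channel current
  bool   mef_on;                  // false: MEF term removed from the build
};

struct ActPar {
  double kT, Phir;                // kPa/mV, mV
  double eps0, epsinf, xi, Phibar;// activation-rate function (1/ms, 1/ms, 1/mV, mV)
};

// simple dense 4th-order tensor in 3d
struct T4 {
  double v[3][3][3][3];
  T4() { zero(); }
  void zero() { std::memset(v, 0, sizeof(v)); }
};

MatPar as_matpar(const Rcpp::List &l);
EpPar  as_eppar(const Rcpp::List &l);
ActPar as_actpar(const Rcpp::List &l);

void pk2_point(const arma::mat33 &F, const arma::vec3 &f0, const arma::vec3 &s0,
               const MatPar &mp, double Tact,
               bool want_tan, bool include_vol, bool vol_only,
               arma::mat33 &S, T4 &CC, double &psi, double &lam, double &J);

arma::mat33 conductivity_point(const arma::mat33 &F, const arma::vec3 &f0,
                               const EpPar &ep, bool want_dD, T4 &dDdC);

double fe_point(double phi, double r, const EpPar &ep);
double fe_dphi(double phi, double r, const EpPar &ep);
double recovery_rhs_point(double phi, double r, const EpPar &ep);
void   recovery_update_point(double phi, double rn, double dtbar, const EpPar &ep,
                             double &rnew, double &drdphi);
double fm_point(double lam, double phi, const EpPar &ep);
void   active_update_point(double Phi, double Tn, double dt, const ActPar &ap,
                           double &Tnew, double &dTdPhi);

#endif
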