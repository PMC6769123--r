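#' Kinematic quantities of a deformation state
#'
#' Computes the right Cauchy-Green tensor, volume ratio, strain invariants,
#' their isochoric counterparts and the fiber stretch for a deformation
#' gradient \code{F} and a material fiber/sheet frame.
#'
#' @param F 3x3 deformation gradient with \code{det(F) > 0}.
#' @param f0,s0 material fiber and sheet unit vectors (orthonormal; the
#'   sheet-normal is \code{n0 = f0 x s0}).
#' @return list with \code{C}, \code{J}, \code{I1}, \code{I4f}, \code{I4s},
#'   \code{I8fs}, isochoric \code{Ib1}, \code{Ib4f}, \code{Ib4s},
#'   \code{Ib8fs}, and \code{lambda} = sqrt(I4f).
#' @examples
#' k <- kinematics(diag(3), c(1, 0, 0), c(0, 1, 0))
#' k$I1   # 3 at the reference state
#' @export
kinematics <- function(F, f0, s0) {
  check_frame(f0, s0)
  .cem_kinematics(F, f0, s0)
}

check_frame <- function(f0, s0, tol = 1e-10) {
  if (abs(sum(f0^2) - 1) > 1e-8 || abs(sum(s0^2) - 1) > 1e-8)
    stop("fiber/sheet vectors must be unit length")
  if (abs(sum(f0 * s0)) > tol)
    stop("fiber and sheet vectors must be orthogonal")
  invisible(TRUE)
}

#' Passive strain-energy density
#'
#' Evaluates the strain-energy density (kPa) of the selected passive model
#' at a deformation state.  Quadratic fiber terms are switched off under
#' fiber compression; the Holzapfel-Ogden exponentials error out when an
#' exponent argument exceeds \code{exp_cap} (nonphysical strain).
#'
#' @inheritParams kinematics
#' @param mat a \code{\link{material_params}} object.
#' @param include_vol include the volumetric penalty term (TII/HO).
#' @return scalar energy density in kPa.
#' @export
psi_passive <- function(F, f0, s0, mat, include_vol = TRUE) {
  check_frame(f0, s0)
  .cem_psi(F, f0, s0, mat, 0, include_vol)
}

#' Passive second Piola-Kirchhoff stress
#'
#' Analytic S = 2 dPsi/dC for the selected passive model.  The isochoric
#' contributions of the nearly incompressible models use the deviatoric
#' projection of the isochoric-invariant derivatives; in the reference
#' configuration the stress vanishes for all three models.
#'
#' @inheritParams psi_passive
#' @return symmetric 3x3 stress tensor (kPa).
#' @export
pk2_passive <- function(F, f0, s0, mat, include_vol = TRUE) {
  check_frame(f0, s0)
  .cem_pk2(F, f0, s0, mat, 0, include_vol)
}

#' Consistent material tangent of the passive stress
#'
#' Fourth-order tensor 2 dS/dC (minor and major symmetric wherever the
#' energy is smooth).  At the tension switch the tangent is one-sided,
#' consistent with the sharp Heaviside switch used in the energy.
#'
#' @inheritParams psi_passive
#' @return numeric array of dimension \code{c(3, 3, 3, 3)}.
#' @export
tangent_passive <- function(F, f0, s0, mat, include_vol = TRUE) {
  check_frame(f0, s0)
  .cem_tangent(F, f0, s0, mat, 0, include_vol)
}

#' Active second Piola-Kirchhoff stress
#'
#' Rank-one fiber stress \code{T_act * (f0 x f0)} in the material frame.
#' The corresponding Cauchy fiber stress is \code{T_act I4f / J}: it falls
#' off as the fibers shorten, which makes active contraction self-limiting
#' at large shortening.
#'
#' @param T_act active fiber tension (kPa).
#' @inheritParams kinematics
#' @return 3x3 stress tensor (kPa).
#' @export
pk2_active <- function(T_act, F, f0) {
  T_act * tcrossprod(f0)
}

#' Deformation-dependent conductivity tensor
#'
#' Material conductivity D = J d_iso C^-1 + J d_ani (f0 x f0) / lambda^2,
#' symmetric positive definite for positive d_iso.
#'
#' @inheritParams kinematics
#' @param electro an \code{\link{electro_params}} object.
#' @return 3x3 conductivity tensor (mm^2/ms).
#' @export
conductivity <- function(F, f0, electro) {
  .cem_conductivity(F, f0, electro)
}

#' Material electrical flux
#'
#' Q = D(C) . gradPhi, linear in the material potential gradient.
#'
#' @inheritParams conductivity
#' @param gradPhi material gradient of the potential (mV/mm).
#' @return flux vector (mV mm / ms).
#' @export
flux <- function(F, f0, gradPhi, electro) {
  drop(conductivity(F, f0, electro) %*% gradPhi)
}
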