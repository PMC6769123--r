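#' Dimensional conversion of the action potential
#'
#' Affine maps between the dimensionless Aliev-Panfilov potential phi and
#' the physical transmembrane potential Phi (mV):
#' \code{Phi = k_phi * phi - delta_phi}.  With the default scaling, phi = 0
#' is the -80 mV resting state and phi = 0.6 corresponds to -20 mV.
#'
#' @param phi dimensionless potential.
#' @param electro an \code{\link{electro_params}} object.
#' @return potential in mV.
#' @examples
#' to_physical(0)    # -80
#' to_physical(0.6)  # -20
#' @export
to_physical <- function(phi, electro = electro_params()) {
  electro$k_phi * phi - electro$delta_phi
}

#' @rdname to_physical
#' @param Phi physical potential (mV).
#' @export
to_dimensionless <- function(Phi, electro = electro_params()) {
  (Phi + electro$delta_phi) / electro$k_phi
}

#' Aliev-Panfilov excitation current
#'
#' Dimensionless effective membrane current
#' \code{f_e = c phi (phi - alpha) (1 - phi) - r phi + I}; the physical
#' source entering the monodomain equation is \code{(k_phi / k_t) f_e}.
#'
#' @param phi dimensionless potential.
#' @param r recovery variable.
#' @inheritParams to_physical
#' @export
f_e <- function(phi, r, electro = electro_params()) {
  vapply(seq_along(phi),
         function(i) .cem_fe(phi[i], if (length(r) == 1) r else r[i], electro),
         numeric(1))
}

#' Recovery-variable kinetics
#'
#' Right-hand side of the recovery ODE (dimensionless time):
#' \code{dr/dtbar = (gamma + mu1 r / (mu2 + phi)) (-r - c phi (phi - b_rec - 1))}.
#'
#' @inheritParams f_e
#' @export
recovery_rhs <- function(phi, r, electro = electro_params()) {
  .cem_recovery_rhs(phi, r, electro)
}

#' Local implicit update of the recovery variable
#'
#' One backward-Euler step of the recovery ODE at fixed phi, as performed
#' per quadrature point inside the global Newton iteration, together with
#' the consistent sensitivity dr/dphi.
#'
#' @param phi dimensionless potential at the end of the step.
#' @param r_n recovery value at the previous time step.
#' @param dtbar dimensionless time increment (dt / k_t).
#' @inheritParams f_e
#' @return list with \code{r} and \code{dr_dphi}.
#' @export
recovery_update <- function(phi, r_n, dtbar, electro = electro_params()) {
  .cem_recovery_update(phi, r_n, dtbar, electro)
}

#' Stretch-activated channel current
#'
#' Mechano-electrical feedback source
#' \code{f_m = theta G_s (lambda - 1)(phi_s - phi)} with the switch
#' theta = 1 iff the fiber stretch lambda exceeds one.  Depolarizing for
#' phi < phi_s under tension.
#'
#' @param lambda fiber stretch sqrt(I4f) at the evaluation point.
#' @inheritParams f_e
#' @export
f_m <- function(lambda, phi, electro = electro_params()) {
  .cem_fm(lambda, phi, electro)
}

#' Single-cell electromechanics trace
#'
#' Integrates the point model (phi, r) with classical RK4 at fixed step and
#' carries the active tension along (backward Euler), under an optional
#' dimensionless stimulus current applied over a time window.  Used for
#' cell-level validation against reference ODE solvers and for protocol
#' design.
#'
#' @param electro,active parameter objects.
#' @param phi0,r0 initial state.
#' @param dt step (ms).
#' @param t_end final time (ms).
#' @param I_stim stimulus amplitude (dimensionless current).
#' @param stim_window numeric length-2 window (ms) during which the
#'   stimulus is applied.
#' @return data.frame with columns t, phi, r, Phi, T_act.
#' @export
cell_trace <- function(electro = electro_params(), active = active_params(),
                       phi0 = 0, r0 = 0, dt = 0.05, t_end = 500,
                       I_stim = 0, stim_window = c(0, 1)) {
  n <- ceiling(t_end / dt)
  tgrid <- (seq_len(n) - 1) * dt
  I_t <- ifelse(tgrid >= stim_window[1] & tgrid < stim_window[2], I_stim, 0)
  out <- .cem_cell_trace(phi0, r0, dt, t_end, electro, active, I_t)
  data.frame(t = out$t, phi = out$phi, r = out$r, Phi = out$Phi,
             T_act = out$T_act)
}
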