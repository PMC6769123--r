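#' Backward-Euler update of the active fiber tension
#'
#' One implicit step of the excitation-contraction law
#' \code{dT/dt = eps(Phi) (k_T (Phi - Phi_r) - T)}.  Under a sustained
#' potential the tension saturates at \code{k_T (Phi - Phi_r)}; after the
#' potential returns to rest the tension relaxes back to zero at rate
#' \code{eps_0}.
#'
#' @param T_act tension at the previous step (kPa).
#' @param Phi transmembrane potential at the end of the step (mV).
#' @param dt time increment (ms).
#' @param active an \code{\link{active_params}} object.
#' @return list with \code{T_act} (updated tension, kPa) and
#'   \code{dT_dPhi} (consistent sensitivity, kPa/mV).
#' @examples
#' # saturation at k_T * (Phi - Phi_r) = 0.49 * 100 = 49 kPa
#' s <- list(T_act = 0)
#' for (i in 1:5000) s <- active_tension_update(s$T_act, 20, 1)
#' s$T_act
#' @export
active_tension_update <- function(T_act, Phi, dt, active = active_params()) {
  stopifnot(dt > 0)
  .cem_active_update(Phi, T_act, dt, active)
}

#' Saturated active tension under a sustained potential
#'
#' Integrates the active-tension ODE to steady state under a constant
#' plateau potential and returns the saturated tension; the fixed point is
#' \code{k_T (Phi - Phi_r)}.
#'
#' @param Phi plateau potential (mV).
#' @param active an \code{\link{active_params}} object.
#' @param dt integration step (ms).
#' @param tol relative change tolerance that stops the integration.
#' @return saturated tension (kPa).
#' @export
active_tension_saturation <- function(Phi, active = active_params(),
                                      dt = 0.5, tol = 1e-12) {
  T_act <- 0
  for (i in seq_len(100000)) {
    up <- .cem_active_update(Phi, T_act, dt, active)
    if (abs(up$T_act - T_act) <= tol * max(1, abs(up$T_act))) {
      T_act <- up$T_act
      break
    }
    T_act <- up$T_act
  }
  T_act
}
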