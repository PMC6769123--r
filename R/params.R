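#' Passive material parameter sets
#'
#' Builds a validated parameter list for one of the three passive myocardial
#' constitutive laws:
#' \describe{
#'   \item{TIC}{transversely isotropic, compressible, polynomial (modified
#'     neo-Hookean plus quadratic fiber term); parameters \code{Lambda},
#'     \code{mu} (Lame constants, kPa) and \code{eta} (fiber stiffness, kPa).}
#'   \item{TII}{transversely isotropic, nearly incompressible, polynomial;
#'     parameters \code{mu}, \code{eta} (kPa) and bulk penalty \code{kappa}
#'     (kPa, default 1e4).}
#'   \item{HO}{orthotropic, nearly incompressible Holzapfel-Ogden exponential
#'     law; parameters \code{a}, \code{a_f}, \code{a_s}, \code{a_fs} (kPa),
#'     \code{b}, \code{b_f}, \code{b_s}, \code{b_fs} (dimensionless) and
#'     \code{kappa} (kPa).}
#' }
#'
#' Defaults are a rat-scale parameter set: the HO constants are one half of
#' the classical simple-shear fit of the Holzapfel-Ogden law to porcine
#' myocardium, and the polynomial models were calibrated once against the
#' same six simple-shear response curves (see the methods vignette).
#' Quadratic fiber terms carry a tension switch: they contribute only when
#' the (isochoric, for TII) fiber stretch exceeds one.
#'
#' @param model one of \code{"TIC"}, \code{"TII"}, \code{"HO"}.
#' @param ... named overrides of individual parameters.
#' @return a list of class \code{cem_material}.
#' @examples
#' material_params("HO")
#' material_params("TIC", eta = 10)
#' @export
material_params <- function(model = c("TIC", "TII", "HO"), ...) {
  model <- match.arg(model)
  p <- switch(model,
    TIC = list(model = "TIC", Lambda = 0.78, mu = 0.39, eta = 21.3),
    TII = list(model = "TII", mu = 0.39, eta = 21.3, kappa = 1e4),
    HO  = list(model = "HO",
               a = 0.0295, b = 8.023, a_f = 9.236, b_f = 16.026,
               a_s = 1.2405, b_s = 11.120, a_fs = 0.108, b_fs = 11.436,
               kappa = 1e4))
  p$exp_cap <- 50
  dots <- list(...)
  bad <- setdiff(names(dots), c(names(p), "kappa"))
  if (length(bad)) stop("unknown material parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  stiff <- p[setdiff(names(p), c("model", "exp_cap"))]
  if (any(unlist(stiff) <= 0))
    stop("all stiffness parameters must be positive")
  structure(p, class = "cem_material")
}

#' Electrophysiology parameter set
#'
#' Two-variable Aliev-Panfilov kinetics with dimensional conversion,
#' deformation-dependent conduction and the stretch-activated channel
#' current.  The dimensionless potential phi in [0, 1] maps to the physical
#' transmembrane potential via Phi = k_phi * phi - delta_phi (mV), and the
#' dimensionless time via t = k_t * tbar (ms).  Defaults give a resting
#' potential of -80 mV and place the stretch-current reversal potential
#' phi_s = 0.6 at -20 mV.
#'
#' @param ... named overrides: \code{alpha}, \code{c}, \code{I_ext},
#'   \code{gamma}, \code{mu1}, \code{mu2}, \code{b_rec} (kinetics);
#'   \code{k_phi} (mV), \code{delta_phi} (mV), \code{k_t} (ms);
#'   \code{d_iso}, \code{d_ani} (mm^2/ms); \code{G_s}, \code{phi_s}
#'   (stretch-activated current); \code{mef_on} (logical, set \code{FALSE}
#'   to compile the feedback term out of the assembled residual).
#' @return a list of class \code{cem_electro}.
#' @export
electro_params <- function(...) {
  p <- list(alpha = 0.01, c = 8, I_ext = 0,
            gamma = 0.012, mu1 = 0.2, mu2 = 0.3, b_rec = 0.15,
            k_phi = 100, delta_phi = 80, k_t = 12.9,
            d_iso = 0.1, d_ani = 0.3,
            G_s = 0, phi_s = 0.6, mef_on = TRUE)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown electro parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(p$k_phi > 0, p$k_t > 0, p$alpha > 0, p$alpha < 1,
            p$d_iso > 0, p$d_ani >= 0, p$G_s >= 0,
            p$phi_s >= 0, p$phi_s <= 1)
  structure(p, class = "cem_electro")
}

#' Active-stress parameter set
#'
#' Excitation-contraction coupling via a fiber tension T obeying
#' dT/dt = eps(Phi) * (k_T (Phi - Phi_r) - T), so sustained depolarization
#' saturates the tension at k_T (Phi - Phi_r).  The activation rate
#' eps(Phi) = eps_0 + (eps_inf - eps_0) exp(-exp(-xi (Phi - Phi_bar)))
#' switches smoothly from the slow resting rate eps_0 to the fast
#' depolarized rate eps_inf around Phi_bar.
#'
#' @param ... named overrides: \code{k_T} (kPa/mV), \code{Phi_r} (mV),
#'   \code{eps_0}, \code{eps_inf} (1/ms), \code{xi} (1/mV), \code{Phi_bar}
#'   (mV).
#' @return a list of class \code{cem_active}.
#' @export
active_params <- function(...) {
  p <- list(k_T = 0.49, Phi_r = -80, eps_0 = 0.1, eps_inf = 1.0,
            xi = 0.1, Phi_bar = 0)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown active parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(p$k_T > 0, p$eps_0 > 0, p$eps_inf > 0)
  structure(p, class = "cem_active")
}

#' Read a parameter configuration file
#'
#' Flat YAML configuration with up to four blocks: \code{material},
#' \code{electro}, \code{active} and \code{solver}.  The \code{units} field,
#' if present, must declare \code{mm-ms-kPa-mV}; anything else is rejected
#' (the solver is unit-committed).
#'
#' @param path path to a YAML file.
#' @return list with elements \code{material}, \code{electro}, \code{active},
#'   \code{solver} (missing blocks give defaults).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$units) && !identical(cfg$units, "mm-ms-kPa-mV"))
    stop("configuration declares units '", cfg$units,
         "'; this solver works in mm-ms-kPa-mV")
  mat <- if (is.null(cfg$material)) material_params("TIC") else
    do.call(material_params, c(list(model = cfg$material$model),
                               cfg$material[setdiff(names(cfg$material), "model")]))
  el <- if (is.null(cfg$electro)) electro_params() else
    do.call(electro_params, cfg$electro)
  act <- if (is.null(cfg$active)) active_params() else
    do.call(active_params, cfg$active)
  list(material = mat, electro = el, active = act,
       solver = do.call(solver_config, as.list(cfg$solver)))
}

#' Solver configuration
#'
#' @param dt time step (ms).
#' @param t_end final time (ms).
#' @param tol absolute Newton residual tolerance.
#' @param rtol relative Newton residual tolerance (vs the first iterate).
#' @param max_iter maximum Newton iterations per step.
#' @param max_halvings maximum number of time-step halvings on failure.
#' @param vol_sri logical; stabilized selectively reduced integration of the
#'   volumetric penalty of the nearly incompressible models: a fraction
#'   \code{vol_sri_frac} of the penalty is kept on the full quadrature (it
#'   keeps the tangent well conditioned for very soft deviatoric responses)
#'   and the remainder is integrated at the element center only, relieving
#'   volumetric locking of coarse hexahedra.
#' @param vol_sri_frac penalty fraction retained on full quadrature.
#' @param dt_late,t_late optional two-level step schedule: after
#'   \code{t_late} (ms) the base step becomes \code{dt_late}.  Used to
#'   coarsen the slow late-repolarization phase of long runs.
#' @param output_every write field output every this many accepted steps
#'   (0 = never).
#' @param out_dir optional output directory for VTU series / probe CSV.
#' @param stop_all_depolarized stop the run once every nodal potential
#'   exceeds \code{depol_threshold}.
#' @param depol_threshold depolarization threshold (mV) used for the
#'   completion-time readout.
#' @return list of class \code{cem_solver_config}.
#' @export
solver_config <- function(dt = 0.5, t_end = 100, tol = 1e-6, rtol = 1e-9,
                          max_iter = 15, max_halvings = 5, vol_sri = FALSE,
                          vol_sri_frac = 0.05, dt_late = NULL, t_late = NULL,
                          output_every = 0, out_dir = NULL,
                          stop_all_depolarized = FALSE, depol_threshold = 0) {
  stopifnot(dt > 0, t_end > 0, tol > 0, max_iter >= 1,
            vol_sri_frac > 0, vol_sri_frac <= 1)
  structure(list(dt = dt, t_end = t_end, tol = tol, rtol = rtol,
                 max_iter = max_iter, max_halvings = max_halvings,
                 vol_sri = vol_sri, vol_sri_frac = vol_sri_frac,
                 dt_late = dt_late, t_late = t_late,
                 output_every = output_every,
                 out_dir = out_dir,
                 stop_all_depolarized = stop_all_depolarized,
                 depol_threshold = depol_threshold),
            class = "cem_solver_config")
}
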