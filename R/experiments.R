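#' Stretch-induced excitation in a plate
#'
#' Benchmark of deformation-triggered depolarization: a plate at rest
#' (-80 mV everywhere, no electrical stimulus) receives a triangular load
#' pulse on its central parallelepiped (linear rise to the peak force at
#' 5 ms, back to zero at 10 ms).  The resulting stretch opens the
#' stretch-activated channels, ignites a depolarization wave, and the
#' earliest time at which every nodal potential exceeds the depolarization
#' threshold (0 mV by default) is reported.
#'
#' The large plate is 100 x 100 x 12 mm with d_iso = 1.0 and
#' d_ani = 0.1 mm^2/ms; the small (rat-scale) plate is 10 x 10 x 1.2 mm
#' with d_iso = 0.1 and d_ani = 0.3 mm^2/ms.  Fibers run along x, sheets
#' along y; the mid-plane edge nodes are fixed in z and two corner nodes
#' pin the remaining in-plane rigid modes.
#'
#' @param size \code{"large"} or \code{"small"}.
#' @param model passive model id (the benchmark uses the compressible TIC).
#' @param G_s maximum stretch-activated conductance.
#' @param peak_load peak of the triangular pulse (mN); defaults (6000 mN
#'   large, 60 mN small) are calibrated so the pulse stretches the central
#'   fibers to about lambda = 1.12, which reliably nucleates a wave (see
#'   the methods vignette on load calibration).
#' @param load_dir direction of the nodal loads (3 = out of plane).
#' @param config optional \code{\link{solver_config}} overriding the
#'   defaults (dt = 0.5 ms, run until complete depolarization or 120/250 ms).
#' @param mat,electro,active optional parameter overrides.
#' @return the \code{cem_run} with element \code{depol_time} (ms).
#' @export
run_plate_benchmark <- function(size = c("small", "large"), model = "TIC",
                                G_s = 15, peak_load = NULL, load_dir = 3,
                                config = NULL, mat = NULL, electro = NULL,
                                active = NULL) {
  size <- match.arg(size)
  if (size == "large") {
    mesh <- make_plate(c(100, 100, 12), c(21, 21, 2))
    if (is.null(electro)) electro <- electro_params(d_iso = 1.0, d_ani = 0.1,
                                                    G_s = G_s)
    if (is.null(peak_load)) peak_load <- 6000
    t_cap <- 250
  } else {
    mesh <- make_plate(c(10, 10, 1.2), c(21, 21, 2))
    if (is.null(electro)) electro <- electro_params(d_iso = 0.1, d_ani = 0.3,
                                                    G_s = G_s)
    if (is.null(peak_load)) peak_load <- 60
    t_cap <- 120
  }
  if (is.null(mat)) mat <- material_params(model)
  if (is.null(active)) active <- active_params()
  if (is.null(config)) config <- solver_config(dt = 0.5, t_end = t_cap,
                                               stop_all_depolarized = TRUE,
                                               tol = 1e-3, max_iter = 25)
  protocol <- list(
    fixed_u = rbind(cbind(mesh$sets$midplane_edge, 3L),
                    cbind(mesh$sets$corner_origin, 1L),
                    cbind(mesh$sets$corner_origin, 2L),
                    cbind(mesh$sets$corner_x, 2L)),
    load = list(nodes = mesh$sets$load, dir = load_dir,
                p = function(t) peak_load * pmax(0, 1 - abs(t - 5) / 5)),
    probes = c(center = mesh$sets$load[ceiling(length(mesh$sets$load) / 2)],
               corner = which.max(rowSums(mesh$nodes^2))))
  run <- run_simulation(mesh, mat, electro, active, protocol, config)
  if (is.na(run$depol_time) && max(run$summary$Phi_max) < config$depol_threshold)
    warning("no depolarization wave was initiated; the load may be too small")
  run
}

#' Isotonic contraction of a cube
#'
#' Drives a free-floating cube (rigid modes pinned) with a prescribed
#' uniform action-potential plateau and records the volume-ratio history
#' J(t).  The compressible TIC model loses volume during the active
#' plateau, while the nearly incompressible TII/HO models hold J within the
#' penalty tolerance.
#'
#' @param model passive model id.
#' @param plateau plateau potential (mV).
#' @param t_on,t_off start/end of the plateau (ms); ramps of 2 ms connect
#'   rest and plateau.
#' @param config optional \code{\link{solver_config}} (default dt = 1 ms,
#'   t_end = 350 ms).
#' @param n element divisions of the cube.
#' @param drive set \code{FALSE} to run without any activation (J stays 1).
#' @param mat,electro,active optional parameter overrides.
#' @return list with the \code{run}, and \code{J} data.frame (t, J_mean,
#'   J_min, J_max).
#' @export
run_cube_isotonic <- function(model = "HO", plateau = 20, t_on = 10,
                              t_off = 250, config = NULL, n = 1,
                              drive = TRUE, mat = NULL, electro = NULL,
                              active = NULL) {
  mesh <- make_cube(1, n)
  if (is.null(mat)) mat <- material_params(model)
  if (is.null(electro)) electro <- electro_params()
  if (is.null(active)) active <- active_params()
  if (is.null(config)) config <- solver_config(dt = 1, t_end = 350,
                                               max_iter = 40)
  rest <- to_physical(0, electro)
  ramp <- function(t) {
    if (t < t_on) rest
    else if (t < t_on + 2) rest + (plateau - rest) * (t - t_on) / 2
    else if (t < t_off) plateau
    else if (t < t_off + 2) plateau + (rest - plateau) * (t - t_off) / 2
    else rest
  }
  protocol <- list(
    fixed_u = rbind(cbind(mesh$sets$pin_xyz, 1L), cbind(mesh$sets$pin_xyz, 2L),
                    cbind(mesh$sets$pin_xyz, 3L), cbind(mesh$sets$pin_yz, 2L),
                    cbind(mesh$sets$pin_yz, 3L), cbind(mesh$sets$pin_z, 3L)),
    probes = c(corner = nrow(mesh$nodes)))
  if (drive)
    protocol$phi_drive <- list(nodes = seq_len(nrow(mesh$nodes)), value = ramp)
  run <- run_simulation(mesh, mat, electro, active, protocol, config)
  list(run = run,
       J = run$summary[, c("t", "J_mean", "J_min", "J_max")])
}

#' Left-ventricle conductance sweep
#'
#' Reproduces the comparative study design on the synthetic left ventricle:
#' for each passive model and each maximum conductance G_s, the base is
#' mechanically fixed, seven basal endocardial nodes are held at -20 mV for
#' 40 ms to trigger the depolarization, and the apical probe records the
#' potential and displacement.  Per (model, G_s) pair the peak metrics and
#' the delta metrics against the feedback-free (G_s = 0) reference of the
#' same model are aggregated.
#'
#' @param models character vector of passive model ids.
#' @param gs_values numeric vector of maximum conductances (must contain 0,
#'   the reference).
#' @param mesh optional prebuilt LV mesh (default \code{make_lv(spec)}).
#' @param spec \code{\link{lv_spec}} used when \code{mesh} is NULL.
#' @param config \code{\link{solver_config}}; defaults to dt = 1 ms,
#'   t_end = 420 ms (a full cycle plus a settled read-out window),
#'   max_iter = 30 (the soft laws need room for damped iterations during
#'   the stimulus phase) and stabilized selective integration of the
#'   volumetric penalty.
#' @param electro,active optional parameter overrides (G_s is set per run).
#' @param mats optional named list of material parameter objects.
#' @return list with \code{metrics} (data.frame: model, G_s, Phi_max, t_max,
#'   u_max, Phi_rest, u_rest, peak2, dt_max, dPhi_rest, du_rest, failed),
#'   and \code{probes} (named list of apex probe series).
#' @export
run_lv_sweep <- function(models = c("TIC", "TII", "HO"),
                         gs_values = c(0, 10, 20, 30, 40, 50),
                         mesh = NULL, spec = lv_spec(target_size = 1.25),
                         config = NULL, electro = NULL, active = NULL,
                         mats = NULL) {
  stopifnot(0 %in% gs_values)
  if (is.null(mesh)) mesh <- make_lv(spec)
  if (is.null(config)) config <- solver_config(dt = 1, t_end = 420,
                                               max_iter = 30, tol = 1e-4,
                                               vol_sri = TRUE,
                                               dt_late = 2, t_late = 150)
  if (is.null(active)) active <- active_params()
  base_el <- if (is.null(electro)) electro_params(d_iso = 0.1, d_ani = 0.3)
             else electro
  protocol <- list(
    fixed_u = cbind(rep(mesh$sets$base, each = 3), rep(1:3, length(mesh$sets$base))),
    stim = list(nodes = mesh$sets$stim, value = -20, t_on = 0, t_off = 40),
    probes = c(apex = mesh$sets$apex))
  rows <- list()
  traces <- list()
  for (mod in models) {
    mat <- if (!is.null(mats) && !is.null(mats[[mod]])) mats[[mod]]
           else material_params(mod)
    ref_series <- NULL
    for (gs in sort(gs_values)) {
      el <- base_el
      el$G_s <- gs
      key <- sprintf("%s_Gs%g", mod, gs)
      run <- tryCatch(
        run_simulation(mesh, mat, el, active, protocol, config),
        error = function(e) e)
      if (inherits(run, "error")) {
        warning(sprintf("run %s failed: %s", key, conditionMessage(run)))
        rows[[key]] <- data.frame(model = mod, G_s = gs, Phi_max = NA,
                                  t_max = NA, u_max = NA, Phi_rest = NA,
                                  u_rest = NA, peak2 = NA, dt_max = NA,
                                  dPhi_rest = NA, du_rest = NA, failed = TRUE)
        next
      }
      series <- run$probes[run$probes$probe == "apex", ]
      traces[[key]] <- series
      if (gs == 0) ref_series <- series
      met <- analyze_probe(series, reference = if (gs > 0) ref_series,
                           rest = to_physical(0, el))
      rows[[key]] <- data.frame(
        model = mod, G_s = gs, Phi_max = met$Phi_max, t_max = met$t_max,
        u_max = met$u_max, Phi_rest = met$Phi_rest, u_rest = met$u_rest,
        peak2 = met$peak2,
        dt_max = if (gs > 0) met$dt_max else 0,
        dPhi_rest = if (gs > 0) met$dPhi_rest else 0,
        du_rest = if (gs > 0) met$du_rest else 0,
        failed = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(metrics = metrics, probes = traces, mesh = mesh)
}
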