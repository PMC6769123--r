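#' Peak metrics of a probe trace
#'
#' Extracts the depolarization peak (peak 1: global maximum of the
#' potential) and the late-repolarization residual level (peak 2) from a
#' probe time series, and, when a reference series is supplied, the
#' absolute differences of every metric against it.
#'
#' Peak 2 is read as the plateau level over the final \code{window} ms of
#' the run; it is flagged absent when the trace decays monotonically back
#' to rest (residual within \code{rest_tol} of the resting potential and no
#' late local maximum).
#'
#' @param series data.frame with columns \code{t} (ms, strictly
#'   increasing), \code{Phi} (mV) and \code{u} (displacement magnitude, mm)
#'   for a single probe.
#' @param reference optional series of the same shape (typically the
#'   feedback-free run) for the delta metrics.
#' @param rest resting potential (mV).
#' @param window residual read-out window (ms) at the end of the run.
#' @param rest_tol tolerance (mV) on the residual level for declaring
#'   peak 2 absent.
#' @param min_t minimal run length (ms) required for residual metrics.
#' @return list of class \code{cem_probe_metrics} with \code{Phi_max},
#'   \code{t_max}, \code{u_max}, \code{Phi_rest}, \code{u_rest},
#'   \code{peak2} (logical) and, given a reference, \code{dPhi_max},
#'   \code{dt_max}, \code{du_max}, \code{dPhi_rest}, \code{du_rest}.
#' @export
analyze_probe <- function(series, reference = NULL, rest = -80, window = 50,
                          rest_tol = 0.5, min_t = 300) {
  stopifnot(all(diff(series$t) > 0))
  if (max(series$t) < min_t)
    stop("run shorter than ", min_t, " ms: residual metrics refused")
  i1 <- which.max(series$Phi)
  out <- list(Phi_max = series$Phi[i1], t_max = series$t[i1],
              u_max = max(series$u))
  late <- series$t >= max(series$t) - window
  out$Phi_rest <- mean(series$Phi[late])
  out$u_rest <- mean(series$u[late])
  # peak 2 present iff the trace fails to settle back at rest
  out$peak2 <- out$Phi_rest > rest + rest_tol
  if (!is.null(reference)) {
    ref <- analyze_probe(reference, NULL, rest, window, rest_tol, min_t)
    out$dPhi_max <- abs(ref$Phi_max - out$Phi_max)
    out$dt_max <- abs(ref$t_max - out$t_max)
    out$du_max <- abs(ref$u_max - out$u_max)
    out$dPhi_rest <- abs(ref$Phi_rest - out$Phi_rest)
    out$du_rest <- abs(ref$u_rest - out$u_rest)
  }
  structure(out, class = "cem_probe_metrics")
}

#' @export
print.cem_probe_metrics <- function(x, ...) {
  cat(sprintf("peak 1: Phi_max = %.2f mV at t = %.1f ms, u_max = %.3f mm\n",
              x$Phi_max, x$t_max, x$u_max))
  cat(sprintf("peak 2 (%s): Phi_rest = %.2f mV, u_rest = %.3f mm\n",
              if (x$peak2) "present" else "absent", x$Phi_rest, x$u_rest))
  if (!is.null(x$dPhi_rest))
    cat(sprintf("vs reference: dt_max = %.1f ms, dPhi_rest = %.2f mV, du_rest = %.3f mm\n",
                x$dt_max, x$dPhi_rest, x$du_rest))
  invisible(x)
}
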