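#' Assemble the coupled global residual and Jacobian
#'
#' Evaluates the weak-form residual of the coupled quasi-static momentum /
#' monodomain problem at the given state, with backward-Euler discretization
#' of the potential rate and of the quadrature-point internal variables
#' (recovery r, active tension T), and optionally the consistent sparse
#' Jacobian including all four coupling blocks.
#'
#' Degrees of freedom are ordered per node: (ux, uy, uz, Phi), so dof
#' \code{4 (i - 1) + 1..4} belongs to node i.
#'
#' @param mesh a \code{cem_mesh}.
#' @param state list with nodal \code{u} (length 3n), \code{Phi} (length n),
#'   previous-step \code{Phi_n}, and quadrature-point matrices \code{r_n},
#'   \code{T_n} (elements x 8).
#' @param mat,electro,active parameter objects.
#' @param dt time increment (ms).
#' @param time current time (ms), used only in diagnostics.
#' @param vol_sri stabilized selectively reduced integration of the
#'   volumetric penalty (see \code{\link{solver_config}}).
#' @param vol_sri_frac fraction of the penalty retained on full quadrature.
#' @param want_matrix return the sparse Jacobian (else residual only).
#' @return list with \code{res} (length 4n), sparse \code{K} (dgCMatrix, when
#'   requested), committed internal-variable candidates \code{r_new},
#'   \code{T_new}, element fields \code{lambda}, \code{J}, \code{T_act} and
#'   the total strain energy \code{psi}.
#' @export
assemble_system <- function(mesh, state, mat, electro, active, dt,
                            time = 0, vol_sri = FALSE, vol_sri_frac = 0.05,
                            want_matrix = TRUE) {
  out <- .cem_assemble(mesh$nodes, mesh$elems, mesh$f0, mesh$s0,
                       state$u, state$Phi, state$Phi_n, state$r_n, state$T_n,
                       dt, time, mat, electro, active, vol_sri, vol_sri_frac,
                       want_matrix, want_matrix)
  if (want_matrix) {
    ndof <- 4L * nrow(mesh$nodes)
    out$K <- Matrix::sparseMatrix(i = out$i, j = out$j, x = out$x,
                                  dims = c(ndof, ndof))
  }
  out$i <- out$j <- out$x <- NULL
  out
}

#' Initial (resting) system state
#'
#' Zero displacement, uniform resting potential, zero recovery variable and
#' zero active tension.
#'
#' @param mesh a \code{cem_mesh}.
#' @param Phi_rest resting potential (mV).
#' @return state list as used by \code{\link{assemble_system}}.
#' @export
rest_state <- function(mesh, Phi_rest = -80) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elems)
  list(u = numeric(3 * n), Phi = rep(Phi_rest, n), Phi_n = rep(Phi_rest, n),
       r_n = matrix(0, m, 8), T_n = matrix(0, m, 8), t = 0)
}

# dof bookkeeping helpers ------------------------------------------------

u_dofs <- function(nodes, dirs) 4L * (rep(nodes, each = length(dirs)) - 1L) +
  rep(dirs, length(nodes))
phi_dofs <- function(nodes) 4L * (nodes - 1L) + 4L

# cached triplet -> dgCMatrix accumulation (pattern fixed per mesh)
make_spattern <- function(i, j, ndof) {
  key <- (as.numeric(j) - 1) * ndof + as.numeric(i)
  uk <- sort(unique(key))
  map <- match(key, uk)
  A <- Matrix::sparseMatrix(i = as.integer((uk - 1) %% ndof) + 1L,
                            j = as.integer((uk - 1) %/% ndof) + 1L,
                            x = rep(0, length(uk)), dims = c(ndof, ndof))
  list(map = map, nnz = length(uk), A = A)
}

fill_spattern <- function(sp, x) {
  sp$A@x <- .cem_accum(sp$map, x, sp$nnz)
  sp$A
}


# solve K dx = b using a (possibly stale) LU factor plus iterative
# refinement; NULL when refinement fails to contract (factor too old)
refine_solve <- function(K, fac, b, rtol = 1e-9, max_ref = 6) {
  bn <- sqrt(sum(b^2))
  if (bn == 0) return(numeric(length(b)))
  dx <- tryCatch(as.numeric(Matrix::solve(fac, b)), error = function(e) NULL)
  if (is.null(dx) || any(!is.finite(dx))) return(NULL)
  rr_prev <- Inf
  for (k in seq_len(max_ref)) {
    r <- b - as.numeric(K %*% dx)
    rr <- sqrt(sum(r^2)) / bn
    if (!is.finite(rr)) return(NULL)
    if (rr < rtol) return(dx)
    if (rr > 0.5 * rr_prev) return(NULL) # not contracting: stale factor
    rr_prev <- rr
    dx <- dx + as.numeric(Matrix::solve(fac, r))
  }
  if (rr_prev < 1e-6) dx else NULL
}

#' One implicit time step by monolithic Newton iteration
#'
#' Solves the fully coupled nonlinear system at t + dt by Newton iteration
#' on the free degrees of freedom, with the internal variables updated
#' inside every iteration (fully consistent linearization).
#'
#' @inheritParams assemble_system
#' @param fixed integer dof indices held at prescribed values (already
#'   written into \code{state}).
#' @param f_ext external nodal force vector (length 4n; mechanical entries
#'   in mN), or NULL.
#' @param config a \code{\link{solver_config}}.
#' @param cache optional solver cache (sparsity pattern and reusable
#'   Jacobian factorization) carried across steps (internal).
#' @return list with the converged \code{state}, iteration count
#'   \code{iters}, residual norm history \code{rnorms} and the solver
#'   \code{cache}.
#' @export
newton_solve <- function(mesh, state, mat, electro, active, dt, fixed,
                         f_ext = NULL, config = solver_config(), cache = NULL,
                         time = 0) {
  ndof <- 4L * nrow(mesh$nodes)
  free <- setdiff(seq_len(ndof), fixed)
  if (is.null(cache)) cache <- list(sp = NULL, fac = NULL, key = NULL)
  key <- c(length(free), sum(free), dt)
  x <- numeric(ndof)
  x[seq(1, ndof, 4)] <- state$u[seq(1, length(state$u), 3)]
  x[seq(2, ndof, 4)] <- state$u[seq(2, length(state$u), 3)]
  x[seq(3, ndof, 4)] <- state$u[seq(3, length(state$u), 3)]
  x[seq(4, ndof, 4)] <- state$Phi
  rnorms <- numeric(0)
  out <- NULL
  dx_last <- NULL
  backtracks <- 0L
  it <- 0L
  passes <- 0L
  while (it < config$max_iter && passes < 10L * config$max_iter) {
    passes <- passes + 1L
    state$u <- as.numeric(rbind(x[seq(1, ndof, 4)], x[seq(2, ndof, 4)],
                                x[seq(3, ndof, 4)]))
    state$Phi <- x[seq(4, ndof, 4)]
    raw <- tryCatch(
      .cem_assemble(mesh$nodes, mesh$elems, mesh$f0, mesh$s0,
                    state$u, state$Phi, state$Phi_n, state$r_n, state$T_n,
                    dt, time, mat, electro, active, config$vol_sri,
                    config$vol_sri_frac, TRUE, is.null(cache$sp)),
      error = function(e) e)
    if (inherits(raw, "error")) {
      # element inversion or nonphysical strain along the Newton path:
      # back off the last update (damped Newton); if that is exhausted,
      # report non-convergence so the caller can halve the time step
      if (!is.null(dx_last) && backtracks < 8L) {
        backtracks <- backtracks + 1L
        dx_last <- dx_last / 2
        x[free] <- x[free] - dx_last
        next
      }
      return(list(converged = FALSE, state = state, iters = it,
                  rnorms = rnorms, cache = cache,
                  message = conditionMessage(raw)))
    }
    res <- raw$res
    if (!is.null(f_ext)) res <- res - f_ext
    rn <- sqrt(sum(res[free]^2))
    if (length(rnorms) && rn > 2 * rnorms[length(rnorms)] &&
        !is.null(dx_last) && backtracks < 8L) {
      # diverging update: damp it and re-evaluate
      backtracks <- backtracks + 1L
      dx_last <- dx_last / 2
      x[free] <- x[free] - dx_last
      next
    }
    it <- it + 1L
    backtracks <- 0L
    rnorms <- c(rnorms, rn)
    tol <- max(config$tol, config$rtol * rnorms[1])
    if (rn < tol) {
      out <- raw
      break
    }
    if (is.null(cache$sp)) cache$sp <- make_spattern(raw$i, raw$j, ndof)
    # the factorization of an earlier Jacobian is reused as long as
    # iterative refinement against the current matrix still converges;
    # otherwise the current matrix is factorized.  Newton directions are
    # therefore (near-)exact in either case, and convergence is always
    # judged on the true assembled residual.
    Kff <- fill_spattern(cache$sp, raw$x)[free, free, drop = FALSE]
    b <- res[free]
    dx <- NULL
    if (!is.null(cache$fac) && identical(cache$key, key)) {
      dx <- refine_solve(Kff, cache$fac, b)
    }
    if (is.null(dx)) {
      cache$fac <- tryCatch(
        Matrix::lu(Kff, order = 1L, tol = 0.1),
        error = function(e) NULL)
      cache$key <- key
      if (is.null(cache$fac)) {
        return(list(converged = FALSE, state = state, iters = it,
                    rnorms = rnorms, cache = cache))
      }
      dx <- refine_solve(Kff, cache$fac, b)
    }
    if (is.null(dx) || any(!is.finite(dx))) {
      cache$fac <- NULL
      return(list(converged = FALSE, state = state, iters = it,
                  rnorms = rnorms, cache = cache))
    }
    x[free] <- x[free] - dx
    dx_last <- -dx
  }
  if (is.null(out)) {
    return(list(converged = FALSE, state = state, iters = it,
                rnorms = rnorms, cache = cache))
  }
  state$r_n_new <- out$r_new
  state$T_n_new <- out$T_new
  list(converged = TRUE, state = state, iters = length(rnorms) - 1L,
       rnorms = rnorms, cache = cache,
       fields = list(lambda = out$lambda, J = out$J, T_act = out$T_act,
                     psi = out$psi))
}

#' Run a coupled electromechanical simulation
#'
#' Advances the fully coupled problem from rest to \code{config$t_end} with
#' backward-Euler steps and monolithic Newton iteration, applying the
#' protocol's Dirichlet constraints, potential stimuli and nodal loads.  On
#' Newton failure the step is retried with a halved increment (up to
#' \code{config$max_halvings} halvings) and the step size recovers
#' geometrically afterwards.
#'
#' @param mesh a \code{cem_mesh}.
#' @param mat,electro,active parameter objects.
#' @param protocol list with optional entries:
#'   \describe{
#'     \item{fixed_u}{2-column matrix (node, direction 1..3) of homogeneous
#'       displacement constraints.}
#'     \item{stim}{list(nodes, value, t_on, t_off): potential Dirichlet
#'       stimulus; nodes are released to free evolution after t_off.}
#'     \item{phi_drive}{list(nodes, value = function(t)): prescribed
#'       potential trajectory (e.g. a uniform plateau).}
#'     \item{load}{list(nodes, dir, p = function(t)): dead nodal loads; p(t)
#'       is the total force (mN) distributed equally over the node set.}
#'     \item{probes}{named integer vector of probe nodes.}
#'   }
#' @param config a \code{\link{solver_config}}.
#' @return list of class \code{cem_run}: \code{probes} (long data.frame with
#'   t, probe, Phi, ux, uy, uz, u), \code{summary} (per-step t, Phi_min,
#'   Phi_max, J_mean, J_min, J_max, lambda_max, psi, iters),
#'   \code{depol_time} (earliest time every nodal potential exceeded the
#'   threshold, NA if never), \code{activation_time} (per-node first
#'   crossing of the threshold), final \code{state}, and the \code{mesh}.
#' @export
run_simulation <- function(mesh, mat, electro, active,
                           protocol = list(), config = solver_config()) {
  n <- nrow(mesh$nodes)
  ndof <- 4L * n
  state <- rest_state(mesh, Phi_rest = to_physical(0, electro))
  vol <- element_volumes(mesh)

  fixed_u_dofs <- integer(0)
  if (!is.null(protocol$fixed_u)) {
    fu <- protocol$fixed_u
    fixed_u_dofs <- unique(4L * (fu[, 1] - 1L) + fu[, 2])
  }
  probes <- protocol$probes
  if (is.null(probes)) probes <- c(center = 1L)

  probe_rows <- list()
  sum_rows <- list()
  cache <- NULL
  act_time <- rep(NA_real_, n)
  t <- 0
  dt_base <- config$dt
  dt <- dt_base
  depol_time <- NA_real_
  step <- 0L
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  record <- function(state, t, fields, iters) {
    for (pn in seq_along(probes)) {
      nd <- probes[pn]
      uu <- state$u[(3 * (nd - 1) + 1):(3 * nd)]
      probe_rows[[length(probe_rows) + 1]] <<- data.frame(
        t = t, probe = names(probes)[pn], Phi = state$Phi[nd],
        ux = uu[1], uy = uu[2], uz = uu[3], u = sqrt(sum(uu^2)))
    }
    jw <- sum(fields$J * vol) / sum(vol)
    sum_rows[[length(sum_rows) + 1]] <<- data.frame(
      t = t, Phi_min = min(state$Phi), Phi_max = max(state$Phi),
      J_mean = jw, J_min = min(fields$J), J_max = max(fields$J),
      lambda_max = max(fields$lambda), psi = fields$psi, iters = iters)
  }

  # initial record with reference fields
  record(state, 0,
         list(J = rep(1, nrow(mesh$elems)), lambda = rep(1, nrow(mesh$elems)),
              psi = 0), 0L)

  while (t < config$t_end - 1e-9) {
    if (!is.null(config$dt_late) && !is.null(config$t_late) &&
        t >= config$t_late - 1e-9)
      dt_base <- config$dt_late
    dt_try <- min(dt, dt_base, config$t_end - t)
    halved <- 0L
    repeat {
      t_new <- t + dt_try
      st <- state
      st$Phi_n <- state$Phi
      fixed <- fixed_u_dofs
      # stimulus window (applies at the end-of-step time)
      if (!is.null(protocol$stim) && t_new <= protocol$stim$t_off + 1e-9 &&
          t_new > protocol$stim$t_on) {
        ramp <- protocol$stim$ramp
        if (is.null(ramp)) ramp <- 2
        f <- if (ramp > 0) min(1, (t_new - protocol$stim$t_on) / ramp) else 1
        rest_val <- to_physical(0, electro)
        st$Phi[protocol$stim$nodes] <-
          rest_val + f * (protocol$stim$value - rest_val)
        fixed <- c(fixed, phi_dofs(protocol$stim$nodes))
      }
      if (!is.null(protocol$phi_drive)) {
        st$Phi[protocol$phi_drive$nodes] <- protocol$phi_drive$value(t_new)
        fixed <- c(fixed, phi_dofs(protocol$phi_drive$nodes))
      }
      f_ext <- NULL
      if (!is.null(protocol$load)) {
        f_ext <- numeric(ndof)
        pt <- protocol$load$p(t_new)
        if (pt != 0) {
          dofs <- 4L * (protocol$load$nodes - 1L) + protocol$load$dir
          f_ext[dofs] <- pt / length(protocol$load$nodes)
        }
      }
      sol <- newton_solve(mesh, st, mat, electro, active, dt_try,
                          fixed = unique(fixed), f_ext = f_ext,
                          config = config, cache = cache, time = t_new)
      cache <- sol$cache
      if (sol$converged) break
      halved <- halved + 1L
      if (halved > config$max_halvings)
        stop(sprintf(paste0("Newton failed at t = %g ms after %d step halvings ",
                            "(last residual %.3e, %d iterations)"),
                     t_new, halved - 1L, tail(sol$rnorms, 1), sol$iters))
      dt_try <- dt_try / 2
    }
    state <- sol$state
    state$r_n <- state$r_n_new
    state$T_n <- state$T_n_new
    state$r_n_new <- state$T_n_new <- NULL
    t <- t + dt_try
    state$t <- t
    step <- step + 1L
    record(state, t, sol$fields, sol$iters)
    newly <- is.na(act_time) & state$Phi > config$depol_threshold
    act_time[newly] <- t
    if (is.na(depol_time) &&
        all(state$Phi > config$depol_threshold)) {
      depol_time <- t
      if (config$stop_all_depolarized) break
    }
    if (!is.null(out_dir) && config$output_every > 0 &&
        step %% config$output_every == 0) {
      write_vtu(mesh, file.path(out_dir, sprintf("state_%05d.vtu", step)),
                point_data = list(
                  u = matrix(state$u, ncol = 3, byrow = TRUE),
                  Phi = state$Phi),
                cell_data = list(lambda = sol$fields$lambda, J = sol$fields$J,
                                 T_act = sol$fields$T_act))
    }
    # recover the base step after halvings
    dt <- if (dt_try < dt_base) min(dt_base, 2 * dt_try) else dt_base
  }

  probes_df <- do.call(rbind, probe_rows)
  summary_df <- do.call(rbind, sum_rows)
  if (!is.null(out_dir)) {
    utils::write.csv(probes_df, file.path(out_dir, "probes.csv"),
                     row.names = FALSE)
  }
  structure(list(probes = probes_df, summary = summary_df,
                 depol_time = depol_time, activation_time = act_time,
                 state = state, mesh = mesh, config = config),
            class = "cem_run")
}

#' @export
print.cem_run <- function(x, ...) {
  cat(sprintf("cem_run: %d recorded steps to t = %g ms\n",
              nrow(x$summary) - 1L, max(x$summary$t)))
  cat(sprintf("  Phi range [%.1f, %.1f] mV; depolarization complete at %s ms\n",
              min(x$summary$Phi_min), max(x$summary$Phi_max),
              format(x$depol_time)))
  invisible(x)
}

#' Reference element volumes
#'
#' @param mesh a \code{cem_mesh}.
#' @return vector of element volumes (mm^3) in the reference configuration.
#' @export
element_volumes <- function(mesh) {
  rowSums(ref_jacobians(mesh))
}
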