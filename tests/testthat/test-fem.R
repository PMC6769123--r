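mat_tii <- material_params("TII")
el_g <- electro_params(G_s = 10)
ac <- active_params()

distorted_hex <- function(seed = 2, amp = 0.08) {
  set.seed(seed)
  m <- make_cube(1, 1)
  m$nodes <- m$nodes + amp * matrix(runif(24, -1, 1), 8, 3)
  m
}

random_state <- function(mesh, seed = 3) {
  set.seed(seed)
  st <- rest_state(mesh)
  n <- nrow(mesh$nodes)
  st$u <- 0.05 * rnorm(3 * n)
  st$Phi <- -80 + 60 * runif(n)
  st$Phi_n <- -80 + 60 * runif(n)
  st$r_n <- matrix(runif(8 * nrow(mesh$elems)), nrow(mesh$elems), 8)
  st$T_n <- matrix(20 * runif(8 * nrow(mesh$elems)), nrow(mesh$elems), 8)
  st
}

# finite differences of the global residual wrt the interleaved dofs
fd_jacobian <- function(mesh, st, mat, el, ac, dt, vol_sri, h = 1e-6) {
  ndof <- 4 * nrow(mesh$nodes)
  getres <- function(d) {
    s2 <- st
    for (i in which(d != 0)) {
      nd <- (i - 1) %/% 4 + 1
      cp <- (i - 1) %% 4 + 1
      if (cp < 4) s2$u[3 * (nd - 1) + cp] <- s2$u[3 * (nd - 1) + cp] + d[i]
      else s2$Phi[nd] <- s2$Phi[nd] + d[i]
    }
    assemble_system(mesh, s2, mat, el, ac, dt, vol_sri = vol_sri,
                    want_matrix = FALSE)$res
  }
  K <- matrix(0, ndof, ndof)
  for (i in seq_len(ndof)) {
    d <- numeric(ndof)
    d[i] <- h
    K[, i] <- (getres(d) - getres(-d)) / (2 * h)
  }
  K
}

test_that("global rest is an exact equilibrium and Newton accepts it unchanged", {
  mesh <- make_cube(1, 1)
  st <- rest_state(mesh)
  out <- assemble_system(mesh, st, mat_tii, el_g, ac, 0.5, want_matrix = FALSE)
  expect_lt(max(abs(out$res)), 1e-12)
  sol <- newton_solve(mesh, st, mat_tii, el_g, ac, 0.5, fixed = integer(0))
  expect_true(sol$converged)
  expect_equal(sol$iters, 0)
  expect_equal(sol$state$u, st$u)
  expect_equal(sol$state$Phi, st$Phi)
})

test_that("coupled element Jacobian matches finite differences of the residual", {
  mesh <- distorted_hex()
  st <- random_state(mesh)
  for (sri in c(FALSE, TRUE)) {
    out <- assemble_system(mesh, st, mat_tii, el_g, ac, 0.5, vol_sri = sri)
    K <- as.matrix(out$K)
    Kfd <- fd_jacobian(mesh, st, mat_tii, el_g, ac, 0.5, sri)
    expect_lt(max(abs(K - Kfd)) / max(abs(K)), 1e-5)
  }
})

test_that("coupled Jacobian is exact for the other passive models too", {
  mesh <- distorted_hex(seed = 9)
  st <- random_state(mesh, seed = 10)
  for (m in c("TIC", "HO")) {
    mat <- material_params(m)
    out <- assemble_system(mesh, st, mat, el_g, ac, 0.5)
    Kfd <- fd_jacobian(mesh, st, mat, el_g, ac, 0.5, FALSE)
    expect_lt(max(abs(as.matrix(out$K) - Kfd)) / max(abs(Kfd)), 1e-5)
  }
})

test_that("assembly equals the hand-scattered sum of element contributions", {
  mesh2 <- make_plate(c(2, 1, 1), c(2, 1, 1)) # two hexes sharing a face
  st <- random_state(mesh2, seed = 4)
  full <- assemble_system(mesh2, st, mat_tii, el_g, ac, 0.5, want_matrix = FALSE)
  # element-wise assembly through two single-element meshes
  res_manual <- numeric(4 * nrow(mesh2$nodes))
  for (e in 1:2) {
    conn <- mesh2$elems[e, ]
    sub <- mesh2
    sub$elems <- matrix(seq_len(8), 1)
    sub$nodes <- mesh2$nodes[conn, ]
    sub$f0 <- mesh2$f0[e, , drop = FALSE]
    sub$s0 <- mesh2$s0[e, , drop = FALSE]
    sst <- rest_state(sub)
    sst$u <- as.numeric(matrix(st$u, 3)[, conn])
    sst$Phi <- st$Phi[conn]
    sst$Phi_n <- st$Phi_n[conn]
    sst$r_n <- st$r_n[e, , drop = FALSE]
    sst$T_n <- st$T_n[e, , drop = FALSE]
    sres <- assemble_system(sub, sst, mat_tii, el_g, ac, 0.5,
                            want_matrix = FALSE)$res
    for (a in 1:8) {
      gd <- 4 * (conn[a] - 1) + 1:4
      res_manual[gd] <- res_manual[gd] + sres[4 * (a - 1) + 1:4]
    }
  }
  expect_equal(full$res, res_manual, tolerance = 1e-14)
})

test_that("Jacobian sparsity structure is symmetric", {
  mesh <- make_plate(c(2, 2, 1), c(2, 2, 1))
  st <- rest_state(mesh)
  K <- assemble_system(mesh, st, mat_tii, el_g, ac, 0.5)$K
  P <- K
  P@x <- rep(1, length(P@x))
  expect_equal(P, Matrix::t(P))
})

test_that("patch test: homogeneous stretch is reproduced at an interior node", {
  mesh <- make_cube(1, 2) # 27 nodes, one interior
  A <- diag(c(1.04, 0.99, 1.01))
  A[1, 2] <- 0.02
  uhom <- t(A %*% t(mesh$nodes)) - mesh$nodes
  n <- nrow(mesh$nodes)
  tol <- 1e-9
  boundary <- which(apply(mesh$nodes, 1, function(x)
    any(abs(x) < tol | abs(x - 1) < tol)))
  interior <- setdiff(seq_len(n), boundary)
  expect_equal(length(interior), 1)
  st <- rest_state(mesh)
  for (nd in boundary) st$u[3 * (nd - 1) + 1:3] <- uhom[nd, ]
  fixed <- c(4 * (rep(boundary, each = 3) - 1) + rep(1:3, length(boundary)),
             4 * seq_len(n)) # clamp all potentials at rest
  sol <- newton_solve(mesh, st, mat_tii, el_g, ac, 0.5, fixed = fixed)
  expect_true(sol$converged)
  got <- sol$state$u[3 * (rep(interior, 3) - 1) + 1:3]
  expect_equal(got, unname(uhom[interior, ]), tolerance = 1e-8)
})

test_that("Newton converges quadratically in the mildly nonlinear regime", {
  mesh <- make_cube(1, 1)
  st <- rest_state(mesh)
  # small dead load on the top face, TIC, no electrical activity
  fixed <- c(4 * (mesh$sets$pin_xyz - 1) + 1:3,
             4 * (mesh$sets$pin_yz - 1) + 2:3,
             4 * (mesh$sets$pin_z - 1) + 3)
  f_ext <- numeric(32)
  top <- which(mesh$nodes[, 3] > 0.5)
  f_ext[4 * (top - 1) + 3] <- 1e-4
  sol <- newton_solve(mesh, st, material_params("TIC"), electro_params(), ac,
                      0.5, fixed = fixed, f_ext = f_ext,
                      config = solver_config(tol = 1e-10))
  expect_true(sol$converged)
  expect_lte(sol$iters, 3)
  rn <- sol$rnorms
  k <- length(rn)
  # final contraction far beyond linear: residual collapses to solver noise
  expect_lt(rn[k] / rn[k - 1], 1e-4)
})

test_that("switching the feedback off equals removing the feedback term", {
  mesh <- make_plate(c(4, 4, 1), c(4, 4, 2))
  protocol <- list(
    fixed_u = rbind(cbind(mesh$sets$corner_origin, 1L),
                    cbind(mesh$sets$corner_origin, 2L),
                    cbind(mesh$sets$corner_origin, 3L),
                    cbind(mesh$sets$corner_x, 2L),
                    cbind(mesh$sets$corner_x, 3L),
                    cbind(mesh$sets$midplane_edge, 3L)),
    load = list(nodes = mesh$sets$load, dir = 3L,
                p = function(t) 2 * pmax(0, 1 - abs(t - 5) / 5)),
    probes = c(center = mesh$sets$load[1]))
  cfg <- solver_config(dt = 1, t_end = 20)
  r1 <- run_simulation(mesh, mat_tii, electro_params(G_s = 0), ac, protocol, cfg)
  r2 <- run_simulation(mesh, mat_tii, electro_params(G_s = 0, mef_on = FALSE),
                       ac, protocol, cfg)
  expect_equal(r1$probes$Phi, r2$probes$Phi, tolerance = 1e-12)
  expect_equal(r1$probes$u, r2$probes$u, tolerance = 1e-12)
})

test_that("a quiescent unloaded run stays exactly at rest", {
  mesh <- make_cube(1, 1)
  protocol <- list(
    fixed_u = rbind(cbind(mesh$sets$pin_xyz, 1L), cbind(mesh$sets$pin_xyz, 2L),
                    cbind(mesh$sets$pin_xyz, 3L), cbind(mesh$sets$pin_yz, 2L),
                    cbind(mesh$sets$pin_yz, 3L), cbind(mesh$sets$pin_z, 3L)),
    probes = c(corner = 7L))
  run <- run_simulation(mesh, mat_tii, el_g, ac, protocol,
                        solver_config(dt = 5, t_end = 50))
  expect_true(all(abs(run$probes$Phi + 80) < 1e-9))
  expect_true(all(run$probes$u < 1e-9))
  expect_true(all(run$summary$psi < 1e-12))
  expect_true(all(run$summary$iters == 0))
})

test_that("travelling front speed is consistent under dt and mesh refinement", {
  # thin fiber-direction strip driven by an end stimulus: compare the time
  # at which the far-end potential crosses 0 mV
  strip <- function(nx, dt) {
    mesh <- make_plate(c(8, 0.5, 0.5), c(nx, 1, 1))
    left <- which(mesh$nodes[, 1] < 1e-9)
    endn <- which(mesh$nodes[, 1] > 8 - 1e-9)[1]
    protocol <- list(
      fixed_u = cbind(rep(seq_len(nrow(mesh$nodes)), each = 3),
                      rep(1:3, nrow(mesh$nodes))), # rigid tissue: pure conduction
      stim = list(nodes = left, value = 20, t_on = 0, t_off = 10),
      probes = c(end = endn))
    run <- run_simulation(mesh, mat_tii, electro_params(d_iso = 0.1, d_ani = 0.3),
                          ac, protocol, solver_config(dt = dt, t_end = 60))
    p <- run$probes
    i <- which(p$Phi > 0)[1]
    # sub-step crossing time by linear interpolation
    p$t[i - 1] + (0 - p$Phi[i - 1]) / (p$Phi[i] - p$Phi[i - 1]) *
      (p$t[i] - p$t[i - 1])
  }
  t_base <- strip(16, 0.5)
  t_dt <- strip(16, 0.25)
  t_mesh <- strip(32, 0.5)
  expect_lt(abs(t_dt - t_base) / t_base, 0.02)
  expect_lt(abs(t_mesh - t_base) / t_base, 0.05)
})

test_that("convergence failure reports structured diagnostics", {
  mesh <- make_cube(1, 1)
  st <- rest_state(mesh)
  f_ext <- numeric(32)
  f_ext[4 * 6 + 3] <- 1e9 # absurd load on a free dof: must fail, not crash
  fixed <- c(4 * (mesh$sets$pin_xyz - 1) + 1:3,
             4 * (mesh$sets$pin_yz - 1) + 2:3,
             4 * (mesh$sets$pin_z - 1) + 3)
  sol <- newton_solve(mesh, st, material_params("HO"), electro_params(), ac,
                      0.5, fixed = fixed, f_ext = f_ext,
                      config = solver_config(max_iter = 5))
  expect_false(sol$converged)
  expect_true(length(sol$rnorms) >= 1)
})
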