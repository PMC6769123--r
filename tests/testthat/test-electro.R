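el <- electro_params()

test_that("dimensional conversion maps rest and reversal potentials", {
  expect_equal(to_physical(0, el), -80)
  expect_equal(to_physical(0.6, el), -20)
  expect_equal(to_physical(1, el), 20)
  set.seed(1)
  x <- runif(20, -0.5, 1.5)
  expect_equal(to_dimensionless(to_physical(x, el), el), x, tolerance = 1e-14)
})

test_that("excitation current has the cubic root structure", {
  expect_equal(f_e(0, 0, el), 0)
  expect_equal(f_e(el$alpha, 0, el), 0)
  expect_equal(f_e(1, 0, el), 0)
  # sub-threshold potentials decay
  for (phi in seq(1e-3, el$alpha - 1e-3, length.out = 5))
    expect_lt(f_e(phi, 0, el), 0)
  # supra-threshold potentials grow
  expect_gt(f_e(0.3, 0, el), 0)
  # recovery current is repolarizing
  expect_lt(f_e(0.3, 2, el), f_e(0.3, 0, el))
})

test_that("rest is a stationary point of the recovery kinetics", {
  expect_equal(recovery_rhs(0, 0, el), 0)
  up <- recovery_update(0, 0, 0.1, el)
  expect_equal(up$r, 0)
})

test_that("implicit recovery update is consistent with its sensitivity", {
  set.seed(2)
  for (i in 1:10) {
    phi <- runif(1, 0, 1)
    rn <- runif(1, 0, 2)
    dtb <- 0.08
    up <- recovery_update(phi, rn, dtb, el)
    # implicit relation holds
    expect_equal(up$r, rn + dtb * recovery_rhs(phi, up$r, el),
                 tolerance = 1e-12)
    h <- 1e-6
    rp <- recovery_update(phi + h, rn, dtb, el)$r
    rm <- recovery_update(phi - h, rn, dtb, el)$r
    expect_equal(up$dr_dphi, (rp - rm) / (2 * h), tolerance = 1e-5)
  }
})

test_that("single-cell action potential matches a high-accuracy ODE reference", {
  skip_if_not_installed("deSolve")
  ac <- active_params()
  dt <- 0.05
  tr <- cell_trace(el, ac, dt = dt, t_end = 500, I_stim = 1,
                   stim_window = c(0, 2))
  rhs <- function(t, y, p) {
    I <- if (t < 2 / el$k_t) 1 else 0
    dphi <- el$c * y[1] * (y[1] - el$alpha) * (1 - y[1]) - y[2] * y[1] + I
    dr <- (el$gamma + el$mu1 * y[2] / (el$mu2 + y[1])) *
      (-y[2] - el$c * y[1] * (y[1] - el$b_rec - 1))
    list(c(dphi, dr))
  }
  times <- seq(0, 500 / el$k_t, by = dt / el$k_t)
  ref <- deSolve::ode(c(phi = 0, r = 0), times, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(nrow(ref), nrow(tr))
  expect_lt(max(abs(tr$phi - ref[, "phi"])), 1e-3)
  expect_lt(max(abs(tr$r - ref[, "r"])), 1e-3)
  # a full excursion that returns to rest within the cycle
  expect_gt(max(tr$Phi), 15)
  expect_lt(abs(tr$Phi[nrow(tr)] + 80), 1)
})

test_that("sub-threshold initial potentials decay monotonically without an AP", {
  tr <- cell_trace(el, active_params(), phi0 = 0.005, dt = 0.05, t_end = 100)
  expect_true(all(diff(tr$phi) <= 0))
  expect_lt(max(tr$Phi), -79)
})

test_that("conductivity reduces to the reference-state formula", {
  f0 <- c(1, 0, 0)
  D <- conductivity(diag(3), f0, el)
  expect_equal(D, el$d_iso * diag(3) + el$d_ani * tcrossprod(f0),
               tolerance = 1e-14)
  el0 <- electro_params(d_ani = 0)
  set.seed(3)
  F <- rand_F()
  C <- t(F) %*% F
  expect_equal(conductivity(F, f0, el0), det(F) * el0$d_iso * solve(C),
               tolerance = 1e-12)
})

test_that("deformed conductivity stays positive definite and matches the formula", {
  set.seed(4)
  f0 <- c(1, 0, 0)
  for (i in 1:20) {
    F <- rand_F(0.15)
    D <- conductivity(F, f0, el)
    expect_true(all(eigen(D, symmetric = TRUE)$values > 0))
    C <- t(F) %*% F
    I4f <- drop(t(f0) %*% C %*% f0)
    Dref <- det(F) * (el$d_iso * solve(C) + el$d_ani * tcrossprod(f0) / I4f)
    expect_equal(D, Dref, tolerance = 1e-12)
  }
})

test_that("electrical flux is linear and anisotropic along the fiber", {
  f0 <- c(1, 0, 0)
  expect_equal(flux(diag(3), f0, c(0, 0, 0), el), c(0, 0, 0))
  g <- c(2, 0, 0)
  expect_equal(sqrt(sum(flux(diag(3), f0, g, el)^2)),
               (el$d_iso + el$d_ani) * 2, tolerance = 1e-14)
  set.seed(5)
  F <- rand_F()
  g1 <- rnorm(3); g2 <- rnorm(3)
  expect_equal(flux(F, f0, g1 + 2 * g2, el),
               flux(F, f0, g1, el) + 2 * flux(F, f0, g2, el),
               tolerance = 1e-12)
})

test_that("stretch-activated current switches on tension and depolarizes", {
  elg <- electro_params(G_s = 10)
  expect_equal(f_m(1, 0, elg), 0)
  expect_equal(f_m(0.95, 0, elg), 0)
  expect_equal(f_m(1.1, 0, elg), 0.6, tolerance = 1e-14)
  # disabled channel
  expect_equal(f_m(1.3, 0, electro_params(G_s = 0)), 0)
  # depolarizing whenever stretched below the reversal potential
  set.seed(6)
  for (i in 1:20) {
    lam <- runif(1, 1.0001, 1.3)
    phi <- runif(1, 0, elg$phi_s - 1e-3)
    expect_gt(f_m(lam, phi, elg), 0)
  }
})
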