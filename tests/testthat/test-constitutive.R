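fr <- frame_xyz()
f0 <- fr$f0
s0 <- fr$s0
models <- c("TIC", "TII", "HO")

test_that("kinematics reproduces reference and isochoric uniaxial states", {
  k <- kinematics(diag(3), f0, s0)
  expect_equal(k$I1, 3)
  expect_equal(k$J, 1)
  expect_equal(k$I4f, 1)
  expect_equal(k$lambda, 1)

  Fu <- diag(c(1.2, 1 / sqrt(1.2), 1 / sqrt(1.2)))
  k2 <- kinematics(Fu, f0, s0)
  expect_equal(k2$J, 1, tolerance = 1e-14)
  expect_equal(k2$I4f, 1.44, tolerance = 1e-14)
  expect_equal(k2$lambda, 1.2, tolerance = 1e-14)
})

test_that("isochoric invariants equal full invariants of the unimodular part", {
  set.seed(11)
  for (i in 1:20) {
    F <- rand_F(0.15)
    k <- kinematics(F, f0, s0)
    Fbar <- det(F)^(-1 / 3) * F
    kb <- kinematics(Fbar, f0, s0)
    expect_equal(k$Ib1, kb$I1, tolerance = 1e-12)
    expect_equal(k$Ib4f, kb$I4f, tolerance = 1e-12)
    expect_equal(k$Ib4s, kb$I4s, tolerance = 1e-12)
    expect_equal(k$Ib8fs, kb$I8fs, tolerance = 1e-12)
  }
})

test_that("degenerate deformation gradients are rejected", {
  expect_error(kinematics(diag(c(1, 1, 0)), f0, s0), "det")
  expect_error(kinematics(diag(c(-1, 1, 1)), f0, s0), "det")
  expect_error(kinematics(diag(3), c(1, 0, 0), c(1, 0, 0)), "orthogonal")
})

test_that("energies match independent literal transcriptions", {
  set.seed(21)
  tic <- material_params("TIC")
  tii <- material_params("TII")
  ho <- material_params("HO")
  for (i in 1:25) {
    F <- rand_F()
    expect_equal(psi_passive(F, f0, s0, tic), psi_tic_oracle(F, f0, tic),
                 tolerance = 1e-12)
    expect_equal(psi_passive(F, f0, s0, tii), psi_tii_oracle(F, f0, tii),
                 tolerance = 1e-12)
    expect_equal(psi_passive(F, f0, s0, ho), psi_ho_oracle(F, f0, s0, ho),
                 tolerance = 1e-12)
  }
})

test_that("reference configuration is stress free for all models", {
  for (m in models) {
    S <- pk2_passive(diag(3), f0, s0, material_params(m))
    expect_lt(max(abs(S)), 1e-10)
  }
  # HO keeps its constant energy offset but the deviatoric projection
  # removes it from the stress
  expect_gt(psi_passive(diag(3), f0, s0, material_params("HO")), 0)
})

test_that("analytic stress matches finite differences of the energy", {
  set.seed(31)
  for (m in models) {
    mat <- material_params(m)
    worst <- 0
    for (i in 1:100) {
      F <- rand_F()
      S <- pk2_passive(F, f0, s0, mat)
      Sfd <- fd_pk2(F, f0, s0, mat)
      worst <- max(worst, max(abs(S - Sfd)) / max(abs(S)))
    }
    expect_lt(worst, 1e-6)
  }
})

test_that("consistent tangent matches finite differences of the stress", {
  set.seed(41)
  for (m in models) {
    mat <- material_params(m)
    worst <- 0
    for (i in 1:100) {
      F <- rand_F()
      CC <- tangent_passive(F, f0, s0, mat)
      CCfd <- fd_tangent(F, f0, s0, mat)
      worst <- max(worst, max(abs(CC - CCfd)) / max(abs(CC)))
    }
    expect_lt(worst, 1e-5)
  }
})

test_that("tangent has minor symmetries and the TIC small-strain limit", {
  set.seed(51)
  for (m in models) {
    CC <- tangent_passive(rand_F(), f0, s0, material_params(m))
    expect_equal(CC, aperm(CC, c(2, 1, 3, 4)))
    expect_equal(CC, aperm(CC, c(1, 2, 4, 3)))
    expect_equal(CC, aperm(CC, c(3, 4, 1, 2)), tolerance = 1e-12)
  }
  # at the reference state the TIC tangent (fiber switch off at lambda = 1)
  # is the isotropic linear elasticity tensor built from the Lame constants
  p <- material_params("TIC")
  CC <- tangent_passive(diag(3), f0, s0, p)
  iso <- array(0, c(3, 3, 3, 3))
  d <- diag(3)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    iso[i, j, k, l] <- p$Lambda * d[i, j] * d[k, l] +
      p$mu * (d[i, k] * d[j, l] + d[i, l] * d[j, k])
  expect_equal(CC, iso, tolerance = 1e-12)
})

test_that("energy is frame indifferent", {
  set.seed(61)
  for (m in models) {
    mat <- material_params(m)
    for (i in 1:20) {
      F <- rand_F()
      Q <- rand_rotation()
      expect_equal(psi_passive(Q %*% F, f0, s0, mat),
                   psi_passive(F, f0, s0, mat), tolerance = 1e-12)
    }
  }
})

test_that("fiber terms switch off exactly under fiber compression", {
  Fc <- diag(c(0.9, 1 / sqrt(0.9), 1 / sqrt(0.9))) # isochoric fiber shortening
  tic <- material_params("TIC")
  tic0 <- material_params("TIC", eta = 1e6) # eta must not matter when off
  expect_equal(psi_passive(Fc, f0, s0, tic), psi_passive(Fc, f0, s0, tic0))
  expect_equal(pk2_passive(Fc, f0, s0, tic), pk2_passive(Fc, f0, s0, tic0))
  tii <- material_params("TII")
  tii0 <- material_params("TII", eta = 1e6)
  expect_equal(psi_passive(Fc, f0, s0, tii), psi_passive(Fc, f0, s0, tii0))
  ho <- material_params("HO")
  ho0 <- material_params("HO", a_f = 1e6)
  expect_equal(pk2_passive(Fc, f0, s0, ho), pk2_passive(Fc, f0, s0, ho0))
})

test_that("orthogonal shear leaves the HO fiber-sheet term silent", {
  # shear in the sheet-normal plane: I8fs stays zero
  g <- 0.3
  F <- diag(3)
  F[2, 3] <- g # s-n shear
  k <- kinematics(F, f0, s0)
  expect_equal(k$Ib8fs, 0)
  ho <- material_params("HO")
  ho2 <- material_params("HO", a_fs = 1e6)
  expect_equal(psi_passive(F, f0, s0, ho), psi_passive(F, f0, s0, ho2))
})

test_that("HO exponent overflow raises an explicit error", {
  F <- diag(c(8, 1 / sqrt(8), 1 / sqrt(8))) # extreme isochoric fiber stretch
  expect_error(psi_passive(F, f0, s0, material_params("HO")), "cap")
})

test_that("HO simple shear stress is strictly increasing in all six modes", {
  ee <- list(f = c(1, 0, 0), s = c(0, 1, 0), n = c(0, 0, 1))
  modes <- list(c("f", "s"), c("f", "n"), c("s", "f"),
                c("s", "n"), c("n", "f"), c("n", "s"))
  ho <- material_params("HO")
  gam <- seq(0.02, 0.5, by = 0.02)
  idx <- c(f = 1, s = 2, n = 3)
  for (mode in modes) {
    sig <- vapply(gam, function(g) {
      F <- diag(3) + g * (ee[[mode[2]]] %o% ee[[mode[1]]])
      S <- pk2_passive(F, ee$f, ee$s, ho)
      sg <- F %*% S %*% t(F) / det(F)
      sg[idx[mode[2]], idx[mode[1]]]
    }, numeric(1))
    expect_true(all(diff(sig) > 0))
  }
})

test_that("active stress is a rank-one fiber tension with self-limiting push-forward", {
  expect_equal(pk2_active(0, rand_F(), f0), matrix(0, 3, 3))
  expect_equal(pk2_active(10, diag(3), f0), 10 * tcrossprod(f0))
  set.seed(71)
  for (i in 1:10) {
    F <- rand_F()
    Tact <- runif(1, 1, 50)
    S <- pk2_active(Tact, F, f0)
    sig <- F %*% S %*% t(F) / det(F)
    fdef <- F %*% f0
    I4f <- sum(fdef^2)
    fdef <- fdef / sqrt(I4f)
    # the deformed fiber is the only eigendirection; its Cauchy eigenvalue
    # scales with I4f / J, so the tension falls off under fiber shortening
    ev <- eigen(sig, symmetric = TRUE)$values
    expect_equal(max(abs(ev)), Tact * I4f / det(F), tolerance = 1e-12)
    expect_equal(drop(t(fdef) %*% sig %*% fdef), Tact * I4f / det(F),
                 tolerance = 1e-12)
  }
})
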