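# shared oracles and fixtures, all generated in code

frame_xyz <- function() list(f0 = c(1, 0, 0), s0 = c(0, 1, 0))

# random admissible deformation gradient (moderate strain, det > 0)
rand_F <- function(amp = 0.08) {
  repeat {
    F <- diag(3) + amp * matrix(stats::rnorm(9), 3, 3)
    if (det(F) > 0.5) return(F)
  }
}

rand_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# symmetric square root of C, for energy-in-C oracles
F_of_C <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors)
}

# central finite differences of the strain energy wrt C: S = 2 dPsi/dC
fd_pk2 <- function(F, f0, s0, mat, h = 1e-6) {
  C0 <- t(F) %*% F
  psiC <- function(C) psi_passive(F_of_C(C), f0, s0, mat)
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    dC <- matrix(0, 3, 3)
    dC[i, j] <- dC[j, i] <- h
    S[i, j] <- (psiC(C0 + dC) - psiC(C0 - dC)) / (2 * h) *
      (if (i == j) 1 else 0.5)
  }
  2 * S
}

# central finite differences of the stress wrt C: 2 dS/dC
fd_tangent <- function(F, f0, s0, mat, h = 1e-5) {
  C0 <- t(F) %*% F
  SC <- function(C) pk2_passive(F_of_C(C), f0, s0, mat)
  CC <- array(0, c(3, 3, 3, 3))
  for (k in 1:3) for (l in 1:3) {
    dC <- matrix(0, 3, 3)
    dC[k, l] <- dC[l, k] <- h
    CC[, , k, l] <- 2 * (SC(C0 + dC) - SC(C0 - dC)) / (2 * h) *
      (if (k == l) 1 else 0.5)
  }
  CC
}

# independent literal transcriptions of the three energies
psi_tic_oracle <- function(F, f0, p) {
  C <- t(F) %*% F
  J <- det(F)
  I1 <- sum(diag(C))
  I4f <- drop(t(f0) %*% C %*% f0)
  th <- as.numeric(sqrt(I4f) > 1)
  p$Lambda / 2 * log(J)^2 + p$mu / 2 * (I1 - 3 - 2 * log(J)) +
    th * p$eta / 2 * (I4f - 1)^2
}

psi_tii_oracle <- function(F, f0, p) {
  C <- t(F) %*% F
  J <- det(F)
  Cb <- J^(-2 / 3) * C
  Ib1 <- sum(diag(Cb))
  Ib4f <- drop(t(f0) %*% Cb %*% f0)
  th <- as.numeric(sqrt(Ib4f) > 1)
  p$mu / 2 * (Ib1 - 3) + th * p$eta / 2 * (Ib4f - 1)^2 + p$kappa * (J - 1)^2
}

psi_ho_oracle <- function(F, f0, s0, p) {
  C <- t(F) %*% F
  J <- det(F)
  Cb <- J^(-2 / 3) * C
  Ib1 <- sum(diag(Cb))
  Ib4f <- drop(t(f0) %*% Cb %*% f0)
  Ib4s <- drop(t(s0) %*% Cb %*% s0)
  Ib8 <- drop(t(f0) %*% Cb %*% s0)
  val <- p$a / (2 * p$b) * exp(p$b * (Ib1 - 3)) +
    p$a_fs / (2 * p$b_fs) * (exp(p$b_fs * Ib8^2) - 1) +
    p$kappa * (J - 1)^2
  if (Ib4f > 1) val <- val + p$a_f / (2 * p$b_f) * (exp(p$b_f * (Ib4f - 1)^2) - 1)
  if (Ib4s > 1) val <- val + p$a_s / (2 * p$b_s) * (exp(p$b_s * (Ib4s - 1)^2) - 1)
  val
}

# memoised expensive runs shared between experiment and acceptance tests
.run_cache <- new.env(parent = emptyenv())

get_small_plate_run <- function() {
  if (is.null(.run_cache$plate))
    .run_cache$plate <- run_plate_benchmark("small")
  .run_cache$plate
}

get_lv_sweep <- function() {
  if (is.null(.run_cache$lv)) {
    mesh <- make_lv(lv_spec(target_size = 1.25))
    .run_cache$lv <- list(
      tic = run_lv_sweep("TIC", c(0, 50), mesh = mesh),
      tii = run_lv_sweep("TII", c(0, 10, 50), mesh = mesh),
      ho  = run_lv_sweep("HO", c(0, 10, 50), mesh = mesh))
  }
  .run_cache$lv
}

get_cube_runs <- function() {
  if (is.null(.run_cache$cube))
    .run_cache$cube <- lapply(
      stats::setNames(c("TIC", "TII", "HO"), c("TIC", "TII", "HO")),
      function(m) run_cube_isotonic(m))
  .run_cache$cube
}
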