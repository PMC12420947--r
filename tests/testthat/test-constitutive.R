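# Material laws: kinematics, tube-law pore pressure, stress, pull-back.
# The normative contract is thermodynamic consistency: every closed-form
# pressure/stress equals the finite-difference derivative of its energy.

central_fd <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)

test_that("kinematics from the displacement gradient", {
  k0 <- kinematics_from_grad(matrix(0, 3, 3))
  expect_equal(k0$F, diag(3))
  expect_equal(k0$J, 1)
  expect_equal(k0$I1_bar, 3)

  k1 <- kinematics_from_grad(diag(c(1, 0, 0)))  # F = diag(2,1,1)
  expect_equal(k1$J, 2)
  expect_equal(k1$I1_bar, 2^(-2 / 3) * 6, tolerance = 1e-12)

  set.seed(1)
  for (i in 1:20) {
    gu <- matrix(0.3 * rnorm(9), 3, 3)
    kin <- tryCatch(kinematics_from_grad(gu), error = function(e) NULL)
    if (is.null(kin)) next
    expect_equal(det(kin$C_bar), 1, tolerance = 1e-12)
  }
  expect_error(kinematics_from_grad(diag(c(-2, 0, 0))), "Jacobian")
})

test_that("tube-law pressures are exact derivatives of their energies", {
  pm <- material_params()   # coronary tube-law constants
  expect_equal(pore_fluid_pressure(0, 0.01, pm)$p_PV, 0)        # reference
  # p_c at v = phi_crit equals c / eps
  m_at_crit <- pm$phi_crit - 0.01
  expect_equal(pore_fluid_pressure(m_at_crit, 0.01, pm)$p_c,
               pm$c_pen / pm$eps, tolerance = 1e-9)

  # FD consistency on 100 random states (including mild suction)
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    phi0 <- 10^runif(1, -3, -1.3)
    m <- runif(1, -0.5 * phi0, 5 * phi0)
    pp <- pore_fluid_pressure(m, phi0, pm)
    h <- 1e-6 * max(abs(m), phi0)
    fd_pv <- central_fd(function(x) poroperf:::pore_energy_pv(x, phi0, pm), m, h)
    fd_c <- central_fd(function(x) poroperf:::pore_energy_c(x, phi0, pm), m, h)
    worst <- max(worst,
                 abs(fd_pv - pp$p_PV) / max(abs(fd_pv), 1),
                 abs(fd_c - pp$p_c) / max(abs(fd_c), 1))
    # dp_dm consistency with the pressure itself
    fd_dp <- central_fd(function(x) {
      q <- pore_fluid_pressure(x, phi0, pm); q$p_PV + q$p_c
    }, m, h)
    worst <- max(worst, abs(fd_dp - pp$dp_dm) / max(abs(fd_dp), 1))
  }
  expect_lt(worst, 1e-6)

  # representative perfusion state
  pp <- pore_fluid_pressure(0.001, 0.01, pm)
  fd <- central_fd(function(x) poroperf:::pore_energy_pv(x, 0.01, pm),
                   0.001, 1e-9)
  expect_equal(pp$p_PV, fd, tolerance = 1e-6)
})

test_that("tube-law inversion recovers m over the full pressure range", {
  pm <- material_params()
  phi0 <- c(1e-3, 5e-3, 2e-2)
  for (ps in c(-2e5, -5e3, 0, 500, 9000, 2e4)) {
    m <- poroperf:::invert_tube_law(rep(ps, 3), phi0, pm)
    tr <- poroperf:::pore_pressure_terms(m, phi0, pm)
    expect_equal(tr$p_pv + tr$p_c, rep(ps, 3), tolerance = 1e-6 * max(abs(ps), 1))
  }
})

test_that("PK2 stress is the exact C-derivative of the free energy", {
  pm <- material_params()
  G <- pm$G
  expect_equal(pk2_stress(kinematics_from_grad(matrix(0, 3, 3)), 0, G),
               matrix(0, 3, 3), tolerance = 1e-14)
  expect_equal(pk2_stress(kinematics_from_grad(matrix(0, 3, 3)), 500, G),
               -500 * diag(3), tolerance = 1e-12)

  # FD of W(C) = G/2 (I1_bar - 3) - p (J - 1): S = 2 dPsi/dC
  energy_of_C <- function(C, p, G) {
    J <- sqrt(det(C))
    G / 2 * (J^(-2 / 3) * sum(diag(C)) - 3) - p * (J - 1)
  }
  set.seed(11)
  worst <- 0
  for (i in 1:30) {
    repeat {
      gu <- matrix(0.15 * rnorm(9), 3, 3)
      F <- diag(3) + gu
      if (det(F) > 0.8 && det(F) < 1.2) break
    }
    kin <- kinematics_from_grad(gu)
    p <- 1000 * rnorm(1)
    S <- pk2_stress(kin, p, G)
    # dPsi(H) = 1/2 S : H for symmetric directions. With H built by adding
    # h/2 to entries (a,b) and (b,a) (the diagonal gets h in total), the
    # central difference divided by h equals S_ab in both cases.
    S_fd <- matrix(0, 3, 3)
    h <- 1e-6
    for (a in 1:3) for (b in 1:3) {
      dC <- matrix(0, 3, 3)
      dC[a, b] <- dC[a, b] + h / 2
      dC[b, a] <- dC[b, a] + h / 2
      S_fd[a, b] <- (energy_of_C(kin$C + dC, p, G) -
                     energy_of_C(kin$C - dC, p, G)) / h
    }
    worst <- max(worst, max(abs(S - S_fd)) / max(abs(S_fd)))
  }
  expect_lt(worst, 1e-5)

  # objectivity: S(RF) = S(F) for rotations R
  set.seed(2)
  gu <- matrix(0.1 * rnorm(9), 3, 3)
  kin <- kinematics_from_grad(gu)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- 0.7
  Kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
  kinR <- kinematics_from_grad(R %*% kin$F - diag(3))
  expect_equal(pk2_stress(kinR, 321, pm$G), pk2_stress(kin, 321, pm$G),
               tolerance = 1e-9)
})

test_that("permeability pull-back: identity, rotation, stretch, PSD", {
  K0 <- diag(c(3, 2, 1))
  kin_id <- kinematics_from_grad(matrix(0, 3, 3))
  pb <- pull_back_permeability(K0, kin_id, dp_dm = 7)
  expect_equal(pb$K00, K0)
  expect_equal(pb$K0m, 7 * K0)

  # rotation: K00 = R^T K0 R, eigenvalues preserved
  th <- 0.5
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  kin_R <- kinematics_from_grad(R - diag(3))
  pbR <- pull_back_permeability(K0, kin_R)
  expect_equal(pbR$K00, t(R) %*% K0 %*% R, tolerance = 1e-12)
  expect_equal(sort(eigen(pbR$K00)$values), c(1, 2, 3), tolerance = 1e-12)

  # isotropic K0 under uniaxial stretch: k diag(1/lambda, lambda, lambda)
  lam <- 1.3
  kin_S <- kinematics_from_grad(diag(c(lam - 1, 0, 0)))
  pbS <- pull_back_permeability(2 * diag(3), kin_S)
  expect_equal(pbS$K00, 2 * diag(c(1 / lam, lam, lam)), tolerance = 1e-12)

  # symmetry exact, PSD to 1e-12, for random F and random PSD K0
  set.seed(5)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3, 3); K0r <- A %*% t(A)
    gu <- matrix(0.2 * rnorm(9), 3, 3)
    kin <- tryCatch(kinematics_from_grad(gu), error = function(e) NULL)
    if (is.null(kin)) next
    pb <- pull_back_permeability(K0r, kin)
    expect_identical(pb$K00, t(pb$K00))
    expect_gt(min(eigen(pb$K00, symmetric = TRUE)$values), -1e-12)
  }
})
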