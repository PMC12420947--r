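# Tetrahedral meshes and the coupled stabilized P1 discretization.

test_that("structured cube meshes have the documented counts and volumes", {
  m1 <- build_cube_mesh(1, 1)
  expect_equal(nrow(m1$tets), 6)
  expect_equal(sum(m1$vol), 1, tolerance = 1e-14)

  m4 <- build_cube_mesh(4, 1)
  expect_equal(nrow(m4$tets), 384)
  expect_equal(nrow(m4$nodes), 125)
  expect_true(all(m4$vol > 0))
  expect_equal(sum(m4$vol), 1, tolerance = 1e-12)

  # boundary faces of a closed cube surface: 2 triangles per square face
  # of each of the 6 n^2 surface cells... each cell face splits in 2
  expect_equal(nrow(m4$boundary_faces), 6 * 16 * 2)
  expect_error(build_cube_mesh(0), "n must be")
})

test_that("point location returns correct barycentric interpolants", {
  mesh <- build_cube_mesh(3, 2)
  set.seed(4)
  pts <- matrix(runif(30, 0.01, 1.99), 10, 3)
  loc <- locate_points(mesh, pts)
  expect_false(anyNA(loc$elem))
  # P1 interpolation of an affine function is exact
  f <- function(x) 2 + 3 * x[, 1] - x[, 2] + 0.5 * x[, 3]
  fn <- f(mesh$nodes)
  fi <- rowSums(matrix(fn[mesh$tets[loc$elem, ]], ncol = 4) * loc$lambda)
  expect_equal(fi, f(pts), tolerance = 1e-12)
  # outside points give NA
  out <- locate_points(mesh, matrix(c(-1, 0.5, 0.5), 1, 3))
  expect_true(is.na(out$elem[1]))
})

test_that("mesh VTK round-trips geometry", {
  mesh <- build_cube_mesh(2, 1)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_mesh_vtk(mesh, path, point_data = list(p = seq_len(nrow(mesh$nodes))))
  back <- read_mesh_vtk(path)
  expect_equal(back$nodes, mesh$nodes, tolerance = 1e-9)
  expect_equal(sum(back$vol), 1, tolerance = 1e-9)
})

test_that("residual vanishes at the stress-free reference with zero sources", {
  mesh <- build_cube_mesh(2, 10)
  fields <- synthetic_fields(mesh, nc = 3)
  fields$p1_bar[] <- 0
  fields$S_ext[] <- 0
  fields$beta[] <- 0
  params <- material_params()
  st0 <- poroperf:::zero_state(nrow(mesh$nodes), 3L)
  sys <- assemble_system(mesh, fields, st0, params, solver_config(),
                         want_jacobian = FALSE)
  expect_equal(max(abs(sys$res)), 0)

  # a constant skeleton-pressure offset leaves the mass equations at zero
  # (pure-Neumann null space of the Darcy operator when beta = 0)
  stp <- st0; stp$p <- rep(123, length(stp$p))
  sysp <- assemble_system(mesh, fields, stp, params, solver_config(),
                          want_jacobian = FALSE)
  NN <- nrow(mesh$nodes)
  mass_rows <- 4 * NN + seq_len(2 * NN)
  expect_lt(max(abs(sysp$res[mass_rows])), 1e-9)
})

test_that("analytic Jacobian matches finite differences of the residual", {
  mesh <- build_cube_mesh(2, 10)
  NN <- nrow(mesh$nodes)
  fields <- synthetic_fields(mesh, nc = 3)
  params <- material_params()
  cfg <- solver_config()
  set.seed(42)
  st <- list(u = matrix(rnorm(NN * 3, sd = 0.05), NN, 3),
             p = rnorm(NN, sd = 100),
             psi = matrix(2000 + rnorm(NN * 2, sd = 500), NN, 2))
  sys <- assemble_system(mesh, fields, st, params, cfg)
  x0 <- poroperf:::state_to_vec(st)
  resfun <- function(x) assemble_system(
    mesh, fields, poroperf:::vec_to_state(x, NN, 3L), params, cfg,
    want_jacobian = FALSE)$res
  idx <- sample(length(x0), 50)
  scale <- pmax(abs(x0), c(rep(0.01, 3 * NN), rep(10, NN), rep(10, 2 * NN)))
  worst <- 0
  for (k in idx) {
    h <- 1e-6 * scale[k]
    xp <- x0; xp[k] <- xp[k] + h
    xm <- x0; xm[k] <- xm[k] - h
    d_fd <- (resfun(xp) - resfun(xm)) / (2 * h)
    d_an <- as.numeric(sys$jac[, k])
    worst <- max(worst, max(abs(d_fd - d_an)) / max(max(abs(d_fd)), 1e-300))
  }
  expect_lt(worst, 1e-5)
})

test_that("coupled Newton: zero-source equilibrium, determinism, convergence", {
  mesh <- build_cube_mesh(3, 10)
  params <- material_params()
  fields <- synthetic_fields(mesh, nc = 2)

  # zero sources: the reference state solves the problem immediately
  # (c_pen = 0 removes the small reference offset of the porosity
  # penalization, which otherwise shifts the zero-load equilibrium)
  f0 <- fields
  f0$p1_bar[] <- 0; f0$S_ext[] <- 0
  f0$pbar_node[] <- 0; f0$pbar[] <- 0
  params0 <- material_params(c_pen = 0)
  sol0 <- newton_solve(mesh, f0, params0, solver_config())
  expect_equal(sol0$iterations, 0)
  expect_lt(max(abs(sol0$u)), 1e-12)

  # loaded problem converges and is bitwise reproducible
  sol1 <- suppressWarnings(newton_solve(mesh, fields, params, solver_config()))
  sol2 <- suppressWarnings(newton_solve(mesh, fields, params, solver_config()))
  expect_true(sol1$converged)
  expect_identical(sol1$u, sol2$u)
  expect_identical(sol1$psi, sol2$psi)
  expect_lt(sol1$res_rel, 0.02)

  # converged state: m is the exact tube-law inverse of psi (psi measures
  # the constitutive pressure relative to its reference value)
  phi_node <- pmax(fields$phi_node, params$phi0_min)
  tr <- poroperf:::pore_pressure_terms(sol1$m[, 1], phi_node[, 2], params)
  pc0 <- poroperf:::pc0_of(phi_node[, 2], params)
  expect_equal(tr$p_pv + tr$p_c - pc0, sol1$psi[, 1], tolerance = 1e-6)
})

test_that("an unanchored compartment raises an informative error", {
  mesh <- build_cube_mesh(2, 10)
  fields <- synthetic_fields(mesh, nc = 3)
  fields$beta[, ] <- 0
  params <- material_params()
  expect_error(newton_solve(mesh, fields, params, solver_config()),
               "no coupling chain")
})

test_that("steady global mass balance closes at the converged state", {
  mesh <- build_cube_mesh(3, 10)
  params <- material_params()
  fields <- synthetic_fields(mesh, nc = 2)
  # balance the sink against the coupling inflow scale is not required:
  # at steady state the compartment-wise integrals must close identically
  sol <- suppressWarnings(newton_solve(mesh, fields, params,
                                       solver_config(newton_tol = 1e-10)))
  # compartment 2 budget: int beta_12 (p1bar - p2pore) + int S_ext = 0
  loc <- list(elem = seq_len(nrow(mesh$tets)))
  pts <- mesh$centroid
  p2 <- interpolate_pore_pressure(sol, fields, mesh, pts,
                                  rep(2L, nrow(pts)), params)
  influx <- sum(fields$beta[, 1] * (fields$p1_bar - p2) * mesh$vol)
  sink <- sum(fields$S_ext * mesh$vol)
  scale <- sum(abs(fields$S_ext) * mesh$vol)
  expect_lt(abs(influx + sink) / scale, 5e-2)
})

test_that("MMS: the Darcy kernel is second-order accurate in L2", {
  # quick variant on coarse meshes; the acceptance suite runs {4, 8, 16}
  out <- darcy_mms_check(c(2, 4, 8), K = diag(3))
  expect_gt(out$order, 1.6)
  expect_true(all(diff(out$errors) < 0))

  # anisotropic diagonal permeability
  outa <- darcy_mms_check(c(2, 4, 8), K = diag(c(2, 1, 0.5)))
  expect_gt(outa$order, 1.6)
  expect_error(darcy_mms_check(c(2, 4)), "3 meshes")
})

test_that("pressure stabilization controls the checkerboard mode", {
  # coupled solve on a coarse mesh; compare the high-frequency content of
  # the skeleton pressure with and without stabilization
  mesh <- build_cube_mesh(3, 10)
  params <- material_params()
  fields <- synthetic_fields(mesh, nc = 2)
  checkerboard <- function(p) {
    # nodal oscillation norm: deviation from the mean of edge neighbours
    conn <- mesh$tets
    NN <- nrow(mesh$nodes)
    adj <- unique(rbind(conn[, c(1, 2)], conn[, c(1, 3)], conn[, c(1, 4)],
                        conn[, c(2, 3)], conn[, c(2, 4)], conn[, c(3, 4)]))
    nb_sum <- as.numeric(Matrix::sparseMatrix(
      i = c(adj[, 1], adj[, 2]), j = rep(1L, 2 * nrow(adj)),
      x = c(p[adj[, 2]], p[adj[, 1]]), dims = c(NN, 1)))
    nb_cnt <- as.numeric(Matrix::sparseMatrix(
      i = c(adj[, 1], adj[, 2]), j = rep(1L, 2 * nrow(adj)),
      x = rep(1, 2 * nrow(adj)), dims = c(NN, 1)))
    sqrt(mean((p - nb_sum / pmax(nb_cnt, 1))^2))
  }
  sol_stab <- suppressWarnings(newton_solve(mesh, fields, params,
                                            solver_config(alpha = 0.2)))
  sol_nost <- tryCatch(
    suppressWarnings(newton_solve(mesh, fields, params,
                                  solver_config(alpha = 0))),
    error = function(e) NULL)
  # either the unstabilized solve fails outright, or its pressure carries
  # more high-frequency oscillation than the stabilized one
  if (is.null(sol_nost)) {
    succeed("unstabilized equal-order solve failed, as expected")
  } else {
    expect_lt(checkerboard(sol_stab$p), checkerboard(sol_nost$p) + 1e-12)
  }
})
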