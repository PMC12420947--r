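# REV averaging: porosity, permeability models, coupling, boundary fields.

make_single_vessel <- function(r = 0.1, l = 1, dir = c(1, 0, 0),
                               origin = c(0, 0, 0)) {
  d <- dir / sqrt(sum(dir^2))
  vascular_network(data.frame(
    id = 1L, parent_id = -1L,
    x0 = origin[1], y0 = origin[2], z0 = origin[3],
    x1 = origin[1] + l * d[1], y1 = origin[2] + l * d[2],
    z1 = origin[3] + l * d[3], radius = r))
}

test_that("REV membership rules: midpoint vs clipped intersection length", {
  nw <- make_single_vessel(l = 10, origin = c(-5, 0, 0))  # centred at origin
  rev_m <- rev_spec(2, "midpoint")
  rev_c <- rev_spec(2, "clipped")

  # midpoint at origin: inside both spheres centred at origin
  mem_m <- rev_members(nw, c(0, 0, 0), rev_m, comp = 1L)
  expect_equal(mem_m[[1]]$effective_length, 10)
  mem_c <- rev_members(nw, c(0, 0, 0), rev_c, comp = 1L)
  expect_equal(mem_c[[1]]$effective_length, 4)  # chord of the 2 mm sphere

  # sphere centred beyond the segment end: midpoint outside -> excluded;
  # clipped includes the in-sphere part only
  mem_m2 <- rev_members(nw, c(4.5, 0, 0), rev_m, comp = 1L)
  expect_equal(nrow(mem_m2[[1]]), 0)
  mem_c2 <- rev_members(nw, c(4.5, 0, 0), rev_c, comp = 1L)
  expect_equal(mem_c2[[1]]$effective_length, 2.5)  # [2.5, 5] of the segment

  # empty sphere
  mem_e <- rev_members(nw, c(50, 50, 50), rev_m, comp = 1L)
  expect_equal(nrow(mem_e[[1]]), 0)
  expect_error(rev_spec(-1), "positive")
})

test_that("porosity field matches the closed form and is additive", {
  nw <- make_single_vessel(r = 0.1, l = 1, origin = c(-0.5, 0, 0))
  rev <- rev_spec(2)
  phi <- porosity_field(nw, comp = 1L, points = c(0, 0, 0), rev)
  expect_equal(phi[1, 1], pi * 0.01 * 1 / (4 / 3 * pi * 8), tolerance = 1e-12)

  # empty REV -> 0
  expect_equal(porosity_field(nw, 1L, c(30, 0, 0), rev)[1, 1], 0)

  # multi-compartment porosities sum to the single-compartment porosity
  cc <- make_fixture("cco200-seed1")
  z <- hierarchy_parameters(cc)
  comp <- assign_compartments(cc, partition_compartments(z, cc$segments$radius, 3))
  pts <- matrix(runif(30, 20, 80), 10, 3)
  phi3 <- porosity_field(cc, comp, pts, rev_spec(10))
  phi1 <- porosity_field(cc, rep(1L, nrow(cc$segments)), pts, rev_spec(10))
  expect_equal(rowSums(phi3), phi1[, 1], tolerance = 1e-12)
  expect_true(all(rowSums(phi3) < 1))
})

test_that("permeability models I-III match closed forms and identities", {
  mu <- 0.004
  V_R <- 4 / 3 * pi * 8
  nw <- make_single_vessel(r = 0.1, l = 1, origin = c(-0.5, 0, 0))
  kval <- pi * 0.1^4 * 1 / (8 * mu * V_R)   # = 2.929e-4

  KI <- permeability_field(nw, 1L, c(0, 0, 0), rev_spec(2), model = "I", mu = mu)
  expect_equal(KI[[1]][1, 1], kval, tolerance = 1e-9)   # e_x (x) e_x component
  expect_equal(KI[[1]][1, 5], 0)
  KII <- permeability_field(nw, 1L, c(0, 0, 0), rev_spec(2), model = "II", mu = mu)
  expect_equal(KII[[1]][1, c(1, 5, 9)], rep(kval, 3), tolerance = 1e-9)

  # three identical orthogonal vessels -> Model I isotropic
  tri <- vascular_network(data.frame(
    id = 1:3, parent_id = c(-1L, 1L, 2L),
    x0 = c(0, 1, 1), y0 = c(0, 0, 1), z0 = c(0, 0, 0),
    x1 = c(1, 1, 1), y1 = c(0, 1, 1), z1 = c(0, 0, 1),
    radius = 0.1), validate = TRUE)
  KT <- permeability_field(tri, rep(1L, 3), c(0.5, 0.5, 0.5), rev_spec(5),
                           model = "I", mu = mu)
  expect_equal(KT[[1]][1, 1], KT[[1]][1, 5], tolerance = 1e-12)
  expect_equal(KT[[1]][1, 5], KT[[1]][1, 9], tolerance = 1e-12)
  expect_equal(KT[[1]][1, c(2, 3, 4, 6, 7, 8)], rep(0, 6), tolerance = 1e-15)

  # trace identity: tr(Model I) = Model II scalar, at every point
  cc <- make_fixture("cco200-seed1")
  comp <- rep(1L, nrow(cc$segments))
  pts <- matrix(runif(15, 20, 80), 5, 3)
  K1 <- permeability_field(cc, comp, pts, rev_spec(8), model = "I", mu = mu)
  K2 <- permeability_field(cc, comp, pts, rev_spec(8), model = "II", mu = mu)
  expect_equal(K1[[1]][, 1] + K1[[1]][, 5] + K1[[1]][, 9], K2[[1]][, 1],
               tolerance = 1e-12)

  # Model III: homogeneous, spatially constant
  K3 <- permeability_field(cc, comp, pts, rev_spec(8), model = "III", mu = mu,
                           V_T = 1e6)
  expect_equal(K3[[1]][1, ], K3[[1]][5, ])
  expect_error(permeability_field(cc, comp, pts, rev_spec(8), model = "III"),
               "V_T")
})

test_that("permeability tensors are symmetric PSD; compartment-1 most anisotropic", {
  cc <- make_fixture("cco200-seed1")
  z <- hierarchy_parameters(cc)
  comp <- assign_compartments(cc, partition_compartments(z, cc$segments$radius, 2))
  pts <- matrix(runif(90, 10, 90), 30, 3)
  K <- permeability_field(cc, comp, pts, rev_spec(10), model = "I")
  aniso <- function(Krow) {
    M <- matrix(Krow, 3, 3)
    expect_equal(M, t(M), tolerance = 1e-14)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-14)
    if (max(ev) == 0) NA_real_ else max(ev) / max(min(ev), 1e-300)
  }
  a1 <- apply(K[[1]], 1, aniso)
  a2 <- apply(K[[2]], 1, aniso)
  # statistical claim: large-vessel compartment is more anisotropic
  expect_gt(median(a1, na.rm = TRUE), median(a2, na.rm = TRUE))
})

test_that("coupling constants match the hand formula with guarded degeneracies", {
  # junction between a compartment-1 parent and compartment-2 child
  nw <- vascular_network(data.frame(
    id = 1:2, parent_id = c(-1L, 1L),
    x0 = c(0, 2), y0 = 0, z0 = 0, x1 = c(2, 4), y1 = 0, z1 = 0,
    radius = c(1, 0.5)))
  bcs <- flow_bcs(100, 0)
  fl <- solve_poiseuille(nw, bcs)
  comp <- c(1L, 2L)
  rev <- rev_spec(2)            # sphere at (2,0,0) holds both midpoints
  beta <- coupling_field(nw, fl, comp, c(2, 0, 0), rev, model = "II")
  Q <- fl$q[2]
  dp <- fl$p_seg_mean[1] - fl$p_seg_mean[2]
  expect_equal(beta[1, 1], Q / (rev$volume * dp), tolerance = 1e-12)
  # spec worked example: beta = Q / (V_R dp)
  expect_equal(10 / (4 / 3 * pi * 8 * 2000), 1.4921e-4, tolerance = 1e-4)

  # zero pressure difference -> clamped to 0 with a warning
  fl0 <- fl
  fl0$p_seg_mean[] <- 5000
  expect_warning(b0 <- coupling_field(nw, fl0, comp, c(2, 0, 0), rev,
                                      model = "II"), "clamped")
  expect_equal(b0[1, 1], 0)

  # REV without the junction -> 0
  bfar <- coupling_field(nw, fl, comp, c(40, 0, 0), rev, model = "II")
  expect_equal(bfar[1, 1], 0)
})

test_that("boundary fields: volume-weighted mean pressure and terminal sink", {
  # two equal-volume compartment-1 vessels at different pressures
  nw <- vascular_network(data.frame(
    id = 1:3, parent_id = c(-1L, 1L, 1L),
    x0 = c(0, 0, 0), y0 = c(0, 0, 0), z0 = c(0, 1, 1),
    x1 = c(0, 1, -1), y1 = c(0, 0, 0), z1 = c(1, 1, 1),
    radius = c(0.2, 0.2, 0.2)))
  fl <- solve_poiseuille(nw, flow_bcs(100, 0))
  fl$p_seg_mean <- c(13332.2, 6666.1, 0)   # prescribe for the average test
  comp <- c(1L, 1L, 2L)
  bf <- boundary_fields(nw, fl, comp, c(0, 0, 1), rev_spec(2))
  expect_equal(bf$p1_bar[1], (13332.2 + 6666.1) / 2, tolerance = 1e-12)

  # one terminal with known flow inside the REV: sink = -Q_t / V_R
  one <- make_single_vessel(r = 0.3, l = 2, origin = c(-1, 0, 0))
  flo <- solve_poiseuille(one, flow_bcs(100, 0))
  bfo <- boundary_fields(one, flo, 1L, c(0, 0, 0), rev_spec(2))
  expect_equal(bfo$S_ext[1], -flo$q[1] / (4 / 3 * pi * 8), tolerance = 1e-12)
  # spec worked value: Q_t = 5, rR = 2 -> -0.1492 s^-1
  expect_equal(-5 / (4 / 3 * pi * 8), -0.1492, tolerance = 1e-3)

  # REV without terminals -> 0
  bff <- boundary_fields(one, flo, 1L, c(50, 0, 0), rev_spec(2))
  expect_equal(bff$S_ext[1], 0)
})

test_that("beta symmetry and global sink consistency on a CCO tree", {
  cc <- make_fixture("cco200-seed1")
  z <- hierarchy_parameters(cc)
  sc <- partition_compartments(z, cc$segments$radius, 2)
  fl <- solve_poiseuille(cc, flow_bcs(100, 0))
  mesh <- build_cube_mesh(6, 100)
  fields <- suppressWarnings(parameterize_porous_fields(
    cc, fl, sc, mesh, rev_spec(10), model = "II"))
  # beta_ki = beta_ik by construction (stored once per unordered pair)
  expect_true(all(fields$beta >= 0))
  # sum over elements of S_ext * V_e ~ -(inlet flow) within 10%
  total_sink <- sum(fields$S_ext * mesh$vol)
  expect_lt(abs(total_sink + fl$q_inlet) / fl$q_inlet, 0.1)
})
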