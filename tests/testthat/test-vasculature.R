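# Tree generation, hierarchy labelling, partitioning, blockage, I/O.

test_that("hierarchy parameter matches hand enumeration on small trees", {
  y <- make_fixture("y3")
  z <- hierarchy_parameters(y)
  expect_equal(z, c(0.5, 0, 0))   # root: 2/4; terminals: exactly 0

  # chain of n equal-length segments: k-th from root has zeta (n-k)/n
  n <- 6
  chain <- vascular_network(data.frame(
    id = 1:n, parent_id = c(-1L, 1:(n - 1)),
    x0 = 0, y0 = 0, z0 = 0:(n - 1), x1 = 0, y1 = 0, z1 = 1:n,
    radius = 1))
  expect_equal(hierarchy_parameters(chain), (n - 1:n) / n)
})

test_that("CCO trees satisfy their structural contracts", {
  nw <- generate_cco_tree(100, n_terminals = 200, inlet_radius = 3, seed = 7)
  seg <- nw$segments
  expect_equal(nrow(seg), 399)
  expect_equal(n_terminals(nw), 200)

  # all midpoints strictly inside the cube
  mids <- (as.matrix(seg[, c("x0", "y0", "z0")]) +
           as.matrix(seg[, c("x1", "y1", "z1")])) / 2
  expect_true(all(mids >= 0 & mids <= 100))

  # Murray's law at every bifurcation, gamma = 3
  pidx <- match(seg$parent_id, seg$id)
  kids <- split(which(!is.na(pidx)), pidx[!is.na(pidx)])
  murray_gap <- vapply(names(kids), function(p) {
    rp <- seg$radius[as.integer(p)]
    abs(rp^3 - sum(seg$radius[kids[[p]]]^3)) / rp^3
  }, numeric(1))
  expect_lt(max(murray_gap), 1e-6)

  # radii non-increasing root -> leaf
  expect_true(all(seg$radius[!is.na(pidx)] <= seg$radius[pidx[!is.na(pidx)]] + 1e-12))

  # determinism: identical seed => bitwise identical table
  nw2 <- generate_cco_tree(100, n_terminals = 200, inlet_radius = 3, seed = 7)
  expect_identical(nw$segments, nw2$segments)

  # zeta strictly decreasing along every root->leaf path
  z <- hierarchy_parameters(nw)
  expect_true(all(z[!is.na(pidx)] < z[pidx[!is.na(pidx)]]))
  # zeta_root >= 1 - l_root/l_T exactly (root feeds everything else)
  root <- which(seg$parent_id < 0)
  len <- sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2 + (seg$z1 - seg$z0)^2)
  expect_equal(z[root], 1 - len[root] / sum(len))
})

test_that("degenerate and invalid CCO inputs are handled", {
  one <- generate_cco_tree(100, n_terminals = 1, inlet_radius = 3, seed = 1)
  expect_equal(nrow(one$segments), 1)
  expect_equal(one$segments$radius, 3)
  expect_error(generate_cco_tree(100, 0, 3), "n_terminals")
  expect_error(generate_cco_tree(100, 5, -1), "radius")
  expect_error(generate_cco_tree(100, 5, 3, inlet_point = c(50, 50, 50)),
               "boundary")
})

test_that("greedy partition finds the separating split and refines monotonely", {
  # two well-separated radius levels around zeta = 0.5
  z <- c(0.9, 0.7, 0.6, 0.4, 0.3, 0.1)
  r <- c(1.0, 1.0, 1.0, 0.1, 0.1, 0.1)
  sc <- partition_compartments(z, r, nc = 2)
  expect_equal(sc$zeta_crit, c(1, 0.5, 0))   # midpoint between 0.4 and 0.6

  # constant radii: tie broken at the median zeta
  rc <- rep(1, 6)
  sct <- partition_compartments(z, rc, nc = 2)
  expect_equal(sct$zeta_crit[2], 0.5)

  # SSE never increases when nc grows; greedy >= DP optimum
  set.seed(3)
  zz <- runif(300)
  rr <- exp(-3 * zz) + 0.05 * rnorm(300)
  sse_by_nc <- vapply(2:5, function(nc) {
    sc <- partition_compartments(zz, rr, nc)
    comp <- assign_compartments(structure(list(), class = "vascular_network"),
                                sc, zeta = zz)
    sum(tapply(rr, comp, function(x) sum((x - mean(x))^2)))
  }, numeric(1))
  expect_true(all(diff(sse_by_nc) <= 1e-12))

  for (nc in 2:4) {
    sc <- partition_compartments(zz, rr, nc)
    comp <- assign_compartments(structure(list(), class = "vascular_network"),
                                sc, zeta = zz)
    sse_greedy <- sum(tapply(rr, comp, function(x) sum((x - mean(x))^2)))
    dp <- dp_partition_sse(zz, rr, nc)
    expect_gte(sse_greedy, dp$sse - 1e-9)
  }

  # on well-separated two-level data, greedy and DP recover the same split
  dp2 <- dp_partition_sse(z, r, 2)
  expect_equal(as.numeric(dp2$cut_zeta), 0.5)
})

test_that("compartment assignment follows the half-open interval convention", {
  sc <- structure(list(nc = 3L, zeta_crit = c(1, 0.6, 0.2, 0)),
                  class = "compartment_scheme")
  fake <- structure(list(), class = "vascular_network")
  z <- c(1, 0.6, 0.2, 0, 0.61, 0.19)
  comp <- assign_compartments(fake, sc, zeta = z)
  # top interval closed at 1; interior boundaries fall to the lower
  # (smaller-vessel) compartment; terminals to compartment nc
  expect_equal(comp, c(1L, 2L, 3L, 3L, 1L, 3L))
  # boundary values: 0.61 just above the cut stays in compartment 1
  expect_error(assign_compartments(fake, sc, zeta = c(0.5, 1.2)), "zeta")
})

test_that("blockage marks the whole distal subtree and keeps the rest connected", {
  b <- make_fixture("bin4")
  z <- hierarchy_parameters(b)
  term_id <- b$segments$id[which(z == 0)[1]]
  b1 <- apply_blockage(b, term_id)
  expect_equal(sum(b1$segments$blocked), 1)

  # blocking one child of the root in the symmetric tree blocks half
  root <- which(b$segments$parent_id < 0)
  child <- which(b$segments$parent_id == b$segments$id[root])[1]
  b2 <- apply_blockage(b, b$segments$id[child])
  expect_equal(sum(b2$segments$blocked), 7)   # (15 - 1) / 2

  # unblocked portion remains connected to the root
  fl <- solve_poiseuille(b2, flow_bcs(100, 0))
  live <- !b2$segments$blocked
  term <- poroperf:::network_is_terminal(b2) & live
  expect_equal(fl$q_inlet, sum(fl$q[term]), tolerance = 1e-12)
  expect_true(all(fl$q[!live] == 0))

  expect_error(apply_blockage(b, b$segments$id[root]), "root")
  expect_error(apply_blockage(b, 999L), "does not exist")
})

test_that("segment-table files round-trip and reject malformed input", {
  nw <- generate_cco_tree(100, n_terminals = 200, inlet_radius = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_network(nw, path)
  back <- read_network(path)
  expect_identical(back$segments$id, nw$segments$id)
  expect_identical(back$segments$parent_id, nw$segments$parent_id)
  expect_equal(back$segments$radius, nw$segments$radius, tolerance = 0)
  coords <- c("x0", "y0", "z0", "x1", "y1", "z1")
  expect_lt(max(abs(as.matrix(back$segments[coords]) -
                    as.matrix(nw$segments[coords]))), 1e-9)

  # orphan parent id -> structured error naming the row
  bad <- nw$segments
  bad$parent_id[5] <- 9999L
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_network(vascular_network(bad[1:4, ], validate = FALSE), path2)
  tab <- utils::read.csv(path2)
  tab <- rbind(tab, data.frame(id = 9000L, parent_id = 8999L,
                               x0 = 0, y0 = 0, z0 = 0, x1 = 1, y1 = 1, z1 = 1,
                               radius_mm = 1, blocked = FALSE))
  utils::write.csv(tab, path2, row.names = FALSE)
  expect_error(read_network(path2), "does not exist")

  # VTK polyline export writes a syntactically complete file
  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_network_vtk(make_fixture("y3"), vtk)
  lines <- readLines(vtk)
  expect_true(any(grepl("^POINTS 6", lines)))
  expect_true(any(grepl("^LINES 3", lines)))
})

test_that("fixtures regenerate deterministically with documented shapes", {
  y <- make_fixture("y3")
  expect_equal(sum(poroperf:::network_lengths(y)), 4)
  expect_equal(y$segments$radius, c(1, 2^(-1 / 3), 2^(-1 / 3)))
  b <- make_fixture("bin4")
  expect_equal(nrow(b$segments), 15)
  expect_equal(n_terminals(b), 8)
  c1 <- make_fixture("cco200-seed1")
  c2 <- make_fixture("cco200-seed1")
  expect_identical(c1$segments, c2$segments)
})
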