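# Validation against the discrete network: pore-pressure error, MBF
# fields, and the cube benchmark driver.

#' Continuum pore pressure at arbitrary points
#'
#' Evaluates `p_pore = p(X) + p_PV_i(X) + p_c_i(X)` by P1 interpolation of
#' the nodal skeleton pressure and the nodal constitutive pressure
#' `psi_i = p_PV_i + p_c_i` of the compartment each point belongs to. Points in compartment 1 return the prescribed
#' first-compartment pressure: the REV volume-weighted mean Poiseuille
#' pressure evaluated directly at the point when `nw`/`flow` are supplied,
#' otherwise the element value of `fields$p1_bar`.
#'
#' @param state a [newton_solve()] solution.
#' @param fields the [parameterize_porous_fields()] used for the solve.
#' @param mesh the mesh.
#' @param points M x 3 evaluation points, mm.
#' @param compartment integer vector (length M): compartment of each point.
#' @param params the [material_params()] used for the solve.
#' @param nw,flow optionally, the network and its flow solution, used to
#'   evaluate the compartment-1 prescribed pressure exactly at the points.
#' @return numeric vector of pore pressures, Pa; `NA` for points outside
#'   the mesh.
#' @export
interpolate_pore_pressure <- function(state, fields, mesh, points, compartment,
                                      params, nw = NULL, flow = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  loc <- locate_points(mesh, points)
  out <- rep(NA_real_, nrow(points))
  inside <- !is.na(loc$elem)
  solved <- which(compartment > 1L & inside)
  if (length(solved) > 0) {
    el <- loc$elem[solved]
    lam <- loc$lambda[solved, , drop = FALSE]
    conn <- mesh$tets[el, , drop = FALSE]
    pval <- rowSums(matrix(state$p[conn], ncol = 4) * lam)
    phi_node <- pmax(fields$phi_node, params$phi0_min)
    for (i in unique(compartment[solved])) {
      sel <- compartment[solved] == i
      nodal <- state$psi[, i - 1L] +
        pc0_of(phi_node[, i], params)
      psival <- rowSums(matrix(nodal[conn[sel, , drop = FALSE]],
                               ncol = 4) * lam[sel, , drop = FALSE])
      out[solved[sel]] <- pval[sel] + psival
    }
  }
  c1 <- which(compartment == 1L & inside)
  if (length(c1) > 0) {
    if (!is.null(nw) && !is.null(flow)) {
      comp <- fields$comp
      mem <- rev_membership(nw, points[c1, , drop = FALSE], fields$rev)
      pbar <- rev_mean_pressure(nw, flow, comp, mem, fields$nc, fields$rev,
                                fields$normalization)
      out[c1] <- pbar[, 1]
    } else {
      out[c1] <- fields$p1_bar[loc$elem[c1]]
    }
  }
  out
}

#' Normalized RMS pore-pressure error
#'
#' `Perr = sqrt( mean( ((p_pore - p_PL) / pin)^2 ) )` over vessel
#' segments: the pin-normalized root mean square discrepancy between the
#' continuum pore pressure at vessel midpoints and the mean discrete
#' Poiseuille pressure of each vessel. Dimensionless; invariant under a
#' global change of pressure units.
#'
#' @param p_pl discrete mean Poiseuille pressures per vessel, Pa.
#' @param p_pore continuum pore pressures at the vessel midpoints, Pa.
#' @param pin inlet pressure used for normalization, Pa.
#' @return scalar error.
#' @examples
#' pressure_error(c(10000, 5000), c(9000, 6000), 13332.2)  # 0.0750
#' @export
pressure_error <- function(p_pl, p_pore, pin) {
  keep <- !is.na(p_pore) & !is.na(p_pl)
  if (!any(keep)) stop("no vessels with valid pressures")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " vessel(s) outside the mesh excluded from Perr")
  sqrt(mean(((p_pore[keep] - p_pl[keep]) / pin)^2))
}

#' Compare continuum and network pore pressures vessel by vessel
#'
#' Evaluates the continuum pore pressure at the midpoint of every
#' unblocked vessel and the pin-normalized RMS error against the discrete
#' Poiseuille mean pressures.
#'
#' @inheritParams interpolate_pore_pressure
#' @param nw the network. @param flow its Poiseuille solution.
#' @param include_comp1 include compartment-1 vessels (whose continuum
#'   pressure is the prescribed field) in the error.
#' @return list with `Perr` and the per-vessel `table` (segment id,
#'   compartment, both pressures, normalized deviation).
#' @export
validate_solution <- function(nw, flow, state, fields, mesh, params,
                              include_comp1 = TRUE) {
  comp <- fields$comp
  live <- which(!nw$segments$blocked)
  if (!include_comp1) live <- live[comp[live] > 1L]
  mids <- network_midpoints(nw)[live, , drop = FALSE]
  p_pore <- interpolate_pore_pressure(state, fields, mesh, mids, comp[live],
                                      params, nw = nw, flow = flow)
  p_pl <- flow$p_seg_mean[live]
  pin <- flow$bcs$pin
  tab <- data.frame(
    id = nw$segments$id[live], compartment = comp[live],
    p_pl = p_pl, p_pore = p_pore,
    deviation = (p_pore - p_pl) / pin
  )
  list(Perr = pressure_error(p_pl, p_pore, pin), table = tab)
}

# REV junction-flow density (1/V_R) Q_{k,i} at the given points
junction_flow_field <- function(nw, flow, comp, points, rev, k, i) {
  points <- matrix(as.numeric(points), ncol = 3)
  npts <- nrow(points)
  jun <- network_junctions(nw, comp)
  sel <- which((jun$k == k & jun$i == i) | (jun$k == i & jun$i == k))
  if (length(sel) == 0) return(numeric(npts))
  mem <- rev_membership(nw, points, rev)
  if (length(mem$ipt) == 0) return(numeric(npts))
  B <- Matrix::sparseMatrix(i = mem$ipt, j = mem$iseg, x = 1,
                            dims = c(npts, nrow(nw$segments)))
  both <- B[, jun$parent[sel], drop = FALSE] * B[, jun$child[sel], drop = FALSE]
  as.numeric(both %*% flow$q[jun$child[sel]]) / rev$volume
}

#' Myocardial blood flow fields from the continuum and the network
#'
#' The continuum estimate is the volumetric flow density into the last
#' compartment, `MBF_D = beta_{nc-1,nc} (p_{nc-1}^pore - p_nc^pore)`
#' (s^-1), evaluated at element centroids; the discrete reference is
#' `MBF_PL = Q_{nc-1,nc} / V_R`, the REV-averaged Poiseuille junction
#' flow into the last compartment. `MBF_err` is the element-wise relative
#' error with a denominator floor.
#'
#' @param state a converged [newton_solve()] solution.
#' @param fields the porous fields used for the solve.
#' @param mesh the mesh.
#' @param params the material parameters.
#' @param nw,flow network and Poiseuille solution.
#' @param floor denominator floor for the relative error, s^-1.
#' @return data frame with `MBF_D`, `MBF_PL`, `MBF_err` per element.
#' @export
mbf_fields <- function(state, fields, mesh, params, nw, flow, floor = 1e-12) {
  nc <- fields$nc
  comp <- fields$comp
  pts <- mesh$centroid
  p_hi <- interpolate_pore_pressure(state, fields, mesh, pts,
                                    rep(nc - 1L, nrow(pts)), params,
                                    nw = if (nc - 1L == 1L) nw else NULL,
                                    flow = if (nc - 1L == 1L) flow else NULL)
  if (nc - 1L == 1L) p_hi[is.na(p_hi)] <- fields$p1_bar[is.na(p_hi)]
  p_lo <- interpolate_pore_pressure(state, fields, mesh, pts,
                                    rep(nc, nrow(pts)), params)
  pr_col <- which(fields$pairs$k == nc - 1L & fields$pairs$i == nc)
  beta <- fields$beta[, pr_col]
  MBF_D <- beta * (p_hi - p_lo)
  MBF_PL <- junction_flow_field(nw, flow, comp, pts, fields$rev, nc - 1L, nc)
  MBF_err <- abs(MBF_D - MBF_PL) / pmax(abs(MBF_PL), floor)
  data.frame(MBF_D = MBF_D, MBF_PL = MBF_PL, MBF_err = MBF_err)
}

#' Run the cube perfusion benchmark
#'
#' Executes the full pipeline — tree generation, Poiseuille solve,
#' compartment partitioning, REV parameterization, coupled FEM solve,
#' pore-pressure validation — over a grid of (model, nc, REV radius)
#' configurations and seeds, optionally repeating a vessel-blockage
#' scenario.
#'
#' @param n_terminals terminals of the CCO tree per seed.
#' @param domain_size cube edge, mm.
#' @param inlet_radius inlet vessel radius, mm.
#' @param mesh_n cube mesh subdivisions per edge.
#' @param pin,pout boundary pressures, mmHg.
#' @param grid data frame with columns `model`, `nc`, `rR` (one row per
#'   healthy configuration); default: Model I over `nc` 2 and 3, Models
#'   II/III at `nc = 3`, each across the `rR` sweep.
#' @param rR_sweep REV radii for the default grid, mm.
#' @param seeds integer vector of tree seeds.
#' @param blockage run the occlusion scenario as well.
#' @param blockage_grid configurations for the blocked runs (default all
#'   three models at `nc = 3`, `rR = 5`).
#' @param blockage_fraction fraction of terminals removed by the occlusion.
#' @param params a [material_params()].
#' @param config a [solver_config()].
#' @param quiet suppress progress messages.
#' @return a `benchmark_report`: list with data frames `healthy` and
#'   `blocked` (seed, model, nc, rR, Perr, newton iterations, inlet flow).
#' @export
run_benchmark <- function(n_terminals = 2000, domain_size = 100,
                          inlet_radius = 3, mesh_n = 6,
                          pin = 100, pout = 0,
                          grid = NULL, rR_sweep = c(3, 4, 5, 6, 8, 10),
                          seeds = 1:3,
                          blockage = TRUE, blockage_grid = NULL,
                          blockage_fraction = 0.25,
                          params = material_params(),
                          config = solver_config(max_newton = 6),
                          quiet = TRUE) {
  if (is.null(grid)) {
    grid <- rbind(
      expand.grid(model = "I", nc = c(2L, 3L), rR = rR_sweep,
                  stringsAsFactors = FALSE),
      expand.grid(model = c("II", "III"), nc = 3L, rR = rR_sweep,
                  stringsAsFactors = FALSE)
    )
  }
  if (blockage && is.null(blockage_grid)) {
    blockage_grid <- expand.grid(model = c("I", "II", "III"), nc = 3L, rR = 5,
                                 stringsAsFactors = FALSE)
  }
  mesh <- build_cube_mesh(mesh_n, domain_size)
  bcs <- flow_bcs(pin, pout, params$mu, units = "mmHg")

  run_cell <- function(nw, flow, zeta, cell) {
    sc <- partition_compartments(zeta, nw$segments$radius, cell$nc)
    comp <- assign_compartments(nw, sc, zeta)
    fields <- parameterize_porous_fields(
      nw, flow, sc, mesh, rev_spec(cell$rR), model = cell$model,
      mu = params$mu, comp = comp)
    sol <- tryCatch(newton_solve(mesh, fields, params, config),
                    error = function(e) NULL)
    if (is.null(sol)) {
      # rare rough-field plateau just above the acceptance level:
      # retry once with more staggered cycles and a longer polish
      deep <- config; deep$max_newton <- 2L * config$max_newton
      sol <- tryCatch(newton_solve(mesh, fields, params, deep,
                                   max_outer = 25),
                      error = function(e) NULL)
    }
    if (is.null(sol)) {
      warning("benchmark cell failed (model ", cell$model, ", nc ",
              cell$nc, ", rR ", cell$rR, "); recorded as NA")
      return(list(Perr = NA_real_, iterations = NA_integer_,
                  fields = fields, sol = NULL))
    }
    val <- validate_solution(nw, flow, sol, fields, mesh, params)
    list(Perr = val$Perr, iterations = sol$iterations,
         fields = fields, sol = sol)
  }

  healthy <- list(); blocked <- list(); nrow_h <- 0L; nrow_b <- 0L
  for (sd in seeds) {
    nw <- generate_cco_tree(domain_size, n_terminals, inlet_radius, seed = sd)
    flow <- solve_poiseuille(nw, bcs)
    zeta <- hierarchy_parameters(nw)
    for (r in seq_len(nrow(grid))) {
      cell <- grid[r, ]
      out <- suppressWarnings(run_cell(nw, flow, zeta, cell))
      nrow_h <- nrow_h + 1L
      healthy[[nrow_h]] <- data.frame(
        seed = sd, model = cell$model, nc = cell$nc, rR = cell$rR,
        Perr = out$Perr, iterations = out$iterations,
        q_inlet = flow$q_inlet)
      if (!quiet)
        message(sprintf("seed %d model %-3s nc %d rR %4.1f: Perr = %.4f (%d it)",
                        sd, cell$model, cell$nc, cell$rR, out$Perr,
                        out$iterations))
    }
    if (blockage) {
      iblk <- choose_blockage_segment(nw, blockage_fraction)
      nwb <- apply_blockage(nw, nw$segments$id[iblk])
      flowb <- solve_poiseuille(nwb, bcs)
      zetab <- hierarchy_parameters(nwb)
      for (r in seq_len(nrow(blockage_grid))) {
        cell <- blockage_grid[r, ]
        out <- suppressWarnings(run_cell(nwb, flowb, zetab, cell))
        nrow_b <- nrow_b + 1L
        blocked[[nrow_b]] <- data.frame(
          seed = sd, model = cell$model, nc = cell$nc, rR = cell$rR,
          Perr = out$Perr, iterations = out$iterations,
          q_inlet = flowb$q_inlet)
        if (!quiet)
          message(sprintf("seed %d BLOCKED model %-3s nc %d rR %4.1f: Perr = %.4f",
                          sd, cell$model, cell$nc, cell$rR, out$Perr))
      }
    }
  }
  structure(list(
    healthy = do.call(rbind, healthy),
    blocked = if (length(blocked) > 0) do.call(rbind, blocked) else NULL,
    grid = grid, seeds = seeds, mesh_n = mesh_n,
    n_terminals = n_terminals
  ), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>", x$n_terminals, "terminals, mesh n =", x$mesh_n,
      ",", length(x$seeds), "seeds\n")
  agg <- stats::aggregate(Perr ~ model + nc + rR, data = x$healthy,
                          function(v) median(v, na.rm = TRUE))
  cat("median healthy Perr by (model, nc, rR):\n")
  print(agg, row.names = FALSE)
  if (!is.null(x$blocked)) {
    aggb <- stats::aggregate(Perr ~ model + nc + rR, data = x$blocked,
                           function(v) median(v, na.rm = TRUE))
    cat("median blocked Perr:\n")
    print(aggb, row.names = FALSE)
  }
  invisible(x)
}
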