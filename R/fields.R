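# Assembled porous-field container for a mesh: the continuum-side input
# of the coupled Darcy-poroelastic solve.

#' Parameterize continuum porous fields from a flow-solved network
#'
#' Runs the full REV homogenization for the centroids of a tetrahedral
#' mesh: per-compartment porosity and permeability (Models I-III),
#' inter-compartment coupling constants, the prescribed first-compartment
#' pressure field and the terminal sink density. Fields are piecewise
#' constant per element.
#'
#' @param nw a [vascular_network()] with hierarchy computed.
#' @param flow a [solve_poiseuille()] solution on the same network.
#' @param scheme a [partition_compartments()] scheme (or `comp`, a
#'   precomputed per-segment compartment vector).
#' @param mesh a [build_cube_mesh()] / [tet_mesh()] mesh of the domain.
#' @param rev a [rev_spec()].
#' @param model permeability/coupling model, `"I"`, `"II"` or `"III"`.
#' @param mu blood viscosity, Pa s.
#' @param comp optional per-segment compartment indices overriding
#'   `scheme`.
#' @param normalization REV pressure normalization passed to
#'   [coupling_field()] and [boundary_fields()].
#' @return an object of class `porous_fields`: element-wise fields `phi`
#'   (NE x nc), `K` (list of NE x 9 tensors per compartment), `beta`
#'   (NE x npair with `pairs` attribute), `p1_bar`, `S_ext`, plus
#'   bookkeeping (`nc`, `model`, `rev`, `mu`, `vol`, `q_inlet`).
#' @export
parameterize_porous_fields <- function(nw, flow, scheme, mesh, rev,
                                       model = c("I", "II", "III"),
                                       mu = 0.004, comp = NULL,
                                       normalization = c("mean", "printed")) {
  model <- match.arg(model)
  normalization <- match.arg(normalization)
  if (is.null(comp)) comp <- assign_compartments(nw, scheme)
  nc <- max(comp)
  pts <- mesh$centroid
  V_T <- sum(mesh$vol)
  # one REV membership pass each for element centroids and mesh nodes,
  # shared by every field kernel
  mem <- rev_membership(nw, pts, rev)
  phi <- porosity_field(nw, comp, pts, rev, mem = mem)
  K <- permeability_field(nw, comp, pts, rev, model = model, mu = mu,
                          V_T = V_T, mem = mem)
  beta <- coupling_field(nw, flow, comp, pts, rev, model = model, V_T = V_T,
                         normalization = normalization, mem = mem)
  bf <- boundary_fields(nw, flow, comp, pts, rev,
                        normalization = normalization, mem = mem)
  pbar <- rev_mean_pressure(nw, flow, comp, mem, nc, rev, normalization)
  # nodal fields for the constitutive law and the solver warm start: the
  # tube law needs a continuous reference porosity, so phi0 is sampled at
  # mesh nodes and P1-interpolated
  mem_n <- rev_membership(nw, mesh$nodes, rev)
  phi_node <- porosity_field(nw, comp, mesh$nodes, rev, mem = mem_n)
  pbar_node <- rev_mean_pressure(nw, flow, comp, mem_n, nc, rev, normalization)
  p1_bar <- bf$p1_bar
  # where no compartment-1 vessel is in reach the coupling to compartment 1
  # is zero, so the prescribed pressure value there is inert; use 0
  p1_bar[is.na(p1_bar)] <- 0
  structure(list(
    phi = phi, phi_node = phi_node, K = K, beta = beta,
    pairs = attr(beta, "pairs"),
    p1_bar = p1_bar, pbar = pbar, pbar_node = pbar_node, S_ext = bf$S_ext,
    nc = nc, model = model, rev = rev, mu = mu,
    vol = mesh$vol, points = pts, q_inlet = flow$q_inlet,
    comp = comp, normalization = normalization
  ), class = "porous_fields")
}

#' @export
print.porous_fields <- function(x, ...) {
  cat("<porous_fields> model", x$model, "on", nrow(x$phi), "elements,",
      x$nc, "compartments\n")
  cat("  REV radius:", x$rev$radius, "mm (", x$rev$inclusion_rule, ")\n")
  cat("  mean porosity by compartment:",
      paste(format(colMeans(x$phi), digits = 3), collapse = ", "), "\n")
  cat("  sink total:", format(sum(x$S_ext * x$vol), digits = 6),
      "mm^3/s vs inlet", format(-x$q_inlet, digits = 6), "\n")
  invisible(x)
}

#' Export porous fields as VTK cell data
#'
#' @param fields a [parameterize_porous_fields()] object.
#' @param mesh the mesh the fields live on.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_fields_vtk <- function(fields, mesh, path) {
  cd <- list()
  for (i in seq_len(fields$nc)) {
    cd[[paste0("phi_", i)]] <- fields$phi[, i]
    K <- fields$K[[i]]
    for (cmp in list(c("xx", 1), c("yy", 5), c("zz", 9),
                     c("xy", 4), c("xz", 7), c("yz", 8))) {
      cd[[paste0("K", i, "_", cmp[1])]] <- K[, as.integer(cmp[2])]
    }
  }
  for (pr in seq_len(nrow(fields$pairs))) {
    cd[[paste0("beta_", fields$pairs$k[pr], "_", fields$pairs$i[pr])]] <-
      fields$beta[, pr]
  }
  cd$p1bar <- fields$p1_bar
  cd$Sext <- fields$S_ext
  write_mesh_vtk(mesh, path, cell_data = cd)
}
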