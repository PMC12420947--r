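# Structured tetrahedral meshes of box domains and P1 geometry caches.

#' Build a structured tetrahedral mesh of a cube
#'
#' Subdivides the cube into `n^3` hexahedral cells and each cell into 6
#' tetrahedra (Kuhn triangulation, all sharing the cell's main diagonal),
#' giving `6 n^3` positively oriented tets on `(n + 1)^3` nodes whose
#' volumes sum exactly to `size^3`.
#'
#' @param n number of subdivisions per edge, `>= 1`.
#' @param size edge length, mm.
#' @param origin position of the lowest corner, mm.
#' @return an object of class `tet_mesh`: list with `nodes` (N x 3),
#'   `tets` (NE x 4 node indices), `boundary_faces` (NB x 3), per-element
#'   `vol`, `h` (max edge), `centroid` (NE x 3), and the P1 gradient cache
#'   `grads` (list of four NE x 3 matrices).
#' @export
build_cube_mesh <- function(n, size = 1, origin = c(0, 0, 0)) {
  if (n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  hgrid <- size / n
  coords1 <- origin[1] + seq(0, size, length.out = n + 1)
  coords2 <- origin[2] + seq(0, size, length.out = n + 1)
  coords3 <- origin[3] + seq(0, size, length.out = n + 1)
  nodes <- as.matrix(expand.grid(x = coords1, y = coords2, z = coords3,
                                 KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) 1L + i + (n + 1L) * (j + (n + 1L) * k)

  # Kuhn subdivision: 6 tets per cell, one per permutation of the unit steps
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  eye <- diag(3)
  cell_tets <- lapply(perms, function(p) {
    v <- matrix(0, 4, 3)
    v[2, ] <- v[1, ] + eye[p[1], ]
    v[3, ] <- v[2, ] + eye[p[2], ]
    v[4, ] <- v[3, ] + eye[p[3], ]
    v
  })

  ijk <- as.matrix(expand.grid(i = 0:(n - 1), j = 0:(n - 1), k = 0:(n - 1),
                               KEEP.OUT.ATTRS = FALSE))
  ncell <- nrow(ijk)
  tets <- matrix(0L, 6L * ncell, 4)
  for (t in 1:6) {
    v <- cell_tets[[t]]
    for (a in 1:4) {
      tets[seq(t, by = 6L, length.out = ncell), a] <-
        nid(ijk[, 1] + v[a, 1], ijk[, 2] + v[a, 2], ijk[, 3] + v[a, 3])
    }
  }
  mesh <- tet_mesh(nodes, tets)
  mesh$structured <- list(n = n, size = size, origin = origin)
  mesh
}

#' Assemble a tet_mesh object from nodes and connectivity
#'
#' Computes the per-element P1 geometry cache (volumes, barycentric
#' gradients, characteristic lengths, centroids) and the boundary faces.
#' Elements with negative volume are reoriented by swapping two vertices.
#'
#' @param nodes N x 3 node coordinates, mm.
#' @param tets NE x 4 node indices.
#' @return a `tet_mesh` object.
#' @export
tet_mesh <- function(nodes, tets) {
  storage.mode(tets) <- "integer"
  x1 <- nodes[tets[, 1], , drop = FALSE]
  x2 <- nodes[tets[, 2], , drop = FALSE]
  x3 <- nodes[tets[, 3], , drop = FALSE]
  x4 <- nodes[tets[, 4], , drop = FALSE]
  # T columns are the edge vectors from vertex 1; cbind of the three edge
  # vectors is exactly the column-major t3 layout
  Tm <- cbind(x2 - x1, x3 - x1, x4 - x1)
  det <- t3_det(Tm)
  flip <- det < 0
  if (any(flip)) {
    tmp <- tets[flip, 3]; tets[flip, 3] <- tets[flip, 4]; tets[flip, 4] <- tmp
    x3 <- nodes[tets[, 3], , drop = FALSE]
    x4 <- nodes[tets[, 4], , drop = FALSE]
    Tm <- cbind(x2 - x1, x3 - x1, x4 - x1)
    det <- t3_det(Tm)
  }
  if (any(det <= 0)) stop("degenerate (zero-volume) element")
  vol <- det / 6
  Tinv <- t3_inv(Tm, det)
  # grad lambda_{a} for a = 2..4 are the rows of Tinv; grad lambda_1 = -sum
  g2 <- t3_row(Tinv, 1)
  g3 <- t3_row(Tinv, 2)
  g4 <- t3_row(Tinv, 3)
  g1 <- -(g2 + g3 + g4)
  edge <- function(a, b) sqrt(rowSums((nodes[tets[, a], , drop = FALSE] -
                                       nodes[tets[, b], , drop = FALSE])^2))
  h <- pmax(edge(1, 2), edge(1, 3), edge(1, 4),
            edge(2, 3), edge(2, 4), edge(3, 4))
  centroid <- (x1 + x2 + x3 + x4) / 4

  # boundary faces: the ones appearing exactly once
  fl <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
              tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  key <- apply(t(apply(fl, 1, sort)), 1, paste, collapse = "-")
  once <- names(which(table(key) == 1))
  boundary_faces <- fl[match(once, key), , drop = FALSE]

  structure(list(
    nodes = nodes, tets = tets, boundary_faces = boundary_faces,
    vol = vol, h = h, centroid = centroid,
    grads = list(g1, g2, g3, g4)
  ), class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("<tet_mesh>\n")
  cat("  nodes:    ", nrow(x$nodes), "\n", sep = "")
  cat("  tets:     ", nrow(x$tets), "\n", sep = "")
  cat("  volume:   ", format(sum(x$vol), digits = 8), " mm^3\n", sep = "")
  cat("  h range:  [", format(min(x$h), digits = 4), ", ",
      format(max(x$h), digits = 4), "] mm\n", sep = "")
  invisible(x)
}

# barycentric coordinates of points within given tets
tet_barycentric <- function(mesh, elem, pts) {
  x1 <- mesh$nodes[mesh$tets[elem, 1], , drop = FALSE]
  lam234 <- cbind(
    t3_dot(mesh$grads[[2]][elem, , drop = FALSE], pts - x1),
    t3_dot(mesh$grads[[3]][elem, , drop = FALSE], pts - x1),
    t3_dot(mesh$grads[[4]][elem, , drop = FALSE], pts - x1)
  )
  cbind(1 - rowSums(lam234), lam234)
}

#' Locate points inside a tetrahedral mesh
#'
#' Returns, for each query point, the containing element and its P1
#' barycentric weights. Structured cube meshes use direct cell lookup;
#' general meshes fall back to a bounding-box search. Points outside the
#' mesh yield `NA` (no extrapolation).
#'
#' @param mesh a `tet_mesh`.
#' @param pts M x 3 matrix of query points, mm.
#' @param tol barycentric tolerance for containment.
#' @return list with integer vector `elem` and M x 4 matrix `lambda`.
#' @export
locate_points <- function(mesh, pts, tol = 1e-9) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  m <- nrow(pts)
  elem <- rep(NA_integer_, m)
  lambda <- matrix(NA_real_, m, 4)
  if (!is.null(mesh$structured)) {
    st <- mesh$structured
    hh <- st$size / st$n
    ic <- pmin(pmax(floor((pts[, 1] - st$origin[1]) / hh), 0), st$n - 1)
    jc <- pmin(pmax(floor((pts[, 2] - st$origin[2]) / hh), 0), st$n - 1)
    kc <- pmin(pmax(floor((pts[, 3] - st$origin[3]) / hh), 0), st$n - 1)
    base <- 6 * (ic + st$n * (jc + st$n * kc))
    for (t in 1:6) {
      unresolved <- which(is.na(elem))
      if (length(unresolved) == 0) break
      cand <- as.integer(base[unresolved] + t)
      lam <- tet_barycentric(mesh, cand, pts[unresolved, , drop = FALSE])
      ok <- apply(lam >= -tol, 1, all)
      elem[unresolved[ok]] <- cand[ok]
      lambda[unresolved[ok], ] <- lam[ok, , drop = FALSE]
    }
    # points outside the structured box stay NA
    out <- pts[, 1] < st$origin[1] - tol | pts[, 1] > st$origin[1] + st$size + tol |
           pts[, 2] < st$origin[2] - tol | pts[, 2] > st$origin[2] + st$size + tol |
           pts[, 3] < st$origin[3] - tol | pts[, 3] > st$origin[3] + st$size + tol
    elem[out] <- NA_integer_
    lambda[out, ] <- NA_real_
    return(list(elem = elem, lambda = lambda))
  }
  # generic fallback: bbox prefilter per point
  bb_lo <- pmin(pmin(mesh$nodes[mesh$tets[, 1], ], mesh$nodes[mesh$tets[, 2], ]),
                pmin(mesh$nodes[mesh$tets[, 3], ], mesh$nodes[mesh$tets[, 4], ]))
  bb_hi <- pmax(pmax(mesh$nodes[mesh$tets[, 1], ], mesh$nodes[mesh$tets[, 2], ]),
                pmax(mesh$nodes[mesh$tets[, 3], ], mesh$nodes[mesh$tets[, 4], ]))
  for (q in seq_len(m)) {
    cand <- which(pts[q, 1] >= bb_lo[, 1] - tol & pts[q, 1] <= bb_hi[, 1] + tol &
                  pts[q, 2] >= bb_lo[, 2] - tol & pts[q, 2] <= bb_hi[, 2] + tol &
                  pts[q, 3] >= bb_lo[, 3] - tol & pts[q, 3] <= bb_hi[, 3] + tol)
    if (length(cand) == 0) next
    lam <- tet_barycentric(mesh, cand, pts[rep(q, length(cand)), , drop = FALSE])
    ok <- which(apply(lam >= -tol, 1, all))
    if (length(ok) > 0) {
      elem[q] <- cand[ok[1]]
      lambda[q, ] <- lam[ok[1], ]
    }
  }
  list(elem = elem, lambda = lambda)
}

#' Write a tetrahedral mesh with data fields as legacy VTK
#'
#' @param mesh a `tet_mesh`.
#' @param path output `.vtk` path.
#' @param point_data named list of per-node vectors (length N) or matrices
#'   (N x 3, written as vectors).
#' @param cell_data named list of per-element vectors (length NE).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  nN <- nrow(mesh$nodes); nE <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", "poroperf mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nN)), con)
  writeLines(apply(mesh$nodes, 1, function(r)
    paste(sprintf("%.9g", r), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", nE, 5L * nE), con)
  writeLines(apply(mesh$tets - 1L, 1, function(r)
    paste(c(4L, r), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", nE), con)
  writeLines(rep("10", nE), con)
  write_fields <- function(fields, n, label) {
    writeLines(sprintf("%s %d", label, n), con)
    for (nm in names(fields)) {
      f <- fields[[nm]]
      if (is.matrix(f) && ncol(f) == 3) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(apply(f, 1, function(r)
          paste(sprintf("%.9g", r), collapse = " ")), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.9g", f), con)
      }
    }
  }
  if (length(point_data) > 0) write_fields(point_data, nN, "POINT_DATA")
  if (length(cell_data) > 0) write_fields(cell_data, nE, "CELL_DATA")
  invisible(path)
}

#' Read a tetrahedral mesh from a legacy-ASCII VTK file
#'
#' Minimal reader for `DATASET UNSTRUCTURED_GRID` files containing
#' tetrahedra (cell type 10), as written by [write_mesh_vtk()], Gmsh or
#' ParaView exports. Data fields are ignored; only the geometry is read.
#'
#' @param path `.vtk` file path.
#' @return a `tet_mesh`.
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)
  if (length(ip) != 1) stop("malformed VTK file: no POINTS section")
  npts <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  vals <- scan(text = lines[(ip + 1):length(lines)], what = numeric(),
               n = 3 * npts, quiet = TRUE)
  nodes <- matrix(vals, npts, 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)
  if (length(ic) != 1) stop("malformed VTK file: no CELLS section")
  ncell <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cvals <- scan(text = lines[(ic + 1):length(lines)], what = integer(),
                n = 5 * ncell, quiet = TRUE)
  cm <- matrix(cvals, ncell, 5, byrow = TRUE)
  if (any(cm[, 1] != 4L)) stop("non-tetrahedral cells in VTK file")
  tet_mesh(nodes, cm[, 2:5] + 1L)
}
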