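# Deterministic fixture objects used by examples, tests and the pipeline.

#' Named deterministic fixtures
#'
#' Regenerates, bitwise-identically, one of the named fixture objects:
#' \describe{
#'   \item{`"y3"`}{3-segment Y-tree: root of length 2 mm and radius 1 mm,
#'     two children of length 1 mm and radius `2^(-1/3)` mm (Murray
#'     exponent 3); total length 4 mm.}
#'   \item{`"bin4"`}{symmetric binary tree of depth 4 with explicit
#'     coordinates: 15 segments, 8 terminals, Murray-law radii.}
#'   \item{`"cco200-seed1"`}{CCO tree with 200 terminals in a 100 mm cube,
#'     3 mm inlet radius, seed 1.}
#'   \item{`"cube-n2"`, `"cube-n4"`, `"cube-n8"`}{unit-cube tetrahedral
#'     meshes with 2, 4 or 8 subdivisions per edge.}
#' }
#'
#' @param name fixture name.
#' @return a [vascular_network()] or a [build_cube_mesh()] mesh.
#' @export
make_fixture <- function(name) {
  switch(name,
    "y3" = fixture_y3(),
    "bin4" = fixture_bin4(),
    "cco200-seed1" = generate_cco_tree(100, n_terminals = 200,
                                       inlet_radius = 3, seed = 1),
    "cube-n2" = build_cube_mesh(2, 1),
    "cube-n4" = build_cube_mesh(4, 1),
    "cube-n8" = build_cube_mesh(8, 1),
    stop("unknown fixture: ", name)
  )
}

fixture_y3 <- function() {
  rc <- 2^(-1 / 3)
  vascular_network(data.frame(
    id = 1:3, parent_id = c(-1L, 1L, 1L),
    x0 = c(0, 0, 0), y0 = c(0, 0, 0), z0 = c(0, 2, 2),
    x1 = c(0, 0.6, -0.6), y1 = c(0, 0, 0), z1 = c(2, 2.8, 2.8),
    radius = c(1, rc, rc), blocked = FALSE
  ))
}

# symmetric depth-4 binary tree; branching alternates between the x and y
# planes, segment length halves per level, radii follow Murray with gamma 3
fixture_bin4 <- function() {
  segs <- list()
  add_seg <- function(id, parent, p0, p1, radius) {
    segs[[id]] <<- data.frame(id = id, parent_id = parent,
                              x0 = p0[1], y0 = p0[2], z0 = p0[3],
                              x1 = p1[1], y1 = p1[2], z1 = p1[3],
                              radius = radius, blocked = FALSE)
  }
  next_id <- 0L
  grow <- function(parent_id, p0, level, offset_dir) {
    next_id <<- next_id + 1L
    id <- next_id
    len <- 8 / 2^(level - 1)
    n_term <- 2^(4 - level)
    radius <- (n_term / 8)^(1 / 3)
    # vertical rise len, lateral offset len/2 alternating between x and y
    lateral <- if (level == 1) c(0, 0) else
      if (level %% 2 == 0) c(offset_dir * len / 2, 0) else
      c(0, offset_dir * len / 2)
    p1 <- p0 + c(lateral, len)
    add_seg(id, parent_id, p0, p1, radius)
    if (level < 4) {
      grow(id, p1, level + 1L, -1)
      grow(id, p1, level + 1L, +1)
    }
    id
  }
  grow(-1L, c(0, 0, 0), 1L, 0)
  vascular_network(do.call(rbind, segs))
}
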