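# Steady Poiseuille flow on the discrete vascular tree.

#' Poiseuille conductance of a cylindrical segment
#'
#' Returns `g = pi r^4 / (8 mu l)` in mm^3/(Pa s), so that the volumetric
#' flow through the segment is `q = g * (p_prox - p_dist)`.
#'
#' @param radius segment radius, mm.
#' @param length segment length, mm.
#' @param mu dynamic viscosity of blood, Pa s.
#' @return conductance, mm^3/(Pa s). Vectorized over all arguments.
#' @examples
#' segment_conductance(1, 10, 0.004)   # pi / 0.32
#' @export
segment_conductance <- function(radius, length, mu) {
  if (any(radius <= 0)) stop("non-positive radius")
  if (any(length <= 0)) stop("non-positive length")
  if (any(mu <= 0)) stop("non-positive viscosity")
  pi * radius^4 / (8 * mu * length)
}

#' Flow boundary conditions for the network solve
#'
#' @param pin inlet pressure. @param pout outlet (terminal) pressure.
#' @param mu blood viscosity, Pa s. The value is not stated by typical
#'   perfusion benchmarks; 0.004 Pa s is the standard bulk blood viscosity.
#' @param units `"Pa"` or `"mmHg"` for `pin`/`pout`.
#' @return a `flow_bcs` list with pressures in Pa.
#' @export
flow_bcs <- function(pin = 100, pout = 0, mu = 0.004, units = c("mmHg", "Pa")) {
  units <- match.arg(units)
  if (units == "mmHg") { pin <- mmhg_to_pa(pin); pout <- mmhg_to_pa(pout) }
  if (pin <= pout) stop("pin must exceed pout")
  if (mu <= 0) stop("non-positive viscosity")
  structure(list(pin = pin, pout = pout, mu = mu), class = "flow_bcs")
}

#' Solve steady Poiseuille flow on a vascular tree
#'
#' Nodal pressures solve the sparse conductance-weighted Laplacian system
#' with Dirichlet conditions: `pin` at the inlet (root proximal) node and
#' `pout` at the distal node of every unblocked terminal. Flow balance
#' holds at every interior junction. Blocked segments are removed from the
#' system entirely and report zero flow.
#'
#' @param nw a [vascular_network()].
#' @param bcs a [flow_bcs()].
#' @return a `network_flow` object: list with
#'   \describe{
#'     \item{q}{per-segment signed flow (positive proximal to distal), mm^3/s;}
#'     \item{p_prox, p_dist}{segment endpoint pressures, Pa;}
#'     \item{p_seg_mean}{mean of the two endpoint pressures, Pa;}
#'     \item{q_inlet}{total inlet flow, mm^3/s;}
#'     \item{bcs}{the boundary conditions used.}
#'   }
#' @examples
#' y <- make_fixture("y3")
#' fl <- solve_poiseuille(y, flow_bcs(100, 0))
#' fl$q[1] - (fl$q[2] + fl$q[3])   # conservation at the junction
#' @export
solve_poiseuille <- function(nw, bcs) {
  stopifnot(inherits(nw, "vascular_network"), inherits(bcs, "flow_bcs"))
  seg <- nw$segments
  n <- nrow(seg)
  live <- !seg$blocked
  if (!any(live)) stop("no unblocked segments")
  root <- network_root_index(nw)
  if (!live[root]) stop("root segment is blocked")
  pidx <- network_parent_index(nw)
  if (any(live & !is.na(pidx) & !live[ifelse(is.na(pidx), root, pidx)]))
    stop("unblocked segment below a blocked parent: perfused subgraph disconnected")

  # node numbering: node 1 = inlet (root proximal); node i+1 = distal of seg i
  nn <- n + 1L
  prox_node <- ifelse(is.na(pidx), 1L, pidx + 1L)
  dist_node <- seq_len(n) + 1L

  g <- segment_conductance(seg$radius, network_lengths(nw), bcs$mu)
  li <- which(live)
  gi <- g[li]
  a <- prox_node[li]; b <- dist_node[li]
  # graph Laplacian over live nodes
  L <- Matrix::sparseMatrix(
    i = c(a, b, a, b), j = c(a, b, b, a),
    x = c(gi, gi, -gi, -gi), dims = c(nn, nn))

  term <- network_is_terminal(nw) & live
  fixed <- c(1L, dist_node[term])
  pfix <- c(bcs$pin, rep(bcs$pout, sum(term)))
  live_nodes <- sort(unique(c(a, b)))
  free <- setdiff(live_nodes, fixed)

  p <- rep(NA_real_, nn)
  p[fixed] <- pfix
  if (length(free) > 0) {
    rhs <- -L[free, fixed, drop = FALSE] %*% pfix
    sol <- Matrix::solve(L[free, free, drop = FALSE], rhs)
    p[free] <- as.numeric(sol)
  }

  q <- numeric(n)
  q[li] <- gi * (p[prox_node[li]] - p[dist_node[li]])
  pp <- p[prox_node]; pd <- p[dist_node]
  pp[!live] <- NA_real_; pd[!live] <- NA_real_

  structure(list(
    q = q, p_prox = pp, p_dist = pd,
    p_seg_mean = (pp + pd) / 2,
    q_inlet = q[root], bcs = bcs
  ), class = "network_flow")
}

#' @export
print.network_flow <- function(x, ...) {
  cat("<network_flow>\n")
  cat("  segments:    ", length(x$q), "\n", sep = "")
  cat("  inlet flow:  ", format(x$q_inlet, digits = 6), " mm^3/s\n", sep = "")
  cat("  pressure BCs:", format(x$bcs$pin, digits = 6), "->",
      format(x$bcs$pout, digits = 6), "Pa\n")
  invisible(x)
}

#' Maximum relative nodal flow imbalance
#'
#' For every interior junction of the perfused tree, compares inflow and
#' outflow; returns the worst relative mismatch. An exact solve is balanced
#' to the linear-solver tolerance (about 1e-12); values much above 1e-10
#' indicate a corrupted solution.
#'
#' @param flow a `network_flow` from [solve_poiseuille()].
#' @param nw the network it was solved on.
#' @param floor denominator floor guarding against zero-flow junctions.
#' @return scalar, `max |q_in - sum q_out| / max(|q_in|, floor)`; 0 when the
#'   tree has no interior junction.
#' @export
conservation_report <- function(flow, nw, floor = 1e-300) {
  seg <- nw$segments
  live <- !seg$blocked
  pidx <- network_parent_index(nw)
  term <- network_is_terminal(nw)
  interior <- which(live & !term)     # distal node of each non-terminal segment
  if (length(interior) == 0) return(0)
  worst <- 0
  kids_of <- split(seq_len(nrow(seg)), pidx)
  for (i in interior) {
    kids <- kids_of[[as.character(i)]]
    kids <- kids[live[kids]]
    qin <- flow$q[i]
    qout <- sum(flow$q[kids])
    worst <- max(worst, abs(qin - qout) / max(abs(qin), floor))
  }
  worst
}
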