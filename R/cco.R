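# Synthetic vascular tree growth by constrained constructive optimization.

# normalize a domain spec: a single number (cube side, origin 0) or a
# length-6 vector c(xmin, xmax, ymin, ymax, zmin, zmax), mm
as_box_domain <- function(domain) {
  if (length(domain) == 1) domain <- c(0, domain, 0, domain, 0, domain)
  if (length(domain) != 6) stop("domain must be a side length or a length-6 box")
  if (any(domain[c(2, 4, 6)] <= domain[c(1, 3, 5)]))
    stop("degenerate domain box")
  as.numeric(domain)
}

point_on_box_boundary <- function(p, box, tol = 1e-9) {
  ext <- max(box[c(2, 4, 6)] - box[c(1, 3, 5)])
  inside <- all(p >= box[c(1, 3, 5)] - tol * ext) &&
            all(p <= box[c(2, 4, 6)] + tol * ext)
  onface <- any(abs(p - box[c(1, 3, 5)]) <= tol * ext) ||
            any(abs(p - box[c(2, 4, 6)]) <= tol * ext)
  inside && onface
}

# distances from point p to a batch of segments (A -> B), plus the segment
# parameter of the closest point
point_segment_distance <- function(p, A, B) {
  D <- B - A
  len2 <- rowSums(D^2)
  t <- ((p[1] - A[, 1]) * D[, 1] + (p[2] - A[, 2]) * D[, 2] +
        (p[3] - A[, 3]) * D[, 3]) / pmax(len2, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  dx <- A[, 1] + t * D[, 1] - p[1]
  dy <- A[, 2] + t * D[, 2] - p[2]
  dz <- A[, 3] + t * D[, 3] - p[3]
  list(dist = sqrt(dx^2 + dy^2 + dz^2), t = t)
}

#' Grow a synthetic vascular tree by constrained constructive optimization
#'
#' Staged CCO growth: terminal sites are sampled uniformly in the domain
#' subject to a minimum-distance threshold that shrinks as the tree fills
#' space; each new terminal is connected to a nearby segment through a new
#' bifurcation whose position is chosen to minimize the added segment
#' volume (`sum pi r^2 l` over the affected segments). Radii follow
#' Murray's law with exponent `gamma`
#' (`r_parent^gamma = r_child1^gamma + r_child2^gamma`) under the
#' assumption that every terminal carries the same outflow, which makes
#' every segment radius `r = inlet_radius * (n_distal_terminals /
#' n_terminals)^(1/gamma)`. The result is deterministic for a fixed seed.
#'
#' @param domain cube side length (mm, origin at 0) or a length-6 box
#'   `c(xmin, xmax, ymin, ymax, zmin, zmax)`.
#' @param n_terminals number of terminal segments to grow, `>= 1`.
#' @param inlet_radius radius of the inlet (root) segment, mm.
#' @param inlet_point location of the inlet on the domain boundary;
#'   defaults to the centre of the `x = xmin` face.
#' @param seed integer RNG seed; identical seeds give bitwise-identical
#'   trees.
#' @param gamma Murray bifurcation exponent (3 for the classical law).
#' @param n_candidates number of nearest segments considered when
#'   connecting a new terminal.
#' @return a [vascular_network()] with `2 * n_terminals - 1` segments.
#' @examples
#' nw <- generate_cco_tree(100, n_terminals = 20, inlet_radius = 3, seed = 1)
#' n_terminals(nw)
#' @export
generate_cco_tree <- function(domain, n_terminals, inlet_radius,
                              inlet_point = NULL, seed = 1, gamma = 3,
                              n_candidates = 5) {
  box <- as_box_domain(domain)
  lo <- box[c(1, 3, 5)]; hi <- box[c(2, 4, 6)]
  ext <- hi - lo
  if (n_terminals < 1) stop("n_terminals must be >= 1")
  if (inlet_radius <= 0) stop("non-positive inlet radius")
  if (is.null(inlet_point))
    inlet_point <- c(lo[1], (lo[2] + hi[2]) / 2, (lo[3] + hi[3]) / 2)
  inlet_point <- as.numeric(inlet_point)
  if (!point_on_box_boundary(inlet_point, box))
    stop("inlet_point must lie on the domain boundary")

  # local RNG so callers' random streams are untouched
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  nseg_max <- 2L * n_terminals - 1L
  P0 <- matrix(0, nseg_max, 3)   # proximal
  P1 <- matrix(0, nseg_max, 3)   # distal
  parent <- rep(NA_integer_, nseg_max)
  cnt <- integer(nseg_max)       # terminals in the subtree of each segment
  nseg <- 1L

  vol_dom <- prod(ext)
  runif_point <- function() lo + runif(3) * ext

  # first terminal: keep it away from the inlet so the root has finite length
  repeat {
    p <- runif_point()
    if (sqrt(sum((p - inlet_point)^2)) > 0.25 * max(ext)) break
  }
  P0[1, ] <- inlet_point; P1[1, ] <- p
  parent[1] <- -1L
  cnt[1] <- 1L

  min_len <- 1e-6 * max(ext)
  e_gamma <- 2 / gamma           # cost uses r^2 ~ cnt^(2/gamma)

  for (k in seq_len(n_terminals - 1L)) {
    live <- seq_len(nseg)
    d_thresh <- 0.6 * (vol_dom / (k + 1))^(1 / 3)
    # sample an admissible terminal site
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      xt <- runif_point()
      ds <- point_segment_distance(xt, P0[live, , drop = FALSE],
                                   P1[live, , drop = FALSE])
      if (min(ds$dist) > d_thresh) break
      if (attempt %% 10L == 0L) d_thresh <- d_thresh * 0.85
    }

    ordc <- order(ds$dist)[seq_len(min(n_candidates, nseg))]
    best <- NULL
    for (s_idx in ordc) {
      A <- P0[s_idx, ]; B <- P1[s_idx, ]
      seg_len <- sqrt(sum((B - A)^2))
      if (seg_len < 2 * min_len) next
      for (s in c(0.2, 0.35, 0.5, 0.65, 0.8)) {
        P <- A + s * (B - A)
        lnew <- sqrt(sum((xt - P)^2))
        if (lnew < min_len) next
        # local segment-volume cost with Murray-scaled radii weights
        w_up <- (cnt[s_idx] + 1)^e_gamma
        w_keep <- cnt[s_idx]^e_gamma
        cost <- w_up * s * seg_len + w_keep * (1 - s) * seg_len + lnew
        if (is.null(best) || cost < best$cost)
          best <- list(seg = s_idx, s = s, P = P, cost = cost)
      }
    }
    if (is.null(best)) stop("failed to connect terminal ", k + 1L)

    # split best$seg at P: new mid segment inherits the distal part,
    # new terminal segment runs P -> xt
    sidx <- best$seg
    P <- best$P
    mid <- nseg + 1L
    newt <- nseg + 2L
    P0[mid, ] <- P; P1[mid, ] <- P1[sidx, ]
    P0[newt, ] <- P; P1[newt, ] <- xt
    # re-home children of sidx to mid
    kids <- which(parent[seq_len(nseg)] == sidx)
    if (length(kids) > 0) parent[kids] <- mid
    parent[mid] <- sidx
    parent[newt] <- sidx
    P1[sidx, ] <- P
    cnt[mid] <- cnt[sidx]
    cnt[newt] <- 1L
    # the subtree of sidx and of all its ancestors gains one terminal
    a <- sidx
    while (!is.na(a) && a > 0) {
      cnt[a] <- cnt[a] + 1L
      a <- parent[a]
    }
    nseg <- nseg + 2L
  }

  radius <- inlet_radius * (cnt[seq_len(nseg)] / n_terminals)^(1 / gamma)
  seg <- data.frame(
    id = seq_len(nseg),
    parent_id = ifelse(is.na(parent[seq_len(nseg)]) |
                         parent[seq_len(nseg)] < 0, -1L, parent[seq_len(nseg)]),
    x0 = P0[seq_len(nseg), 1], y0 = P0[seq_len(nseg), 2], z0 = P0[seq_len(nseg), 3],
    x1 = P1[seq_len(nseg), 1], y1 = P1[seq_len(nseg), 2], z1 = P1[seq_len(nseg), 3],
    radius = radius,
    blocked = FALSE
  )
  vascular_network(seg)
}
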