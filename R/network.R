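# Vascular network container: a rooted binary tree of cylindrical segments.

#' Construct a vascular network from a segment table
#'
#' A vascular network is a rooted tree of straight cylindrical segments.
#' Each segment runs from its proximal endpoint `(x0, y0, z0)` to its distal
#' endpoint `(x1, y1, z1)` (mm) with a constant `radius` (mm). The proximal
#' endpoint of a child coincides with the distal endpoint of its parent.
#'
#' @param segments data frame with columns `id`, `parent_id` (`-1` or `NA`
#'   for the root), `x0`, `y0`, `z0`, `x1`, `y1`, `z1`, `radius` and
#'   optionally `blocked` (logical, default `FALSE`).
#' @param validate check the tree invariants (single root, connectivity,
#'   acyclicity, positive radii and lengths, endpoint matching).
#' @return an object of class `vascular_network`.
#' @seealso [read_network()], [generate_cco_tree()], [hierarchy_parameters()]
#' @export
vascular_network <- function(segments, validate = TRUE) {
  required <- c("id", "parent_id", "x0", "y0", "z0", "x1", "y1", "z1", "radius")
  missing <- setdiff(required, names(segments))
  if (length(missing) > 0)
    stop("segment table lacks columns: ", paste(missing, collapse = ", "))
  segments <- as.data.frame(segments)
  if (is.null(segments$blocked)) segments$blocked <- FALSE
  segments$id <- as.integer(segments$id)
  segments$parent_id <- as.integer(segments$parent_id)
  segments$parent_id[is.na(segments$parent_id)] <- -1L
  segments$blocked <- as.logical(segments$blocked)
  nw <- structure(list(segments = segments), class = "vascular_network")
  if (validate) validate_network(nw)
  nw
}

validate_network <- function(nw, tol = 1e-8) {
  seg <- nw$segments
  n <- nrow(seg)
  if (n == 0) stop("empty segment table")
  if (anyDuplicated(seg$id)) {
    dup <- seg$id[duplicated(seg$id)]
    stop("duplicate segment ids: ", paste(unique(dup), collapse = ", "))
  }
  is_root <- seg$parent_id < 0
  if (sum(is_root) != 1)
    stop("network must have exactly one root, found ", sum(is_root))
  pidx <- match(seg$parent_id, seg$id)
  orphan <- which(!is_root & is.na(pidx))
  if (length(orphan) > 0)
    stop("row ", orphan[1], ": parent id ", seg$parent_id[orphan[1]],
         " does not exist")
  if (any(seg$radius <= 0)) stop("non-positive segment radius")
  len <- network_lengths(nw)
  if (any(len <= 0)) stop("zero-length segment")
  # connectivity/acyclicity: every segment must reach the root by parents
  depth <- rep(NA_integer_, n)
  depth[is_root] <- 0L
  frontier <- which(is_root)
  while (length(frontier) > 0) {
    kids <- which(pidx %in% frontier & is.na(depth))
    if (length(kids) == 0) break
    depth[kids] <- 1L
    frontier <- kids
  }
  if (anyNA(depth)) stop("network is disconnected or cyclic")
  # geometric continuity: child proximal == parent distal
  notroot <- which(!is_root)
  if (length(notroot) > 0) {
    pd <- as.matrix(seg[pidx[notroot], c("x1", "y1", "z1")])
    cp <- as.matrix(seg[notroot, c("x0", "y0", "z0")])
    gap <- sqrt(rowSums((pd - cp)^2))
    scale <- max(len)
    if (any(gap > tol * max(1, scale)))
      stop("child proximal endpoint does not match parent distal endpoint (max gap ",
           format(max(gap)), " mm)")
  }
  invisible(nw)
}

# --- accessors ---------------------------------------------------------------

network_lengths <- function(nw) {
  seg <- nw$segments
  sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2 + (seg$z1 - seg$z0)^2)
}

network_midpoints <- function(nw) {
  seg <- nw$segments
  cbind((seg$x0 + seg$x1) / 2, (seg$y0 + seg$y1) / 2, (seg$z0 + seg$z1) / 2)
}

# unit direction vectors proximal -> distal, n x 3
network_directions <- function(nw) {
  seg <- nw$segments
  d <- cbind(seg$x1 - seg$x0, seg$y1 - seg$y0, seg$z1 - seg$z0)
  d / sqrt(rowSums(d^2))
}

network_parent_index <- function(nw) {
  match(nw$segments$parent_id, nw$segments$id)
}

network_root_index <- function(nw) which(nw$segments$parent_id < 0)

# logical: segment has no children
network_is_terminal <- function(nw) {
  pidx <- network_parent_index(nw)
  out <- rep(TRUE, nrow(nw$segments))
  out[pidx[!is.na(pidx)]] <- FALSE
  out
}

#' Number of terminal segments of a network
#'
#' @param nw a [vascular_network()].
#' @param perfused_only count only unblocked terminals.
#' @return integer count of segments without children.
#' @export
n_terminals <- function(nw, perfused_only = FALSE) {
  term <- network_is_terminal(nw)
  if (perfused_only) term <- term & !nw$segments$blocked
  sum(term)
}

# indices ordered root-first (parents always precede children)
network_topo_order <- function(nw) {
  pidx <- network_parent_index(nw)
  n <- nrow(nw$segments)
  depth <- integer(n)
  root <- network_root_index(nw)
  depth[root] <- 0L
  todo <- setdiff(seq_len(n), root)
  # peel segments whose parent depth is already known (table order is free)
  while (length(todo) > 0) {
    done <- todo[!(pidx[todo] %in% todo)]
    depth[done] <- depth[pidx[done]] + 1L
    todo <- setdiff(todo, done)
  }
  order(depth)
}

# number of terminals distal to (and including terminals of) each segment
network_terminal_counts <- function(nw) {
  ord <- network_topo_order(nw)
  pidx <- network_parent_index(nw)
  cnt <- as.integer(network_is_terminal(nw))
  for (i in rev(ord)) {
    p <- pidx[i]
    if (!is.na(p)) cnt[p] <- cnt[p] + cnt[i]
  }
  cnt
}

#' @export
print.vascular_network <- function(x, ...) {
  seg <- x$segments
  cat("<vascular_network>\n")
  cat("  segments:  ", nrow(seg), "\n", sep = "")
  cat("  terminals: ", n_terminals(x), "\n", sep = "")
  cat("  blocked:   ", sum(seg$blocked), "\n", sep = "")
  cat("  total length: ", format(sum(network_lengths(x)), digits = 6),
      " mm\n", sep = "")
  cat("  radius range: [", format(min(seg$radius), digits = 4), ", ",
      format(max(seg$radius), digits = 4), "] mm\n", sep = "")
  invisible(x)
}

# --- input / output ----------------------------------------------------------

NETWORK_COLUMNS <- c("id", "parent_id", "x0", "y0", "z0",
                     "x1", "y1", "z1", "radius_mm", "blocked")

#' Read or write a vascular network segment table
#'
#' The on-disk format is delimited text with a header line and one row per
#' segment, columns `id, parent_id, x0, y0, z0, x1, y1, z1, radius_mm,
#' blocked`; the root has `parent_id = -1`. Coordinates are written with 17
#' significant digits so that write-then-read round-trips exactly.
#'
#' @param path file path.
#' @param nw a [vascular_network()].
#' @return `read_network()` returns a [vascular_network()];
#'   `write_network()` returns `path` invisibly.
#' @export
read_network <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(NETWORK_COLUMNS, names(tab))
  if (length(missing) > 0)
    stop("malformed segment table ", path, ": missing columns ",
         paste(missing, collapse = ", "))
  names(tab)[names(tab) == "radius_mm"] <- "radius"
  vascular_network(tab)
}

#' @rdname read_network
#' @export
write_network <- function(nw, path) {
  seg <- nw$segments
  out <- data.frame(
    id = seg$id, parent_id = seg$parent_id,
    x0 = sprintf("%.17g", seg$x0), y0 = sprintf("%.17g", seg$y0),
    z0 = sprintf("%.17g", seg$z0), x1 = sprintf("%.17g", seg$x1),
    y1 = sprintf("%.17g", seg$y1), z1 = sprintf("%.17g", seg$z1),
    radius_mm = sprintf("%.17g", seg$radius),
    blocked = seg$blocked
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a vascular network as VTK polylines
#'
#' Writes a legacy-ASCII VTK polydata file with one two-point line per
#' segment and the radius (mm) attached as point data, for visualization in
#' ParaView or similar tools.
#'
#' @param nw a [vascular_network()].
#' @param path output file path (`.vtk`).
#' @param point_data optional named list of per-segment numeric vectors to
#'   attach (each value is replicated to the segment's two endpoints).
#' @return `path`, invisibly.
#' @export
write_network_vtk <- function(nw, path, point_data = list()) {
  seg <- nw$segments
  n <- nrow(seg)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "vascular network", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", 2L * n)), con)
  # interleave proximal/distal per segment
  pts <- matrix(0, 2L * n, 3)
  pts[seq(1, 2 * n, 2), ] <- as.matrix(seg[, c("x0", "y0", "z0")])
  pts[seq(2, 2 * n, 2), ] <- as.matrix(seg[, c("x1", "y1", "z1")])
  writeLines(apply(pts, 1, function(r) paste(sprintf("%.9g", r), collapse = " ")), con)
  writeLines(sprintf("LINES %d %d", n, 3L * n), con)
  i0 <- seq(0, 2 * n - 1, 2)
  writeLines(sprintf("2 %d %d", i0, i0 + 1), con)
  writeLines(sprintf("POINT_DATA %d", 2L * n), con)
  fields <- c(list(radius_mm = seg$radius), point_data)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", rep(fields[[nm]], each = 2)), con)
  }
  invisible(path)
}
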