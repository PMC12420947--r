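# Hierarchy parameter, compartment partitioning and blockage editing.

#' Hierarchy parameter of every vessel segment
#'
#' The hierarchy parameter of segment `j` is
#' `zeta_j = l_D,j / l_T`, where `l_D,j` is the summed length of all
#' segments strictly distal to `j` (excluding `j` itself) and `l_T` is the
#' total length of the network. With this convention every terminal segment
#' has exactly `zeta = 0`, and the root approaches 1 from below as the tree
#' grows (`zeta_root = 1 - l_root / l_T` for a tree whose root feeds
#' everything else). `zeta` is strictly decreasing from parent to child.
#'
#' Blocked segments are included: the hierarchy is a property of the
#' geometry, not of the flow state.
#'
#' @param nw a [vascular_network()].
#' @return numeric vector of per-segment hierarchy parameters in `[0, 1)`,
#'   in segment-table order.
#' @examples
#' y <- make_fixture("y3")
#' hierarchy_parameters(y)   # 0.5 at the root, 0 at both terminals
#' @export
hierarchy_parameters <- function(nw) {
  stopifnot(inherits(nw, "vascular_network"))
  len <- network_lengths(nw)
  lT <- sum(len)
  ord <- network_topo_order(nw)
  pidx <- network_parent_index(nw)
  # l_D excludes the segment's own length: accumulate child (l + l_D) upward
  lD <- numeric(nrow(nw$segments))
  for (i in rev(ord)) {
    p <- pidx[i]
    if (!is.na(p)) lD[p] <- lD[p] + len[i] + lD[i]
  }
  lD / lT
}

#' Partition a network into compartments by hierarchy parameter
#'
#' Grows a greedy binary regression tree with the hierarchy parameter
#' `zeta` as the single predictor and the vessel radius as the target,
#' expanded to exactly `nc` leaves by always splitting the leaf whose best
#' split yields the largest reduction in total within-leaf sum of squared
#' radius deviations (SSE). Because the predictor is scalar, every leaf is
#' a contiguous `zeta` interval and the split points become the critical
#' values separating compartments.
#'
#' Candidate split points are midpoints between adjacent distinct `zeta`
#' values. When no split of any leaf reduces the SSE (e.g., constant
#' radii), the widest splittable leaf is split at its median `zeta` so the
#' requested number of compartments is always produced.
#'
#' @param zeta per-segment hierarchy parameters (from
#'   [hierarchy_parameters()]).
#' @param radius per-segment radii, mm.
#' @param nc number of compartments, `>= 2`.
#' @return an object of class `compartment_scheme`: a list with `nc` and
#'   `zeta_crit`, a strictly decreasing vector of length `nc + 1` starting
#'   at 1 and ending at 0. Compartment `i` is the half-open interval
#'   `[zeta_crit[i + 1], zeta_crit[i])`, with the top interval closed at 1.
#' @examples
#' z <- c(0.9, 0.7, 0.3, 0.1)
#' r <- c(1.0, 1.0, 0.1, 0.1)
#' partition_compartments(z, r, nc = 2)   # split near 0.5
#' @export
partition_compartments <- function(zeta, radius, nc) {
  stopifnot(length(zeta) == length(radius), nc >= 2)
  if (any(zeta < 0 | zeta > 1)) stop("zeta outside [0, 1]")
  uz <- sort(unique(zeta))
  if (length(uz) < nc)
    stop("nc = ", nc, " exceeds the number of distinct zeta values (",
         length(uz), ")")
  ord <- order(zeta)
  z <- zeta[ord]
  r <- radius[ord]

  # best split of the subrange [lo, hi] (indices into z/r, sorted order);
  # prefix sums give all candidate SSE reductions in O(length)
  best_split <- function(lo, hi) {
    zz <- z[lo:hi]
    rr <- r[lo:hi]
    k <- length(zz)
    newv <- which(diff(zz) > 0)        # last index of each distinct-z run
    if (length(newv) == 0) return(NULL)
    cs <- cumsum(rr)
    cs2 <- cumsum(rr^2)
    nL <- newv
    nR <- k - nL
    sseL <- cs2[nL] - cs[nL]^2 / nL
    sseR <- (cs2[k] - cs2[nL]) - (cs[k] - cs[nL])^2 / nR
    total <- cs2[k] - cs[k]^2 / k
    red <- total - sseL - sseR
    cuts <- (zz[newv] + zz[newv + 1]) / 2
    ib <- which.max(red)
    best <- list(cut = cuts[ib], reduction = red[ib])
    # zero-reduction tie-break: split at the median zeta of the leaf
    if (best$reduction <= 1e-12 * max(total, 1)) {
      med <- stats::median(zz)
      best <- list(cut = cuts[which.min(abs(cuts - med))], reduction = 0)
    }
    best
  }

  # leaves as index ranges; grow to nc leaves
  leaves <- list(list(lo = 1L, hi = length(z)))
  cuts <- numeric(0)
  while (length(leaves) < nc) {
    cand <- lapply(leaves, function(L) best_split(L$lo, L$hi))
    splittable <- which(!vapply(cand, is.null, logical(1)))
    if (length(splittable) == 0)
      stop("cannot grow ", nc, " leaves: too few distinct zeta values")
    red <- vapply(splittable, function(k) cand[[k]]$reduction, numeric(1))
    k <- splittable[which.max(red)]
    s <- cand[[k]]$cut
    L <- leaves[[k]]
    ileft <- L$lo + sum(z[L$lo:L$hi] < s) - 1L
    leaves[[k]] <- list(lo = L$lo, hi = ileft)
    leaves[[length(leaves) + 1L]] <- list(lo = ileft + 1L, hi = L$hi)
    cuts <- c(cuts, s)
  }
  zeta_crit <- c(1, sort(cuts, decreasing = TRUE), 0)
  structure(list(nc = as.integer(nc), zeta_crit = zeta_crit),
            class = "compartment_scheme")
}

#' @export
print.compartment_scheme <- function(x, ...) {
  cat("<compartment_scheme> nc =", x$nc, "\n")
  cat("  zeta_crit:", paste(format(x$zeta_crit, digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Assign each segment to a compartment
#'
#' Compartment `i` covers the half-open hierarchy interval
#' `(zeta_crit[i + 1], zeta_crit[i]]`; the top interval is closed at 1 so
#' the root always falls in compartment 1, the bottom interval is closed
#' at 0, and a value exactly on an interior critical value falls into the
#' lower (smaller-vessel) compartment.
#'
#' @param nw a [vascular_network()].
#' @param scheme a `compartment_scheme` from [partition_compartments()].
#' @param zeta optional precomputed hierarchy parameters.
#' @return integer vector of compartment indices in `1..nc`, non-decreasing
#'   along every root-to-leaf path.
#' @export
assign_compartments <- function(nw, scheme, zeta = NULL) {
  stopifnot(inherits(scheme, "compartment_scheme"))
  if (is.null(zeta)) zeta <- hierarchy_parameters(nw)
  if (any(zeta < 0 | zeta > 1)) stop("zeta outside [0, 1]")
  zc <- scheme$zeta_crit          # decreasing: 1, ..., 0
  nc <- scheme$nc
  comp <- rep(NA_integer_, length(zeta))
  # intervals are half-open at the bottom, (zc[i+1], zc[i]], so a value
  # exactly on an interior critical value falls to the smaller-vessel
  # compartment; the last interval is closed at 0
  for (i in seq_len(nc)) {
    upper <- zc[i]; lower <- zc[i + 1]
    inside <- if (i == nc) zeta >= lower & zeta <= upper else
                           zeta > lower & zeta <= upper
    comp[inside & is.na(comp)] <- i
  }
  comp
}

#' Block a segment and its distal subtree
#'
#' Marks the given segment and every segment distal to it as blocked.
#' Blocked segments are excluded from flow solving and from porous
#' parameterization: an occluded subtree carries no flow and contributes
#' no permeability, which is what produces the impermeable regions that
#' heterogeneous parameterizations can represent and homogeneous ones
#' cannot.
#'
#' @param nw a [vascular_network()].
#' @param segment_id id of the segment at which the occlusion occurs.
#' @return the modified [vascular_network()].
#' @export
apply_blockage <- function(nw, segment_id) {
  seg <- nw$segments
  i0 <- match(segment_id, seg$id)
  if (is.na(i0)) stop("segment id ", segment_id, " does not exist")
  if (seg$parent_id[i0] < 0)
    stop("cannot block the root segment: no perfused network would remain")
  pidx <- network_parent_index(nw)
  blocked <- rep(FALSE, nrow(seg))
  blocked[i0] <- TRUE
  repeat {
    newly <- !blocked & !is.na(pidx) & blocked[ifelse(is.na(pidx), 1L, pidx)]
    if (!any(newly)) break
    blocked[newly] <- TRUE
  }
  nw$segments$blocked <- nw$segments$blocked | blocked
  nw
}

# pick a large-vessel segment whose occlusion removes roughly `fraction`
# of the terminals; used by the blockage scenario driver
choose_blockage_segment <- function(nw, fraction = 0.25) {
  cnt <- network_terminal_counts(nw)
  root <- network_root_index(nw)
  target <- fraction * cnt[root]
  cand <- setdiff(seq_len(nrow(nw$segments)), root)
  cand[which.min(abs(cnt[cand] - target))]
}
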