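# REV homogenization: discrete vessel data -> continuum porous fields.

#' Spherical representative elementary volume specification
#'
#' @param radius REV radius `r_R`, mm.
#' @param inclusion_rule `"midpoint"` counts a whole segment when its
#'   midpoint lies inside the sphere (the homogenization sums whole-segment
#'   quantities `pi r^2 l`); `"clipped"` weights each segment by the length
#'   of its intersection with the sphere, for sensitivity studies.
#' @return a `rev_spec` list with `radius`, `inclusion_rule` and the
#'   sphere volume `volume = 4/3 pi radius^3` (mm^3).
#' @export
rev_spec <- function(radius, inclusion_rule = c("midpoint", "clipped")) {
  if (radius <= 0) stop("REV radius must be positive")
  inclusion_rule <- match.arg(inclusion_rule)
  structure(list(radius = radius, inclusion_rule = inclusion_rule,
                 volume = 4 / 3 * pi * radius^3), class = "rev_spec")
}

# membership triplets (ipt, iseg, w) for REV spheres centred at `points`;
# w is the effective member length (mm). Blocked segments never members.
rev_membership <- function(nw, points, rev, chunk = 2000L) {
  stopifnot(inherits(rev, "rev_spec"))
  points <- matrix(as.numeric(points), ncol = 3)
  mids <- network_midpoints(nw)
  len <- network_lengths(nw)
  live <- which(!nw$segments$blocked)
  npts <- nrow(points)
  rR <- rev$radius
  out_i <- list(); out_s <- list(); out_w <- list(); nb <- 0L
  p2 <- rowSums(points^2)
  for (start in seq(1, length(live), by = chunk)) {
    idx <- live[start:min(start + chunk - 1L, length(live))]
    M <- mids[idx, , drop = FALSE]
    d2 <- outer(p2, rowSums(M^2), "+") - 2 * points %*% t(M)
    if (rev$inclusion_rule == "midpoint") {
      hit <- which(d2 <= rR^2, arr.ind = TRUE)
      if (nrow(hit) > 0) {
        nb <- nb + 1L
        out_i[[nb]] <- hit[, 1]
        out_s[[nb]] <- idx[hit[, 2]]
        out_w[[nb]] <- len[idx[hit[, 2]]]
      }
    } else {
      # coarse prefilter, then exact chord of the segment-sphere overlap
      reach <- (rR + len[idx] / 2)^2
      hit <- which(d2 <= rep(reach, each = npts), arr.ind = TRUE)
      if (nrow(hit) > 0) {
        ip <- hit[, 1]; is <- idx[hit[, 2]]
        A <- as.matrix(nw$segments[is, c("x0", "y0", "z0")])
        u <- network_directions(nw)[is, , drop = FALSE]
        XA <- points[ip, , drop = FALSE] - A
        t0 <- rowSums(XA * u)
        dperp2 <- pmax(rowSums(XA^2) - t0^2, 0)
        half2 <- rR^2 - dperp2
        w <- numeric(length(ip))
        okc <- half2 > 0
        half <- sqrt(pmax(half2, 0))
        wlo <- pmax(t0 - half, 0)
        whi <- pmin(t0 + half, len[is])
        w[okc] <- pmax(whi - wlo, 0)[okc]
        keep <- w > 0
        if (any(keep)) {
          nb <- nb + 1L
          out_i[[nb]] <- ip[keep]
          out_s[[nb]] <- is[keep]
          out_w[[nb]] <- w[keep]
        }
      }
    }
  }
  list(ipt = unlist(out_i), iseg = unlist(out_s), w = unlist(out_w),
       npts = npts)
}

#' Segments of each compartment inside one REV
#'
#' @param nw a [vascular_network()] with compartments assigned.
#' @param X centre of the REV, mm (3-vector).
#' @param rev a [rev_spec()].
#' @param comp per-segment compartment indices (from
#'   [assign_compartments()]).
#' @return a list with one element per compartment, each a data frame of
#'   `segment` (row index into the segment table) and `effective_length`
#'   (mm). Blocked segments are never included.
#' @export
rev_members <- function(nw, X, rev, comp) {
  mem <- rev_membership(nw, matrix(X, 1, 3), rev)
  nc <- max(comp)
  lapply(seq_len(nc), function(i) {
    sel <- mem$iseg[comp[mem$iseg] == i]
    data.frame(segment = sel,
               effective_length = mem$w[comp[mem$iseg] == i])
  })
}

# sparse accumulation helper: sums val over (ipt, compartment-of-segment)
rev_accumulate <- function(mem, comp, val, nc) {
  as.matrix(Matrix::sparseMatrix(
    i = mem$ipt, j = comp[mem$iseg], x = val,
    dims = c(mem$npts, nc)))
}

#' Reference porosity field per compartment
#'
#' `phi0_i(X) = sum_j pi r_j^2 l_j / V_R` over the compartment-`i` segments
#' inside the REV centred at `X`; empty REVs give 0.
#'
#' @inheritParams rev_members
#' @param points M x 3 evaluation points, mm.
#' @param mem optional precomputed membership from an internal call;
#'   computed from `points` when omitted.
#' @return M x nc matrix of porosities.
#' @export
porosity_field <- function(nw, comp, points, rev, mem = NULL) {
  if (is.null(mem)) mem <- rev_membership(nw, points, rev)
  nc <- max(comp)
  if (length(mem$ipt) == 0) return(matrix(0, mem$npts, nc))
  val <- pi * nw$segments$radius[mem$iseg]^2 * mem$w
  rev_accumulate(mem, comp, val, nc) / rev$volume
}

#' Permeability tensor field per compartment (Models I-III)
#'
#' Model I (heterogeneous, anisotropic):
#' `K_i(X) = sum_j pi r_j^4 l_j (t_j x t_j) / (8 mu V_R)` over the REV
#' members, with `t_j` the unit segment direction. Model II replaces
#' `t_j x t_j` by the identity (heterogeneous, isotropic). Model III sums
#' over all compartment segments in the whole domain and divides by the
#' domain volume `V_T` (homogeneous, isotropic).
#'
#' @inheritParams porosity_field
#' @param model `"I"`, `"II"` or `"III"`.
#' @param mu blood viscosity, Pa s.
#' @param V_T total domain volume, mm^3 (required for Model III).
#' @return a list of length `nc`; element `i` is an M x 9 matrix of
#'   tensors in column-major 3 x 3 layout (Model III rows are identical).
#' @export
permeability_field <- function(nw, comp, points, rev, model = c("I", "II", "III"),
                               mu = 0.004, V_T = NULL, mem = NULL) {
  model <- match.arg(model)
  nc <- max(comp)
  points <- matrix(as.numeric(points), ncol = 3)
  npts <- nrow(points)
  dirs <- network_directions(nw)
  r4 <- nw$segments$radius^4
  if (model == "III") {
    if (is.null(V_T)) stop("Model III requires the domain volume V_T")
    live <- which(!nw$segments$blocked)
    len <- network_lengths(nw)
    out <- vector("list", nc)
    for (i in seq_len(nc)) {
      sel <- live[comp[live] == i]
      kscal <- sum(pi * r4[sel] * len[sel]) / (8 * mu * V_T)
      K <- matrix(0, npts, 9)
      K[, c(1, 5, 9)] <- kscal
      out[[i]] <- K
    }
    return(out)
  }
  if (is.null(mem)) mem <- rev_membership(nw, points, rev)
  base <- pi * r4[mem$iseg] * mem$w / (8 * mu * rev$volume)
  out <- vector("list", nc)
  for (i in seq_len(nc)) out[[i]] <- matrix(0, npts, 9)
  if (length(mem$ipt) == 0) return(out)
  tj <- dirs[mem$iseg, , drop = FALSE]
  comp_mem <- comp[mem$iseg]
  for (i in seq_len(nc)) {
    sel <- comp_mem == i
    if (!any(sel)) next
    ip <- mem$ipt[sel]; b <- base[sel]; t_ <- tj[sel, , drop = FALSE]
    acc <- function(v) as.numeric(Matrix::sparseMatrix(
      i = ip, j = rep(1L, length(ip)), x = v, dims = c(npts, 1)))
    if (model == "I") {
      K <- out[[i]]
      K[, 1] <- acc(b * t_[, 1] * t_[, 1])
      K[, 5] <- acc(b * t_[, 2] * t_[, 2])
      K[, 9] <- acc(b * t_[, 3] * t_[, 3])
      K[, 2] <- K[, 4] <- acc(b * t_[, 1] * t_[, 2])
      K[, 3] <- K[, 7] <- acc(b * t_[, 1] * t_[, 3])
      K[, 6] <- K[, 8] <- acc(b * t_[, 2] * t_[, 3])
      out[[i]] <- K
    } else {
      s <- acc(b)
      out[[i]][, c(1, 5, 9)] <- s
    }
  }
  out
}

# volume-weighted mean Poiseuille pressure per (point, compartment);
# normalization "mean" divides by the compartment vessel volume in the REV
# (pressure units); "printed" divides by V_R.
rev_mean_pressure <- function(nw, flow, comp, mem, nc, rev,
                              normalization = "mean") {
  r2l <- pi * nw$segments$radius[mem$iseg]^2 * mem$w
  num <- rev_accumulate(mem, comp, r2l * flow$p_seg_mean[mem$iseg], nc)
  if (normalization == "printed") return(num / rev$volume)
  den <- rev_accumulate(mem, comp, r2l, nc)
  pbar <- num / den
  pbar[den == 0] <- NA_real_
  pbar
}

# all inter-compartment junctions of the live tree:
# parent segment in compartment k feeds child segment in compartment i
network_junctions <- function(nw, comp) {
  pidx <- network_parent_index(nw)
  live <- !nw$segments$blocked
  child <- which(!is.na(pidx) & live & live[ifelse(is.na(pidx), 1L, pidx)])
  parent <- pidx[child]
  sel <- comp[parent] != comp[child]
  data.frame(parent = parent[sel], child = child[sel],
             k = comp[parent[sel]], i = comp[child[sel]])
}

# ordered compartment pairs (k < i)
compartment_pairs <- function(nc) {
  kp <- which(upper.tri(matrix(0, nc, nc)), arr.ind = TRUE)
  data.frame(k = kp[, 1], i = kp[, 2])
}

#' Inter-compartment coupling constant field
#'
#' For Models I and II the coupling constant between compartments `k` and
#' `i` at a point `X` is `beta = Q_ki / (V_R (pbar_k - pbar_i))`, where
#' `Q_ki` is the summed Poiseuille flow through junctions whose parent
#' segment (compartment `k`) and child segment (compartment `i`) are both
#' REV members, and `pbar` are the volume-weighted mean segment pressures
#' in the REV. For Model III a single uniform value is used, built from
#' the domain-total junction flow and domain-averaged pressures. Negative
#' or undefined values (zero pressure difference, empty REV) are clamped
#' to 0 with a warning.
#'
#' @inheritParams porosity_field
#' @param flow a [solve_poiseuille()] solution.
#' @param model `"I"`, `"II"` (heterogeneous) or `"III"` (uniform).
#' @param V_T domain volume, mm^3 (Model III).
#' @param normalization `"mean"` (volume-weighted mean pressures; default)
#'   or `"printed"` (weighted sums divided by `V_R`).
#' @return M x npair matrix, (Pa s)^-1, with `attr(, "pairs")` the data
#'   frame of compartment pairs `(k, i)`; `beta_ki = beta_ik` by
#'   construction.
#' @export
coupling_field <- function(nw, flow, comp, points, rev,
                           model = c("I", "II", "III"), V_T = NULL,
                           normalization = c("mean", "printed"),
                           mem = NULL) {
  model <- match.arg(model)
  normalization <- match.arg(normalization)
  nc <- max(comp)
  points <- matrix(as.numeric(points), ncol = 3)
  npts <- nrow(points)
  pairs <- compartment_pairs(nc)
  beta <- matrix(0, npts, nrow(pairs))
  jun <- network_junctions(nw, comp)

  if (model == "III") {
    live <- which(!nw$segments$blocked)
    len <- network_lengths(nw)
    r2l <- pi * nw$segments$radius[live]^2 * len[live]
    if (is.null(V_T)) stop("Model III requires the domain volume V_T")
    for (pr in seq_len(nrow(pairs))) {
      k <- pairs$k[pr]; i <- pairs$i[pr]
      sel <- (jun$k == k & jun$i == i) | (jun$k == i & jun$i == k)
      Qtot <- sum(flow$q[jun$child[sel]])
      if (Qtot == 0) next
      if (normalization == "mean") {
        pk <- sum(r2l[comp[live] == k] * flow$p_seg_mean[live][comp[live] == k]) /
              sum(r2l[comp[live] == k])
        pi_ <- sum(r2l[comp[live] == i] * flow$p_seg_mean[live][comp[live] == i]) /
               sum(r2l[comp[live] == i])
        denom <- V_T * (pk - pi_)
      } else {
        pk <- sum(r2l[comp[live] == k] * flow$p_seg_mean[live][comp[live] == k])
        pi_ <- sum(r2l[comp[live] == i] * flow$p_seg_mean[live][comp[live] == i])
        denom <- pk - pi_
      }
      b <- if (abs(denom) > 0) Qtot / denom else 0
      if (b < 0) { warning("negative uniform coupling clamped to 0"); b <- 0 }
      beta[, pr] <- b
    }
    attr(beta, "pairs") <- pairs
    return(beta)
  }

  if (is.null(mem)) mem <- rev_membership(nw, points, rev)
  if (length(mem$ipt) == 0 || nrow(jun) == 0) {
    attr(beta, "pairs") <- pairs
    return(beta)
  }
  pbar <- rev_mean_pressure(nw, flow, comp, mem, nc, rev, normalization)
  # sparse membership indicator for junction end-segments
  B <- Matrix::sparseMatrix(i = mem$ipt, j = mem$iseg, x = 1,
                            dims = c(npts, nrow(nw$segments)))
  B@x[] <- 1   # indicator regardless of effective length
  n_clamped <- 0L
  for (pr in seq_len(nrow(pairs))) {
    k <- pairs$k[pr]; i <- pairs$i[pr]
    sel <- which((jun$k == k & jun$i == i) | (jun$k == i & jun$i == k))
    if (length(sel) == 0) next
    both <- B[, jun$parent[sel], drop = FALSE] * B[, jun$child[sel], drop = FALSE]
    Q <- as.numeric(both %*% flow$q[jun$child[sel]])
    dp <- pbar[, k] - pbar[, i]
    b <- ifelse(Q > 0 & !is.na(dp) & abs(dp) > 0, Q / (rev$volume * dp), 0)
    n_clamped <- n_clamped + sum(b < 0) + sum(Q > 0 & (is.na(dp) | dp == 0))
    b[b < 0] <- 0
    beta[, pr] <- b
  }
  if (n_clamped > 0)
    warning(n_clamped, " negative/undefined coupling values clamped to 0")
  attr(beta, "pairs") <- pairs
  beta
}

#' Boundary fields: first-compartment pressure and terminal sink
#'
#' `p1_bar(X)` is the volume-weighted mean Poiseuille pressure of the
#' compartment-1 segments in the REV (the prescribed pore pressure of the
#' first compartment); `NA` where the REV holds no compartment-1 vessel.
#' `S_ext_nc(X) = -(1/V_R) sum Q_t` over the unblocked terminal segments
#' inside the REV: a volumetric sink (s^-1) that carries the terminal
#' outflow out of the last compartment, so that the continuum mass budget
#' closes against the network inlet flow.
#'
#' @inheritParams coupling_field
#' @return list with numeric vectors `p1_bar` (Pa) and `S_ext` (s^-1).
#' @export
boundary_fields <- function(nw, flow, comp, points, rev,
                            normalization = c("mean", "printed"),
                            mem = NULL) {
  normalization <- match.arg(normalization)
  nc <- max(comp)
  points <- matrix(as.numeric(points), ncol = 3)
  if (is.null(mem)) mem <- rev_membership(nw, points, rev)
  if (length(mem$ipt) == 0)
    return(list(p1_bar = rep(NA_real_, nrow(points)),
                S_ext = rep(0, nrow(points))))
  pbar <- rev_mean_pressure(nw, flow, comp, mem, nc, rev, normalization)
  term <- network_is_terminal(nw) & !nw$segments$blocked
  sel <- term[mem$iseg]
  S_ext <- -as.numeric(Matrix::sparseMatrix(
    i = mem$ipt[sel], j = rep(1L, sum(sel)), x = flow$q[mem$iseg[sel]],
    dims = c(mem$npts, 1))) / rev$volume
  list(p1_bar = pbar[, 1], S_ext = S_ext)
}
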