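# Shared helpers: small deterministic objects and independent oracles.

# dense Poiseuille oracle: build the nodal conductance system as a dense
# matrix straight from the segment table and solve with base R
dense_poiseuille_oracle <- function(nw, bcs) {
  seg <- nw$segments
  n <- nrow(seg)
  pidx <- match(seg$parent_id, seg$id)
  prox <- ifelse(is.na(pidx), 1L, pidx + 1L)
  dist <- seq_len(n) + 1L
  len <- sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2 + (seg$z1 - seg$z0)^2)
  g <- pi * seg$radius^4 / (8 * bcs$mu * len)
  nn <- n + 1L
  L <- matrix(0, nn, nn)
  for (k in seq_len(n)) {
    a <- prox[k]; b <- dist[k]
    L[a, a] <- L[a, a] + g[k]; L[b, b] <- L[b, b] + g[k]
    L[a, b] <- L[a, b] - g[k]; L[b, a] <- L[b, a] - g[k]
  }
  has_child <- seq_len(n) %in% pidx[!is.na(pidx)]
  fixed <- c(1L, dist[!has_child])
  pfix <- c(bcs$pin, rep(bcs$pout, sum(!has_child)))
  free <- setdiff(seq_len(nn), fixed)
  p <- numeric(nn)
  p[fixed] <- pfix
  if (length(free) > 0)
    p[free] <- solve(L[free, free], -L[free, fixed, drop = FALSE] %*% pfix)
  list(p_node = p, q = g * (p[prox] - p[dist]))
}

# exact optimal contiguous partition of sorted (zeta, radius) data into k
# intervals minimizing total within-interval SSE, by dynamic programming
dp_partition_sse <- function(zeta, radius, k) {
  ord <- order(zeta)
  r <- radius[ord]
  z <- zeta[ord]
  # merge ties in zeta (they cannot be separated by any threshold)
  grp <- cumsum(c(1, diff(z) > 0))
  n <- max(grp)
  cnt <- tabulate(grp, n)
  s1 <- tapply(r, grp, sum)
  s2 <- tapply(r^2, grp, sum)
  cs0 <- c(0, cumsum(cnt)); cs1 <- c(0, cumsum(s1)); cs2 <- c(0, cumsum(s2))
  sse <- function(a, b) {  # groups a..b (1-based, inclusive)
    m <- cs0[b + 1] - cs0[a]
    s <- cs1[b + 1] - cs1[a]
    q <- cs2[b + 1] - cs2[a]
    q - s^2 / m
  }
  if (n < k) stop("not enough distinct zeta values")
  best <- matrix(Inf, k, n)
  cut <- matrix(NA_integer_, k, n)
  for (j in 1:n) best[1, j] <- sse(1, j)
  if (k > 1) for (kk in 2:k) for (j in kk:n) {
    for (t in (kk - 1):(j - 1)) {
      v <- best[kk - 1, t] + sse(t + 1, j)
      if (v < best[kk, j]) { best[kk, j] <- v; cut[kk, j] <- t }
    }
  }
  # recover the cut positions in zeta terms
  cuts <- integer(0)
  j <- n
  for (kk in k:2) { t <- cut[kk, j]; cuts <- c(t, cuts); j <- t }
  zu <- tapply(z, grp, max)
  zlo <- tapply(z, grp, min)
  list(sse = best[k, n],
       cut_zeta = (zu[cuts] + zlo[cuts + 1]) / 2)
}

# total within-compartment SSE of radii for a given scheme
scheme_sse <- function(zeta, radius, scheme) {
  comp <- assign_compartments(
    structure(list(), class = "vascular_network"), scheme, zeta = zeta)
  sum(tapply(radius, comp, function(x) sum((x - mean(x))^2)))
}

# small synthetic porous-fields object for FEM tests (no network needed)
synthetic_fields <- function(mesh, nc = 3L, seed = 42,
                             k_scales = c(1e-3, 1e-5, 1e-7),
                             beta_scales = c(1e-4, 1e-6, 1e-5),
                             p1 = 12000, sink = -0.02) {
  set.seed(seed)
  NE <- nrow(mesh$tets); NN <- nrow(mesh$nodes)
  mkK <- function(s) { K <- matrix(0, NE, 9); K[, c(1, 5, 9)] <- s; K }
  pairs <- compartment_pairs_public(nc)
  phi <- cbind(rep(0.02, NE),
               matrix(0.002 + 0.002 * runif(NE * (nc - 1)), NE, nc - 1))
  phi_node <- cbind(rep(0.02, NN),
                    matrix(0.002 + 0.002 * runif(NN * (nc - 1)), NN, nc - 1))
  beta <- sapply(seq_len(nrow(pairs)), function(i)
    beta_scales[((i - 1) %% length(beta_scales)) + 1] * runif(NE))
  structure(list(
    phi = phi, phi_node = phi_node,
    K = lapply(seq_len(nc), function(i) mkK(k_scales[((i - 1) %% 3) + 1])),
    beta = beta, pairs = pairs,
    p1_bar = p1 * (0.8 + 0.4 * runif(NE)),
    pbar = cbind(p1, matrix(5000 * runif(NE * (nc - 1)), NE, nc - 1)),
    pbar_node = cbind(p1, matrix(5000 * runif(NN * (nc - 1)), NN, nc - 1)),
    S_ext = sink * runif(NE),
    nc = as.integer(nc), model = "II", rev = rev_spec(5), mu = 0.004,
    vol = mesh$vol, points = mesh$centroid, q_inlet = 1,
    comp = NULL, normalization = "mean"
  ), class = "porous_fields")
}

compartment_pairs_public <- function(nc) {
  kp <- which(upper.tri(matrix(0, nc, nc)), arr.ind = TRUE)
  data.frame(k = kp[, 1], i = kp[, 2])
}
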