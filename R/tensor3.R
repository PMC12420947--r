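# Vectorized 3x3 tensor algebra over element batches.
#
# A batch of n 3x3 matrices is stored as an n x 9 numeric matrix in
# column-major component order: [11, 21, 31, 12, 22, 32, 13, 23, 33].
# All helpers are internal; they let the FEM assembly and homogenization
# code operate on whole element sets without R-level loops.

t3_index <- function(i, j) (j - 1L) * 3L + i

t3_identity <- function(n) {
  out <- matrix(0, n, 9)
  out[, c(1, 5, 9)] <- 1
  out
}

t3_from_matrix <- function(A, n = 1L) {
  matrix(rep(as.numeric(A), each = n), n, 9)
}

t3_transpose <- function(A) A[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]

t3_trace <- function(A) A[, 1] + A[, 5] + A[, 9]

# C = A %*% B for each row
t3_mul <- function(A, B) {
  out <- matrix(0, nrow(A), 9)
  for (i in 1:3) for (j in 1:3) {
    out[, t3_index(i, j)] <-
      A[, t3_index(i, 1)] * B[, t3_index(1, j)] +
      A[, t3_index(i, 2)] * B[, t3_index(2, j)] +
      A[, t3_index(i, 3)] * B[, t3_index(3, j)]
  }
  out
}

# y = A %*% v for each row; v is n x 3, returns n x 3
t3_matvec <- function(A, v) {
  cbind(
    A[, 1] * v[, 1] + A[, 4] * v[, 2] + A[, 7] * v[, 3],
    A[, 2] * v[, 1] + A[, 5] * v[, 2] + A[, 8] * v[, 3],
    A[, 3] * v[, 1] + A[, 6] * v[, 2] + A[, 9] * v[, 3]
  )
}

t3_det <- function(A) {
  A[, 1] * (A[, 5] * A[, 9] - A[, 8] * A[, 6]) -
  A[, 4] * (A[, 2] * A[, 9] - A[, 8] * A[, 3]) +
  A[, 7] * (A[, 2] * A[, 6] - A[, 5] * A[, 3])
}

# closed-form inverse; caller guarantees det != 0
t3_inv <- function(A, det = NULL) {
  if (is.null(det)) det <- t3_det(A)
  out <- matrix(0, nrow(A), 9)
  out[, 1] <- (A[, 5] * A[, 9] - A[, 8] * A[, 6])
  out[, 2] <- -(A[, 2] * A[, 9] - A[, 8] * A[, 3])
  out[, 3] <- (A[, 2] * A[, 6] - A[, 5] * A[, 3])
  out[, 4] <- -(A[, 4] * A[, 9] - A[, 7] * A[, 6])
  out[, 5] <- (A[, 1] * A[, 9] - A[, 7] * A[, 3])
  out[, 6] <- -(A[, 1] * A[, 6] - A[, 4] * A[, 3])
  out[, 7] <- (A[, 4] * A[, 8] - A[, 7] * A[, 5])
  out[, 8] <- -(A[, 1] * A[, 8] - A[, 7] * A[, 2])
  out[, 9] <- (A[, 1] * A[, 5] - A[, 4] * A[, 2])
  out / det
}

# outer product per row: u, v are n x 3; returns n x 9 with [i,j] = u_i v_j
t3_outer <- function(u, v) {
  cbind(u[, 1] * v[, 1], u[, 2] * v[, 1], u[, 3] * v[, 1],
        u[, 1] * v[, 2], u[, 2] * v[, 2], u[, 3] * v[, 2],
        u[, 1] * v[, 3], u[, 2] * v[, 3], u[, 3] * v[, 3])
}

# row-wise dot product of n x 3 matrices
t3_dot <- function(u, v) u[, 1] * v[, 1] + u[, 2] * v[, 2] + u[, 3] * v[, 3]

# extract row i of each matrix in the batch (n x 3)
t3_row <- function(A, i) A[, t3_index(i, 1:3), drop = FALSE]

# extract column j of each matrix in the batch (n x 3)
t3_col <- function(A, j) A[, t3_index(1:3, j), drop = FALSE]
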