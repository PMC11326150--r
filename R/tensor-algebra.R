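# Vectorised 3x3 tensor algebra on N x 9 matrices.
#
# A row holds one 3x3 tensor in R's column-major order:
#   cols 1:3 = first column (T11, T21, T31),
#   cols 4:6 = second column, cols 7:9 = third column,
# so component (i, j) sits at column i + 3*(j - 1). All operations are
# elementwise over rows, which keeps the voxelwise mechanics loop-free.

T9_IDENTITY <- c(1, 0, 0, 0, 1, 0, 0, 0, 1)

t9_index <- function(i, j) i + 3L * (j - 1L)

t9_transpose <- function(A) A[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]

t9_matmul <- function(A, B) {
  C <- matrix(NA_real_, nrow(A), 9)
  for (i in 1:3) for (j in 1:3) {
    C[, t9_index(i, j)] <-
      A[, t9_index(i, 1)] * B[, t9_index(1, j)] +
      A[, t9_index(i, 2)] * B[, t9_index(2, j)] +
      A[, t9_index(i, 3)] * B[, t9_index(3, j)]
  }
  C
}

t9_det <- function(A) {
  A[, 1] * (A[, 5] * A[, 9] - A[, 6] * A[, 8]) -
  A[, 4] * (A[, 2] * A[, 9] - A[, 3] * A[, 8]) +
  A[, 7] * (A[, 2] * A[, 6] - A[, 3] * A[, 5])
}

# Inverse via the adjugate; rows with |det| <= det_floor come back NaN.
t9_inv <- function(A, det_floor = 0) {
  d <- t9_det(A)
  bad <- !is.finite(d) | abs(d) <= det_floor
  d[bad] <- NA_real_
  Inv <- matrix(NA_real_, nrow(A), 9)
  Inv[, 1] <- (A[, 5] * A[, 9] - A[, 6] * A[, 8]) / d
  Inv[, 2] <- (A[, 3] * A[, 8] - A[, 2] * A[, 9]) / d
  Inv[, 3] <- (A[, 2] * A[, 6] - A[, 3] * A[, 5]) / d
  Inv[, 4] <- (A[, 6] * A[, 7] - A[, 4] * A[, 9]) / d
  Inv[, 5] <- (A[, 1] * A[, 9] - A[, 3] * A[, 7]) / d
  Inv[, 6] <- (A[, 3] * A[, 4] - A[, 1] * A[, 6]) / d
  Inv[, 7] <- (A[, 4] * A[, 8] - A[, 5] * A[, 7]) / d
  Inv[, 8] <- (A[, 2] * A[, 7] - A[, 1] * A[, 8]) / d
  Inv[, 9] <- (A[, 1] * A[, 5] - A[, 2] * A[, 4]) / d
  Inv[bad, ] <- NA_real_
  Inv
}

t9_trace <- function(A) A[, 1] + A[, 5] + A[, 9]

# Deviatoric part: A - tr(A)/3 * I
t9_dev <- function(A) {
  p <- t9_trace(A) / 3
  A[, c(1, 5, 9)] <- A[, c(1, 5, 9)] - p
  A
}

# Double contraction A : B = sum_ij A_ij B_ij
t9_ddot <- function(A, B) rowSums(A * B)

t9_frobenius <- function(A) sqrt(rowSums(A^2))

# Identity matrix replicated over n rows.
t9_eye <- function(n) matrix(T9_IDENTITY, n, 9, byrow = TRUE)

# Max |A - A^T| per row; 0 for exactly symmetric tensors.
t9_asymmetry <- function(A) {
  m <- abs(A - t9_transpose(A))
  do.call(pmax, c(as.data.frame(m), na.rm = FALSE))
}
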