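# Independent oracles used across the suite. These deliberately avoid the
# package's vectorised tensor code paths: plain 3x3 base-R linear algebra
# and numerical differentiation only.

# Mooney-Rivlin strain energy (kPa) for one 3x3 F, straight from the
# constitutive definition.
mr_energy <- function(F, G, K) {
  J <- det(F)
  I1bar <- J^(-2 / 3) * sum(diag(t(F) %*% F))
  G / 2 * (I1bar - 3) + K * ((J^2 - 1) / 4 - log(J) / 2)
}

# Cauchy stress by central-difference differentiation of the energy:
# sigma = (1/J) (dW/dF) F^T, with dW/dF_ij estimated numerically.
numerical_cauchy <- function(F, G, K, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (mr_energy(Fp, G, K) - mr_energy(Fm, G, K)) / (2 * h)
  }
  P %*% t(F) / det(F)
}

# Isotropic linear-elastic stress from a (small) displacement gradient:
# sigma = 2 mu dev(eps) + K tr(eps) I, eps = sym(gradU).
linear_elastic_stress <- function(gradU, mu, K) {
  eps <- (gradU + t(gradU)) / 2
  tr <- sum(diag(eps))
  2 * mu * (eps - tr / 3 * diag(3)) + K * tr * diag(3)
}

# Random deformation gradients with J confined to [Jmin, Jmax]: a random
# perturbation of the identity rescaled to a uniformly drawn determinant.
random_F <- function(n, Jmin = 0.9, Jmax = 1.1, spread = 0.1) {
  lapply(seq_len(n), function(i) {
    repeat {
      A <- diag(3) + matrix(stats::rnorm(9, sd = spread), 3, 3)
      if (det(A) > 0.2) break
    }
    Jt <- stats::runif(1, Jmin, Jmax)
    A * (Jt / det(A))^(1 / 3)
  })
}

# Pack a list of 3x3 matrices into a 1x1x1xN-frame... no: into an
# (n,1,1,1,9) tensor-field array is awkward; instead embed n tensors as a
# (n,1,1,1,9) grid so vectorised package code sees them as voxels.
tensors_as_field <- function(mats, quantity = "F", symmetric = FALSE) {
  n <- length(mats)
  vals <- array(NA_real_, c(n, 1, 1, 1, 9))
  for (i in seq_len(n)) vals[i, 1, 1, 1, ] <- as.vector(mats[[i]])
  geom <- grid_geometry(c(n, 1, 1), spacing = c(1, 1, 1), frames = 1L)
  tensor_field(vals, geom, quantity = quantity, symmetric = symmetric)
}

# Uniform-label volume covering a whole grid with one tissue class.
uniform_labels <- function(geom, label = 3L, lookup = NULL) {
  label_volume(array(label, geom$shape),
               grid_geometry(geom$shape, affine = geom$affine, frames = 1L),
               lookup = lookup)
}

# Rotation matrix about z by `deg` degrees.
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# Extract interior voxels (margin m from every face) of a tensor field as
# an N x 9 matrix, one frame.
interior_tensors <- function(tf, frame = 1L, margin = 2L) {
  sh <- tf$geometry$shape
  ix <- (1 + margin):(sh[1] - margin)
  iy <- (1 + margin):(sh[2] - margin)
  iz <- (1 + margin):(sh[3] - margin)
  matrix(tf$values[ix, iy, iz, frame, , drop = FALSE], ncol = 9)
}

interior_truth <- function(arr, frame = 1L, margin = 2L) {
  sh <- dim(arr)[1:3]
  ix <- (1 + margin):(sh[1] - margin)
  iy <- (1 + margin):(sh[2] - margin)
  iz <- (1 + margin):(sh[3] - margin)
  matrix(arr[ix, iy, iz, frame, , drop = FALSE], ncol = 9)
}
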