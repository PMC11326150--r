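# Finite-strain mechanics on the voxel grid.
#
# The displacement field U(x, t) is Eulerian: it gives, at each point x of
# the current (deformed) grid, the displacement from the reference
# configuration (diastole). Under that convention the deformation gradient
# follows from F^-1 = I - grad U, so F = (I - grad U)^-1 per voxel, and
# everything downstream (strain, Mooney-Rivlin stress, energy) is closed
# form in F.

# NA-padded shift of a 3D array along one axis by +-1.
shift3 <- function(a, axis, by) {
  d <- dim(a)
  out <- array(NA_real_, d)
  src <- dst <- lapply(d, seq_len)
  n <- d[axis]
  if (by == 1L) { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
  else          { dst[[axis]] <- 2:n;       src[[axis]] <- 1:(n - 1) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# d/dx_axis of one 3D component: second-order central where both
# neighbours are finite, first-order one-sided at mask boundaries,
# NaN where the voxel itself or all neighbours are invalid.
axis_gradient <- function(u, axis, h) {
  up <- shift3(u, axis, 1L)   # value at index + 1
  dn <- shift3(u, axis, -1L)  # value at index - 1
  f0 <- is.finite(u); fu <- is.finite(up); fd <- is.finite(dn)
  g <- array(NaN, dim(u))
  ctr <- f0 & fu & fd
  g[ctr] <- (up[ctr] - dn[ctr]) / (2 * h)
  fwd <- f0 & fu & !fd
  g[fwd] <- (up[fwd] - u[fwd]) / h
  bwd <- f0 & !fu & fd
  g[bwd] <- (u[bwd] - dn[bwd]) / h
  g
}

#' Spatial displacement gradient
#'
#' Computes (grad U)_ij = du_i/dx_j on the voxel grid with physical
#' spacing: second-order central differences in the interior, first-order
#' one-sided differences at mask boundaries, NaN where no finite
#' neighbour exists along an axis. Central differences are exact for
#' affine displacement fields.
#'
#' @param field a [displacement_field()] (typically masked).
#' @param frames frame indices to evaluate (default all).
#' @return A [tensor_field()] with quantity `"gradU"`.
#' @export
displacement_gradient <- function(field, frames = NULL) {
  geom <- field$geometry
  if (sum(is.finite(field$data[, , , 1, 1])) <= 1L &&
      prod(geom$shape) > 1L)
    stop("mask contains a single voxel: no gradient computable")
  if (is.null(frames)) frames <- seq_len(geom$frames)
  h <- geom$spacing
  vals <- array(NaN, c(geom$shape, length(frames), 9L))
  for (f_i in seq_along(frames)) {
    t_k <- frames[f_i]
    for (i in 1:3) {
      u <- field$data[, , , t_k, i]
      for (j in 1:3)
        vals[, , , f_i, t9_index(i, j)] <- axis_gradient(u, j, h[j])
    }
  }
  out_geom <- grid_geometry(geom$shape, affine = geom$affine,
                            frames = length(frames),
                            frame_interval = geom$frame_interval)
  tf <- tensor_field(vals, out_geom, quantity = "gradU")
  attr(tf, "frames_used") <- frames
  tf
}

#' Deformation gradient from the displacement gradient
#'
#' F = (I - grad U)^-1 per voxel. Voxels where det(I - grad U) is at or
#' below `det_floor`, or whose Frobenius-estimated condition number
#' exceeds `cond_ceiling`, are marked invalid (NaN) rather than raising an
#' error; their count is reported via the `n_degenerate` attribute.
#'
#' @param gradU a `"gradU"` [tensor_field()].
#' @param det_floor determinant floor (default 1e-8).
#' @param cond_ceiling condition-number ceiling (default 1e8).
#' @return A `"F"` [tensor_field()] with element `J` (det F array).
#' @export
deformation_gradient <- function(gradU, det_floor = 1e-8,
                                 cond_ceiling = 1e8) {
  A <- t9_eye(prod(dim(gradU$values)[1:4])) - tensor_as_matrix(gradU)
  detA <- t9_det(A)
  Finv_ok <- is.finite(detA) & detA > det_floor
  Fm <- t9_inv(A, det_floor = det_floor)
  Fm[!Finv_ok, ] <- NaN
  condA <- t9_frobenius(A) * t9_frobenius(Fm)
  bad_cond <- is.finite(condA) & condA > cond_ceiling
  Fm[bad_cond, ] <- NaN
  had_input <- rowSums(is.finite(A)) == 9L
  n_degenerate <- sum(had_input & (rowSums(is.finite(Fm)) != 9L))
  vals <- matrix_as_tensor(Fm, gradU$geometry)
  tf <- tensor_field(vals, gradU$geometry, quantity = "F")
  J <- 1 / detA
  J[rowSums(is.finite(Fm)) != 9L] <- NaN
  tf$J <- array(J, dim(gradU$values)[1:4])
  attr(tf, "n_degenerate") <- n_degenerate
  tf
}

#' Green-Lagrange strain
#'
#' The conventional definition is E = (F'F - I)/2 (`convention =
#' "standard"`, the default); `"paper"` drops the 1/2 factor, i.e.
#' E = F'F - I. Both vanish for rigid motion.
#'
#' @param F a `"F"` [tensor_field()].
#' @param convention `"standard"` or `"paper"`.
#' @return A symmetric `"E"` [tensor_field()].
#' @export
green_lagrange_strain <- function(F, convention = c("standard", "paper")) {
  convention <- match.arg(convention)
  Fm <- tensor_as_matrix(F)
  C <- t9_matmul(t9_transpose(Fm), Fm)
  E <- C - t9_eye(nrow(C))
  if (convention == "standard") E <- E / 2
  # enforce exact symmetry against rounding in the matmul
  E <- (E + t9_transpose(E)) / 2
  tf <- tensor_field(matrix_as_tensor(E, F$geometry), F$geometry,
                     quantity = "E", symmetric = TRUE)
  attr(tf, "convention") <- convention
  tf
}

#' Strain rate over the cardiac cycle
#'
#' Time derivative of the strain tensor by central differences with
#' periodic wrap-around (the cardiac cycle is periodic):
#' Edot(t_k) = (E(t_{k+1}) - E(t_{k-1})) / (2 dt), dt = frame interval.
#'
#' @param E a symmetric strain [tensor_field()] with at least 3 frames.
#' @param frame_interval seconds per frame; defaults to the field's
#'   geometry.
#' @return A symmetric `"E_rate"` [tensor_field()] in 1/s.
#' @export
strain_rate <- function(E, frame_interval = E$geometry$frame_interval) {
  nt <- E$geometry$frames
  if (nt < 3L) stop("strain rate needs at least 3 frames, got ", nt)
  nxt <- c(2:nt, 1L)
  prv <- c(nt, 1:(nt - 1L))
  vals <- (E$values[, , , nxt, , drop = FALSE] -
           E$values[, , , prv, , drop = FALSE]) / (2 * frame_interval)
  tensor_field(vals, E$geometry, quantity = "E_rate", symmetric = TRUE,
               units = "1/s")
}

# Shared constitutive ingredients: J, I1-bar, isochoric left Cauchy-Green.
mooney_rivlin_kinematics <- function(Fm) {
  J <- t9_det(Fm)
  B <- t9_matmul(Fm, t9_transpose(Fm))
  Jm23 <- J^(-2 / 3)
  list(J = J, Bbar = B * Jm23, I1bar = Jm23 * t9_trace(B))
}

#' Mooney-Rivlin strain energy density
#'
#' Compressible, isotropic form with the isochoric/volumetric split:
#' W = (G/2)(I1bar - 3) + K[(J^2 - 1)/4 - ln(J)/2], with
#' I1bar = J^(-2/3) tr(F'F). W = 0 at the stress-free reference F = I and
#' W >= 0 for all J > 0. Units kPa (= kJ/m^3) when G, K are in kPa.
#'
#' Each voxel takes (G, K) from its tissue class; CSF voxels are invalid
#' unless the material table includes CSF.
#'
#' @param F a `"F"` [tensor_field()].
#' @param material a [material_table()].
#' @param labels a [label_volume()] on the same grid.
#' @return A `"W"` [scalar_field()] in kPa.
#' @export
strain_energy_density <- function(F, material, labels) {
  if (!same_grid(F$geometry, labels$geometry))
    stop("label grid does not match tensor grid")
  Fm <- tensor_as_matrix(F)
  kin <- mooney_rivlin_kinematics(Fm)
  gk <- material_per_voxel(material, labels)
  nt <- F$geometry$frames
  G <- rep(gk$G, times = nt)
  K <- rep(gk$K, times = nt)
  W <- G / 2 * (kin$I1bar - 3) +
       K * ((kin$J^2 - 1) / 4 - log(kin$J) / 2)
  W[!is.finite(kin$J) | kin$J <= 0] <- NaN
  scalar_field(array(W, c(F$geometry$shape, nt)), F$geometry,
               quantity = "W", units = "kPa")
}

#' Mooney-Rivlin Cauchy stress
#'
#' Closed-form derivative of the strain energy, sigma =
#' (1/J) (dW/dF) F':
#' sigma = (G/J) dev(Bbar) + (K/2)(J - 1/J) I, with
#' Bbar = J^(-2/3) F F' and dev(A) = A - tr(A)/3 I. Symmetric, in kPa.
#' CSF voxels are invalid unless the material table includes CSF.
#'
#' @inheritParams strain_energy_density
#' @return A symmetric `"sigma"` [tensor_field()] in kPa.
#' @export
cauchy_stress <- function(F, material, labels) {
  if (!same_grid(F$geometry, labels$geometry))
    stop("label grid does not match tensor grid")
  Fm <- tensor_as_matrix(F)
  kin <- mooney_rivlin_kinematics(Fm)
  gk <- material_per_voxel(material, labels)
  nt <- F$geometry$frames
  G <- rep(gk$G, times = nt)
  K <- rep(gk$K, times = nt)
  sig <- t9_dev(kin$Bbar) * (G / kin$J)
  vol <- K / 2 * (kin$J - 1 / kin$J)
  sig[, c(1, 5, 9)] <- sig[, c(1, 5, 9)] + vol
  sig[!is.finite(kin$J) | kin$J <= 0, ] <- NaN
  sig <- (sig + t9_transpose(sig)) / 2
  tensor_field(matrix_as_tensor(sig, F$geometry), F$geometry,
               quantity = "sigma", symmetric = TRUE, units = "kPa")
}

#' Von Mises scalar of a symmetric tensor field
#'
#' Stress-like fields use sigma_vm = sqrt(3/2 dev(s):dev(s)); strain-like
#' fields use eps_vm = sqrt(2/3 dev(E):dev(E)). The kind is inferred from
#' the field's quantity (`sigma` -> stress; `E`, `E_rate` -> strain) and
#' can be overridden.
#'
#' @param field a symmetric [tensor_field()].
#' @param kind `"stress"` or `"strain"`; default inferred.
#' @return A [scalar_field()] in the field's units.
#' @export
von_mises <- function(field, kind = NULL) {
  if (!isTRUE(field$symmetric))
    stop("von Mises requires a symmetric tensor field")
  if (is.null(kind))
    kind <- if (field$quantity == "sigma") "stress" else "strain"
  kind <- match.arg(kind, c("stress", "strain"))
  m <- t9_dev(tensor_as_matrix(field))
  fac <- if (kind == "stress") 3 / 2 else 2 / 3
  v <- sqrt(fac * t9_ddot(m, m))
  qty <- switch(field$quantity, sigma = "vm_stress",
                E_rate = "vm_strain_rate", "vm_strain")
  scalar_field(array(v, dim(field$values)[1:4]), field$geometry,
               quantity = qty, units = field$units)
}
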