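test_that("displacement gradient is zero for zero fields and exact for affine fields", {
  ph <- make_phantom("zero", shape = c(8, 8, 8), n_t = 1)
  g0 <- displacement_gradient(ph$field)
  expect_true(all(g0$values == 0))

  # u_x = a x: central AND one-sided differences are exact for affine u
  a <- 0.07
  ph <- make_phantom("uniaxial_stretch", amplitude = a, shape = c(8, 8, 8),
                     n_t = 1)
  g <- displacement_gradient(ph$field)
  expect_equal(max(abs(g$values[, , , 1, 1] - a)), 0, tolerance = 1e-12)
  off <- g$values[, , , 1, -1]
  expect_equal(max(abs(off)), 0, tolerance = 1e-12)
})

test_that("gradient error is O(h^2): quartering under spacing halving", {
  err_at <- function(h) {
    n <- round(19.2 / h)  # fixed physical extent, varying resolution
    ph <- make_phantom("pulsatile_composite", amplitude = 0.05, n_t = 2,
                       shape = rep(n, 3), spacing = rep(h, 3))
    g <- displacement_gradient(ph$field, frames = 2)
    got <- interior_tensors(g, frame = 1, margin = 2)
    want <- interior_truth(ph$truth$gradU, frame = 2, margin = 2)
    max(abs(got - want))
  }
  e1 <- err_at(1.2)
  e2 <- err_at(0.6)
  expect_gt(e1 / e2, 3.5)  # second-order stencil: ratio ~4
})

test_that("gradient handles mask boundaries with one-sided differences", {
  # linear field masked to half the volume: still exact everywhere inside
  ph <- make_phantom("simple_shear", amplitude = 0.1, shape = c(8, 8, 8),
                     n_t = 1)
  lab <- array(0L, c(8, 8, 8)); lab[, 1:4, ] <- 3L
  mask <- label_volume(lab, grid_geometry(c(8, 8, 8),
                                          spacing = c(1.2, 1.2, 1.2)))
  f <- trim_to_mask(ph$field, mask)
  g <- displacement_gradient(f)
  inside <- g$values[, 1:4, , 1, 4]  # d u_x / d y
  expect_equal(max(abs(inside - 0.1)), 0, tolerance = 1e-12)
  expect_true(all(is.na(g$values[, 5:8, , 1, 4])))

  single <- array(NaN, c(8, 8, 8, 1, 3)); single[4, 4, 4, 1, ] <- 1
  sf <- displacement_field(single, grid_geometry(c(8, 8, 8), frames = 1))
  expect_error(displacement_gradient(sf), "single voxel")
})

test_that("deformation gradient inverts I - gradU with degeneracy guards", {
  geom <- grid_geometry(c(2, 2, 2))
  mk <- function(g9) {
    vals <- array(rep(g9, each = 8), c(2, 2, 2, 1, 9))
    tensor_field(vals, geom, quantity = "gradU")
  }
  # gradU = 0 -> F = I, J = 1
  Ftf <- deformation_gradient(mk(rep(0, 9)))
  expect_equal(matrix(Ftf$values[1, 1, 1, 1, ], 3, 3), diag(3))
  expect_equal(Ftf$J[1, 1, 1, 1], 1)

  # gradU = diag(0.1, 0, 0) -> F = diag(1/0.9, 1, 1)
  Ftf <- deformation_gradient(mk(c(0.1, 0, 0, 0, 0, 0, 0, 0, 0)))
  expect_equal(matrix(Ftf$values[1, 1, 1, 1, ], 3, 3),
               diag(c(1 / 0.9, 1, 1)), tolerance = 1e-14)
  expect_equal(Ftf$J[1, 1, 1, 1], 1 / 0.9, tolerance = 1e-14)

  # singular I - gradU: voxel invalidated, no error
  Ftf <- deformation_gradient(mk(as.vector(diag(3))))
  expect_true(all(!is.finite(Ftf$values)))
  expect_equal(attr(Ftf, "n_degenerate"), 8)
})

test_that("Green-Lagrange strain honours both conventions and rigid motion", {
  I3 <- diag(3)
  Fi <- tensors_as_field(list(I3, rot_z(17), diag(c(1.1, 1, 1))))
  Es <- green_lagrange_strain(Fi, "standard")
  Ep <- green_lagrange_strain(Fi, "paper")
  # F = I and F = R give E = 0 in both conventions
  for (E in list(Es, Ep)) {
    expect_equal(max(abs(E$values[1, 1, 1, 1, ])), 0, tolerance = 1e-14)
    expect_equal(max(abs(E$values[2, 1, 1, 1, ])), 0, tolerance = 1e-14)
  }
  # F = diag(1.1, 1, 1): E_xx = 0.105 standard, 0.21 as printed
  expect_equal(Es$values[3, 1, 1, 1, 1], 0.105, tolerance = 1e-14)
  expect_equal(Ep$values[3, 1, 1, 1, 1], 0.21, tolerance = 1e-14)
  expect_true(Es$symmetric)
})

test_that("strain rate is a periodic central difference in time", {
  n_t <- 32; T <- 1; c0 <- 0.02
  geom <- grid_geometry(c(2, 2, 2), frames = n_t, cycle_duration = T)
  tt <- (0:(n_t - 1)) / n_t * T
  vals <- array(0, c(2, 2, 2, n_t, 9))
  for (k in seq_len(n_t)) vals[, , , k, 1] <- c0 * sin(2 * pi * tt[k] / T)
  E <- tensor_field(vals, geom, quantity = "E", symmetric = TRUE)
  Ed <- strain_rate(E)
  want <- 2 * pi * c0 / T * cos(2 * pi * tt / T)
  got <- Ed$values[1, 1, 1, , 1]
  # periodic central difference of a sinusoid: exact shape, O(dt^2) scale
  expect_equal(got, want * sin(2 * pi / n_t) / (2 * pi / n_t),
               tolerance = 1e-12)
  expect_equal(got, want, tolerance = 1e-2)
  expect_equal(Ed$units, "1/s")

  # constant strain -> zero rate
  vals[] <- 0.3
  Ed0 <- strain_rate(tensor_field(vals, geom, quantity = "E",
                                  symmetric = TRUE))
  expect_true(all(Ed0$values == 0))

  g2 <- grid_geometry(c(2, 2, 2), frames = 2)
  E2 <- tensor_field(array(0, c(2, 2, 2, 2, 9)), g2, quantity = "E",
                     symmetric = TRUE)
  expect_error(strain_rate(E2), "at least 3 frames")
})

test_that("strain energy density matches closed forms per deformation mode", {
  geom <- grid_geometry(c(3, 1, 1))
  lab_wm <- label_volume(array(3L, c(3, 1, 1)), geom)
  mat <- material_table()
  G_wm <- 0.624; K_wm <- 5.00e4
  J <- 1.01; gam <- 0.1
  Fs <- tensors_as_field(list(
    diag(3),                         # reference
    J^(1 / 3) * diag(3),             # pure dilation
    matrix(c(1, 0, 0, gam, 1, 0, 0, 0, 1), 3, 3)))  # simple shear
  W <- strain_energy_density(Fs, mat, lab_wm)
  expect_equal(W$values[1, 1, 1, 1], 0)
  expect_equal(W$values[2, 1, 1, 1],
               K_wm * ((J^2 - 1) / 4 - log(J) / 2), tolerance = 1e-12)
  expect_equal(W$values[3, 1, 1, 1], G_wm / 2 * gam^2, tolerance = 1e-12)
  expect_equal(W$units, "kPa")
})

test_that("Cauchy stress matches closed forms and respects CSF exclusion", {
  geom <- grid_geometry(c(3, 1, 1))
  mat <- material_table()
  G_wm <- 0.624; K_wm <- 5.00e4
  J <- 1.01; gam <- 0.01
  Fs <- tensors_as_field(list(
    diag(3),
    J^(1 / 3) * diag(3),
    matrix(c(1, 0, 0, gam, 1, 0, 0, 0, 1), 3, 3)))
  lab_wm <- label_volume(array(3L, c(3, 1, 1)), geom)
  sig <- cauchy_stress(Fs, mat, lab_wm)
  # stress-free reference
  expect_equal(max(abs(sig$values[1, 1, 1, 1, ])), 0)
  # pure dilation: hydrostatic (K/2)(J - 1/J) I, zero off-diagonals
  s2 <- matrix(sig$values[2, 1, 1, 1, ], 3, 3)
  expect_equal(s2, K_wm / 2 * (J - 1 / J) * diag(3), tolerance = 1e-9)
  # simple shear: sigma_12 = G*gamma to first order
  s3 <- matrix(sig$values[3, 1, 1, 1, ], 3, 3)
  expect_equal(s3[1, 2], G_wm * gam, tolerance = G_wm * gam * 1e-3)
  expect_true(sig$symmetric)
  expect_equal(sig$units, "kPa")

  # CSF voxels invalid by default, valid when included
  lab_csf <- label_volume(array(1L, c(3, 1, 1)), geom)
  sig_csf <- cauchy_stress(Fs, mat, lab_csf)
  expect_true(all(!is.finite(sig_csf$values)))
  sig_csf_in <- cauchy_stress(Fs, material_table(include_csf = TRUE),
                              lab_csf)
  expect_true(all(is.finite(sig_csf_in$values)))

  # missing material entry for a present class errors
  mat_nogm <- material_table(data.frame(
    tissue_class = "WM", G_kPa = 0.624, K_kPa = 5e4))
  lab_gm <- label_volume(array(2L, c(3, 1, 1)), geom)
  expect_error(cauchy_stress(Fs, mat_nogm, lab_gm), "GM")
})

test_that("the closed-form stress equals the numerical energy derivative", {
  set.seed(99)
  mats <- random_F(60)
  Fi <- tensors_as_field(mats)
  geom <- Fi$geometry
  mat <- material_table()
  lab <- label_volume(array(3L, geom$shape), geom)
  sig <- cauchy_stress(Fi, mat, lab)
  for (i in seq(1, 60, by = 7)) {
    want <- numerical_cauchy(mats[[i]], G = 0.624, K = 5e4)
    got <- matrix(sig$values[i, 1, 1, 1, ], 3, 3)
    expect_equal(got, want,
                 tolerance = 1e-5 * max(1, max(abs(want))))
  }
})

test_that("strain energy is non-negative over random admissible F", {
  set.seed(123)
  mats <- random_F(300, Jmin = 0.85, Jmax = 1.15, spread = 0.15)
  Fi <- tensors_as_field(mats)
  lab <- label_volume(array(3L, Fi$geometry$shape), Fi$geometry)
  W <- strain_energy_density(Fi, material_table(), lab)
  expect_true(all(W$values > -1e-12))
})

test_that("von Mises scalars satisfy their closed forms", {
  p <- 3.3; s <- -1.7; tau <- 0.45
  mk <- function(m) tensors_as_field(list(m), quantity = "sigma",
                                     symmetric = TRUE)
  hydro <- von_mises(mk(p * diag(3)))
  expect_equal(hydro$values[1, 1, 1, 1], 0, tolerance = 1e-14)
  uni <- von_mises(mk(diag(c(s, 0, 0))))
  expect_equal(uni$values[1, 1, 1, 1], abs(s), tolerance = 1e-12)
  shear <- von_mises(mk(matrix(c(0, tau, 0, tau, 0, 0, 0, 0, 0), 3, 3)))
  expect_equal(shear$values[1, 1, 1, 1], sqrt(3) * tau, tolerance = 1e-12)

  # strain convention uses the 2/3 factor: uniaxial strain e -> e_vm = 2e/3...
  e <- 0.05
  Emat <- diag(c(e, 0, 0))
  ev <- von_mises(tensors_as_field(list(Emat), quantity = "E",
                                   symmetric = TRUE))
  dev_ <- Emat - sum(diag(Emat)) / 3 * diag(3)
  expect_equal(ev$values[1, 1, 1, 1],
               sqrt(2 / 3 * sum(dev_^2)), tolerance = 1e-12)

  gen <- tensors_as_field(list(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)))
  expect_error(von_mises(gen), "symmetric")
})

test_that("small-strain stress reduces to isotropic linear elasticity", {
  set.seed(21)
  for (rep in 1:5) {
    g <- matrix(rnorm(9), 3, 3)
    g <- g / max(abs(g)) * 1e-4   # ||gradU|| = 1e-4
    Fm <- solve(diag(3) - g)
    Fi <- tensors_as_field(list(Fm))
    lab <- label_volume(array(3L, Fi$geometry$shape), Fi$geometry)
    sig <- matrix(cauchy_stress(Fi, material_table(),
                                lab)$values[1, 1, 1, 1, ], 3, 3)
    want <- linear_elastic_stress(g, mu = 0.624, K = 5e4)
    expect_equal(sig, want, tolerance = 1e-2 * max(abs(want)))
  }
})

test_that("strain and von Mises fields are objective under rigid rotation", {
  ph <- make_phantom("rigid_rotation", amplitude = 5, shape = c(12, 12, 12),
                     n_t = 2)
  f <- trim_to_mask(ph$field, ph$labels)
  expect_gt(max(abs(f$data), na.rm = TRUE), 0)  # genuinely nonzero motion
  Ftf <- deformation_gradient(displacement_gradient(f))
  for (conv in c("standard", "paper")) {
    E <- green_lagrange_strain(Ftf, conv)
    expect_lt(max(abs(E$values), na.rm = TRUE), 1e-8)
  }
  sig <- cauchy_stress(Ftf, material_table(), ph$labels)
  vm <- von_mises(sig)
  expect_lt(max(vm$values, na.rm = TRUE), 1e-8)
})
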