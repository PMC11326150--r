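# Brute-force nearest-neighbour resampling oracle: per target voxel, loop.
nn_resample_oracle <- function(labels, M, target) {
  inv_src <- solve(labels$geometry$affine)
  inv_M <- solve(M)
  out <- array(0L, target$shape)
  for (k in 0:(target$shape[3] - 1))
    for (j in 0:(target$shape[2] - 1))
      for (i in 0:(target$shape[1] - 1)) {
        w <- target$affine %*% c(i, j, k, 1)
        s <- inv_src %*% (inv_M %*% w)
        idx <- floor(s[1:3] + 0.5)
        if (all(idx >= 0) && all(idx < labels$geometry$shape))
          out[i + 1, j + 1, k + 1] <-
            labels$labels[idx[1] + 1, idx[2] + 1, idx[3] + 1]
      }
  out
}

test_that("label resampling: identity affine on identical grids is a no-op", {
  ph <- make_phantom("zero", shape = c(10, 10, 10), n_t = 1)
  out <- resample_labels(ph$labels, diag(4), ph$labels$geometry)
  expect_identical(out$labels, ph$labels$labels)
})

test_that("2x upsampling a single-voxel label yields an 8-voxel block", {
  src_geom <- grid_geometry(c(4, 4, 4), spacing = c(2, 2, 2))
  lab <- array(0L, c(4, 4, 4)); lab[2, 2, 2] <- 3L
  src <- label_volume(lab, src_geom)
  tgt <- grid_geometry(c(8, 8, 8), spacing = c(1, 1, 1))
  out <- resample_labels(src, diag(4), tgt)
  expect_equal(sum(out$labels == 3L), 8)
  expect_identical(out$labels, nn_resample_oracle(src, diag(4), tgt))
})

test_that("resampling matches the brute-force oracle under a general affine", {
  set.seed(11)
  src_geom <- grid_geometry(c(6, 5, 4), spacing = c(1.5, 2, 2.5))
  src <- label_volume(array(sample(0:3, 120, TRUE), c(6, 5, 4)), src_geom)
  M <- diag(4); M[1:3, 4] <- c(1.1, -0.7, 0.4)  # world shift
  tgt_aff <- diag(c(1.2, 1.2, 1.2, 1)); tgt_aff[1:3, 4] <- c(-1, 0, 1)
  tgt <- grid_geometry(c(7, 7, 7), affine = tgt_aff)
  out <- resample_labels(src, M, tgt)
  expect_identical(out$labels, nn_resample_oracle(src, M, tgt))
  # no new labels created; outside-extent voxels are background
  expect_true(all(out$labels %in% c(0L, unique(as.vector(src$labels)))))
})

test_that("targets beyond the source extent become background", {
  src_geom <- grid_geometry(c(4, 4, 4), spacing = c(1, 1, 1))
  src <- label_volume(array(2L, c(4, 4, 4)), src_geom)
  far <- diag(4); far[1:3, 4] <- c(100, 0, 0)  # target shifted far away
  tgt <- grid_geometry(c(4, 4, 4), affine = far)
  out <- resample_labels(src, diag(4), tgt)
  expect_true(all(out$labels == 0L))
  expect_error(resample_labels(src, matrix(0, 4, 4), tgt), "singular")
})

test_that("masking sets exactly the outside voxels to NaN", {
  geom <- grid_geometry(c(6, 6, 6), frames = 2)
  set.seed(2)
  f <- displacement_field(array(rnorm(6^3 * 2 * 3), c(6, 6, 6, 2, 3)), geom)
  # half mask: x-index <= 3 inside
  lab <- array(0L, c(6, 6, 6)); lab[1:3, , ] <- 3L
  mask <- label_volume(lab, grid_geometry(c(6, 6, 6)))
  out <- trim_to_mask(f, mask)
  expect_equal(sum(!is.finite(out$data)), 3 * 6 * 6 * 2 * 3)
  expect_equal(out$data[1:3, , , , ], f$data[1:3, , , , ])
  expect_equal(attr(out, "bounding_box"), rbind(c(1, 1, 1), c(3, 6, 6)),
               ignore_attr = TRUE)

  full <- label_volume(array(1L, c(6, 6, 6)), grid_geometry(c(6, 6, 6)))
  expect_equal(trim_to_mask(f, full)$data, f$data)

  empty <- label_volume(array(0L, c(6, 6, 6)), grid_geometry(c(6, 6, 6)))
  expect_warning(out0 <- trim_to_mask(f, empty), "empty")
  expect_true(all(!is.finite(out0$data)))

  other <- label_volume(array(1L, c(5, 5, 5)), grid_geometry(c(5, 5, 5)))
  expect_error(trim_to_mask(f, other), "grid")
})

test_that("downscaling rescales the maximum displacement to the target", {
  ph <- make_phantom("uniaxial_stretch", amplitude = 0.02, n_t = 3)
  # force a known maximum of 4.675 mm
  mag <- brainstrain:::displacement_magnitude(ph$field)
  f <- ph$field
  f$data <- f$data * (4.675 / max(mag))
  ds <- downscale_displacement(f, pipeline_config())
  expect_equal(ds$scale_factor, 0.187 / 4.675)  # = 0.04
  newmax <- max(brainstrain:::displacement_magnitude(ds$field),
                na.rm = TRUE)
  expect_equal(newmax, 0.187, tolerance = 1e-12)

  # idempotent: a second application is the identity
  ds2 <- downscale_displacement(ds$field, pipeline_config())
  expect_equal(ds2$scale_factor, 1, tolerance = 1e-12)

  # component-max norm uses the largest |component| instead
  dsc <- downscale_displacement(f, pipeline_config(
    downscale_norm = "component_max"))
  expect_equal(max(abs(dsc$field$data), na.rm = TRUE), 0.187,
               tolerance = 1e-12)
  expect_true(dsc$scale_factor >= ds$scale_factor)

  zero <- displacement_field(array(0, c(4, 4, 4, 1, 3)),
                             grid_geometry(c(4, 4, 4)))
  expect_error(downscale_displacement(zero), "zero field")
})

test_that("downscaling commutes with amplification (linearity of strain)", {
  ph <- make_phantom("pulsatile_composite", amplitude = 0.05, n_t = 4,
                     shape = c(12, 12, 12))
  base <- downscale_displacement(trim_to_mask(ph$field, ph$labels))$field
  for (k in c(5, 25)) {
    ampk <- make_amplified_phantom(ph$field, k)
    dsk <- downscale_displacement(trim_to_mask(ampk, ph$labels))$field
    expect_equal(dsk$data, base$data, tolerance = 1e-12)
  }
  E0 <- green_lagrange_strain(deformation_gradient(
    displacement_gradient(base)))
  E25 <- green_lagrange_strain(deformation_gradient(displacement_gradient(
    downscale_displacement(trim_to_mask(
      make_amplified_phantom(ph$field, 25), ph$labels))$field)))
  expect_equal(E25$values, E0$values, tolerance = 1e-10)
})

test_that("time-point selection maximises the in-mask percentile metric", {
  # hand-built field with per-frame p90 displacement [0.1, 0.5, 0.3]
  geom <- grid_geometry(c(5, 5, 5), frames = 3)
  data <- array(0, c(5, 5, 5, 3, 3))
  for (k in 1:3) data[, , , k, 1] <- c(0.1, 0.5, 0.3)[k]
  f <- displacement_field(data, geom)
  k <- select_timepoint(f, config = pipeline_config(
    temporal_mode = "single_timepoint"))
  expect_equal(as.integer(k), 2)
  expect_equal(attr(k, "metric"), c(0.1, 0.5, 0.3))

  # all frames identical: earliest frame wins
  data[] <- 0.2
  expect_equal(as.integer(select_timepoint(
    displacement_field(data, geom))), 1)

  # no finite values anywhere
  data[] <- NaN
  expect_error(select_timepoint(displacement_field(data, geom)),
               "no finite")
})

test_that("a pulsatile phantom selects its peak phase by either metric", {
  n_t <- 8
  ph <- make_phantom("pulsatile_composite", amplitude = 0.05, n_t = n_t,
                     shape = c(12, 12, 12))
  f <- trim_to_mask(ph$field, ph$labels)
  # sin^2(pi t/T) peaks at t = T/2, i.e. frame n_t/2 + 1
  expect_equal(as.integer(select_timepoint(f)), n_t / 2 + 1)
  E <- green_lagrange_strain(deformation_gradient(
    displacement_gradient(f)))
  k <- select_timepoint(f, strain = E, config = pipeline_config(
    selection_metric = "strain_p90"))
  expect_equal(as.integer(k), n_t / 2 + 1)
  expect_error(select_timepoint(f, config = pipeline_config(
    selection_metric = "strain_p90")), "strain field required")
})

test_that("configs validate and round-trip through YAML", {
  expect_error(pipeline_config(target_max_displacement = 0), "> 0")
  expect_error(pipeline_config(percentile = 100), "percentile")
  cfg <- pipeline_config(target_max_displacement = 0.2,
                         temporal_mode = "single_timepoint")
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  yaml::write_yaml(list(target_max_displacement = 0.2,
                        temporal_mode = "single_timepoint"), path)
  got <- read_pipeline_config(path)
  expect_equal(got$target_max_displacement, 0.2)
  expect_equal(got$temporal_mode, "single_timepoint")
  expect_equal(got$percentile, 90)
  yaml::write_yaml(list(bogus_key = 1), path)
  expect_error(read_pipeline_config(path), "unknown config keys")
})
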