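# Synthetic displacement phantoms with closed-form ground truth.
#
# Phantom displacements are defined as Eulerian fields (a function of the
# current-configuration position), so F = (I - grad U)^-1 holds exactly and
# the analytic grad U below IS the ground truth, not an approximation.

PHANTOM_KINDS <- c("zero", "rigid_rotation", "uniaxial_stretch",
                   "simple_shear", "dilation", "pulsatile_composite")

#' Generate a synthetic displacement phantom with ground truth
#'
#' Builds a displacement field on a regular grid together with matching
#' tissue labels (concentric WM/GM/CSF shells inside a spherical "brain"),
#' an atlas-style label volume (the 12 vascular-dementia region ids split
#' over hemispheres and angular sectors), and exact voxelwise ground-truth
#' tensors computed analytically from the phantom's closed-form gradient.
#'
#' Kinds: `zero` (no motion); `rigid_rotation` (rotation by `amplitude`
#' degrees about z, zero strain); `uniaxial_stretch` (Eulerian gradient
#' `amplitude` along x, F = diag(1/(1-a), 1, 1)); `simple_shear`
#' (du_x/dy = `amplitude`, J = 1); `dilation` (grad U = a I);
#' `pulsatile_composite` (smooth trigonometric field whose amplitude is
#' modulated by sin^2(pi t / T) across the cardiac cycle, peaking at
#' mid-cycle, with optional seeded Gaussian noise).
#'
#' Time-constant kinds replicate the same deformation in every frame;
#' only `pulsatile_composite` is time-varying. Generation fails if the
#' requested amplitude drives det(I - grad U) (and hence J) non-positive
#' anywhere.
#'
#' @param kind one of the phantom kinds above.
#' @param amplitude dimensionless gradient amplitude (degrees for
#'   `rigid_rotation`).
#' @param n_t number of frames.
#' @param shape voxel counts, length 3.
#' @param spacing voxel spacing in mm, length 3.
#' @param cycle_duration cardiac cycle length (s).
#' @param noise_sd standard deviation (mm) of Gaussian noise added to the
#'   composite phantom's displacements (ground truth stays noiseless).
#' @param seed RNG seed for the composite noise.
#' @param material a [material_table()] used for the ground-truth stress.
#' @return List with `field` ([displacement_field()]), `labels` (3-label
#'   [label_volume()]), `atlas` (atlas-style `label_volume`), and `truth`:
#'   arrays `gradU`, `F`, `E` (standard convention), `sigma`, `J` with
#'   tensor dims `c(shape, n_t, 9)`. Ground-truth stress is NaN where the
#'   material excludes the tissue (CSF, background).
#' @export
make_phantom <- function(kind = PHANTOM_KINDS, amplitude = 0.01, n_t = 8L,
                         shape = c(16L, 16L, 16L),
                         spacing = c(1.2, 1.2, 1.2),
                         cycle_duration = 1, noise_sd = 0,
                         seed = 20240801L,
                         material = material_table()) {
  kind <- match.arg(kind)
  geom <- grid_geometry(shape, spacing = spacing, frames = n_t,
                        cycle_duration = cycle_duration)
  xyz <- voxel_world_coords(geom)
  centre <- colMeans(xyz)
  X <- sweep(xyz, 2, centre)
  nvox <- nrow(X)

  # per-frame amplitude modulation; only the composite kind pulses
  tt <- (seq_len(n_t) - 1) * geom$frame_interval
  amp_t <- if (kind == "pulsatile_composite")
    amplitude * sin(pi * tt / cycle_duration)^2 else rep(amplitude, n_t)

  # closed-form u (n x 3) and gradU (n x 9) at unit amplitude scale `a`
  eval_frame <- function(a) {
    u <- matrix(0, nvox, 3)
    g <- matrix(0, nvox, 9)
    if (kind == "zero" || a == 0) {
    } else if (kind == "rigid_rotation") {
      th <- a * pi / 180
      R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
                  3, 3)
      u <- X - X %*% R           # u = (I - R^T) x ; X %*% R == x R = R^T x
      IRt <- diag(3) - t(R)
      g <- matrix(rep(as.vector(IRt), each = nvox), nvox, 9)
    } else if (kind == "uniaxial_stretch") {
      u[, 1] <- a * X[, 1]
      g[, t9_index(1, 1)] <- a
    } else if (kind == "simple_shear") {
      u[, 1] <- a * X[, 2]
      g[, t9_index(1, 2)] <- a
    } else if (kind == "dilation") {
      u <- a * X
      g[, c(1, 5, 9)] <- a
    } else { # pulsatile_composite
      ext <- geom$shape * geom$spacing
      om <- 2 * pi / ext
      s1 <- sin(om[1] * X[, 1]); c1 <- cos(om[1] * X[, 1])
      s2 <- sin(om[2] * X[, 2]); c2 <- cos(om[2] * X[, 2])
      s3 <- sin(om[3] * X[, 3]); c3 <- cos(om[3] * X[, 3])
      L <- min(ext) # length scale so `a` stays a dimensionless gradient
      b <- a * L / (2 * pi)
      u[, 1] <- b * s1 * c2
      u[, 2] <- b * s2 * c3
      u[, 3] <- b * s3 * c1
      g[, t9_index(1, 1)] <- b * om[1] * c1 * c2
      g[, t9_index(1, 2)] <- -b * om[2] * s1 * s2
      g[, t9_index(2, 2)] <- b * om[2] * c2 * c3
      g[, t9_index(2, 3)] <- -b * om[3] * s2 * s3
      g[, t9_index(3, 3)] <- b * om[3] * c3 * c1
      g[, t9_index(3, 1)] <- -b * om[1] * s3 * s1
    }
    list(u = u, g = g)
  }

  labels <- phantom_labels(geom, xyz, centre)
  atlas <- phantom_atlas(geom, xyz, centre, labels)

  data <- array(NA_real_, c(geom$shape, n_t, 3L))
  gradU <- array(NA_real_, c(geom$shape, n_t, 9L))
  Farr <- array(NA_real_, c(geom$shape, n_t, 9L))
  for (k in seq_len(n_t)) {
    fr <- eval_frame(amp_t[k])
    A <- t9_eye(nvox) - fr$g
    dA <- t9_det(A)
    if (any(dA <= 0))
      stop("amplitude ", amplitude, " causes J <= 0 (min det(I - gradU) = ",
           signif(min(dA), 3), ")")
    data[, , , k, ] <- fr$u
    gradU[, , , k, ] <- fr$g
    Farr[, , , k, ] <- t9_inv(A)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    data <- data + stats::rnorm(length(data), sd = noise_sd)
  }

  Fm <- matrix(Farr, ncol = 9)
  J <- t9_det(Fm)
  C <- t9_matmul(t9_transpose(Fm), Fm)
  E <- (C - t9_eye(nrow(Fm))) / 2
  kin <- mooney_rivlin_kinematics(Fm)
  gk <- material_per_voxel(material, labels)
  G <- rep(gk$G, times = n_t); K <- rep(gk$K, times = n_t)
  sig <- t9_dev(kin$Bbar) * (G / kin$J)
  sig[, c(1, 5, 9)] <- sig[, c(1, 5, 9)] + K / 2 * (kin$J - 1 / kin$J)

  list(field = displacement_field(data, geom),
       labels = labels, atlas = atlas,
       truth = list(gradU = gradU, F = Farr,
                    E = array(E, c(geom$shape, n_t, 9L)),
                    sigma = array(sig, c(geom$shape, n_t, 9L)),
                    J = array(J, c(geom$shape, n_t))),
       kind = kind, amplitude = amplitude)
}

# Concentric-shell tissue labels: WM core, GM shell, CSF rim, background.
phantom_labels <- function(geom, xyz, centre) {
  r <- sqrt(rowSums(sweep(xyz, 2, centre)^2))
  R <- 0.95 * min(geom$shape * geom$spacing) / 2
  lab <- integer(length(r))
  lab[r <= R] <- 1L                 # CSF rim
  lab[r <= 0.8 * R] <- 2L           # GM shell
  lab[r <= 0.55 * R] <- 3L          # WM core
  label_volume(array(lab, geom$shape),
               grid_geometry(geom$shape, affine = geom$affine, frames = 1L))
}

# Atlas-style labels: the 12 vascular-dementia ids split by hemisphere
# (x sign) and angular sector in the (y, z) plane; brain voxels only.
phantom_atlas <- function(geom, xyz, centre, labels) {
  rs <- builtin_region_set("vascular_dementia")
  right <- rs$label_ids[grepl("^Right", rs$label_names)]
  left <- rs$label_ids[grepl("^Left", rs$label_names)]
  X <- sweep(xyz, 2, centre)
  sector <- 1L + floor((atan2(X[, 3], X[, 2]) + pi) / (2 * pi) * 6) %% 6L
  ids <- ifelse(X[, 1] >= 0, right[sector], left[sector])
  ids[as.vector(labels$labels) == 0L] <- 0L
  label_volume(array(as.integer(ids), geom$shape),
               grid_geometry(geom$shape, affine = geom$affine, frames = 1L),
               lookup = slant_lookup())
}

#' Amplified phantom displacement field
#'
#' Multiplies a phantom's displacements by an amplification factor,
#' emulating amplified-MRI output prior to the downscaling step.
#'
#' @param phantom a [make_phantom()] result or a [displacement_field()].
#' @param amplification multiplicative factor (> 1 emulates amplification;
#'   1 is the identity).
#' @return A [displacement_field()].
#' @export
make_amplified_phantom <- function(phantom, amplification) {
  field <- if (inherits(phantom, "displacement_field")) phantom
           else phantom$field
  if (!is.numeric(amplification) || amplification <= 0)
    stop("'amplification' must be positive")
  out <- field
  out$data <- field$data * amplification
  out
}
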