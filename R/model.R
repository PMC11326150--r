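#' Voxelwise brain biomechanics from a displacement field
#'
#' The core entry point: runs the full finite-strain chain on a masked
#' displacement field. Steps: (1) trim to the brain mask; (2) rescale
#' amplified displacements so the maximum in-brain displacement equals the
#' configured physiological target (187 um by default); (3) differentiate
#' to the displacement gradient; (4) invert to the deformation gradient
#' F = (I - grad U)^-1; (5) Green-Lagrange strain; (6) strain rate over
#' the cardiac cycle (full-history mode, 3+ frames); (7) Mooney-Rivlin
#' Cauchy stress and strain energy density with per-tissue constants;
#' (8) von Mises scalars. In single-timepoint mode only the automatically
#' selected peak frame is retained.
#'
#' @param field a [displacement_field()].
#' @param labels a [label_volume()] with the 3-label tissue segmentation
#'   (CSF = 1, GM = 2, WM = 3) on the same grid.
#' @param material a [material_table()].
#' @param config a [pipeline_config()].
#' @return An object of class `brain_mechanics`: a list with the input
#'   geometry and config, `scale_factor`, `selected_frame` (single-
#'   timepoint mode), tensor fields `F`, `E`, `E_rate` (when computable),
#'   `sigma`, scalar fields `W`, `J`, `vm_strain`, `vm_stress`,
#'   `vm_strain_rate`, the masked/rescaled `displacement`, `labels`, and
#'   per-stage invalid-voxel counts in `counts`.
#' @seealso [summary.brain_mechanics()], [summarize_regions()],
#'   [run_pipeline()]
#' @export
brain_mechanics <- function(field, labels,
                            material = material_table(),
                            config = pipeline_config()) {
  if (!same_grid(field$geometry, labels$geometry))
    stop("segmentation grid does not match displacement grid")
  field <- trim_to_mask(field, labels)
  bb <- attr(field, "bounding_box")

  scale_factor <- 1
  if (config$downscale) {
    ds <- downscale_displacement(field, config)
    field <- ds$field
    scale_factor <- ds$scale_factor
  }

  gradU <- displacement_gradient(field)
  F_tf <- deformation_gradient(gradU, det_floor = config$det_floor,
                               cond_ceiling = config$cond_ceiling)
  E <- green_lagrange_strain(F_tf, convention = config$strain_convention)

  selected_frame <- NULL
  if (config$temporal_mode == "single_timepoint") {
    selected_frame <- as.integer(select_timepoint(field, strain = E,
                                                  config = config))
    keep <- function(tf) {
      tf$values <- tf$values[, , , selected_frame, , drop = FALSE]
      tf$geometry <- grid_geometry(tf$geometry$shape,
                                   affine = tf$geometry$affine, frames = 1L,
                                   frame_interval = tf$geometry$frame_interval)
      tf
    }
    gradU <- keep(gradU)
    J_arr <- F_tf$J[, , , selected_frame, drop = FALSE]
    F_tf <- keep(F_tf); F_tf$J <- J_arr
    E <- keep(E)
  }

  E_rate <- if (config$temporal_mode == "full_history" &&
                E$geometry$frames >= 3L)
    strain_rate(E) else NULL

  W <- strain_energy_density(F_tf, material, labels)
  sigma <- cauchy_stress(F_tf, material, labels)
  vm_strain <- von_mises(E)
  vm_stress <- von_mises(sigma)
  vm_strain_rate <- if (!is.null(E_rate)) von_mises(E_rate) else NULL

  counts <- list(
    in_mask = sum(labels$labels > 0L),
    gradU_valid = sum(tensor_validity(gradU)),
    F_valid = sum(tensor_validity(F_tf)),
    F_degenerate = attr(F_tf, "n_degenerate"),
    sigma_valid = sum(tensor_validity(sigma)))

  structure(list(
    displacement = field, labels = labels, material = material,
    config = config, geometry = field$geometry,
    scale_factor = scale_factor, selected_frame = selected_frame,
    bounding_box = bb,
    gradU = gradU, F = F_tf, E = E, E_rate = E_rate, sigma = sigma,
    W = W, J = scalar_field(F_tf$J, F_tf$geometry, quantity = "J"),
    vm_strain = vm_strain, vm_stress = vm_stress,
    vm_strain_rate = vm_strain_rate,
    counts = counts), class = "brain_mechanics")
}

#' @export
print.brain_mechanics <- function(x, ...) {
  cat("Brain biomechanics model\n")
  print(x$geometry)
  cat(sprintf("Displacement scale factor: %.6g\n", x$scale_factor))
  if (!is.null(x$selected_frame))
    cat(sprintf("Single-timepoint mode: frame %d selected (%s)\n",
                x$selected_frame, x$config$selection_metric))
  cat(sprintf("Valid stress voxels per frame: %.0f of %d in mask\n",
              x$counts$sigma_valid / x$sigma$geometry$frames,
              x$counts$in_mask))
  vm <- x$vm_strain$values
  fin <- is.finite(vm)
  if (any(fin))
    cat(sprintf("Peak von Mises strain: %.4g %% | peak von Mises stress: %.4g kPa\n",
                100 * max(vm[fin]),
                max(x$vm_stress$values[is.finite(x$vm_stress$values)])))
  invisible(x)
}

#' Per-tissue summary of a brain mechanics model
#'
#' Mean, SD, median and 5th/95th percentiles of the von Mises strain
#' (in percent), von Mises stress (kPa) and, when present, von Mises
#' strain rate (1/s), over valid voxels of each tissue class and frame
#' set.
#'
#' @param object a `brain_mechanics` object.
#' @param ... unused.
#' @return A data frame of class `summary.brain_mechanics`.
#' @export
summary.brain_mechanics <- function(object, ...) {
  cls <- voxel_tissue_class(object$labels)
  nt <- object$sigma$geometry$frames
  cls_t <- rep(cls, times = nt)
  rows <- list()
  fields <- list(vm_strain_pct = list(f = object$vm_strain, s = 100),
                 vm_stress_kPa = list(f = object$vm_stress, s = 1))
  if (!is.null(object$vm_strain_rate))
    fields$vm_strain_rate_per_s <- list(f = object$vm_strain_rate, s = 1)
  for (qn in names(fields)) {
    v <- as.vector(fields[[qn]]$f$values) * fields[[qn]]$s
    for (tc in c("WM", "GM", "CSF")) {
      x <- v[cls_t == tc & is.finite(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = qn, tissue = tc, n = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) > 1) stats::sd(x) else NA_real_,
        median = if (length(x)) stats::median(x) else NA_real_,
        p5 = if (length(x)) stats::quantile(x, 0.05, names = FALSE)
             else NA_real_,
        p95 = if (length(x)) stats::quantile(x, 0.95, names = FALSE)
              else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "scale_factor") <- object$scale_factor
  attr(out, "selected_frame") <- object$selected_frame
  class(out) <- c("summary.brain_mechanics", "data.frame")
  out
}

#' @export
print.summary.brain_mechanics <- function(x, ...) {
  cat("Per-tissue biomechanics summary (valid voxels, all frames)\n")
  cat(sprintf("Displacement scale factor: %.6g\n\n",
              attr(x, "scale_factor")))
  df <- x
  class(df) <- "data.frame"
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Violin-style plot of a brain mechanics model
#'
#' Draws mirrored-density (violin) outlines of the von Mises strain or
#' stress distribution per tissue class, using base graphics.
#'
#' @param x a `brain_mechanics` object.
#' @param quantity `"vm_strain"` (plotted in percent) or `"vm_stress"`
#'   (kPa).
#' @param ... passed to [graphics::plot()].
#' @export
plot.brain_mechanics <- function(x, quantity = c("vm_strain", "vm_stress"),
                                 ...) {
  quantity <- match.arg(quantity)
  f <- x[[quantity]]
  scale <- if (quantity == "vm_strain") 100 else 1
  ylab <- if (quantity == "vm_strain") "von Mises strain (%)"
          else "von Mises stress (kPa)"
  cls <- rep(voxel_tissue_class(x$labels), times = f$geometry$frames)
  v <- as.vector(f$values) * scale
  groups <- list()
  for (tc in c("WM", "GM", "CSF")) {
    g <- v[cls == tc & is.finite(v)]
    if (length(g) > 1) groups[[tc]] <- g
  }
  draw_violins(groups, ylab = ylab, ...)
  invisible(x)
}

# Minimal base-graphics violin renderer shared with region plots.
draw_violins <- function(groups, ylab = "", main = "", width = 0.4, ...) {
  if (!length(groups)) stop("nothing to plot: no groups with data")
  k <- length(groups)
  rng <- range(unlist(groups))
  graphics::plot(NA, xlim = c(0.5, k + 0.5), ylim = rng, xaxt = "n",
                 xlab = "", ylab = ylab, main = main, ...)
  graphics::axis(1, at = seq_len(k), labels = names(groups), las = 2,
                 cex.axis = 0.8)
  for (i in seq_len(k)) {
    g <- groups[[i]]
    if (length(unique(g)) > 1) {
      d <- suppressWarnings(stats::density(g, cut = 0))
      w <- d$y / max(d$y) * width
      graphics::polygon(c(i - w, rev(i + w)), c(d$x, rev(d$x)),
                        col = "grey80", border = "grey40")
    }
    med <- stats::median(g)
    graphics::segments(i - width / 2, med, i + width / 2, med, lwd = 2)
  }
  invisible(NULL)
}
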