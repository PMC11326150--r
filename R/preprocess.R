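#' Pipeline configuration
#'
#' All tunable parameters of the displacement-to-stress pipeline in one
#' place. The defaults reproduce the standard automated run: amplified
#' displacements rescaled so the maximum in-brain displacement magnitude
#' over all frames equals 187 um, full time-history evaluated, strain in
#' the conventional Green-Lagrange form, CSF excluded from stress.
#'
#' @param target_max_displacement mm; amplified displacements are rescaled
#'   so the maximum equals this (default 0.187 mm = 187 um).
#' @param cycle_duration cardiac cycle length, seconds.
#' @param temporal_mode `"full_history"` (every frame) or
#'   `"single_timepoint"` (one automatically selected frame).
#' @param selection_metric frame-selection metric for single-timepoint
#'   mode: `"displacement_p90"` or `"strain_p90"`.
#' @param percentile percentile (0-100) used by the selection metric.
#' @param downscale_norm how "maximum displacement" is measured:
#'   `"vector_magnitude"` (Euclidean norm, default) or `"component_max"`.
#' @param strain_convention `"standard"` for E = (F'F - I)/2 or `"paper"`
#'   for E = F'F - I.
#' @param components displacement components expressed in `"world"`
#'   (scanner mm, default) or `"voxel"` coordinates; voxel components are
#'   rotated/scaled into world mm via the affine before differentiation.
#' @param det_floor voxels with det(I - grad U) at or below this are
#'   marked invalid.
#' @param cond_ceiling voxels whose (Frobenius-estimated) condition number
#'   of I - grad U exceeds this are marked invalid.
#' @param downscale logical; apply the amplitude rescaling step?
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(target_max_displacement = 0.187,
                            cycle_duration = 1.0,
                            temporal_mode = c("full_history",
                                              "single_timepoint"),
                            selection_metric = c("displacement_p90",
                                                 "strain_p90"),
                            percentile = 90,
                            downscale_norm = c("vector_magnitude",
                                               "component_max"),
                            strain_convention = c("standard", "paper"),
                            components = c("world", "voxel"),
                            det_floor = 1e-8,
                            cond_ceiling = 1e8,
                            downscale = TRUE) {
  if (!is.numeric(target_max_displacement) || target_max_displacement <= 0)
    stop("'target_max_displacement' must be > 0")
  if (percentile <= 0 || percentile >= 100)
    stop("'percentile' must lie in (0, 100)")
  structure(list(
    target_max_displacement = target_max_displacement,
    cycle_duration = cycle_duration,
    temporal_mode = match.arg(temporal_mode),
    selection_metric = match.arg(selection_metric),
    percentile = percentile,
    downscale_norm = match.arg(downscale_norm),
    strain_convention = match.arg(strain_convention),
    components = match.arg(components),
    det_floor = det_floor,
    cond_ceiling = cond_ceiling,
    downscale = isTRUE(downscale)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys error.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Nearest-neighbour resampling of a label volume onto a target grid
#'
#' Each target voxel centre is mapped to world coordinates via the target
#' affine, through the given world-to-world transform (source world to
#' target world, FLIRT-style; its inverse is applied), and into source
#' voxel indices via the inverse source affine; the nearest source voxel
#' supplies the label. Targets falling outside the source extent get
#' background 0. No new labels can be created.
#'
#' @param labels a [label_volume()].
#' @param affine_to_target 4x4 matrix mapping source world coordinates to
#'   target world coordinates (identity when both are in the same space).
#' @param target a [grid_geometry()] describing the output grid.
#' @return A [label_volume()] on the target grid.
#' @export
resample_labels <- function(labels, affine_to_target = diag(4), target) {
  affine_to_target <- matrix(as.numeric(affine_to_target), 4, 4)
  if (abs(det(affine_to_target)) <= .Machine$double.eps)
    stop("singular affine")
  # target voxel -> target world -> source world -> source voxel
  m <- solve(labels$geometry$affine) %*% solve(affine_to_target) %*%
       target$affine
  sh <- target$shape
  idx <- as.matrix(expand.grid(i = 0:(sh[1] - 1), j = 0:(sh[2] - 1),
                               k = 0:(sh[3] - 1)))
  src <- idx %*% t(m[1:3, 1:3])
  src <- sweep(src, 2, m[1:3, 4], "+")
  src <- floor(src + 0.5)  # nearest neighbour, half-up tie-break
  ssh <- labels$geometry$shape
  inside <- src[, 1] >= 0 & src[, 1] < ssh[1] &
            src[, 2] >= 0 & src[, 2] < ssh[2] &
            src[, 3] >= 0 & src[, 3] < ssh[3]
  out <- integer(nrow(src))
  lin <- 1L + src[inside, 1] + ssh[1] * (src[inside, 2] +
                                         ssh[2] * src[inside, 3])
  out[inside] <- labels$labels[lin]
  geom <- grid_geometry(sh, affine = target$affine, frames = 1L)
  label_volume(array(out, sh), geom, lookup = labels$lookup)
}

#' Mask a displacement field to the brain
#'
#' Voxels outside the mask (label 0) are set to NaN in every component and
#' frame; the bounding box of nonzero labels is recorded for cropping
#' exported volumes.
#'
#' @param field a [displacement_field()].
#' @param mask a [label_volume()] on the same grid.
#' @return The masked `displacement_field`, with attribute `bounding_box`
#'   (a 2x3 matrix of 1-based index ranges, NA when the mask is empty).
#' @export
trim_to_mask <- function(field, mask) {
  if (!same_grid(field$geometry, mask$geometry))
    stop("mask grid does not match displacement grid")
  inside <- mask$labels > 0L
  if (!any(inside)) {
    warning("mask is empty: all displacements set to NaN")
    bb <- matrix(NA_integer_, 2, 3)
  } else {
    w <- which(inside, arr.ind = TRUE)
    bb <- rbind(apply(w, 2, min), apply(w, 2, max))
  }
  out <- field$data
  nt <- field$geometry$frames
  outside <- !inside
  for (t_i in seq_len(nt)) for (c_i in 1:3) {
    comp <- out[, , , t_i, c_i]
    comp[outside] <- NaN
    out[, , , t_i, c_i] <- comp
  }
  res <- displacement_field(out, field$geometry, field$reference_frame)
  attr(res, "bounding_box") <- bb
  res
}

#' Rescale amplified displacements to physiological amplitude
#'
#' Amplified-MRI displacement fields exaggerate brain motion (up to ~25x);
#' one global scalar rescales the whole field so that the maximum
#' displacement over all in-mask voxels, components and frames equals
#' `target_max_displacement` (187 um by default, a literature value for
#' peak cardiac-cycle brain displacement). A single factor per subject
#' preserves relative spatial and temporal dynamics.
#'
#' @param field a [displacement_field()] (already masked, or unmasked).
#' @param config a [pipeline_config()]; uses `target_max_displacement` and
#'   `downscale_norm`.
#' @return List with `field` (rescaled) and `scale_factor`.
#' @export
downscale_displacement <- function(field, config = pipeline_config()) {
  M <- switch(config$downscale_norm,
    vector_magnitude = {
      mag <- displacement_magnitude(field)
      if (!any(is.finite(mag))) NaN else max(mag[is.finite(mag)])
    },
    component_max = {
      a <- abs(field$data)
      if (!any(is.finite(a))) NaN else max(a[is.finite(a)])
    })
  if (!is.finite(M) || M == 0)
    stop("cannot downscale zero field (no finite nonzero displacement)")
  s <- config$target_max_displacement / M
  out <- field
  out$data <- field$data * s
  list(field = out, scale_factor = s)
}

#' Automatic time-point selection
#'
#' For single-timepoint analyses, picks the cardiac phase whose in-mask
#' 90th-percentile (configurable) metric is largest: either the
#' displacement magnitude or the von Mises strain. Percentiles use linear
#' interpolation between order statistics over finite voxels, per frame.
#' Ties break to the earliest frame.
#'
#' @param field a [displacement_field()].
#' @param strain optional symmetric strain [tensor_field()] over all
#'   frames; required when `selection_metric = "strain_p90"`.
#' @param config a [pipeline_config()].
#' @return Integer frame index (1-based), with attribute `metric` holding
#'   the per-frame percentile values.
#' @export
select_timepoint <- function(field, strain = NULL,
                             config = pipeline_config()) {
  nt <- field$geometry$frames
  p <- config$percentile / 100
  per_frame <- switch(config$selection_metric,
    displacement_p90 = {
      mag <- displacement_magnitude(field)
      dim(mag) <- c(prod(field$geometry$shape), nt)
      apply(mag, 2, function(v) {
        v <- v[is.finite(v)]
        if (!length(v)) NA_real_ else stats::quantile(v, p, names = FALSE,
                                                      type = 7)
      })
    },
    strain_p90 = {
      if (is.null(strain))
        stop("strain field required for selection_metric = 'strain_p90'")
      vm <- von_mises(strain)
      v <- vm$values
      dim(v) <- c(prod(field$geometry$shape), dim(v)[4])
      apply(v, 2, function(x) {
        x <- x[is.finite(x)]
        if (!length(x)) NA_real_ else stats::quantile(x, p, names = FALSE,
                                                      type = 7)
      })
    })
  if (all(!is.finite(per_frame)))
    stop("no finite in-mask values in any frame")
  k <- which.max(per_frame)  # which.max takes the earliest maximum
  attr(k, "metric") <- per_frame
  k
}
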