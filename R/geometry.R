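#' Grid geometry of an image volume
#'
#' Describes the sampling grid every field in the pipeline lives on: voxel
#' counts, voxel spacing in mm, the 4x4 voxel-index-to-world affine, the
#' number of cardiac phases and the time between them.
#'
#' Voxel indices are 0-based in the affine convention (NIfTI style): world
#' coordinates of voxel `(i, j, k)` (R indices `i+1, j+1, k+1`) are
#' `affine %*% c(i, j, k, 1)`.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing numeric length 3, voxel spacing in mm. Derived from
#'   `affine` when omitted.
#' @param affine 4x4 voxel-to-world matrix (mm). Defaults to a diagonal
#'   matrix built from `spacing` with the origin at voxel (0,0,0).
#' @param frames number of time frames (cardiac phases), in `[1, 64]`.
#' @param frame_interval seconds per frame; defaults to
#'   `cycle_duration / frames`.
#' @param cycle_duration cardiac cycle duration in seconds (used only to
#'   derive `frame_interval`).
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(shape, spacing = NULL, affine = NULL, frames = 1L,
                          frame_interval = NULL, cycle_duration = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("'shape' must be 3 positive integers")
  if (is.null(affine)) {
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    affine <- diag(c(spacing, 1))
  }
  affine <- matrix(as.numeric(affine), 4, 4)
  if (is.null(spacing)) spacing <- spacing_from_affine(affine)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' components must be strictly positive")
  if (abs(det(affine[1:3, 1:3])) <= .Machine$double.eps)
    stop("affine 3x3 block is singular")
  frames <- as.integer(frames)
  if (frames < 1L || frames > 64L)
    stop("'frames' must lie in [1, 64]")
  if (is.null(frame_interval)) frame_interval <- cycle_duration / frames
  structure(
    list(shape = shape, spacing = spacing, affine = affine,
         frames = frames, frame_interval = as.numeric(frame_interval)),
    class = "grid_geometry")
}

#' Voxel spacing implied by an affine
#'
#' Spacing along each voxel axis is the Euclidean norm of the corresponding
#' column of the affine's 3x3 block.
#'
#' @param affine 4x4 (or 3x3) matrix.
#' @return Numeric length 3.
#' @export
spacing_from_affine <- function(affine) {
  b <- affine[1:3, 1:3]
  sqrt(colSums(b^2))
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("Grid: %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("Frames: %d (%.4g s interval)\n", x$frames, x$frame_interval))
  invisible(x)
}

# Same spatial grid (shape + affine to tolerance); frames may differ.
same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) < tol
}

# World coordinates (n x 3) of all voxels, 0-based index convention.
voxel_world_coords <- function(geom) {
  sh <- geom$shape
  idx <- as.matrix(expand.grid(i = 0:(sh[1] - 1), j = 0:(sh[2] - 1),
                               k = 0:(sh[3] - 1)))
  xyz <- idx %*% t(geom$affine[1:3, 1:3])
  sweep(xyz, 2, geom$affine[1:3, 4], "+")
}
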