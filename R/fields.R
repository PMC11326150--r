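#' Time-resolved 3D displacement field
#'
#' The central input object: a 3-component displacement vector (mm) at
#' every voxel and cardiac phase, relative to the reference configuration
#' (frame 1, assumed diastole). Components are expressed in world (scanner)
#' mm coordinates by default; see `components` in [pipeline_config()].
#'
#' @param data numeric array of dim `c(nx, ny, nz, n_t, 3)` (mm). A 4D
#'   array `c(nx, ny, nz, 3)` is promoted to a single frame.
#' @param geometry a [grid_geometry()] whose `frames` matches `dim(data)[4]`.
#' @param reference_frame integer, the reference (diastole) frame; default 1.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(data, geometry, reference_frame = 1L) {
  data <- as.array(data)
  if (length(dim(data)) == 4L && dim(data)[4] == 3L)
    dim(data) <- c(dim(data)[1:3], 1L, 3L)
  d <- dim(data)
  if (length(d) != 5L || d[5] != 3L)
    stop("'data' must have dim (nx, ny, nz, n_t, 3)")
  if (!identical(as.integer(d[1:3]), geometry$shape))
    stop("data shape does not match geometry")
  if (geometry$frames != d[4])
    stop("geometry frames (", geometry$frames, ") != data frames (", d[4], ")")
  structure(list(data = data, geometry = geometry,
                 reference_frame = as.integer(reference_frame)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat("Displacement field (mm)\n")
  print(x$geometry)
  mag <- sqrt(x$data[, , , , 1]^2 + x$data[, , , , 2]^2 + x$data[, , , , 3]^2)
  fin <- is.finite(mag)
  if (any(fin))
    cat(sprintf("Max |u| over finite voxels/frames: %.6g mm (%d/%d voxels valid)\n",
                max(mag[fin]), sum(fin), length(mag)))
  else cat("No finite displacement values\n")
  invisible(x)
}

# Magnitude array (nx, ny, nz, n_t) of a displacement field.
displacement_magnitude <- function(field) {
  sqrt(field$data[, , , , 1, drop = FALSE]^2 +
       field$data[, , , , 2, drop = FALSE]^2 +
       field$data[, , , , 3, drop = FALSE]^2)[, , , , 1]
}

#' Voxelwise 3x3 tensor field
#'
#' Holds one 3x3 tensor per voxel per frame (deformation gradient, strain,
#' strain rate or stress). Invalid voxels carry `NaN` in all nine
#' components and are excluded from every downstream statistic.
#'
#' @param values array of dim `c(nx, ny, nz, n_t, 9)`; the last axis stores
#'   the tensor in column-major order (component `(i, j)` at `i + 3*(j-1)`).
#' @param geometry a [grid_geometry()].
#' @param quantity one of `"gradU"`, `"F"`, `"E"`, `"E_rate"`, `"sigma"`.
#' @param symmetric logical; symmetric fields are validated to `T == t(T)`.
#' @param units unit string (`""`, `"1/s"`, `"kPa"`).
#' @return Object of class `tensor_field`.
#' @export
tensor_field <- function(values, geometry,
                         quantity = c("gradU", "F", "E", "E_rate", "sigma"),
                         symmetric = FALSE, units = "") {
  quantity <- match.arg(quantity)
  values <- as.array(values)
  d <- dim(values)
  if (length(d) != 5L || d[5] != 9L)
    stop("'values' must have dim (nx, ny, nz, n_t, 9)")
  if (!identical(as.integer(d[1:3]), geometry$shape))
    stop("values shape does not match geometry")
  if (symmetric) {
    m <- matrix(values, ncol = 9)
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) && max(t9_asymmetry(m)) > 1e-10)
      stop("tensor field marked symmetric violates T == t(T) beyond 1e-10")
  }
  structure(list(values = values, geometry = geometry, quantity = quantity,
                 symmetric = symmetric, units = units),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("Tensor field '%s'%s%s\n", x$quantity,
              if (x$symmetric) " (symmetric)" else "",
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  print(x$geometry)
  v <- tensor_validity(x)
  cat(sprintf("Valid voxels: %d/%d\n", sum(v), length(v)))
  invisible(x)
}

# Flatten a tensor field (or compatible array) to an N x 9 matrix.
tensor_as_matrix <- function(tf) {
  v <- if (inherits(tf, "tensor_field")) tf$values else tf
  matrix(v, ncol = 9)
}

# Rebuild the 5D array from an N x 9 matrix given a geometry.
matrix_as_tensor <- function(m, geometry, frames = geometry$frames) {
  array(m, dim = c(geometry$shape, frames, 9L))
}

# Logical array (nx, ny, nz, n_t): all nine components finite.
tensor_validity <- function(tf) {
  m <- tensor_as_matrix(tf)
  ok <- rowSums(is.finite(m)) == 9L
  array(ok, dim = dim(tf$values)[1:4])
}

# Extract component (i, j) as an (nx, ny, nz, n_t) array.
tensor_component <- function(tf, i, j) {
  tf$values[, , , , t9_index(i, j)]
}

#' Voxelwise scalar field
#'
#' @param values array of dim `c(nx, ny, nz, n_t)` (or `c(nx, ny, nz)` for a
#'   single frame). `NaN` marks invalid voxels.
#' @param geometry a [grid_geometry()].
#' @param quantity one of `"vm_strain"`, `"vm_stress"`, `"vm_strain_rate"`,
#'   `"J"`, `"W"`, `"disp_magnitude"`.
#' @param units unit string.
#' @return Object of class `scalar_field`.
#' @export
scalar_field <- function(values, geometry,
                         quantity = c("vm_strain", "vm_stress",
                                      "vm_strain_rate", "J", "W",
                                      "disp_magnitude"),
                         units = "") {
  quantity <- match.arg(quantity)
  values <- as.array(values)
  if (length(dim(values)) == 3L) dim(values) <- c(dim(values), 1L)
  if (!identical(as.integer(dim(values)[1:3]), geometry$shape))
    stop("values shape does not match geometry")
  structure(list(values = values, geometry = geometry, quantity = quantity,
                 units = units),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("Scalar field '%s'%s\n", x$quantity,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  print(x$geometry)
  fin <- is.finite(x$values)
  if (any(fin))
    cat(sprintf("Range over %d valid voxels: [%.6g, %.6g]\n",
                sum(fin), min(x$values[fin]), max(x$values[fin])))
  invisible(x)
}

#' Integer label volume with tissue lookup
#'
#' A segmentation on a single-frame grid. Label 0 is background. Every
#' nonzero label present in the volume must have a lookup row giving its
#' name and tissue class (`CSF`, `GM`, `WM` or `background`).
#'
#' @param labels integer array of dim `c(nx, ny, nz)`.
#' @param geometry a [grid_geometry()] with `frames == 1`.
#' @param lookup data frame with columns `id`, `name`, `tissue_class`;
#'   defaults to the 3-label FAST convention via [default_tissue_lookup()].
#' @return Object of class `label_volume`.
#' @export
label_volume <- function(labels, geometry, lookup = NULL) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (!identical(as.integer(dim(labels)), geometry$shape))
    stop("labels shape does not match geometry")
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be non-negative")
  if (is.null(lookup)) lookup <- default_tissue_lookup()
  lookup <- as.data.frame(lookup)
  need <- c("id", "name", "tissue_class")
  if (!all(need %in% names(lookup)))
    stop("lookup must have columns id, name, tissue_class")
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  orphan <- setdiff(present, lookup$id)
  if (length(orphan))
    stop("labels present with no lookup entry: ",
         paste(orphan, collapse = ", "))
  structure(list(labels = labels, geometry = geometry, lookup = lookup),
            class = "label_volume")
}

#' Default 3-label tissue lookup (FAST convention)
#'
#' Label 1 = cerebrospinal fluid, 2 = grey matter, 3 = white matter.
#'
#' @return Data frame with columns `id`, `name`, `tissue_class`.
#' @export
default_tissue_lookup <- function() {
  data.frame(id = 1:3,
             name = c("Cerebrospinal Fluid", "Gray Matter", "White Matter"),
             tissue_class = c("CSF", "GM", "WM"),
             stringsAsFactors = FALSE)
}

#' @export
print.label_volume <- function(x, ...) {
  cat("Label volume\n")
  print(x$geometry)
  tab <- table(x$labels[x$labels > 0L])
  cat(sprintf("Nonzero labels: %d distinct, %d voxels\n",
              length(tab), sum(tab)))
  invisible(x)
}

# Tissue class per voxel as a character array-shaped vector ("" outside).
voxel_tissue_class <- function(labels_vol) {
  cls <- rep("", length(labels_vol$labels))
  lv <- as.vector(labels_vol$labels)
  lk <- labels_vol$lookup
  m <- match(lv, lk$id)
  hit <- !is.na(m)
  cls[hit] <- lk$tissue_class[m[hit]]
  cls
}
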