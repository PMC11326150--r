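#' @importFrom RNifti readNifti writeNifti asNifti xform pixdim niftiHeader
#' @importFrom RNifti `pixdim<-` `sform<-` `qform<-`
NULL

# Build a grid_geometry from an RNifti image header.
nifti_geometry <- function(img, frames = 1L, cycle_duration = 1) {
  aff <- structure(xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  pd <- pixdim(img)
  frame_interval <- if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0)
    pd[4] else cycle_duration / frames
  grid_geometry(shape = dim(img)[1:3], affine = aff, frames = frames,
                frame_interval = frame_interval)
}

# Attach geometry to an array and write as NIfTI.
write_nifti_with_geometry <- function(arr, geometry, path) {
  img <- asNifti(arr)
  nd <- length(dim(arr))
  pd <- c(geometry$spacing, geometry$frame_interval, rep(1, max(0, nd - 4)))
  pixdim(img) <- pd[seq_len(nd)]
  RNifti::`sform<-`(img, structure(geometry$affine, code = 2L)) -> img
  writeNifti(img, path)
  invisible(path)
}

#' Read a 4D displacement field from NIfTI
#'
#' Accepts either one 5D NIfTI whose 5th dimension holds the 3 vector
#' components (dim 4 = time), or three 4D component files (x, y, z).
#' Geometry (spacing, affine, frame interval) is taken from the header;
#' spacing equals the column norms of the affine's 3x3 block. Components
#' are interpreted in world (scanner) mm coordinates.
#'
#' @param path one file path (5D layout) or a character vector of three
#'   paths (component files).
#' @param layout `"auto"` (default), `"5d"` or `"component-files"`.
#' @param cycle_duration cardiac cycle duration in seconds, used when the
#'   header carries no time step.
#' @return A [displacement_field()].
#' @export
read_displacement_field <- function(path,
                                    layout = c("auto", "5d",
                                               "component-files"),
                                    cycle_duration = 1) {
  layout <- match.arg(layout)
  if (layout == "auto")
    layout <- if (length(path) == 3L) "component-files" else "5d"
  missing <- path[!file.exists(path)]
  if (length(missing)) stop("file not found: ", paste(missing, collapse = ", "))
  if (layout == "5d") {
    img <- readNifti(path)
    d <- dim(img)
    if (length(d) == 4L) dim(img) <- d <- c(d[1:3], 1L, d[4])
    if (length(d) != 5L || d[5] != 3L)
      stop("expected a 5D NIfTI with 3 vector components, got dim ",
           paste(d, collapse = "x"))
    geom <- nifti_geometry(img, frames = d[4], cycle_duration = cycle_duration)
    data <- array(as.numeric(img), dim = d)
  } else {
    if (length(path) != 3L) stop("component-files layout needs 3 paths")
    imgs <- lapply(path, readNifti)
    dims <- lapply(imgs, dim)
    dims <- lapply(dims, function(d) if (length(d) == 3L) c(d, 1L) else d)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
      stop("inconsistent component geometry across files")
    affs <- lapply(imgs, function(i) matrix(as.numeric(xform(i)), 4, 4))
    if (max(abs(affs[[1]] - affs[[2]])) > 1e-4 ||
        max(abs(affs[[1]] - affs[[3]])) > 1e-4)
      stop("inconsistent component geometry: affines differ")
    d <- dims[[1]]
    geom <- nifti_geometry(imgs[[1]], frames = d[4],
                           cycle_duration = cycle_duration)
    data <- array(NA_real_, c(d, 3L))
    for (c_i in 1:3) data[, , , , c_i] <- as.numeric(imgs[[c_i]])
  }
  displacement_field(data, geom)
}

#' Write a displacement field as a 5D NIfTI
#'
#' Canonical layout: dim 4 = time, dim 5 = vector component.
#'
#' @param field a [displacement_field()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_displacement_field <- function(field, path) {
  write_nifti_with_geometry(field$data, field$geometry, path)
}

#' Read an integer label volume from NIfTI
#'
#' Voxel values must be integers to within `tol` (segmentations stored as
#' floats are accepted and rounded). Without a lookup file the default
#' 3-label convention (1 = CSF, 2 = GM, 3 = WM) applies; every nonzero
#' label present must have a lookup row.
#'
#' @param path NIfTI path.
#' @param lookup_path optional CSV/TSV with columns `id`, `name`,
#'   `tissue_class` (alternatively pass a data frame as `lookup`).
#' @param lookup optional lookup data frame, overrides `lookup_path`.
#' @param tol tolerance for the integer check.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, lookup_path = NULL, lookup = NULL,
                              tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- readNifti(path)
  if (length(dim(img)) != 3L)
    stop("label volume must be 3D, got dim ", paste(dim(img), collapse = "x"))
  vals <- as.numeric(img)
  rounded <- round(vals)
  if (max(abs(vals - rounded), na.rm = TRUE) > tol)
    stop("non-integer voxel values beyond tolerance ", tol)
  if (is.null(lookup) && !is.null(lookup_path)) {
    sep <- if (grepl("\\.tsv$", lookup_path)) "\t" else ","
    lookup <- utils::read.table(lookup_path, sep = sep, header = TRUE,
                                stringsAsFactors = FALSE)
  }
  geom <- nifti_geometry(img)
  label_volume(array(as.integer(rounded), dim(img)), geom, lookup = lookup)
}

#' Write a label volume as NIfTI
#' @param labels a [label_volume()].
#' @param path output path.
#' @export
write_label_volume <- function(labels, path) {
  write_nifti_with_geometry(labels$labels, labels$geometry, path)
}

#' Read a FLIRT-style 4x4 affine from a text file
#'
#' Whitespace-separated, row-major, four rows of four numbers.
#'
#' @param path text file path.
#' @return 4x4 numeric matrix.
#' @export
read_affine <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(utils::read.table(path))
  if (!identical(dim(m), c(4L, 4L))) stop("affine file must be 4x4")
  dimnames(m) <- NULL
  m
}

# Symmetric storage order xx, yy, zz, xy, xz, yz -> column-major indices.
SYM6_COLS <- c(1L, 5L, 9L, 4L, 7L, 8L)

#' Write a tensor field to NIfTI or VTK
#'
#' NIfTI: components are stacked on a trailing dimension — 6 for symmetric
#' tensors (order xx, yy, zz, xy, xz, yz) or 9 for general tensors
#' (column-major). VTK: one frame as a legacy-ASCII structured-points file
#' with a 9-component `TENSORS` array. Invalid voxels are written as NaN.
#'
#' @param field a [tensor_field()].
#' @param path output path.
#' @param format `"nifti"` or `"vtk"`.
#' @param frame frame to export for VTK (default 1).
#' @export
write_tensor_field <- function(field, path, format = c("nifti", "vtk"),
                               frame = 1L) {
  format <- match.arg(format)
  if (format == "nifti") {
    v <- field$values
    if (field$symmetric) v <- v[, , , , SYM6_COLS, drop = FALSE]
    write_nifti_with_geometry(v, field$geometry, path)
  } else {
    write_vtk_tensor(field, path, frame = frame)
  }
  invisible(path)
}

#' Read a tensor field previously written as NIfTI
#'
#' A trailing dimension of 6 is expanded from symmetric storage back to
#' the full 9 components.
#'
#' @param path NIfTI path.
#' @param quantity the quantity stored (see [tensor_field()]).
#' @param units unit string.
#' @return A [tensor_field()].
#' @export
read_tensor_field <- function(path, quantity = "E", units = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- readNifti(path)
  d <- dim(img)
  if (length(d) != 5L || !(d[5] %in% c(6L, 9L)))
    stop("expected a 5D NIfTI with 6 or 9 tensor components")
  geom <- nifti_geometry(img, frames = d[4])
  a <- array(as.numeric(img), d)
  if (d[5] == 6L) {
    full <- array(NA_real_, c(d[1:4], 9L))
    full[, , , , SYM6_COLS] <- a
    full[, , , , c(2L, 3L, 6L)] <- a[, , , , 4:6]  # mirror lower triangle
    a <- full
    sym <- TRUE
  } else sym <- max(abs(a - a[, , , , c(1, 4, 7, 2, 5, 8, 3, 6, 9)]),
                    na.rm = TRUE) < 1e-10
  tensor_field(a, geom, quantity = quantity, symmetric = sym, units = units)
}

#' Write a scalar field as NIfTI
#' @param field a [scalar_field()].
#' @param path output path.
#' @export
write_scalar_field <- function(field, path) {
  write_nifti_with_geometry(field$values, field$geometry, path)
}
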