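# Legacy-ASCII VTK structured-points export. Write-only: the pipeline
# emits VTK for external visualisation (ParaView etc.) and never reads it
# back. Point order in STRUCTURED_POINTS is x-fastest, which matches R's
# column-major array layout, so values stream out without reordering.

vtk_header_lines <- function(geom, title) {
  org <- geom$affine[1:3, 4]
  c("# vtk DataFile Version 3.0",
    title,
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    paste("DIMENSIONS", paste(geom$shape, collapse = " ")),
    paste("ORIGIN", paste(format(org, digits = 10), collapse = " ")),
    paste("SPACING", paste(format(geom$spacing, digits = 10),
                           collapse = " ")),
    paste("POINT_DATA", prod(geom$shape)))
}

fmt_vtk_num <- function(x) {
  out <- formatC(x, digits = 9, format = "g")
  out[!is.finite(x)] <- "nan"
  out
}

#' Write one frame of a tensor field as legacy VTK
#'
#' Emits a `STRUCTURED_POINTS` dataset with a 9-component `TENSORS` array
#' (row-major per point, as VTK expects). Invalid voxels are NaN.
#'
#' @param field a [tensor_field()].
#' @param path output `.vtk` path.
#' @param frame frame index (1-based).
#' @param name array name in the file.
#' @export
write_vtk_tensor <- function(field, path, frame = 1L,
                             name = field$quantity) {
  geom <- field$geometry
  m <- matrix(field$values[, , , frame, , drop = FALSE], ncol = 9)
  # column-major (T11,T21,T31,T12,...) -> VTK row-major (T11,T12,T13,T21,...)
  m <- m[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(vtk_header_lines(geom, paste("brainstrain tensor", name)), con)
  writeLines(paste("TENSORS", name, "double"), con)
  txt <- apply(matrix(fmt_vtk_num(t(m)), nrow = 3), 2, paste, collapse = " ")
  writeLines(txt, con)
  invisible(path)
}

#' Write one frame of a scalar field as legacy VTK
#'
#' @param field a [scalar_field()].
#' @param path output `.vtk` path.
#' @param frame frame index (1-based).
#' @param name array name in the file.
#' @export
write_vtk_scalar <- function(field, path, frame = 1L,
                             name = field$quantity) {
  geom <- field$geometry
  v <- as.vector(field$values[, , , frame])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(vtk_header_lines(geom, paste("brainstrain scalar", name)), con)
  writeLines(c(paste("SCALARS", name, "double 1"), "LOOKUP_TABLE default"),
             con)
  writeLines(fmt_vtk_num(v), con)
  invisible(path)
}
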