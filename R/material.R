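#' Per-tissue Mooney-Rivlin material constants
#'
#' Shear modulus G and bulk modulus K, in kPa, per tissue class. The
#' defaults are the literature-derived constants used throughout: white
#' matter G = 0.624 kPa, grey matter G = 1.10 kPa, both with
#' K = 5.00e4 kPa; CSF G = 0.50 kPa, K = 2.1e6 kPa. The CSF domain is
#' excluded from stress evaluation by default (`include_csf = FALSE`)
#' because displacement contrast in the fluid is unreliable; its constants
#' are retained for completeness.
#'
#' @param table data frame with columns `tissue_class`, `G_kPa`, `K_kPa`;
#'   defaults to the table above.
#' @param include_csf logical; evaluate stress/energy in CSF voxels?
#' @return Object of class `material_table`.
#' @export
material_table <- function(table = NULL, include_csf = FALSE) {
  if (is.null(table)) {
    table <- data.frame(
      tissue_class = c("WM", "GM", "CSF"),
      G_kPa = c(0.624, 1.10, 0.50),
      K_kPa = c(5.00e4, 5.00e4, 2.1e6),
      stringsAsFactors = FALSE)
  }
  table <- as.data.frame(table)
  need <- c("tissue_class", "G_kPa", "K_kPa")
  if (!all(need %in% names(table)))
    stop("material table needs columns tissue_class, G_kPa, K_kPa")
  if (any(!is.finite(table$G_kPa)) || any(table$G_kPa <= 0) ||
      any(!is.finite(table$K_kPa)) || any(table$K_kPa <= 0))
    stop("G and K must be finite and > 0 for every tissue class")
  structure(list(table = table, include_csf = isTRUE(include_csf)),
            class = "material_table")
}

#' @export
print.material_table <- function(x, ...) {
  cat("Mooney-Rivlin material constants (kPa):\n")
  print(x$table, row.names = FALSE)
  cat("CSF included in stress evaluation:", x$include_csf, "\n")
  invisible(x)
}

#' Read a material table from CSV
#'
#' Expects columns `tissue_class`, `G_kPa`, `K_kPa`.
#'
#' @param path CSV file path.
#' @param include_csf see [material_table()].
#' @return A `material_table`.
#' @export
read_material_table <- function(path, include_csf = FALSE) {
  if (!file.exists(path)) stop("material table not found: ", path)
  material_table(utils::read.csv(path, stringsAsFactors = FALSE),
                 include_csf = include_csf)
}

#' Write a material table to CSV
#' @param material a `material_table`.
#' @param path output CSV path.
#' @export
write_material_table <- function(material, path) {
  utils::write.csv(material$table, path, row.names = FALSE)
  invisible(path)
}

# G and K (kPa) per voxel given labels; NA where the class is excluded or
# unknown. Errors if a present tissue class has no material entry.
material_per_voxel <- function(material, labels_vol) {
  cls <- voxel_tissue_class(labels_vol)
  tab <- material$table
  present <- setdiff(unique(cls), c("", "background"))
  missing <- setdiff(present, tab$tissue_class)
  if (length(missing))
    stop("no material entry for tissue class: ",
         paste(missing, collapse = ", "))
  m <- match(cls, tab$tissue_class)
  G <- tab$G_kPa[m]
  K <- tab$K_kPa[m]
  if (!material$include_csf) {
    drop <- cls == "CSF"
    G[drop] <- NA_real_
    K[drop] <- NA_real_
  }
  list(G = G, K = K)
}
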