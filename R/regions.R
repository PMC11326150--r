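#' Bundled 133-label functional atlas lookup
#'
#' Label table for SLANT-style whole-brain segmentations following the
#' BrainCOLOR naming convention (subcortical ids 4-76, paired cortical
#' ids 100-207; right = even, left = odd). This is a synthetic stand-in
#' table assembled for interpreting atlas label volumes without running
#' the segmentation tool itself; ids and names follow the public protocol
#' but the file is not the tool's official distribution (see
#' `inst/extdata/slant_labels_synthetic.csv`).
#'
#' @return Data frame with columns `id`, `name`, `tissue_class`
#'   (exactly 133 rows).
#' @export
slant_lookup <- function() {
  path <- system.file("extdata", "slant_labels_synthetic.csv",
                      package = "brainstrain", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Named region set
#'
#' A set of atlas labels analysed together. `"vascular_dementia"` is the
#' built-in set of the 12 areas implicated in vascular dementia: left and
#' right caudate, cerebral white matter, hippocampus, pallidum, putamen
#' and thalamus proper.
#'
#' @param name currently `"vascular_dementia"`.
#' @return Object of class `region_set`: list with `name`, `label_ids`,
#'   `label_names`.
#' @export
builtin_region_set <- function(name = "vascular_dementia") {
  sets <- list(
    vascular_dementia = c("Caudate", "Cerebral White Matter", "Hippocampus",
                          "Pallidum", "Putamen", "Thalamus Proper"))
  if (!name %in% names(sets))
    stop("unknown region set '", name, "'; available: ",
         paste(names(sets), collapse = ", "))
  lk <- slant_lookup()
  wanted <- as.vector(outer(c("Right ", "Left "), sets[[name]], paste0))
  m <- match(wanted, lk$name)
  if (anyNA(m)) stop("region set names missing from atlas lookup: ",
                     paste(wanted[is.na(m)], collapse = ", "))
  structure(list(name = name, label_ids = lk$id[m],
                 label_names = lk$name[m]), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("Region set '%s' (%d labels):\n", x$name,
              length(x$label_ids)))
  cat(paste(sprintf("  %3d  %s", x$label_ids, x$label_names),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Region-wise distribution summaries of a scalar field
#'
#' Collects the valid (finite) voxel samples of a scalar field within
#' each requested atlas label and summarises them: count, mean, sample
#' (n-1) standard deviation, median and 5th/95th percentiles. A region
#' with no valid voxels yields n = 0 with NaN statistics and a warning.
#'
#' @param field a [scalar_field()].
#' @param atlas a [label_volume()] on the field's grid.
#' @param regions a [builtin_region_set()] result, an integer vector of
#'   label ids, or NULL for every nonzero label present in the atlas.
#' @param frame integer frame to restrict to, or NULL for all frames
#'   pooled (reported as frame `"all"`).
#' @param warn_empty warn when a requested region has no valid voxels?
#'   Set FALSE when empty regions are expected by design (e.g. CSF under
#'   a material table that excludes it).
#' @return Object of class `region_summary`: list with `summary` (data
#'   frame), `values` (named list of per-region sample vectors),
#'   `quantity`, `units`.
#' @export
summarize_regions <- function(field, atlas, regions = NULL, frame = NULL,
                              warn_empty = TRUE) {
  if (!same_grid(field$geometry, atlas$geometry))
    stop("atlas grid does not match field grid")
  ids <- if (is.null(regions)) {
    setdiff(sort(unique(as.vector(atlas$labels))), 0L)
  } else if (inherits(regions, "region_set")) {
    regions$label_ids
  } else as.integer(regions)
  lk <- atlas$lookup
  nm <- lk$name[match(ids, lk$id)]
  nm[is.na(nm)] <- paste0("label_", ids[is.na(nm)])
  nt <- dim(field$values)[4]
  vals <- field$values
  if (!is.null(frame)) {
    vals <- vals[, , , frame, drop = FALSE]
    frame_lab <- as.character(frame)
    nt <- 1L
  } else frame_lab <- "all"
  lab_t <- rep(as.vector(atlas$labels), times = nt)
  v <- as.vector(vals)
  values <- list()
  rows <- list()
  for (s in seq_along(ids)) {
    x <- v[lab_t == ids[s]]
    x <- x[is.finite(x)]
    values[[nm[s]]] <- x
    if (!length(x) && warn_empty)
      warning("region '", nm[s], "' has no valid voxels")
    rows[[s]] <- data.frame(
      label = ids[s], name = nm[s], n_voxels = length(x),
      mean = if (length(x)) mean(x) else NaN,
      sd = if (length(x) > 1) stats::sd(x) else NaN,
      median = if (length(x)) stats::median(x) else NaN,
      p5 = if (length(x)) stats::quantile(x, 0.05, names = FALSE) else NaN,
      p95 = if (length(x)) stats::quantile(x, 0.95, names = FALSE) else NaN,
      frame = frame_lab, stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, rows), values = values,
                 quantity = field$quantity, units = field$units),
            class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("Region summaries of '%s'%s\n", x$quantity,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  df <- x$summary
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Export region distributions for violin plotting
#'
#' Writes a long-format CSV (`subject`, `region`, `quantity`, `frame`,
#' `value`) with one row per valid voxel sample, and a companion summary
#' CSV (`*_summary.csv`) with the per-region statistics. Regions with
#' n = 0 appear in the summary but contribute no data rows.
#'
#' @param summaries a [summarize_regions()] result.
#' @param path output CSV path for the long-format data.
#' @param subject subject identifier written to every row.
#' @return Invisibly, `c(data = path, summary = summary_path)`.
#' @export
export_violin_data <- function(summaries, path, subject = "subject") {
  if (!length(summaries$values)) stop("no region summaries to export")
  sm <- summaries$summary
  long <- do.call(rbind, lapply(seq_len(nrow(sm)), function(s) {
    x <- summaries$values[[sm$name[s]]]
    if (!length(x)) return(NULL)
    data.frame(subject = subject, region = sm$name[s],
               quantity = summaries$quantity, frame = sm$frame[s],
               value = x, stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  spath <- sub("\\.csv$", "_summary.csv", path)
  if (identical(spath, path)) spath <- paste0(path, "_summary.csv")
  utils::write.csv(cbind(subject = subject, sm), spath, row.names = FALSE)
  invisible(c(data = path, summary = spath))
}

#' Violin plot of region summaries
#'
#' @param x a [summarize_regions()] result.
#' @param scale multiplier applied to the samples before plotting (e.g.
#'   100 to show strain in percent).
#' @param ylab y-axis label.
#' @param ... passed to the plot.
#' @export
plot.region_summary <- function(x, scale = 1,
                                ylab = paste(x$quantity, x$units), ...) {
  groups <- lapply(x$values, function(g) g * scale)
  groups <- groups[vapply(groups, length, 1L) > 1]
  draw_violins(groups, ylab = ylab, ...)
  invisible(x)
}
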