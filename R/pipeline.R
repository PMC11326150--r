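#' Run the full displacement-to-stress pipeline
#'
#' End-to-end automated run: load inputs (paths or in-memory objects),
#' reslice segmentations onto the displacement grid, trim to the brain,
#' rescale amplitude, compute the mechanics fields, summarise regions and
#' write all outputs plus a JSON run manifest into one directory.
#'
#' Outputs, named `<subject>_<quantity>_<frames>.nii.gz`: displacement,
#' strain/stress tensors (symmetric 6-component NIfTI), von Mises
#' scalars, J and W; region CSVs (long-format violin data + summary) when
#' an atlas is given, otherwise per-tissue summaries; `manifest.json`
#' recording input hashes, the config, the applied scale factor, the
#' selected frame and invalid-voxel counts.
#'
#' @param displacement a [displacement_field()] or NIfTI path.
#' @param labels a 3-label [label_volume()] or NIfTI path (required).
#' @param out_dir output directory (created if needed).
#' @param atlas optional atlas `label_volume` or NIfTI path.
#' @param affine optional 4x4 matrix or FLIRT-style text file mapping
#'   segmentation world coordinates to displacement world coordinates;
#'   segmentations on a different grid are nearest-neighbour resampled.
#' @param material a [material_table()] or CSV path.
#' @param config a [pipeline_config()] or YAML path.
#' @param subject subject identifier used in file names.
#' @param vtk also export one VTK tensor file per tensor quantity
#'   (first/selected frame)?
#' @param verbose print per-stage progress?
#' @return Invisibly, the [brain_mechanics()] object, with attribute
#'   `manifest` (the manifest list) and `out_dir`.
#' @export
run_pipeline <- function(displacement, labels, out_dir, atlas = NULL,
                         affine = NULL, material = material_table(),
                         config = pipeline_config(), subject = "subject",
                         vtk = FALSE, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  if (missing(labels) || is.null(labels))
    stop("segmentation required: supply a 3-label volume")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  input_paths <- c(
    displacement = if (is.character(displacement)) displacement[1] else NA,
    labels = if (is.character(labels)) labels else NA,
    atlas = if (is.character(atlas)) atlas else NA)
  if (is.character(displacement))
    displacement <- read_displacement_field(displacement,
                                            cycle_duration =
                                              config$cycle_duration)
  if (is.character(labels)) labels <- read_label_volume(labels)
  if (is.character(atlas))
    atlas <- read_label_volume(atlas, lookup = slant_lookup())
  if (is.character(affine)) affine <- read_affine(affine)
  if (is.character(material)) material <- read_material_table(material)
  if (is.character(config)) config <- read_pipeline_config(config)

  if (!same_grid(labels$geometry, displacement$geometry)) {
    say("stage resample: reslicing segmentation onto displacement grid")
    labels <- resample_labels(labels,
                              affine_to_target = if (is.null(affine))
                                diag(4) else affine,
                              target = displacement$geometry)
  }
  if (!is.null(atlas) && !same_grid(atlas$geometry, displacement$geometry)) {
    say("stage resample: reslicing atlas onto displacement grid")
    atlas <- resample_labels(atlas,
                             affine_to_target = if (is.null(affine))
                               diag(4) else affine,
                             target = displacement$geometry)
  }

  say("stage mechanics: %s mode", config$temporal_mode)
  model <- brain_mechanics(displacement, labels, material = material,
                           config = config)
  say("stage mechanics: scale factor %.6g, %d degenerate voxels",
      model$scale_factor, model$counts$F_degenerate)

  frames_tag <- if (is.null(model$selected_frame)) "all"
                else sprintf("frame%d", model$selected_frame)
  p <- function(q) file.path(out_dir,
                             sprintf("%s_%s_%s.nii.gz", subject, q,
                                     frames_tag))
  say("stage export: writing NIfTI volumes")
  write_displacement_field(model$displacement, p("displacement"))
  write_tensor_field(model$E, p("strain"))
  write_tensor_field(model$sigma, p("stress"))
  if (!is.null(model$E_rate)) write_tensor_field(model$E_rate,
                                                 p("strain_rate"))
  write_scalar_field(model$vm_strain, p("vm_strain"))
  write_scalar_field(model$vm_stress, p("vm_stress"))
  write_scalar_field(model$W, p("energy_density"))
  write_scalar_field(model$J, p("jacobian"))
  if (vtk) {
    write_vtk_tensor(model$E, file.path(out_dir,
      sprintf("%s_strain_%s.vtk", subject, frames_tag)))
    write_vtk_tensor(model$sigma, file.path(out_dir,
      sprintf("%s_stress_%s.vtk", subject, frames_tag)))
  }

  say("stage regions: summarising")
  region_atlas <- if (!is.null(atlas)) atlas else labels
  rs_strain <- summarize_regions(model$vm_strain, region_atlas,
                                 warn_empty = FALSE)
  rs_stress <- summarize_regions(model$vm_stress, region_atlas,
                                 warn_empty = FALSE)
  export_violin_data(rs_strain,
                     file.path(out_dir, sprintf("%s_vm_strain_regions.csv",
                                                subject)),
                     subject = subject)
  export_violin_data(rs_stress,
                     file.path(out_dir, sprintf("%s_vm_stress_regions.csv",
                                                subject)),
                     subject = subject)

  manifest <- list(
    software = paste("brainstrain",
                     as.character(utils::packageVersion("brainstrain"))),
    subject = subject,
    inputs = lapply(input_paths[!is.na(input_paths)], function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    config = unclass(config),
    scale_factor = model$scale_factor,
    selected_frame = model$selected_frame,
    invalid_voxel_counts = model$counts,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  say("done in %.1f s", manifest$elapsed_s)
  attr(model, "manifest") <- manifest
  attr(model, "out_dir") <- out_dir
  invisible(model)
}
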