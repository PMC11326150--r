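Package: brainstrain
Title: Voxelwise Brain Biomechanics from 4D MRI Displacement Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes subject-specific biomechanical fields of the human
    brain under cardiac-driven loading from time-resolved 3D MRI
    displacement fields. Given a 4D displacement field, a 3-label tissue
    segmentation (CSF, grey matter, white matter) and optionally a
    133-label functional atlas, the package resamples segmentations onto
    the displacement grid, rescales amplified displacements to
    physiological amplitude, and evaluates voxelwise finite-strain
    quantities: the deformation gradient, Green-Lagrange strain, strain
    rate, compressible Mooney-Rivlin Cauchy stress and strain energy
    density, plus von Mises scalar summaries. Results can be summarised
    over labelled brain regions and exported as NIfTI or VTK volumes and
    long-format CSV suitable for violin plots. Synthetic phantom
    displacement fields with closed-form ground truth support validation
    throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
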