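# brainstrain

Voxelwise biomechanics of the human brain under cardiac-driven loading,
computed directly from time-resolved MRI displacement fields.

Every heartbeat deforms the brain by a fraction of a millimetre. Amplified
cine MRI reconstructs this motion as a 4D displacement field — a 3-vector
per voxel per cardiac phase, relative to diastole — and those displacements
carry mechanical information that numerical head models can only
approximate. `brainstrain` turns such a displacement field, together with a
CSF / grey-matter / white-matter segmentation (and optionally a 133-label
functional atlas), into voxelwise strain, strain-rate and stress maps, and
summarises them over labelled brain regions. It is aimed at researchers
studying the mechanical environment of brain tissue — periventricular
white-matter lesions, vascular dementia, degenerative disease — who have
displacement-field MRI (amplified cine or elastography-derived) and want
subject-specific mechanics without finite-element modelling.

## The model

All computations run on the displacement-field grid under the Eulerian
convention: `U(x, t)` is the displacement of the material point currently
at voxel position `x`, relative to the reference configuration at diastole
(`t = 0`). Per voxel and frame:

- **Deformation gradient** — `F⁻¹ = I − ∇U`, with `∇U` evaluated by
  second-order central differences (first-order one-sided at mask edges);
  `J = det F` is the local volume ratio.
- **Green-Lagrange strain** — `E = ½(FᵀF − I)` (a convention switch
  provides the variant without the ½).
- **Strain rate** — `Ė(t_k) = [E(t_{k+1}) − E(t_{k−1})] / 2Δt` with
  periodic wrap-around over the cardiac cycle.
- **Constitutive law** — compressible, isotropic Mooney-Rivlin strain
  energy with the isochoric/volumetric split

  `W = (G/2)(Ī₁ − 3) + K[(J² − 1)/4 − ln(J)/2]`, `Ī₁ = J^(−2/3) tr(FᵀF)`,

  with per-tissue shear and bulk moduli (defaults: WM `G = 0.624` kPa,
  GM `G = 1.10` kPa, both `K = 5.00e4` kPa; CSF is excluded from stress by
  default).
- **Cauchy stress** — the closed-form derivative
  `σ = (1/J)(∂W/∂F)Fᵀ = (G/J) dev(B̄) + (K/2)(J − 1/J) I`,
  `B̄ = J^(−2/3) FFᵀ`.
- **Von Mises scalars** — `σ_vm = √(3/2 dev σ : dev σ)`,
  `ε_vm = √(2/3 dev E : dev E)`.

Before differentiation the amplified displacements are rescaled by one
global factor so that the maximum in-brain displacement magnitude over all
frames equals 187 µm, a literature value for peak cardiac-cycle brain
displacement. Analysis can cover the full time history or a single,
automatically selected peak frame (largest in-mask 90th-percentile
displacement or strain).

## Worked example

No subject data ships with the package; the phantom generator produces
displacement fields with closed-form ground truth that stand in for
amplified-MRI input (here: a pulsatile field over 16 cardiac phases,
amplified 25×, on a 24³ grid with concentric WM/GM/CSF shells):

```r
library(brainstrain)

ph        <- make_phantom("pulsatile_composite", amplitude = 0.05,
                          n_t = 16, shape = c(24, 24, 24))
amplified <- make_amplified_phantom(ph$field, 25)
model     <- brain_mechanics(amplified, ph$labels)
model
#> Brain biomechanics model
#> Grid: 24 x 24 x 24 voxels, spacing 1.2 x 1.2 x 1.2 mm
#> Frames: 16 (0.0625 s interval)
#> Displacement scale factor: 0.0329144
#> Valid stress voxels per frame: 3184 of 6152 in mask
#> Peak von Mises strain: 5.129 % | peak von Mises stress: 0.1479 kPa
```

The scale factor is the single number that brought the amplified maximum
displacement down to 187 µm. Stress is evaluated on fewer voxels than the
mask holds because the CSF shell is excluded by default. Per-tissue
distributions:

```r
summary(model)
#>              quantity tissue     n    mean      sd  median p5     p95
#>         vm_strain_pct     WM 17020 0.88000 0.74150 0.72170  0 2.22900
#>         vm_strain_pct     GM 33920 1.53100 1.12000 1.52000  0 3.27400
#>         vm_strain_pct    CSF 47490 1.65200 1.22100 1.63700  0 3.60500
#>         vm_stress_kPa     WM 17020 0.01529 0.01281 0.01250  0 0.03892
#>         vm_stress_kPa     GM 33920 0.04994 0.03659 0.04921  0 0.10710
#>         vm_stress_kPa    CSF     0      NA      NA      NA  NA     NA
#>  ...
```

Mean von Mises strains here are of order 1 % — the magnitude expected for
brain tissue once displacements are capped at 187 µm. Region-wise
summaries against the atlas labels (the built-in vascular-dementia set:
left/right caudate, cerebral white matter, hippocampus, pallidum, putamen,
thalamus proper) and violin-plot exports:

```r
rs <- summarize_regions(von_mises(model$E), ph$atlas,
                        regions = builtin_region_set("vascular_dementia"))
rs$summary[1:2, 1:6]
#>  label          name n_voxels    mean      sd  median
#>     36 Right Caudate     8304 0.01475 0.01150 0.01324
#>     37  Left Caudate     8304 0.01475 0.01150 0.01324
export_violin_data(rs, "regions.csv")
plot(model)   # per-tissue violins
```

`run_pipeline()` wraps the whole chain — label reslicing, masking,
rescaling, mechanics, region summaries, NIfTI/VTK export and a JSON run
manifest — around file paths instead of objects, and
`inst/cli/brainstrain.R` exposes it as a shell command with `run`,
`phantom` and `summarize` subcommands.

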