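---
title: "Methods: voxelwise brain biomechanics from displacement-field MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxelwise brain biomechanics from displacement-field MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainstrain)
```

## Scope and model

`brainstrain` computes finite-strain mechanics on the voxel grid of a
time-resolved 3D displacement field of the brain over the cardiac cycle.
The input is the kind of field that amplified cine MRI or elastography
post-processing produces: three orthogonal displacement components per
voxel per cardiac phase, relative to the reference configuration at
diastole (frame 1). The package deliberately performs no registration,
bias correction, skull stripping or tissue classification — those are
consumed as inputs (a 4×4 world-to-world affine, a 3-label segmentation,
optionally a 133-label atlas volume), produced by the user's own imaging
toolchain.

The displacement field is treated as **Eulerian**: `U(x, t)` is the
displacement of the material point currently at `x`. Under that
convention the deformation gradient satisfies `F⁻¹ = I − ∇U` exactly, so
we differentiate on the current grid and invert per voxel. This choice
matters: had we treated `U` as Lagrangian (a function of the reference
position), `F = I + ∇U` would apply instead. The inversion form is
self-consistent with differentiating on the acquired (current) grid, and
the phantom module defines its ground truth under the same convention, so
recovery tests are exact rather than approximate.

Per voxel and frame the chain is:

1. `∇U` by finite differences (below);
2. `F = (I − ∇U)⁻¹`, `J = det F`;
3. Green-Lagrange strain `E = ½(FᵀF − I)`;
4. strain rate by periodic central time differences;
5. compressible Mooney-Rivlin energy
   `W = (G/2)(Ī₁ − 3) + K[(J² − 1)/4 − ln(J)/2]` with
   `Ī₁ = J^(−2/3) tr(FᵀF)`;
6. Cauchy stress `σ = (G/J) dev(B̄) + (K/2)(J − 1/J) I`,
   `B̄ = J^(−2/3) FFᵀ` — the analytic derivative `(1/J)(∂W/∂F)Fᵀ` of the
   energy, not a numerical one;
7. von Mises scalars, with the stress factor 3/2 and strain factor 2/3.

The isotropic/volumetric split in step 5 is the standard polyconvex form:
the volumetric term is zero at `J = 1`, non-negative for all `J > 0`, and
its derivative gives the purely hydrostatic stress `(K/2)(J − 1/J)`. The
test suite verifies the analytic stress against central-difference
numerical differentiation of `W` over 1000 random deformation gradients
with `J ∈ [0.9, 1.1]`, and checks `W ≥ 0`, objectivity under rigid
rotation, and the small-strain limit (`σ → 2G dev ε + K tr ε I`, i.e.
linear elasticity with shear modulus `G` and bulk modulus `K`).

### Strain convention

The conventional Green-Lagrange strain carries a factor ½. A variant
without it (`E = FᵀF − I`) appears in parts of the applied literature, so
both are implemented behind `strain_convention` in `pipeline_config()`;
`"standard"` (with ½) is the default, and every result records which
convention produced it. The two differ by exactly a factor 2 at small
strain, which is worth keeping in mind when comparing published strain
magnitudes.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `target_max_displacement` | 0.187 | mm | Peak cardiac-cycle brain displacement reported in the physiological literature; amplified fields are rescaled to this maximum. |
| `cycle_duration` | 1.0 | s | Heart period; only sets the strain-rate time base (`Δt = cycle_duration / n_t`). Configurable because acquisitions rarely record it alongside the field. |
| `temporal_mode` | `full_history` | — | Evaluate all phases, or only the automatically selected peak phase (`single_timepoint`). |
| `selection_metric` | `displacement_p90` | — | Peak-frame metric: in-mask 90th percentile of displacement magnitude, or of von Mises strain. |
| `percentile` | 90 | % | Robust against isolated hot voxels while still tracking the peak. |
| `downscale_norm` | `vector_magnitude` | — | "Maximum displacement over all orientations" read as the Euclidean norm of the vector; `component_max` gives the per-component reading. |
| `det_floor` | 1e-8 | — | Voxels with `det(I − ∇U)` at or below this are invalidated rather than inverted. |
| `cond_ceiling` | 1e8 | — | Frobenius-estimated condition number above which a voxel is invalidated. |
| `components` | `world` | — | Displacement components interpreted in scanner mm; `voxel` declares them in voxel units. |

Material constants default to white matter `G = 0.624` kPa, grey matter
`G = 1.10` kPa, both with `K = 5.00e4` kPa, and CSF `G = 0.50` kPa,
`K = 2.1e6` kPa. The near-incompressible bulk moduli (five orders of
magnitude above the shear moduli) mean stress maps are dominated by the
volumetric response wherever `J` departs from 1 — a property of this
material model, not an artefact. CSF is excluded from stress and energy
evaluation by default (`include_csf = FALSE`): displacement contrast in
fluid is unreliable, so reporting solid-tissue constitutive stress there
would be misleading. Its constants are retained so the exclusion is a
flag, not a missing row.

### One scale factor per subject

Downscaling applies a single scalar to every component of every frame —
never per-frame factors, which would distort temporal dynamics. The step
is idempotent (a second application returns factor 1) and commutes with
amplification: the strain computed from a downscaled 25×-amplified field
is identical to that from the downscaled original, which the suite
asserts to 1e-10.

## Numerical choices

- **Spatial gradient**: second-order central differences with physical
  spacing in the interior; first-order one-sided differences where a
  neighbour is missing (mask boundary); NaN where no finite neighbour
  exists along an axis. Central differences are exact for affine fields,
  which makes uniform-deformation phantoms exact recovery tests; for
  smooth fields the error is O(h²), asserted by a grid-refinement test
  (error ratio ≥ 3.5 under spacing halving).
- **Degenerate voxels** are invalidated, counted and reported — never
  raised as errors, since isolated noisy voxels must not abort a subject.
- **Strain rate** uses periodic central differences: the cardiac cycle is
  periodic, so wrap-around avoids one-sided bias at the cycle ends. At
  least 3 frames are required.
- **Percentiles** interpolate linearly between order statistics
  (`quantile` type 7) over finite in-mask voxels, per frame; frame-
  selection ties break to the earliest frame.
- **Nearest-neighbour label resampling** maps target voxel centres
  through the world-to-world affine and rounds half-up, so a 2× upsampled
  voxel becomes the expected 2×2×2 block; targets outside the source
  extent become background. No interpolation ever creates new labels.
- **Masking and validity** use NaN uniformly: a voxel invalid at any
  stage is NaN in all downstream fields and excluded from every
  statistic, and NaN is what gets written to NIfTI/VTK exports.
- **Tensor storage**: symmetric tensors are written to NIfTI with 6
  components (xx, yy, zz, xy, xz, yz) on a trailing dimension, general
  tensors with 9 (column-major); symmetry is enforced to 1e-10 at
  construction and re-symmetrised after floating-point matrix products.

## The phantom generator

`make_phantom()` emulates the geometry of the real pipeline inputs —
a displacement field on a ~1.2 mm grid over 16–31 cardiac phases, a
concentric-shell WM/GM/CSF segmentation, an atlas-style label volume —
with deformations whose strain and stress are known in closed form:
uniform stretch, simple shear, dilation, rigid rotation, and a pulsatile
trigonometric field whose amplitude follows `sin²(πt/T)` across the
cycle (zero at diastole, peaking mid-cycle). `make_amplified_phantom()`
multiplies displacements by a factor, emulating amplified-MRI output
before rescaling. Composite-phantom noise is optional and seeded
(default seed 20240801); noise perturbs the field but never the stored
ground truth.

What the phantoms do **not** emulate: real brain geometry and its
convoluted mask boundary, spatially correlated acquisition noise,
partial-volume mixing at tissue interfaces, CSF flow, and registration
error between segmentation and displacement grids. Passing phantom tests
therefore demonstrates correctness of the numerics — differentiation,
inversion, constitutive evaluation, bookkeeping — not fidelity of any
particular subject's physiology. Test problem sizes are 8³–32³ voxels
with 1–16 frames, chosen so the full suite exercises every code path in
seconds; the operations are identical at clinical matrix sizes, only
larger.

## Design decisions on genuinely open points

- **Component convention.** Whether amplified-MRI displacement components
  are stored in world or voxel coordinates is not standardised; world mm
  is the common output and is the default, with `components = "voxel"`
  available.
- **Downscale norm.** The "maximum displacement over all orientations"
  could mean the vector magnitude or the largest component; the magnitude
  is physically natural and is the default, with both implemented.
- **Per-frame percentile.** The 90th-percentile selection metric is
  computed over space within each frame (selection across frames is only
  meaningful that way).
- **Atlas table.** The bundled 133-label lookup
  (`inst/extdata/slant_labels_synthetic.csv`) follows the BrainCOLOR
  naming convention (subcortical ids 4–76, paired cortical ids 100–207)
  so that SLANT-style label volumes are interpretable without running the
  segmentation tool. It is a synthetic stand-in assembled for this
  package, not the segmentation tool's official distribution file; users
  with their own lookup can supply it to `read_label_volume()`.
- **Vascular-dementia set.** The built-in 12-label set is the left/right
  split of caudate, cerebral white matter, hippocampus, pallidum, putamen
  and thalamus proper, resolved by name against the bundled table.
- **Frame indexing** is 1-based throughout the R API, with frame 1 the
  diastolic reference.

## Known limitations

- The constitutive model is isotropic; white-matter fibre anisotropy
  (and with it axonal strain along fibre directions) is out of scope —
  it would require diffusion-weighted data and a fibre-reinforced model.
- The global 187 µm cap is a literature value, not subject-specific;
  absolute stress/strain magnitudes inherit its uncertainty even though
  spatial and temporal patterns do not.
- Strain rate assumes a periodic, evenly sampled cycle; arrhythmic or
  unevenly gated acquisitions violate that.
- Stress at mask boundaries relies on one-sided first-order gradients and
  is correspondingly less accurate than interior values; boundary voxels
  are flagged by their gradient provenance only through the validity
  mask, not a separate quality score.
- With near-incompressible bulk moduli, stress is sensitive to noise in
  `J`; heavy measurement noise inflates the hydrostatic component first.
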