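---
title: "Reconstructing serial block-face grinding stacks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing serial block-face grinding stacks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grindstack)
```

## The measurement process

Serial block-face grinding images an epoxy-embedded specimen by repeatedly
removing a thin layer of material and photographing the freshly exposed
face. The result is an ordered stack of colour micrographs with three
defects that any reconstruction has to undo:

1. **In-plane misalignment.** Between grinds the block is re-mounted and
   re-imaged, so each slice carries its own in-plane transform —
   translation, rotation, and (through mounting pressure and optics) small
   shear and scale components. The specimen itself offers no stable
   landmark, but the *embedding mould* does: its cross-section is invariant
   along the grind axis, so its outline serves as the reference geometry
   every slice is matched against.
2. **Inhomogeneous slice thickness.** The removal per grind is only
   nominally constant. The true axial position of each slice is measured
   (with a micrometre gauge on the remaining block height) rather than
   assumed, which leaves the stack irregularly spaced.
3. **Imaging nuisances.** Stitched microscope tiles can be offset by a
   pixel, and illumination drifts between sessions.

`grindstack` implements the full chain — outline alignment, virtual-stack
interpolation, volume assembly, landmark registration to CT, and surface
validation — together with a synthetic phantom that simulates the chain
forward with known ground truth.

## Alignment to the mould outline

### The match score

The score between a candidate transform $t$ (a pull transform, mapping
reference-frame pixel coordinates to source-image coordinates) and a slice
is a symmetric, saturated distance-field residual between two outline
contours:

$$ s(t) = 1 - \frac{1}{2\,d_{sat}}\left[
   \frac{1}{|T|}\sum_{p \in T} \min(D_S(t\,p),\, d_{sat}) +
   \frac{1}{|S|}\sum_{q \in S} \min(D_T(t^{-1}q),\, d_{sat})
 \right] $$

where $T$ and $S$ are the template and slice outline point sets, $D_T$ and
$D_S$ their Euclidean distance maps, and $d_{sat}$ a saturation distance
(default 25 px). Saturation bounds the influence of any single point and
maps the score to $[0, 1]$: 1 means coincident outlines, 0 means everywhere
farther than $d_{sat}$. Distance fields are smooth almost everywhere, which
suits the derivative-free local optimizer; a Dice-overlap score is
available as an alternative metric (`metric = "dice"`).

### Sub-pixel outlines

Recovering scale to $5\times10^{-3}$ and rotation to $0.2°$ on a
$\sim$200-px-wide outline requires localizing the outline to a few
hundredths of a pixel. A binary outline ring (threshold, largest connected
component, one-pixel boundary) quantizes the contour at half-pixel
granularity and, worse, biases it anisotropically, which we measured as
systematic shear/scale/rotation errors at exactly the tolerance scale.
The package therefore extracts *sub-pixel contours*: wherever two adjacent
pixels straddle the segmentation threshold across the block boundary, the
edge position is estimated by mass conservation over a four-pixel window
normalized to its local plateau levels
($\hat e = r_0 - 0.5 + \sum_q (1 - v_q)$). This estimator is exact for any
monotone antialiased step profile, independent of edge orientation and
sub-pixel phase — the property that matters, because an axis-aligned
template edge has *constant* phase along its whole length, so any
phase-dependent bias acts like a rigid offset of that edge and is absorbed
into the fitted affine parameters.

For the distance maps the contour samples are densified by pairing the two
crossings of each boundary cell (marching-squares connectivity) and adding
the interior points of the resulting segments; the maps are rasterized on a
2$\times$ finer grid. Without densification, the $\sim$1 px tangential gaps
between samples add structured noise to the distance field that tilts the
shallow rotation–shear valley of the objective.

### Search strategy

Alignment is a two-stage template match:

* **Coarse brute force** over translation and rotation only
  (default $t_x, t_y \in [-50, 50]$ px step 2, $\theta \in [-15°, 15°]$
  step 1°, $\approx 8\times10^4$ nodes), evaluated batch-wise in C++.
  Exact score ties break toward the smallest
  $(|t_x|, |t_y|, |\theta|)$ lexicographically, making the stage fully
  deterministic. Within a stack, slice $i{+}1$'s grid is centred on slice
  $i$'s solution by default (`chain_seed`), reflecting the physical
  continuity of the mould between grinds.
* **Simplex refinement** over the five-parameter vector
  $(t_x, t_y, \theta, s, k)$ — translation, rotation, shear, uniform
  scale — with Nelder–Mead (500 evaluations per start, two deterministic
  restarts from the incumbent; restarting rebuilds the collapsed simplex
  and recovers precision in the narrow rotation–shear valley). The affine
  is composed in the fixed order
  $T(t_x,t_y)\, C\, R(\theta)\, Sh(s)\, Sc(k)\, C^{-1}$ with $C$ centring
  at the image centre; the matrix and parameter views agree to $10^{-9}$
  and matrices are validated to be reflection-free.

A refined result is only accepted if it does not lower the score; a slice
whose outline cannot be extracted or matched is reported and skipped rather
than aborting the stack.

## Virtual image stack

Measured positions are snapped to a homogeneous grid of spacing
$\Delta z$ (default 0.150 mm, the published micro-slicing layer spacing):
slice $i$ goes to slot $\mathrm{round}(z_i/\Delta z)$. When two slices
round to the same slot the positionally closer one is kept (ties keep the
earlier slice) and the loser is dropped — dropping loses less information
than averaging blurs, and it keeps every retained layer an *original*
image. Empty interior slots are filled per RGB channel by linear
interpolation between the nearest placed slices, weighted by slot heights,
and rounded half-to-even to 8 bits (bias-free quantization); slots outside
the outermost placed slices would clamp to the nearest slice (with a
position table starting at 0 this cannot occur, but the policy is defined).
Slices landing exactly on grid multiples pass through bit-exactly, and any
intensity field affine in $z$ is reproduced to within one quantization
level when slices sit on grid multiples — both are enforced by tests.

The assembled volume uses the published micro-slicing geometry by default:
$0.050 \times 0.050 \times 0.150$ mm voxels, x along slice columns, y along
slice rows, z along the grind direction, origin at the first slice.
`resample_volume()` moves a volume to any other spacing (for instance the
0.125 mm isotropic CT grid) by trilinear interpolation in physical
coordinates, clamping at the data boundary so the physical extent is
preserved within one voxel.

## Landmark registration to CT

The link between the colour reconstruction and CT volumes is the
closed-form least-squares (Umeyama/Kabsch) fit on paired landmarks: SVD of
the cross-covariance of the centred point sets, determinant corrected to
$+1$ so a reflection can never be returned, optional uniform scale
(`allow_scale`) because dehydration shrinkage can change scale between
modalities — the default is rigid. The fiducial registration error (FRE) is
the RMS of the per-pair Euclidean residuals. In the Monte-Carlo calibration
used by the tests, "isotropic noise of 0.1 mm" means a perturbation whose
*total* 3-D displacement has 0.1 mm RMS (per-axis s.d. $0.1/\sqrt{3}$);
with 10 landmarks the expected mean FRE is then
$0.1\sqrt{1 - 6/30} \approx 0.089$ mm, which the implementation reproduces.
Collinear landmark sets are rejected (the rotation would be
underdetermined). Transforms are exported as plain-text 4×4 matrices and as
ITK-style text transforms for 3D-Slicer interoperability; an intensity-based
refinement stage downstream of this initial transform is deliberately out of
scope.

## Validation metrics

Accuracy is quantified exactly the way block-face reconstructions are
audited in practice: threshold segmentations of the mould in both
modalities are turned into surfaces and compared.

* **Isosurface.** Marching tetrahedra (Kuhn six-tetrahedra decomposition,
  0.5 level, shared linearly interpolated edge vertices) in physical
  coordinates; the mask is padded with one outside layer so the surface is
  watertight and consistently outward-oriented by construction.
* **Sampled symmetric Hausdorff distance.** Area-weighted uniform samples
  (default 70 points/mm², matching the published mesh density; mesh
  vertices are included so sharp features are always represented) are
  measured against the *surface* of the other mesh with exact
  point-to-triangle distances, accelerated by a uniform spatial grid. Both
  directed means/maxima are reported; the symmetric summary uses
  $\mathrm{mean}_{sym} = (\mathrm{mean}_{AB} + \mathrm{mean}_{BA})/2$ and
  $\max_{sym} = \max(\max_{AB}, \max_{BA})$, and the report always states
  both directions because one-directional Hausdorff filters are common and
  not interchangeable with the symmetric version.
* **Volumetric error.** Enclosed volumes by the divergence theorem over
  watertight meshes; the error is the unsigned percent difference relative
  to the reference (CT) volume.

Triangle selection during sampling uses inverse-CDF draws over face areas
rather than alias tables: the draw is then stable under last-ulp area
perturbations, so a rigid motion applied to both meshes reproduces the
sample set and the report exactly.

## The phantom

The phantom is a digital embedded specimen: a rounded-rectangle mould
cross-section (9 × 7 mm at the small preset) with an asymmetric notch that
breaks every in-plane symmetry (no rotation or reflection of the outline
matches itself, so the alignment optimum is unique), an ellipsoidal
inclusion, a tilted cylindrical canal and a thin membrane sheet, each with
its own colour. The forward model applies, per slice:

| noise source                | model                                   | default |
|-----------------------------|-----------------------------------------|---------|
| removal per grind           | $\mathcal N(0.15, \sigma^2)$ mm, floored | $\sigma = 0.03$ mm |
| gauge measurement           | additive $\mathcal N(0, \sigma_g^2)$    | $\sigma_g = 0.005$ mm |
| mounting jitter             | uniform $t_x, t_y, \theta, s, k$        | ±20 px, ±10°, ±0.05, 1±0.02 |
| stitching seam              | 1-px shift of a half-plane, prob. $p$   | $p = 0.1$ |
| illumination drift          | multiplicative sinusoidal gain          | amplitude 0.02 |

Jitter half-widths are the study conditions of the recovery experiments;
the removal noise (20 % of the nominal) and the 5 µm gauge noise are what a
grinder-polisher and a micrometre gauge realistically deliver. Raw slices
are rendered through the *inverse* of the per-slice truth transform, so
aligning a raw slice recovers exactly that transform. Interior structures
are rendered at 2× resolution and box-downsampled; the mould/background
edge is composited analytically from the signed distance of the mould
cross-section, because 4-sample coverage quantization would otherwise put
$\sim$0.25 px of orientation-dependent noise on the very edge the alignment
relies on — rendering error would then dominate algorithmic error, which is
exactly what the phantom must avoid. Stitching seams and illumination
drift are non-affine nuisances: they perturb the images but leave the true
transforms unchanged, which is why `corrupt_stack()` is a separate
operation.

What the phantom does *not* emulate: photorealistic tissue texture, CT
physics (CT-side masks are rasterized from the true labels), mechanical
deformation of the specimen inside the mould, and z-dependent colour
drift. Passing tests therefore demonstrate correctness of the
reconstruction machinery under the modelled error sources, not robustness
to tissue-level appearance variation.

## Numerical choices

* Pixel coordinates are 0-based with transforms acting on
  $(\text{row}, \text{col}, 1)$; `tx` translates the first (row) axis.
  Transform CSVs store row-major 3×3 matrices, one slice per row; because
  published tables do not state the direction convention, the reader takes
  an `invert` flag.
* Warping snaps source coordinates within $10^{-9}$ px to the integer
  grid, so the identity and pure integer translations are bit-exact.
* 8-bit quantization always rounds half-to-even.
* NRRD files are written with explicit diagonal `space directions` and
  `space origin`, gzip raster (RFC 1952, zero mtime so outputs are
  byte-identical across runs), without asserting any anatomical frame.
  PLY vertices are written double-precision so geometry round-trips
  losslessly.
* All stochastic operations take explicit seeds; the end-to-end pipeline
  writes a manifest with MD5 checksums and is bit-reproducible for a fixed
  configuration and seed.
* Configuration files are YAML; unknown blocks or keys abort the run
  before any stage executes, and the resolved configuration is archived
  next to the outputs.

## Problem sizes

The default test and validation scale is the small phantom preset: 20
slices of 256 × 256 px (12.8 mm field at 0.050 mm pixels), which exercises
every stage in about a minute; parameter-recovery experiments use 50–100
independently jittered slices; Hausdorff oracle checks use meshes of a few
hundred vertices where exhaustive enumeration is feasible. A `large`
preset (1024 px, 60 slices) approximates the aspect ratios of real
acquisitions for scaling studies.

## Known limitations

* The alignment metric assumes the mould outline is a closed, mostly
  convex curve with a unique asymmetric feature; moulds with rotational
  symmetry would need a different tie-breaking policy.
* The sub-pixel contour estimator assumes locally monotone edge profiles;
  heavy texture on the block face within two pixels of the outline would
  degrade it toward the binary-ring fallback.
* Landmark registration covers the manual initialization step only;
  intensity-based refinement belongs to downstream tools.
* Published transform tables from other implementations may differ in the
  sub-pixel regime (metric and optimizer are not standardized), so they
  should be treated as approximate, not as bit ground truth.
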