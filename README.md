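# grindstack

Reconstruction and validation of serial block-face grinding image stacks.

Block-face micro-grinding ("micro-slicing") images an epoxy-embedded
specimen — for example a human temporal bone — by repeatedly grinding away
a thin layer and photographing the freshly exposed face in colour. The raw
product is an ordered TIFF stack in which every slice is individually
misaligned (the block is re-mounted between grinds), the slice spacing is
irregular (the true removal per grind is measured with a micrometre gauge,
not assumed), and the images carry stitching and illumination artefacts.
`grindstack` turns such a stack into a registered voxel volume and
quantifies how good the reconstruction is. It is aimed at labs building
colour anatomical volume datasets from embedded specimens and at anyone who
needs a tested, scriptable implementation of this reconstruction chain.

The pipeline:

1. **Alignment** (`align_stack`): each slice is matched to the invariant
   embedding-mould outline by template matching — a brute-force search over
   translation and rotation followed by derivative-free simplex refinement
   of the five-parameter in-plane affine $(t_x, t_y, \theta, s, k)$
   (translation px, rotation°, shear, uniform scale). The match score is a
   symmetric saturated distance-field residual between sub-pixel outline
   contours, $s(t) = 1 - \overline{\min(d, d_{sat})}/d_{sat} \in [0, 1]$.
2. **Reconstruction** (`reconstruct_volume`): aligned slices are placed on
   a homogeneous *virtual image stack* (default spacing 150 µm) at their
   nearest grid position; unfilled layers are linearly interpolated between
   the nearest placed slices, and the result is assembled into an RGB
   volume with 50×50×150 µm voxels (NRRD output).
3. **Registration** (`landmark_register`): closed-form least-squares
   (SVD/Umeyama) rigid or similarity transform from paired landmarks,
   reported with its fiducial registration error (FRE); the exported 4×4
   transform initializes intensity-based refinement in external tools.
4. **Validation** (`compare_overmould`): mould surfaces are extracted from
   binary masks (marching tetrahedra), sampled (default 70 points/mm²),
   and compared by exact point-to-triangle symmetric Hausdorff distances
   plus the unsigned volumetric error in percent of the reference volume.

A synthetic embedded-specimen **phantom** (`generate_phantom`) simulates
the whole acquisition forward — per-slice affine jitter, noisy removal
thickness, gauge error, stitching seams, illumination drift — with exact
ground truth, so every stage is testable without any external data.

## Worked example

Simulate an experiment, align it, reconstruct, and validate against the
phantom's ground truth:

```r
library(grindstack)

res <- run_pipeline(list(global = list(seed = 7)), out_dir = "demo_run")

res$report$hausdorff
#> hausdorff_report (mm): mean A->B 0.000307555 (max 0.05), mean B->A 0.000362957 (max 0.05)
#>   symmetric mean 0.000335256, max 0.05 (268560 + 269044 samples)
res$report$volume$volumetric_error_pct
#> [1] 0.08091075
```

The pipeline generated a 20-slice phantom (256×256 px, 50 µm pixels,
nominal 150 µm removal with 30 µm scatter, mounting jitter up to ±20 px /
±10° / ±5 % shear / ±2 % scale), aligned every slice to the mould outline,
interpolated the stack onto the 150 µm virtual grid and compared the
reconstructed mould against the true one: the surfaces agree to a mean of
~0.0003 mm (the worst sampled point is one in-plane voxel, 0.05 mm, at the
staircase of the notch corners) and the enclosed volumes to ~0.08 %.
`demo_run/` now contains the raw TIFF stack, the recovered `transforms.csv`
(nine-column row-major 3×3 matrices, one row per slice), the
reconstruction as NRRD, the accuracy report, and a `manifest.json` with MD5
checksums — rerunning with the same seed reproduces it byte for byte.

Individual stages are plain functions (`align_stack`, `assign_grid_positions`,
`interpolate_missing`, `assemble_volume`, `landmark_register`,
`extract_isosurface`, `hausdorff_distance`, `mesh_volume`, ...); a thin
command-line front end is included:

```sh
Rscript exec/grindstack phantom     --out run --seed 5
Rscript exec/grindstack align       --stack run/images --positions run/positions.csv \
                                    --template run/template.tif --out run/transforms.csv
Rscript exec/grindstack reconstruct --stack run/images --positions run/positions.csv \
                                    --transforms run/transforms.csv --out run/volume.nrrd
```

See the methods vignette (`vignettes/reconstruction-methods.Rmd`) for the
models, parameter meanings and numerical policies.

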