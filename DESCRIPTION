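Package: grindstack
Title: Reconstruction and Validation of Serial Block-Face Grinding Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for turning serial micro-grinding (block-face sectioning)
    colour image stacks into registered voxel volumes. Each newly exposed face
    of an epoxy-embedded specimen is aligned to the invariant embedding-mould
    outline by template matching (brute-force translation/rotation search plus
    derivative-free affine refinement), the irregularly spaced slices are
    placed on a homogeneous virtual image stack and linearly interpolated,
    and the result is assembled into an RGB voxel volume. Landmark-based
    rigid/similarity registration links the reconstruction to CT volumes, and
    a validation module quantifies reconstruction accuracy via sampled
    symmetric Hausdorff distances and volumetric error between mould
    surfaces. A fully synthetic embedded-specimen phantom with known ground
    truth (per-slice affine jitter, grinding-thickness and gauge noise,
    stitching seams, illumination drift) makes every stage testable without
    any external data. Includes readers/writers for TIFF stacks, layer
    position and transform tables (CSV), NRRD volumes and PLY meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    tools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
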