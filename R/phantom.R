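#' Specification of the synthetic embedded-specimen phantom
#'
#' A digital stand-in for an epoxy-embedded specimen undergoing serial
#' grinding: a rounded-rectangle mould cross-section with an asymmetric
#' notch (so in-plane alignment has a unique optimum), three internal
#' structures (an ellipsoidal inclusion, a tube-like canal, a thin membrane
#' sheet), and a forward model of the acquisition errors: per-slice affine
#' jitter (mounting/placement), noisy grinding removal (inhomogeneous slice
#' thickness), gauge measurement noise, and optional stitching seams and
#' illumination drift.
#'
#' @param size_px image size in pixels (square slices).
#' @param pixel_spacing in-plane pixel spacing (mm).
#' @param n_slices number of grinding steps imaged.
#' @param nominal_removal nominal material removal per grind (mm).
#' @param sigma_removal s.d. of the actual removal (mm).
#' @param sigma_gauge s.d. of the micrometre gauge measurement noise (mm).
#' @param jitter list of per-slice perturbation half-widths: `tx`, `ty`
#'   (px, uniform), `theta` (degrees, uniform), `shear` (uniform),
#'   `scale` (uniform half-width around 1).
#' @param seam_prob probability that a slice carries a 1-px stitching seam.
#' @param drift_amplitude amplitude of the multiplicative illumination
#'   gain field.
#' @param seed RNG seed making the phantom fully deterministic.
#' @param preset `"small"` (256 px, 20 slices; default) or `"large"`
#'   (1024 px, 60 slices) before other overrides are applied.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(size_px = NULL, pixel_spacing = 0.05,
                         n_slices = NULL, nominal_removal = 0.15,
                         sigma_removal = 0.03, sigma_gauge = 0.005,
                         jitter = list(tx = 20, ty = 20, theta = 10,
                                       shear = 0.05, scale = 0.02),
                         seam_prob = 0.1, drift_amplitude = 0.02,
                         seed = 42, preset = c("small", "large")) {
  preset <- match.arg(preset)
  if (is.null(size_px)) size_px <- if (preset == "small") 256L else 1024L
  if (is.null(n_slices)) n_slices <- if (preset == "small") 20L else 60L
  stopifnot(nominal_removal > 0, sigma_removal >= 0, sigma_gauge >= 0,
            seam_prob >= 0, seam_prob <= 1, drift_amplitude >= 0)
  jd <- list(tx = 20, ty = 20, theta = 10, shear = 0.05, scale = 0.02)
  jd[names(jitter)] <- jitter
  scale_mm <- size_px * pixel_spacing / 12.8  # geometry scales with field
  structure(list(
    size_px = as.integer(size_px), pixel_spacing = pixel_spacing,
    n_slices = as.integer(n_slices), nominal_removal = nominal_removal,
    sigma_removal = sigma_removal, sigma_gauge = sigma_gauge,
    jitter = jd, seam_prob = seam_prob, drift_amplitude = drift_amplitude,
    seed = as.integer(seed),
    # mould cross-section (mm, centred coordinates)
    mould = list(hx = 4.5 * scale_mm, hy = 3.5 * scale_mm,
                 radius = 0.8 * scale_mm,
                 notch_centre = 1.8 * scale_mm,
                 notch_width = 1.4 * scale_mm,
                 notch_depth = 0.8 * scale_mm),
    structures = list(
      ellipsoid = list(centre = c(-1.0, 0.6, 1.4) * scale_mm,
                       semi = c(2.0, 1.4, 1.1) * scale_mm,
                       colour = c(170, 70, 70)),
      canal = list(x0 = 1.8 * scale_mm, slope = 0.3, y = -1.4 * scale_mm,
                   radius = 0.5 * scale_mm, colour = c(70, 100, 170)),
      membrane = list(y = -2.3 * scale_mm, half_thickness = 0.06 * scale_mm,
                      half_width = 3.0 * scale_mm,
                      colour = c(235, 235, 215))),
    colours = list(background = c(18, 18, 18), epoxy = c(205, 170, 90))),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: %d slices of %dx%d px @ %g mm, removal %g +/- %g mm, seed %d\n",
    x$n_slices, x$size_px, x$size_px, x$pixel_spacing,
    x$nominal_removal, x$sigma_removal, x$seed))
  invisible(x)
}

#' Analytic cross-section area of the phantom mould (mm^2)
#' @param spec a [phantom_spec()].
#' @export
phantom_mould_area <- function(spec) {
  m <- spec$mould
  4 * m$hx * m$hy - (4 - pi) * m$radius^2 - m$notch_width * m$notch_depth
}

# signed distance (mm) to the mould boundary; negative inside
mould_sdf <- function(spec, x, y) {
  m <- spec$mould
  qx <- abs(x) - (m$hx - m$radius)
  qy <- abs(y) - (m$hy - m$radius)
  d_rr <- sqrt(pmax(qx, 0)^2 + pmax(qy, 0)^2) + pmin(pmax(qx, qy), 0) -
    m$radius
  # notch: axis-aligned rectangle biting into the straight top edge
  nx <- abs(x - m$notch_centre) - m$notch_width / 2
  ny <- abs(y - m$hy) - m$notch_depth
  d_notch <- pmin(pmax(nx, ny), 0) + sqrt(pmax(nx, 0)^2 + pmax(ny, 0)^2)
  pmax(d_rr, -d_notch)
}

# label id at (x, y, z): 0 background, 1 epoxy, 2 ellipsoid, 3 canal,
# 4 membrane
phantom_labels_at <- function(spec, x, y, z) {
  lab <- ifelse(mould_sdf(spec, x, y) <= 0, 1L, 0L)
  s <- spec$structures
  inside <- lab == 1L
  mem <- inside & abs(y - s$membrane$y) <= s$membrane$half_thickness &
    abs(x) <= s$membrane$half_width
  lab[mem] <- 4L
  cx <- s$canal$x0 + s$canal$slope * z
  can <- inside & (x - cx)^2 + (y - s$canal$y)^2 <= s$canal$radius^2
  lab[can] <- 3L
  e <- s$ellipsoid
  ell <- inside & ((x - e$centre[1]) / e$semi[1])^2 +
    ((y - e$centre[2]) / e$semi[2])^2 +
    ((z - e$centre[3]) / e$semi[3])^2 <= 1
  lab[ell] <- 2L
  lab
}

label_colours <- function(spec) {
  rbind(spec$colours$background, spec$colours$epoxy,
        spec$structures$ellipsoid$colour, spec$structures$canal$colour,
        spec$structures$membrane$colour)
}

# render one slice at axial position z, pulled through the inverse of the
# per-slice true transform. Interior structures are rendered at 2x
# resolution and box-downsampled; the mould/background boundary is
# composited analytically from the signed distance (exact sub-pixel edge
# coverage, so outline localization error does not dominate the alignment
# error budget).
render_slice <- function(spec, z, transform = NULL, mould_only = FALSE) {
  n <- spec$size_px
  sp <- spec$pixel_spacing
  ctr <- (n - 1) / 2
  minv <- NULL
  k_scale <- 1
  if (!is.null(transform) && !is_identity_affine(transform)) {
    minv <- unclass(affine2d_invert(transform))
    k_scale <- sqrt(det(unclass(transform)[1:2, 1:2]))
  }
  to_ref_mm <- function(rr, cc) {
    if (!is.null(minv)) {
      r2 <- minv[1, 1] * rr + minv[1, 2] * cc + minv[1, 3]
      c2 <- minv[2, 1] * rr + minv[2, 2] * cc + minv[2, 3]
      rr <- r2; cc <- c2
    }
    list(x = (cc - ctr) * sp, y = (rr - ctr) * sp)
  }
  bg <- spec$colours$background
  cols <- label_colours(spec)
  # interior colours at 2x (outside the mould clamped to epoxy so the edge
  # band blends epoxy against background only)
  fine <- 2L * n
  coord <- (seq_len(fine) - 1 - 0.5) / 2
  p2 <- to_ref_mm(matrix(coord, fine, fine),
                  matrix(coord, fine, fine, byrow = TRUE))
  lab <- if (mould_only) matrix(1L, fine, fine)
         else pmax(phantom_labels_at(spec, p2$x, p2$y, z), 1L)
  interior <- array(0, c(n, n, 3))
  idx <- seq(1, fine, by = 2)
  for (ch in 1:3) {
    p <- matrix(cols[lab + 1L, ch], fine, fine)
    interior[, , ch] <- (p[idx, idx] + p[idx + 1, idx] + p[idx, idx + 1] +
                           p[idx + 1, idx + 1]) / 4
  }
  # analytic mould-edge coverage at 1x pixel centres: signed distance in
  # source-frame pixels (reference distance scaled by the transform's
  # uniform scale)
  p1 <- to_ref_mm(matrix(0:(n - 1), n, n),
                  matrix(0:(n - 1), n, n, byrow = TRUE))
  d_px <- mould_sdf(spec, p1$x, p1$y) / sp * k_scale
  alpha <- pmin(pmax(0.5 - d_px, 0), 1)
  out <- array(0, c(n, n, 3))
  for (ch in 1:3)
    out[, , ch] <- alpha * interior[, , ch] + (1 - alpha) * bg[ch]
  out <- round(out)
  storage.mode(out) <- "integer"
  out
}

#' Generate a synthetic micro-grinding experiment with ground truth
#'
#' Renders the true sections at the (noisy) grinding depths, perturbs each
#' by the inverse of a per-slice true affine transform (so that aligning a
#' raw slice to the template recovers exactly that transform), and returns
#' the raw stack, the gauge-measured layer positions, the reference
#' template outline and the full ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return list with `stack` (raw [image_stack()] with measured positions),
#'   `template` (a [template_outline()]), and `truth`: list of
#'   `transforms` (true per-slice [affine2d()]), `params` (n x 5 matrix),
#'   `positions_true`, `positions_measured` (mm), `mould_area_mm2`
#'   (analytic) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (phantom_mould_area(spec) <= 0)
    stop("phantom spec produces an empty mould", call. = FALSE)
  n <- spec$n_slices
  res <- phantom_draw(spec)
  centre <- rep((spec$size_px - 1) / 2, 2)
  zero_jitter <- all(unlist(spec$jitter) == 0)
  transforms <- lapply(seq_len(n), function(i) {
    if (zero_jitter) affine2d(centre = centre)
    else affine2d(res$params[i, 1], res$params[i, 2], res$params[i, 3],
                  res$params[i, 4], res$params[i, 5], centre = centre)
  })
  slices <- lapply(seq_len(n), function(i)
    slice_image(render_slice(spec, res$pos_true[i], transforms[[i]]),
                rep(spec$pixel_spacing, 2), index = i))
  stack <- image_stack(slices, positions = res$pos_meas)
  # template: unperturbed mould rendered in the reference frame
  tpl_slice <- slice_image(render_slice(spec, z = 0, mould_only = TRUE),
                           rep(spec$pixel_spacing, 2))
  template <- template_outline(tpl_slice,
                               pixel_spacing = rep(spec$pixel_spacing, 2))
  params <- res$params
  if (zero_jitter) params[] <- rep(c(0, 0, 0, 0, 1), each = n)
  list(stack = stack, template = template,
       truth = list(transforms = transforms, params = params,
                    positions_true = res$pos_true,
                    positions_measured = res$pos_meas,
                    mould_area_mm2 = phantom_mould_area(spec),
                    spec = spec))
}

# deterministic draw of the per-slice noise realisation (positions, jitter)
phantom_draw <- function(spec) {
  n <- spec$n_slices
  with_local_seed(spec$seed, {
    removal <- pmax(spec$nominal_removal +
                      stats::rnorm(n - 1, 0, spec$sigma_removal),
                    0.2 * spec$nominal_removal)
    pos_true <- c(0, cumsum(removal))
    pos_meas <- pos_true + c(0, stats::rnorm(n - 1, 0, spec$sigma_gauge))
    # gauge noise must not reorder slices
    for (i in seq_len(n - 1))
      if (pos_meas[i + 1] <= pos_meas[i])
        pos_meas[i + 1] <- pos_meas[i] + 1e-6
    j <- spec$jitter
    params <- cbind(
      tx = stats::runif(n, -j$tx, j$tx),
      ty = stats::runif(n, -j$ty, j$ty),
      theta = stats::runif(n, -j$theta, j$theta),
      shear = stats::runif(n, -j$shear, j$shear),
      scale = stats::runif(n, 1 - j$scale, 1 + j$scale))
    list(pos_true = pos_true, pos_meas = pos_meas, params = params)
  })
}

#' Rasterize the phantom's true label volume
#'
#' Renders the unperturbed phantom labels on a regular voxel grid matching
#' the reconstruction geometry (x along columns, y along rows, z along the
#' grind axis, origin at the first slice).
#'
#' @param spec a [phantom_spec()].
#' @param dz axial spacing (mm); in-plane spacing is the spec's.
#' @param n_slots number of axial layers; defaults to the nominal stack
#'   extent `round(nominal_removal * (n_slices - 1) / dz) + 1`.
#' @param z_positions explicit layer heights (mm) overriding `n_slots`.
#' @return scalar uint8 [volume_grid()] of label ids (0 background,
#'   1 epoxy, 2 inclusion, 3 canal, 4 membrane).
#' @export
phantom_label_volume <- function(spec, dz = 0.15, n_slots = NULL,
                                 z_positions = NULL) {
  n <- spec$size_px
  sp <- spec$pixel_spacing
  if (is.null(z_positions)) {
    if (is.null(n_slots))
      n_slots <- as.integer(
        round(spec$nominal_removal * (spec$n_slices - 1) / dz)) + 1L
    z_positions <- (seq_len(n_slots) - 1) * dz
  }
  ctr <- (n - 1) / 2
  xy <- (seq_len(n) - 1 - ctr) * sp
  # volume axes: (x = columns, y = rows, z)
  X <- matrix(xy, n, n)            # x varies along first axis
  Y <- matrix(xy, n, n, byrow = TRUE)
  vox <- array(0L, c(n, n, length(z_positions)))
  for (k in seq_along(z_positions))
    vox[, , k] <- phantom_labels_at(spec, X, Y, z_positions[k])
  volume_grid(vox, spacing = c(sp, sp, dz), origin = c(0, 0, 0),
              type = "uint8")
}

#' Add stitching seams and illumination drift to a stack
#'
#' Non-affine nuisance model: with probability `seam_prob` a slice gets a
#' one-pixel shift of the half-plane right of a random column (image
#' stitching error); every slice is multiplied by a smooth sinusoidal gain
#' field of amplitude `drift_amplitude` (illumination drift). Ground-truth
#' transforms are unaffected.
#'
#' @param stack an [image_stack()].
#' @param spec a [phantom_spec()] providing `seam_prob` and
#'   `drift_amplitude`.
#' @param seed RNG seed (default: spec seed + 1).
#' @return the corrupted stack.
#' @export
corrupt_stack <- function(stack, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(stack, "image_stack"), inherits(spec, "phantom_spec"))
  if (spec$seam_prob == 0 && spec$drift_amplitude == 0) return(stack)
  n <- length(stack$slices)
  out <- stack
  with_local_seed(seed, {
    for (i in seq_len(n)) {
      px <- out$slices[[i]]$pixels
      d <- dim(px)
      if (spec$seam_prob > 0 && stats::runif(1) < spec$seam_prob) {
        col0 <- sample.int(d[2] - 2, 1) + 1
        shift <- sample(c(-1L, 1L), 1)
        half <- px[, col0:d[2], , drop = FALSE]
        rows <- seq_len(d[1])
        src <- pmin(pmax(rows - shift, 1L), d[1])
        px[, col0:d[2], ] <- half[src, , , drop = FALSE]
      }
      if (spec$drift_amplitude > 0) {
        fr <- sample(1:2, 1); fc <- sample(1:2, 1)
        phr <- stats::runif(1, 0, 2 * pi); phc <- stats::runif(1, 0, 2 * pi)
        gr <- sin(2 * pi * fr * (seq_len(d[1]) - 0.5) / d[1] + phr)
        gc <- sin(2 * pi * fc * (seq_len(d[2]) - 0.5) / d[2] + phc)
        gain <- 1 + spec$drift_amplitude * outer(gr, gc)
        for (ch in 1:3) px[, , ch] <- px[, , ch] * gain
        px <- round(px)
        px[px > 255] <- 255L
        px[px < 0] <- 0L
      }
      storage.mode(px) <- "integer"
      out$slices[[i]]$pixels <- px
    }
  })
  out
}

#' Export a phantom to disk in the standard acquisition layout
#'
#' Writes the raw slices as numbered TIFFs, the measured layer positions as
#' a single-column CSV, the template outline as a PNG mask, and a
#' `ground_truth/` subfolder with the true transforms (nine-column CSV),
#' true positions and the label volume as NRRD — everything needed to run
#' and check the full pipeline from files.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory.
#' @param dz axial spacing for the exported label volume (mm).
#' @return invisibly, a named list of the paths written.
#' @export
export_fixture <- function(phantom, dir, dz = 0.15) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img_dir <- file.path(dir, "images")
  tiffs <- write_tiff_stack(phantom$stack, img_dir)
  pos_csv <- file.path(dir, "positions.csv")
  write_layer_positions(phantom$stack$positions, pos_csv)
  tpl_png <- file.path(dir, "template.png")
  png::writePNG(unclass(phantom$template$mask) * 1, tpl_png)
  tpl_tif <- file.path(dir, "template.tif")
  if (!is.null(phantom$template$image))
    tiff::writeTIFF(phantom$template$image$pixels / 255, tpl_tif,
                    bits.per.sample = 8L, compression = "deflate")
  gt_dir <- file.path(dir, "ground_truth")
  if (!dir.exists(gt_dir)) dir.create(gt_dir)
  tr_csv <- file.path(gt_dir, "transforms.csv")
  write_transform_table(phantom$truth$transforms, tr_csv)
  pos_true_csv <- file.path(gt_dir, "positions_true.csv")
  write_layer_positions(phantom$truth$positions_true, pos_true_csv)
  lab_nrrd <- file.path(gt_dir, "labels.nrrd")
  spec <- phantom$truth$spec
  n_slots <- as.integer(round(max(phantom$stack$positions) / dz)) + 1L
  write_nrrd(phantom_label_volume(spec, dz = dz, n_slots = n_slots),
             lab_nrrd)
  invisible(list(images = tiffs, positions = pos_csv, template = tpl_png,
                 template_image = if (!is.null(phantom$template$image))
                   tpl_tif,
                 transforms_true = tr_csv, positions_true = pos_true_csv,
                 labels = lab_nrrd))
}
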