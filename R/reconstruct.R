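#' Assign slices to virtual-stack grid positions
#'
#' Each slice goes to the homogeneous grid slot nearest its measured
#' position (`round(position / dz)`). When two slices round to the same
#' slot, the one with the smaller `|position - slot * dz|` is kept (ties to
#' the lower slice index) and the loser is marked unplaced.
#'
#' @param positions strictly increasing axial positions (mm), first 0.
#' @param dz virtual slice thickness in mm (default 0.150).
#' @return list with `slots` (1-based slot per slice, NA if unplaced),
#'   `n_slots`, `placed` (slot -> slice index map, NA for empty slots),
#'   and `dz`.
#' @export
assign_grid_positions <- function(positions, dz = 0.150) {
  positions <- validate_positions(as.numeric(positions))
  stopifnot(dz > 0)
  n_slots <- as.integer(round(max(positions) / dz)) + 1L
  slot <- as.integer(round(positions / dz))  # 0-based
  placed <- rep(NA_integer_, n_slots)
  for (i in seq_along(positions)) {
    s <- slot[i] + 1L
    if (is.na(placed[s])) {
      placed[s] <- i
    } else {
      j <- placed[s]
      d_new <- abs(positions[i] - slot[i] * dz)
      d_old <- abs(positions[j] - slot[j] * dz)
      if (d_new < d_old) placed[s] <- i  # tie keeps lower index j
    }
  }
  slice_slot <- rep(NA_integer_, length(positions))
  ok <- !is.na(placed)
  slice_slot[placed[ok]] <- which(ok)
  list(slots = slice_slot, n_slots = n_slots, placed = placed, dz = dz)
}

#' Fill a virtual image stack by linear interpolation
#'
#' Slots without an original slice are linearly interpolated between the
#' nearest placed slices: a slot at height `z` between placed neighbours at
#' `z_lo < z < z_hi` gets `w * lower + (1 - w) * upper` with
#' `w = (z_hi - z)/(z_hi - z_lo)`, per RGB channel, rounded half-to-even to
#' 8 bits. Slots outside the outermost placed slices are clamped to the
#' nearest placed slice.
#'
#' @param stack an aligned [image_stack()] (transforms applied with
#'   [warp_slice()] beforehand, or pass `warp = TRUE`).
#' @param assignment result of [assign_grid_positions()]; computed from
#'   `stack$positions` when `NULL`.
#' @param dz virtual slice thickness (mm).
#' @param warp apply `stack$transforms` to each slice before placement.
#' @param background background colour used when warping.
#' @return a `virtual_stack`: list with `dz`, `images` (one H x W x 3
#'   integer array per slot) and `slots` (per-slot provenance records).
#' @export
interpolate_missing <- function(stack, assignment = NULL, dz = 0.150,
                                warp = FALSE, background = c(0, 0, 0)) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(stack$positions))
    stop("stack has no layer positions", call. = FALSE)
  if (is.null(assignment))
    assignment <- assign_grid_positions(stack$positions, dz)
  dz <- assignment$dz
  placed_slots <- which(!is.na(assignment$placed))
  if (length(placed_slots) < 2)
    stop("reconstruction requires at least 2 placed slices", call. = FALSE)
  get_pixels <- function(i) {
    s <- stack$slices[[i]]
    if (warp && !is.null(stack$transforms))
      s <- warp_slice(s, stack$transforms[[i]], background = background)
    s$pixels
  }
  cache <- new.env(parent = emptyenv())
  pix <- function(i) {
    key <- as.character(i)
    val <- get0(key, envir = cache, inherits = FALSE)
    if (is.null(val)) {
      val <- get_pixels(i)
      assign(key, val, envir = cache)
    }
    val
  }
  n <- assignment$n_slots
  images <- vector("list", n)
  slots <- vector("list", n)
  for (s in seq_len(n)) {
    si <- assignment$placed[s]
    if (!is.na(si)) {
      images[[s]] <- pix(si)
      slots[[s]] <- list(kind = "original", slice = si)
    } else if (s < min(placed_slots) || s > max(placed_slots)) {
      nearest <- placed_slots[which.min(abs(placed_slots - s))]
      images[[s]] <- pix(assignment$placed[nearest])
      slots[[s]] <- list(kind = "clamped", slice = assignment$placed[nearest])
    } else {
      lo <- max(placed_slots[placed_slots < s])
      hi <- min(placed_slots[placed_slots > s])
      w <- (hi - s) / (hi - lo)
      blend <- w * pix(assignment$placed[lo]) +
        (1 - w) * pix(assignment$placed[hi])
      img <- round(blend)  # round half to even
      storage.mode(img) <- "integer"
      images[[s]] <- img
      slots[[s]] <- list(kind = "interpolated",
                         lower = assignment$placed[lo],
                         upper = assignment$placed[hi], weight = w)
    }
  }
  structure(list(dz = dz, images = images, slots = slots,
                 pixel_spacing = stack$slices[[1]]$pixel_spacing),
            class = "virtual_stack")
}

#' @export
print.virtual_stack <- function(x, ...) {
  kinds <- vapply(x$slots, `[[`, character(1), "kind")
  cat(sprintf(
    "virtual_stack: %d slots at dz = %g mm (%d original, %d interpolated, %d clamped)\n",
    length(x$images), x$dz, sum(kinds == "original"),
    sum(kinds == "interpolated"), sum(kinds == "clamped")))
  invisible(x)
}

#' Assemble a virtual stack into an RGB voxel volume
#'
#' Axis order: x along slice columns, y along slice rows, z along the grind
#' direction; origin at the first slice. Default geometry is the published
#' micro-slicing voxel layout, 0.050 x 0.050 mm in-plane and 0.150 mm axial.
#'
#' @param vstack a `virtual_stack` from [interpolate_missing()].
#' @param pixel_spacing in-plane `(row, col)` spacing in mm; defaults to the
#'   stack's own.
#' @return an RGB [volume_grid()].
#' @export
assemble_volume <- function(vstack, pixel_spacing = NULL) {
  stopifnot(inherits(vstack, "virtual_stack"))
  if (is.null(pixel_spacing)) pixel_spacing <- vstack$pixel_spacing
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  d <- dim(vstack$images[[1]])
  nz <- length(vstack$images)
  vox <- array(0L, c(3L, d[2], d[1], nz))
  for (k in seq_len(nz)) {
    # slice (row, col, ch) -> volume (ch, x = col, y = row)
    vox[, , , k] <- aperm(vstack$images[[k]], c(3, 2, 1))
  }
  volume_grid(vox,
              spacing = c(pixel_spacing[2], pixel_spacing[1], vstack$dz),
              origin = c(0, 0, 0), type = "uint8")
}

#' Resample a volume onto a new spacing
#'
#' Trilinear resampling in physical coordinates on the same origin; the
#' physical extent is preserved to within one voxel. Identity spacing
#' returns a bit-exact copy.
#'
#' @param volume a [volume_grid()].
#' @param new_spacing length-3 target spacing (mm), > 0.
#' @export
resample_volume <- function(volume, new_spacing) {
  stopifnot(inherits(volume, "volume_grid"))
  new_spacing <- as.numeric(new_spacing)
  if (length(new_spacing) == 1) new_spacing <- rep(new_spacing, 3)
  stopifnot(length(new_spacing) == 3, all(new_spacing > 0))
  if (isTRUE(all.equal(new_spacing, volume$spacing, tolerance = 1e-12)))
    return(volume)
  d <- vol_dims(volume)
  nd <- pmax(1L, as.integer(round((d - 1) * volume$spacing / new_spacing)) + 1L)
  M <- diag(4)
  resample_channel <- function(ch) {
    array(cpp_resample_trilinear(ch + 0.0, dim(ch), volume$spacing,
                                 volume$origin, nd, new_spacing,
                                 volume$origin, M, 0.0, TRUE), nd)
  }
  if (volume$rgb) {
    vox <- array(0L, c(3L, nd))
    for (c in 1:3) {
      out <- round(resample_channel(array(volume$voxels[c, , , ],
                                          dim(volume$voxels)[-1])))
      out[out < 0] <- 0; out[out > 255] <- 255
      vox[c, , , ] <- out
    }
    volume_grid(vox, new_spacing, volume$origin, type = "uint8")
  } else {
    out <- resample_channel(volume$voxels)
    if (volume$type %in% c("uint8", "uint16", "int16")) {
      out <- round(out)
      storage.mode(out) <- "integer"
    }
    volume_grid(out, new_spacing, volume$origin, type = volume$type)
  }
}

#' Align, interpolate and assemble in one call
#'
#' Convenience wrapper running [warp_slice()] on every slice of an aligned
#' stack, [assign_grid_positions()], [interpolate_missing()] and
#' [assemble_volume()].
#'
#' @param stack an aligned [image_stack()] with positions and transforms.
#' @param dz virtual slice thickness (mm).
#' @param background warp background colour.
#' @return an RGB [volume_grid()].
#' @export
reconstruct_volume <- function(stack, dz = 0.150, background = c(0, 0, 0)) {
  stopifnot(inherits(stack, "image_stack"))
  vstack <- interpolate_missing(stack, dz = dz, warp = TRUE,
                                background = background)
  assemble_volume(vstack)
}
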