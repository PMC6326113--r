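#' Slice images and image stacks
#'
#' A `slice_image` is one colour micrograph of a freshly exposed block face:
#' an H x W x 3 integer array of 8-bit RGB values plus the in-plane pixel
#' spacing in mm. An `image_stack` is the ordered list of slices with their
#' measured axial positions (distance from the first slice, mm) and,
#' once aligned, one in-plane transform per slice.
#'
#' @param pixels H x W x 3 numeric/integer array, values in 0..255.
#' @param pixel_spacing length-2 numeric `(row, col)` spacing in mm, > 0.
#' @param index ordinal position in acquisition order.
#' @return object of class `slice_image`.
#' @export
slice_image <- function(pixels, pixel_spacing, index = NA_integer_) {
  pixels <- as_rgb_array(pixels)
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (length(pixel_spacing) != 2 || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0))
    stop("pixel_spacing must be two positive values (mm)", call. = FALSE)
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing,
                 index = as.integer(index)),
            class = "slice_image")
}

as_rgb_array <- function(pixels) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop("pixels must be an H x W x 3 array", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in 0..255", call. = FALSE)
  storage.mode(pixels) <- "integer"
  pixels
}

#' @export
print.slice_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("slice_image %dx%d px, spacing (%.4g, %.4g) mm, index %s\n",
              d[1], d[2], x$pixel_spacing[1], x$pixel_spacing[2],
              ifelse(is.na(x$index), "?", x$index)))
  invisible(x)
}

#' @param slices list of `slice_image`, all sharing dimensions and spacing.
#' @param positions optional numeric vector of axial positions (mm), one per
#'   slice, first value 0, strictly increasing.
#' @param transforms optional list of [affine2d()] transforms, one per slice.
#' @rdname slice_image
#' @export
image_stack <- function(slices, positions = NULL, transforms = NULL) {
  stopifnot(length(slices) >= 1)
  dims <- lapply(slices, function(s) dim(s$pixels))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("all slices in a stack must share dimensions", call. = FALSE)
  if (!is.null(positions)) {
    positions <- validate_positions(as.numeric(positions))
    if (length(positions) != length(slices))
      stop(sprintf("stack has %d slices but %d layer positions",
                   length(slices), length(positions)), call. = FALSE)
  }
  if (!is.null(transforms) && length(transforms) != length(slices))
    stop("one transform per slice required", call. = FALSE)
  structure(list(slices = slices, positions = positions,
                 transforms = transforms),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$slices[[1]]$pixels)
  cat(sprintf("image_stack: %d slices of %dx%d px%s%s\n",
              length(x$slices), d[1], d[2],
              if (is.null(x$positions)) "" else
                sprintf(", z extent %.3g mm", max(x$positions)),
              if (is.null(x$transforms)) "" else ", aligned"))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$slices)

validate_positions <- function(p) {
  if (anyNA(p) || any(!is.finite(p)))
    stop("layer positions must be finite numbers", call. = FALSE)
  bad <- which(diff(p) <= 0)
  if (length(bad))
    stop(sprintf("layer positions not strictly increasing at index %s",
                 paste(bad + 1, collapse = ", ")), call. = FALSE)
  if (p[1] != 0)
    stop("layer positions must start at 0", call. = FALSE)
  p
}

#' Read an ordered series of RGB TIFF files into a stack
#'
#' @param paths character vector (>= 2) of TIFF files in acquisition order.
#' @param pixel_spacing in-plane `(row, col)` spacing in mm.
#' @return an `image_stack` without positions or transforms.
#' @export
read_tiff_stack <- function(paths, pixel_spacing) {
  stopifnot(length(paths) >= 2)
  slices <- vector("list", length(paths))
  ref_dim <- NULL
  for (i in seq_along(paths)) {
    img <- tryCatch(tiff::readTIFF(paths[[i]]),
                    error = function(e)
                      stop(sprintf("not a decodable TIFF image: %s (%s)",
                                   paths[[i]], conditionMessage(e)),
                           call. = FALSE))
    img <- round(img * 255)  # readTIFF normalizes 8-bit samples to [0, 1]
    if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
    if (length(dim(img)) == 3 && dim(img)[3] == 4)
      img <- img[, , 1:3, drop = FALSE]  # drop alpha
    if (is.null(ref_dim)) {
      ref_dim <- dim(img)[1:2]
    } else if (!all(dim(img)[1:2] == ref_dim)) {
      stop(sprintf(
        "dimension mismatch in %s: %dx%d, expected %dx%d",
        paths[[i]], dim(img)[1], dim(img)[2], ref_dim[1], ref_dim[2]),
        call. = FALSE)
    }
    slices[[i]] <- slice_image(img, pixel_spacing, index = i)
  }
  image_stack(slices)
}

#' Write a stack as numbered TIFF files
#'
#' @param stack an `image_stack`.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return character vector of file paths written.
#' @export
write_tiff_stack <- function(stack, dir, prefix = "slice") {
  stopifnot(inherits(stack, "image_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%04d.tif", prefix,
                                  seq_along(stack$slices)))
  for (i in seq_along(stack$slices)) {
    tiff::writeTIFF(stack$slices[[i]]$pixels / 255, paths[[i]],
                    bits.per.sample = 8L, compression = "deflate")
  }
  paths
}

#' Read a layer-position table
#'
#' One numeric value per row: the axial distance (mm) of each slice from the
#' first slice, as measured on the remaining overmould with a micrometre
#' gauge. A nonzero first value is treated as a constant offset: the whole
#' column is shifted to start at 0 with a warning. Non-monotone sequences are
#' rejected.
#'
#' @param path CSV path (single column, no header).
#' @return numeric vector of positions in mm, first element 0.
#' @export
read_layer_positions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  p <- suppressWarnings(as.numeric(lines))
  if (anyNA(p)) {
    bad <- which(is.na(p))[1]
    stop(sprintf("layer positions %s row %d: not numeric", path, bad),
         call. = FALSE)
  }
  if (length(p) && p[1] != 0) {
    warning(sprintf(
      "layer positions start at %g mm, not 0; shifting to distance from first slice",
      p[1]), call. = FALSE)
    p <- p - p[1]
  }
  validate_positions(p)
}

#' @param positions numeric vector of positions (mm).
#' @rdname read_layer_positions
#' @export
write_layer_positions <- function(positions, path) {
  writeLines(format(as.numeric(positions), digits = 17, trim = TRUE,
                    scientific = FALSE), path)
  invisible(path)
}
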