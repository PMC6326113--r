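#' In-plane affine transforms for slice alignment
#'
#' An `affine2d` object is a 3x3 homogeneous matrix acting on 0-based pixel
#' coordinates `(row, col, 1)`. Matrices follow the *pull* convention: they
#' map reference-frame coordinates to source-image coordinates, because
#' warping resamples by inverse mapping. Use [affine2d_invert()] to flip the
#' direction.
#'
#' The parameter view composes, in this fixed order,
#' `T(tx, ty) %*% C %*% R(theta) %*% Sh(s) %*% Sc(k) %*% C^-1`
#' where `C` centres the rotation/shear/scale at the image centre,
#' `theta` is in degrees, `s` is the (dimensionless) shear applied to the
#' column coordinate, and `k` a uniform scale. `tx` translates along the
#' first (row) axis and `ty` along the second (column) axis, both in pixels
#' of the source image.
#'
#' @param tx,ty translation in pixels (rows, columns).
#' @param theta rotation in degrees about `centre`.
#' @param shear dimensionless shear coefficient.
#' @param scale uniform scale factor (> 0).
#' @param centre numeric length-2 `(row, col)` centre of rotation in 0-based
#'   pixel coordinates; defaults to the origin.
#' @return an object of class `affine2d` (a 3x3 matrix with a `centre`
#'   attribute).
#' @export
affine2d <- function(tx = 0, ty = 0, theta = 0, shear = 0, scale = 1,
                     centre = c(0, 0)) {
  stopifnot(is.numeric(centre), length(centre) == 2, scale > 0)
  th <- theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Sh <- matrix(c(1, 0, shear, 1), 2, 2)
  Sc <- diag(c(scale, scale))
  A <- R %*% Sh %*% Sc
  cen <- as.numeric(centre)
  t_vec <- c(tx, ty) + cen - A %*% cen
  m <- rbind(cbind(A, t_vec), c(0, 0, 1))
  affine2d_from_matrix(m, centre = cen)
}

#' Build an affine2d from an explicit 3x3 matrix
#'
#' @param m 3x3 numeric matrix, bottom row `(0, 0, 1)`, positive determinant
#'   of the upper-left 2x2 block (no reflection).
#' @param centre rotation centre recorded for the parameter view.
#' @export
affine2d_from_matrix <- function(m, centre = c(0, 0)) {
  m <- unname(as.matrix(m))
  if (!all(dim(m) == c(3, 3)) || !all(is.finite(m)))
    stop("affine2d matrix must be a finite 3x3 matrix", call. = FALSE)
  if (max(abs(m[3, ] - c(0, 0, 1))) > 1e-9)
    stop("affine2d bottom row must be (0, 0, 1)", call. = FALSE)
  if (det(m[1:2, 1:2]) <= 0)
    stop("affine2d must not contain a reflection (det <= 0)", call. = FALSE)
  m[3, ] <- c(0, 0, 1)
  structure(m, centre = as.numeric(centre), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  p <- affine2d_params(x)
  cat(sprintf(
    "affine2d: tx=%.4g px, ty=%.4g px, theta=%.4g deg, shear=%.4g, scale=%.6g\n",
    p["tx"], p["ty"], p["theta"], p["shear"], p["scale"]))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Recover the (tx, ty, theta, shear, scale) parameter view
#'
#' Decomposes the upper-left block as rotation times upper-triangular
#' shear/scale (unique for reflection-free matrices built by [affine2d()]).
#'
#' @param t an `affine2d`.
#' @param centre optional centre overriding the one stored on `t`.
#' @return named numeric vector `tx, ty, theta, shear, scale`.
#' @export
affine2d_params <- function(t, centre = NULL) {
  stopifnot(inherits(t, "affine2d"))
  cen <- if (is.null(centre)) attr(t, "centre") else as.numeric(centre)
  A <- unclass(t)[1:2, 1:2]
  theta <- atan2(A[2, 1], A[1, 1])
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  U <- t(R) %*% A
  k <- U[2, 2]
  s <- U[1, 2] / k
  t_vec <- unclass(t)[1:2, 3] - cen + A %*% cen
  c(tx = t_vec[1], ty = t_vec[2], theta = theta * 180 / pi,
    shear = s, scale = k)
}

#' Invert an affine transform
#' @param t an `affine2d`.
#' @export
affine2d_invert <- function(t) {
  stopifnot(inherits(t, "affine2d"))
  affine2d_from_matrix(solve(unclass(t)), centre = attr(t, "centre"))
}

#' Compose two affine transforms (`a` applied after `b`: `a %*% b`)
#' @param a,b `affine2d` objects.
#' @export
affine2d_compose <- function(a, b) {
  stopifnot(inherits(a, "affine2d"), inherits(b, "affine2d"))
  affine2d_from_matrix(unclass(a) %*% unclass(b), centre = attr(a, "centre"))
}

#' Apply a transform to 0-based (row, col) points
#' @param t an `affine2d`.
#' @param pts n x 2 matrix of `(row, col)` coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
affine2d_apply <- function(t, pts) {
  pts <- rbind(t(as.matrix(pts)), 1)
  out <- unclass(t) %*% pts
  t(out[1:2, , drop = FALSE])
}

is_identity_affine <- function(t, tol = 1e-9) {
  max(abs(unclass(t) - diag(3))) <= tol
}

#' Write per-slice transforms as a nine-column CSV
#'
#' Row `i` holds the 3x3 matrix of slice `i` flattened in C-like/row-major
#' order, nine comma-separated values, no header — the table layout used for
#' published micro-slicing transform files.
#'
#' @param transforms list of `affine2d`.
#' @param path output CSV path.
#' @export
write_transform_table <- function(transforms, path) {
  stopifnot(length(transforms) >= 1)
  rows <- vapply(transforms, function(t) {
    stopifnot(inherits(t, "affine2d"))
    paste(format(as.vector(t(unclass(t))), digits = 17, trim = TRUE,
                 scientific = FALSE),
          collapse = ",")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read a transform CSV written by [write_transform_table()]
#'
#' Published transform tables do not state whether rows map image-to-reference
#' or reference-to-image; `invert = TRUE` flips every matrix on read so either
#' convention can be consumed.
#'
#' @param path CSV path, nine numeric fields per row.
#' @param invert invert each matrix after reading.
#' @param centre rotation centre attached to each transform.
#' @return list of `affine2d`.
#' @export
read_transform_table <- function(path, invert = FALSE, centre = c(0, 0)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    vals <- suppressWarnings(as.numeric(strsplit(lines[[i]], ",")[[1]]))
    if (length(vals) != 9 || anyNA(vals))
      stop(sprintf("transform table row %d: expected 9 numeric fields", i),
           call. = FALSE)
    m <- matrix(vals, 3, 3, byrow = TRUE)
    t <- affine2d_from_matrix(m, centre = centre)
    out[[i]] <- if (invert) affine2d_invert(t) else t
  }
  out
}
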