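#' Rigid/similarity 3D transforms
#'
#' A `rigid3d` holds a rotation `R` (3x3, orthonormal, det +1), a
#' translation (mm) and an optional uniform scale; it maps moving-volume
#' physical coordinates into fixed-volume physical coordinates:
#' `x_fixed = scale * R %*% x_moving + t`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric (mm).
#' @param scale uniform scale factor (> 0).
#' @export
rigid3d <- function(rotation = diag(3), translation = c(0, 0, 0),
                    scale = 1) {
  rotation <- unname(as.matrix(rotation))
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      det(rotation) < 0)
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  stopifnot(is.numeric(scale), length(scale) == 1, scale > 0)
  structure(list(rotation = rotation,
                 translation = as.numeric(translation),
                 scale = as.numeric(scale)),
            class = "rigid3d")
}

#' @export
print.rigid3d <- function(x, ...) {
  cat(sprintf("rigid3d: translation (%.4g, %.4g, %.4g) mm, scale %.6g\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$scale))
  print(x$rotation)
  invisible(x)
}

#' 4x4 homogeneous matrix of a rigid3d (moving -> fixed)
#' @param t a `rigid3d`.
#' @export
rigid3d_matrix <- function(t) {
  m <- diag(4)
  m[1:3, 1:3] <- t$scale * t$rotation
  m[1:3, 4] <- t$translation
  m
}

#' Apply a rigid3d to an n x 3 point matrix
#' @param t a `rigid3d`.
#' @param pts n x 3 matrix of points (mm).
#' @export
rigid3d_apply <- function(t, pts) {
  pts <- as.matrix(pts)
  t(t$scale * t$rotation %*% t(pts) + t$translation)
}

#' Invert a rigid3d
#' @param t a `rigid3d`.
#' @export
rigid3d_invert <- function(t) {
  Rinv <- t(t$rotation)
  rigid3d(Rinv, -Rinv %*% t$translation / t$scale, 1 / t$scale)
}

#' Closed-form landmark registration (Umeyama / Kabsch)
#'
#' Finds the rigid (optionally similarity) transform minimizing the sum of
#' squared residuals between paired landmarks: SVD of the cross-covariance
#' of the centred point sets, with the determinant corrected to +1 so no
#' reflection can be returned. The fiducial registration error (FRE) is the
#' RMS residual over the pairs after alignment.
#'
#' @param fixed n x 3 matrix of fixed-volume landmarks (mm).
#' @param moving n x 3 matrix of corresponding moving-volume landmarks (mm).
#' @param allow_scale estimate a uniform scale (similarity transform);
#'   `FALSE` (default) forces scale exactly 1 (rigid).
#' @return list with `transform` (a [rigid3d()], moving -> fixed) and `fre`
#'   (mm).
#' @export
landmark_register <- function(fixed, moving, allow_scale = FALSE) {
  fixed <- unname(as.matrix(fixed))
  moving <- unname(as.matrix(moving))
  if (!is.numeric(fixed) || !is.numeric(moving) ||
      ncol(fixed) != 3 || ncol(moving) != 3 ||
      nrow(fixed) != nrow(moving))
    stop("landmarks must be two n x 3 matrices of paired points",
         call. = FALSE)
  n <- nrow(fixed)
  if (n < 3)
    stop("at least 3 landmark pairs are required", call. = FALSE)
  mf <- colMeans(fixed)
  mm <- colMeans(moving)
  X <- sweep(moving, 2, mm)  # centred moving
  Y <- sweep(fixed, 2, mf)   # centred fixed
  # collinearity check on the moving set
  sv_m <- svd(X)$d
  if (sv_m[2] <= 1e-9 * max(sv_m[1], 1))
    stop("degenerate landmark configuration: points are collinear",
         call. = FALSE)
  H <- crossprod(Y, X) / n   # sum over pairs of y x^T / n
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  k <- if (allow_scale) {
    var_m <- sum(X^2) / n
    sum(s$d * diag(D)) / var_m
  } else 1
  t_vec <- mf - k * R %*% mm
  transform <- rigid3d(R, t_vec, k)
  resid <- fixed - rigid3d_apply(transform, moving)
  fre <- sqrt(mean(rowSums(resid^2)))
  list(transform = transform, fre = fre)
}

#' Resample a moving volume through a rigid3d into a reference grid
#'
#' Trilinear interpolation in physical coordinates: every voxel of the
#' reference geometry is pulled back through the inverse transform into the
#' moving volume. Out-of-field voxels receive `padding`.
#'
#' @param moving a scalar [volume_grid()].
#' @param transform a [rigid3d()] mapping moving -> fixed coordinates.
#' @param reference a [volume_grid()] (or list with `dims`, `spacing`,
#'   `origin`) defining the output geometry.
#' @param padding value for out-of-field voxels.
#' @export
apply_transform_volume <- function(moving, transform, reference,
                                   padding = 0) {
  stopifnot(inherits(moving, "volume_grid"), inherits(transform, "rigid3d"))
  if (moving$rgb)
    stop("apply_transform_volume expects a scalar volume", call. = FALSE)
  if (inherits(reference, "volume_grid")) {
    ref <- list(dims = vol_dims(reference), spacing = reference$spacing,
                origin = reference$origin)
  } else ref <- reference
  Minv <- rigid3d_matrix(rigid3d_invert(transform))
  out <- cpp_resample_trilinear(moving$voxels + 0.0, dim(moving$voxels),
                                moving$spacing, moving$origin,
                                as.integer(ref$dims), ref$spacing,
                                ref$origin, Minv, padding)
  out <- array(out, ref$dims)
  if (moving$type %in% c("uint8", "uint16", "int16")) {
    out <- round(out)
    storage.mode(out) <- "integer"
  }
  volume_grid(out, ref$spacing, ref$origin, type = moving$type)
}

#' Export / import a rigid3d as a plain-text 4x4 matrix
#'
#' The file holds the homogeneous moving-to-fixed matrix, four
#' whitespace-separated values per row. [import_transform()] validates that
#' the rotation block is orthonormal up to a uniform scale.
#'
#' @param transform a [rigid3d()].
#' @param path output path.
#' @export
export_transform <- function(transform, path) {
  stopifnot(inherits(transform, "rigid3d"))
  m <- rigid3d_matrix(transform)
  writeLines(apply(m, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " ")), path)
  invisible(path)
}

#' @rdname export_transform
#' @export
import_transform <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 4)
    stop(sprintf("%s: expected a 4x4 matrix (4 rows)", path), call. = FALSE)
  m <- t(vapply(strsplit(trimws(lines), "\\s+"), function(s) {
    v <- suppressWarnings(as.numeric(s))
    if (length(v) != 4 || anyNA(v))
      stop(sprintf("%s: malformed matrix row", path), call. = FALSE)
    v
  }, numeric(4)))
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop(sprintf("%s: bottom row must be (0 0 0 1)", path), call. = FALSE)
  A <- m[1:3, 1:3]
  k <- det(A)^(1 / 3)
  if (!is.finite(k) || k <= 0)
    stop(sprintf("%s: rotation block must have positive determinant", path),
         call. = FALSE)
  R <- A / k
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop(sprintf("%s: rotation block is not orthonormal (up to scale)",
                 path), call. = FALSE)
  # re-orthonormalize exactly via SVD to satisfy the 1e-9 invariant
  s <- svd(R)
  R <- s$u %*% t(s$v)
  rigid3d(R, m[1:3, 4], k)
}

#' Write a rigid3d in ITK text transform form (3D Slicer interop)
#'
#' Emits an `.tfm`-style `AffineTransform_double_3_3` with the 3x3 matrix in
#' row-major order followed by the translation, the format 3D Slicer reads
#' for linear transforms.
#'
#' @param transform a [rigid3d()].
#' @param path output path (conventionally `.tfm`).
#' @export
export_transform_itk <- function(transform, path) {
  stopifnot(inherits(transform, "rigid3d"))
  A <- transform$scale * transform$rotation
  params <- c(as.vector(t(A)), transform$translation)
  writeLines(c(
    "#Insight Transform File V1.0",
    "#Transform 0",
    "Transform: AffineTransform_double_3_3",
    paste("Parameters:", paste(format(params, digits = 17, trim = TRUE,
                                      scientific = FALSE), collapse = " ")),
    "FixedParameters: 0 0 0"), path)
  invisible(path)
}

#' Read a six-column landmark pair CSV (fx,fy,fz,mx,my,mz in mm)
#'
#' @param path CSV path; a header row is detected and skipped.
#' @return list with `fixed` and `moving` n x 3 matrices.
#' @export
read_landmarks <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- anyNA(suppressWarnings(as.numeric(
    strsplit(first, ",")[[1]])))
  tab <- utils::read.csv(path, header = has_header)
  if (ncol(tab) != 6)
    stop(sprintf("%s: expected 6 columns (fx,fy,fz,mx,my,mz)", path),
         call. = FALSE)
  list(fixed = as.matrix(tab[, 1:3]), moving = as.matrix(tab[, 4:6]))
}
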