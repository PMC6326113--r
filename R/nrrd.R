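#' Voxel volumes and NRRD serialization
#'
#' A `volume_grid` is a right-handed 3D voxel array with per-axis spacing and
#' origin in mm. Axis order is fixed: x (slice columns), y (slice rows),
#' z (grind direction); the first array index is x and is the fastest-varying
#' axis on disk. Scalar volumes are stored as a `(nx, ny, nz)` array (8-bit
#' colour channels use `uint8`, CT-style data `uint16`/`int16`), RGB volumes
#' as `(3, nx, ny, nz)` with the colour axis fastest.
#'
#' @param voxels 3D numeric/integer array, or 4D with first dim 3 for RGB.
#' @param spacing length-3 numeric `(x, y, z)` voxel spacing in mm, > 0.
#' @param origin length-3 numeric origin (mm) of voxel `(1,1,1)`.
#' @param type storage type, one of `"uint8"`, `"uint16"`, `"int16"`,
#'   `"float"`, `"double"`; inferred from the data when `NULL`.
#' @return object of class `volume_grid`.
#' @export
volume_grid <- function(voxels, spacing, origin = c(0, 0, 0), type = NULL) {
  d <- dim(voxels)
  if (is.null(d) || !(length(d) %in% c(3, 4)))
    stop("voxels must be a 3D array or a (3, nx, ny, nz) RGB array",
         call. = FALSE)
  rgb <- length(d) == 4
  if (rgb && d[1] != 3)
    stop("RGB volumes must have the 3-sample colour axis first",
         call. = FALSE)
  if (any(d == 0) || prod(d) == 0)
    stop("empty volume: all dimensions must be positive", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (mm)", call. = FALSE)
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3, all(is.finite(origin)))
  if (is.null(type)) {
    type <- if (is.integer(voxels) || max(abs(voxels - round(voxels))) == 0) {
      if (min(voxels) >= 0 && max(voxels) <= 255) "uint8"
      else if (min(voxels) >= 0 && max(voxels) <= 65535) "uint16"
      else "double"
    } else "double"
  }
  type <- match.arg(type, c("uint8", "uint16", "int16", "float", "double"))
  if (rgb && type != "uint8")
    stop("RGB volumes are stored as uint8", call. = FALSE)
  storage.mode(voxels) <- if (type %in% c("float", "double")) "double"
                          else "integer"
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 type = type, rgb = rgb),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- vol_dims(x)
  cat(sprintf("volume_grid %s %dx%dx%d, spacing (%g, %g, %g) mm, %s\n",
              if (x$rgb) "RGB" else "scalar", d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3], x$type))
  invisible(x)
}

vol_dims <- function(v) {
  d <- dim(v$voxels)
  if (v$rgb) d[-1] else d
}

nrrd_type_string <- c(uint8 = "unsigned char", uint16 = "unsigned short",
                      int16 = "short", float = "float", double = "double")
nrrd_type_bytes <- c(uint8 = 1L, uint16 = 2L, int16 = 2L, float = 4L,
                     double = 8L)

#' Write a volume as NRRD
#'
#' Writes an NRRD0004 header with explicit `space directions` (diagonal, mm)
#' and `space origin`, gzip-encoded little-endian raster. RGB volumes get a
#' leading 3-sample colour axis with kind `RGB-color`. No anatomical frame is
#' asserted (`space dimension: 3`).
#'
#' @param volume a `volume_grid`.
#' @param path output path.
#' @export
write_nrrd <- function(volume, path) {
  stopifnot(inherits(volume, "volume_grid"))
  d <- dim(volume$voxels)
  sp <- volume$spacing
  dirs <- sprintf("(%.17g,0,0) (0,%.17g,0) (0,0,%.17g)", sp[1], sp[2], sp[3])
  if (volume$rgb) dirs <- paste("none", dirs)
  hdr <- c(
    "NRRD0004",
    "# written by grindstack",
    sprintf("type: %s", nrrd_type_string[[volume$type]]),
    sprintf("dimension: %d", length(d)),
    sprintf("sizes: %s", paste(d, collapse = " ")),
    "space dimension: 3",
    sprintf("space directions: %s", dirs),
    sprintf("kinds: %s", paste(c(if (volume$rgb) "RGB-color", "domain",
                                 "domain", "domain"), collapse = " ")),
    "endian: little",
    "encoding: gzip",
    sprintf("space origin: (%.17g,%.17g,%.17g)", volume$origin[1],
            volume$origin[2], volume$origin[3]),
    "")
  nbytes <- nrrd_type_bytes[[volume$type]]
  raw_data <- if (volume$type == "float") {
    writeBin(as.numeric(volume$voxels), raw(), size = 4, endian = "little")
  } else if (volume$type == "double") {
    writeBin(as.numeric(volume$voxels), raw(), size = 8, endian = "little")
  } else {
    writeBin(as.integer(volume$voxels), raw(), size = nbytes,
             endian = "little")
  }
  # RFC 1952 gzip via gzfile (zero mtime: byte-identical across runs)
  tmp <- tempfile(fileext = ".gz")
  gz <- gzfile(tmp, "wb")
  writeBin(raw_data, gz)
  close(gz)
  con <- file(path, "wb")
  on.exit({close(con); unlink(tmp)})
  writeLines(hdr, con, sep = "\n")
  writeBin(readBin(tmp, "raw", file.info(tmp)$size), con)
  invisible(path)
}

#' Read an NRRD volume
#'
#' Supports the dialect written by [write_nrrd()] plus common variants:
#' raw or gzip encoding, little/big endian, `spacings` or diagonal
#' `space directions`, 3D scalar or 4D 3-channel colour data. Anything else
#' (e.g. other encodings, non-diagonal direction matrices) is rejected with
#' an explicit unsupported-feature error.
#'
#' @param path NRRD file path.
#' @return a `volume_grid`.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD"))
    stop(sprintf("%s: not an NRRD file", path), call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !nzchar(line)) break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
    if (length(kv) == 2) fields[[tolower(kv[1])]] <- kv[2]
  }
  need <- function(k) {
    if (is.null(fields[[k]]))
      stop(sprintf("%s: missing NRRD field '%s'", path, k), call. = FALSE)
    fields[[k]]
  }
  sizes <- as.integer(strsplit(trimws(need("sizes")), "\\s+")[[1]])
  ndim <- as.integer(need("dimension"))
  if (length(sizes) != ndim || !(ndim %in% c(3, 4)))
    stop(sprintf("%s: unsupported NRRD dimension %d", path, ndim),
         call. = FALSE)
  rgb <- ndim == 4
  if (rgb && sizes[1] != 3)
    stop(sprintf("%s: unsupported 4D NRRD (first axis must be 3 samples)",
                 path), call. = FALSE)
  type_raw <- tolower(need("type"))
  type <- switch(type_raw,
    "unsigned char" = , "uchar" = , "uint8" = , "uint8_t" = "uint8",
    "unsigned short" = , "ushort" = , "uint16" = , "uint16_t" = "uint16",
    "short" = , "int16" = , "int16_t" = , "signed short" = "int16",
    "float" = "float",
    "double" = "double",
    stop(sprintf("%s: unsupported NRRD type '%s'", path, type_raw),
         call. = FALSE))
  encoding <- tolower(need("encoding"))
  if (!encoding %in% c("raw", "gzip", "gz"))
    stop(sprintf("%s: unsupported NRRD encoding '%s'", path, encoding),
         call. = FALSE)
  endian <- tolower(fields[["endian"]] %||% "little")
  # geometry
  spacing <- NULL
  if (!is.null(fields[["space directions"]])) {
    toks <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)|none", fields[["space directions"]]))[[1]]
    vecs <- toks[toks != "none"]
    if (length(vecs) != 3)
      stop(sprintf("%s: expected 3 space direction vectors", path),
           call. = FALSE)
    m <- t(vapply(vecs, function(s)
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]), numeric(3)))
    if (max(abs(m - diag(diag(m)))) > 1e-12)
      stop(sprintf("%s: unsupported non-axis-aligned space directions", path),
           call. = FALSE)
    spacing <- diag(m)
  } else if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(trimws(fields[["spacings"]]), "\\s+")[[1]])
    spacing <- sp[!is.na(sp)]
  } else {
    spacing <- c(1, 1, 1)
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  # raster
  payload <- readBin(con, "raw", n = file.info(path)$size)
  if (encoding != "raw")
    payload <- memDecompress(payload, type = "gzip")
  n <- prod(sizes)
  nbytes <- nrrd_type_bytes[[type]]
  if (length(payload) < n * nbytes)
    stop(sprintf("%s: truncated NRRD raster", path), call. = FALSE)
  vals <- if (type %in% c("float", "double")) {
    readBin(payload, "double", n = n, size = nbytes, endian = endian)
  } else {
    readBin(payload, "integer", n = n, size = nbytes,
            signed = (type == "int16"), endian = endian)
  }
  voxels <- array(vals, dim = sizes)
  volume_grid(voxels, spacing = spacing, origin = origin, type = type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
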