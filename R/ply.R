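#' Triangle meshes and PLY serialization
#'
#' Validation surfaces are plain indexed triangle meshes: an n x 3 vertex
#' matrix in mm and an m x 3 matrix of 1-based vertex indices. Degenerate
#' (zero-area) faces are dropped at construction.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param clean drop exactly-degenerate faces (default TRUE).
#' @return object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, clean = TRUE) {
  vertices <- unname(as.matrix(vertices))
  faces <- unname(as.matrix(faces))
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || ncol(faces) != 3)
    stop("vertices and faces must have 3 columns", call. = FALSE)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  if (clean && nrow(faces) > 0) {
    a <- vertices[faces[, 1], , drop = FALSE]
    e1 <- vertices[faces[, 2], , drop = FALSE] - a
    e2 <- vertices[faces[, 3], , drop = FALSE] - a
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    area2 <- rowSums(cr^2)
    faces <- faces[area2 > 0, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is_watertight(x)) ", watertight" else ""))
  invisible(x)
}

#' Per-face areas (mm^2) of a mesh
#' @param mesh a `triangle_mesh`.
#' @export
face_areas <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] - a
  e2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Is the mesh watertight and consistently oriented?
#'
#' TRUE iff every undirected edge is shared by exactly two faces traversing
#' it in opposite directions.
#'
#' @param mesh a `triangle_mesh`.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  tab <- table(key)
  if (any(tab != 2)) return(FALSE)
  dir_key <- paste(he[, 1], he[, 2])
  all(table(dir_key) == 1)
}

#' Write a mesh as PLY
#'
#' Binary little-endian by default with double-precision vertex coordinates
#' (so geometry round-trips losslessly); `ascii = TRUE` writes the text form.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path.
#' @param ascii write ASCII PLY instead of binary.
#' @export
write_ply <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (ascii) "ascii" else "binary_little_endian"),
           "comment written by grindstack",
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (ascii) {
    vtx <- apply(mesh$vertices, 1, function(r)
      paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
            collapse = " "))
    fc <- apply(mesh$faces - 1L, 1, function(r)
      paste(c(3L, r), collapse = " "))
    writeLines(c(hdr, vtx, fc), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.numeric(t(mesh$vertices)), con, size = 8, endian = "little")
    if (nf > 0) {
      fm <- t(mesh$faces - 1L)
      for (i in seq_len(nf)) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(fm[, i]), con, size = 4, endian = "little")
      }
    }
  }
  invisible(path)
}

#' Read a PLY mesh (positions and triangular faces only)
#'
#' Accepts ASCII and binary little-endian files with float or double vertex
#' coordinates; other formats or non-triangular faces are rejected.
#'
#' @param path PLY file path.
#' @return a `triangle_mesh`.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readLines(con, n = 1), "ply"))
    stop(sprintf("%s: not a PLY file", path), call. = FALSE)
  fmt <- NULL; nv <- 0L; nf <- 0L
  vprops <- character(0)
  element <- ""
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0)
      stop(sprintf("%s: truncated PLY header", path), call. = FALSE)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      element <- tok[2]
      if (element == "vertex") nv <- as.integer(tok[3])
      if (element == "face") nf <- as.integer(tok[3])
    } else if (tok[1] == "property" && element == "vertex") {
      if (tok[2] == "list")
        stop(sprintf("%s: list properties on vertices unsupported", path),
             call. = FALSE)
      vprops <- c(vprops, tok[2])
    } else if (tok[1] == "end_header") break
  }
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop(sprintf("%s: unsupported PLY format '%s'", path, fmt), call. = FALSE)
  np <- length(vprops)
  if (np < 3)
    stop(sprintf("%s: vertices must carry x, y, z", path), call. = FALSE)
  if (fmt == "ascii") {
    rest <- readLines(con)
    rest <- rest[nzchar(trimws(rest))]
    vl <- rest[seq_len(nv)]
    V <- t(vapply(strsplit(trimws(vl), "\\s+"),
                  function(s) as.numeric(s[1:3]), numeric(3)))
    fl <- rest[nv + seq_len(nf)]
    F <- t(vapply(strsplit(trimws(fl), "\\s+"), function(s) {
      n <- as.integer(s[1])
      if (n != 3) stop(sprintf("%s: non-triangular face", path),
                       call. = FALSE)
      as.integer(s[2:4])
    }, integer(3)))
  } else {
    psize <- vapply(vprops, function(p) switch(p,
      float = 4L, float32 = 4L, double = 8L, float64 = 8L,
      stop(sprintf("%s: unsupported vertex property type '%s'", path, p),
           call. = FALSE)), integer(1))
    V <- matrix(0, nv, 3)
    for (i in seq_len(nv)) {
      for (j in seq_len(np)) {
        val <- readBin(con, "double", n = 1, size = psize[j],
                       endian = "little")
        if (j <= 3) V[i, j] <- val
      }
    }
    F <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1))
      if (cnt != 3L) stop(sprintf("%s: non-triangular face", path),
                          call. = FALSE)
      F[i, ] <- readBin(con, "integer", n = 3, size = 4, endian = "little")
    }
  }
  triangle_mesh(V, F + 1L, clean = FALSE)
}
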