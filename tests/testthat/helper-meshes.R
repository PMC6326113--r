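# Mesh fixtures built in code, plus an independent point-to-mesh distance
# oracle used to check the accelerated implementation.

cube_mesh <- function(side = 1, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side),
                             z = c(0, side)))
  v <- sweep(v, 2, origin, "+")
  # 12 outward-oriented triangles (vertex rows follow expand.grid order)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),      # z = 0 face (normal -z)
    c(5, 6, 7), c(6, 8, 7),      # z = side (+z)
    c(1, 2, 5), c(2, 6, 5),      # y = 0 (-y)
    c(3, 7, 4), c(4, 7, 8),      # y = side (+y)
    c(1, 5, 3), c(3, 5, 7),      # x = 0 (-x)
    c(2, 4, 6), c(4, 8, 6))      # x = side (+x)
  triangle_mesh(v, f)
}

icosphere <- function(subdiv = 2, radius = 1, centre = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    edge_id <- new.env(parent = emptyenv())
    mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- get0(key, envir = edge_id)
      if (is.null(id)) {
        v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
        id <- nrow(v)
        assign(key, id, envir = edge_id)
      }
      id
    }
    nf <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- mid(a, b); bc <- mid(b, c); ca <- mid(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, centre, "+")
  triangle_mesh(v, f)
}

# distance from each row of P to the closest point of any triangle,
# by exhaustive enumeration of candidates (plane projection if the foot is
# inside the triangle, plus the three clamped edge segments)
oracle_point_mesh_dist <- function(P, mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  E0 <- B - A
  E1 <- C - A
  d00 <- rowSums(E0 * E0)
  d01 <- rowSums(E0 * E1)
  d11 <- rowSums(E1 * E1)
  denom <- d00 * d11 - d01^2
  seg_d2 <- function(p, U, W) {
    D <- W - U
    L2 <- rowSums(D * D)
    PU <- sweep(U, 2, p, "-")
    t <- pmin(pmax(-rowSums(PU * D) / pmax(L2, 1e-300), 0), 1)
    Q <- U + D * t
    rowSums(sweep(Q, 2, p)^2)
  }
  vapply(seq_len(nrow(P)), function(i) {
    p <- P[i, ]
    AP <- sweep(A, 2, p, "-") * -1
    d20 <- rowSums(AP * E0)
    d21 <- rowSums(AP * E1)
    v <- (d11 * d20 - d01 * d21) / denom
    w <- (d00 * d21 - d01 * d20) / denom
    foot <- A + E0 * v + E1 * w
    d2_face <- rowSums(sweep(foot, 2, p)^2)
    d2_face[!(v >= 0 & w >= 0 & v + w <= 1) | denom <= 0] <- Inf
    d2 <- pmin(d2_face, seg_d2(p, A, B), seg_d2(p, B, C), seg_d2(p, C, A))
    sqrt(min(d2))
  }, numeric(1))
}

# deterministic pseudo-random valid affine transforms for round-trip tests
random_affine_list <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    affine2d(runif(1, -30, 30), runif(1, -30, 30), runif(1, -20, 20),
             runif(1, -0.1, 0.1), runif(1, 0.8, 1.2),
             centre = runif(2, 0, 200)))
}

random_rotation3d <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

sphere_mask <- function(radius_vox, n = NULL, spacing = 1) {
  if (is.null(n)) n <- ceiling(2 * radius_vox) + 8
  ctr <- (n - 1) / 2
  g <- (seq_len(n) - 1 - ctr)
  a <- array(0L, c(n, n, n))
  for (k in seq_len(n))
    a[, , k] <- (outer(g^2, g^2, "+") + g[k]^2 <= radius_vox^2) * 1L
  volume_grid(a, rep(spacing, 3), type = "uint8")
}
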