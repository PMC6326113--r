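test_that("surface sampling honours count, support and determinism", {
  sq <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                            c(0, 1, 0)),
                      rbind(c(1, 2, 3), c(1, 3, 4)))
  p <- sample_surface(sq, density = 100, seed = 4)
  expect_identical(nrow(p), 100L)
  expect_true(all(p[, 1] >= 0 & p[, 1] <= 1 & p[, 2] >= 0 & p[, 2] <= 1))
  expect_true(all(p[, 3] == 0))
  expect_identical(sample_surface(sq, 100, seed = 4), p)
  expect_false(identical(sample_surface(sq, 100, seed = 5), p))
  zero <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                        rbind(c(1, 2, 3)), clean = FALSE)
  expect_error(sample_surface(zero, 10), "zero surface area")
})

test_that("per-triangle sample counts are proportional to area", {
  # two triangles with areas 0.5 and 1.5: expect 25% / 75% split
  m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                           c(1, -3, 0)),
                     rbind(c(1, 2, 3), c(1, 4, 2)))
  hits <- 0L
  n_total <- 0L
  for (s in 1:50) {
    p <- sample_surface(m, density = 50, seed = s)
    hits <- hits + sum(p[, 2] > 0)  # triangle 1 lives at y > 0
    n_total <- n_total + nrow(p)
  }
  frac <- hits / n_total
  p0 <- 0.25
  tol <- 4 * sqrt(p0 * (1 - p0) / n_total)  # 4 sigma binomial band
  expect_lt(abs(frac - p0), tol)
})

test_that("identical meshes have zero Hausdorff distance", {
  m <- icosphere(2, radius = 2)
  h <- hausdorff_distance(m, m, density = 20, seed = 1)
  expect_lt(h$max_sym, 1e-9)
  expect_lt(h$mean_sym, 1e-9)
})

test_that("offset unit cubes give max 0.1 mm and smaller mean", {
  a <- cube_mesh(1)
  b <- cube_mesh(1, origin = c(0.1, 0, 0))
  h <- hausdorff_distance(a, b, density = 300, seed = 2)
  expect_equal(h$max_sym, 0.1, tolerance = 1e-12)
  expect_lt(h$mean_sym, 0.1)
  expect_equal(h$max_sym, max(h$max_ab, h$max_ba))
  expect_equal(h$mean_sym, (h$mean_ab + h$mean_ba) / 2)
  expect_gte(h$max_ab, h$mean_ab)
})

test_that("sampled distances match the brute-force oracle", {
  set.seed(31)
  for (k in 1:3) {
    a <- icosphere(1, radius = runif(1, 1, 2))
    b <- icosphere(1, radius = runif(1, 1, 2),
                   centre = runif(3, -0.5, 0.5))
    b$vertices <- b$vertices + matrix(rnorm(nrow(b$vertices) * 3, 0, 0.05),
                                      ncol = 3)
    pa <- sample_surface(a, density = 5, seed = k, include_vertices = TRUE)
    d_fast <- grindstack:::cpp_point_mesh_dist(pa, b$vertices, b$faces)
    d_slow <- oracle_point_mesh_dist(pa, b)
    expect_lt(max(abs(d_fast - d_slow)), 1e-9)
  }
})

test_that("swapping meshes swaps directed fields, keeps symmetric summary", {
  a <- icosphere(1, radius = 1.3)
  b <- cube_mesh(2, origin = c(-1, -1, -1))
  h1 <- hausdorff_distance(a, b, density = 40, seed = 3)
  h2 <- hausdorff_distance(b, a, density = 40, seed = 3)
  # sampling seeds differ per direction, so compare loosely for the means
  expect_equal(h1$max_sym, max(h2$max_ab, h2$max_ba), tolerance = 0.05)
  expect_equal(h1$mean_sym, h2$mean_sym, tolerance = 0.05)
})

test_that("reports are invariant under a common rigid motion", {
  a <- icosphere(1, radius = 1.2)
  b <- icosphere(1, radius = 1.0, centre = c(0.2, 0, 0))
  h0 <- hausdorff_distance(a, b, density = 30, seed = 6)
  set.seed(40)
  tr <- rigid3d(random_rotation3d(), c(3, -1, 2))
  a2 <- triangle_mesh(rigid3d_apply(tr, a$vertices), a$faces)
  b2 <- triangle_mesh(rigid3d_apply(tr, b$vertices), b$faces)
  h1 <- hausdorff_distance(a2, b2, density = 30, seed = 6)
  expect_equal(h1$mean_sym, h0$mean_sym, tolerance = 1e-9)
  expect_equal(h1$max_sym, h0$max_sym, tolerance = 1e-9)
})

test_that("denser sampling does not shrink the maximum distance", {
  a <- icosphere(1, radius = 1.5)
  b <- cube_mesh(2.2, origin = c(-1.1, -1.1, -1.1))
  lo <- mean(vapply(1:8, function(s)
    hausdorff_distance(a, b, density = 10, seed = s)$max_sym, numeric(1)))
  hi <- mean(vapply(1:8, function(s)
    hausdorff_distance(a, b, density = 200, seed = s)$max_sym, numeric(1)))
  expect_gte(hi, lo - 1e-9)
})

test_that("mask comparison reports zero error against itself and the
           analytic error for a scaled mask", {
  vol <- sphere_mask(16)
  self <- compare_overmould(vol, vol, density = 10, seed = 1)
  expect_lt(self$hausdorff$max_sym, 1e-9)
  expect_equal(self$volume$volumetric_error_pct, 0)
  big <- sphere_mask(16 * 1.01, n = dim(vol$voxels)[1])
  scaled <- compare_overmould(vol, big, density = 10, seed = 1)
  expect_equal(scaled$volume$volumetric_error_pct, 100 * (1.01^3 - 1),
               tolerance = 0.15)
})
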