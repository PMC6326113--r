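test_that("noise-free landmark registration is exact", {
  th <- pi / 2
  Rm <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  tr <- rigid3d(Rm, c(1, 2, 3))
  mov <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  fix <- rigid3d_apply(tr, mov)
  fit <- landmark_register(fix, mov)
  expect_lt(max(abs(fit$transform$rotation - Rm)), 1e-9)
  expect_lt(max(abs(fit$transform$translation - c(1, 2, 3))), 1e-9)
  expect_lt(fit$fre, 1e-9)
  # identity correspondence
  fit0 <- landmark_register(mov, mov)
  expect_lt(max(abs(fit0$transform$rotation - diag(3))), 1e-9)
  expect_equal(fit0$fre, 0)
})

test_that("similarity mode recovers scale; rigid mode pins it to 1", {
  set.seed(2)
  Rm <- random_rotation3d()
  tr <- rigid3d(Rm, c(-4, 2, 9), scale = 1.02)
  mov <- matrix(runif(30, -15, 15), 10, 3)
  fix <- rigid3d_apply(tr, mov)
  sim <- landmark_register(fix, mov, allow_scale = TRUE)
  expect_equal(sim$transform$scale, 1.02, tolerance = 1e-9)
  rig <- landmark_register(fix, mov, allow_scale = FALSE)
  expect_identical(rig$transform$scale, 1)
})

test_that("Monte-Carlo FRE under 0.1 mm landmark noise sits in band", {
  th <- 30 * pi / 180
  Rm <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  tr <- rigid3d(Rm, c(5, -3, 2))
  fres <- rot_err <- numeric(100)
  for (s in 1:100) {
    set.seed(s)
    mov <- matrix(runif(30, -20, 20), 10, 3)
    # isotropic noise with 0.1 mm RMS total displacement
    fix <- rigid3d_apply(tr, mov) +
      matrix(rnorm(30, 0, 0.1 / sqrt(3)), 10, 3)
    fit <- landmark_register(fix, mov)
    fres[s] <- fit$fre
    tr_cos <- (sum(diag(crossprod(fit$transform$rotation, Rm))) - 1) / 2
    rot_err[s] <- acos(pmin(1, tr_cos)) * 180 / pi
  }
  expect_gte(mean(fres), 0.07)
  expect_lte(mean(fres), 0.13)
  expect_lt(max(rot_err), 1)
})

test_that("FRE is invariant under a common rigid motion of both sets", {
  set.seed(5)
  mov <- matrix(runif(18, -10, 10), 6, 3)
  fix <- mov + matrix(rnorm(18, 0, 0.2), 6, 3)
  base <- landmark_register(fix, mov)$fre
  common <- rigid3d(random_rotation3d(), c(7, -2, 4))
  moved <- landmark_register(rigid3d_apply(common, fix),
                             rigid3d_apply(common, mov))$fre
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("degenerate configurations are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(landmark_register(line, line), "collinear")
  expect_error(landmark_register(line[1:2, ], line[1:2, ]), "at least 3")
})

test_that("landmark registration agrees with an independent Procrustes fit", {
  skip_if_not_installed("vegan")
  set.seed(7)
  mov <- matrix(runif(24, -10, 10), 8, 3)
  fix <- rigid3d_apply(rigid3d(random_rotation3d(), c(1, -1, 2)), mov) +
    matrix(rnorm(24, 0, 0.05), 8, 3)
  fit <- landmark_register(fix, mov)
  pro <- vegan::procrustes(fix, mov, scale = FALSE)
  # vegan: X ~ Y %*% rotation + translation (row-vector convention)
  expect_lt(max(abs(t(pro$rotation) - fit$transform$rotation)), 1e-6)
  expect_equal(sqrt(mean(residuals(pro)^2)), fit$fre, tolerance = 1e-6)
})

test_that("transform export/import round-trips and validates", {
  f <- withr::local_tempfile(fileext = ".txt")
  set.seed(11)
  tr <- rigid3d(random_rotation3d(), c(0.5, -4.25, 9), scale = 1.015)
  export_transform(tr, f)
  back <- import_transform(f)
  expect_lt(max(abs(back$rotation - tr$rotation)), 1e-12)
  expect_lt(max(abs(back$translation - tr$translation)), 1e-12)
  expect_equal(back$scale, tr$scale, tolerance = 1e-12)
  # identity writes a clean 4x4 identity
  export_transform(rigid3d(), f)
  m <- as.numeric(unlist(strsplit(readLines(f), "\\s+")))
  expect_identical(m, as.numeric(t(diag(4))))
  writeLines(c("1 0 0 0", "0 1 0.5 0", "0 0 1 0", "0 0 0 1"), f)
  expect_error(import_transform(f), "not orthonormal")
})

test_that("volume resampling through transforms is exact for identity and
           integer-voxel shifts", {
  set.seed(13)
  v <- volume_grid(array(sample(0:4095, 6 * 6 * 6, TRUE), c(6, 6, 6)),
                   c(0.5, 0.5, 0.5), type = "uint16")
  same <- apply_transform_volume(v, rigid3d(), v)
  expect_identical(same$voxels, v$voxels)
  shift <- rigid3d(diag(3), c(0.5, 0, 0))  # one voxel along +x
  out <- apply_transform_volume(v, shift, v, padding = 0)
  expect_identical(out$voxels[2:6, , ], v$voxels[1:5, , ])
  expect_true(all(out$voxels[1, , ] == 0L))
})

test_that("transforming forth and back bounds interpolation error", {
  # smooth volume: trilinear interpolation error stays small
  g <- seq(0, 1, length.out = 20)
  sm <- outer(outer(sin(2 * pi * g), cos(2 * pi * g), "+"), g, "+") * 50 + 100
  v <- volume_grid(sm, c(1, 1, 1), type = "double")
  th <- 10 * pi / 180
  Rm <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  tr <- rigid3d(Rm, c(0.3, -0.2, 0.1))
  fwd <- apply_transform_volume(v, tr, v, padding = NA)
  back <- apply_transform_volume(fwd, rigid3d_invert(tr), v, padding = NA)
  core <- 6:15
  dev <- abs(back$voxels[core, core, core] - v$voxels[core, core, core])
  expect_lt(max(dev, na.rm = TRUE), 5)
})
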