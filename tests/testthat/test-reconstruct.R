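uniform_stack <- function(values, positions, dim = c(8, 8)) {
  image_stack(lapply(seq_along(values), function(i)
    slice_image(array(as.integer(values[i]), c(dim, 3)), c(0.05, 0.05),
                index = i)), positions = positions)
}

test_that("grid assignment matches hand-computed nearest-slot rounding", {
  a <- assign_grid_positions(c(0, 0.14, 0.31, 0.46), 0.15)
  expect_identical(a$slots, c(1L, 2L, 3L, 4L))
  expect_identical(a$n_slots, 4L)
  # collision: slices at 0.07 and 0.08 mm fight over a slot; nearest wins,
  # the loser is unplaced
  a <- assign_grid_positions(c(0, 0.07, 0.08), 0.15)
  expect_identical(a$placed, c(1L, 3L))
  expect_true(is.na(a$slots[2]))
  # exact multiples: identity assignment
  a <- assign_grid_positions(c(0, 0.15, 0.30, 0.45), 0.15)
  expect_identical(a$slots, 1:4)
  expect_false(anyNA(a$slots))
})

test_that("assignment preserves slice order", {
  set.seed(12)
  for (rep in 1:20) {
    pos <- c(0, cumsum(runif(15, 0.05, 0.3)))
    a <- assign_grid_positions(pos, 0.15)
    expect_true(all(diff(stats::na.omit(a$slots)) > 0))
  }
})

test_that("midpoint interpolation yields 128 from black and white", {
  st <- uniform_stack(c(0, 255), c(0, 0.30))
  vs <- interpolate_missing(st, dz = 0.15)
  expect_identical(vs$slots[[2]]$kind, "interpolated")
  expect_equal(vs$slots[[2]]$weight, 0.5)
  expect_true(all(vs$images[[2]] == 128L))
})

test_that("fields linear in z are reproduced within one intensity level", {
  # slices on grid multiples with gaps: interpolation happens at slot
  # heights that coincide with true positions, so an affine field must be
  # reproduced up to 8-bit quantization
  pos <- c(0, 0.15, 0.60, 0.90)
  vals <- round(40 + 200 * pos / 0.9)
  st <- uniform_stack(vals, pos)
  vs <- interpolate_missing(st, dz = 0.15)
  z <- (seq_along(vs$images) - 1) * 0.15
  kinds <- vapply(vs$slots, `[[`, character(1), "kind")
  expect_gte(sum(kinds == "interpolated"), 3)
  for (k in which(kinds == "interpolated")) {
    expected <- 40 + 200 * z[k] / 0.9
    expect_lte(max(abs(vs$images[[k]] - expected)), 1)
  }
})

test_that("exact-multiple slices pass through bit-exactly and collisions
           leave interior slots to interpolation", {
  set.seed(3)
  imgs <- lapply(1:3, function(i)
    array(sample(0:255, 8 * 8 * 3, TRUE), c(8, 8, 3)))
  st <- image_stack(lapply(1:3, function(i)
    slice_image(imgs[[i]], c(0.05, 0.05))), positions = c(0, 0.15, 0.30))
  vs <- interpolate_missing(st, dz = 0.15)
  for (i in 1:3) {
    expect_identical(vs$slots[[i]]$kind, "original")
    expect_identical(vs$images[[i]], st$slices[[i]]$pixels)
  }
  # a collision empties interior slots, which are then interpolated
  st2 <- uniform_stack(c(10, 200, 60), c(0, 0.02, 0.60))
  a <- assign_grid_positions(st2$positions, 0.15)
  expect_identical(a$placed, c(1L, NA, NA, NA, 3L))
  vs2 <- interpolate_missing(st2, a, dz = 0.15)
  expect_identical(vs2$slots[[2]]$kind, "interpolated")
  expect_error(interpolate_missing(uniform_stack(c(1, 2), c(0, 0.01)),
                                   dz = 0.15), "at least 2 placed")
})

test_that("assembled volumes carry the micro-slicing geometry", {
  st <- uniform_stack(c(0, 60, 120, 180), c(0, 0.15, 0.30, 0.45),
                      dim = c(6, 10))
  v <- assemble_volume(interpolate_missing(st, dz = 0.15))
  expect_true(v$rgb)
  expect_identical(dim(v$voxels), c(3L, 10L, 6L, 4L))  # (ch, x, y, z)
  expect_equal(v$spacing, c(0.05, 0.05, 0.15))
  f <- withr::local_tempfile(fileext = ".nrrd")
  write_nrrd(v, f)
  expect_identical(read_nrrd(f)$voxels, v$voxels)
})

test_that("resampling preserves identity, constants and linear ramps", {
  set.seed(9)
  v <- volume_grid(array(runif(6 * 5 * 4), c(6, 5, 4)), c(1, 1, 1),
                   type = "double")
  expect_identical(resample_volume(v, c(1, 1, 1))$voxels, v$voxels)
  cv <- volume_grid(array(3.5, c(6, 6, 6)), c(1, 1, 1), type = "double")
  out <- resample_volume(cv, c(0.7, 1.3, 2.1))
  expect_true(all(abs(out$voxels - 3.5) < 1e-12))
  ramp <- volume_grid(array(rep(0:16, each = 9) * 10, c(3, 3, 17)),
                      c(1, 1, 1), type = "double")
  down <- resample_volume(ramp, c(1, 1, 2))
  expect_identical(dim(down$voxels)[3], 9L)
  expected <- rep(seq(0, 160, by = 20), each = 9)
  expect_lte(max(abs(down$voxels - expected)), 1)
})
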