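test_that("phantom generation is deterministic for a fixed seed", {
  spec <- phantom_spec(n_slices = 3, seed = 17)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$stack$slices[[2]]$pixels, b$stack$slices[[2]]$pixels)
  expect_identical(a$truth$params, b$truth$params)
  expect_identical(a$stack$positions, b$stack$positions)
  c <- generate_phantom(phantom_spec(n_slices = 3, seed = 18))
  expect_false(identical(a$truth$params, c$truth$params))
})

test_that("zero noise collapses the forward model to the identity", {
  spec <- phantom_spec(n_slices = 4, sigma_removal = 0, sigma_gauge = 0,
                       jitter = list(tx = 0, ty = 0, theta = 0, shear = 0,
                                     scale = 0), seed = 1)
  ph <- generate_phantom(spec)
  expect_equal(ph$truth$positions_measured, ph$truth$positions_true)
  expect_equal(ph$truth$positions_true, 0.15 * (0:3))
  for (t in ph$truth$transforms)
    expect_lt(max(abs(unclass(t) - diag(3))), 1e-12)
})

test_that("rendered label volume matches the analytic mould volume", {
  spec <- phantom_spec(n_slices = 20, seed = 5)
  lab <- phantom_label_volume(spec, dz = 0.15)
  vox_vol <- prod(lab$spacing)
  rendered <- sum(lab$voxels >= 1L) * vox_vol
  analytic <- phantom_mould_area(spec) * dim(lab$voxels)[3] * 0.15
  expect_lt(abs(rendered - analytic) / analytic, 0.01)
})

test_that("gauge-noise magnitude is reproduced over many slices", {
  spec <- phantom_spec(n_slices = 1000, seed = 3)
  draw <- grindstack:::phantom_draw(spec)
  sds <- sd(draw$pos_meas - draw$pos_true)
  expect_lt(abs(sds - spec$sigma_gauge) / spec$sigma_gauge, 0.10)
})

test_that("an empty mould specification is rejected", {
  spec <- phantom_spec(n_slices = 2, seed = 1)
  spec$mould$notch_width <- 1000
  spec$mould$notch_depth <- 1000
  expect_error(generate_phantom(spec), "empty mould")
})

test_that("corruption is a no-op at zero amplitude and preserves the mean
           gain at one", {
  spec <- phantom_spec(n_slices = 2, seam_prob = 0, drift_amplitude = 0,
                       seed = 2)
  ph <- generate_phantom(spec)
  same <- corrupt_stack(ph$stack, spec)
  expect_identical(same$slices[[1]]$pixels, ph$stack$slices[[1]]$pixels)
  # constant image: mean must survive the multiplicative drift
  flat <- image_stack(list(slice_image(array(128L, c(64, 64, 3)),
                                       c(0.05, 0.05))))
  spec2 <- phantom_spec(n_slices = 2, seam_prob = 0,
                        drift_amplitude = 0.02, seed = 2)
  drifted <- corrupt_stack(flat, spec2, seed = 9)
  expect_lt(abs(mean(drifted$slices[[1]]$pixels) / 128 - 1), 1.5e-3)
})

test_that("alignment still recovers transforms under stitching seams", {
  spec <- phantom_spec(n_slices = 3, seam_prob = 1, drift_amplitude = 0.02,
                       seed = 13)
  ph <- generate_phantom(spec)
  corrupted <- corrupt_stack(ph$stack, spec)
  aligned <- align_stack(corrupted, ph$template, chain_seed = FALSE)
  rep <- attr(aligned, "alignment_report")
  expect_false(any(rep$failed))
  for (i in 1:3) {
    got <- affine2d_params(aligned$transforms[[i]])
    err <- abs(got - ph$truth$params[i, ])
    expect_lt(err[["tx"]], 1)   # relaxed: seams cost up to the seam width
    expect_lt(err[["ty"]], 1)
    expect_lt(err[["theta"]], 0.5)
  }
})

test_that("exported fixtures re-import to the in-memory objects", {
  dir <- withr::local_tempdir()
  ph <- generate_phantom(phantom_spec(n_slices = 3, seed = 23))
  paths <- export_fixture(ph, dir)
  expect_true(all(file.exists(unlist(paths))))
  st <- read_tiff_stack(paths$images, c(0.05, 0.05))
  for (i in 1:3)
    expect_identical(st$slices[[i]]$pixels, ph$stack$slices[[i]]$pixels)
  expect_equal(read_layer_positions(paths$positions), ph$stack$positions,
               tolerance = 1e-12)
  tr <- read_transform_table(paths$transforms_true)
  for (i in 1:3)
    expect_lt(max(abs(unclass(tr[[i]]) -
                        unclass(ph$truth$transforms[[i]]))), 1e-12)
  # transforms CSV layout: one nine-field row per slice
  rows <- readLines(paths$transforms_true)
  expect_length(rows, 3)
  expect_true(all(lengths(strsplit(rows, ",")) == 9))
  tpl <- png::readPNG(paths$template)
  expect_identical(tpl > 0.5, unclass(ph$template$mask))
})
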