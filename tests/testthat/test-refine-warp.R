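test_that("refinement recovers a five-parameter perturbation", {
  spec <- phantom_spec(n_slices = 1, sigma_removal = 0, sigma_gauge = 0,
                       jitter = list(tx = 0, ty = 0, theta = 0, shear = 0,
                                     scale = 0),
                       seed = 2)
  truth <- c(tx = 3.4, ty = -2.1, theta = 2.7, shear = 0.02, scale = 1.01)
  cen <- rep((spec$size_px - 1) / 2, 2)
  t_true <- affine2d(truth[1], truth[2], truth[3], truth[4], truth[5],
                     centre = cen)
  raw <- grindstack:::render_slice(spec, z = 0.1, transform = t_true)
  ph <- generate_phantom(spec)
  mt <- outline_matcher(slice_image(raw, c(0.05, 0.05)), ph$template)
  co <- coarse_search(mt, search_grid(c(-10, 10), c(-10, 10), c(-5, 5)))
  fi <- refine_affine(mt, co)
  err <- abs(fi$params - truth)
  expect_lt(err[["tx"]], 0.5)
  expect_lt(err[["ty"]], 0.5)
  expect_lt(err[["theta"]], 0.2)
  expect_lt(err[["shear"]], 0.01)
  expect_lt(err[["scale"]], 0.005)
  expect_gte(fi$score, co$score)  # monotone improvement
})

test_that("an already optimal init is a fixed point of refinement", {
  n <- 48
  d <- sqrt(outer((seq_len(n) - 24)^2, (seq_len(n) - 24)^2, "+"))
  m <- d >= 12 & d <= 14
  mt <- outline_matcher(m, template_outline(m))
  init <- grindstack:::alignment_result(affine2d(), 1, FALSE, 0,
                                        c(tx = 0, ty = 0, theta = 0,
                                          shear = 0, scale = 1))
  fi <- refine_affine(mt, init)
  expect_equal(fi$score, 1)
  expect_lt(max(abs(fi$params - init$params)), 1e-3)
})

test_that("refinement far from the basin returns the init unconverged", {
  a <- matrix(FALSE, 60, 60); a[10:12, 10:12] <- TRUE
  b <- matrix(FALSE, 60, 60); b[50:52, 50:52] <- TRUE
  mt <- outline_matcher(a, template_outline(b), dsat = 3)
  init <- grindstack:::alignment_result(affine2d(), 0, FALSE, 0,
                                        c(tx = 0, ty = 0, theta = 0,
                                          shear = 0, scale = 1))
  fi <- refine_affine(mt, init)
  expect_false(fi$converged)
  expect_identical(unclass(fi$transform), unclass(init$transform))
})

test_that("identity warp and integer translations are exact", {
  set.seed(8)
  s <- slice_image(array(sample(0:255, 24 * 24 * 3, TRUE), c(24, 24, 3)),
                   c(0.05, 0.05))
  w <- warp_slice(s, affine2d())
  expect_identical(w$pixels, s$pixels)
  # pure integer translation: pull by (2, -3) shifts content
  w <- warp_slice(s, affine2d(tx = 2, ty = -3), background = c(7, 7, 7))
  expect_identical(w$pixels[1:22, 4:24, ], s$pixels[3:24, 1:21, ])
  expect_true(all(w$pixels[23:24, , ] == 7L))
  expect_error(warp_slice(s, structure(matrix(c(1, 0, 0, 1, 0, 0, 0, 0, 1),
                                              3, 3), centre = c(0, 0),
                                       class = "affine2d")), "singular")
})

test_that("warp round trip is lossless away from image and colour edges", {
  ph <- generate_phantom(phantom_spec(n_slices = 2, seed = 5))
  s <- ph$stack$slices[[1]]
  t <- affine2d(3.4, -2.1, 2.7, 0.02, 1.01, centre = c(127.5, 127.5))
  back <- warp_slice(warp_slice(s, t), affine2d_invert(t))
  lum <- s$pixels[, , 1]
  edge <- abs(diff(lum)) > 0
  edge <- rbind(edge, FALSE) | rbind(FALSE, edge)
  edgec <- abs(t(diff(t(lum)))) > 0
  edge <- edge | cbind(edgec, FALSE) | cbind(FALSE, edgec)
  dt <- grindstack:::outline_distance_map(edge)
  interior <- dt > 4
  interior[c(1:12, 245:256), ] <- FALSE
  interior[, c(1:12, 245:256)] <- FALSE
  dev <- pmax(abs(back$pixels[, , 1] - s$pixels[, , 1]),
              abs(back$pixels[, , 2] - s$pixels[, , 2]),
              abs(back$pixels[, , 3] - s$pixels[, , 3]))
  expect_lte(max(dev[interior]), 2)
})
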