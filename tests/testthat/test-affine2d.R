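test_that("parameter and matrix views agree and round-trip", {
  for (t in random_affine_list(25, seed = 11)) {
    p <- affine2d_params(t)
    t2 <- affine2d(p["tx"], p["ty"], p["theta"], p["shear"], p["scale"],
                   centre = attr(t, "centre"))
    expect_lt(max(abs(unclass(t) - unclass(t2))), 1e-9)
  }
  # explicit composition order: T(tx,ty) C R Sh Sc C^-1
  cen <- c(10, 20)
  th <- 7 * pi / 180
  Cm <- diag(3); Cm[1:2, 3] <- cen
  Rm <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Sh <- rbind(c(1, 0.03, 0), c(0, 1, 0), c(0, 0, 1))
  Sc <- diag(c(1.05, 1.05, 1))
  Tm <- diag(3); Tm[1:2, 3] <- c(2, -3)
  ref <- Tm %*% Cm %*% Rm %*% Sh %*% Sc %*% solve(Cm)
  t <- affine2d(2, -3, 7, 0.03, 1.05, centre = cen)
  expect_lt(max(abs(unclass(t) - ref)), 1e-9)
})

test_that("affine invariants are enforced", {
  expect_error(affine2d_from_matrix(rbind(c(1, 0, 0), c(0, 1, 0),
                                          c(0, 0.1, 1))), "bottom row")
  expect_error(affine2d_from_matrix(diag(c(-1, 1, 1))), "reflection")
  t <- affine2d(4, -2, 10, 0.02, 1.1)
  ident <- affine2d_compose(t, affine2d_invert(t))
  expect_lt(max(abs(unclass(ident) - diag(3))), 1e-12)
})

test_that("transform table uses row-major nine-field rows", {
  tf <- withr::local_tempfile(fileext = ".csv")
  write_transform_table(list(affine2d(), affine2d(3, -2)), tf)
  expect_identical(readLines(tf),
                   c("1,0,0,0,1,0,0,0,1", "1,0,3,0,1,-2,0,0,1"))
})

test_that("transform table round-trips and rejects bad rows", {
  tf <- withr::local_tempfile(fileext = ".csv")
  trans <- random_affine_list(100, seed = 3)
  write_transform_table(trans, tf)
  back <- read_transform_table(tf)
  dev <- max(vapply(seq_along(trans), function(i)
    max(abs(unclass(trans[[i]]) - unclass(back[[i]]))), numeric(1)))
  expect_lt(dev, 1e-12)
  # invert flag recovers the opposite convention
  inv <- read_transform_table(tf, invert = TRUE)
  expect_lt(max(abs(unclass(inv[[1]]) -
                      unclass(affine2d_invert(trans[[1]])))), 1e-12)
  writeLines(c("1,0,0,0,1,0,0,0,1", "1,2,3,4"), tf)
  expect_error(read_transform_table(tf), "row 2")
})
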