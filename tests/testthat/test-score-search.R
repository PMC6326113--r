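ring_mask <- function(n = 48, r0 = 12, r1 = 14, centre = NULL) {
  if (is.null(centre)) centre <- c((n - 1) / 2, (n - 1) / 2)
  d <- sqrt(outer((seq_len(n) - 1 - centre[1])^2,
                  (seq_len(n) - 1 - centre[2])^2, "+"))
  d >= r0 & d <= r1
}

test_that("score is 1 for coincident outlines and 0 for disjoint ones", {
  m <- ring_mask()
  tpl <- template_outline(m)
  mt <- outline_matcher(m, tpl, dsat = 5)
  expect_equal(score_match(mt, affine2d()), 1)
  expect_equal(score_match(mt, affine2d(), metric = "dice"), 1)
  far <- ring_mask(96, 8, 9, centre = c(12, 12))
  tpl2 <- template_outline(ring_mask(96, 8, 9, centre = c(80, 80)))
  mt2 <- outline_matcher(far, tpl2, dsat = 5)
  expect_equal(score_match(mt2, affine2d()), 0)
  expect_equal(score_match(mt2, affine2d(), metric = "dice"), 0)
})

test_that("score decreases with growing rigid displacement near optimum", {
  tpl <- template_outline(ring_mask())
  mt <- outline_matcher(ring_mask(), tpl)
  s <- vapply(c(0, 1, 2, 4, 8), function(tx)
    score_match(mt, affine2d(tx = tx)), numeric(1))
  expect_true(all(diff(s) < 0))
})

test_that("dice score equals the exhaustive pixel-overlap oracle", {
  # 8x8 toy outline: small L-shaped set of pixels
  m <- matrix(FALSE, 8, 8)
  m[3, 3:6] <- TRUE
  m[4:6, 3] <- TRUE
  tpl <- template_outline(m)
  mt <- outline_matcher(m, tpl)
  for (shift in list(c(1, 0), c(0, 1), c(1, 1), c(2, 0))) {
    got <- score_match(mt, affine2d(tx = shift[1], ty = shift[2]),
                       metric = "dice")
    # oracle: count overlapping pixels after an integer shift of the mask
    shifted <- matrix(FALSE, 8, 8)
    rows <- seq_len(8 - shift[1])
    cols <- seq_len(8 - shift[2])
    shifted[rows + shift[1], cols + shift[2]] <- m[rows, cols]
    overlap <- sum(shifted & m)
    expect_equal(got, 2 * overlap / (sum(m) + sum(shifted)))
  }
})

test_that("coarse search equals exhaustive score_match re-evaluation", {
  ph <- generate_phantom(phantom_spec(n_slices = 2, seed = 21))
  ol <- extract_outline_mask(ph$stack$slices[[1]])
  mt <- outline_matcher(ol, ph$template, subsample = 4L)
  grid <- search_grid(tx_range = c(-20, 20), ty_range = c(-20, 20),
                      theta_range = c(-3, 3), tx_step = 4, ty_step = 4,
                      theta_step = 1)
  res <- coarse_search(mt, grid)
  # independent exhaustive scan in the same deterministic node order
  nodes <- grindstack:::grid_nodes(grid)
  scores <- vapply(seq_len(nrow(nodes)), function(i)
    score_match(mt, affine2d(nodes$tx[i], nodes$ty[i], nodes$theta[i],
                             centre = mt$centre)), numeric(1))
  best <- which.max(scores)
  expect_identical(res$score, scores[best])
  expect_identical(res$iterations, nrow(nodes))
  expect_lt(max(abs(unclass(res$transform) -
                      unclass(affine2d(nodes$tx[best], nodes$ty[best],
                                       nodes$theta[best],
                                       centre = mt$centre)))), 1e-15)
})

test_that("unperturbed slices win at the identity node", {
  tpl <- template_outline(ring_mask(64, 14, 16))
  mt <- outline_matcher(ring_mask(64, 14, 16), tpl)
  res <- coarse_search(mt, search_grid(c(-10, 10), c(-10, 10), c(-5, 5)))
  expect_equal(unname(res$params[c("tx", "ty", "theta")]), c(0, 0, 0))
  expect_equal(res$score, 1)
})

test_that("coarse search errors when nothing matches", {
  small <- ring_mask(40, 4, 5, centre = c(6, 6))
  tpl <- template_outline(ring_mask(40, 4, 5, centre = c(34, 34)))
  mt <- outline_matcher(small, tpl, dsat = 2)
  expect_error(coarse_search(mt, search_grid(c(-2, 2), c(-2, 2),
                                             c(-1, 1))), "no match")
})

test_that("search grids validate their ranges and steps", {
  expect_error(search_grid(tx_step = 0), "tx_step")
  expect_error(search_grid(tx_range = c(5, 10)), "tx_range")
})
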