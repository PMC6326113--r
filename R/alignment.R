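#' Extract the embedding-mould outline from a slice image
#'
#' The epoxy block is segmented from the background by thresholding the
#' luminance (Otsu by default), keeping the largest connected component,
#' filling holes, and taking the one-pixel boundary of the filled block as
#' the outline. The foreground polarity is chosen automatically as the side
#' of the threshold that does not dominate the image border (the border is
#' assumed to be background).
#'
#' @param slice a [slice_image()] or an H x W x 3 array / binary matrix.
#' @param threshold `"otsu"` or a fixed luminance threshold in `[0, 1]`.
#' @return binary outline matrix (class `outline_mask`) with the filled
#'   block stored in attribute `"block"`.
#' @export
extract_outline_mask <- function(slice, threshold = "otsu") {
  px <- if (inherits(slice, "slice_image")) slice$pixels else slice
  if (length(dim(px)) == 3) {
    lum <- (0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]) / 255
  } else {
    lum <- px / max(1, max(px))
  }
  thr <- if (identical(threshold, "otsu")) {
    if (diff(range(lum)) < 1e-6)
      stop("outline extraction failed: uniform image", call. = FALSE)
    EBImage::otsu(EBImage::Image(lum), range = c(0, 1))
  } else as.numeric(threshold)
  fg <- lum > thr
  border <- c(fg[1, ], fg[nrow(fg), ], fg[, 1], fg[, ncol(fg)])
  if (mean(border) > 0.5) fg <- !fg
  if (!any(fg))
    stop("outline extraction failed: empty foreground", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  tab <- tabulate(as.integer(lab))
  block <- matrix(as.integer(lab) == which.max(tab), nrow(fg), ncol(fg))
  block <- EBImage::fillHull(EBImage::Image(block * 1)) > 0
  block <- matrix(block, nrow(fg), ncol(fg))
  eroded <- EBImage::erode(EBImage::Image(block * 1),
                           EBImage::makeBrush(3, shape = "box")) > 0
  outline <- block & !matrix(eroded, nrow(fg), ncol(fg))
  if (!any(outline))
    stop("outline extraction failed: degenerate block", call. = FALSE)
  structure(outline, block = block, threshold = as.numeric(thr),
            class = c("outline_mask", "matrix", "array"))
}

#' Sub-pixel outline contour of a slice
#'
#' Locates the mould boundary at sub-pixel precision: the luminance field of
#' the (antialiased) slice crosses the segmentation threshold smoothly, so
#' every pair of adjacent pixels straddling the threshold across the block
#' boundary yields one linearly interpolated crossing point. This removes
#' most of the half-pixel quantization that a binary outline ring carries.
#'
#' @param slice a [slice_image()] or RGB array.
#' @param threshold `"otsu"` or a fixed luminance threshold in `[0, 1]`.
#' @return n x 2 matrix of 0-based `(row, col)` contour points.
#' @export
subpixel_outline_points <- function(slice, threshold = "otsu") {
  px <- if (inherits(slice, "slice_image")) slice$pixels else slice
  if (length(dim(px)) == 3) {
    lum <- (0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]) / 255
  } else {
    lum <- px / max(1, max(px))
  }
  out <- extract_outline_mask(slice, threshold = threshold)
  block <- attr(out, "block")
  thr <- attr(out, "threshold")
  f <- lum - thr
  H <- nrow(lum); W <- ncol(lum)
  # Edge position by mass conservation over a plateau-to-plateau window:
  # with the profile normalized to its local plateau levels, the crossing
  # sits at (window start - 0.5) + sum(1 - v). Exact for any monotone
  # antialiased step profile, unlike mid-level linear interpolation, which
  # biases edges whose sub-pixel phase is constant along their length.
  add_crossings <- function(vertical) {
    if (vertical) {
      a <- f[-H, ]; b <- f[-1, ]
      cr <- (a * b < 0) & (block[-H, ] != block[-1, ])
    } else {
      a <- f[, -W]; b <- f[, -1]
      cr <- (a * b < 0) & (block[, -W] != block[, -1])
    }
    if (!any(cr)) return(NULL)
    idx <- which(cr, arr.ind = TRUE)
    r <- idx[, 1]; c <- idx[, 2]
    at <- function(dq) {
      if (vertical) lum[cbind(pmin(pmax(r + dq, 1), H), c)]
      else lum[cbind(r, pmin(pmax(c + dq, 1), W))]
    }
    v0 <- at(-1); v1 <- at(0); v2 <- at(1); v3 <- at(2)
    lo <- pmin(v0, v3); hi <- pmax(v0, v3)
    span <- hi - lo
    rising <- v3 >= v0
    nrm <- function(v) {
      vn <- (v - lo) / span
      vn <- pmin(pmax(vn, 0), 1)
      ifelse(rising, vn, 1 - vn)
    }
    e <- -1.5 + (1 - nrm(v0)) + (1 - nrm(v1)) + (1 - nrm(v2)) +
      (1 - nrm(v3))
    # degenerate window (no contrast): fall back to the pair midpoint
    e[span < 0.05] <- 0.5
    e <- pmin(pmax(e, 0), 1)
    out <- if (vertical) cbind(r - 1 + e, c - 1) else cbind(r - 1, c - 1 + e)
    # the two 2x2 pixel cells this crossing borders (marching-squares)
    cells <- if (vertical) cbind(r - 1, c - 2, r - 1, c - 1)
             else cbind(r - 2, c - 1, r - 1, c - 1)
    attr(out, "cells") <- cells
    out
  }
  pv <- add_crossings(TRUE)
  ph <- add_crossings(FALSE)
  pts <- rbind(pv, ph)
  if (is.null(pts) || nrow(pts) == 0)
    stop("no sub-pixel outline crossings found", call. = FALSE)
  # contour densification: pair the two crossings of each boundary cell
  # into a segment and emit its interior points; used to rasterize the
  # outline distance map without tangential sampling gaps
  cells <- rbind(if (!is.null(pv)) attr(pv, "cells"),
                 if (!is.null(ph)) attr(ph, "cells"))
  cell_key <- c(cells[, 1] * 1e6 + cells[, 2], cells[, 3] * 1e6 + cells[, 4])
  pt_id <- rep(seq_len(nrow(pts)), 2)
  ord <- order(cell_key)
  ck <- cell_key[ord]; pid <- pt_id[ord]
  same <- which(ck[-1] == ck[-length(ck)])
  dense <- pts
  if (length(same)) {
    a <- pts[pid[same], , drop = FALSE]
    b <- pts[pid[same + 1], , drop = FALSE]
    seg_ok <- rowSums((a - b)^2) <= 2.25  # genuine neighbours only
    a <- a[seg_ok, , drop = FALSE]; b <- b[seg_ok, , drop = FALSE]
    dense <- rbind(pts, 0.75 * a + 0.25 * b, 0.5 * (a + b),
                   0.25 * a + 0.75 * b)
  }
  o <- order(pts[, 1], pts[, 2])
  out <- pts[o, , drop = FALSE]
  attr(out, "dense") <- dense
  out
}

#' Template outline for alignment
#'
#' Wraps the reference-frame mould outline. Built from a reference slice
#' image the outline is a sub-pixel contour (preferred); built from a binary
#' mask the pixel centres of the mask are used.
#'
#' @param x a [slice_image()] of the unperturbed mould, a binary outline
#'   mask matrix, or an `outline_mask`.
#' @param pixel_spacing in-plane spacing (mm), must match the slices.
#' @export
template_outline <- function(x, pixel_spacing = c(1, 1)) {
  if (inherits(x, "slice_image")) {
    mask <- extract_outline_mask(x)
    pts <- subpixel_outline_points(x)
    dims <- dim(mask)
  } else {
    mask <- x > 0
    if (!any(mask)) stop("template outline mask is empty", call. = FALSE)
    pts <- mask_points(mask)
    dims <- dim(mask)
  }
  dense <- attr(pts, "dense") %||% pts
  attr(pts, "dense") <- NULL
  mask <- matrix(as.logical(mask), nrow(mask))
  structure(list(mask = mask, pts = pts, dense = dense,
                 dims = dims,
                 image = if (inherits(x, "slice_image")) x,
                 pixel_spacing = as.numeric(pixel_spacing)),
            class = "template_outline")
}

# exact Euclidean distance map (in px of the coarse grid) to a sub-pixel
# point set, rasterized on an `upsample`-times finer grid
point_distance_map <- function(pts, dims, upsample = 2L) {
  u <- as.integer(upsample)
  fd <- (dims - 1L) * u + 1L
  marked <- matrix(FALSE, fd[1], fd[2])
  r <- pmin(pmax(round(pts[, 1] * u), 0), fd[1] - 1) + 1
  c <- pmin(pmax(round(pts[, 2] * u), 0), fd[2] - 1) + 1
  marked[cbind(r, c)] <- TRUE
  matrix(EBImage::distmap(EBImage::Image((!marked) * 1),
                          metric = "euclidean"), fd[1], fd[2]) / u
}

outline_distance_map <- function(mask) {
  inv <- EBImage::Image((!mask) * 1)
  matrix(EBImage::distmap(inv, metric = "euclidean"),
         nrow(mask), ncol(mask))
}

mask_points <- function(mask, subsample = 1L) {
  pts <- which(mask > 0, arr.ind = TRUE) - 1  # 0-based (row, col)
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  if (subsample > 1L)
    pts <- pts[seq(1, nrow(pts), by = subsample), , drop = FALSE]
  storage.mode(pts) <- "double"
  pts
}

#' Prepare a matcher pairing one slice outline with the template
#'
#' Precomputes distance maps and outline point lists so that [score_match()]
#' and the search operations are cheap to evaluate many times. Given a
#' [slice_image()], the slice outline is a sub-pixel contour
#' ([subpixel_outline_points()]); given a binary mask, its pixel centres are
#' used. Distance maps are rasterized on an `upsample`-times finer grid to
#' keep sub-pixel fidelity.
#'
#' @param slice a [slice_image()], or a binary outline mask of the slice
#'   (e.g. from [extract_outline_mask()]).
#' @param template a [template_outline()].
#' @param dsat saturation distance (px) for the distance-field metric.
#' @param subsample evaluate every k-th outline point (speed/accuracy
#'   trade-off; 1 = all points).
#' @param upsample distance-map refinement factor (integer >= 1).
#' @export
outline_matcher <- function(slice, template, dsat = 25, subsample = 1L,
                            upsample = 2L) {
  stopifnot(inherits(template, "template_outline"), dsat > 0,
            upsample >= 1)
  if (inherits(slice, "slice_image")) {
    pts_src <- subpixel_outline_points(slice)
    src_dims <- dim(slice$pixels)[1:2]
  } else {
    slice_mask <- slice > 0
    if (!any(slice_mask)) stop("slice outline mask is empty", call. = FALSE)
    pts_src <- mask_points(slice_mask)
    src_dims <- dim(slice_mask)
  }
  dense_src <- attr(pts_src, "dense") %||% pts_src
  attr(pts_src, "dense") <- NULL
  sub <- function(p) {
    if (subsample > 1L) p[seq(1, nrow(p), by = subsample), , drop = FALSE]
    else p
  }
  # rounded source pixels for the dice metric
  src_px <- unique(round(pts_src))
  src_set <- matrix(FALSE, src_dims[1], src_dims[2])
  keep <- src_px[, 1] >= 0 & src_px[, 1] < src_dims[1] &
    src_px[, 2] >= 0 & src_px[, 2] < src_dims[2]
  src_set[src_px[keep, , drop = FALSE] + 1] <- TRUE
  structure(list(
    dt_src = point_distance_map(dense_src, src_dims, upsample),
    dt_tpl = point_distance_map(template$dense, template$dims, upsample),
    pts_tpl = sub(template$pts),
    pts_src = sub(pts_src),
    src_pixels = src_set, n_src = sum(src_set),
    centre = (template$dims - 1) / 2,
    dsat = dsat, upsample = as.numeric(upsample)),
    class = "outline_matcher")
}

transform_rows <- function(transforms) {
  t(vapply(transforms, function(t) {
    m <- unclass(t)
    c(m[1, 1], m[1, 2], m[1, 3], m[2, 1], m[2, 2], m[2, 3])
  }, numeric(6)))
}

#' Score how well a transform maps the template outline onto a slice outline
#'
#' The default metric is a symmetric saturated distance-field residual:
#' template outline points are pulled into the slice frame and read off the
#' slice-outline distance map, slice outline points are pushed back into the
#' reference frame and read off the template distance map; distances saturate
#' at `dsat` px and the score is `1 - mean(saturated distance)/dsat`, so 1
#' means coincident outlines and 0 means everywhere farther than `dsat`.
#' The `"dice"` alternative is the overlap coefficient of the rasterized
#' transformed outline with the slice outline.
#'
#' @param matcher an [outline_matcher()].
#' @param t an [affine2d()] transform (reference -> source).
#' @param metric `"dtf"` (distance field, default) or `"dice"`.
#' @return score in `[0, 1]`.
#' @export
score_match <- function(matcher, t, metric = c("dtf", "dice")) {
  metric <- match.arg(metric)
  stopifnot(inherits(matcher, "outline_matcher"), inherits(t, "affine2d"))
  if (metric == "dtf") {
    as.numeric(cpp_score_dtf_batch(transform_rows(list(t)),
                                   matcher$dt_src, matcher$dt_tpl,
                                   matcher$pts_tpl, matcher$pts_src,
                                   matcher$dsat, matcher$upsample))
  } else {
    score_dice(matcher, t)
  }
}

score_dice <- function(matcher, t) {
  pts <- affine2d_apply(t, matcher$pts_tpl)
  r <- round(pts[, 1]) + 1
  c <- round(pts[, 2]) + 1
  d <- dim(matcher$src_pixels)
  keep <- r >= 1 & r <= d[1] & c >= 1 & c <= d[2]
  idx <- unique(cbind(r[keep], c[keep]))
  ov <- if (nrow(idx)) sum(matcher$src_pixels[idx]) else 0
  nb <- nrow(idx)
  2 * ov / (matcher$n_src + nb)
}

#' Search grid for the coarse brute-force stage
#'
#' @param tx_range,ty_range translation search ranges in px (must contain 0).
#' @param theta_range rotation range in degrees (must contain 0).
#' @param tx_step,ty_step,theta_step step sizes (> 0).
#' @export
search_grid <- function(tx_range = c(-50, 50), ty_range = c(-50, 50),
                        theta_range = c(-15, 15), tx_step = 2, ty_step = 2,
                        theta_step = 1) {
  stopifnot(tx_step > 0, ty_step > 0, theta_step > 0,
            tx_range[1] <= 0, tx_range[2] >= 0,
            ty_range[1] <= 0, ty_range[2] >= 0,
            theta_range[1] <= 0, theta_range[2] >= 0)
  structure(list(tx = seq(tx_range[1], tx_range[2], by = tx_step),
                 ty = seq(ty_range[1], ty_range[2], by = ty_step),
                 theta = seq(theta_range[1], theta_range[2],
                             by = theta_step)),
            class = "search_grid")
}

grid_nodes <- function(grid, offset = c(0, 0, 0)) {
  nodes <- expand.grid(tx = grid$tx + offset[1], ty = grid$ty + offset[2],
                       theta = grid$theta + offset[3],
                       KEEP.OUT.ATTRS = FALSE)
  # deterministic tie-break order: smallest (|tx|, |ty|, |theta|) first
  nodes[order(abs(nodes$tx - offset[1]), abs(nodes$ty - offset[2]),
              abs(nodes$theta - offset[3]),
              nodes$tx, nodes$ty, nodes$theta), , drop = FALSE]
}

#' Brute-force translation/rotation search
#'
#' Evaluates [score_match()] at every grid node (shear 0, scale 1) and
#' returns the maximizing node; exact score ties are broken toward the
#' smallest `(|tx|, |ty|, |theta|)` lexicographically, so the result is
#' deterministic.
#'
#' @param matcher an [outline_matcher()].
#' @param grid a [search_grid()].
#' @param metric see [score_match()].
#' @param offset length-3 `(tx, ty, theta)` added to every node (used to
#'   seed the search from a neighbouring slice's solution).
#' @return an `alignment_result`: list with `transform`, `score`,
#'   `converged`, `iterations`.
#' @export
coarse_search <- function(matcher, grid, metric = c("dtf", "dice"),
                          offset = c(0, 0, 0)) {
  metric <- match.arg(metric)
  stopifnot(inherits(grid, "search_grid"))
  nodes <- grid_nodes(grid, offset)
  # vectorized row-major (2x3) pull matrices for rigid nodes:
  # A = R(theta), t_vec = (tx, ty) + c - A c
  th <- nodes$theta * pi / 180
  ct <- cos(th); st <- sin(th)
  cen <- matcher$centre
  rows <- cbind(ct, -st, nodes$tx + cen[1] - (ct * cen[1] - st * cen[2]),
                st, ct, nodes$ty + cen[2] - (st * cen[1] + ct * cen[2]))
  scores <- if (metric == "dtf") {
    as.numeric(cpp_score_dtf_batch(rows, matcher$dt_src, matcher$dt_tpl,
                                   matcher$pts_tpl, matcher$pts_src,
                                   matcher$dsat, matcher$upsample))
  } else {
    vapply(seq_len(nrow(nodes)), function(i)
      score_dice(matcher, affine2d(nodes$tx[i], nodes$ty[i],
                                   nodes$theta[i], centre = cen)),
      numeric(1))
  }
  if (all(scores == 0))
    stop("coarse search found no match (all scores zero)", call. = FALSE)
  best <- which.max(scores)  # first maximum == smallest-|.| tie-break
  alignment_result(
    affine2d(nodes$tx[best], nodes$ty[best], nodes$theta[best],
             centre = cen),
    scores[[best]], converged = FALSE, iterations = nrow(nodes),
    params = c(tx = nodes$tx[best], ty = nodes$ty[best],
               theta = nodes$theta[best], shear = 0, scale = 1))
}

alignment_result <- function(transform, score, converged, iterations,
                             params = NULL) {
  stopifnot(score >= 0, score <= 1)
  structure(list(transform = transform, score = score,
                 converged = converged, iterations = iterations,
                 params = params),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment_result: score %.4f, %s after %d evaluations\n",
              x$score, if (x$converged) "converged" else "not converged",
              x$iterations))
  print(x$transform)
  invisible(x)
}

#' Local affine refinement of an alignment
#'
#' Derivative-free simplex (Nelder-Mead) optimization of the five-parameter
#' vector `(tx, ty, theta, shear, scale)` starting from the coarse result.
#' The refined result is returned only if it does not degrade the score;
#' otherwise the initial result is returned with `converged = FALSE`.
#'
#' @param matcher an [outline_matcher()].
#' @param init an `alignment_result` (from [coarse_search()] or built by the
#'   caller).
#' @param metric see [score_match()].
#' @param maxit maximum simplex function evaluations per start.
#' @param tol relative convergence tolerance on the score.
#' @param restarts number of deterministic simplex restarts from the
#'   incumbent solution (each restart rebuilds the simplex, which recovers
#'   precision a single collapsed simplex cannot reach).
#' @export
refine_affine <- function(matcher, init, metric = c("dtf", "dice"),
                          maxit = 500, tol = 1e-10, restarts = 2) {
  metric <- match.arg(metric)
  stopifnot(inherits(init, "alignment_result"))
  p0 <- if (!is.null(init$params)) init$params
        else affine2d_params(init$transform, centre = matcher$centre)
  objective <- function(p) {
    if (p[5] <= 0.1) return(0)  # guard absurd scales
    t <- affine2d(p[1], p[2], p[3], p[4], p[5], centre = matcher$centre)
    -score_match(matcher, t, metric = metric)
  }
  p <- unname(p0)
  value <- Inf
  evals <- 0L
  conv <- 1L
  for (r in seq_len(1 + restarts)) {
    fit <- stats::optim(p, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = tol,
                                       parscale = c(1, 1, 0.5, 0.01,
                                                    0.01)))
    evals <- evals + as.integer(fit$counts[["function"]])
    improved <- fit$value < value
    p <- fit$par
    value <- fit$value
    conv <- fit$convergence
    if (conv == 0L && !improved) break
  }
  score <- -value
  if (score <= 0 || score < init$score) {
    out <- init
    out$converged <- FALSE
    return(out)
  }
  alignment_result(
    affine2d(p[1], p[2], p[3], p[4], p[5], centre = matcher$centre),
    score, converged = (conv == 0L && score > 0),
    iterations = evals,
    params = c(tx = p[1], ty = p[2], theta = p[3], shear = p[4],
               scale = p[5]))
}

#' Align every slice of a stack to the template outline
#'
#' Runs outline extraction, coarse search and affine refinement per slice.
#' By default slice `i + 1`'s coarse search is seeded with slice `i`'s
#' refined `(tx, ty, theta)` (the mould moves little between grinds);
#' `chain_seed = FALSE` makes slices independent. Slices whose outline
#' cannot be extracted or matched are given identity transforms and listed
#' in the report; the pipeline continues.
#'
#' @param stack an [image_stack()].
#' @param template a [template_outline()].
#' @param grid a [search_grid()].
#' @param metric see [score_match()].
#' @param chain_seed seed each slice's search from the previous solution.
#' @param dsat,subsample passed to [outline_matcher()].
#' @param refine run the simplex refinement after the coarse stage.
#' @param verbose log one line per slice.
#' @return the stack with `transforms` set; a per-slice data.frame report in
#'   attribute `"alignment_report"` (columns: slice, coarse_score, score,
#'   converged, failed).
#' @export
align_stack <- function(stack, template, grid = search_grid(),
                        metric = c("dtf", "dice"), chain_seed = TRUE,
                        dsat = 25, subsample = 1L, refine = TRUE,
                        verbose = FALSE) {
  metric <- match.arg(metric)
  stopifnot(inherits(stack, "image_stack"), length(stack$slices) >= 1)
  n <- length(stack$slices)
  transforms <- vector("list", n)
  report <- data.frame(slice = seq_len(n), coarse_score = NA_real_,
                       score = NA_real_, converged = FALSE, failed = FALSE)
  seed <- c(0, 0, 0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      m_coarse <- outline_matcher(stack$slices[[i]], template, dsat = dsat,
                                  subsample = max(subsample, 4L))
      coarse <- coarse_search(m_coarse, grid, metric = metric,
                              offset = if (chain_seed) seed else c(0, 0, 0))
      m_fine <- if (subsample == max(subsample, 4L)) m_coarse
                else outline_matcher(stack$slices[[i]], template,
                                     dsat = dsat, subsample = subsample)
      coarse$score <- score_match(m_fine, coarse$transform, metric = metric)
      if (refine) {
        fine <- refine_affine(m_fine, coarse, metric = metric)
      } else fine <- coarse
      list(coarse = coarse, fine = fine)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      transforms[[i]] <- affine2d(centre = (dim(template$mask) - 1) / 2)
      report$failed[i] <- TRUE
      if (verbose) message(sprintf("slice %d: FAILED (%s)", i,
                                   conditionMessage(res)))
      next
    }
    transforms[[i]] <- res$fine$transform
    report$coarse_score[i] <- res$coarse$score
    report$score[i] <- res$fine$score
    report$converged[i] <- res$fine$converged
    if (chain_seed && !is.null(res$fine$params))
      seed <- unname(res$fine$params[c("tx", "ty", "theta")])
    if (verbose) message(sprintf("slice %d: score %.4f%s", i,
                                 res$fine$score,
                                 if (res$fine$converged) "" else " (*)"))
  }
  out <- stack
  out$transforms <- transforms
  attr(out, "alignment_report") <- report
  out
}

#' Warp a slice into the reference frame
#'
#' Inverse-mapping resample: output pixel `(r, c)` takes the bilinearly
#' interpolated value of the source image at `t %*% (r, c, 1)`, per RGB
#' channel, rounded half-to-even to 8 bits. Out-of-bounds pixels get the
#' background colour. Integer source coordinates are sampled exactly, so the
#' identity transform and pure integer translations are lossless.
#'
#' @param slice a [slice_image()].
#' @param t an [affine2d()] pull transform (reference -> source).
#' @param out_shape `(rows, cols)` of the output; defaults to the input
#'   shape.
#' @param background RGB background triplet (0..255).
#' @export
warp_slice <- function(slice, t, out_shape = NULL,
                       background = c(0, 0, 0)) {
  stopifnot(inherits(slice, "slice_image"), inherits(t, "affine2d"))
  m <- unclass(t)
  if (abs(det(m[1:2, 1:2])) < 1e-12)
    stop("singular transform cannot be used for warping", call. = FALSE)
  d <- dim(slice$pixels)
  if (is.null(out_shape)) out_shape <- d[1:2]
  out <- cpp_warp_bilinear(slice$pixels + 0.0, dim(slice$pixels), m,
                           as.integer(out_shape[1]),
                           as.integer(out_shape[2]),
                           as.numeric(background))
  out <- round(out)
  out[out < 0] <- 0
  out[out > 255] <- 255
  slice_image(out, slice$pixel_spacing, index = slice$index)
}
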