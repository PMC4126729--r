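#' Box counting over a binary image
#'
#' Counts, for each box size `eps`, the number of grid boxes containing at
#' least one filled in-mask pixel. To reduce grid-placement bias the count
#' at each scale is the minimum over the four corner-anchored grid offsets
#' (top-left, top-right, bottom-left, bottom-right); `offsets = "none"`
#' uses the top-left anchoring only.
#'
#' @param image A [raster_image].
#' @param scales Integer box sizes in pixels, strictly increasing; each must
#'   be at most `min(H, W) / 2`. Default: dyadic sizes 2, 4, ... up to
#'   `min(H, W) / 4` (at least 5 scales are required).
#' @param offsets `"corners"` (default) or `"none"`.
#' @return An object of class `box_count_series` with fields `scales`,
#'   `counts` and `grid_offsets_used`.
#' @examples
#' img <- generate_sierpinski_carpet(3)
#' box_count(img, scales = 3^(0:2))$counts  # 512, 64, 8
#' @export
box_count <- function(image, scales = NULL, offsets = c("corners", "none")) {
  if (!inherits(image, "raster_image")) stopf("image must be a raster_image")
  offsets <- match.arg(offsets)
  g <- image$grid
  h <- nrow(g); w <- ncol(g)
  filled <- which(g == 1L, arr.ind = TRUE)
  if (nrow(filled) == 0L) stopf("empty image: nothing to box-count")
  if (is.null(scales)) scales <- default_scales(min(h, w))
  scales <- sort(unique(as.integer(scales)))
  if (any(scales < 1L)) stopf("box sizes must be >= 1 pixel")
  if (any(scales > min(h, w) / 2))
    stopf("box sizes must be at most min(H, W) / 2")
  counts <- vapply(scales, function(eps) {
    offs <- if (offsets == "corners") {
      or <- (eps - h %% eps) %% eps
      oc <- (eps - w %% eps) %% eps
      unique(list(c(0L, 0L), c(or, 0L), c(0L, oc), c(or, oc)))
    } else list(c(0L, 0L))
    min(vapply(offs, function(o) {
      bi <- (filled[, 1L] - 1L + o[1L]) %/% eps
      bj <- (filled[, 2L] - 1L + o[2L]) %/% eps
      length(unique(bi * (w %/% eps + 2L) + bj))
    }, numeric(1)))
  }, numeric(1))
  structure(list(scales = scales, counts = counts,
                 grid_offsets_used = if (offsets == "corners") 4L else 1L),
            class = "box_count_series")
}

default_scales <- function(side) {
  s <- 2^(1:30)
  out <- s[s <= side / 4]
  # small images: extend the dyadic series to side/2 so the regression
  # still has 5 scales
  if (length(out) < 5L) out <- s[s <= side / 2]
  out
}

#' Fit the box-counting fractal dimension
#'
#' The box-counting dimension D_B is the magnitude of the slope of the
#' least-squares regression of log N(eps) on log eps. The regression uses
#' natural logs and unweighted ordinary least squares over the (optionally
#' restricted) fit range; R^2 is reported so poor scaling fits are visible.
#'
#' @param series A `box_count_series` from [box_count()].
#' @param fit_range Optional `c(eps_min, eps_max)` restricting the scales
#'   used in the regression.
#' @return An object of class `fractal_fit` with fields `D_B`, `r_squared`,
#'   `fit_range` and `n_scales`.
#' @export
fit_fd <- function(series, fit_range = NULL) {
  if (!inherits(series, "box_count_series"))
    stopf("series must come from box_count()")
  if (length(series$scales) < 5L)
    stopf("need at least 5 scales for the dimension fit, got %d",
          length(series$scales))
  eps <- series$scales; n <- series$counts
  if (!is.null(fit_range)) {
    keep <- eps >= fit_range[1L] & eps <= fit_range[2L]
    eps <- eps[keep]; n <- n[keep]
  }
  if (length(eps) < 2L) stopf("fit range leaves fewer than 2 scales")
  if (stats::var(n) == 0 && length(eps) > 1L)
    stopf("degenerate box-count series: all counts equal (%g)", n[1L])
  fit <- ols_slope(log(eps), log(n))
  structure(list(D_B = -unname(fit["slope"]),
                 r_squared = unname(fit["r2"]),
                 fit_range = range(eps), n_scales = length(eps)),
            class = "fractal_fit")
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("fractal_fit: D_B = %.4f (R^2 = %.4f, %d scales in [%g, %g])\n",
              x$D_B, x$r_squared, x$n_scales, x$fit_range[1L],
              x$fit_range[2L]))
  invisible(x)
}

#' Whole-image and region-of-interest fractal dimension
#'
#' `fd_entire()` runs box counting plus regression on the full image;
#' `fd_roi()` crops a rectangular region of interest first (the crop is
#' analyzed as an unmasked subimage) and is exactly `fd_entire()` of the
#' cropped subimage. A lower ROI dimension than the whole image indicates a
#' locally less complex, less space-filling pattern.
#'
#' @inheritParams box_count
#' @param roi Region `c(x0, y0, x1, y1)` in pixel units, half-open, with x
#'   the column measured from the left and y the row measured from the top
#'   (0-based, as in image viewers). Both sides must be at least 32 px.
#' @param ... Passed on to [box_count()].
#' @return A `fractal_fit`.
#' @export
fd_entire <- function(image, scales = NULL, ...) {
  fit_fd(box_count(image, scales = scales, ...))
}

#' @rdname fd_entire
#' @export
fd_roi <- function(image, roi, scales = NULL, ...) {
  fit_fd(box_count(crop_roi(image, roi), scales = scales, ...))
}

# crop [y0, y1) x [x0, x1) (0-based, row = y from top) into an unmasked image
crop_roi <- function(image, roi) {
  if (length(roi) != 4L) stopf("roi must be c(x0, y0, x1, y1)")
  x0 <- roi[1L]; y0 <- roi[2L]; x1 <- roi[3L]; y1 <- roi[4L]
  if (x1 - x0 < 32L || y1 - y0 < 32L) stopf("ROI sides must be >= 32 px")
  if (x0 < 0L || y0 < 0L || x1 > ncol(image$grid) || y1 > nrow(image$grid))
    stopf("ROI outside the image")
  sub <- image$grid[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE]
  if (sum(sub) == 0L) stopf("empty ROI crop")
  raster_image(sub, pixel_size = image$pixel_size, mask_diameter = NULL)
}

#' Local fractal dimension on a tiled grid
#'
#' Splits the image into an `tiles[1]` x `tiles[2]` grid (default 6 x 6, a
#' normalized caliber of 1/6 x 1/6) and fits the box-counting dimension in
#' each tile. Tiles with fewer than 2 filled pixels (or a degenerate count
#' series) are reported as `NA`, never as 0. When a baseline grid is given,
#' the ratio map `beta = FD(tile) / FD(baseline tile)` is attached; beta
#' maps against the healthy condition localize where a disease changes
#' pattern complexity.
#'
#' @inheritParams box_count
#' @param tiles Integer vector `c(rows, cols)`.
#' @param baseline Optional `local_fd_grid` computed on a reference image
#'   with the same tiling.
#' @return An object of class `local_fd_grid` with matrices `fd`, `r2`, and
#'   optionally `beta`.
#' @export
local_fd_grid <- function(image, tiles = c(6L, 6L), baseline = NULL) {
  g <- image$grid
  h <- nrow(g); w <- ncol(g)
  rb <- floor(seq(0L, h, length.out = tiles[1L] + 1L))
  cb <- floor(seq(0L, w, length.out = tiles[2L] + 1L))
  tile_side <- min(diff(rb), diff(cb))
  if (tile_side < 32L) stopf("tiles smaller than 32 px")
  sc <- 2^(1:30); sc <- sc[sc <= tile_side / 2]
  if (length(sc) < 5L)
    stopf("tile side %d px too small for 5 dyadic scales", tile_side)
  fd <- matrix(NA_real_, tiles[1L], tiles[2L])
  r2 <- matrix(NA_real_, tiles[1L], tiles[2L])
  for (i in seq_len(tiles[1L])) for (j in seq_len(tiles[2L])) {
    sub <- g[(rb[i] + 1L):rb[i + 1L], (cb[j] + 1L):cb[j + 1L], drop = FALSE]
    if (sum(sub) < 2L) next
    fit <- tryCatch(
      fit_fd(box_count(raster_image(sub, image$pixel_size, NULL),
                       scales = sc)),
      error = function(e) NULL)
    if (!is.null(fit)) { fd[i, j] <- fit$D_B; r2[i, j] <- fit$r_squared }
  }
  out <- structure(list(fd = fd, r2 = r2, tiles = tiles,
                        row_bounds = rb, col_bounds = cb, beta = NULL),
                   class = "local_fd_grid")
  if (!is.null(baseline)) {
    if (!identical(baseline$tiles, tiles)) stopf("baseline tiling mismatch")
    out$beta <- fd / baseline$fd
  }
  out
}
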