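#' Sliding-box pixel counts
#'
#' Slides an `eps` x `eps` window across the image with the given stride and
#' returns the filled-pixel count of every window position. For a circularly
#' masked image, windows are restricted to positions fully inside the mask's
#' inscribed square, so the circular boundary does not inject artificial
#' heterogeneity; unmasked images use the full frame.
#'
#' @param image A [raster_image].
#' @param eps Window side in pixels.
#' @param stride Window step in pixels (1 = full sliding).
#' @return Integer vector of per-window filled-pixel counts, each in
#'   `[0, eps^2]`.
#' @export
sliding_box_counts <- function(image, eps, stride = 1L) {
  if (!inherits(image, "raster_image")) stopf("image must be a raster_image")
  g <- image$grid
  h <- nrow(g); w <- ncol(g)
  if (eps > min(h, w)) stopf("box size %d exceeds image side", eps)
  if (stride < 1L) stopf("stride must be >= 1")
  r0 <- 1L; c0 <- 1L; r1 <- h; c1 <- w
  if (!is.null(image$mask_diameter)) {
    # inscribed square of the disk, in pixels
    res <- h
    half <- floor(res / (2 * sqrt(2)))
    ctr <- res / 2
    r0 <- max(1L, ceiling(ctr - half)); r1 <- min(h, floor(ctr + half))
    c0 <- r0; c1 <- r1
  }
  if (r1 - r0 + 1L < eps) stopf("box size %d exceeds the analysis region", eps)
  s <- sat(g[r0:r1, c0:c1, drop = FALSE])
  hh <- r1 - r0 + 1L; ww <- c1 - c0 + 1L
  ri <- seq(1L, hh - eps + 1L, by = stride)
  ci <- seq(1L, ww - eps + 1L, by = stride)
  counts <- outer(ri, ci, function(i, j)
    s[cbind(i + eps, j + eps)] - s[cbind(i, j + eps)] -
      s[cbind(i + eps, j)] + s[cbind(i, j)])
  # row-major scan order: left-to-right, then top-to-bottom
  as.integer(round(t(counts)))
}

#' Sliding-box lacunarity
#'
#' For each box size eps, lacunarity is the squared coefficient of variation
#' lambda(eps) = (sigma / mu)^2 of the sliding-window filled-pixel counts
#' (population standard deviation), and the aggregate Lambda is the mean of
#' lambda over the E box sizes. Translation-invariant patterns at a scale
#' (all-filled images, a checkerboard at its period) give lambda = 0;
#' clumpy, heterogeneous patterns give large values. Lacunarity separates
#' patterns that share a fractal dimension but fill space differently.
#'
#' @param image A [raster_image] with at least one filled pixel in the
#'   analysis region.
#' @param box_sizes Integer box sides; default the dyadic series shared
#'   with the fractal module, capped at the analysis-region side.
#' @param stride Window step in pixels (default 1, full sliding; larger
#'   strides subsample window positions and slightly bias sigma).
#' @return An object of class `lacunarity_series` with fields `box_sizes`,
#'   `lambda_eps`, `mu`, `sigma`, `E` and `Lambda`.
#' @examples
#' img <- raster_image(matrix(1L, 16, 16))
#' lacunarity_series(img, box_sizes = 2:6)$Lambda  # 0
#' @export
lacunarity_series <- function(image, box_sizes = NULL, stride = 1L) {
  g <- image$grid
  if (sum(g) == 0L) stopf("empty image: lacunarity undefined (mu = 0)")
  side <- min(nrow(g), ncol(g))
  if (is.null(box_sizes)) {
    lim <- if (is.null(image$mask_diameter)) side / 4
           else floor(side / sqrt(2)) / 4
    box_sizes <- 2^(1:30); box_sizes <- box_sizes[box_sizes <= lim]
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  stats_per <- lapply(box_sizes, function(eps) {
    counts <- sliding_box_counts(image, eps, stride)
    mu <- mean(counts)
    if (mu == 0) stopf("no filled pixels under box size %d", eps)
    sigma <- sqrt(mean((counts - mu)^2))
    c(mu = mu, sigma = sigma, lambda = (sigma / mu)^2)
  })
  m <- do.call(rbind, stats_per)
  structure(list(box_sizes = box_sizes, lambda_eps = unname(m[, "lambda"]),
                 mu = unname(m[, "mu"]), sigma = unname(m[, "sigma"]),
                 E = length(box_sizes), Lambda = mean(m[, "lambda"])),
            class = "lacunarity_series")
}

#' @export
print.lacunarity_series <- function(x, ...) {
  cat(sprintf("lacunarity_series: Lambda = %.4f over E = %d box sizes [%d..%d]\n",
              x$Lambda, x$E, min(x$box_sizes), max(x$box_sizes)))
  invisible(x)
}

#' @rdname lacunarity_series
#' @param roi Region `c(x0, y0, x1, y1)` in pixels, half-open (see
#'   [fd_roi()]).
#' @export
lacunarity_roi <- function(image, roi, box_sizes = NULL, stride = 1L) {
  lacunarity_series(crop_roi(image, roi), box_sizes = box_sizes,
                    stride = stride)
}
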