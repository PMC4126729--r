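#' Raster containers for fingerprint images
#'
#' `raster_image()` wraps a binary occupancy grid with its physical pixel
#' size and an optional circular mask; `concentration_map()` wraps a
#' non-negative grid of local-to-overall concentration ratios. Grids are
#' matrices with row 1 at the top of the image and column 1 at the left;
#' physically, the disk center is at the grid center, x increases with
#' column and y increases upward (i.e. decreases with row). A pixel belongs
#' to the mask when its center lies inside the closed disk. With
#' `mask_diameter = NULL` the full rectangle is the domain (used by square
#' analytic fixtures such as the Sierpinski carpet).
#'
#' @param grid Numeric/integer matrix; for `raster_image` values in {0, 1}.
#' @param pixel_size Physical pixel edge in mm.
#' @param mask_diameter Disk diameter in mm, or `NULL` for no mask.
#' @param total_particles Particle count behind a concentration map (used to
#'   report point masses; `NA` for analytic measures).
#' @return An object of class `raster_image` or `concentration_map`.
#' @export
raster_image <- function(grid, pixel_size = 1, mask_diameter = NULL) {
  grid <- as.matrix(grid)
  if (nrow(grid) < 3L || ncol(grid) < 3L) stopf("grid must be at least 3x3")
  if (!all(grid %in% c(0, 1))) stopf("occupancy grid must be binary")
  storage.mode(grid) <- "integer"
  if (!is.null(mask_diameter)) {
    if (nrow(grid) != ncol(grid)) stopf("masked images must be square")
    m <- disk_mask(nrow(grid), mask_diameter)
    grid[!m] <- 0L
  }
  structure(list(grid = grid, pixel_size = pixel_size,
                 mask_diameter = mask_diameter),
            class = "raster_image")
}

#' @rdname raster_image
#' @export
concentration_map <- function(grid, pixel_size = 1, mask_diameter = NULL,
                              total_particles = NA_real_) {
  grid <- as.matrix(grid)
  if (any(grid < 0)) stopf("concentration ratios must be non-negative")
  if (!is.null(mask_diameter)) {
    m <- disk_mask(nrow(grid), mask_diameter)
    grid[!m] <- 0
  }
  structure(list(grid = grid, pixel_size = pixel_size,
                 mask_diameter = mask_diameter,
                 total_particles = total_particles),
            class = "concentration_map")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("raster_image: %dx%d px (%.4f mm/px), %d filled, mask %s\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size, sum(x$grid),
              if (is.null(x$mask_diameter)) "none"
              else sprintf("disk %.1f mm", x$mask_diameter)))
  invisible(x)
}

#' @export
print.concentration_map <- function(x, ...) {
  cat(sprintf("concentration_map: %dx%d px (%.4f mm/px), mask %s\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size,
              if (is.null(x$mask_diameter)) "none"
              else sprintf("disk %.1f mm", x$mask_diameter)))
  invisible(x)
}

# logical in-mask matrix for an image-like object
mask_of <- function(img) {
  if (is.null(img$mask_diameter))
    matrix(TRUE, nrow(img$grid), ncol(img$grid))
  else disk_mask(nrow(img$grid), img$mask_diameter)
}

# (row, col) pixel indices of particle coordinates; closed boundary points
# are clamped into the edge pixels
px_index <- function(cloud, resolution) {
  d <- cloud$diameter
  h <- d / resolution
  col <- pmin(pmax(floor((cloud$x + d / 2) / h), 0), resolution - 1L) + 1L
  row <- pmin(pmax(floor((d / 2 - cloud$y) / h), 0), resolution - 1L) + 1L
  cbind(row, col)
}

#' Rasterize a particle cloud into a binary occupancy image
#'
#' A pixel is set to 1 when at least one particle center falls inside it.
#' Pixels are half-open in x (left edge included) and in y (top edge
#' included); particles exactly on the disk boundary are clamped into the
#' edge pixel they touch.
#'
#' @param cloud A [particle_cloud].
#' @param resolution Pixels per image side (default 512).
#' @return A [raster_image] whose mask diameter is the cloud's disk diameter.
#' @examples
#' cl <- particle_cloud(0, 0, diameter = 20)
#' img <- rasterize(cl, resolution = 64)
#' sum(img$grid)  # 1
#' @export
rasterize <- function(cloud, resolution = 512) {
  if (!inherits(cloud, "particle_cloud")) stopf("cloud must be a particle_cloud")
  if (resolution < 8L) stopf("resolution must be >= 8")
  idx <- px_index(cloud, resolution)
  g <- matrix(0L, resolution, resolution)
  g[idx] <- 1L
  raster_image(g, pixel_size = cloud$diameter / resolution,
               mask_diameter = cloud$diameter)
}

#' Relative particle concentration map
#'
#' Bins particle counts on a square grid and converts them to the ratio of
#' local concentration to the overall (disk-average) concentration, so the
#' in-mask mean ratio is exactly 1. A uniform cloud gives ratios near 1
#' everywhere; a point mass concentrates the whole ratio budget in one cell.
#'
#' @inheritParams rasterize
#' @return A [concentration_map].
#' @export
particle_concentration <- function(cloud, resolution = 512) {
  if (!inherits(cloud, "particle_cloud")) stopf("cloud must be a particle_cloud")
  if (resolution < 8L) stopf("resolution must be >= 8")
  idx <- px_index(cloud, resolution)
  counts <- matrix(0, resolution, resolution)
  tab <- table(factor(idx[, 1L], levels = seq_len(resolution)),
               factor(idx[, 2L], levels = seq_len(resolution)))
  counts[] <- as.numeric(tab)
  m <- disk_mask(resolution, cloud$diameter)
  # ratio = (count / cell area) / (overall in-mask count / mask area);
  # normalizing by the in-mask total keeps the in-mask mean at exactly 1
  # even when boundary particles fall into pixels whose center lies just
  # outside the disk
  n_in <- sum(counts[m])
  if (n_in == 0) stopf("no particles fall inside the pixel mask")
  ratio <- counts * sum(m) / n_in
  ratio[!m] <- 0
  concentration_map(ratio, pixel_size = cloud$diameter / resolution,
                    mask_diameter = cloud$diameter,
                    total_particles = n_particles(cloud))
}

#' Concentration-disparity map against a baseline
#'
#' Signed elementwise difference `case - baseline` between two concentration
#' maps on identical grids. The self-difference is identically zero; swapping
#' the arguments flips the sign, so paired positive/negative spots mark
#' accumulation shifted between the two conditions.
#'
#' @param case,baseline [concentration_map]s with identical shape, pixel
#'   size and mask.
#' @param case_label,baseline_label Labels carried into the result.
#' @return An object of class `difference_map`.
#' @export
difference_map <- function(case, baseline, case_label = "case",
                           baseline_label = "baseline") {
  if (!inherits(case, "concentration_map") ||
      !inherits(baseline, "concentration_map"))
    stopf("both inputs must be concentration_map objects")
  if (!identical(dim(case$grid), dim(baseline$grid)))
    stopf("grid shape mismatch")
  if (!isTRUE(all.equal(case$pixel_size, baseline$pixel_size)) ||
      !identical(case$mask_diameter, baseline$mask_diameter))
    stopf("pixel size / mask mismatch")
  structure(list(grid = case$grid - baseline$grid,
                 pixel_size = case$pixel_size,
                 mask_diameter = case$mask_diameter,
                 case_label = case_label, baseline_label = baseline_label),
            class = "difference_map")
}

#' Read and write fingerprint images
#'
#' Binary occupancy images are persisted as 8-bit PNG; concentration maps as
#' 16-bit TIFF with the ratio linearly scaled into [0, 1] by the stored
#' factor. Both carry a JSON sidecar (`<path>.json`) with the pixel size,
#' mask diameter and scale factor, so reading restores physical units
#' (16-bit quantization limits the concentration round trip to about 1 part
#' in 65535 of the maximum ratio).
#'
#' @param img A [raster_image] or [concentration_map].
#' @param path Output path (`.png` for binary, `.tiff` for grayscale).
#' @return Writers return `path` invisibly; readers return the restored
#'   object.
#' @export
write_raster_png <- function(img, path) {
  if (!inherits(img, "raster_image")) stopf("img must be a raster_image")
  png::writePNG(matrix(as.numeric(img$grid), nrow(img$grid)), path)
  sidecar <- list(pixel_size = img$pixel_size,
                  mask_diameter = img$mask_diameter)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_raster_png
#' @export
read_raster_png <- function(path) {
  g <- png::readPNG(path)
  if (length(dim(g)) == 3L) g <- g[, , 1L]
  meta <- jsonlite::read_json(paste0(path, ".json"))
  raster_image(round(g), pixel_size = meta$pixel_size,
               mask_diameter = meta$mask_diameter)
}

#' @rdname write_raster_png
#' @export
write_concentration_tiff <- function(img, path) {
  if (!inherits(img, "concentration_map")) stopf("img must be a concentration_map")
  scale <- max(img$grid, 1e-12)
  tiff::writeTIFF(img$grid / scale, path, bits.per.sample = 16L)
  sidecar <- list(pixel_size = img$pixel_size,
                  mask_diameter = img$mask_diameter,
                  scale_factor = scale,
                  total_particles = img$total_particles)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_raster_png
#' @export
read_concentration_tiff <- function(path) {
  g <- tiff::readTIFF(path)
  if (length(dim(g)) == 3L) g <- g[, , 1L]
  meta <- jsonlite::read_json(paste0(path, ".json"))
  concentration_map(g * meta$scale_factor, pixel_size = meta$pixel_size,
                    mask_diameter = meta$mask_diameter,
                    total_particles = if (is.null(meta$total_particles))
                      NA_real_ else meta$total_particles)
}
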