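# exact strip area of the disk between vertical chords at a < b (mm, origin
# at center, radius R): integral of 2*sqrt(R^2 - t^2) dt
strip_area <- function(a, b, R) {
  Fi <- function(t) {
    t <- pmin(pmax(t, -R), R)
    t * sqrt(pmax(R^2 - t^2, 0)) + R^2 * asin(t / R)
  }
  Fi(b) - Fi(a)
}

#' Directional probability profile of a particle cloud
#'
#' Scans the fingerprint in one of four directions and bins the particles
#' into `n_bins` equal-width bins of the normalized coordinate: horizontal
#' x/X and vertical z/Z map the disk's bounding square to [0, 1] (z is the
#' vertical axis, positive up), radial r/R spans [0, 1], and the
#' circumferential angle theta spans [0, 360) degrees counterclockwise from
#' the +x axis. Per-bin counts are normalized by the total particle number
#' and by the physical in-disk bin area (computed analytically from
#' circle-strip, annulus or sector geometry), yielding a probability
#' density in %/mm^2 whose area-weighted sum is exactly 100%. Edge bins
#' whose in-disk area falls below 1% of the mean bin area are merged
#' inward to avoid density blow-up.
#'
#' @param cloud A [particle_cloud].
#' @param direction One of `"horizontal"`, `"vertical"`, `"radial"`,
#'   `"circumferential"`.
#' @param n_bins Number of bins (default 50, >= 4).
#' @return An object of class `directional_profile`: a data frame with
#'   columns `bin_lo`, `bin_hi`, `mid` (normalized coordinate, or degrees),
#'   `count`, `area_mm2`, `density` and attributes `direction`, `n_total`,
#'   `diameter`.
#' @examples
#' cl <- generate_fingerprint(fingerprint_params(n_particles = 5000, seed = 3))
#' pr <- directional_profile(cl, "radial")
#' sum(pr$density * pr$area_mm2)  # 100
#' @export
directional_profile <- function(cloud,
                                direction = c("horizontal", "vertical",
                                              "radial", "circumferential"),
                                n_bins = 50L) {
  if (!inherits(cloud, "particle_cloud")) stopf("cloud must be a particle_cloud")
  direction <- match.arg(direction)
  if (n_bins < 4L) stopf("n_bins must be >= 4")
  R <- cloud$diameter / 2
  coord <- switch(direction,
    horizontal = (cloud$x + R) / (2 * R),
    vertical = (cloud$y + R) / (2 * R),
    radial = sqrt(cloud$x^2 + cloud$y^2) / R,
    circumferential = (atan2(cloud$y, cloud$x) * 180 / pi) %% 360)
  hi <- if (direction == "circumferential") 360 else 1
  edges <- seq(0, hi, length.out = n_bins + 1L)
  area_fun <- switch(direction,
    horizontal = ,
    vertical = function(a, b) strip_area((a - 0.5) * 2 * R,
                                         (b - 0.5) * 2 * R, R),
    radial = function(a, b) pi * R^2 * (b^2 - a^2),
    circumferential = function(a, b) pi * R^2 * (b - a) / 360)
  areas <- area_fun(edges[-(n_bins + 1L)], edges[-1L])
  # merge near-zero-area edge bins inward (possible only for very fine
  # horizontal/vertical binning)
  while (length(areas) > 4L && min(areas) < 0.01 * mean(areas)) {
    i <- which.min(areas)
    j <- if (i == 1L) 2L else if (i == length(areas)) i - 1L else
      if (areas[i - 1L] < areas[i + 1L]) i - 1L else i + 1L
    lo <- min(i, j); hi2 <- max(i, j)
    edges <- edges[-(lo + 1L)]
    areas[lo] <- areas[lo] + areas[hi2]
    areas <- areas[-hi2]
  }
  nb <- length(areas)
  bin <- pmin(findInterval(coord, edges, rightmost.closed = TRUE), nb)
  counts <- tabulate(bin, nbins = nb)
  n <- n_particles(cloud)
  density <- (counts / n * 100) / areas
  out <- data.frame(bin_lo = edges[-(nb + 1L)], bin_hi = edges[-1L],
                    mid = (edges[-(nb + 1L)] + edges[-1L]) / 2,
                    count = counts, area_mm2 = areas, density = density)
  class(out) <- c("directional_profile", "data.frame")
  attr(out, "direction") <- direction
  attr(out, "n_total") <- n
  attr(out, "diameter") <- cloud$diameter
  out
}

#' @rdname directional_profile
#' @param n_sectors Number of angular sectors for the rose plot.
#' @export
rose_profile <- function(cloud, n_sectors = 36L) {
  directional_profile(cloud, "circumferential", n_bins = n_sectors)
}

#' Locate density spikes in a directional profile
#'
#' Smooths the density with a 3-bin moving average (circular for the
#' circumferential direction) and reports local maxima whose smoothed
#' density reaches `prominence` times the disk-mean density
#' (100% / disk area). Spikes in two orthogonal directions jointly
#' triangulate a hot spot's 2-D position.
#'
#' @param profile A [directional_profile()].
#' @param prominence Multiple of the mean density a spike must reach
#'   (default 2).
#' @return A data frame (possibly empty) with columns `direction`, `bin`,
#'   `coord` (bin midpoint) and `density` (smoothed), ordered by density.
#' @export
find_spikes <- function(profile, prominence = 2) {
  if (!inherits(profile, "directional_profile"))
    stopf("profile must come from directional_profile()")
  d <- profile$density
  nb <- length(d)
  circular <- attr(profile, "direction") == "circumferential"
  sm <- vapply(seq_len(nb), function(i) {
    idx <- (i - 1L):(i + 1L)
    if (circular) idx <- ((idx - 1L) %% nb) + 1L else idx <- idx[idx >= 1L & idx <= nb]
    mean(d[idx])
  }, numeric(1))
  mean_density <- 100 / sum(profile$area_mm2)
  is_max <- vapply(seq_len(nb), function(i) {
    left <- if (i > 1L) sm[i - 1L] else if (circular) sm[nb] else -Inf
    right <- if (i < nb) sm[i + 1L] else if (circular) sm[1L] else -Inf
    sm[i] >= left && sm[i] >= right && (sm[i] > left || sm[i] > right)
  }, logical(1))
  hit <- which(is_max & sm >= prominence * mean_density)
  out <- data.frame(direction = rep(attr(profile, "direction"), length(hit)),
                    bin = hit, coord = profile$mid[hit], density = sm[hit])
  out[order(-out$density), , drop = FALSE]
}
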