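#' Parameters of the synthetic fingerprint generator
#'
#' The generator emulates the qualitative features of exhaled-aerosol
#' patterns on the mouth-exit plane: a pair of vortex-like particle
#' accumulations, a central stripe, a diffuse background, left/right
#' asymmetry, and optional disease perturbations -- a crescent-shaped void
#' (particle depletion in an annular sector) and a shifted hot spot.
#' Positions are sampled from a truncated Gaussian mixture on the closed
#' disk, with an angular swirl displacement around each vortex center; the
#' void is applied by rejection thinning, so exactly `n_particles` points
#' are always returned.
#'
#' Normalized coordinates map the disk's bounding square to [0, 1]^2 with
#' (0, 0) at the lower-left: a normalized point (u, v) sits at physical
#' x = (u - 1/2) * D, y = (v - 1/2) * D.
#'
#' @param n_particles Number of particles to generate (>= 1).
#' @param diameter Disk diameter in mm (default 20).
#' @param vortex_centers 2x2 matrix of normalized vortex centers (rows).
#' @param vortex_spread Normalized Gaussian spread of each vortex.
#' @param vortex_weight,stripe_weight,background_weight Non-negative mixture
#'   weights (normalized to sum 1 internally).
#' @param vortex_balance Fraction of the vortex weight assigned to the first
#'   (left) vortex; values away from 1/2 create the left/right asymmetry.
#' @param swirl Angular displacement amplitude (radians) applied around each
#'   vortex center, decaying with distance.
#' @param stripe_sd Normalized width of the central vertical stripe.
#' @param void_spec Optional crescent void:
#'   `list(theta_deg, r_frac, width_deg, r_width_frac, depletion)` -- an
#'   annular sector centered at polar angle `theta_deg` and radius
#'   `r_frac * R`, of angular width `width_deg` and radial thickness
#'   `r_width_frac * R`, inside which particles are thinned with probability
#'   `depletion` in [0, 1].
#' @param hotspot_spec Optional hot spot:
#'   `list(center, spread, weight)` with a normalized center, a normalized
#'   Gaussian spread and an excess mixture weight.
#' @param seed Integer seed; every draw is a pure function of the
#'   parameters and this seed.
#' @return A parameter list of class `fingerprint_params`.
#' @export
fingerprint_params <- function(n_particles = 20000, diameter = 20,
                               vortex_centers = rbind(c(0.33, 0.58),
                                                      c(0.67, 0.52)),
                               vortex_spread = 0.10,
                               vortex_weight = 0.55,
                               stripe_weight = 0.25,
                               background_weight = 0.20,
                               vortex_balance = 0.56,
                               swirl = 0.6,
                               stripe_sd = 0.06,
                               void_spec = NULL,
                               hotspot_spec = NULL,
                               seed = 1L) {
  if (n_particles < 1L) stopf("n_particles must be >= 1")
  w <- c(vortex_weight, stripe_weight, background_weight)
  if (any(w < 0) || sum(w) <= 0) stopf("mixture weights must be non-negative")
  if (!is.null(void_spec)) {
    d <- void_spec$depletion
    if (is.null(d) || d < 0 || d > 1)
      stopf("void depletion must lie in [0, 1]")
    if (void_spec$r_frac < 0 || void_spec$r_frac > 1)
      stopf("void center radius outside the unit disk")
  }
  if (!is.null(hotspot_spec)) {
    ctr <- hotspot_spec$center
    if (sqrt(sum((ctr - 0.5)^2)) > 0.5)
      stopf("hotspot center outside the unit disk")
  }
  structure(list(n_particles = as.integer(n_particles), diameter = diameter,
                 vortex_centers = vortex_centers,
                 vortex_spread = vortex_spread,
                 vortex_weight = vortex_weight,
                 stripe_weight = stripe_weight,
                 background_weight = background_weight,
                 vortex_balance = vortex_balance, swirl = swirl,
                 stripe_sd = stripe_sd, void_spec = void_spec,
                 hotspot_spec = hotspot_spec, seed = as.integer(seed)),
            class = "fingerprint_params")
}

#' Fingerprint templates for the four airway models
#'
#' Canned parameter sets emulating one healthy and three diseased exhalation
#' patterns: "A" (normal; two well-defined vortices plus central stripe),
#' "B" (large central obstruction; left vortex nearly vanished, pattern
#' blurred, lower regions disturbed), "C" (small lower-left obstruction;
#' left vortex weakened and displaced downward), and "D" (asthma-like;
#' normal pattern plus an upper-left crescent void and a hot spot at
#' normalized (0.2, 0.65)).
#'
#' @param model One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param n_particles,seed Passed to [fingerprint_params()].
#' @return A `fingerprint_params` object.
#' @export
fingerprint_template <- function(model = c("A", "B", "C", "D"),
                                 n_particles = 20000, seed = 1L) {
  model <- match.arg(model)
  base <- switch(model,
    A = fingerprint_params(n_particles = n_particles, seed = seed),
    B = fingerprint_params(n_particles = n_particles, seed = seed,
                           vortex_balance = 0.12, vortex_spread = 0.16,
                           stripe_weight = 0.12, background_weight = 0.38,
                           swirl = 0.3),
    C = fingerprint_params(n_particles = n_particles, seed = seed,
                           vortex_centers = rbind(c(0.30, 0.42),
                                                  c(0.67, 0.52)),
                           vortex_balance = 0.35, vortex_spread = 0.13,
                           stripe_weight = 0.18, background_weight = 0.27),
    D = fingerprint_params(n_particles = n_particles, seed = seed,
                           void_spec = list(theta_deg = 135, r_frac = 0.72,
                                            width_deg = 80,
                                            r_width_frac = 0.40,
                                            depletion = 0.85),
                           hotspot_spec = list(center = c(0.20, 0.65),
                                               spread = 0.025,
                                               weight = 0.12)))
  base$model <- model
  base
}

# TRUE for points inside the annular-sector void region (physical mm coords)
in_void <- function(x, y, void_spec, diameter) {
  R <- diameter / 2
  r <- sqrt(x^2 + y^2) / R
  th <- atan2(y, x) * 180 / pi
  dth <- abs(((th - void_spec$theta_deg + 180) %% 360) - 180)
  r >= void_spec$r_frac - void_spec$r_width_frac / 2 &
    r <= void_spec$r_frac + void_spec$r_width_frac / 2 &
    dth <= void_spec$width_deg / 2
}

# one batch of m candidate points from the mixture, in physical mm
sample_mixture <- function(p, m) {
  R <- p$diameter / 2
  w <- c(p$vortex_weight * p$vortex_balance,
         p$vortex_weight * (1 - p$vortex_balance),
         p$stripe_weight, p$background_weight)
  if (!is.null(p$hotspot_spec)) w <- c(w, p$hotspot_spec$weight)
  comp <- sample.int(length(w), m, replace = TRUE, prob = w / sum(w))
  x <- numeric(m); y <- numeric(m)
  for (k in 1:2) {
    i <- comp == k
    if (!any(i)) next
    ctr <- (p$vortex_centers[k, ] - 0.5) * p$diameter
    sx <- stats::rnorm(sum(i), 0, p$vortex_spread * p$diameter)
    sy <- stats::rnorm(sum(i), 0, p$vortex_spread * p$diameter)
    # swirl: rotate each offset about the vortex center, strongest nearby
    rr <- sqrt(sx^2 + sy^2)
    ang <- p$swirl * exp(-rr / (p$vortex_spread * p$diameter))
    x[i] <- ctr[1L] + sx * cos(ang) - sy * sin(ang)
    y[i] <- ctr[2L] + sx * sin(ang) + sy * cos(ang)
  }
  i <- comp == 3L  # central vertical stripe
  if (any(i)) {
    x[i] <- stats::rnorm(sum(i), 0, p$stripe_sd * p$diameter)
    y[i] <- stats::runif(sum(i), -R, R)
  }
  i <- comp == 4L  # uniform background over the disk
  if (any(i)) {
    rr <- R * sqrt(stats::runif(sum(i)))
    th <- stats::runif(sum(i), 0, 2 * pi)
    x[i] <- rr * cos(th); y[i] <- rr * sin(th)
  }
  if (!is.null(p$hotspot_spec)) {
    i <- comp == 5L
    if (any(i)) {
      ctr <- (p$hotspot_spec$center - 0.5) * p$diameter
      x[i] <- stats::rnorm(sum(i), ctr[1L], p$hotspot_spec$spread * p$diameter)
      y[i] <- stats::rnorm(sum(i), ctr[2L], p$hotspot_spec$spread * p$diameter)
    }
  }
  list(x = x, y = y, hotspot = comp == 5L)
}

#' Generate a synthetic aerosol fingerprint
#'
#' Draws exactly `n_particles` positions on the closed disk from the
#' mixture described in [fingerprint_params()], applying disk truncation and
#' void thinning by rejection. Identical parameters and seed give bitwise
#' identical output. After thinning, the expected particle density inside
#' the void region is `(1 - depletion)` times the no-void density (up to
#' the renormalization that keeps the total count fixed). Hot-spot
#' particles are exempt from void thinning: a disease hot spot is an
#' accumulation feature that coexists with the adjacent void.
#'
#' @param params A [fingerprint_params()] object.
#' @return A [particle_cloud] labeled with the template's model (if set).
#' @examples
#' cl <- generate_fingerprint(fingerprint_params(n_particles = 1000, seed = 7))
#' n_particles(cl)
#' @export
generate_fingerprint <- function(params) {
  if (!inherits(params, "fingerprint_params"))
    stopf("params must come from fingerprint_params()")
  p <- params
  R <- p$diameter / 2
  withr::with_seed(p$seed, {
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < p$n_particles) {
      m <- max(1000L, ceiling((p$n_particles - length(xs)) * 1.6))
      b <- sample_mixture(p, m)
      keep <- sqrt(b$x^2 + b$y^2) <= R
      if (!is.null(p$void_spec) && p$void_spec$depletion > 0) {
        # the hot spot is an accumulation feature that coexists with the
        # void (flow diverted around the constriction), so its component
        # is exempt from thinning
        v <- in_void(b$x, b$y, p$void_spec, p$diameter) & !b$hotspot
        thin <- v & stats::runif(m) < p$void_spec$depletion
        keep <- keep & !thin
      }
      xs <- c(xs, b$x[keep]); ys <- c(ys, b$y[keep])
    }
    particle_cloud(xs[seq_len(p$n_particles)], ys[seq_len(p$n_particles)],
                   diameter = p$diameter,
                   model = if (is.null(p$model)) "synthetic" else p$model,
                   replicate = 1L)
  })
}

#' Severity levels for the asthma-like series
#'
#' A severity level carries a label and two constriction fractions (for the
#' two modeled constricted bronchi); these are mapped to the void's
#' depletion (first fraction) and to a widening of its angular extent
#' (second fraction). The default series has zero depletion at D0 and
#' strictly increasing depletion through D3, so the crescent void becomes
#' progressively more obvious.
#'
#' @param label One of `"D0".."D3"` (free-form labels are accepted).
#' @param constriction Two fractions in [0, 1].
#' @return An object of class `severity_level`.
#' @export
severity_level <- function(label, constriction) {
  if (length(constriction) != 2L || any(constriction < 0 | constriction > 1))
    stopf("constriction must be two fractions in [0, 1]")
  structure(list(label = label, constriction = as.numeric(constriction)),
            class = "severity_level")
}

#' @rdname severity_level
#' @export
default_severity_levels <- function() {
  list(severity_level("D0", c(0.00, 0.00)),
       severity_level("D1", c(0.30, 0.20)),
       severity_level("D2", c(0.60, 0.45)),
       severity_level("D3", c(0.90, 0.70)))
}

#' Generate a graded severity series of fingerprints
#'
#' Applies each severity level to a base parameter set: the level's first
#' constriction fraction becomes the crescent void's depletion and its
#' second fraction widens the void's angular extent. All levels share the
#' base seed, so a zero-depletion level reproduces the base cloud exactly
#' and the expected in-void particle count is non-increasing along the
#' series.
#'
#' @param base A [fingerprint_params()] object; if it has no `void_spec`,
#'   the model-D template's crescent geometry is used.
#' @param levels List of [severity_level()] objects, ordered by severity.
#' @return A list of [particle_cloud]s, one per level, labeled by level.
#' @export
generate_severity_series <- function(base,
                                     levels = default_severity_levels()) {
  if (length(levels) == 0L) stopf("empty severity level list")
  void0 <- base$void_spec
  if (is.null(void0))
    void0 <- fingerprint_template("D")$void_spec
  lapply(levels, function(lv) {
    p <- base
    p$void_spec <- void0
    p$void_spec$depletion <- lv$constriction[1L]
    p$void_spec$width_deg <- void0$width_deg * (1 + 0.5 * lv$constriction[2L])
    if (lv$constriction[1L] == 0) p$void_spec <- NULL
    cl <- generate_fingerprint(p)
    cl$model <- lv$label
    cl
  })
}

#' Sierpinski carpet occupancy fixture
#'
#' Deterministic `3^levels` x `3^levels` binary image of the level-`levels`
#' Sierpinski carpet, whose box-counting dimension is log 8 / log 3
#' (about 1.8928) with exactly `8^levels` filled pixels.
#'
#' @param levels Recursion depth (>= 1; image side `3^levels` pixels).
#' @return A [raster_image] without a circular mask.
#' @export
generate_sierpinski_carpet <- function(levels) {
  if (levels < 1L) stopf("levels must be >= 1")
  if (3^levels > 4096) stopf("levels too large (side %d px)", 3^levels)
  cell <- matrix(1L, 3, 3); cell[2, 2] <- 0L
  g <- Reduce(function(a, b) kronecker(a, b), rep(list(cell), levels))
  raster_image(g, pixel_size = 1, mask_diameter = NULL)
}

#' Deterministic multiplicative cascade fixture
#'
#' Builds a `2^depth` x `2^depth` measure by recursively splitting mass into
#' four quadrants with the given weights (top-left, top-right, bottom-left,
#' bottom-right). The generalized dimensions of the limit measure have the
#' closed form D_q = log2(sum w_i^q) / (1 - q), making this the reference
#' fixture for the multifractal estimators. Total mass is exactly 1; the
#' map is returned in local/overall-ratio convention (grid mean 1).
#'
#' @param weights Four non-negative fractions summing to 1 (within 1e-12).
#' @param depth Number of dyadic subdivisions (>= 1; side `2^depth`).
#' @return A [concentration_map] without a circular mask.
#' @export
generate_cascade <- function(weights = c(0.4, 0.3, 0.2, 0.1), depth = 8) {
  if (length(weights) != 4L || any(weights < 0))
    stopf("weights must be four non-negative fractions")
  if (abs(sum(weights) - 1) > 1e-12) stopf("weights must sum to 1")
  if (depth < 1L) stopf("depth must be >= 1")
  if (2^depth > 4096) stopf("depth too large (side %d px)", 2^depth)
  w <- matrix(weights, 2, 2, byrow = TRUE)  # [1,1]=TL, [1,2]=TR, [2,1]=BL, [2,2]=BR
  mass <- Reduce(function(a, b) kronecker(a, b), rep(list(w), depth))
  concentration_map(mass * length(mass), pixel_size = 1,
                    mask_diameter = NULL, total_particles = NA_real_)
}
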