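test_that("generation is a pure function of parameters and seed", {
  p <- fingerprint_params(n_particles = 2000, seed = 42)
  a <- generate_fingerprint(p)
  b <- generate_fingerprint(p)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  p2 <- fingerprint_params(n_particles = 2000, seed = 43)
  expect_false(identical(generate_fingerprint(p2)$x, a$x))
})

test_that("clouds have exactly n particles, all inside the disk", {
  for (n in c(1, 17, 5000)) {
    cl <- generate_fingerprint(fingerprint_params(n_particles = n, seed = 1))
    expect_equal(n_particles(cl), n)
    expect_true(all(sqrt(cl$x^2 + cl$y^2) <= cl$diameter / 2 + 1e-9))
  }
  expect_error(fingerprint_params(n_particles = 0), "n_particles")
})

test_that("the vortex pair shows up as two density modes at the centers", {
  skip_if_not_installed("MASS")
  p <- fingerprint_params(n_particles = 10000, seed = 42)
  cl <- generate_fingerprint(p)
  # kernel-density argmax oracle: top two local maxima of a 2-D KDE
  k <- MASS::kde2d(cl$x, cl$y, n = 50, lims = c(-10, 10, -10, 10))
  z <- k$z
  nbr_max <- matrix(pmax(rbind(-Inf, z[-50, ]), rbind(z[-1, ], -Inf),
                         cbind(-Inf, z[, -50]), cbind(z[, -1], -Inf)),
                    50, 50)
  peaks <- which(z >= nbr_max, arr.ind = TRUE)
  peaks <- peaks[order(-z[peaks]), , drop = FALSE][1:2, ]
  px <- (k$x[peaks[, 1L]] + 10) / 20
  py <- (k$y[peaks[, 2L]] + 10) / 20
  for (v in 1:2) {
    dists <- sqrt((px - p$vortex_centers[v, 1L])^2 +
                  (py - p$vortex_centers[v, 2L])^2)
    expect_lt(min(dists), p$vortex_spread)
  }
})

test_that("void thinning depletes density by the requested fraction", {
  void <- list(theta_deg = 135, r_frac = 0.72, width_deg = 80,
               r_width_frac = 0.40, depletion = 0.6)
  in_void_frac <- function(cl) {
    R <- cl$diameter / 2
    r <- sqrt(cl$x^2 + cl$y^2) / R
    th <- (atan2(cl$y, cl$x) * 180 / pi)
    dth <- abs(((th - void$theta_deg + 180) %% 360) - 180)
    mean(r >= void$r_frac - void$r_width_frac / 2 &
         r <= void$r_frac + void$r_width_frac / 2 &
         dth <= void$width_deg / 2)
  }
  f_with <- f_without <- numeric(5)
  for (s in 1:5) {
    f_without[s] <- in_void_frac(generate_fingerprint(
      fingerprint_params(n_particles = 40000, seed = s)))
    f_with[s] <- in_void_frac(generate_fingerprint(
      fingerprint_params(n_particles = 40000, seed = s, void_spec = void)))
  }
  # expectation: (1 - d) x no-void density, up to the fixed-count
  # renormalization (1 - d * p_void)^-1 outside the void
  ratio <- mean(f_with) / mean(f_without)
  expected <- (1 - void$depletion) /
    (1 - void$depletion * mean(f_without))
  expect_lt(abs(ratio - expected), 0.1 * expected)
})

test_that("full depletion of a quadrant leaves it empty", {
  void <- list(theta_deg = 45, r_frac = 0.5, width_deg = 90,
               r_width_frac = 1.0, depletion = 1.0)
  cl <- generate_fingerprint(fingerprint_params(n_particles = 5000, seed = 9,
                                                void_spec = void))
  expect_equal(sum(cl$x > 0 & cl$y > 0), 0)
})

test_that("in-void counts fall strictly along the severity series", {
  void <- fingerprint_template("D")$void_spec
  count_in_void <- function(cl) {
    sum(in_void <- {
      R <- cl$diameter / 2
      r <- sqrt(cl$x^2 + cl$y^2) / R
      th <- atan2(cl$y, cl$x) * 180 / pi
      dth <- abs(((th - void$theta_deg + 180) %% 360) - 180)
      r >= void$r_frac - void$r_width_frac / 2 &
        r <= void$r_frac + void$r_width_frac / 2 &
        dth <= void$width_deg / 2
    })
  }
  counts <- sapply(1:5, function(s) {
    base <- fingerprint_params(n_particles = 20000, seed = s)
    vapply(generate_severity_series(base), count_in_void, numeric(1))
  })
  expect_true(all(diff(rowMeans(counts)) < 0))
  expect_error(generate_severity_series(fingerprint_params(), list()),
               "empty")
})

test_that("a depletion-free severity level reproduces the base cloud", {
  base <- fingerprint_params(n_particles = 3000, seed = 5)
  series <- generate_severity_series(base,
                                     list(severity_level("D0", c(0, 0))))
  ref <- generate_fingerprint(base)
  expect_identical(series[[1L]]$x, ref$x)
  expect_identical(series[[1L]]$y, ref$y)
  expect_equal(series[[1L]]$model, "D0")
})

test_that("Sierpinski carpet has the exact construction counts", {
  c1 <- generate_sierpinski_carpet(1)
  expect_equal(dim(c1$grid), c(3L, 3L))
  expect_equal(sum(c1$grid), 8)
  expect_equal(c1$grid[2, 2], 0L)
  c3 <- generate_sierpinski_carpet(3)
  expect_equal(sum(c3$grid), 8^3)
  expect_equal(length(c3$grid), 729L)
  expect_error(generate_sierpinski_carpet(0), "levels")
})

test_that("cascade masses follow the weight products exactly", {
  u <- generate_cascade(rep(0.25, 4), depth = 6)
  mass <- u$grid / sum(u$grid)
  expect_true(all(abs(mass - 4^-6) < 1e-15))
  w <- c(0.4, 0.3, 0.2, 0.1)
  c1 <- generate_cascade(w, depth = 1)
  expect_equal(c1$grid / sum(c1$grid),
               matrix(w, 2, 2, byrow = TRUE), tolerance = 1e-12)
  # quadrant mass at level 1 of a deep cascade equals its weight
  c3 <- generate_cascade(w, depth = 3)
  mass3 <- c3$grid / sum(c3$grid)
  expect_equal(sum(mass3[1:4, 1:4]), w[1L], tolerance = 1e-12)
  expect_equal(sum(mass3[5:8, 5:8]), w[4L], tolerance = 1e-12)
  expect_lt(abs(sum(mass3) - 1), 1e-9)
  expect_error(generate_cascade(c(0.5, 0.3, 0.1, 0.2)), "sum to 1")
})
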