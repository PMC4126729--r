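test_that("box masses match brute-force block sums", {
  g <- withr::with_seed(21, matrix(runif(64 * 64), 64, 64))
  map <- concentration_map(g)
  mg <- box_masses(map, scales = c(2, 4, 8, 16))
  for (k in seq_along(mg$scales)) {
    expect_equal(sort(mg$P[[k]]),
                 sort(brute_block_masses(g, mg$scales[k])),
                 tolerance = 1e-12)
    expect_lt(abs(sum(mg$P[[k]]) - 1), 1e-9)
  }
  # uniform map: all masses equal at every scale
  mu <- box_masses(concentration_map(matrix(1, 64, 64)), scales = c(2, 4, 8))
  for (P in mu$P) expect_true(all(abs(P - P[1L]) < 1e-12))
  # depth-1 cascade at half-side boxes: masses are exactly the weights
  w <- c(0.4, 0.3, 0.2, 0.1)
  mc <- box_masses(generate_cascade(w, depth = 4), scales = 8)
  expect_equal(sort(mc$P[[1L]]), sort(w), tolerance = 1e-12)
  expect_error(box_masses(concentration_map(matrix(0, 16, 16))), "zero-mass")
})

test_that("the normalized q-measure follows its closed forms", {
  P <- c(0.75, 0.25)
  expect_equal(normalized_measure(P, 2), c(0.9, 0.1), tolerance = 1e-12)
  expect_equal(normalized_measure(P, 1), P, tolerance = 1e-12)
  expect_equal(normalized_measure(P, 0), c(0.5, 0.5), tolerance = 1e-12)
  # extreme q stay finite thanks to log-domain accumulation
  P2 <- c(1e-300, 1 - 1e-300)
  expect_true(all(is.finite(normalized_measure(P2, 40))))
  expect_error(normalized_measure(c(0.5, 0), 2), "positive")
})

test_that("cascade spectra match the closed-form dimensions", {
  w <- c(0.4, 0.3, 0.2, 0.1)
  sp <- mf_spectrum(generate_cascade(w, depth = 8),
                    q_grid = seq(-5, 5, by = 0.25), scales = 2^(1:6))
  dq_true <- vapply(sp$q, function(q) cascade_dq(w, q), numeric(1))
  a_true <- vapply(sp$q, function(q) cascade_alpha(w, q), numeric(1))
  expect_lt(max(abs(sp$D_q - dq_true)), 0.02)
  expect_lt(max(abs(sp$alpha - a_true)), 0.02)
  # Legendre relation f = q*alpha - (q-1)*D_q
  f_true <- sp$q * a_true - (sp$q - 1) * dq_true
  expect_lt(max(abs(sp$f_alpha - f_true)), 0.02)
  expect_true(all(sp$r_squared > 0.999))
})

test_that("spectrum invariants hold: monotone D_q, tangency, apex at D0", {
  w <- c(0.5, 0.25, 0.15, 0.1)
  sp <- mf_spectrum(generate_cascade(w, depth = 7), scales = 2^(1:5))
  expect_true(all(diff(sp$D_q) <= 1e-9))
  expect_true(all(diff(sp$alpha) <= 1e-9))
  i0 <- which(sp$q == 0); i1 <- which(sp$q == 1)
  expect_equal(max(sp$f_alpha), sp$D_q[i0], tolerance = 1e-6)
  expect_equal(sp$f_alpha[i1], sp$alpha[i1], tolerance = 0.02)
  expect_equal(sp$alpha[i1], sp$D_q[i1], tolerance = 0.02)
})

test_that("uniform measures give a flat spectrum at the plane dimension", {
  sp <- mf_spectrum(concentration_map(matrix(1, 256, 256)),
                    scales = 2^(1:6))
  expect_lt(stats::sd(sp$D_q), 0.02)
  expect_equal(mean(sp$D_q), 2, tolerance = 0.02)
  sm <- spectrum_summary(sp)
  expect_lt(sm$alpha_width, 0.05)
  expect_true(is.na(sm$asymmetry))
})

test_that("spectra are invariant to global rescaling of the map", {
  g <- withr::with_seed(31, matrix(rexp(128 * 128), 128, 128))
  a <- mf_spectrum(concentration_map(g), scales = 2^(1:5), quiet = TRUE)
  b <- mf_spectrum(concentration_map(5 * g), scales = 2^(1:5), quiet = TRUE)
  expect_equal(a$D_q, b$D_q, tolerance = 1e-12)
  expect_equal(a$alpha, b$alpha, tolerance = 1e-12)
})

test_that("summaries are symmetric under weight permutations", {
  w <- c(0.4, 0.3, 0.2, 0.1)
  s1 <- spectrum_summary(mf_spectrum(generate_cascade(w, 6),
                                     scales = 2^(1:4)))
  s2 <- spectrum_summary(mf_spectrum(generate_cascade(rev(w), 6),
                                     scales = 2^(1:4)))
  for (f in c("alpha_width", "f_width", "asymmetry", "D0", "D1", "D2"))
    expect_equal(s1[[f]], s2[[f]], tolerance = 1e-9)
  # realized width at the q = +/-5 endpoints matches the closed form
  expect_equal(s1$alpha_width, cascade_alpha(w, -5) - cascade_alpha(w, 5),
               tolerance = 0.05)
})

test_that("an ROI over a homogeneous region narrows the spectrum", {
  # left half uniform, right half strongly multifractal
  w <- c(0.55, 0.25, 0.15, 0.05)
  casc <- generate_cascade(w, depth = 7)$grid
  g <- cbind(matrix(mean(casc), 128, 128), casc)
  whole <- spectrum_summary(mf_spectrum(concentration_map(g),
                                        scales = 2^(1:5), quiet = TRUE))
  roi <- spectrum_summary(mf_spectrum(
    concentration_map(g[, 1:128]), scales = 2^(1:5), quiet = TRUE))
  expect_lt(roi$alpha_width, whole$alpha_width)
})

test_that("a point measure degenerates to a flagged point spectrum", {
  g <- matrix(0, 64, 64); g[5, 9] <- 1
  sp <- mf_spectrum(concentration_map(g), scales = 2^(1:4))
  expect_true(attr(sp, "degenerate"))
  expect_true(all(sp$D_q == 0))
  sm <- spectrum_summary(sp)
  expect_equal(sm$alpha_width, 0)
  expect_true(is.na(sm$asymmetry))
  expect_true(sm$degenerate)
})
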