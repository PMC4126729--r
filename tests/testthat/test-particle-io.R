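test_that("particle files round-trip exactly", {
  cl <- generate_fingerprint(fingerprint_params(n_particles = 500, seed = 3))
  cl$tag <- rep(c(TRUE, FALSE), length.out = 500)
  path <- withr::local_tempfile(fileext = ".csv")
  write_particles(cl, path)
  back <- read_particles(path)
  expect_equal(back$x, cl$x, tolerance = 1e-9)
  expect_equal(back$y, cl$y, tolerance = 1e-9)
  expect_equal(back$model, cl$model)
  expect_equal(back$tag, cl$tag)
})

test_that("malformed particle files are rejected with useful errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x_mm,y_mm", "1,2", "3,4", "15,0"), path)
  expect_error(read_particles(path), "row 3")
  expect_warning(cl <- read_particles(path, strict = FALSE), "dropping")
  expect_equal(n_particles(cl), 2)
  writeLines(c("a,b", "1,2"), path)
  expect_error(read_particles(path), "missing column")
  writeLines("x_mm,y_mm", path)
  expect_error(read_particles(path), "empty")
})

test_that("rasterization sets one pixel per occupied cell", {
  cl <- particle_cloud(0, 0, diameter = 20)
  img <- rasterize(cl, 64)
  expect_equal(sum(img$grid), 1)
  expect_equal(img$grid[33, 33], 1L)  # y-flip: origin maps just below/right of center
  # two particles in the same cell leave one filled pixel
  cl2 <- particle_cloud(c(0.01, 0.02), c(0.01, 0.02), diameter = 20)
  expect_equal(sum(rasterize(cl2, 64)$grid), 1)
  # occupancy never exceeds particle count
  cl3 <- generate_fingerprint(fingerprint_params(n_particles = 300, seed = 2))
  expect_lte(sum(rasterize(cl3, 512)$grid), 300)
})

test_that("a dense uniform cloud fills every in-mask pixel", {
  # P(empty cell) = (1 - 1/n_cells)^n < 1e-6 at n = 1e5, 32x32
  cl <- uniform_cloud(1e5, seed = 8)
  img <- rasterize(cl, 32)
  mask <- abs(outer((1:32 - 0.5) * 20 / 32 - 10,
                    (1:32 - 0.5) * 20 / 32 - 10,
                    function(y, x) sqrt(x^2 + y^2))) <= 10
  expect_true(all(img$grid[mask] == 1L))
  expect_true(all(img$grid[!mask] == 0L))
})

test_that("rasterization commutes with integer-pixel translation", {
  cl <- generate_fingerprint(fingerprint_params(
    n_particles = 2000, seed = 4, vortex_weight = 1, stripe_weight = 0,
    background_weight = 0, vortex_spread = 0.05, vortex_balance = 1,
    vortex_centers = rbind(c(0.4, 0.5), c(0.6, 0.5))))
  res <- 64L; px <- cl$diameter / res
  shifted <- particle_cloud(cl$x + 3 * px, cl$y, diameter = cl$diameter)
  a <- rasterize(cl, res)$grid
  b <- rasterize(shifted, res)$grid
  # compare away from the mask edge
  expect_equal(b[20:45, 23:50], a[20:45, 20:47])
})

test_that("concentration maps average to 1 in-mask and honor point masses", {
  cl <- generate_fingerprint(fingerprint_params(n_particles = 4000, seed = 6))
  cm <- particle_concentration(cl, 64)
  mask <- outer((1:64 - 0.5) * 20 / 64 - 10, (1:64 - 0.5) * 20 / 64 - 10,
                function(y, x) sqrt(x^2 + y^2) <= 10)
  expect_lt(abs(mean(cm$grid[mask]) - 1), 1e-6)
  expect_true(all(cm$grid >= 0))
  # point mass: single occupied cell carries the whole ratio budget
  pm <- particle_concentration(particle_cloud(rep(0, 7), rep(0, 7)), 32)
  expect_equal(max(pm$grid), sum(disk_mask_cells <- {
    outer((1:32 - 0.5) * 20 / 32 - 10, (1:32 - 0.5) * 20 / 32 - 10,
          function(y, x) sqrt(x^2 + y^2) <= 10)
  }))
  expect_equal(sum(pm$grid > 0), 1)
})

test_that("uniform concentration ratios converge to 1 in the interior", {
  cl <- uniform_cloud(1e6, seed = 12)
  cm <- particle_concentration(cl, 16)
  cc <- (1:16 - 0.5) * 20 / 16 - 10
  rad <- outer(cc, cc, function(y, x) sqrt(x^2 + y^2))
  interior <- rad <= 10 - sqrt(2) * 20 / 16  # cells fully inside the disk
  expect_lt(max(abs(cm$grid[interior] - 1)), 0.1)
  # doubling n leaves the map unchanged in expectation
  cm2 <- particle_concentration(uniform_cloud(2e6, seed = 13), 16)
  expect_lt(mean(abs(cm$grid[interior] - cm2$grid[interior])), 0.05)
})

test_that("concentration maps are invariant to particle order", {
  cl <- generate_fingerprint(fingerprint_params(n_particles = 1000, seed = 1))
  perm <- withr::with_seed(99, sample(1000))
  cl2 <- particle_cloud(cl$x[perm], cl$y[perm], diameter = cl$diameter)
  expect_equal(particle_concentration(cl, 64)$grid,
               particle_concentration(cl2, 64)$grid)
})

test_that("difference maps are null on self and antisymmetric", {
  a <- particle_concentration(
    generate_fingerprint(fingerprint_params(n_particles = 2000, seed = 1)), 64)
  b <- particle_concentration(
    generate_fingerprint(fingerprint_params(n_particles = 2000, seed = 2)), 64)
  expect_true(all(difference_map(a, a)$grid == 0))
  expect_equal(difference_map(a, b)$grid, -difference_map(b, a)$grid)
  zero <- concentration_map(matrix(0, 64, 64), pixel_size = a$pixel_size,
                            mask_diameter = a$mask_diameter)
  expect_equal(difference_map(a, zero)$grid, a$grid)
  small <- particle_concentration(
    generate_fingerprint(fingerprint_params(n_particles = 100, seed = 1)), 32)
  expect_error(difference_map(a, small), "mismatch")
})

test_that("images survive PNG/TIFF round trips with sidecar metadata", {
  cl <- generate_fingerprint(fingerprint_params(n_particles = 2000, seed = 7))
  img <- rasterize(cl, 128)
  p1 <- withr::local_tempfile(fileext = ".png")
  write_raster_png(img, p1)
  back <- read_raster_png(p1)
  expect_equal(back$grid, img$grid)
  expect_equal(back$pixel_size, img$pixel_size)
  cm <- particle_concentration(cl, 128)
  p2 <- withr::local_tempfile(fileext = ".tiff")
  write_concentration_tiff(cm, p2)
  cback <- read_concentration_tiff(p2)
  expect_equal(cback$grid, cm$grid, tolerance = 2 * max(cm$grid) / 65535)
  expect_equal(cback$total_particles, 2000)
})
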