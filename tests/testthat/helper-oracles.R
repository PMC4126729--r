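# Brute-force reference implementations used as independent oracles.
# These deliberately use the most naive algorithm available and never call
# back into the package's optimized paths.

# double-loop box counter, grid anchored at the top-left corner
brute_box_count <- function(grid, eps) {
  h <- nrow(grid); w <- ncol(grid)
  n <- 0L
  for (i0 in seq(1L, h, by = eps)) {
    for (j0 in seq(1L, w, by = eps)) {
      blk <- grid[i0:min(i0 + eps - 1L, h), j0:min(j0 + eps - 1L, w)]
      if (any(blk == 1L)) n <- n + 1L
    }
  }
  n
}

# naive sliding-window sums over the full (unmasked) frame
brute_window_sums <- function(grid, eps, stride = 1L) {
  h <- nrow(grid); w <- ncol(grid)
  out <- c()
  for (i in seq(1L, h - eps + 1L, by = stride))
    for (j in seq(1L, w - eps + 1L, by = stride))
      out <- c(out, sum(grid[i:(i + eps - 1L), j:(j + eps - 1L)]))
  out
}

# naive block masses (top-left anchored, partial edge blocks kept)
brute_block_masses <- function(grid, eps) {
  h <- nrow(grid); w <- ncol(grid)
  out <- c()
  for (i0 in seq(1L, h, by = eps))
    for (j0 in seq(1L, w, by = eps))
      out <- c(out, sum(grid[i0:min(i0 + eps - 1L, h),
                             j0:min(j0 + eps - 1L, w)]))
  out <- out[out > 0]
  out / sum(out)
}

# all distinct multiset permutations of a label vector (small N only)
label_arrangements <- function(labels) {
  labels <- sort(labels)
  recurse <- function(lab) {
    if (length(lab) == 1L) return(list(lab))
    out <- list()
    for (u in unique(lab)) {
      rest <- lab[-match(u, lab)]
      out <- c(out, lapply(recurse(rest), function(r) c(u, r)))
    }
    out
  }
  recurse(labels)
}

# exact Kruskal-Wallis permutation p via kruskal.test on every distinct
# relabeling (independent of the package's partition enumeration)
brute_kw_exact_p <- function(values, groups) {
  h_obs <- unname(stats::kruskal.test(values, factor(groups))$statistic)
  arr <- label_arrangements(as.character(groups))
  hs <- vapply(arr, function(g)
    unname(stats::kruskal.test(values, factor(g))$statistic), numeric(1))
  mean(hs >= h_obs - 1e-12)
}

# closed-form multifractal quantities of the 4-weight dyadic cascade
cascade_dq <- function(w, q) {
  if (abs(q - 1) < 1e-9) -sum(w * log2(w)) else log2(sum(w^q)) / (1 - q)
}
cascade_alpha <- function(w, q) -sum(w^q * log2(w)) / sum(w^q)

# uniform cloud over the disk (background-only mixture)
uniform_cloud <- function(n, seed, diameter = 20) {
  generate_fingerprint(fingerprint_params(
    n_particles = n, diameter = diameter, seed = seed,
    vortex_weight = 0, stripe_weight = 0, background_weight = 1))
}

# tight single-cluster cloud (one narrow vortex, no swirl)
clustered_cloud <- function(n, seed, diameter = 20) {
  generate_fingerprint(fingerprint_params(
    n_particles = n, diameter = diameter, seed = seed,
    vortex_weight = 1, stripe_weight = 0, background_weight = 0,
    vortex_balance = 1, vortex_spread = 0.04, swirl = 0))
}

# cloud of uniform background plus one planted Gaussian hotspot
hotspot_cloud <- function(n, seed, center = c(0.2, 0.65), weight = 0.2,
                          spread = 0.02) {
  generate_fingerprint(fingerprint_params(
    n_particles = n, seed = seed, vortex_weight = 0, stripe_weight = 0,
    background_weight = 1 - weight,
    hotspot_spec = list(center = center, spread = spread, weight = weight)))
}

# polar truth for a normalized hotspot center on the default 20 mm disk
hotspot_truth <- function(center = c(0.2, 0.65), diameter = 20) {
  ctr <- (center - 0.5) * diameter
  c(horizontal = center[1L], vertical = center[2L],
    radial = sqrt(sum(ctr^2)) / (diameter / 2),
    circumferential = (atan2(ctr[2L], ctr[1L]) * 180 / pi) %% 360)
}
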