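# afpq — quantification of exhaled-aerosol fingerprint patterns

Exhaled tracer aerosols collect on the mouth-exit plane into a spatial
pattern — an *aerosol fingerprint* (AFP) — that carries an imprint of the
airway structure the particles travelled through. Obstructions, tumors and
asthmatic constrictions distort the exhaled flow and leave characteristic
marks in the fingerprint: vanished vortices, crescent-shaped voids, shifted
accumulation hot spots. `afpq` turns such fingerprints, supplied as 2-D
particle position files or raster images, into quantitative feature sets
that can be compared across subjects, disease models and severities.

The package is aimed at researchers working on aerosol-based breath tests
and, more generally, at anyone who needs box-counting fractal, lacunarity
and multifractal measurements of planar point patterns or grayscale
density maps with validated, oracle-tested estimators.

## What it computes

For a binary occupancy image of the fingerprint (and optional regions of
interest):

- **Box-counting fractal dimension** `D_B`: the magnitude of the slope of
  the regression of `log N(ε)` on `log ε`, where `N(ε)` is the number of
  `ε`-boxes containing filled pixels (minimum over four corner-anchored
  grid offsets). Whole-image, ROI, and tiled 6×6 local grids with ratio
  maps `β(i) = FD(i)/FD(baseline)` are supported.
- **Sliding-box lacunarity**: `λ(ε) = (σ/μ)²` of the filled-pixel counts
  in sliding `ε`-boxes, aggregated as `Λ = (1/E) Σ_ε λ(ε)`. Lacunarity
  measures heterogeneity ("gappiness") and separates patterns that share a
  fractal dimension but fill space differently.

For a grayscale relative-concentration map (local concentration / overall
concentration, in-disk mean 1):

- **Direct-method multifractal spectrum**: normalized measures
  `μ_i(q,ε) = P_i^q / Σ_j P_j^q`, singularity strength
  `α(q) = d⟨Σ μ_i log P_i⟩ / d log ε`, spectrum
  `f(q) = d⟨Σ μ_i log μ_i⟩ / d log ε`, and generalized dimensions
  `D_q = [d log Σ P_i^q / d log ε]/(q−1)` (information-dimension limit at
  `q = 1`). Spectrum shape summaries: `Δα`, `Δf`, asymmetry, `D0, D1, D2`.

For the particle cloud itself:

- **Directional probability profiles** in four scan directions
  (horizontal `x/X`, vertical `z/Z`, radial `r/R`, circumferential `θ`),
  each binned into 50 bins and normalized by particle count and analytic
  in-disk bin area to %/mm², plus spike detection that localizes hot spots
  by cross-direction triangulation.
- **Concentration-disparity maps** (signed difference against a healthy
  baseline), **replicate statistics** (mean ± SD over breath tests), and
  **Kruskal–Wallis** comparison across models with an exact permutation p
  value for small samples; all metrics assemble into a fixed-order
  26-slot feature vector for downstream classification.

Because no public deposit of measured fingerprints exists, the package
ships a seeded synthetic generator (`generate_fingerprint()`,
`generate_severity_series()`) emulating the qualitative AFP template —
vortex pair, central stripe, asymmetry, disease voids and hot spots — and
analytic fixtures with known dimensions (`generate_sierpinski_carpet()`,
`generate_cascade()`) against which every estimator is validated.

## Worked example

```r
library(afpq)

# a healthy and an asthma-like fingerprint, 20k particles each
healthy <- generate_fingerprint(fingerprint_template("A", seed = 1))
asthma  <- generate_fingerprint(fingerprint_template("D", seed = 1))

img <- rasterize(asthma, 512)
fd_entire(img)
#> fractal_fit: D_B = 1.6676 (R^2 = 0.9892, 7 scales in [2, 128])

lacunarity_series(img)
#> lacunarity_series: Lambda = 1.0772 over E = 6 box sizes [2..64]

cm <- particle_concentration(asthma, 512)
spectrum_summary(mf_spectrum(cm, quiet = TRUE))
#> spectrum_summary: alpha width 0.8481, f width 1.4602, asymmetry -0.5008,
#>   D0 1.6676, D1 1.7410, D2 1.7201

# where is the hot spot?
find_spikes(directional_profile(asthma, "horizontal"), prominence = 1.5)
#>    direction bin coord   density
#> 1 horizontal  10  0.19 0.5780091
#> 2 horizontal  26  0.51 0.5714913
find_spikes(directional_profile(asthma, "vertical"), prominence = 1.5)
#>   direction bin coord   density
#> 2  vertical  33  0.65 0.8089068
#> 1  vertical  27  0.53 0.5750983
```

`fd_entire()` reports the image's box-counting dimension with the fit's
R²: values near 2 mean a nearly space-filling pattern, and the asthma-like
void lowers `D_B` relative to the healthy template. `Lambda` grows with
clumpiness. `alpha width` (Δα) measures multifractality: 0 for a uniform
measure, wider for more heterogeneous concentration fields. (At this
particle count D1/D2 sit slightly above D0 — finite-sampling bias of the
direct estimator on point data; the methods vignette discusses when the
monotone ordering is recovered.) The spike reports triangulate the
diseased template's hot spot: the horizontal scan peaks at x/X ≈ 0.19 and
the vertical scan at z/Z ≈ 0.65, jointly pointing at the planted
accumulation at normalized (0.2, 0.65); the secondary ≈0.5 spikes are the
central stripe.

A full cohort analysis (4 models × 5 replicates → features, replicate
summaries, Kruskal–Wallis comparisons) is one call:

```r
res <- run_pipeline(analysis_config(out_dir = "afpq_out"))
res$comparisons$fd_entire
```

A command-line interface over the same functions is installed at
`inst/cli/afpq.R` (subcommands `simulate`, `rasterize`, `concmap`,
`diffmap`, `fractal`, `lacunarity`, `multifractal`, `scan`, `compare`,
`pipeline`).

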