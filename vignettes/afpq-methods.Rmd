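---
title: "Methods: fractal, lacunarity and multifractal quantification of exhaled-aerosol fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractal, lacunarity and multifractal quantification of exhaled-aerosol fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afpq)
```

## The measurement problem

An exhaled-aerosol breath test records, on the circular mouth-exit plane,
the 2-D positions of tracer particles that were inhaled, carried through
the airway tree, and exhaled. The resulting pattern — the aerosol
fingerprint (AFP) — is shaped by the airway geometry: obstructions and
constrictions divert the expiratory flow and leave voids, blurred
vortices and shifted accumulation spots in the exhaled pattern. `afpq`
quantifies such patterns so that different airway conditions, and grades
of one condition, can be told apart numerically rather than by eye.

The package deliberately stops at *feature extraction*. It does not model
airflow, does not reconstruct airway geometry, and does not classify; its
output is a fixed-order feature vector per image plus replicate statistics
and rank-based comparisons, suitable as input to any downstream
classifier.

## Data model and conventions

A `particle_cloud` is a set of (x, y) positions in mm on a closed disk of
diameter `D` (default 20 mm — the physical mouth-exit diameter is not
standardized, so it is a configurable convention, not a measurement).
The origin is the disk center, x points right, y points up. Rasters put
grid row 1 at the top of the image, so the y axis is flipped relative to
row index; pixel bins are half-open (left/top edge included), and
particles exactly on the disk boundary are kept (closed disk) and clamped
into their edge pixel.

Binary occupancy images mark a pixel 1 when at least one particle center
falls in it. Relative-concentration maps divide each cell's particle
concentration by the overall in-disk concentration, so the in-mask mean
ratio is exactly 1 by construction; normalization uses the in-mask count
so that the handful of boundary particles falling in pixels whose center
lies just outside the disk cannot bias it. The default raster is
512 × 512, which leaves at least five dyadic scales below a quarter of
the image side for the scaling regressions.

## Box-counting fractal dimension

For box sizes $\varepsilon$, $N_\varepsilon$ counts the grid boxes
containing at least one filled in-mask pixel, and

$$D_B = -\,\mathrm{slope}\left[\log N_\varepsilon \sim \log \varepsilon\right]$$

by unweighted ordinary least squares in natural logs. Choices that the
literature leaves open, fixed here:

* **Scale series.** Dyadic, $\varepsilon = 2, 4, \dots \le \min(H,W)/4$;
  if that leaves fewer than five scales the series extends to
  $\min(H,W)/2$. The regression refuses to run on fewer than five scales.
* **Grid placement.** $N_\varepsilon$ is the minimum over the four
  corner-anchored grid offsets, a standard placement-bias reduction; a
  single top-left anchoring is available for oracle comparisons.
* **Fit quality.** $R^2$ is always reported; a straight power law gives
  $R^2 = 1$ to machine precision, and poor scaling is visible rather than
  silent.
* **Degenerate inputs.** An empty image is an error; a series with all
  counts equal (e.g. a single filled pixel) is a degenerate regression
  and is refused rather than reported as 0.

Regions of interest are rectangular pixel ranges (half-open, x from the
left, y from the top); the ROI dimension is by definition the whole-image
dimension of the crop, analyzed unmasked. Local structure is mapped on a
6 × 6 tile grid (normalized caliber 1/6 × 1/6); tiles with fewer than two
filled pixels are reported as `NA`, never 0, so ratio maps
$\beta(i) = FD(i)/FD(\mathrm{baseline}\ i)$ are not corrupted by empty
tiles.

## Sliding-box lacunarity

For each box size, an $\varepsilon$-window slides with stride 1 and the
filled-pixel count of every position is collected;

$$\lambda(\varepsilon) = \left(\sigma_\varepsilon/\mu_\varepsilon\right)^2,
\qquad \Lambda = \frac{1}{E} \sum_{\varepsilon} \lambda(\varepsilon),$$

with the population standard deviation. The $(\sigma/\mu)^2$ convention
(rather than $1 + (\sigma/\mu)^2$) is used; every comparative statement
is invariant to this monotone shift. Homogeneous patterns at the probed
scale — an all-filled frame, a checkerboard probed at its period — give
$\lambda = 0$ exactly. For circular masks, windows are restricted to the
disk's inscribed square: windows straddling the mask boundary would
register the mask itself as heterogeneity. Box sizes default to the
fractal module's dyadic series (capped to the inscribed square) so the
two measures describe the same scales. Strides larger than 1 subsample
window positions; they are offered for speed with the caveat that the
variance estimate then rests on fewer, non-overlapping-by-chance windows.

## Direct-method multifractal spectrum

Concentration maps are partitioned into $\varepsilon$-boxes with masses
$P_i(\varepsilon)$ (normalized to 1 per scale, empty boxes dropped,
partial edge boxes kept). For each exponent $q$ the normalized measure

$$\mu_i(q,\varepsilon) = \frac{P_i^q}{\sum_j P_j^q}$$

is computed in the log domain (a log-sum-exp accumulation), so $|q|$ up
to the default grid bound of 5 — and far beyond — cannot overflow. The
singularity strength and spectrum follow from scaling regressions over
the dyadic scale series:

$$\alpha(q) = \frac{d\,\sum_i \mu_i \log P_i}{d \log \varepsilon}, \qquad
  f(q) = \frac{d\,\sum_i \mu_i \log \mu_i}{d \log \varepsilon},$$

and the generalized dimensions from
$D_q = \frac{1}{q-1}\frac{d \log \sum_i P_i^q}{d\log\varepsilon}$, with
the information-dimension limit $D_1 = \alpha(1)$ used inside a
$|q-1| < 10^{-9}$ window. The direct (normalized-measure) estimator is
used rather than a Legendre transform of $\tau(q)$ because it is
numerically stable and returns $f$ at the same $q$ grid. The default grid
is $q \in [-5, 5]$ in steps of 0.25. Per-$q$ $R^2$ of the $D_q$
regression is reported, with a consolidated warning (not an error) when
any $R^2 < 0.9$. A measure concentrated in a single box at every scale is
reported as a flagged point spectrum ($D_q \equiv 0$, widths 0, asymmetry
`NA`).

On the closed-form reference — the four-weight dyadic multiplicative
cascade, for which $D_q = \log_2 \sum_i w_i^q/(1-q)$ and
$\alpha(q) = -\sum_i w_i^q \log_2 w_i / \sum_i w_i^q$ — the estimators
reproduce the analytic values to machine precision at every probed $q$,
because the cascade scales exactly at the dyadic box sizes. The test
suite asserts this at depth 8 (256 × 256), together with the tangency
invariants $\max_q f = D_0$ and $f(\alpha(1)) = \alpha(1) = D_1$ and the
monotone decrease of $D_q$ and $\alpha(q)$.

**Sampled point data and the $q<0$ branch.** On concentration maps binned
from finitely many particles, boxes holding a single particle have the
same mass at every scale; their scale-constant mass drags $\alpha(q)$ for
negative $q$ toward 0 and can invert the $D_0 \ge D_1 \ge D_2$ ordering.
This is a property of the estimator on under-sampled measures, not a
defect of a particular pattern: spectrum-shape comparisons between
patterns are only meaningful at matched particle count and matched
scales, and the monotonicity invariants are asserted on measures with
true scaling (cascades, uniform fields). This is also why the severity
study below fixes a large particle count.

## Directional probability profiles

Clouds are scanned in four directions — horizontal $x/X$, vertical $z/Z$
(both mapping the disk's bounding square to $[0,1]$), radial $r/R$, and
circumferential $\theta \in [0^\circ, 360^\circ)$ counterclockwise from
+x — with 50 equal-width bins by default. Bin counts are divided by the
total particle count and by the bin's physical in-disk area in mm²
(computed analytically from circle-strip, annulus and sector geometry,
never by pixel counting), yielding a density in %/mm² whose area-weighted
sum is exactly 100. Edge strips whose in-disk area falls below 1% of the
mean bin area would blow the density up and are merged inward; at the
default 50 bins no merging triggers (the thinnest strip still holds about
24% of the mean area). Spike detection smooths the density with a 3-bin
moving average (circular in $\theta$) and reports local maxima reaching a
prominence multiple (default 2, conservative and user-tunable) of the
disk-mean density $100/(\pi R^2)$. A hot spot found in two orthogonal
scans triangulates a 2-D position; the tests assert that the (x, z) and
(r, θ) pairs agree within one bin diagonal on planted hot spots.

The vertical coordinate is named z in scan output for continuity with the
breath-test literature, and is oriented upward; this orientation is a
declared convention.

## Replicate statistics and comparison

Metrics are aggregated over replicate breath tests (default n = 5) as
mean ± sample SD. Cross-model comparison uses the Kruskal–Wallis rank
test with average ranks and the standard tie-correction divisor, as
provided by `stats::kruskal.test()`. Because the typical design (4–5
replicates per model) sits near the edge of validity of the chi-squared
approximation, an exact permutation p value is computed automatically
whenever the pooled sample size is at most 12, by enumerating all
partitions of the pooled ranks into the observed group sizes; the exact p
drives the significance stars (\* for p < 0.05, \*\* for p < 0.01). No
multiple-testing correction is applied across metrics — the comparison
report says so, and users can apply their own.

The feature vector has 26 fixed slots (whole-image and ROI $D_B$ and
$\Lambda$; $\Delta\alpha$, $\Delta f$, asymmetry, $D_0, D_1, D_2$; and
per-direction profile mean, variance, spike count and first spike
location). Missing metrics stay `NA` in place so feature matrices align
across runs.

## The synthetic fingerprint generator

No public deposit of breath-test fingerprints exists, so the package
generates its own test inputs. `generate_fingerprint()` samples a
truncated Gaussian mixture on the disk: two vortex accumulations (with an
angular swirl displacement that decays away from each center), a central
vertical stripe, a uniform background, and optionally a Gaussian hot
spot. Disease perturbations are a crescent void — an annular sector in
which particles are thinned with a depletion probability — and the hot
spot, which is exempt from void thinning because an accumulation spot is
a flow-diversion feature that coexists with the adjacent void. Rejection
sampling guarantees exactly `n_particles` inside the disk, and every draw
is a pure function of the parameters and seed (replicate k of a cohort
uses seed base + k). Four canned templates emulate one healthy and three
diseased patterns: "A" (well-defined vortex pair plus stripe), "B"
(left vortex nearly vanished, blurred), "C" (left vortex weakened and
displaced), "D" ("A" plus upper-left crescent void and a hot spot at
normalized (0.2, 0.65)).

What the generator does **not** emulate: any actual fluid mechanics, the
correlation structure a real expiratory flow imprints on particle
positions, particle-size dependence, or inter-subject geometry
variability. Passing tests therefore demonstrate that the estimators
recover planted structure and analytic dimensions — not that any
particular clinical effect size is realistic.

Analytic fixtures close the loop: the Sierpinski carpet (dimension
$\log 8/\log 3$, filled-pixel count $8^{\mathrm{levels}}$) for the
box-counting estimator, and the dyadic cascade for the multifractal
estimators.

## The severity study

`severity_study()` applies a graded series D0–D3 to the healthy template:
each level's first constriction fraction becomes the void's depletion
(0, 0.30, 0.60, 0.90 by default, zero at D0 and strictly increasing) and
its second fraction widens the void's angular extent. All levels share
the seed, so D0 reproduces the base cloud exactly and in-void particle
counts fall monotonically in expectation.

The study conditions are fixed at one million particles per cloud, a
1024 px occupancy raster for the fractal dimensions, and 512 px
concentration maps with scales 8–48 px for the ROI spectrum (the ROI is
the upper-left region covering the void). These sizes follow from the
sampling analysis above: at sparse counts the thinned void fills with
single-particle boxes whose artifactual $q<0$ exponents *widen* the
spectrum, whereas the sampling-adequate measure shows the genuine effect
of severity — the thinned region's low-density tail leaves the measure,
and the realized $\Delta\alpha$ narrows; likewise a 512 px raster is
nearly saturated at $10^6$ particles, compressing the entire-image $D_B$
differences that the 1024 px raster resolves. Under these conditions the
test suite asserts that mean entire-image $D_B$, ROI $D_B$ and ROI
$\Delta\alpha$ all trend monotonically (downward) from D0 to D3 across
five seeds.

## Problem sizes and runtime envelope

The shipped tests and the acceptance script use: carpet level 5
(243 × 243), cascade depth 8 (256 × 256), cohort clouds of 3 000–40 000
particles for distributional checks, $10^6$ particles for the profile
flatness/hot-spot and severity studies, and pooled N ≤ 12 for exact
permutation enumeration. These sizes were chosen as the smallest at which
each property is comfortably resolved; all of them run on a single CPU
core in a few minutes total.

## Known limitations

* Binary box counting is reported for occupancy images only; grayscale
  images are handled by the multifractal module (no mass/differential
  box counting for the monofractal estimate).
* Lacunarity is binary and orientation-agnostic; no grayscale or
  directional variants.
* The profile module bins densities; it performs no kernel density
  estimation and no continuous circular statistics.
* The exact permutation test enumerates partitions and is restricted to
  pooled N ≤ 12 (about 370 000 partitions at 4 × 3); larger designs fall
  back to the chi-squared approximation.
* Point-sampled multifractal spectra are biased at $q < 0$ when boxes are
  under-filled (see above); compare spectra only at matched sampling.
* The generator's disease templates are qualitative emulations; no
  physiological fidelity is claimed beyond the planted pattern features.
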