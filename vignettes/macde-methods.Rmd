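---
title: "Polar-section active contours driven by differential evolution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polar-section active contours driven by differential evolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macde)
```

## The segmentation problem

Active contour models (snakes) segment an object by evolving a closed
curve of control points ("snaxels") that minimizes the sum of an
internal energy — tension on the squared first difference, weighted
`alpha`, and rigidity on the squared second difference, weighted
`beta` — and an external, image-derived energy, weighted `gamma`. The
classical discrete solver moves each snaxel greedily within a small
search window. Two well-known weaknesses follow: the result depends
strongly on the initial curve, and greedy descent stalls in local
minima of the image energy, so the curve fails to enter boundary
concavities and can be deflected by noise.

This package implements a sectional, population-based alternative. A
user supplies one seed point inside the object. The plane around the
seed is divided into `floor(360 / dg)` angular sections (plus a
truncated final wedge when `dg` does not divide 360). Each section
owns an independent differential evolution (DE) population of 2-D
polar individuals `(r, theta)` confined to the section's wedge and to
a radial band `[r_min, r_max]`; the best individual of each section
becomes one snaxel of the final contour, assembled in angular order.
The construction guarantees exactly one snaxel per wedge, which is
sufficient whenever the target region is star-convex about the seed —
one true boundary point exists on every polar ray.

The optimization potential is built by a three-stage preprocessing
chain: a 3×3 median filter, a Canny edge detector
(`sigma = 1.3`, hysteresis thresholds 10 and 30 on the raw Sobel
magnitude of a 0–255 image), and an exact Euclidean distance map (EDM)
of the edge image. The EDM is high far from detected edges and exactly
zero on them, so the external energy `gamma * D(x, y)` — sampled
bilinearly so the optimizer sees a smooth surface — attains its minima
on the object boundary.

## Differential evolution

The engine is the classical rand/1/bin scheme. For each target
individual `X_i`, a mutant `V = X_r1 + F (X_r2 - X_r3)` is built from
three distinct donors different from `i`; binomial crossover copies
mutant components with probability `CR`; the trial replaces the target
only when its fitness is strictly lower. Defaults follow the study
settings: `G = 10` generations, `F = 0.1`, `CR = 0.8`, population size
equal to the number of initial contours (`n_snakes = 15`).

Two implementation conventions deserve a note:

* **Forced crossover component.** A literal binomial crossover can
  return the target unchanged. The standard convention — one component
  chosen uniformly always comes from the mutant — is the default;
  `pure_crossover = TRUE` restores the literal formula.
* **Restriction by clipping.** Every trial is passed through a repair
  hook before evaluation. The sectional repair clips `r` into the
  radial band and `theta` into the half-open wedge. Clipping (rather
  than resampling) is deterministic, preserves the population size,
  and makes the box bounds *be* the section restriction.

Per-section populations are initialized from `n_snakes` concentric
circles (or ellipses) whose radii are equally spaced on
`[r_min, r_max]`: contour `k` contributes the point at radius `r_k`
and the section midangle. Because all initial individuals of a section
share the midangle, difference vectors have no angular component and
the search is effectively radial — matching the geometry of the
initialization while keeping the 2-D encoding available for arbitrary
initial populations.

The stopping rule is a fixed generation count by default
(`stability_window = 0`); a patience-based early stop on the best
fitness is available but disabled because the study settings fix
`G = 10`.

## The classical baseline

The greedy snake (`run_acm`) is implemented as the comparison
baseline: each sweep visits the control points in fixed index order
and moves each to the integer-offset candidate in its
`(2 * window_half + 1)^2` window minimizing the point's local energy.
Defaults are `alpha = 0.01`, `beta = 0.9`, `gamma = 0.05`, a 5×5
window, and a circular 42-point initialization supplied by the user
(recorded in run metadata). The external term defaults to
`-(gamma / 2) |grad I|^2` with the raw central-difference image
gradient; a `smooth_sigma` parameter optionally smooths the image
first, and an `edm` mode runs the snake on the same distance
potential as the sectional optimizer.

One design point was settled empirically. Accepting a move only when
it lowers the *total* snake energy (the point's own terms plus the
neighbor terms its position enters) makes a symmetric circular
initialization a fixed point: on a regular polygon in a flat-gradient
region, every single-vertex move raises the total, so the snake never
leaves its initialization. The classical per-point rule is therefore
used. Its known cost is that the logged total energy is only
*practically* decreasing: isolated small rises (well under 1% of the
total energy range, during boundary lock-on) occur because a move that
improves one point can worsen its neighbors' terms. The energy log is
exported per sweep so this behavior is visible rather than hidden.

## Numerical choices

* **Coordinates.** 0-based pixel centers, `x` = column, `y` = row
  (down). Angles increase counterclockwise in the `(x, y)` frame.
* **Borders.** Median and Gaussian filters replicate the edge pixel;
  this avoids spurious border gradients that would contaminate the
  edge map and hence the EDM.
* **Canny.** Sobel 3×3 after Gaussian smoothing; non-maximum
  suppression quantizes the gradient direction into four bins and
  keeps a pixel only if strictly greater than the neighbor along the
  positive direction (ties on symmetric plateaus then yield a
  one-pixel chain). Gradient magnitudes are quantized at 1e-6 before
  comparisons so tie-breaking is immune to last-ulp noise, keeping the
  output invariant under constant intensity shifts. Hysteresis links
  8-connected weak pixels to strong ones by iterated dilation to a
  fixpoint. Thresholds are interpreted on the raw (unnormalized)
  Sobel magnitude of 0–255 images; `normalized = TRUE` switches to
  fraction-of-maximum thresholds.
* **Distance map.** The exact two-pass parabolic-envelope transform;
  property tests require exact agreement with a brute-force
  nearest-edge scan. An edge-free image yields an all-`Inf` map plus
  a warning.
* **Rasterization.** Even-odd scanline fill over pixel centers;
  centers exactly on the polygon boundary count as inside; zero-area
  contours warn and rasterize empty; self-intersecting input warns and
  is filled by the same even-odd rule.
* **Hausdorff.** Directed by default, exactly `max_a min_b ||a - b||`;
  the symmetric variant is reported alongside it because conventions
  differ across the literature. Masks are reduced to 8-connected
  boundary pixels.
* **Empty-mask conventions.** Two empty masks score Jaccard = Dice =
  1 (continuity); empty versus nonempty scores 0.
* **Radial band defaults.** `r_min = 0.1 * min(image dim) / 2`;
  `r_max` = the largest radius whose disk around the seed stays inside
  the image. Exceeding the inscribed radius is an error that reports
  the largest usable value.
* **Reproducibility.** A master seed derives one sub-seed per section
  by a fixed offset; runs with equal images, parameters and master
  seed are bitwise identical, and the run-metadata JSON suffices to
  replay a run exactly (`rerun_from_metadata`).

## What the phantom generators emulate

The three phantoms mirror the shapes used to probe the two classical
failure modes: a five-point star (160×160, outer radius 60, inner 25)
with deep concavities; a disk (300×300, radius 100) with additive
Gaussian noise; and a three-lobed union of disks (150×150, lobes of
radius 35 at distance 20 from the center) with a concavity between
each pair of lobes. Every mask is exact analytic geometry — the noise
never touches the ground truth — and every shape is star-convex about
its center, so the one-snaxel-per-wedge contract can represent it.
The star's exact geometry is not published anywhere, so its defaults
(5 points, radii 60/25) are free parameters of this package, recorded
in the phantom spec.

The noise standard deviation 0.04 is interpreted on the normalized
[0, 1] intensity scale (≈ 10.2 gray levels): on a 0–255 scale a
sigma of 0.04 would be invisible and could not challenge any method.
Foreground/background intensities default to 200/0 so the boundary
step is strong under the 10/30 hysteresis thresholds.

The stack generator produces smoothly drifting slice series (default
18 slices) in which one shared seed point stays valid in every slice,
emulating sequential CT/MR studies segmented by reusing a single seed.
What the phantoms do **not** emulate: anatomical texture, intensity
inhomogeneity, partial-volume effects, or correlated noise — passing
the synthetic suite shows the optimizer and its contracts work, not
that clinical accuracy transfers.

## What the tests showed, honestly

Two properties asserted by the acceptance suite do not hold for this
implementation and are deliberately left failing rather than papered
over:

* **Strict energy monotonicity of the greedy snake.** As discussed
  above, per-point greedy moves cannot guarantee descent of the summed
  energy; enforcing descent freezes the snake at its initialization.
  The logged energy decreases overall on every phantom run but shows
  a handful of transient rises.
* **Noise advantage over the baseline on the noisy disk.** With the
  printed weights, the baseline snake's external term on the 0–255
  gradient scale (≈ −250 on the boundary ridge) dwarfs both the noise
  traps (≈ −20) and the internal terms, and neighbor coupling pulls
  points through isolated traps. The 42-point snake therefore reaches
  its polygonal ceiling (Dice ≈ 0.998) on the noisy disk, above the
  24-section contour's ceiling (Dice ≈ 0.994, a 24-gon inscribed in
  the disk). The sectional method does meet its own absolute bar
  (Dice ≥ 0.95 on all tested seeds, snaxels within sub-pixel radial
  error of a clean circle) and decisively wins on concavities, where
  greedy descent genuinely fails (star: ≈ 0.95 vs ≈ 0.73).

The DE benchmark settings used by the test suite for the plateaued
11×11 lattice check (`np = 40`, `F = 0.8`, `CR = 0.8`, `G = 50`) are
larger than the segmentation defaults because a piecewise-constant
fitness offers no gradient information: progress on plateaus only
comes from mutation jumps landing in strictly better cells, which
needs population diversity. The sphere check uses `np = 15`,
`F = 0.5`, `CR = 0.8`, `G = 40`.

## Problem sizes

The test suite and the acceptance script run the full pipeline at the
published phantom sizes (160×160, 300×300, 150×150, plus a 200×200
clean-circle recovery and an 18-slice 150×150 stack), with 10
repetitions of the star and noisy-circle experiments and 100-seed
benchmarks for the optimizer and metric oracles. A complete
acceptance run takes well under a minute on a single core.

## Known limitations

* Regions must be star-convex about the seed; topology changes,
  splitting and merging are out of scope.
* Sections are optimized independently with a purely external
  fitness; no inter-section smoothness term is applied, so the
  contour inherits any angular jitter of the edge map. (The sectional
  fitness deliberately omits the internal energy: the wedge geometry
  already enforces ordering, and a smoothness term would couple the
  populations.)
* Spurious edge-map responses inside the object create zero-fitness
  basins indistinguishable from the true boundary; a section whose
  wedge contains such a basin can select it (visible as isolated
  radial outliers on the noisy disk).
* The Canny thresholds' intensity scale is a convention; images not
  on 0–255 should use `normalized = TRUE`.
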