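---
title: "Measuring tree structural complexity: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tree structural complexity: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: what each
stage computes, which knobs matter, what the synthetic generator does
and does not emulate, and where design choices were genuinely open.

```{r setup, message = FALSE}
library(treecomplexity)
```

## The box-counting dimension

The central statistic treats a tree's TLS point cloud as a geometric
set and asks how its occupied volume scales. An initial cube of edge
`s0` = tree height (the maximum normalized point height) is placed with
its base at the ground and horizontally centered on the cloud's xy
centroid. The edge is then divided by 2 per level (the default eight
levels run `s0 … s0/128`; a base-3 schedule is available for fixtures
built on powers of three), occupied boxes `N(s)` are counted on a fixed
axis-aligned grid anchored at the initial box's minimum corner, and the
box dimension is the OLS slope of `ln N` against `ln(s0/s)`.

Numerical conventions, fixed for reproducibility:

* **Grid anchoring.** Boxes at every level belong to one grid anchored
  at the initial box's minimum corner; counts are therefore
  deterministic and checkable against a brute-force cell enumerator.
* **Scale invariance.** Counting works on coordinates normalized to the
  initial box, rounded at 1e-12 relative precision, so uniformly
  rescaling a cloud changes neither slope, intercept, nor R².
  Points lying exactly on the top faces are clamped into the last cell,
  making `N(s0) = 1` exact.
* **Fit.** Unweighted OLS over all levels including `k = 0` (where both
  logarithms are zero); `drop_first = TRUE` removes that level.
* **Occupancy.** Any non-ground point counts, stem and crown alike;
  ground-labeled points are excluded.
* **Overflow.** If a cloud is wider than tall, the initial edge grows to
  the horizontal extent and the expansion is flagged (`expanded`) —
  with the default pine-like geometry this does not occur.
* **Degenerate input.** A cloud with fewer than two distinct points
  reports slope 0 with undefined R².
* **No absolute floor on the box edge.** The schedule runs to `s0/128`
  regardless of the metric size of the smallest box; an optional
  `min_edge` floor exists for sensitivity analyses but is off by
  default.

Reference objects with known dimension validate the implementation: a
pole (1), a vertical plane (2), a solid cube (3), and Menger sponges
(ln 20 / ln 3 ≈ 2.727). Two sampling details deserve a note. The pole
fixture's axis carries a gentle 1% sweep: a perfectly straight,
radially symmetric pole has its axis exactly on a corner of the
counting grid at every level (the centroid centering guarantees this
degeneracy), which quadruples every count and biases the fitted slope
upward; the sweep restores the generic position that any real object
occupies. The Menger fixtures pin the two extreme cube corners so the
initial box aligns exactly with the construction, making base-3 counts
exactly `20^k`.

```{r menger}
bd <- box_dimension(make_primitive("menger", level = 3, seed = 1),
                    n_levels = 4, schedule = "base3")
bd$levels
bd$slope - log(20) / log(3)
```

For the dyadic (default) schedule the finite recursion depth of a
sampled sponge truncates self-similarity below the smallest retained
subcube, so the slope is checked on a level-4 sponge against the
rounded literature value 2.72 with a wider (±0.1) band.

## Topography removal

Ground is modeled per square grid cell (default 1 m) from the cell's
lowest point. Each populated cell carries a plane anchored exactly at
that minimum point, with slopes estimated by least squares through the
minima of the 3×3 neighborhood (capped at gradient 2 m/m; degenerate
neighborhoods fall back to a flat plane). Unpopulated cells inherit the
nearest populated cell's plane. Anchoring at the minimum has two exact
consequences: an inclined plane is reproduced without the half-cell
bias of a piecewise-constant minimum filter, and normalization is
idempotent — after one pass every cell's lowest point sits at height
zero, so a second pass subtracts a zero surface. Points ending below
0.1 m after normalization are labeled ground. Clouds whose planar
extent is smaller than one cell fall back to global min-z subtraction
with a warning. The surface is piecewise planar and discontinuous at
cell borders; for tree-scale heights this is irrelevant, but the model
is not meant as a general-purpose DTM.

## Tree isolation

The canopy height model takes the per-cell maximum height at 0.20 m
resolution. Tree tops are cells not exceeded within a height-dependent
circular window, `radius = max(0.5, 0.05·h)` by default — the window
coefficients and the single 3×3 median smoothing pass (on by default,
`smooth = FALSE` to disable) are explicit knobs, not claims of fidelity
to any particular parameterization. Ties keep the smaller (row, col)
cell, so a flat canopy yields exactly one top. Crown segments come from
watershed by immersion: canopy cells (≥ 5 m, the `min_tree_height`
default chosen to exclude understory returns) are processed in
decreasing height order and attached to the segment of their highest
already-labeled 8-neighbor, starting from the tops. Points are assigned
by exact half-open cell membership — equivalent to point-in-polygon
against the segment's cell-union boundary but unambiguous on
boundaries; the exported GeoJSON outlines are convex hulls of the cell
corners, for display only.

## Stem classification and taper

Stem points are found bottom-up in 0.5-m height bins: an algebraic
(Kåsa) circle fit with one Tukey-biweight reweighting pass per bin,
candidates restricted to a disc around the tracked center, inliers
within a ±2.5 cm radial band (about eight times the generator's stem
surface noise — wide enough for real ranging noise, narrow enough to
reject branch points running close to the stem). The track stops when
the inlier fraction collapses (< 0.25), the radius jumps more than 50%,
or the center moves implausibly; remaining points are crown. Trees with
no points below 2 m are flagged as classification failures and treated
as all-crown.

The taper curve interpolates the per-bin (height, radius) knots with a
natural cubic spline after dropping outlier knots: those whose radius
jumps more than 30% against the previous surviving knot, and those
whose radius *rises* beyond noise level (5% + 2 mm) — a conifer stem
tapers monotonically above the butt, so an upward jump inside the crown
marks branch contamination of the circle fit. Above the last knot the radius
decreases linearly to zero at the tree top; below the first knot it
extends linearly from the first two knots. DBH is twice the curve's
radius at exactly 1.30 m and is reported missing when the curve starts
more than half a bin above breast height. Stem volume sums 10-cm
cylindrical slices over the curve; halving the slice height changes the
result by well under 1%.

Crown metrics use convex hulls of the crown-labeled points: width is
the maximal pairwise horizontal distance (computed on the 2D hull
vertices), projection area the 2D hull area, volume and surface area
the 3D hull. The 3D hull is a small compiled incremental algorithm with
a distance-based visibility tolerance (10⁻⁹ of the extent) and a
deterministic insertion shuffle; points whose insertion would produce a
numerically inconsistent horizon lie on the hull boundary within
tolerance and are skipped. Degenerate sets (collinear, coplanar) yield
missing values with a reason string rather than errors. The
benefit-to-cost ratio divides crown surface area (m²) by stem volume
(m³); the per-tree table keeps stem volume in dm³ to match forestry
convention, and the conversion happens inside the ratio.

The growth module differences the two field-inventory occasions. The
ratio ΔH/DBH divides height growth by the *last-occasion* DBH by
default; the denominator is genuinely ambiguous in common usage, so
`dhdbh_denominator` exposes `"first"` and `"growth"` as alternatives.

## Competition

Hegyi's index sums `(DBH_j / DBH_i) / dist_ij` over competitors
strictly within 5 m, in the standard orientation (larger neighbors
compete harder); the printed sources sometimes typeset the ratio
ambiguously, so `form = "inverted"` exposes the other reading.
Distances are between stem positions in the xy plane. No edge
correction is applied; trees nearer the plot boundary than the search
radius are flagged instead (`edge`), leaving the choice to the analyst.

## The synthetic generator

The generator exists so that every downstream stage can be tested
against known truth. A tree is a stem of power-law taper
`r(h) = r0 (1 − h/H)^e` (default `e = 1`, a cone, calibrated so the
diameter at 1.3 m equals the nominal DBH) plus a conical crown envelope
from the crown base (55% of height on average) to the tip, populated by
branch whorls every 0.4 m with six branches each, azimuths rotated by
the golden angle per whorl. Stem surfaces carry 3 mm radial noise,
crowns 2 cm jitter. Ground-truth stem attributes follow in closed form;
crown truth comes from the designed branch-tip geometry.

A stand draws surviving trees from per-treatment truncated-normal
DBH/height distributions (survivor means 18.7/22.2/26.4 cm and
densities 1,337/716/289 stems·ha⁻¹ for none/moderate/intensive,
matching the study conditions the package targets), places them by a
hard-core process with 1.5 m minimum spacing (managed even-aged stands
are regular, not Poisson), and back-dates a first measurement occasion
by the observed 13-year growth increments. A generic form-factor
allometry (`V = 0.5 · (π/4) d²h`) supplies field-table volumes — a
deliberate simplification; species-specific volume equations are out of
scope. Thinning enters through three channels: the stem density, the
survivor size distribution, and a crown-radius enlargement factor for
released trees (1.0 / 1.15 / 1.3 for none / moderate / intensive).
Because the survivor distributions already embody the
selection effect of thinning from below, survivors are drawn from them
directly rather than by generating a pre-thinning population and
culling it; an explicit `thin_from_below()` helper performs
smallest-first removal where the removal process itself is under test
(the competition monotonicity property). With these defaults the mean
box dimension comes out near 1.40 / 1.46 / 1.52 across the treatments —
ordered as expected, with magnitudes in the reported range for managed
pine.

What the generator does **not** emulate: occlusion and ranging
artifacts of real scanners, needle-level geometry, stem sinuosity and
branching irregularity, understory vegetation, mixed species, and
terrain (plots are flat; the normalization module is tested on its own
sloped fixtures). Passing tests therefore demonstrate the correctness
of the measurement chain on clean geometry, not robustness to every
field condition.

## The statistical layer

The treatment analysis is a nested two-level linear mixed model fitted
by REML with `lme4`: fixed cell means per treatment (no global
intercept, so estimates are directly comparable group means), random
intercepts for site and for plot within site, independent residuals.
The simulation layout mirrors the targeted design: three sites, each
holding one plot per treatment (a split-plot), with ~60 trees per plot.

Denominator degrees of freedom for the treatment F-test and the Tukey
contrasts use the **Kenward-Roger** method. This was a genuinely open
choice: with only nine plots the plot-within-site variance is estimated
near its boundary, and in a 200-replicate null simulation the
Satterthwaite approximation rejected at 6.5% for a nominal 5% while
Kenward-Roger held 4.0%; KR is also the standard small-sample
recommendation for REML F-tests. `ddf = "satterthwaite"` remains
available (and is the fallback when `pbkrtest` is absent). Tukey
contrasts are computed on the mixed-model estimated marginal means via
`emmeans` with the same df method. Pearson correlations between box
dimension and each attribute are computed per treatment with two-sided
p-values, starring p < .001 and flagging |r| > 0.5, mirroring the
conventional reporting format. Tally-tree heights are imputed per plot
with a Näslund curve `h = 1.3 + d²/(a + b·d)²` fitted by least squares
on the linearizing transform `d/√(h−1.3) = a + b·d`; plots with fewer
than three sample trees fall back to a pooled fit with a warning.

No multiple-testing correction is applied across the per-attribute
models — each models a distinct response and is reported as such.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale by
design: fixture clouds of 10⁴–10⁶ points, stands of 250–1,000 m²
sampled at 5–10 cm point spacing, and 20–200 simulation replicates per
statistical property. These sizes were chosen so the full suite
exercises every stage — including two complete pipeline runs — while
each property retains enough resolution to fail informatively.
Every stochastic step takes an explicit integer seed, and the pipeline
derives all stage seeds from the single seed in its configuration, so
identical configurations produce byte-identical output files.

## Known limitations

* The stem classifier is a deliberately simple circle-tracking
  procedure; heavily leaning or forked stems would defeat it.
* The box dimension of a finite point sample depends on sampling
  density at the finest levels; comparisons are meaningful at matched
  scanning density, which the generator provides but field data may
  not.
* The watershed operates on the 2D canopy surface and cannot separate
  understory trees beneath a closed canopy.
* LAS/LAZ input is recognized but unsupported in this build
  (`has_las_support()`); XYZ and PLY cover the interchange needs.
* The Kenward-Roger / cell-means conventions are fixed choices among
  defensible alternatives; coefficient-level comparisons against other
  software require matching the parameterization.
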