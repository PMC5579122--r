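---
title: "Detecting long-term social avoidance with a spatially explicit null model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting long-term social avoidance with a spatially explicit null model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In longitudinal studies of individually identified animals, two individuals
can share most of their home range and still never be recorded together --
or be recorded together often simply because they use the same places. An
association index alone cannot distinguish social choice from spatial
coincidence in either direction. Social *avoidance* is the harder tail:
a pair that overlaps spatially but associates less than their space use
predicts. `avoidnull` implements a spatially explicit, iterative null model
that predicts how often each dyad *would* associate if individuals moved
independently within their own home ranges, and classifies each pair as
avoidance, random, or preference against that prediction.

## The model

**Associations.** Sightings are grouped into discrete sampling periods (a
survey or a day). Within a period, two individuals associate if their
positions are within a grouping distance `gprox` (pairwise rule), or if
they belong to the same connected component of the graph linking pairs
within `gprox` (chain rule, appropriate for species observed in fluid
groups). Dyadic association strength is the half-weight index

$$\mathrm{HWI} = \frac{N_{ab}}{N_{ab} + 0.5\,(N_a + N_b) + Y_{ab}},$$

where $N_{ab}$ counts periods in which $a$ and $b$ were seen associated,
$Y_{ab}$ periods in which both were seen but not associated, and $N_a$,
$N_b$ the sightings of each member within the dyad's joint availability
window. This is the `"printed"` convention, with $N_a, N_b$ as totals; it
caps at 0.5 for constant companions. Because field practice also uses the
variant in which $N_a, N_b$ count sightings *without* the partner (which
reaches 1 for constant companions), both are available via
`hwi(..., convention = )`, and the choice is surfaced rather than silent.
All dyadic quantities are restricted to periods inside both members'
availability windows -- the span from an individual's first to last
sighting, a conservative stand-in for entry and exit dates under
demographic turnover. Pairs with disjoint windows are excluded from every
analysis: they never had the opportunity to associate.

**The null.** Each individual's space use is summarized by a gridded kernel
utilization distribution (UD): an isotropic Gaussian kernel evaluated at
cell centres, multiplied by cell area, clipped to an optional boundary mask
(e.g. land in a marine study) and renormalized to total mass 1. A null
replicate re-creates the study: for every sampling period, a roster of
individuals is sampled from those temporally available, and each rostered
individual is placed at a random position drawn from its UD (cell by mass,
then uniform jitter within the cell). Rosters have fixed size (the observed
mean number of individuals per period, by default) or, where survey
coverage is uneven, a size derived from a population density times the
area of the period's *effort polygon* -- the buffered convex hull of that
day's survey locations and launch point. With effort geometry, roster
inclusion weights are each individual's UD mass inside the polygon, and
positions are drawn from the UD renormalized within it. Tallying each
replicate exactly as the observed data yields, over `B` replicates, a
per-dyad distribution of random HWIs.

**Calibration.** Independent random placement destroys movement
autocorrelation, so at the observed `gprox` the null under-produces
associations. Following the framework's calibration step, the null's
grouping distance is swept upward in grid-cell increments and the value
whose mean random HWI best matches the observed population mean HWI
(minimum absolute difference; ties to the smaller distance) is selected
for the final run. Candidates are capped at the smallest
centroid-to-contour distance of any individual's 95% home range, keeping
the inflated distance biologically possible. Roster size is deliberately
*not* a calibration knob: inflating per-period sample sizes inflates
co-sighting counts and makes random HWIs incomparable with observed ones.

**Inference.** For each dyad with observed index $X$ and random indices
$Y_1,\dots,Y_B$:

$$p_\mathrm{avoid} = \frac{1}{B}\sum_{j=1}^{B} [\,Y_j \le X\,], \qquad
  p_\mathrm{prefer} = \frac{1}{B}\sum_{j=1}^{B} [\,Y_j \ge X\,].$$

A dyad is an avoidance when $p_\mathrm{avoid} \le \alpha$ (at the default
$\alpha = 0.05$, at least 95% of random HWIs exceed or tie the observed),
a preference when $p_\mathrm{prefer} \le \alpha$, random otherwise. Both
tails use inclusive comparison, exactly matching the counting formula, and
no $+1/(B+1)$ correction is applied; the documented consequence is that
ties -- common when many random HWIs are exactly 0 -- make the test
conservative. No multiple-testing correction is applied across dyads by
default (an opt-in Benjamini–Hochberg flag exists in `run_inference()`).
Among avoidances, pairs are ranked by their volume-of-intersection overlap
(`avoidance_strength()`): avoiding a pair you share 90% of your range with
is a stronger statement than avoiding one you barely meet.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `gprox_observed` | m | user | association proxy in the observed data (e.g. 1.85 m for a terrestrial lizard, 10 m chain for dolphins) |
| `cell_size` | m | user | UD grid cell; also the sweep increment. Keep `cell_size <= bandwidth/2` |
| `bandwidth` | m | `"href"` | kernel smoothing; `href` = $0.5(s_x+s_y)n^{-1/6}$ per individual, or a fixed externally optimized value |
| `min_sightings_ud` | count | 25 | sightings needed for a stable UD; choose by inspecting `stabilization_curve()` |
| `min_sightings_classify` | count | = UD threshold | stricter post-hoc threshold for classifying dyads; choose via `stability_report()` |
| `B` | count | 1000 | null replicates behind each dyad's p-value |
| `alpha` | — | 0.05 | tail probability for classification |
| `ud_level` | — | 1.0 | 1.0 = full range; 0.5 = repeat everything within core ranges |
| `effort_buffer` | m | 1000 | dilation of daily survey hulls |
| `sweep_reps` | count | 100 | replicates per sweep candidate (final run uses full `B`) |

## Numerical choices

- Kernel densities are evaluated at cell centres only (no within-cell
  integration); the error is second order in `cell_size/bandwidth`, which
  is why cells should be at most half a bandwidth.
- Contours are raster cell sets, filled in decreasing density order until
  the level's mass is reached; areas are cell count times cell area, and
  spatial membership tests (core clipping, effort restriction) are
  cell-centre tests. A position jittered inside a boundary cell may
  therefore poke marginally past a vector boundary -- containment is
  defined at cell resolution throughout.
- The calibration sweep uses common random numbers: every candidate
  distance is tallied on the *same* simulated positions, so the sweep
  column is exactly non-decreasing (a larger radius can only convert
  "seen apart" into "seen together"; the number of co-sighted periods is
  fixed, so the HWI denominator is constant while the numerator grows).
- A master seed spawns one deterministic child seed per replicate, so
  results are reproducible and independent of replicate order.
- `select_gprox()` treats absolute differences within `1e-12` as tied and
  takes the smaller distance, so floating-point noise cannot flip a
  selection.
- HWI defines 0/0 as 0 (a dyad never co-available within its window has no
  association signal); degenerate single-cell contour regions report half
  a cell size as their centroid-to-contour distance; buffered effort
  polygons with one or two distinct points are discs or stadiums with
  exact areas.
- Within-period duplicate records keep the *last* row (the convention of
  using the last survey of a day to reduce autocorrelation); rows with
  non-finite coordinates are dropped with a message; coordinates must be
  planar metres, and fractional degree-sized inputs are rejected.

## The synthetic-data generator

`make_world()` builds a population with known ground truth: mixture-of-
Gaussians true UDs whose centres are scaled toward the arena centre until
the realized mean pairwise VI hits a target; availability windows with
optional turnover; a detection probability per individual-period; and a
planted structure matrix. `plant_structure()` registers avoidances and
preferences with a strength in [0, 1]; planting avoidance is only allowed
for pairs whose true VI reaches a floor (default 0.3), because avoidance
between non-overlapping animals is undetectable by construction.
`simulate_surveys()` applies avoidance spatio-temporally -- violating
positions are resampled (up to a 50-try cap, then the later individual is
dropped from the period) -- so the *marginal* space use of avoiders still
overlaps. That is exactly the signal the null model must isolate: pairs
that share space but not at the same time.

What the generator does *not* emulate: movement autocorrelation (positions
are independent draws between periods), home-range drift, observation
error in identity, and density-dependent detection. Because simulated
positions are independent draws from the true UDs, the null model is (up
to UD estimation error) the generative model for neutral dyads; passing
type-I tests on these worlds therefore validates the machinery, not the
robustness of the method to autocorrelated movement in real data -- the
calibration step exists precisely because real animals violate that
assumption.

## Validation at a glance

The test suite checks, among others: UD mass normalization (to 1e-9, with
and without masks) and agreement with a brute-force kernel-sum oracle;
dyadic tallies against a naive per-period double loop; HWI and both
p-value tails against explicit counting; monotonicity of the sweep under
common random numbers; the four worked calibration selections from the
packaged example sweep tables; false-positive rates on a neutral world of
20 individuals and 150 periods at `B = 200` staying within
$\alpha + 2\,\mathrm{SE}$ for both tails; and recovery of three planted
strength-1 avoiders (true VI at least 0.5, 100 shared periods) in at least
80% of 50 seeded runs at `B = 200`. These problem sizes were chosen to
exercise realistic dyad counts (around 190) while keeping a full suite run
on one core in the tens of minutes; production analyses should use
`B = 1000` as the default does.

## Known limitations

- Directionality (who avoids whom) is outside the model; the statistic is
  symmetric in the pair.
- Availability windows are first-to-last sighting; a long-lived but rarely
  seen individual gets an honest window only if detected near its true
  entry and exit.
- With `B` replicates the smallest attainable non-zero p-value is `1/B`;
  at `B = 200` a dyad can be significant only if fewer than 5% of
  replicates tie or undercut it, which is why sparse data push the test
  toward conservatism rather than false positives.
- Core-range runs (`ud_level = 0.5`) clip observed sightings and null
  support to each individual's 50% contour; individuals with few in-core
  sightings may drop below the classification threshold and disappear
  from the core-range dyad set.
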