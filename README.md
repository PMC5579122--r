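# avoidnull

Spatially explicit null models for identifying **long-term social
avoidance** (and preference) between pairs of individually identified
animals in longitudinal sighting data.

## The problem

Behavioural ecologists routinely measure social *preference* with
association indices, but the other half of sociality — pairs that share
space yet consistently do **not** associate — is invisible to an index
alone, because both association and its absence arise partly from
overlapping space use. `avoidnull` disentangles the two with an iterative
null model: individuals are repeatedly placed at random positions drawn
from their own kernel utilization distributions (UDs), subject to temporal
availability, per-period roster sizes and survey-effort geometry, and
random associations are extracted by spatial proximity. Comparing each
dyad's observed half-weight index (HWI) with its null distribution yields
a two-tailed permutation test per pair.

The HWI is

    HWI = N_ab / (N_ab + 0.5 (N_a + N_b) + Y_ab)

with `N_ab` the periods a pair was seen associated, `Y_ab` the periods
both were seen but apart, and `N_a`, `N_b` each member's sightings within
the pair's joint availability window. Per dyad, with observed index `X`
and random indices `Y_1..Y_B`,

    p_avoid  = #{ j : Y_j <= X } / B,      p_prefer = #{ j : Y_j >= X } / B,

and a dyad is an *avoidance* when `p_avoid <= alpha` (at `alpha = 0.05`,
at least 95% of random HWIs exceed or tie the observed), a *preference*
when `p_prefer <= alpha`, random otherwise. Because random placement
under-produces associations relative to real, autocorrelated movement,
the null's grouping distance `gprox` is first calibrated: swept upward in
grid-cell increments (never beyond the smallest centroid-to-contour
distance of any 95% home range) until the null's mean HWI matches the
observed population mean.

Who this is for: researchers with longitudinal, individually resolved
sighting data — one row per individual per survey/day with projected
metric coordinates — who want dyad-level avoidance/preference
classifications with calibration and sample-size diagnostics.

## Worked example

Simulate a population of 12 individuals over 100 sampling periods with one
planted strength-1 avoidance between the two most-overlapping animals
(true VI = 0.79), then run the full pipeline:

```r
library(avoidnull)

w  <- make_world(12, space_extent = 400, overlap_target = 0.5,
                 n_periods = 100, seed = 11, ud_sd = 30, gprox = 20,
                 detection_prob = 0.9, vi_floor = 0.5)
vi <- sort(w$true_vi, decreasing = TRUE)
pr <- strsplit(names(vi)[1], "|", fixed = TRUE)[[1]]
w  <- plant_structure(w, data.frame(id_a = pr[1], id_b = pr[2],
                                    effect = "avoid", strength = 1))
sim <- simulate_surveys(w, seed = 12)

cfg <- study_config(gprox_observed = 20, cell_size = 10, bandwidth = "href",
                    min_sightings_ud = 25, min_sightings_classify = 30,
                    B = 500, sweep_reps = 50, seed = 13)
run <- run_full_analysis(sim$table, cfg)
print(run)
print(run$sweep)
head(run$results, 3)
```

```
<avoidance_run> gprox 20 m, 66 classified dyads: 2 avoidance, 7 preference
<sweep_table> observed mean HWI: 0.02150802
 gprox mean_random_hwi selected
    10     0.004821913
    20     0.019173795        *
    30     0.042547207
    40     0.072848532
    50     0.109132438
   id_a  id_b n_ab y_ab hwi_obs p_avoid p_prefer classification vi_95 strength_rank
1 ind05 ind06    0   77  0.0000   0.002    1.000      avoidance 0.752             1
2 ind06 ind12    0   75  0.0000   0.030    1.000      avoidance 0.502             2
3 ind01 ind02    3   76  0.0179   0.732    0.268         random 0.541            NA
```

Reading the output: the calibration sweep picked `gprox = 20` m because
its mean random HWI (0.0192) is closest to the observed mean (0.0215).
The planted pair `ind05–ind06` is the top-ranked avoidance: they were both
seen in 77 shared periods, never together (`n_ab = 0`), yet share 75% of
their home ranges — and in only 0.2% of the 500 null replicates was their
random HWI that low. The second avoidance (`p_avoid = 0.030`) is a false
positive of the kind expected at `alpha = 0.05` over 66 dyads; no
multiple-testing correction is applied by default, mirroring standard
practice (a Benjamini–Hochberg flag exists in `run_inference()`).

Key functions along the pipeline: `read_sightings()`,
`filter_min_sightings()`, `stabilization_curve()` (how many sightings a
stable home range needs), `estimate_ud()` / `ud_contour()` /
`volume_intersection()`, `association_summary()`, `sweep_gprox()` /
`select_gprox()`, `null_distributions()`, `run_inference()`,
`avoidance_strength()`, and `stability_report()` (how many sightings a
stable *classification* needs). A thin CLI wrapping the same functions is
in `inst/cli/avoidnull.R` (subcommands `simulate`, `homerange`,
`calibrate`, `run`, `stability`).

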