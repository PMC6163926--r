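---
title: "Dynamic exposure assessment with context cubes and space-time tunnels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic exposure assessment with context cubes and space-time tunnels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expocube)
library(dplyr)
```

## The problem

Most environmental-health studies score a person's exposure to features of
the built environment — here, "BMI-unhealthy" food outlets such as fast-food
restaurants and convenience stores — from a *static* delineation of where
that person spends time: a residential buffer, a convex hull of GPS points,
a deviational ellipse. Two things are wrong with this picture at once. The
person moves, so the places that matter change by the minute; and the
environment itself moves, because outlets open and close on schedules that
differ between weekdays, Saturdays and Sundays. Conclusions drawn from
exposure measures that ignore either kind of dynamics are sensitive to how
the contextual unit was drawn — the *uncertain geographic context problem*
(UGCoP).

`expocube` implements a framework that makes both dynamics explicit:

* the **environmental context cube (ECC)** — a regular voxel grid over
  (x, y, time-of-day) in which each voxel holds the distance-decayed
  intensity of the outlets *open during that time slot*;
* the **individual space-time tunnel (ISTT)** — the region swept through
  the cube by a horizontal disc of radius $B_r$ that follows the
  participant's GPS trajectory;
* the **environmental context exposure index (ECEI)** — the weighted sum of
  cube values intersected by the tunnel, per hour of observation:

$$\mathrm{ECEI} = \frac{\sum_{i=1}^{n} EC_i \, W_i}{T},
\qquad
W_i = \begin{cases} 1 & v_i = 0\\ (1/2)^{v_i} & v_i > 0, \end{cases}$$

where $EC_i$ is the cube value at intersected point $i$, $v_i$ the
participant's movement velocity (m/min) when passing it, and $T$ the
observation time in hours. In the framework's reference setting every
$W_i = 1$ (`weight_mode = "constant"`); the velocity mode is provided as a
user-selected alternative.

The package also implements the four conventional comparators — GPS
trajectory buffer (GTB), minimum convex polygon (MCP), and 1- and
2-standard-deviation deviational ellipses (SDE1, SDE2), each scored as
static outlet density — and a binary-logistic harness that contrasts all 22
exposure measures (18 cube-based, 4 static) as predictors of overweight
status (BMI ≥ 25), adjusted for gender, age band and education, compared by
AIC, Nagelkerke $R^2$ and the likelihood-ratio $\chi^2$.

## Preprocessing rules

GPS tracks arrive at a nominal 1-minute cadence with dropouts. Gaps are
handled per the cohort-screening conventions the framework assumes:

* a gap whose bounding fixes are **< 30 m** apart and shorter than an hour
  is filled minute-by-minute *at the earlier fix* (the device sat still);
* a gap with endpoints **≥ 30 m** apart but **< 1 h** long is filled by
  linear interpolation (constant velocity);
* a gap of **an hour or longer is never imputed** — those minutes are
  missing, whatever the endpoint distance.

Boundary semantics are deliberate and tested: exactly 30 m interpolates,
exactly 60 min stays missing. The third rule is global on purpose: if
stationary gaps of any length were imputed, overnight non-wear at home
would count as observation time and the valid-day screen below could never
fail, which would make cohort attrition impossible.

A calendar day is **valid** with ≥ 480 non-missing minutes (8 h); imputed
minutes count — they are valid records by construction. A participant is
retained with ≥ 5 valid weekdays *and* ≥ 2 valid weekend days. Whether
imputed minutes should count toward the 8-hour rule is a genuinely open
convention; we chose "yes" and the choice is isolated in
`flag_valid_days()` should a sensitivity analysis want the other reading.

Velocities are measured in m/min (the native cadence unit): record $k$
carries the planar distance from record $k-1$ divided by the elapsed
minutes.

## Building cubes

For each day type (weekday / Saturday / Sunday), method and cell size, a
food-environment layer is evaluated at each of the 48 half-hour slots: the
sum over outlets open at the slot start of a distance-decay weight at the
cell centroid. Three decay families are available:

| method | form | scale default | rationale |
|---|---|---|---|
| KD | quartic kernel $\tfrac{3}{\pi h^2}(1-(d/h)^2)^2$, 0 beyond $h$ | $h$ = 1000 m | unit-mass kernel density; compact support |
| ISDD | bounded inverse square $1/(1+(d/d_0)^2)$ | $d_0$ = 100 m | inverse-square far-field without the $1/d^2$ singularity at the outlet |
| NEDD | negative exponential $e^{-d/d_0}$ | $d_0$ = 500 m | e-folding accessibility decay |

No canonical bandwidths exist for these surfaces; the defaults above are
round numbers at the walking-to-neighbourhood scale and are fully
config-exposed. Because every exposure is z-scored across the cohort before
modelling, the comparison of measures is invariant to each surface's
overall scale — only the decay *shape* matters.

An outlet is open at minute $t$ of its day type when
$t \in [\mathrm{open}, \mathrm{close})$. Overnight hours
(close < open, e.g. 18:00–02:00) wrap: the outlet is open
$[\mathrm{open}, 1440)$ on its own day type and $[0, \mathrm{close})$ on
the *following* one. With only three schedule strata the predecessor map is
weekday→weekday, weekday→saturday, saturday→sunday; the single
approximation is that a Friday overnight tail is looked up from the
weekday schedule on Saturday mornings, which is the correct schedule for
the outlet, if not the correct calendar day, in all but pathological cases.

The 48-layer cubes are refined to 10-minute resolution by per-pixel linear
interpolation between temporally adjacent layers, the originals kept and
two layers inserted per half hour; after 23:30 interpolation wraps toward
00:00, matching the daily periodicity of schedules. The full menu — 3
methods × 3 cell sizes (100/150/200 m) × 3 day types × 2 temporal
resolutions — yields 54 cubes, 27 per temporal resolution.

For intersection the cube becomes a point cloud: one point per voxel at the
cell centroid and the **slot midpoint** (00:15 for slot [00:00, 00:30)),
carrying the voxel value. Midpoints make the time coordinate symmetric, the
same convention as the spatial centroid.

```{r layer-example}
cfg <- study_config(grid_extent = c(0, 0, 2000, 2000))
sc <- synth_scenario(config = cfg, n_participants = 6,
                     poor_wear_frac = 0, seed = 11)
registry <- make_outlets(sc)
noon <- build_layer(registry, "weekday", 720, "ISDD", 200, cfg)
night <- build_layer(registry, "weekday", 180, "ISDD", 200, cfg)
c(open_at_noon = nrow(open_outlets(registry, "weekday", 720)),
  open_at_3am = nrow(open_outlets(registry, "weekday", 180)),
  peak_noon = max(noon$grid), peak_3am = max(night$grid))
```

## Tunnels and the intersection

The "3-D buffer" around a trajectory cannot be a metric ball, because its
axes carry different units (metres and minutes). The tunnel is therefore a
*sweep*: at each instant with a recorded or imputed position, a horizontal
disc of radius $B_r$ (default 100 m) centred on the time-interpolated
position; instants inside unimputed gaps are simply not covered, leaving
temporal holes. A cloud point $(x, y, t)$ is intersected when the
participant's position at time $t$ on a valid day of the matching day type
lies within $B_r$ of $(x, y)$; a voxel revisited on several days counts
once per day, so repeated exposure accumulates.

Two readings of $T$ are implemented. The default (`t_mode = "observed"`)
takes $T$ as the participant's total valid observation hours on days of
that day type, making the ECEI an exposure rate per observed hour that is
well defined even when the intersection is empty. The alternative
(`t_mode = "span"`) uses the time span of the intersected points. Day types
are combined into one exposure per participant and cube key by a
valid-day-weighted mean, so a typical 5-weekday/2-weekend-day week weights
the strata as the person actually lived them.

The production intersection path shares its geometry across the three decay
methods and two temporal resolutions of one (day type, cell size) group and
looks voxels up through a grid window; it is contractually equivalent to
the literal all-pairs definition, and the test suite asserts set equality
between the two on randomized instances.

## Activity-space comparators

The four static measures deliberately ignore business hours — that temporal
blindness is the point of the contrast:

* **GTB** — the 100 m planar buffer of the valid-day polyline (broken at
  unimputed gaps). With no polygon-geometry engine in the stack the buffer
  is represented exactly as what it is mathematically: the union of discs
  centred on a densified point set along the polyline (spacing $B_r/10$,
  boundary error $\le$ spacing$^2/8B_r \approx 0.13$ m). Its area is
  computed by a scanline quadrature that unions the disc chords exactly in
  x and steps $B_r/10$ in y; on closed forms (disc, stadium) this is
  accurate to ~0.1–0.3%.
* **MCP** — convex hull (`chull`) of all valid-day points; shoelace area.
* **SDE1/SDE2** — mean centre; axes along the eigenvectors of the sample
  (n−1) covariance (the Yuill rotation); semi-axes $k\sigma$ along each
  axis, $k \in \{1, 2\}$, taking "two standard deviations" literally, so
  SDE2 has exactly four times SDE1's area. Several SDE conventions exist
  (n vs n−1, $\sqrt{2}$ corrections); this one is stated here and in the
  function documentation precisely because the choice is not canonical.

Membership is closed (boundary points count), and exposure is outlets per
km² of the delineation, z-scored per kind across the cohort.

## The model harness

Each of the 22 measures enters its own logistic model of overweight status
with gender (male reference), age band (18–30 reference; 18–30/31–65/65+)
and education (below college reference). The LR $\chi^2$ is taken against
the intercept-only model, so it measures the whole model — one LR per
model; a covariates-only null is available by flag. Nagelkerke
$R^2 = \left[1-(L_0/L_1)^{2/n}\right] / \left[1-L_0^{2/n}\right]$. Odds
ratios use Wald 95% intervals. No multiple-testing correction is applied
across the 22 models — the harness reports, it does not gate. When the
exposure coefficient is degenerate (|β| > 15, SE > 50, or aliased), the
model is flagged `separated` and no OR is reported; a sparse covariate cell
(e.g. a single 65+ participant, as expected at a 2% senior share of a
46-person cohort) does not suppress the exposure OR.

## The synthetic world

Because the reference GPS/outlet/participant data are private, the package
ships a first-class generator that emulates their structure:

* **outlets** clustered along two crossing corridors (Poisson cluster
  process); schedules drawn on a 10-minute lattice (06:00–11:00 openings,
  17:00–23:00 closings), with 5% open 24 h, 5% open overnight, 10% closed
  Sundays, and — by construction — at least `schedule_mix` (default 60%)
  with Saturday hours differing from weekday hours;
* **trajectories**: per participant a home/work/errand anchor routine at
  1-min cadence, travel at 150–200 m/min with a hard 250 m/min cap and
  bounded ±5 m jitter; dropouts of all three imputation classes (short
  stationary, sub-hour moving, > 1 h) injected stochastically and — when
  gaps are enabled — at least once each deterministically;
* **cohort**: 51 enrolled, of whom a 10% poor-wear minority records full
  days too rarely to pass the 5+2 screen, leaving 46 valid participants —
  the attrition structure of the reference cohort; covariates drawn at the
  reference shares (61% female; 57/41/2% age bands; 57% college);
* **outcomes**: overweight drawn Bernoulli with
  logit $p$ = −0.17 + 3·z(true exposure) + 0.8·female + 0.3·age31–65 +
  0.5·age65+ − 0.8·college, where the true exposure is the ECEI on the
  ISDD / 100 m / 10 min cube — the finest dynamic measure — so that
  end-to-end runs have a known data-generating measure to recover. The
  slope of 3 per SD is a deliberately strong effect; the intercept offsets
  the mean covariate contribution so prevalence sits near 50%.

All generators are pure functions of (scenario, seed), drawing from named
sub-streams so adding one generator never perturbs another.

What the generator does **not** emulate: road networks and transport modes
(decay is Euclidean), activity type (eating vs working at the same
address), seasonal schedule changes, and GPS error structure beyond
bounded jitter. Tests passing on this world therefore demonstrate the
machinery — filters, geometry, index arithmetic, model fitting — not the
epidemiology of any real cohort.

## Numerical choices

* Grid origin at the south-west corner; cells are half-open
  $[x_0+js, x_0+(j+1)s)$ squares, indexed row-major from the south-west;
  extents that do not divide the cell size are padded upward and the
  padding recorded.
* Layer values below $10^{-9}$ are zeroed to keep rasters sparse (recorded
  in the sidecar); dropped zero-value cloud points contribute 0 to any
  exposure sum, so intersections are unaffected.
* Rasters persist as plain-text ESRI ASCII grids plus JSON sidecars; point
  clouds as CSV. Coordinates live in one projected metric CRS; longitude/
  latitude inputs are projected with a local azimuthal equidistant
  projection about a configured origin (sub-metre distortion at county
  scale, far below the 100 m cell size).
* z-scores use the sample (n−1) standard deviation; a zero-variance
  measure z-scores to 0 with a warning rather than NaN.

## Problem sizes used by the tests

The default study extent is a 4 × 4 km square, so the three cell sizes give
40×40, 27×27 and 20×20 grids — county-scale structure at desk-scale cost. A
full run (51 participants × 9 days at 1-min cadence, 54 cubes, 22 models)
takes well under five minutes on one core. Oracle-equivalence suites run on
clouds up to 19,200 points × 2 days; calibration uses n = 2000 for
coefficient recovery and 200 replicates of n = 500 for CI coverage. The
method-discrimination experiment repeats the end-to-end study 50 times
(fresh trajectories and outcomes per replicate; outlets and cubes fixed, as
properties of the environment) on a 46-participant, 7-day scenario.

## Known limitations

* **Near-collinear cube twins.** The 10-min cube of a method/cell-size pair
  is a linear interpolation of its 30-min parent, so their ECEIs are almost
  collinear whenever participants' within-half-hour movement is modest
  (`scripts/acceptance.R` reports the cohort correlation between
  ISDD100T10 and ISDD100T30 alongside the experiment's win rate). At a
  46-person cohort the AIC contest between such twins runs close to the
  information limit, so single-study rankings among them should be read as
  a family verdict ("finest ISDD cubes win"), not a pointwise one. The
  discrimination experiment quantifies exactly this.
* Friday-night overnight schedules are read from the weekday stratum on
  Saturday mornings (see above).
* GTB areas are numerical (quadrature), not algebraic; the documented
  error bounds are orders of magnitude below the 100 m grid scale.
* The harness explores association only; nothing here supports causal
  claims.
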