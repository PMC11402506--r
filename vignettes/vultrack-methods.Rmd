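---
title: "Methods: life-stage segmentation, home ranges and survival from juvenile vulture telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: life-stage segmentation, home ranges and survival from juvenile vulture telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

vultrack implements the standard analysis arc for GPS-tagged juvenile
trans-Saharan migrants — here, Egyptian vultures (*Neophron
percnopterus*) tagged as nestlings in Iberian breeding nuclei.  The
pipeline turns raw Movebank-dialect fix tables into life-stage
segmentations, kernel home ranges, transmitter-based fates,
stage-specific apparent-mortality rates and Kaplan–Meier survival
comparisons.  Because real juvenile tracking data for this system are
access-restricted, the package also ships a stage-structured movement
simulator with complete ground truth; every estimator is validated
against that truth, against closed-form oracles, or against an
independent reference implementation.

## Quality control and resampling

Fixes with HDOP or VDOP strictly greater than 5 are discarded
(`qc_filter()`).  The threshold is inclusive on the retained side: a
fix with DOP exactly 5 passes.  Fixes with *missing* DOP are retained
by default, because several transmitter models report no DOP at all and
dropping them would delete whole deployments; `drop_missing_dop = TRUE`
switches to strict behaviour.

Tracks are then regularised to a 30-minute grid (`resample_track()`),
anchored at each individual's first retained fix.  Each grid slot takes
the nearest original fix within a 15-minute tolerance; empty slots stay
empty.  Nothing is interpolated: a fabricated position could silently
cross the 200-m nest-departure threshold or leak into the
kernel-density inputs.  Because output fixes are a subset of input
fixes lying exactly on the grid, QC + resampling is idempotent.

## Geometry

All distances are great-circle (haversine) on a sphere of radius
6371.0088 km, delegated to `geosphere`.  At the scales involved
(≤ 4000 km) the difference from ellipsoidal geodesics is below 0.5%,
far smaller than GPS and resampling error.  Daily distances attribute
each inter-fix segment to the UTC day of its *start* fix, so day totals
conserve the full path length; days observed with fewer than two fixes
are reported `NA` rather than zero.

Areas are computed in a spherical Lambert azimuthal equal-area plane
(`project_laea()`), written in closed form inside the package.  The
projection is exact for areas on the sphere; the test suite checks
round-trip errors below 1 m on Sahel-scale point clouds and
spherical-cap areas within 0.5% out to 1500 km radii.

## Life-stage segmentation

Stages are delimited by displacement rules, mirroring how this system
is analysed in the field; no hidden behavioural-state model is
involved.  All thresholds live in `seg_params()`:

* **Nest departure** — first fix ≥ 200 m from the nest (inclusive).
* **Natal departure** — the last fix of an in-territory residence run
  (territory = 2 km radius around the nest) followed by (a) at least 60
  days of absence before any re-entry and (b) a displacement of ≥ 50 km
  within 7 days (the "long and clearly directed journey").  The
  absence window matters: year-round residents revisit their natal
  areas every breeding season, so a naive "never returns" rule would
  fold the whole first year into dependence.  A track that ends before
  the 7-day confirmation window closes returns the candidate flagged
  unconfirmed.  The displacement test uses the *maximum* displacement
  within the window rather than the endpoint, so a bird looping at day
  7 is not missed.
* **Gibraltar crossing** — first southbound crossing of 36.0° N with
  the crossing longitude inside [−6.1, −5.2]°, a window covering the
  Strait; using a lat/lon gate avoids shipping coastline data.
* **Sahara span** — from the last fix at or above 30° N to the first
  fix at or below 22.5° N (the Sahel arrival).  22.5° N is the upper
  edge of the observed Sahel range for this system; 13.3° N the lower.
* **Return start** — the first instant in the Sahel stay with ≥ 100 km
  net northward displacement within 3 days, from which the northward
  run is *sustained*: the bird exits the Sahel band within 30 days,
  with latitude never drawing down more than 15 km below its running
  maximum on the way out, and then either reaches 30° N or stays out of
  the band for 30 days.  The drawdown condition anchors detection to
  the final directed run rather than an earlier wandering excursion
  (without it, birds hugging the southern band edge can trigger weeks
  early); the detected instant is snapped to the last latitude minimum
  of the run, cancelling the lookahead bias of the 3-day window.  An
  aborted return that reaches the desert-entry latitude and turns back
  south still counts, matching observed behaviour.

`segment_stages()` composes these into contiguous, non-overlapping
intervals — migrants: dependence → Iberian pre-migration → Sahara
crossing → Sahel stay [→ return migration → post-return Iberia];
residents: dependence → residency.  Interval boundaries snap to fix
timestamps; with 30-minute fixes, boundary uncertainty is half an hour,
not days.  The pre-migration/Sahara boundary is the Gibraltar crossing
(so that intervals tile the observed span); the 30° → 22.5° N desert
span, the quantity whose duration is typically reported (~11 days), is
returned separately by `detect_sahara_span()`.

A bird is a **migrant** once a Gibraltar crossing is seen, a
**non-migrant** after 365 crossing-free days following natal departure,
and **undetermined** otherwise — so birds lost early are never
force-classified.

## Kernel home ranges

`fit_kde()` evaluates an isotropic Gaussian kernel over an equal-area
grid (default 5-km cells, padded three bandwidths beyond the data).
The reference bandwidth is Silverman's rule on the projected
coordinates, `h = sqrt((var(x)+var(y))/2) * n^(-1/6)`; published
analyses of this system name no bandwidth, so it is an exposed
parameter.  Grid densities are renormalised to integrate to exactly 1
(truncation at three bandwidths would otherwise leave ~0.5% of mass
outside the grid).  The 95% isopleth is the smallest set of cells whose
mass reaches 0.95 — the threshold cell is included — and the area is
the cell count times the cell area, in km².  On 5000 draws from an
isotropic Gaussian (σ = 100 km) smoothed with h = 20 km the area is
within 5% of the analytic value π·χ²₀.₉₅,₂·(σ²+h²), and halving or
doubling the cell size moves it by under 3%.

Pairwise overlap re-grids both isopleth masks onto a shared lattice
centred midway between the two fits (bounding projection distortion
symmetrically) and reports the symmetric index — the mean of
area(A∩B)/area(A) and area(A∩B)/area(B), in percent.  Published work
says only "overlap (in percentage)", so both directed percentages are
also attached as attributes and any convention can be recovered.
Centroids are density-weighted over inside cells; centroid distances
are haversine.  `monthly_kde()` fits per calendar month (≥ 10 fixes)
and, given core polygons, reports the monthly share of fixes inside
each core — the residency two-core calendar.

## Fate classification and apparent mortality

`infer_fate()` applies, in order:

1. **Stationary tag** — all terminal fixes within 50 m of the terminal
   run's median position for ≥ 3 days, with a flat activity channel
   (mean ≤ 2), is a dead bird under a transmitting tag; the event is
   dated at the start of the run.  Without an activity channel the rule
   runs on positions alone and the record is flagged lower-confidence.
2. **Abrupt silence** — transmission ending ≥ 30 days before the study
   end with a healthy last battery reading (≥ 3.6 V) is assimilated to
   death at the last fix.  Only the *terminal* gap is examined, so a
   mid-track outage bridged by later fixes (tags going quiet in the
   Sahel and reviving on the way north) never kills a live bird.  The
   same silence with a dying battery censors instead.
3. **Old-tag intermittency** — a tag older than 5 years whose reception
   turns irregular (inter-fix gaps > 24 h dominating the tail) censors
   the bird alive at the last regular fix.
4. Otherwise the bird is alive and transmitting.

The 30-day / 3.6-V operationalisation of "signal lost abruptly despite
good transmission and battery performance" is this package's choice;
no numeric rule is published.  These are *apparent* fates: an
unrecovered tag failure is indistinguishable from death, and every
output labels the rates accordingly.

`stage_mortality_table()` cross-tabulates deaths by reporting stage ×
nucleus × sex.  Pre-migration, Sahara and return legs roll up to
"migration".  The per-stage duration is the mean observed stage
duration over individuals entering the stage (an individual's several
migration legs are summed first), and the rate is deaths/duration
**truncated** — not rounded — to two decimals, the convention under
which 5 deaths over a 28-day stage print as 0.17 and 14 over 631 days
as 0.02.  Whether published durations are means or medians is not
stated; they are treated as means here.

`kaplan_meier()` and `log_rank()` are authored implementations of the
product-limit estimator and the log-rank test (age since tagging as
the time axis, censored-at-death-time individuals kept at risk).  The
`survival` package serves purely as an independent oracle: the test
suite checks agreement to 10⁻⁹ (KM) and 10⁻⁶ (log-rank) on dozens of
random censored datasets.  Capture–recapture and multistate models are
deliberately out of scope, as is mixed-model inference on movement
metrics: `run_pipeline()` emits descriptive group summaries
(mean ± SD, n, range by nucleus and sex) instead of LMM fits.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design: 32 nestlings (17
Arribes, 10 Galicia, 5 Segovia), exactly balanced sexes, three
year-round residents drawn from Arribes only, July tagging, ~750-day
observation horizons, 30-minute fixes.  Movement is built from two
kernels — exact-discretisation Ornstein–Uhlenbeck wandering around an
attraction centre, and a biased correlated random walk whose heading
mixes persistence with the bearing to a target.  These are the simplest
processes that reproduce the qualitative stage phenomenology; they are
not Lévy walks and carry no energetics, wind or habitat structure.

Calibration anchors, fixed once from the study system: dependence
wandering tuned to ~10 km/day daily paths and ~20-day durations (a
3–8-day tight nestling phase precedes it); pre-migration transit of
Iberia averaging ~2 weeks; Sahara speed set so the 30°→22.5° N span
takes ~11 ± 5 days; Sahel Ornstein–Uhlenbeck wandering with 90-km
stationary SD inside the 13.3–22.5° N band (reflected at the edges),
giving 95% KDE areas of order 10⁵ km²; return after ~600 Sahel days;
resident cores at Cáceres (occupied September–March) and Salamanca
(April–August) with 18-km SD, giving two-core ranges of order
1.5×10⁴ km².  Per-stage daily hazards default to 0 (dependence),
6×10⁻³ (migration legs), 9×10⁻⁴ (Sahel), with small return/post-return
and residency hazards — the migration/Sahel ordering seen in the field.

The transmitter layer thins fixes (5% missingness), jitters positions
(20 m SD alive, 5 m for a motionless tag), draws DOP values with a
configurable per-fix probability (default 5%) of failing the DOP > 5
filter, writes battery voltages and an activity index (near zero after
death), and applies one of two post-death modes: a stationary
still-transmitting tag (probability 0.7, 15–30 days) or abrupt silence.
A mid-Sahel outage (10–25 days, probability 0.1) exercises the
gap-bridging logic, and tags older than 5 years can turn intermittent.

Every generative boundary, death and artifact is recorded as ground
truth.  One master seed drives a per-individual substream
(`cohort_plan()`), so cohorts are byte-reproducible and identical
whether birds are simulated together or one at a time.

What the simulator does *not* emulate — and hence what passing
recovery tests cannot show about real data: geographic structure beyond
nest points, a gate and latitude bands (no coastlines, so no
detours around water bodies); shared roosts or conspecific attraction
(simulated Sahel ranges overlap less than real ones, whose birds
converge on common areas); flexible 5–30-minute duty cycles (the
simulator emits the post-resampling 30-minute cadence directly);
heterogeneous transmitter models; and any covariance between movement
and mortality risk.

## Numerical choices and degenerate inputs

Duplicate timestamps keep the first occurrence; resampling ties at
exactly half an interval round up, deterministically.  Empty post-QC
tracks segment as `undetermined` with zero intervals.  `fit_kde()`
refuses fewer than 10 points or an all-identical cloud.  The log-rank
statistic returns exactly 0 (p = 1) when observed equals expected in
every group, avoiding a singular solve.  All boundary instants are fix
timestamps — no sub-fix interpolation anywhere.

## Validation problem sizes

The shipped test suite runs the boundary-recovery experiment on 110
simulated individuals (100 migrants + 10 residents, fixed seed,
defaults otherwise), requiring ≥ 90% of nest-departure and
Sahel-arrival estimates within one day of truth and 100% strategy
classification for spans ≥ 400 days, and the hazard-recovery experiment
on 500 individuals over 500-day horizons, requiring the recovered
migration rate to exceed the Sahel rate and each deaths/duration rate
to fall within 25% of its ground-truth value.  `scripts/acceptance.R`
reruns the default 32-bird cohort end to end and writes the main
computed quantities as JSON.

## Known limitations

Apparent mortality conflates death with permanent tag failure; the
rates are upper bounds on true mortality.  Displacement thresholds are
operational defaults, not published constants — they are all exposed
in `seg_params()`/`fate_params()` and logged with every pipeline run.
Home-range areas depend on bandwidth and grid choices that published
analyses do not pin down, so absolute area values should be compared
across configurations, not across studies.  The schematic geography
makes simulated Iberian transit distances and Sahel overlaps only
order-of-magnitude analogues of the real ones.
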