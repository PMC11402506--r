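# vultrack

Life-stage segmentation, home ranges and survival from raptor GPS
telemetry.

## The problem

Juvenile trans-Saharan migrants — here, Egyptian vultures (*Neophron
percnopterus*) GPS-tagged as nestlings in Iberian breeding nuclei —
pass through a stereotyped sequence of early-life stages: a dependence
period wandering near the nest, a pre-migration transit of Iberia, a
fast Sahara crossing through the Strait of Gibraltar, one or more years
in the Sahel, and (for survivors) a spring return; a minority never
migrate and live year-round between two seasonal core areas in western
Iberia.  Conservation questions hinge on *where in this sequence birds
are lost*, which requires welding together telemetry quality control,
displacement-rule stage detection, kernel home ranges, transmitter
forensics and survival analysis.  vultrack implements that full
pipeline for movement ecologists working with Movebank-dialect
tracking tables, plus a stage-structured simulator so every step can be
validated with known ground truth.

## What it computes

* **QC + resampling** — drop fixes with HDOP/VDOP > 5, regularise to a
  30-min grid by nearest-fix selection (never interpolation).
* **Stage segmentation** — nest departure (first fix ≥ 200 m from the
  nest), natal departure (last territory fix followed by ≥ 60 days of
  absence and a ≥ 50 km directed journey within 7 days), southbound
  Gibraltar-gate crossing, Sahara span (30° N → 22.5° N), Sahel stay
  (13.3–22.5° N), sustained-northward return detection.
* **Home ranges** — Gaussian-kernel utilization distributions on an
  equal-area grid; 95% isopleth areas (km²), pairwise percentage
  overlaps, centroid distances, monthly ranges and core-occupancy
  calendars for residents; GeoJSON export.
* **Fate + survival** — classify each transmitter's end
  (stationary dead tag / abrupt silence assimilated to death /
  old-tag intermittency censored alive / alive); stage × nucleus × sex
  apparent-mortality table with deaths/duration rates truncated to two
  decimals, e.g. 14 deaths over a 631-day stage → 0.02, 5 over 28
  days → 0.17; Kaplan–Meier curves

  S(t) = ∏_{tᵢ ≤ t} (1 − dᵢ/nᵢ)

  and log-rank comparisons between sexes, nuclei and strategies.
* **Simulation** — Ornstein–Uhlenbeck + biased-correlated-random-walk
  cohorts (default: 32 birds, 17/10/5 across three nuclei, 16 M/16 F,
  3 residents, ~11-day desert crossings, ~10⁵ km² Sahel ranges,
  per-stage hazards, DOP noise, missed fixes, post-death stationary or
  silent tags) with full ground truth.

## Worked example

```r
library(vultrack)

cohort <- simulate_cohort(sim_config(), seed = 1)
pipe   <- run_pipeline(cohort, out_dir = "results/run1")

seg <- segment_stages(resample_track(qc_filter(cohort$tracks[["Gal03"]])))
seg
#> <vt_segmentation> Gal03 (migrant)
#>   dependence          2020-07-14 -> 2020-07-27 (  13.5 d)
#>   iberia_premigration 2020-07-27 -> 2020-08-14 (  18.3 d)
#>   sahara_crossing     2020-08-14 -> 2020-09-02 (  18.9 d)
#>   sahel_stay          2020-09-02 -> 2022-05-11 ( 615.9 d)
#>   return_migration    2022-05-11 -> 2022-05-26 (  14.9 d)
#>   iberia_postreturn   2022-05-26 -> 2022-08-02 (  68.5 d)

pipe
#> <vt_pipeline> 32 individuals
#>   strategies: migrant=25, non_migrant=2, undetermined=5
#> <vt_mortality_table> apparent mortality by stage
#>               stage deaths duration rate
#> 1        dependence      0       25 0.00
#> 2         migration      7       51 0.13
#> 3        sahel_stay     10      473 0.02
#> 4 iberia_postreturn      0       62 0.00
#> 5         residency      0      717 0.00
#> per-nucleus losses: Arribes 8/17 (47%); Galicia 6/10 (60%); Segovia 3/5 (60%)

pipe$km
#> <vt_km> n = 32, deaths = 17, censored = 15
#>   median survival: 669 days
```

Reading the output: this simulated cohort loses nobody during
dependence, seven birds during migration legs and ten in the Sahel —
but because migration lasts ~50 days against ~470 in the Sahel, the
per-day apparent-mortality rate is nearly an order of magnitude higher
on migration (0.13 vs 0.02).  `undetermined` marks birds lost before a
year of post-departure observation, which are never force-classified.
The report bundle (`stages.csv`, `kde.csv`, `kde.geojson`, `fates.csv`,
`mortality_table.csv`, `km_curves.csv`, `group_summary.csv`,
`overlaps.csv`, a run log and an md5 manifest) lands in `out_dir`.

Real data go in the same way: `run_pipeline(c("fixes.csv",
"deployments.csv"), out_dir = ...)` with Movebank-style columns
(`timestamp`, `location-long`, `location-lat`,
`individual-local-identifier`, optional `gps:hdop`, `gps:vdop`,
`tag-voltage`, `activity`).

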