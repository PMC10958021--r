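# HomingTrack

Analysis of GPS-based **translocation (displacement–release) experiments**
on terrestrial vertebrates, for movement ecologists who need a tested,
reproducible path from raw telemetry to homing statistics. Given a fix
table (one GPS position per row) and an event table (who was released
where, when, and where home is), the package:

1. **Classifies homing success** — an event is homed when a fix within a
   time window (default 180 d) lies at or inside a radius (default 1 km)
   of the capture site; homing time runs to the first such fix.
2. **Extracts homeward bearings** at distance rings around the release
   site (default 100 m, 500 m, 1 km, 5 km): the first fix at or beyond
   each ring, rotated so 0° points home.
3. **Tests directedness** with circular statistics: mean resultant vector
   (mean direction, r), Rayleigh test, a MANOVA-type test of the (cos θ,
   sin θ) mean against the origin — with a per-animal random intercept
   (lme4) for repeatedly translocated individuals — and cluster-bootstrap
   confidence arcs for significant distributions (minimum five bearings).
4. **Segments trajectories** by Lavielle penalized-contrast change-point
   analysis of the step-length series: dynamic-programming optimal
   partitions for each K (segment length ≥ 4, K ≤ 4, mean contrast), with
   K chosen by the normalized contrast-decrease rule (D(K) > 0.75).
5. **Summarizes segments** (average speed, straightness r of step
   headings, proportion of track) and correlates homing duration with the
   number of segments (Pearson).
6. **Simulates whole studies** with a three-phase biased correlated
   random walk (slow tortuous exploration → fast straight homing → slow
   arrival) and known ground truth, so every stage is verifiable without
   field data.

## Worked example

```r
library(HomingTrack)

# a synthetic 35-event study with known ground truth
study <- simulateStudy(studySpec(seed = 7))
res <- runPipeline(tracks = study$tracks, events = study$events,
                   config = pipelineConfig(frame = "planar", seed = 1))

str(res$summary[c("n_events", "n_homed", "percent_homed",
                  "median_homing_days")])
#> List of 4
#>  $ n_events          : int 35
#>  $ n_homed           : int 31
#>  $ percent_homed     : num 88.6
#>  $ median_homing_days: num 2.65

subset(res$ringStats, subset == "homed" & ring == 100,
       c(n, mean_angle_deg, r, p, status))
#>    n mean_angle_deg         r            p status
#> 5 31        1.90261 0.915077 2.595796e-12     ok
```

31 of 35 simulated events homed (88.6%), the median homing time was about
2.7 days, and the 31 homed events were strongly oriented toward home at
the 100 m ring (mean home-relative bearing ≈ 2°, r ≈ 0.92, mixed-model
directedness p < 1e-11). `res$segmentations` holds the per-track
segmentation (chosen K, boundaries, contrast curves) and
`res$segmentMetrics` the per-segment speed/straightness/proportion table;
with `outDir=` set, everything is also written as CSV plus a JSON summary
and run log.

The same analysis runs from the shell on CSV inputs:

```sh
Rscript inst/exec/homingtrack simulate --out study --seed 7
Rscript inst/exec/homingtrack analyze --telemetry study/telemetry.csv \
    --events study/events.csv --frame planar --out results
```

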