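# modaccess

Sociospatial accessibility analysis of physical activity facilities: who can
reach how many places to be active, by which mode of transport, and how that
varies with neighbourhood deprivation.

People in more deprived areas tend to have higher obesity rates and lower
physical activity. One environmental hypothesis is unequal *access* to
facilities — swimming pools, pitches, golf courses — and the answer can
differ by travel mode: a pattern visible on foot may reverse by car.
`modaccess` implements the full analysis chain for this question at desk
scale, with a synthetic-region generator standing in for proprietary
national datasets so every stage is testable with known ground truth.

## The method

1. **MET intensity classification.** Each facility type carries a typical
   energy cost in METs; standard cut-points grade facilities as light
   (< 3 METs), moderate (3–6) or vigorous (> 6). Duplicates collapse;
   unmatched hall-like types default to moderate; light facilities are
   excluded from counts by default.
2. **Cumulative-opportunity accessibility.** For zone *i*, mode *m* and
   threshold *t*, the measure is
   `A_im(t) = #{ facilities f : T_m(c_i, f) ≤ t }`,
   where `c_i` is the zone's population-weighted centroid and `T_m` the
   modal journey time: shortest-by-distance at 5 km/h (walk) or 14 km/h
   (cycle), fastest free-flow path with junction turn penalties (car), or
   scheduled timetable itineraries with ≤ 2 transfers, ≤ 30-minute
   access/egress walks and ≤ 5-minute waits in a 10:00–16:00 window (bus).
   Thresholds default to 20 and 30 minutes; counts are also reported per
   1,000 residents.
3. **Multilevel count models.** Within urban, small-town and rural strata,
   `count ~ quintile + offset(log population) + (1 | local authority)`,
   negative binomial (or Poisson when no overdispersion is found), giving
   rate ratios versus the most affluent quintile Q1 with 99% confidence
   intervals. Moran's I permutation tests screen responses and residuals
   for spatial autocorrelation over shared-border contiguity; a spatial lag
   covariate is included only when it reduces residual autocorrelation.

## Worked example

```r
library(modaccess)

region <- generate_region(region_config(seed = 42))
region
#> Synthetic region: 50 zones (rural=9, small town=6, urban=35), 207 facilities,
#>   66 road nodes, 97 bus trips

fac <- classify_facilities(region$facilities)
attr(fac, "counts")
#>    light moderate vigorous
#>       13      102       92

walk <- build_mode_graph(region$network, mode_config("walk"))
tt_walk <- travel_time_matrix("walk", walk,
                              region$zones[, c("zone_id", "x", "y")],
                              fac[, c("facility_id", "x", "y")])
acc  <- accessibility_table(tt_walk, fac, region$zones)
summ <- quintile_summary(acc, region$zones)
subset(summ, intensity == "moderate" & threshold == 20,
       c(label, n_zones, count_median, count_min, count_max, adjusted_median))
#>                label n_zones count_median count_min count_max adjusted_median
#> 1 Q1 (most affluent)      10          1.0         0         2        1.386957
#> 2                 Q2      10          1.5         0         4        1.926637
#> 3      Q3 (middling)      10          1.5         0         4        1.635603
#> 4                 Q4      10          3.0         1         6        3.533246
#> 5 Q5 (most deprived)      10          2.5         0         5        3.478319
```

The generator placed facilities with true rate ratios (1, 1.2, 1.4, 1.6,
1.8) for Q1..Q5, and the walkable-count medians rise accordingly from the
most affluent to the most deprived quintile. Modelling the counts:

```r
fit <- stratified_analysis(acc, region$zones, region$adjacency, seed = 42)
subset(fit$results, stratum == "urban" & intensity == "moderate" & threshold == 20)
#>  quintile    rr ci_low ci_high  family spatial_cov morans_i p_perm
#>         1 1.000  1.000    1.00 poisson       FALSE   -0.115   0.77
#>         2 0.977  0.258    3.71 poisson       FALSE   -0.115   0.77
#>         3 1.352  0.416    4.40 poisson       FALSE   -0.115   0.77
#>         4 2.623  0.886    7.76 poisson       FALSE   -0.115   0.77
#>         5 1.641  0.461    5.84 poisson       FALSE   -0.115   0.77
```

Rate ratios above 1 mean more accessible facilities than Q1; with only 35
urban zones the 99% intervals are wide, as expected at this scale. The
Poisson family was chosen here because no overdispersion was found; the
residual Moran's I is near zero with a non-significant permutation p.

The whole chain — simulate, classify, route all four modes, count, model —
runs as one call with cached stages and a hash manifest:

```r
run_pipeline(pipeline_config(region = region_config(seed = 42)), "out/")
```

A thin command-line wrapper is included at `inst/cli/modaccess.R`
(`simulate`, `classify`, `run-all`, ... with `--config`, `--seed`, `--out`).

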