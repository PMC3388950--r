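---
title: "Modelling multimodal access to physical activity facilities by area deprivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multimodal access to physical activity facilities by area deprivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the measure

Do people in more deprived neighbourhoods have better or worse access to
facilities for moderate and vigorous intensity physical activity, and does
the answer depend on how they travel? `modaccess` implements the full
analysis chain for this question as a reusable, testable pipeline:

1. **Facility intensity classification.** Each facility type carries a
   typical energy cost in METs (multiples of resting metabolic rate) from a
   curated lookup. Standard cut-points grade facilities: light below
   3 METs, moderate from 3 to 6 METs inclusive, vigorous above 6 METs. Golf
   courses, bowling greens and cricket squares are typical moderate
   facilities; swimming pools, athletics tracks, shinty and Gaelic football
   pitches are vigorous. Generic halls that cannot be matched to a single
   activity are conservatively assigned to the moderate class, on the
   assumption that activities such as badminton and table tennis dominate
   there. Light facilities are a tiny, heterogeneous class and are excluded
   from accessibility counts by default (a flag retains them). Duplicate
   records -- identical type at identical coordinates -- collapse to one.

2. **Cumulative-opportunity accessibility.** For each small-area zone the
   pipeline counts the moderate- and vigorous-intensity facilities reachable
   within 20 and 30 minutes from the zone's population-weighted centroid,
   separately by four modes: walking, cycling, car and bus. "Within" is read
   as an inclusive bound (a 20.0-minute journey counts at the 20-minute
   threshold); this convention is fixed so that counts are deterministic.

3. **Sociospatial models.** Counts are modelled on income-deprivation
   quintile (Q1, most affluent, is always the baseline) with a
   log-population offset and a local-authority random intercept, separately
   within urban, small-town and rural strata. Rate ratios are reported with
   99% confidence intervals -- a deliberately conservative level, because
   residual spatial autocorrelation typically remains even after spatial
   adjustment. Moran's I with a permutation test screens responses and
   residuals for spatial autocorrelation over shared-border contiguity.

## Network and journey-time model

Each mode routes over its own graph derived from one road network whose
links carry length (m), a road class (motorway, A, B, minor, local) and
per-mode permissions:

* **Walking and cycling** remove links the mode may not use (motorways) and
  follow the *shortest path by distance*, converted to time at a single
  average speed: 5 km/h walking, 14 km/h cycling. Time is deliberately not
  re-minimised: the route is the distance-shortest one, so cycle time is
  exactly 5/14 of walk time for every reachable pair -- a strong invariant
  the tests exploit.
* **Car** journeys assume uncongested conditions: each link is traversed at
  the free-flow speed of its road class (defaults, configurable: motorway
  112, A 80, B 64, minor 48, local 32 km/h), and left/right turning
  movements at junctions incur time penalties (defaults 6 s left, 9 s
  right; placeholders -- no test depends on them). A movement is straight
  when the signed bearing change is within ±30°; this threshold is not part
  of the scientific claim but must be fixed for determinism. Penalties
  participate in the search itself: routing runs over an arc-expanded graph
  whose vertices are directed road links, so a turn-heavy short route can
  lose to a longer turn-free one. Immediate U-turns are disallowed.
* **Bus** journeys are itineraries over a scheduled timetable: access walk
  to a stop, one or more boardings, interchange walks and waits, egress
  walk. Constraints follow inter-peak practice: at most 2 transfers, access
  and egress walks of at most 30 minutes each, waits of at most 5 minutes,
  and departures inside a 10:00--16:00 weekday window. The traveller is
  assumed to know the timetable and time their arrival at the first stop to
  the departure, so no initial wait is counted; the wait cap binds at
  transfer boardings. Walk-only journeys are never substituted -- the bus
  mode requires at least one boarding. The engine enumerates boarding
  events exactly (a small time-expanded dynamic programme), which makes the
  transfer and wait caps exact rather than heuristic.

Off-network points -- zone centroids and facilities -- attach to the
Euclidean-nearest node by a dummy link traversed at walking speed (walk and
bus), cycling speed, or local-street speed (car); nearest-node ties break by
lowest node id. Unreachable pairs are reported as `NA`, never as a large
sentinel time, so downstream counts cannot be corrupted.

The reported travel time for the matrix entry (zone, facility) is the
minimum total journey time under these rules. One interpretive choice
deserves flagging: whether the in-system bus time includes initial waiting
is ambiguous in common practice; here the journey clock starts when the
traveller leaves the origin, timed to the first departure, so pre-window
slack and first-stop waiting are excluded.

## The synthetic region generator

No public dataset reproduces the original national inputs, so the package
ships a generator whose outputs have known ground truth. It emulates:

* **Geometry:** zones are cells of a perturbed rectangular lattice in a
  planar metre-based coordinate system (10 km default extent), which makes
  border adjacency and centroids trivially computable and lets the tests
  verify the adjacency independently from the polygons.
* **Roads:** the lattice edges, carrying a road-class hierarchy; one
  interior line is a motorway (car-only), exercising the walk/cycle
  exclusion rule.
* **Population:** zone populations drawn uniformly in [500, 1000]; five
  household points per zone give a non-trivial population-weighted
  centroid.
* **Deprivation:** an i.i.d. Gaussian field smoothed over the adjacency
  graph, cut into five equal-count quintiles -- guaranteeing exactly five
  non-empty quintiles with positive spatial autocorrelation, as real
  small-area deprivation shows.
* **Urban--rural structure:** zones ranked by distance to the region's
  population-gravity core are assigned six-fold categories (large urban ...
  remote rural) in configured proportions (default 70/13/17
  urban/small-town/rural), collapsed to three strata; local authorities are
  contiguous column slabs.
* **Facilities:** an inhomogeneous Poisson point process whose intensity in
  a quintile-q zone is proportional to a configurable rate ratio
  (default 1, 1.2, 1.4, 1.6, 1.8 for Q1..Q5). These are the *true* rate
  ratios that downstream model-recovery tests check against. The absolute
  level (`facility_intensity`, default 3 expected facilities per Q1 zone)
  scales totals linearly. Facility types are drawn from the shipped MET
  lookup, so the light-exclusion rule is exercised end to end.
* **Timetable:** routes are shortest road paths between sampled endpoints
  with stops at alternate nodes; trips run at a 20-minute headway within
  the 10:00--16:00 window at 20 km/h in-vehicle speed plus a 15-second
  dwell per stop. Six routes is the default for a 10 km region.

One global seed governs everything through per-component sub-streams;
identical configurations produce byte-identical regions.

What the generator does *not* emulate: real street-network topology and
density gradients, island/mainland separation, congestion, topography,
route quality, fare or capacity effects, and any empirical relationship
between deprivation and facility provision (the gradient is a synthetic
stand-in for recovery testing, not an empirical claim). Passing tests
therefore demonstrate that the machinery is correct and calibrated, not
that any substantive result about real regions is reproduced.

## Statistical choices

* **Family choice.** Negative binomial is the default for overdispersed
  counts; the Poisson family is kept when a Poisson fit shows no
  overdispersion (Pearson dispersion ≤ 1) or when a likelihood-ratio test
  of NB against Poisson is not significant at 0.05.
* **Population adjustment.** Models use a log-population offset
  (equivalently, they model per-capita rates); descriptive tables report
  counts per 1,000 residents. The per-1,000 definition of the "adjusted"
  column is a documented package convention.
* **Random-intercept integration.** Poisson mixed models use adaptive
  Gauss--Hermite quadrature with 10 nodes (deterministic and accurate at
  small cluster counts). Negative binomial mixed models use the Laplace
  approximation: the theta-profiling loop in `lme4::glmer.nb` is unreliable
  when combined with higher-order quadrature (we observed order-of-magnitude
  theta errors), and Laplace estimates were accurate in recovery checks.
  Strata with a single local authority fall back to single-level fits, with
  a note in the result.
* **Spatial covariate.** When the pre-model Moran permutation test on the
  response is significant at 0.05, a response-dependent spatial lag
  covariate, `log(1 + mean response over border-sharing neighbours)`, is
  offered to the model -- and kept only if it reduces the absolute Moran's I
  of the Pearson residuals. The functional form is a documented assumption.
  Because residual autocorrelation can persist regardless, intervals are
  reported at the 99% level throughout.
* **Intervals.** Wald intervals on the log scale (the 0.995 normal
  quantile), exponentiated to rate ratios; deterministic, unlike profile
  intervals.
* **Permutation tests** default to 999 permutations with the seed recorded
  in the output; `p = (1 + #{permuted I ≥ observed}) / (1 + N)`, one-sided
  for positive autocorrelation.
* **Degenerate inputs.** Moran's I on constant values is an explicit error;
  empty quintiles yield explicit missing rows in summaries; strata with
  fewer than 30 zones are fitted but flagged `low_n`; model failures are
  recorded per combination, never silently dropped.

## Verification strategy and problem sizes

The test suite verifies each routing mode against exhaustive enumeration on
random graphs of up to 8 nodes (200 instances for walk/cycle/car, 40 toy
timetables for bus), the permutation test's type-I error on 500 null
datasets over a 50-zone lattice, rate-ratio recovery on 50 replicates of a
200-zone, 8-authority region with true rate ratios (1, 1.2, 1.4, 1.6, 1.8),
family-choice accuracy on 100 simulations under each truth, and end-to-end
determinism (hash-identical artifacts) of a full 30-zone pipeline run.
`scripts/acceptance.R` recomputes scaled versions of the same quantities
from scratch against the installed package. These sizes were chosen as the
smallest at which the Monte-Carlo error of each check is comfortably below
its acceptance margin.

## Known limitations

* The MET lookup is a curated ~40-type table, not a full activity
  compendium; unmatched non-hall types are reported as rejects rather than
  guessed.
* A facility carries a single intensity label, although real facilities
  host activities at many intensities.
* Travel times from a single centroid per zone understate within-zone
  variation, especially for large rural zones.
* The bus engine models scheduled times only: no reliability, capacity,
  fares, or multi-criteria trade-offs between time and transfers.
* Turn-penalty magnitudes and free-flow speeds are configuration, not
  estimates; analyses sensitive to them should vary them explicitly.
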