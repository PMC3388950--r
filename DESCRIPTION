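Package: modaccess
Title: Multimodal Accessibility of Physical Activity Facilities by Area Deprivation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sociospatial accessibility analysis of physical
    activity facilities. Classifies facilities by metabolic equivalent of
    task (MET) intensity, builds mode-specific routable networks (walk,
    cycle, car with junction turn penalties, bus with timetable
    constraints), computes cumulative-opportunity counts of facilities
    reachable from small-area population-weighted centroids within travel
    time thresholds, and models the counts against area income-deprivation
    quintiles with multilevel negative binomial or Poisson regression,
    including Moran's I permutation diagnostics for residual spatial
    autocorrelation. A synthetic-region generator with known ground truth
    supports end-to-end testing without proprietary national datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    lme4,
    MASS,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
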