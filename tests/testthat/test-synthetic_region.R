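test_that("config validation enforces the documented invariants", {
  expect_error(region_config(urban_fraction = 0.5, smalltown_fraction = 0.2,
                             rural_fraction = 0.2), "sum to 1")
  expect_error(region_config(n_zones = 3, n_local_authorities = 5),
               "n_zones")
  expect_error(region_config(facility_rate_ratios = c(1, 1, 1, 1, -1)),
               "positive")
  expect_error(region_config(service_window = c("16:00", "10:00")),
               "precede")
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- region_config(seed = 321, n_zones = 30, bus_routes = 2)
  b1 <- generate_region(cfg)
  b2 <- generate_region(cfg)
  expect_identical(b1$zones, b2$zones)
  expect_identical(b1$network, b2$network)
  expect_identical(b1$facilities, b2$facilities)
  expect_identical(b1$timetable, b2$timetable)
  expect_identical(b1$zone_polygons, b2$zone_polygons)
  # and a different seed changes the draw
  b3 <- generate_region(region_config(seed = 322, n_zones = 30,
                                      bus_routes = 2))
  expect_false(identical(b1$zones$population, b3$zones$population))
})

test_that("zones carry the documented attribute structure", {
  b <- generate_region(region_config(seed = 5, n_zones = 50))
  z <- b$zones
  expect_equal(nrow(z), 50L)
  expect_true(all(z$population >= 500 & z$population <= 1000))
  # quintiles take exactly the values 1-5, in equal counts
  expect_equal(sort(unique(z$quintile)), 1:5)
  expect_equal(as.integer(table(z$quintile)), rep(10L, 5))
  expect_true(all(z$urc6 %in% 1:6))
  expect_equal(unname(c("urban", "urban", "small town", "small town",
                        "rural", "rural")[z$urc6]), z$stratum)
  # stratum mix follows the configured fractions
  expect_equal(sum(z$stratum == "urban"), 35L)
  # local authorities: all present, zones nest within them
  expect_equal(length(unique(z$la_id)), 4L)
  # centroids fall inside the region
  expect_true(all(z$x >= 0 & z$x <= 10000))
})

test_that("zone adjacency equals border-sharing computed from the polygons", {
  b <- generate_region(region_config(seed = 9, n_zones = 24, bus_routes = 0))
  # independent reconstruction: two zones are adjacent iff their polygons
  # share two corner vertices (an edge of the perturbed lattice)
  ids <- b$zones$zone_id
  corner_keys <- lapply(b$zone_polygons[ids], function(p) {
    apply(round(p, 6), 1, paste, collapse = "|")
  })
  expected <- character(0)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i < j && length(intersect(corner_keys[[i]], corner_keys[[j]])) >= 2) {
      expected <- c(expected, paste(ids[i], ids[j]))
    }
  }
  got <- with(b$adjacency$edges,
              paste(pmin(a, b), pmax(a, b)))
  expect_setequal(got, expected)
  # symmetry is structural: each pair stored once, no self-pairs
  expect_false(any(b$adjacency$edges$a == b$adjacency$edges$b))
})

test_that("deprivation quintiles are spatially autocorrelated", {
  b <- generate_region(region_config(seed = 13, n_zones = 50, bus_routes = 0))
  i_obs <- morans_i(b$zones$quintile, b$adjacency)
  expect_gt(i_obs, 0.15)
})

test_that("flat rate ratios make facility counts independent of quintile", {
  # chi-square goodness of fit of per-quintile facility totals against the
  # zones-per-quintile expectation, over many seeds: p should look uniform
  pvals <- vapply(1:100, function(s) {
    cfg <- region_config(seed = s, n_zones = 30, bus_routes = 0,
                         facility_rate_ratios = c(1, 1, 1, 1, 1))
    b <- generate_region(cfg)
    tot <- table(factor(b$zones$quintile[match(b$facilities$zone_id,
                                               b$zones$zone_id)],
                        levels = 1:5))
    exp_p <- as.integer(table(factor(b$zones$quintile, levels = 1:5)))
    suppressWarnings(stats::chisq.test(as.integer(tot),
                                       p = exp_p / sum(exp_p)))$p.value
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.15)
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
})

test_that("facility totals scale linearly with the intensity parameter", {
  mean_total <- function(intensity) {
    mean(vapply(1:40, function(s) {
      nrow(generate_region(region_config(
        seed = s, n_zones = 30, bus_routes = 0,
        facility_rate_ratios = c(1, 1, 1, 1, 1),
        facility_intensity = intensity))$facilities)
    }, numeric(1)))
  }
  m1 <- mean_total(1); m3 <- mean_total(3)
  slope <- (m3 - m1) / 2
  # E[total] = intensity * n_zones when all rate ratios are 1
  expect_lt(abs(slope - 30) / 30, 0.05)
})

test_that("timetable respects the service window and follows the roads", {
  b <- generate_region(region_config(seed = 17, n_zones = 40, bus_routes = 4))
  tt <- b$timetable
  expect_gt(nrow(tt$trips), 0L)
  dep <- parse_clock(tt$stop_times$departure)
  expect_true(all(dep >= parse_clock("10:00") & dep < parse_clock("16:00")))
  # per-trip times strictly increase (constructor invariant, re-checked)
  for (tid in unique(tt$stop_times$trip_id)) {
    d <- dep[tt$stop_times$trip_id == tid]
    expect_true(all(diff(d) > 0))
  }
  # consecutive stops of each route are connected in the walk graph
  mg <- build_mode_graph(b$network, mode_config("bus"))
  for (rid in unique(tt$route_stops$route_id)) {
    sids <- tt$route_stops$stop_id[tt$route_stops$route_id == rid]
    nodes <- paste0("N", tt$stops$node_id[match(sids, tt$stops$stop_id)])
    d <- igraph::distances(mg$graph, v = nodes[-length(nodes)],
                           to = nodes[-1],
                           weights = igraph::E(mg$graph)$length_m)
    expect_true(all(is.finite(diag(d))))
  }
})

test_that("zero bus routes yield an empty timetable and zero bus counts", {
  b <- generate_region(region_config(seed = 3, n_zones = 12, bus_routes = 0))
  expect_equal(nrow(b$timetable$trips), 0L)
  cls <- classify_facilities(b$facilities)
  mg <- build_mode_graph(b$network, mode_config("bus"))
  m <- travel_time_matrix("bus", mg, b$zones[, c("zone_id", "x", "y")],
                          cls[, c("facility_id", "x", "y")],
                          timetable = b$timetable)
  expect_true(all(is.na(m$minutes)))
  acc <- accessibility_table(m, cls, b$zones)
  expect_true(all(acc$count == 0))
})

test_that("a region round-trips through the on-disk format", {
  b <- generate_region(region_config(seed = 29, n_zones = 20, bus_routes = 2))
  dir <- withr::local_tempdir()
  write_region(b, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "network.geojson", "zones.geojson", "zones.csv", "facilities.csv",
    "adjacency.csv", "truth.json")))))
  r <- read_region(dir)
  expect_equal(r$zones$zone_id, b$zones$zone_id)
  expect_equal(r$zones$population, b$zones$population)
  expect_equal(r$zones$quintile, b$zones$quintile)
  expect_equal(r$network$links$length_m, b$network$links$length_m,
               tolerance = 1e-8)
  expect_equal(r$network$links$road_class, b$network$links$road_class)
  expect_equal(r$facilities$facility_type, b$facilities$facility_type)
  expect_equal(r$adjacency$edges, b$adjacency$edges)
  expect_equal(r$timetable$stop_times$departure,
               b$timetable$stop_times$departure)
  expect_equal(unlist(r$truth$facility_rate_ratios),
               b$truth$facility_rate_ratios, ignore_attr = TRUE)
  # polygons survive with coordinates intact
  expect_equal(r$zone_polygons[["Z001"]], b$zone_polygons[["Z001"]],
               tolerance = 1e-8, ignore_attr = TRUE)
})
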