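# Toy instances for each routing mode, checked against definitions and the
# enumeration oracles (the large randomised oracle sweep lives in the
# acceptance tests).

two_route_net <- function(direct_len = 1200, via_len = c(500, 500)) {
  road_network(
    nodes = data.frame(node_id = 1:3, x = c(0, 500, 1000), y = c(0, 100, 0)),
    links = data.frame(from = c(1, 1, 2), to = c(3, 2, 3),
                       length_m = c(direct_len, via_len),
                       road_class = "minor", walk = TRUE, cycle = TRUE,
                       car = TRUE))
}

test_that("walking and cycling take the shortest route by distance", {
  net <- two_route_net()           # 1,200 m direct vs 1,000 m via
  walk <- build_mode_graph(net, mode_config("walk"))
  expect_equal(walk_cycle_time(walk, "N1", "N3"), 12)   # 1 km at 5 km/h
  cyc <- build_mode_graph(net, mode_config("cycle"))
  expect_equal(walk_cycle_time(cyc, "N1", "N3"), 60 / 14)
  expect_equal(walk_cycle_time(walk, "N2", "N2"), 0)
})

test_that("disconnected pairs are unreachable, not an error", {
  net <- road_network(
    nodes = data.frame(node_id = 1:4, x = c(0, 100, 5000, 5100), y = 0),
    links = data.frame(from = c(1, 3), to = c(2, 4), length_m = 100,
                       road_class = "minor", walk = TRUE, cycle = TRUE,
                       car = TRUE))
  walk <- build_mode_graph(net, mode_config("walk"))
  expect_true(is.na(walk_cycle_time(walk, "N1", "N3")))
  car <- build_mode_graph(net, mode_config("car"))
  expect_true(is.na(car_time(car, "N1", "N3")))
})

test_that("car routing trades distance against turn penalties in-search", {
  # U-shaped route: 1,500 m with two right turns; direct: 1,600 m, no turns
  net <- road_network(
    nodes = data.frame(node_id = 1:4,
                       x = c(0, 500, 500, 0), y = c(0, 0, -500, -500)),
    links = data.frame(from = c(1, 2, 3, 1), to = c(2, 3, 4, 4),
                       length_m = c(500, 500, 500, 1600),
                       road_class = "minor", walk = TRUE, cycle = TRUE,
                       car = TRUE))
  cfg <- mode_config("car", turn_penalty = c(left = 6, right = 60))
  mg <- build_mode_graph(net, cfg)
  got <- car_time(mg, "N1", "N4", cfg)
  # turn-free longer route wins: 1.6 km at 48 km/h = 2 min
  expect_equal(got, 1.6 / 48 * 60)
  expect_equal(got, oracle_car(mg, "N1", "N4", cfg))
  # with negligible penalties the shorter U-route wins
  cfg0 <- mode_config("car", turn_penalty = c(left = 0, right = 0))
  mg0 <- build_mode_graph(net, cfg0)
  expect_equal(car_time(mg0, "N1", "N4", cfg0), 1.5 / 48 * 60)
})

test_that("a single free-flow link yields length/speed minutes", {
  net <- line_network(1000, "A")
  cfg <- mode_config("car", freeflow = c(motorway = 112, A = 60, B = 64,
                                         minor = 48, local = 32))
  mg <- build_mode_graph(net, cfg)
  expect_equal(car_time(mg, "N1", "N2", cfg), 1.0)
})

# ---- bus ---------------------------------------------------------------

# chain network with stops at alternate nodes and one single-leg route per
# consecutive stop pair; departures chain with `gap_min` minutes slack.
# Stops sit 4 km apart so inter-stop walks blow the access/egress cap and
# journeys must ride every leg.
chain_bus_fixture <- function(n_routes = 3, gap_min = 2) {
  net <- line_network(rep(2000, 2 * n_routes))
  stop_nodes <- seq(1, 2 * n_routes + 1, by = 2)
  stops <- data.frame(stop_id = sprintf("S%d", seq_along(stop_nodes)),
                      node_id = stop_nodes,
                      x = net$nodes$x[stop_nodes], y = 0)
  rs <- list(); tr <- list(); st <- list()
  t0 <- 600
  for (r in seq_len(n_routes)) {
    rid <- sprintf("R%d", r)
    sid <- stops$stop_id[c(r, r + 1)]
    rs[[r]] <- data.frame(route_id = rid, stop_sequence = 1:2, stop_id = sid)
    tr[[r]] <- data.frame(trip_id = paste0(rid, "_T1"), route_id = rid)
    st[[r]] <- data.frame(trip_id = paste0(rid, "_T1"), stop_sequence = 1:2,
                          stop_id = sid,
                          departure = format_clock(c(t0, t0 + 10)))
    t0 <- t0 + 10 + gap_min
  }
  list(net = net,
       tt = bus_timetable(stops, do.call(rbind, rs), do.call(rbind, tr),
                          do.call(rbind, st)))
}

test_that("transfer cap: two transfers allowed, three are not", {
  fx <- chain_bus_fixture(n_routes = 3)   # 3 boardings needed end to end
  walk <- build_mode_graph(fx$net, mode_config("bus"))
  walk <- connect_point(walk, "O", 0, 0)
  walk <- connect_point(walk, "D", 12000, 0)
  got <- bus_time(fx$tt, walk, "O", "D", bus_config(max_transfers = 2))
  expect_equal(got, 34)   # 10:00 dep, 10:34 final arrival, zero-length walks
  expect_true(is.na(bus_time(fx$tt, walk, "O", "D",
                             bus_config(max_transfers = 1))))
  # four boardings stay unreachable at the cap of two transfers
  fx4 <- chain_bus_fixture(n_routes = 4)
  walk4 <- build_mode_graph(fx4$net, mode_config("bus"))
  walk4 <- connect_point(walk4, "O", 0, 0)
  walk4 <- connect_point(walk4, "D", 16000, 0)
  expect_true(is.na(bus_time(fx4$tt, walk4, "O", "D",
                             bus_config(max_transfers = 2))))
  expect_false(is.na(bus_time(fx4$tt, walk4, "O", "D",
                              bus_config(max_transfers = 3))))
})

test_that("an 8-minute transfer wait exceeds the 5-minute cap", {
  fx <- chain_bus_fixture(n_routes = 2, gap_min = 8)
  walk <- build_mode_graph(fx$net, mode_config("bus"))
  walk <- connect_point(walk, "O", 0, 0)
  walk <- connect_point(walk, "D", 8000, 0)
  expect_true(is.na(bus_time(fx$tt, walk, "O", "D", bus_config())))
  got <- bus_time(fx$tt, walk, "O", "D", bus_config(max_wait = 10))
  expect_equal(got, 28)   # 10 + 8 wait + 10
})

test_that("bus feasibility is monotone in each relaxed constraint", {
  for (s in 1:8) {
    net <- random_small_network(s)
    tt <- random_toy_timetable(s, net)
    walk <- build_mode_graph(net, mode_config("bus"))
    set.seed(s + 900)
    walk <- connect_point(walk, "O", runif(1, 0, 1000), runif(1, 0, 1000))
    walk <- connect_point(walk, "D", runif(1, 0, 1000), runif(1, 0, 1000))
    base <- bus_config()
    relaxed <- list(bus_config(max_transfers = 5),
                    bus_config(max_access_egress_walk = 60),
                    bus_config(max_wait = 15),
                    bus_config(max_transfers = 5,
                               max_access_egress_walk = 120, max_wait = 1e6))
    t0 <- bus_time(tt, walk, "O", "D", base)
    for (cfg in relaxed) {
      t1 <- bus_time(tt, walk, "O", "D", cfg)
      if (!is.na(t0)) {
        expect_false(is.na(t1))
        expect_lte(t1, t0 + 1e-9)
      }
    }
  }
})

test_that("bus journeys equal exhaustive itinerary enumeration on toys", {
  for (s in 1:10) {
    net <- random_small_network(s)
    tt <- random_toy_timetable(s, net)
    walk <- build_mode_graph(net, mode_config("bus"))
    set.seed(s + 300)
    walk <- connect_point(walk, "O", runif(1, 0, 1000), runif(1, 0, 1000))
    walk <- connect_point(walk, "D", runif(1, 0, 1000), runif(1, 0, 1000))
    cfg <- bus_config(max_wait = 20, max_access_egress_walk = 20)
    expect_equal(bus_time(tt, walk, "O", "D", cfg),
                 oracle_bus(tt, walk, "O", "D", cfg))
  }
})

test_that("travel time matrices have one entry per pair and are consistent", {
  net <- random_small_network(77)
  set.seed(77)
  zones <- data.frame(zone_id = c("Z1", "Z2", "Z3"),
                      x = runif(3, 0, 1000), y = runif(3, 0, 1000))
  fac <- data.frame(facility_id = c("F1", "F2", "F3", "F4"),
                    x = runif(4, 0, 1000), y = runif(4, 0, 1000))
  mg <- build_mode_graph(net, mode_config("walk"))
  m <- travel_time_matrix("walk", mg, zones, fac)
  expect_equal(nrow(m), 12L)
  expect_s3_class(m, "travel_time_matrix")
  # order invariance under permuted facilities
  m2 <- travel_time_matrix("walk", mg, zones, fac[c(3, 1, 4, 2), ])
  key <- function(d) d[order(d$zone_id, d$facility_id), ]
  expect_equal(key(m2), key(m), ignore_attr = TRUE)
  # entries match per-pair calls on pairwise-attached graphs
  for (i in seq_len(nrow(m))) {
    mgi <- connect_point(mg, "O", zones$x[zones$zone_id == m$zone_id[i]],
                         zones$y[zones$zone_id == m$zone_id[i]])
    mgi <- connect_point(mgi, "D", fac$x[fac$facility_id == m$facility_id[i]],
                         fac$y[fac$facility_id == m$facility_id[i]])
    expect_equal(m$minutes[i], walk_cycle_time(mgi, "O", "D"))
  }
})

test_that("bus matrix entries match single-pair journeys", {
  net <- random_small_network(55)
  tt <- random_toy_timetable(55, net)
  set.seed(55)
  zones <- data.frame(zone_id = c("Z1", "Z2"),
                      x = runif(2, 0, 1000), y = runif(2, 0, 1000))
  fac <- data.frame(facility_id = c("F1", "F2"),
                    x = runif(2, 0, 1000), y = runif(2, 0, 1000))
  mg <- build_mode_graph(net, mode_config("bus"))
  m <- travel_time_matrix("bus", mg, zones, fac, timetable = tt)
  for (i in seq_len(nrow(m))) {
    mgi <- connect_point(mg, "O", zones$x[zones$zone_id == m$zone_id[i]],
                         zones$y[zones$zone_id == m$zone_id[i]])
    mgi <- connect_point(mgi, "D", fac$x[fac$facility_id == m$facility_id[i]],
                         fac$y[fac$facility_id == m$facility_id[i]])
    expect_equal(m$minutes[i], bus_time(tt, mgi, "O", "D", bus_config()))
  }
})
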