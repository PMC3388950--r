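# Synthetic study region generator.
#
# Produces a complete region with known ground truth: a planar road network
# with a road-class hierarchy on a perturbed rectangular lattice, small-area
# zones (populations ~500-1000, spatially autocorrelated deprivation
# quintiles, urban / small town / rural mix, nested local authorities),
# physical-activity facilities placed with a controllable deprivation
# gradient (true rate ratios known), and a scheduled bus timetable in a
# weekday inter-peak service window. Everything is deterministic under one
# global seed, with per-component sub-streams derived from it.

#' Region generator configuration
#'
#' @param seed master seed governing all randomness.
#' @param n_zones number of zones (lattice cells).
#' @param n_local_authorities number of local authorities the zones nest in.
#' @param urban_fraction,smalltown_fraction,rural_fraction stratum mix;
#'   must sum to 1.
#' @param grid_extent_m width of the region in metres.
#' @param facility_rate_ratios named (`Q1`..`Q5`) positive reals: true rate
#'   ratio of facility density in each deprivation quintile versus Q1.
#'   Default `c(1, 1.2, 1.4, 1.6, 1.8)`: a moderate affluent-to-deprived
#'   gradient whose recovery downstream models are tested against.
#' @param facility_intensity mean facility count in a Q1 zone.
#' @param mean_population mean zone population; populations are drawn
#'   uniformly within +-250 of it (default 750, i.e. the 500--1000 range of
#'   roughly-equal small-area units).
#' @param bus_routes number of scheduled bus routes.
#' @param service_window clock interval of the timetable, default
#'   `c("10:00", "16:00")` (weekday inter-peak).
#' @param bus_speed in-vehicle bus speed in km/h, default 20.
#' @param headway_min minutes between successive trips of a route, default 20.
#' @return an object of class `region_config`.
#' @export
region_config <- function(seed = 1, n_zones = 50, n_local_authorities = 4,
                          urban_fraction = 0.70, smalltown_fraction = 0.13,
                          rural_fraction = 0.17, grid_extent_m = 10000,
                          facility_rate_ratios = c(Q1 = 1, Q2 = 1.2, Q3 = 1.4,
                                                   Q4 = 1.6, Q5 = 1.8),
                          facility_intensity = 3, mean_population = 750,
                          bus_routes = 6,
                          service_window = c("10:00", "16:00"),
                          bus_speed = 20, headway_min = 20) {
  fr <- c(urban_fraction, smalltown_fraction, rural_fraction)
  if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-9) {
    stop("stratum fractions must lie in [0,1] and sum to 1", call. = FALSE)
  }
  if (n_zones < n_local_authorities || n_local_authorities < 1) {
    stop("need n_zones >= n_local_authorities >= 1", call. = FALSE)
  }
  if (length(facility_rate_ratios) != 5L || any(facility_rate_ratios <= 0)) {
    stop("'facility_rate_ratios' must be 5 positive values (Q1..Q5)",
         call. = FALSE)
  }
  names(facility_rate_ratios) <- paste0("Q", 1:5)
  stop_if_not_scalar_number(grid_extent_m, "grid_extent_m", positive = TRUE)
  stop_if_not_scalar_number(facility_intensity, "facility_intensity",
                            positive = TRUE)
  stop_if_not_scalar_number(mean_population, "mean_population", positive = TRUE)
  w <- parse_clock(service_window)
  if (w[1] >= w[2]) stop("service window start must precede end", call. = FALSE)
  structure(list(seed = as.integer(seed), n_zones = as.integer(n_zones),
                 n_local_authorities = as.integer(n_local_authorities),
                 urban_fraction = urban_fraction,
                 smalltown_fraction = smalltown_fraction,
                 rural_fraction = rural_fraction,
                 grid_extent_m = grid_extent_m,
                 facility_rate_ratios = facility_rate_ratios,
                 facility_intensity = facility_intensity,
                 mean_population = mean_population,
                 bus_routes = as.integer(bus_routes),
                 service_window = service_window,
                 bus_speed = bus_speed, headway_min = headway_min),
            class = "region_config")
}

# Bilinear map of unit-square points into a quad (corners bl, br, tr, tl).
.quad_point <- function(u, v, q) {
  bl <- q[1, ]; br <- q[2, ]; tr <- q[3, ]; tl <- q[4, ]
  (1 - v) * ((1 - u) * bl + u * br) + v * ((1 - u) * tl + u * tr)
}

.shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Generate a synthetic study region
#'
#' @param config a [region_config()].
#' @return an object of class `region_bundle`: road network, zones (with
#'   populations, deprivation quintiles, urban-rural categories, local
#'   authorities and population-weighted centroids), zone polygons and
#'   shared-border adjacency, raw facility table, bus timetable, and the
#'   generating ground truth.
#' @export
generate_region <- function(config = region_config()) {
  stopifnot(inherits(config, "region_config"))
  n <- config$n_zones
  nc <- ceiling(sqrt(n))
  nr <- ceiling(n / nc)
  cs <- config$grid_extent_m / nc

  # perturbed lattice vertices; interior vertices jittered, boundary fixed so
  # the region outline stays rectangular
  vid <- function(r, c) r * (nc + 1L) + c + 1L   # r, c in 0..nr / 0..nc
  vx <- outer(0:nr, 0:nc, function(r, c) c * cs)
  vy <- outer(0:nr, 0:nc, function(r, c) r * cs)
  with_seed(substream_seed(config$seed, "geometry"), {
    for (r in 1:(nr - 1L)) for (c in 1:(nc - 1L)) {
      vx[r + 1L, c + 1L] <- vx[r + 1L, c + 1L] + runif(1, -0.15, 0.15) * cs
      vy[r + 1L, c + 1L] <- vy[r + 1L, c + 1L] + runif(1, -0.15, 0.15) * cs
    }
  })

  # zones: first n cells in row-major order
  cells <- data.frame(r = rep(0:(nr - 1L), each = nc), c = rep(0:(nc - 1L), nr))
  cells <- cells[seq_len(n), ]
  zone_ids <- sprintf("Z%03d", seq_len(n))
  polys <- vector("list", n)
  area <- numeric(n)
  for (i in seq_len(n)) {
    r <- cells$r[i]; c <- cells$c[i]
    q <- rbind(c(vx[r + 1L, c + 1L], vy[r + 1L, c + 1L]),         # bl
               c(vx[r + 1L, c + 2L], vy[r + 1L, c + 2L]),         # br
               c(vx[r + 2L, c + 2L], vy[r + 2L, c + 2L]),         # tr
               c(vx[r + 2L, c + 1L], vy[r + 2L, c + 1L]))         # tl
    polys[[i]] <- q
    area[i] <- .shoelace_area(q)
  }
  names(polys) <- zone_ids

  # rook adjacency among kept cells
  cell_index <- matrix(NA_integer_, nr, nc)
  for (i in seq_len(n)) cell_index[cells$r[i] + 1L, cells$c[i] + 1L] <- i
  ea <- character(0); eb <- character(0)
  for (i in seq_len(n)) {
    r <- cells$r[i] + 1L; c <- cells$c[i] + 1L
    if (c < nc && !is.na(cell_index[r, c + 1L])) {
      ea <- c(ea, zone_ids[i]); eb <- c(eb, zone_ids[cell_index[r, c + 1L]])
    }
    if (r < nr && !is.na(cell_index[r + 1L, c])) {
      ea <- c(ea, zone_ids[i]); eb <- c(eb, zone_ids[cell_index[r + 1L, c]])
    }
  }
  adjacency <- zone_adjacency(data.frame(a = ea, b = eb), zone_ids)

  # road network: lattice segments bounding the kept cells, deduplicated;
  # one interior horizontal line is a motorway (car only), the rest cycle
  # through the A / B / minor / local hierarchy
  mrow <- if (nr >= 3L) nr %/% 2L else -1L
  class_for <- function(orient, line) {
    if (orient == "h" && line == mrow) return("motorway")
    c("A", "minor", "B", "local")[(line %% 4L) + 1L]
  }
  ekey <- character(0)
  efrom <- integer(0); eto <- integer(0); ecls <- character(0)
  add_edge <- function(v1, v2, cls) {
    k <- paste(min(v1, v2), max(v1, v2))
    if (k %in% ekey) return()
    ekey <<- c(ekey, k); efrom <<- c(efrom, v1); eto <<- c(eto, v2)
    ecls <<- c(ecls, cls)
  }
  for (i in seq_len(n)) {
    r <- cells$r[i]; c <- cells$c[i]
    add_edge(vid(r, c), vid(r, c + 1L), class_for("h", r))          # bottom
    add_edge(vid(r + 1L, c), vid(r + 1L, c + 1L), class_for("h", r + 1L)) # top
    add_edge(vid(r, c), vid(r + 1L, c), class_for("v", c))          # left
    add_edge(vid(r, c + 1L), vid(r + 1L, c + 1L), class_for("v", c + 1L)) # right
  }
  used <- sort(unique(c(efrom, eto)))
  vr <- (used - 1L) %/% (nc + 1L); vc <- (used - 1L) %% (nc + 1L)
  nodes <- data.frame(node_id = used,
                      x = vx[cbind(vr + 1L, vc + 1L)],
                      y = vy[cbind(vr + 1L, vc + 1L)])
  nvr <- (efrom - 1L) %/% (nc + 1L); nvc <- (efrom - 1L) %% (nc + 1L)
  tvr <- (eto - 1L) %/% (nc + 1L); tvc <- (eto - 1L) %% (nc + 1L)
  len <- sqrt((vx[cbind(nvr + 1L, nvc + 1L)] - vx[cbind(tvr + 1L, tvc + 1L)])^2 +
                (vy[cbind(nvr + 1L, nvc + 1L)] - vy[cbind(tvr + 1L, tvc + 1L)])^2)
  links <- data.frame(from = efrom, to = eto, length_m = len,
                      road_class = ecls,
                      walk = ecls != "motorway", cycle = ecls != "motorway",
                      car = TRUE, stringsAsFactors = FALSE)
  network <- road_network(nodes, links)

  # reject configurations whose permitted networks are disconnected: every
  # zone centroid/facility must be able to reach the rest of the region
  for (m in c("walk", "car")) {
    mg <- build_mode_graph(network, mode_config(m))
    if (igraph::components(mg$graph)$no != 1L) {
      stop(sprintf("generated %s network is disconnected; adjust the config", m),
           call. = FALSE)
    }
  }

  # populations and household points -> population-weighted centroids
  pop <- with_seed(substream_seed(config$seed, "population"),
                   round(runif(n, config$mean_population - 250,
                               config$mean_population + 250)))
  centroids <- matrix(NA_real_, n, 2)
  households <- with_seed(substream_seed(config$seed, "households"), {
    lapply(seq_len(n), function(i) {
      u <- runif(5); v <- runif(5); w <- runif(5)
      pts <- t(vapply(1:5, function(k) .quad_point(u[k], v[k], polys[[i]]),
                      numeric(2)))
      data.frame(x = pts[, 1], y = pts[, 2],
                 population = w / sum(w) * pop[i])
    })
  })
  for (i in seq_len(n)) {
    centroids[i, ] <- population_weighted_centroid(households[[i]])
  }

  # deprivation quintiles: i.i.d. Gaussian field smoothed over the adjacency
  # graph, then cut into five equal-count groups (guarantees 5 non-empty
  # quintiles with positive spatial autocorrelation)
  nb <- neighbour_list(adjacency)
  depr <- with_seed(substream_seed(config$seed, "deprivation"), rnorm(n))
  names(depr) <- zone_ids
  for (it in 1:4) {
    depr <- vapply(zone_ids, function(z) {
      v <- nb[[z]]
      if (length(v) == 0L) depr[[z]] else 0.5 * depr[[z]] + 0.5 * mean(depr[v])
    }, numeric(1))
  }
  quintile <- ceiling(5 * rank(depr, ties.method = "first") / n)

  # urban-rural six-fold category: zones ordered by distance to the region
  # core (the population-gravity point), urban nearest, rural farthest; each
  # stratum split into its accessible/remote (or large/other) halves
  core <- c(sum(centroids[, 1] * pop), sum(centroids[, 2] * pop)) / sum(pop)
  d_core <- sqrt((centroids[, 1] - core[1])^2 + (centroids[, 2] - core[2])^2)
  ord <- order(d_core, -area, zone_ids)
  n_urban <- round(config$urban_fraction * n)
  n_small <- round(config$smalltown_fraction * n)
  urc6 <- integer(n)
  ranks <- match(seq_len(n), ord)  # rank of each zone by core distance
  urc6[ranks <= ceiling(n_urban / 2)] <- 1L
  urc6[ranks > ceiling(n_urban / 2) & ranks <= n_urban] <- 2L
  urc6[ranks > n_urban & ranks <= n_urban + ceiling(n_small / 2)] <- 3L
  urc6[ranks > n_urban + ceiling(n_small / 2) & ranks <= n_urban + n_small] <- 4L
  rest <- ranks > n_urban + n_small
  half_rural <- n_urban + n_small + ceiling(sum(rest) / 2)
  urc6[rest & ranks <= half_rural] <- 5L
  urc6[rest & ranks > half_rural] <- 6L
  stratum <- c("urban", "urban", "small town", "small town",
               "rural", "rural")[urc6]

  # local authorities: contiguous column slabs of roughly equal size
  ord_la <- order(cells$c, cells$r)
  la <- integer(n)
  la[ord_la] <- ceiling(config$n_local_authorities * seq_len(n) / n)
  la_id <- sprintf("LA%d", la)

  zones <- data.frame(zone_id = zone_ids, population = pop,
                      quintile = quintile, urc6 = urc6, stratum = stratum,
                      la_id = la_id, area_m2 = area,
                      x = centroids[, 1], y = centroids[, 2],
                      stringsAsFactors = FALSE)

  # facilities: inhomogeneous point process, intensity proportional to the
  # true quintile rate ratio; types drawn from the shipped MET lookup
  lk <- met_lookup()
  facilities <- with_seed(substream_seed(config$seed, "facilities"), {
    lam <- config$facility_intensity *
      unname(config$facility_rate_ratios[quintile])
    cnt <- rpois(n, lam)
    rows <- list()
    for (i in seq_len(n)) {
      if (cnt[i] == 0L) next
      u <- runif(cnt[i]); v <- runif(cnt[i])
      typ <- sample(lk$facility_type, cnt[i], replace = TRUE)
      pts <- t(vapply(seq_len(cnt[i]),
                      function(k) .quad_point(u[k], v[k], polys[[i]]),
                      numeric(2)))
      rows[[length(rows) + 1L]] <- data.frame(
        zone_id = zone_ids[i], facility_type = typ,
        x = pts[, 1], y = pts[, 2], stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      out <- do.call(rbind, rows)
      out$facility_id <- sprintf("F%03d", seq_len(nrow(out)))
      rownames(out) <- NULL
      out[, c("facility_id", "facility_type", "x", "y", "zone_id")]
    } else {
      data.frame(facility_id = character(0), facility_type = character(0),
                 x = numeric(0), y = numeric(0), zone_id = character(0))
    }
  })

  timetable <- generate_timetable(config, network)

  structure(list(config = config, network = network, zones = zones,
                 zone_polygons = polys, adjacency = adjacency,
                 facilities = facilities, timetable = timetable,
                 truth = list(seed = config$seed,
                              facility_rate_ratios = config$facility_rate_ratios,
                              facility_intensity = config$facility_intensity)),
            class = "region_bundle")
}

#' @export
print.region_bundle <- function(x, ...) {
  cat(sprintf(
    "Synthetic region: %d zones (%s), %d facilities, %d road nodes, %d bus trips\n",
    nrow(x$zones),
    paste(sprintf("%s=%d", names(table(x$zones$stratum)),
                  as.integer(table(x$zones$stratum))), collapse = ", "),
    nrow(x$facilities), nrow(x$network$nodes), nrow(x$timetable$trips)))
  invisible(x)
}

#' Generate a scheduled bus timetable over a road network
#'
#' Each route is the shortest road path between two sampled stops-candidate
#' nodes, with stops at every second node along it; trips depart at a fixed
#' headway, staggered across routes, with per-stop times from cumulative path
#' distance at the bus in-vehicle speed plus a short dwell. Only trips whose
#' departures all fall inside the service window are scheduled.
#'
#' @param config a [region_config()].
#' @param network a [road_network()] with walk-permitted (non-motorway) links
#'   for bus stops to sit on.
#' @return a [bus_timetable()]; empty when `config$bus_routes` is zero.
#' @export
generate_timetable <- function(config, network) {
  stopifnot(inherits(config, "region_config"),
            inherits(network, "road_network"))
  empty <- bus_timetable(
    stops = data.frame(stop_id = character(0), node_id = integer(0),
                       x = numeric(0), y = numeric(0)),
    route_stops = data.frame(route_id = character(0),
                             stop_sequence = integer(0),
                             stop_id = character(0)),
    trips = data.frame(trip_id = character(0), route_id = character(0)),
    stop_times = data.frame(trip_id = character(0), stop_sequence = integer(0),
                            stop_id = character(0), departure = character(0)))
  if (config$bus_routes == 0L) return(empty)

  mg <- build_mode_graph(network, mode_config("bus"))
  g <- mg$graph
  cand <- igraph::V(g)$name   # candidate stop nodes: walk-reachable junctions
  w <- parse_clock(config$service_window)

  stop_of_node <- character(0)   # node name -> stop id
  route_stops <- list(); trips <- list(); stop_times <- list()
  with_seed(substream_seed(config$seed, "timetable"), {
    for (r in seq_len(config$bus_routes)) {
      rid <- sprintf("R%d", r)
      # sample endpoints until a usefully long connected path is found
      path <- NULL
      for (try in 1:25) {
        ends <- sample(cand, 2)
        sp <- igraph::shortest_paths(g, from = ends[1], to = ends[2],
                                     weights = igraph::E(g)$length_m,
                                     output = "vpath")$vpath[[1]]
        if (length(sp) >= 4L) { path <- igraph::as_ids(sp); break }
      }
      if (is.null(path)) next
      idx <- unique(c(seq(1L, length(path), by = 2L), length(path)))
      pnodes <- path[idx]
      # cumulative distance along the full path at stop positions
      seg <- igraph::E(g, path = path)$length_m
      cum <- c(0, cumsum(seg))
      offs <- minutes_at_speed(cum[idx], config$bus_speed) +
        0.25 * (seq_along(idx) - 1L)          # dwell keeps times increasing
      for (nm in pnodes) {
        if (!nm %in% names(stop_of_node)) {
          sid <- sprintf("S%d", length(stop_of_node) + 1L)
          stop_of_node[[nm]] <- sid
        }
      }
      sids <- unname(stop_of_node[pnodes])
      route_stops[[rid]] <- data.frame(route_id = rid,
                                        stop_sequence = seq_along(sids),
                                        stop_id = sids,
                                        stringsAsFactors = FALSE)
      dep0 <- w[1] + (r - 1L) * 7
      k <- 0L
      while (TRUE) {
        start <- dep0 + k * config$headway_min
        if (start >= w[2]) break
        times <- start + offs
        if (max(times) < w[2]) {   # all departures inside the window
          tid <- sprintf("%s_T%d", rid, k + 1L)
          trips[[tid]] <- data.frame(trip_id = tid, route_id = rid,
                                      stringsAsFactors = FALSE)
          stop_times[[tid]] <- data.frame(
            trip_id = tid, stop_sequence = seq_along(sids), stop_id = sids,
            departure = format_clock(times), stringsAsFactors = FALSE)
        }
        k <- k + 1L
      }
    }
  })
  if (length(trips) == 0L) return(empty)
  vx <- igraph::V(g)$x; vy <- igraph::V(g)$y; vn <- igraph::V(g)$name
  node_names <- names(stop_of_node)
  stops <- data.frame(stop_id = unname(stop_of_node),
                      node_id = as.integer(sub("^N", "", node_names)),
                      x = vx[match(node_names, vn)],
                      y = vy[match(node_names, vn)],
                      stringsAsFactors = FALSE)
  bus_timetable(stops = stops,
                route_stops = do.call(rbind, c(route_stops,
                                               make.row.names = FALSE)),
                trips = do.call(rbind, c(trips, make.row.names = FALSE)),
                stop_times = do.call(rbind, c(stop_times,
                                              make.row.names = FALSE)))
}
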