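# Origin-destination journey times per mode.
#
# Walking and cycling follow the shortest path by DISTANCE, converted to time
# at the mode speed. Car journeys minimise link free-flow time plus junction
# turn penalties jointly (penalties inside the search, via the arc-expanded
# graph). Bus journeys are itineraries over a scheduled timetable -- access
# walk, boardings, in-vehicle legs, interchange walks and waits, egress walk
# -- under caps on transfers, access/egress walk time and waiting time.
# Unreachable pairs are reported as NA, never as a large number.

#' Bus journey constraints
#'
#' @param max_transfers maximum number of transfers between services
#'   (boardings minus one); default 2.
#' @param max_access_egress_walk cap in minutes on each of the access and
#'   egress walks; default 30.
#' @param max_wait cap in minutes on the wait at a boarding; default 5. The
#'   first boarding is timed (the traveller knows the timetable and arrives as
#'   the bus departs), so the cap binds at transfer boardings.
#' @param service_window clock interval (half-open) of departures considered,
#'   default `c("10:00", "16:00")`: a weekday inter-peak window.
#' @return an object of class `bus_config`.
#' @export
bus_config <- function(max_transfers = 2, max_access_egress_walk = 30,
                       max_wait = 5, service_window = c("10:00", "16:00")) {
  w <- parse_clock(service_window)
  if (max_transfers < 0 || max_access_egress_walk < 0 || max_wait < 0) {
    stop("bus constraints must be non-negative", call. = FALSE)
  }
  if (w[1] >= w[2]) stop("service window start must precede end", call. = FALSE)
  structure(list(max_transfers = as.integer(max_transfers),
                 max_access_egress_walk = max_access_egress_walk,
                 max_wait = max_wait, window_min = w,
                 service_window = service_window),
            class = "bus_config")
}

#' Construct a bus timetable
#'
#' @param stops data frame `stop_id`, `node_id`, `x`, `y`.
#' @param route_stops data frame `route_id`, `stop_sequence`, `stop_id`:
#'   the ordered stop sequence of each route.
#' @param trips data frame `trip_id`, `route_id`.
#' @param stop_times data frame `trip_id`, `stop_sequence`, `stop_id`,
#'   `departure` (`"HH:MM:SS"`) giving scheduled departures; times must
#'   strictly increase along each trip.
#' @return an object of class `bus_timetable`.
#' @export
bus_timetable <- function(stops, route_stops, trips, stop_times) {
  stopifnot(is.data.frame(stops), is.data.frame(route_stops),
            is.data.frame(trips), is.data.frame(stop_times))
  if (nrow(stop_times)) {
    if (!all(stop_times$stop_id %in% stops$stop_id)) {
      stop("stop_times references unknown stops", call. = FALSE)
    }
    st <- stop_times[order(stop_times$trip_id, stop_times$stop_sequence), ]
    dep <- parse_clock(st$departure)
    ok <- tapply(dep, st$trip_id, function(d) all(diff(d) > 0))
    if (!all(ok)) {
      stop("departure times must strictly increase along each trip",
           call. = FALSE)
    }
    stop_times <- st
    stop_times$dep_min <- dep
  } else {
    stop_times$dep_min <- numeric(0)
  }
  structure(list(stops = stops, route_stops = route_stops, trips = trips,
                 stop_times = stop_times),
            class = "bus_timetable")
}

#' @export
print.bus_timetable <- function(x, ...) {
  cat(sprintf("Bus timetable: %d stops, %d routes, %d trips, %d stop-times\n",
              nrow(x$stops), length(unique(x$route_stops$route_id)),
              nrow(x$trips), nrow(x$stop_times)))
  invisible(x)
}

.vertex_index <- function(g, name) {
  i <- match(name, igraph::V(g)$name)
  if (is.na(i)) stop(sprintf("vertex '%s' not in graph", name), call. = FALSE)
  i
}

#' Walking or cycling journey time
#'
#' Minimum-distance path between two attached vertices, converted to minutes
#' at the mode speed. Time is not independently minimised: the route is the
#' distance-shortest one.
#'
#' @param mg a walk or cycle `mode_graph` with both points attached.
#' @param origin,dest vertex names.
#' @return minutes, or `NA` if disconnected.
#' @export
walk_cycle_time <- function(mg, origin, dest) {
  stopifnot(inherits(mg, "mode_graph"), mg$mode %in% c("walk", "cycle"))
  if (origin == dest) return(0)
  d <- igraph::distances(mg$graph, v = .vertex_index(mg$graph, origin),
                         to = .vertex_index(mg$graph, dest),
                         weights = igraph::E(mg$graph)$length_m)[1, 1]
  if (!is.finite(d)) return(NA_real_)
  speed <- if (mg$mode == "walk") mg$config$walk_speed else mg$config$cycle_speed
  minutes_at_speed(d, speed)
}

#' Car journey time with turn penalties
#'
#' Minimises total travel time -- link free-flow times plus left/right turn
#' penalties at junctions -- over all routes, searching the arc-expanded graph
#' so that penalties influence route choice rather than being added post hoc.
#'
#' @param mg the car `mode_graph` with both points attached.
#' @param origin,dest vertex names.
#' @param config a [mode_config()]; defaults to the graph's.
#' @param arc_graph optional precomputed arc-expanded graph (built otherwise).
#' @return minutes, or `NA` if disconnected.
#' @export
car_time <- function(mg, origin, dest, config = mg$config, arc_graph = NULL) {
  stopifnot(inherits(mg, "mode_graph"))
  if (origin == dest) return(0)
  ag <- arc_graph %||% car_arc_graph(mg, config)
  d <- igraph::distances(ag, v = .vertex_index(ag, paste0("SRC:", origin)),
                         to = .vertex_index(ag, paste0("SNK:", dest)),
                         mode = "out", weights = igraph::E(ag)$weight)[1, 1]
  if (!is.finite(d)) NA_real_ else d
}

# ---- bus journey engine -----------------------------------------------------

# Precompute, per timetable + walk graph, everything destination-independent:
# stop-to-stop interchange walk times, boarding events within the service
# window, and for each alighting the set of feasible next boardings under the
# wait cap.
bus_prepare <- function(timetable, walk_mg, config) {
  stopifnot(inherits(timetable, "bus_timetable"),
            inherits(walk_mg, "mode_graph"),
            inherits(config, "bus_config"))
  g <- walk_mg$graph
  stops <- timetable$stops
  if (nrow(stops) == 0L || nrow(timetable$stop_times) == 0L) {
    return(structure(list(stops = stops, stop_verts = character(0),
                          SW = matrix(numeric(0), 0, 0), E = data.frame(),
                          alights = list(), TR = list(), config = config,
                          n_events = 0L),
                     class = "bus_prep"))
  }
  sv <- paste0("N", stops$node_id)
  if (!all(sv %in% igraph::V(g)$name)) {
    stop("every stop must map to a walk-graph node", call. = FALSE)
  }
  svi <- match(sv, igraph::V(g)$name)
  SW <- igraph::distances(g, v = svi, to = svi,
                          weights = igraph::E(g)$length_m)
  SW <- minutes_at_speed(SW, walk_mg$config$walk_speed)
  rownames(SW) <- colnames(SW) <- stops$stop_id

  st <- timetable$stop_times
  if (nrow(st) == 0L) {
    return(structure(list(stops = stops, stop_verts = sv, SW = SW,
                          E = data.frame(), alights = list(), TR = list(),
                          config = config, n_events = 0L),
                     class = "bus_prep"))
  }
  # per-trip ordered rows
  trips <- split(seq_len(nrow(st)), st$trip_id)
  # boarding events: any trip stop except the last, departing inside window
  eids <- integer(0); e_trip <- character(0); e_idx <- integer(0)
  e_stop <- character(0); e_dep <- numeric(0)
  for (tid in names(trips)) {
    rows <- trips[[tid]]
    n <- length(rows)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      dep <- st$dep_min[rows[i]]
      if (dep >= config$window_min[1] && dep < config$window_min[2]) {
        e_trip <- c(e_trip, tid); e_idx <- c(e_idx, i)
        e_stop <- c(e_stop, st$stop_id[rows[i]]); e_dep <- c(e_dep, dep)
      }
    }
  }
  E <- data.frame(eid = seq_along(e_trip), trip = e_trip, idx = e_idx,
                  stop = e_stop, dep = e_dep, stringsAsFactors = FALSE)
  # alightings per event: stops after the boarding index on the same trip
  si <- match(E$stop, stops$stop_id)  # unused guard: all stops known
  alights <- vector("list", nrow(E))
  TRmap <- new.env(parent = emptyenv())
  for (e in seq_len(nrow(E))) {
    rows <- trips[[E$trip[e]]]
    js <- (E$idx[e] + 1L):length(rows)
    alights[[e]] <- data.frame(stop = st$stop_id[rows[js]],
                               clock = st$dep_min[rows[js]],
                               akey = paste0(E$trip[e], "#", js),
                               stringsAsFactors = FALSE)
    for (k in seq_along(js)) {
      akey <- alights[[e]]$akey[k]
      if (!is.null(TRmap[[akey]])) next
      s_j <- alights[[e]]$stop[k]; c_j <- alights[[e]]$clock[k]
      arr <- c_j + SW[s_j, E$stop]
      feas <- which(is.finite(arr) & E$dep >= arr & E$dep <= arr + config$max_wait)
      TRmap[[akey]] <- feas
    }
  }
  structure(list(stops = stops, stop_verts = sv, SW = SW, E = E,
                 alights = alights, TR = TRmap, config = config,
                 n_events = nrow(E)),
            class = "bus_prep")
}

# Best completion clock (alighting clock + egress walk) from boarding each
# event, given per-stop egress walk times `eg` (Inf when over the cap or
# disconnected). Returns the vector over events for the full boarding budget.
bus_best_completion <- function(prep, eg) {
  nb <- prep$config$max_transfers + 1L
  nE <- prep$n_events
  if (nE == 0L) return(numeric(0))
  G <- matrix(Inf, nE, nb)
  for (e in seq_len(nE)) {
    al <- prep$alights[[e]]
    G[e, 1] <- min(al$clock + eg[al$stop], Inf)
  }
  if (nb > 1L) for (k in 2:nb) {
    for (e in seq_len(nE)) {
      best <- G[e, 1]
      al <- prep$alights[[e]]
      for (r in seq_len(nrow(al))) {
        nxt <- prep$TR[[al$akey[r]]]
        if (length(nxt)) best <- min(best, min(G[nxt, k - 1L]))
      }
      G[e, k] <- best
    }
  }
  G[, nb]
}

#' Bus journey time under timetable constraints
#'
#' Minimum total time -- access walk, in-vehicle legs, interchange walks and
#' waits, egress walk -- over all itineraries with at most
#' `max_transfers + 1` boardings, access and egress walks within
#' `max_access_egress_walk`, every transfer wait within `max_wait`, and all
#' boarded departures inside the service window. The traveller times arrival
#' at the first stop to the timetable, so no initial wait is counted.
#' Walk-only itineraries are not substituted: a bus journey requires at least
#' one boarding (unless origin equals destination).
#'
#' @param timetable a [bus_timetable()].
#' @param walk_mg the walk-mode graph with origin and destination attached.
#' @param origin,dest vertex names.
#' @param config a [bus_config()].
#' @param prep optional precomputed [bus_prepare()] engine state.
#' @return minutes, or `NA` if no feasible itinerary exists.
#' @export
bus_time <- function(timetable, walk_mg, origin, dest, config = bus_config(),
                     prep = NULL) {
  if (origin == dest) return(0)
  prep <- prep %||% bus_prepare(timetable, walk_mg, config)
  if (prep$n_events == 0L) return(NA_real_)
  g <- walk_mg$graph
  wlen <- igraph::E(g)$length_m
  svi <- match(prep$stop_verts, igraph::V(g)$name)
  ao <- minutes_at_speed(
    igraph::distances(g, v = .vertex_index(g, origin), to = svi,
                      weights = wlen)[1, ],
    walk_mg$config$walk_speed)
  eg <- minutes_at_speed(
    igraph::distances(g, v = .vertex_index(g, dest), to = svi,
                      weights = wlen)[1, ],
    walk_mg$config$walk_speed)
  names(ao) <- names(eg) <- prep$stops$stop_id
  ao[ao > config$max_access_egress_walk] <- Inf
  eg[eg > config$max_access_egress_walk] <- Inf
  comp <- bus_best_completion(prep, eg)
  tot <- ao[prep$E$stop] + (comp - prep$E$dep)
  best <- suppressWarnings(min(tot, na.rm = TRUE))
  if (!is.finite(best)) NA_real_ else unname(best)
}

# ---- travel time matrices ---------------------------------------------------

#' Origin-destination travel time matrix for one mode
#'
#' Attaches every zone centroid and facility to the mode graph by dummy links,
#' then computes one journey time per (zone, facility) pair: shortest-by-
#' distance for walk/cycle, fastest with turn penalties for car, constrained
#' timetable journeys for bus. Origins are the zones' population-weighted
#' centroids as supplied in `zones`.
#'
#' @param mode `"walk"`, `"cycle"`, `"car"` or `"bus"`.
#' @param mg the corresponding `mode_graph` (the walk graph for bus), without
#'   points attached.
#' @param zones data frame `zone_id`, `x`, `y` (centroid coordinates).
#' @param facilities data frame `facility_id`, `x`, `y`.
#' @param timetable a [bus_timetable()] (bus only).
#' @param bus_cfg a [bus_config()] (bus only).
#' @return a long data frame (`travel_time_matrix`) with columns `zone_id`,
#'   `facility_id`, `mode`, `minutes` (`NA` = unreachable).
#' @export
travel_time_matrix <- function(mode, mg, zones, facilities, timetable = NULL,
                               bus_cfg = bus_config()) {
  stopifnot(mode %in% c("walk", "cycle", "car", "bus"),
            inherits(mg, "mode_graph"),
            all(c("zone_id", "x", "y") %in% names(zones)),
            all(c("facility_id", "x", "y") %in% names(facilities)))
  zid <- as.character(zones$zone_id)
  fid <- as.character(facilities$facility_id)
  if (anyDuplicated(c(zid, fid))) {
    stop("zone and facility ids must be jointly unique", call. = FALSE)
  }
  mg <- connect_points(mg, data.frame(point_id = zid, x = zones$x, y = zones$y))
  mg <- connect_points(mg, data.frame(point_id = fid, x = facilities$x,
                                      y = facilities$y))
  g <- mg$graph

  if (mode %in% c("walk", "cycle")) {
    D <- igraph::distances(g, v = match(zid, igraph::V(g)$name),
                           to = match(fid, igraph::V(g)$name),
                           weights = igraph::E(g)$length_m)
    speed <- if (mode == "walk") mg$config$walk_speed else mg$config$cycle_speed
    M <- minutes_at_speed(D, speed)
  } else if (mode == "car") {
    ag <- car_arc_graph(mg)
    M <- igraph::distances(ag, v = match(paste0("SRC:", zid),
                                         igraph::V(ag)$name),
                           to = match(paste0("SNK:", fid),
                                      igraph::V(ag)$name),
                           mode = "out", weights = igraph::E(ag)$weight)
  } else {
    if (is.null(timetable)) stop("bus mode needs a timetable", call. = FALSE)
    prep <- bus_prepare(timetable, mg, bus_cfg)
    wlen <- igraph::E(g)$length_m
    svi <- match(prep$stop_verts, igraph::V(g)$name)
    speed <- mg$config$walk_speed
    AO <- minutes_at_speed(
      igraph::distances(g, v = match(zid, igraph::V(g)$name), to = svi,
                        weights = wlen), speed)
    EG <- minutes_at_speed(
      igraph::distances(g, v = match(fid, igraph::V(g)$name), to = svi,
                        weights = wlen), speed)
    AO[AO > bus_cfg$max_access_egress_walk] <- Inf
    EG[EG > bus_cfg$max_access_egress_walk] <- Inf
    colnames(AO) <- colnames(EG) <- prep$stops$stop_id
    M <- matrix(Inf, length(zid), length(fid))
    if (prep$n_events > 0L) {
      for (j in seq_along(fid)) {
        comp <- bus_best_completion(prep, EG[j, ])
        delta <- comp - prep$E$dep   # in-system time from first departure
        for (i in seq_along(zid)) {
          tot <- AO[i, prep$E$stop] + delta
          m <- suppressWarnings(min(tot, na.rm = TRUE))
          M[i, j] <- m
        }
      }
    }
  }
  M[!is.finite(M)] <- NA_real_
  out <- data.frame(
    zone_id = rep(zid, times = length(fid)),
    facility_id = rep(fid, each = length(zid)),
    mode = mode,
    minutes = as.vector(M),
    stringsAsFactors = FALSE)
  class(out) <- c("travel_time_matrix", "data.frame")
  out
}
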