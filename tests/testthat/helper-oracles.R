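# Exhaustive small-instance oracles, kept independent of the package's
# search implementations: path enumeration instead of Dijkstra, acos/cross
# trigonometry instead of atan2 bearings, recursive itinerary enumeration
# instead of the event DP.

path_edge_sum <- function(g, path, attr) {
  sum(vapply(seq_len(length(path) - 1L), function(i) {
    eid <- igraph::get_edge_ids(g, c(path[i], path[i + 1L]))
    igraph::edge_attr(g, attr, eid)
  }, numeric(1)))
}

all_simple_vpaths <- function(g, origin, dest) {
  lapply(igraph::all_simple_paths(g, from = origin, to = dest),
         igraph::as_ids)
}

oracle_walk_cycle <- function(mg, origin, dest) {
  if (origin == dest) return(0)
  paths <- all_simple_vpaths(mg$graph, origin, dest)
  if (!length(paths)) return(NA_real_)
  lens <- vapply(paths, function(p) path_edge_sum(mg$graph, p, "length_m"),
                 numeric(1))
  speed <- if (mg$mode == "walk") mg$config$walk_speed else
    mg$config$cycle_speed
  min(lens) / 1000 / speed * 60
}

# unsigned angle by acos, side by cross-product sign (>= 0 counts as left,
# matching the +180-degree convention for dead-ahead reversals)
oracle_turn_seconds <- function(coords, pen, thr) {
  tot <- 0
  if (nrow(coords) < 3L) return(tot)
  for (i in 2:(nrow(coords) - 1L)) {
    v1 <- coords[i, ] - coords[i - 1L, ]
    v2 <- coords[i + 1L, ] - coords[i, ]
    if (all(v1 == 0) || all(v2 == 0)) next
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    ang <- acos(min(max(cosang, -1), 1)) * 180 / pi
    if (ang <= thr) next
    cross <- v1[1] * v2[2] - v1[2] * v2[1]
    tot <- tot + if (cross >= 0) pen[["left"]] else pen[["right"]]
  }
  tot
}

oracle_car <- function(mg, origin, dest, config = mg$config) {
  if (origin == dest) return(0)
  g <- mg$graph
  paths <- all_simple_vpaths(g, origin, dest)
  if (!length(paths)) return(NA_real_)
  vx <- igraph::V(g)$x; vy <- igraph::V(g)$y; vn <- igraph::V(g)$name
  best <- Inf
  for (p in paths) {
    tt <- path_edge_sum(g, p, "time_min")
    coords <- cbind(vx[match(p, vn)], vy[match(p, vn)])
    tt <- tt + oracle_turn_seconds(coords, config$turn_penalty,
                                   config$straight_threshold_deg) / 60
    best <- min(best, tt)
  }
  best
}

# Direct itinerary enumeration from the journey definition: access walk,
# boardings within the window, in-vehicle legs, transfer walk + capped wait,
# egress walk; at most max_transfers + 1 boardings; no walk-only journeys.
oracle_bus <- function(timetable, walk_mg, origin, dest, config) {
  if (origin == dest) return(0)
  g <- walk_mg$graph
  speed <- walk_mg$config$walk_speed
  stops <- timetable$stops
  sv <- paste0("N", stops$node_id)
  svi <- match(sv, igraph::V(g)$name)
  wlen <- igraph::E(g)$length_m
  wm <- function(d) ifelse(is.finite(d), d / 1000 / speed * 60, Inf)
  access <- wm(igraph::distances(g, v = origin, to = svi, weights = wlen)[1, ])
  egress <- wm(igraph::distances(g, v = dest, to = svi, weights = wlen)[1, ])
  SW <- wm(igraph::distances(g, v = svi, to = svi, weights = wlen))
  names(access) <- names(egress) <- stops$stop_id
  rownames(SW) <- colnames(SW) <- stops$stop_id

  st <- timetable$stop_times
  if (nrow(st) == 0L) return(NA_real_)
  st <- st[order(st$trip_id, st$stop_sequence), ]
  dep <- modaccess::parse_clock(st$departure)
  trips <- split(seq_len(nrow(st)), st$trip_id)
  w <- config$window_min
  maxb <- config$max_transfers + 1L
  events <- list()
  for (tid in names(trips)) {
    rows <- trips[[tid]]
    if (length(rows) < 2L) next
    for (i in seq_len(length(rows) - 1L)) {
      if (dep[rows[i]] >= w[1] && dep[rows[i]] < w[2]) {
        events[[length(events) + 1L]] <- list(
          trip = tid, i = i, stop = st$stop_id[rows[i]], dep = dep[rows[i]])
      }
    }
  }
  if (!length(events)) return(NA_real_)
  best <- Inf
  rec <- function(ev, nboard, start_clock) {
    rows <- trips[[ev$trip]]
    for (j in (ev$i + 1L):length(rows)) {
      s_j <- st$stop_id[rows[j]]; c_j <- dep[rows[j]]
      if (egress[s_j] <= config$max_access_egress_walk) {
        best <<- min(best, c_j + egress[s_j] - start_clock)
      }
      if (nboard < maxb) {
        for (e2 in events) {
          wt <- e2$dep - (c_j + SW[s_j, e2$stop])
          if (is.finite(wt) && wt >= 0 && wt <= config$max_wait) {
            rec(e2, nboard + 1L, start_clock)
          }
        }
      }
    }
  }
  for (ev in events) {
    if (access[ev$stop] <= config$max_access_egress_walk) {
      rec(ev, 1L, ev$dep - access[ev$stop])
    }
  }
  if (is.finite(best)) best else NA_real_
}

# dense-matrix Moran's I for cross-checking the edge-list implementation
oracle_morans_dense <- function(values, adj) {
  n <- length(values)
  W <- matrix(0, n, n, dimnames = list(adj$zone_ids, adj$zone_ids))
  for (i in seq_len(nrow(adj$edges))) {
    W[adj$edges$a[i], adj$edges$b[i]] <- 1
    W[adj$edges$b[i], adj$edges$a[i]] <- 1
  }
  z <- values - mean(values)
  (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
}
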