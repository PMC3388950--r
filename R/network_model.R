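# Mode-specific routable networks.
#
# A road network is a planar graph of junction nodes and links carrying a
# length in metres, a road class and per-mode permissions. Each travel mode
# gets its own graph: links the mode may not use (e.g. motorways on foot) are
# removed, and link traversal times come from the mode speed (walk, cycle) or
# the free-flow speed of the road class (car). Off-network points -- zone
# centroids and facilities -- are attached by dummy links to the nearest node.

ROAD_CLASSES <- c("motorway", "A", "B", "minor", "local")

#' Construct a road network
#'
#' @param nodes data frame with columns `node_id` (unique), `x`, `y`
#'   (planar metres).
#' @param links data frame with columns `from`, `to` (node ids), `length_m`
#'   (> 0), `road_class` (one of motorway, A, B, minor, local) and logical
#'   permission columns `walk`, `cycle`, `car`.
#' @return an object of class `road_network`.
#' @export
road_network <- function(nodes, links) {
  stopifnot(is.data.frame(nodes), is.data.frame(links))
  if (!all(c("node_id", "x", "y") %in% names(nodes))) {
    stop("'nodes' needs columns node_id, x, y", call. = FALSE)
  }
  need <- c("from", "to", "length_m", "road_class", "walk", "cycle", "car")
  if (!all(need %in% names(links))) {
    stop("'links' needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(nodes$node_id)) stop("duplicate node ids", call. = FALSE)
  if (any(links$length_m <= 0)) stop("link lengths must be positive", call. = FALSE)
  if (!all(links$road_class %in% ROAD_CLASSES)) {
    stop("unknown road class; allowed: ", paste(ROAD_CLASSES, collapse = ", "),
         call. = FALSE)
  }
  if (!all(links$from %in% nodes$node_id) || !all(links$to %in% nodes$node_id)) {
    stop("link endpoints must exist in 'nodes'", call. = FALSE)
  }
  structure(list(nodes = nodes, links = links), class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("Road network: %d nodes, %d links (%s)\n",
              nrow(x$nodes), nrow(x$links),
              paste(sprintf("%s=%d", names(table(x$links$road_class)),
                            as.integer(table(x$links$road_class))),
                    collapse = ", ")))
  invisible(x)
}

#' Mode routing configuration
#'
#' Speeds and car junction penalties used to convert link lengths into travel
#' times. Walking and cycling use a single average speed (defaults 5 and
#' 14 km/h). Car links are traversed at the free-flow speed of their road
#' class (uncongested conditions); left/right turning movements at junctions
#' incur configurable time penalties, with a movement counted as straight when
#' the signed bearing change is within `straight_threshold_deg`.
#'
#' @param mode one of `"walk"`, `"cycle"`, `"car"`, `"bus"`.
#' @param walk_speed km/h, default 5.
#' @param cycle_speed km/h, default 14.
#' @param freeflow named km/h per road class.
#' @param turn_penalty named seconds for `left` and `right` movements.
#' @param straight_threshold_deg movements with |bearing change| at or below
#'   this are straight (no penalty). Default 30.
#' @return an object of class `mode_config`.
#' @export
mode_config <- function(mode = c("walk", "cycle", "car", "bus"),
                        walk_speed = 5, cycle_speed = 14,
                        freeflow = c(motorway = 112, A = 80, B = 64,
                                     minor = 48, local = 32),
                        turn_penalty = c(left = 6, right = 9),
                        straight_threshold_deg = 30) {
  mode <- match.arg(mode)
  stop_if_not_scalar_number(walk_speed, "walk_speed", positive = TRUE)
  stop_if_not_scalar_number(cycle_speed, "cycle_speed", positive = TRUE)
  if (!all(ROAD_CLASSES %in% names(freeflow)) || any(freeflow <= 0)) {
    stop("'freeflow' must name positive speeds for all road classes",
         call. = FALSE)
  }
  if (!all(c("left", "right") %in% names(turn_penalty)) || any(turn_penalty < 0)) {
    stop("'turn_penalty' must name non-negative 'left' and 'right' seconds",
         call. = FALSE)
  }
  structure(list(mode = mode, walk_speed = walk_speed,
                 cycle_speed = cycle_speed, freeflow = freeflow,
                 turn_penalty = turn_penalty,
                 straight_threshold_deg = straight_threshold_deg),
            class = "mode_config")
}

# Speed (km/h) used for a dummy link or a uniform-speed mode.
.mode_point_speed <- function(config) {
  switch(config$mode,
         walk = config$walk_speed,
         bus = config$walk_speed,
         cycle = config$cycle_speed,
         car = unname(config$freeflow[["local"]]))
}

minutes_at_speed <- function(length_m, speed_kmh) length_m / 1000 / speed_kmh * 60

#' Build the routable graph for one travel mode
#'
#' Filters links to those the mode may use (bus reuses the walking
#' permissions: the walk graph carries access, egress and interchange stages)
#' and attaches per-link distance and traversal time. Walk and cycle link
#' times are `length / speed`; car link times use the free-flow speed of the
#' road class.
#'
#' @param network a [road_network()].
#' @param config a [mode_config()].
#' @return an object of class `mode_graph` wrapping an undirected igraph whose
#'   vertices are road nodes (named `N<id>`).
#' @export
build_mode_graph <- function(network, config) {
  stopifnot(inherits(network, "road_network"), inherits(config, "mode_config"))
  perm_col <- if (config$mode == "bus") "walk" else config$mode
  links <- network$links[network$links[[perm_col]], , drop = FALSE]
  if (nrow(links) == 0L) {
    stop(sprintf("no links permit mode '%s'", config$mode), call. = FALSE)
  }
  time_min <- switch(config$mode,
    walk = minutes_at_speed(links$length_m, config$walk_speed),
    bus = minutes_at_speed(links$length_m, config$walk_speed),
    cycle = minutes_at_speed(links$length_m, config$cycle_speed),
    car = minutes_at_speed(links$length_m,
                           unname(config$freeflow[links$road_class])))
  nodes <- network$nodes
  vname <- paste0("N", nodes$node_id)
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("N", links$from), to = paste0("N", links$to),
               length_m = links$length_m, time_min = time_min,
               road_class = links$road_class, dummy = FALSE,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = vname, x = nodes$x, y = nodes$y,
                          kind = "node", stringsAsFactors = FALSE))
  structure(list(mode = config$mode, graph = g, config = config),
            class = "mode_graph")
}

#' @export
print.mode_graph <- function(x, ...) {
  np <- sum(igraph::V(x$graph)$kind == "point")
  cat(sprintf("Mode graph (%s): %d road nodes, %d links, %d attached point(s)\n",
              x$mode, sum(igraph::V(x$graph)$kind == "node"),
              igraph::ecount(x$graph), np))
  invisible(x)
}

#' Attach an off-network point by a dummy link
#'
#' Adds the point as a new vertex joined to the Euclidean-nearest road node by
#' a dummy link whose length is the Euclidean distance, traversed at walking
#' speed for the walk and bus graphs, at the mode speed for cycling, and at
#' the local-street free-flow speed for the car graph. Ties in nearest-node
#' distance are broken by the lowest node id.
#'
#' @param mg a [build_mode_graph()] result.
#' @param point_id unique vertex name for the point (must not collide with
#'   `N<id>` road-node names).
#' @param x,y planar coordinates in metres.
#' @return the `mode_graph` with one added vertex and dummy edge.
#' @export
connect_point <- function(mg, point_id, x, y) {
  stopifnot(inherits(mg, "mode_graph"))
  g <- mg$graph
  if (point_id %in% igraph::V(g)$name) {
    stop(sprintf("vertex '%s' already present", point_id), call. = FALSE)
  }
  is_node <- igraph::V(g)$kind == "node"
  nx <- igraph::V(g)$x[is_node]
  ny <- igraph::V(g)$y[is_node]
  nm <- igraph::V(g)$name[is_node]
  d2 <- (nx - x)^2 + (ny - y)^2
  # tie-break: lowest numeric node id
  ids <- as.numeric(sub("^N", "", nm))
  ord <- order(d2, ids)
  best <- ord[1L]
  dist <- sqrt(d2[best])
  speed <- .mode_point_speed(mg$config)
  g <- igraph::add_vertices(g, 1, name = point_id, x = x, y = y, kind = "point")
  g <- igraph::add_edges(g, c(point_id, nm[best]),
                         attr = list(length_m = dist,
                                     time_min = minutes_at_speed(dist, speed),
                                     road_class = "local", dummy = TRUE))
  mg$graph <- g
  mg
}

#' Attach many points at once
#'
#' @param mg a `mode_graph`.
#' @param points data frame with columns `point_id`, `x`, `y`.
#' @return the `mode_graph` with all points attached via [connect_point()].
#' @export
connect_points <- function(mg, points) {
  for (i in seq_len(nrow(points))) {
    mg <- connect_point(mg, points$point_id[i], points$x[i], points$y[i])
  }
  mg
}

#' Population-weighted centroid
#'
#' The weighted mean coordinate of a set of population points: the routing
#' origin that minimises total distance for the households of a zone.
#'
#' @param points data frame with columns `x`, `y`, `population`.
#' @return named numeric `c(x, y)`.
#' @export
population_weighted_centroid <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("x", "y", "population") %in% names(points)))
  w <- points$population
  if (any(w < 0) || sum(w) <= 0) {
    stop("total population must be positive", call. = FALSE)
  }
  c(x = sum(points$x * w) / sum(w), y = sum(points$y * w) / sum(w))
}

# Signed bearing change in degrees at p2 for the movement p1 -> p2 -> p3.
# Positive = left (counter-clockwise), negative = right; 180 maps to +180.
turn_angle_deg <- function(p1, p2, p3) {
  v1 <- p2 - p1; v2 <- p3 - p2
  atan2(v1[1] * v2[2] - v1[2] * v2[1], v1[1] * v2[1] + v1[2] * v2[2]) * 180 / pi
}

.movement_class <- function(angle, threshold) {
  if (abs(angle) <= threshold) "straight" else if (angle > 0) "left" else "right"
}

#' Turn penalties along a path
#'
#' Classifies each interior junction movement of a node path as straight, left
#' or right by signed bearing change (straight when within
#' `straight_threshold_deg`) and sums the configured left/right penalties.
#' Movements involving a zero-length segment carry no penalty.
#'
#' @param path character vector of vertex names in graph order.
#' @param mg the car `mode_graph`.
#' @param config a [mode_config()] providing `turn_penalty`.
#' @return penalty in seconds.
#' @export
apply_turn_penalties <- function(path, mg, config = mg$config) {
  g <- mg$graph
  if (length(path) < 3L) return(0)
  vx <- igraph::V(g)$x[match(path, igraph::V(g)$name)]
  vy <- igraph::V(g)$y[match(path, igraph::V(g)$name)]
  total <- 0
  for (i in 2:(length(path) - 1L)) {
    p1 <- c(vx[i - 1], vy[i - 1]); p2 <- c(vx[i], vy[i]); p3 <- c(vx[i + 1], vy[i + 1])
    if (all(p1 == p2) || all(p2 == p3)) next
    cls <- .movement_class(turn_angle_deg(p1, p2, p3),
                           config$straight_threshold_deg)
    if (cls != "straight") total <- total + config$turn_penalty[[cls]]
  }
  unname(total)
}

# Arc-expanded directed graph for car routing: vertices are directed arcs of
# the mode graph plus per-junction SRC/SNK terminals; an edge arc_a -> arc_b
# exists when head(a) == tail(b) and b is not the reversal of a, weighted by
# b's traversal time plus the turn penalty of the a->b movement. Shortest
# paths on this graph minimise link time + turn penalties jointly.
car_arc_graph <- function(mg, config = mg$config) {
  g <- mg$graph
  ed <- igraph::as_data_frame(g, what = "edges")
  vd <- igraph::as_data_frame(g, what = "vertices")
  n_arc <- 2L * nrow(ed)
  arc_u <- c(ed$from, ed$to)
  arc_v <- c(ed$to, ed$from)
  arc_t <- c(ed$time_min, ed$time_min)
  arc_id <- sprintf("A%d", seq_len(n_arc))
  rev_id <- c(sprintf("A%d", nrow(ed) + seq_len(nrow(ed))),
              sprintf("A%d", seq_len(nrow(ed))))
  vx <- setNames(vd$x, vd$name); vy <- setNames(vd$y, vd$name)

  from <- character(0); to <- character(0); w <- numeric(0)
  # transitions at each junction
  by_tail <- split(seq_len(n_arc), arc_u)
  thr <- config$straight_threshold_deg
  pen <- config$turn_penalty
  for (a in seq_len(n_arc)) {
    outs <- by_tail[[arc_v[a]]]
    if (is.null(outs)) next
    for (b in outs) {
      if (arc_id[b] == rev_id[a]) next  # no immediate U-turn
      p1 <- c(vx[[arc_u[a]]], vy[[arc_u[a]]])
      p2 <- c(vx[[arc_v[a]]], vy[[arc_v[a]]])
      p3 <- c(vx[[arc_v[b]]], vy[[arc_v[b]]])
      p <- 0
      if (!all(p1 == p2) && !all(p2 == p3)) {
        cls <- .movement_class(turn_angle_deg(p1, p2, p3), thr)
        if (cls != "straight") p <- pen[[cls]] / 60
      }
      from <- c(from, arc_id[a]); to <- c(to, arc_id[b])
      w <- c(w, arc_t[b] + p)
    }
  }
  # terminals: SRC:<v> feeds arcs leaving v (weight = arc time); arcs entering
  # v feed SNK:<v> (weight 0). SRC has no in-edges, SNK no out-edges, so
  # terminals cannot be used to bypass turn penalties mid-route.
  from <- c(from, paste0("SRC:", arc_u), arc_id)
  to <- c(to, arc_id, paste0("SNK:", arc_v))
  w <- c(w, arc_t, rep(0, n_arc))
  verts <- unique(c(arc_id, paste0("SRC:", vd$name), paste0("SNK:", vd$name)))
  ag <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w, stringsAsFactors = FALSE),
    directed = TRUE, vertices = data.frame(name = verts))
  ag
}
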