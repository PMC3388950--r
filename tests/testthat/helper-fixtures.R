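# Programmatic fixtures: small networks, random instances and toy timetables
# built in code at test time.

# straight west-east chain of nodes with given inter-node lengths
line_network <- function(lengths, classes = rep("minor", length(lengths))) {
  n <- length(lengths) + 1L
  road_network(
    nodes = data.frame(node_id = seq_len(n), x = c(0, cumsum(lengths)), y = 0),
    links = data.frame(from = seq_len(n - 1L), to = 2:n, length_m = lengths,
                       road_class = classes, walk = classes != "motorway",
                       cycle = classes != "motorway", car = TRUE))
}

# random connected planar-ish network with <= n_max nodes, all modes allowed
random_small_network <- function(seed, n_max = 8L) {
  set.seed(seed)
  n <- sample(4:n_max, 1)
  repeat {
    x <- runif(n, 0, 1000); y <- runif(n, 0, 1000)
    # reject near-coincident nodes (zero-length links break the length > 0
    # invariant and make bearings meaningless)
    if (min(dist(cbind(x, y))) > 20) break
  }
  # random spanning tree + extra edges
  from <- integer(0); to <- integer(0)
  for (v in 2:n) { from <- c(from, sample(seq_len(v - 1L), 1)); to <- c(to, v) }
  n_extra <- sample(0:3, 1)
  for (k in seq_len(n_extra)) {
    pr <- sample(n, 2)
    key <- paste(pmin(from, to), pmax(from, to))
    if (!paste(min(pr), max(pr)) %in% key) {
      from <- c(from, pr[1]); to <- c(to, pr[2])
    }
  }
  len <- sqrt((x[from] - x[to])^2 + (y[from] - y[to])^2)
  cls <- sample(c("A", "B", "minor", "local"), length(from), replace = TRUE)
  road_network(
    nodes = data.frame(node_id = seq_len(n), x = x, y = y),
    links = data.frame(from = from, to = to, length_m = len,
                       road_class = cls, walk = TRUE, cycle = TRUE,
                       car = TRUE))
}

# random toy timetable over a network's nodes: a few short routes with
# departures inside the service window
random_toy_timetable <- function(seed, network, n_routes = 2L) {
  set.seed(seed + 5000)
  node_ids <- network$nodes$node_id
  n_stops <- min(length(node_ids), sample(4:6, 1))
  stop_nodes <- sample(node_ids, n_stops)
  stops <- data.frame(stop_id = sprintf("S%d", seq_len(n_stops)),
                      node_id = stop_nodes,
                      x = network$nodes$x[match(stop_nodes,
                                                network$nodes$node_id)],
                      y = network$nodes$y[match(stop_nodes,
                                                network$nodes$node_id)])
  route_stops <- list(); trips <- list(); stop_times <- list()
  for (r in seq_len(n_routes)) {
    rid <- sprintf("R%d", r)
    k <- sample(3:min(5, n_stops), 1)
    seqn <- sample(stops$stop_id, k)
    route_stops[[r]] <- data.frame(route_id = rid, stop_sequence = seq_len(k),
                                   stop_id = seqn)
    for (d in seq_len(sample(2:4, 1))) {
      tid <- sprintf("%s_T%d", rid, d)
      start <- 600 + runif(1, 0, 300)            # within 10:00-16:00
      times <- start + cumsum(c(0, runif(k - 1, 2, 8)))
      trips[[tid]] <- data.frame(trip_id = tid, route_id = rid)
      stop_times[[tid]] <- data.frame(trip_id = tid, stop_sequence = seq_len(k),
                                      stop_id = seqn,
                                      departure = format_clock(times))
    }
  }
  bus_timetable(stops, do.call(rbind, route_stops), do.call(rbind, trips),
                do.call(rbind, stop_times))
}

# rook-contiguity adjacency over an nr x nc lattice of zones
lattice_adjacency <- function(nr, nc) {
  ids <- sprintf("Z%d", seq_len(nr * nc))
  a <- character(0); b <- character(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    i <- (r - 1L) * nc + c
    if (c < nc) { a <- c(a, ids[i]); b <- c(b, ids[i + 1L]) }
    if (r < nr) { a <- c(a, ids[i]); b <- c(b, ids[i + nc]) }
  }
  zone_adjacency(data.frame(a = a, b = b), ids)
}

# simulate one GLMM recovery data set: known quintile rate ratios, nested
# local authorities, log-population offset
sim_recovery_data <- function(seed, n_zones = 200, n_la = 8,
                              rr = c(1, 1.2, 1.4, 1.6, 1.8),
                              base_rate = 20, theta = 5, la_sd = 0.2) {
  set.seed(seed)
  q <- rep(1:5, length.out = n_zones)
  la <- rep(seq_len(n_la), length.out = n_zones)
  pop <- round(runif(n_zones, 500, 1000))
  u <- rnorm(n_la, 0, la_sd)
  mu <- exp(log(base_rate) + log(rr[q]) + u[la] + log(pop / 750))
  cnt <- if (is.finite(theta)) rnbinom(n_zones, size = theta, mu = mu) else
    rpois(n_zones, mu)
  data.frame(count = cnt, quintile = q, population = pop,
             la_id = sprintf("LA%d", la))
}
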