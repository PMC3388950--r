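# On-disk region format.
#
# A region directory holds: network.geojson (LineString features with
# length_m, road_class and per-mode permissions), zones.geojson (polygons)
# plus zones.csv (attribute table), facilities.csv, adjacency.csv, truth.json
# and a GTFS-subset timetable (stops.txt, routes.txt, trips.txt,
# stop_times.txt with HH:MM:SS times).

.feature <- function(geometry_type, coords, props) {
  list(type = "Feature",
       geometry = list(type = geometry_type, coordinates = coords),
       properties = props)
}

.write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = 10), path)
}

#' Write a region bundle to a directory
#'
#' @param bundle a [generate_region()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_region <- function(bundle, dir) {
  stopifnot(inherits(bundle, "region_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  net <- bundle$network
  nx <- setNames(net$nodes$x, net$nodes$node_id)
  ny <- setNames(net$nodes$y, net$nodes$node_id)
  feats <- lapply(seq_len(nrow(net$links)), function(i) {
    l <- net$links[i, ]
    .feature("LineString",
             list(c(nx[[as.character(l$from)]], ny[[as.character(l$from)]]),
                  c(nx[[as.character(l$to)]], ny[[as.character(l$to)]])),
             list(from = l$from, to = l$to, length_m = l$length_m,
                  road_class = l$road_class, walk = l$walk, cycle = l$cycle,
                  car = l$car))
  })
  .write_geojson(feats, file.path(dir, "network.geojson"))

  zfeats <- lapply(seq_len(nrow(bundle$zones)), function(i) {
    zid <- bundle$zones$zone_id[i]
    p <- bundle$zone_polygons[[zid]]
    ring <- lapply(c(seq_len(nrow(p)), 1L), function(k) c(p[k, 1], p[k, 2]))
    .feature("Polygon", list(ring), list(zone_id = zid))
  })
  .write_geojson(zfeats, file.path(dir, "zones.geojson"))

  write.csv(bundle$zones, file.path(dir, "zones.csv"), row.names = FALSE)
  fac <- bundle$facilities
  names(fac)[names(fac) == "facility_type"] <- "type"
  write.csv(fac, file.path(dir, "facilities.csv"), row.names = FALSE)
  write.csv(bundle$adjacency$edges, file.path(dir, "adjacency.csv"),
            row.names = FALSE)
  writeLines(jsonlite::toJSON(bundle$truth, auto_unbox = TRUE, digits = NA),
             file.path(dir, "truth.json"))

  gdir <- file.path(dir, "gtfs")
  dir.create(gdir, showWarnings = FALSE)
  tt <- bundle$timetable
  write.csv(tt$stops, file.path(gdir, "stops.txt"), row.names = FALSE)
  write.csv(data.frame(route_id = unique(tt$route_stops$route_id)),
            file.path(gdir, "routes.txt"), row.names = FALSE)
  write.csv(tt$trips, file.path(gdir, "trips.txt"), row.names = FALSE)
  st <- tt$stop_times
  st$dep_min <- NULL
  write.csv(st, file.path(gdir, "stop_times.txt"), row.names = FALSE)
  # route stop sequences (not part of core GTFS; needed to rebuild routes)
  write.csv(tt$route_stops, file.path(gdir, "route_stops.txt"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a road network from GeoJSON
#'
#' Expects LineString features with properties `from`, `to`, `length_m`,
#' `road_class`, `walk`, `cycle`, `car` (as written by [write_region()]).
#'
#' @param path path to a network GeoJSON file.
#' @return a [road_network()].
#' @export
read_network_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  links <- do.call(rbind, lapply(fc$features, function(f) {
    p <- f$properties
    data.frame(from = p$from, to = p$to, length_m = p$length_m,
               road_class = p$road_class, walk = p$walk, cycle = p$cycle,
               car = p$car, stringsAsFactors = FALSE)
  }))
  coords <- list()
  for (f in fc$features) {
    p <- f$properties
    cc <- f$geometry$coordinates
    coords[[as.character(p$from)]] <- unlist(cc[[1]])
    coords[[as.character(p$to)]] <- unlist(cc[[2]])
  }
  ids <- sort(as.integer(names(coords)))
  nodes <- data.frame(node_id = ids,
                      x = vapply(as.character(ids),
                                 function(k) coords[[k]][1], numeric(1)),
                      y = vapply(as.character(ids),
                                 function(k) coords[[k]][2], numeric(1)))
  rownames(nodes) <- NULL
  road_network(nodes, links)
}

#' Read a region directory back into a bundle
#'
#' @param dir a directory written by [write_region()].
#' @return a `region_bundle` (without the generating config; `truth` holds
#'   the recorded seed and rate ratios).
#' @export
read_region <- function(dir) {
  network <- read_network_geojson(file.path(dir, "network.geojson"))
  zones <- read.csv(file.path(dir, "zones.csv"), stringsAsFactors = FALSE)
  fac <- read.csv(file.path(dir, "facilities.csv"), stringsAsFactors = FALSE)
  names(fac)[names(fac) == "type"] <- "facility_type"
  adj_edges <- read.csv(file.path(dir, "adjacency.csv"),
                        stringsAsFactors = FALSE)
  adjacency <- zone_adjacency(adj_edges, zones$zone_id)
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))

  zj <- jsonlite::fromJSON(file.path(dir, "zones.geojson"),
                           simplifyVector = FALSE)
  polys <- list()
  for (f in zj$features) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, unlist))
    polys[[f$properties$zone_id]] <- m[-nrow(m), , drop = FALSE]
  }

  gdir <- file.path(dir, "gtfs")
  stops <- read.csv(file.path(gdir, "stops.txt"), stringsAsFactors = FALSE)
  trips <- read.csv(file.path(gdir, "trips.txt"), stringsAsFactors = FALSE)
  stop_times <- read.csv(file.path(gdir, "stop_times.txt"),
                         stringsAsFactors = FALSE)
  route_stops <- read.csv(file.path(gdir, "route_stops.txt"),
                          stringsAsFactors = FALSE)
  timetable <- bus_timetable(stops, route_stops, trips, stop_times)

  structure(list(config = NULL, network = network, zones = zones,
                 zone_polygons = polys, adjacency = adjacency,
                 facilities = fac, timetable = timetable, truth = truth),
            class = "region_bundle")
}
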