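# Plain-text exchange formats: CSV tables, ESRI-style ASCII grids for the
# density raster, and minimal GeoJSON FeatureCollections (Point/LineString)
# written via jsonlite.

#' Write / read a density raster as an ASCII grid
#'
#' ESRI ASCII-grid layout (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`, then rows top-to-bottom). Row 1 of the region's
#' density matrix is the southernmost row, so rows are flipped on write and
#' restored on read.
#'
#' @param region A `region`.
#' @param path Output file.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a `region` (total population recomputed from the raster).
#' @export
write_ascii_grid <- function(region, path) {
  dens <- region$density
  hdr <- c(
    sprintf("ncols %d", ncol(dens)),
    sprintf("nrows %d", nrow(dens)),
    "xllcorner 0", "yllcorner 0",
    sprintf("cellsize %.10g", region$cell_km),
    "NODATA_value -9999"
  )
  rows <- apply(dens[rev(seq_len(nrow(dens))), , drop = FALSE], 1,
                function(r) paste(formatC(r, format = "g", digits = 10), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- val("ncols"); nrows <- val("nrows"); cell <- val("cellsize")
  body <- lines[-(1:6)]
  dens <- do.call(rbind, lapply(body, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  stopifnot(nrow(dens) == nrows, ncol(dens) == ncols)
  dens <- dens[rev(seq_len(nrows)), , drop = FALSE]
  dens[dens == -9999] <- NA
  structure(
    list(width_km = ncols * cell, height_km = nrows * cell, cell_km = cell,
         density = dens, total_population = sum(dens, na.rm = TRUE) * cell^2),
    class = "region"
  )
}

#' Write a density raster as a CSV grid
#'
#' Row-major grid with a two-line comment header recording the cell size and
#' origin; row 1 is the southernmost row (y = 0 edge).
#'
#' @param region A `region`.
#' @param path Output file.
#' @export
write_density_csv <- function(region, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cell_km=%.10g origin=0,0 total_population=%.10g",
                     region$cell_km, region$total_population), con)
  utils::write.table(region$density, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_density_csv
#' @export
read_density_csv <- function(path) {
  first <- readLines(path, n = 1)
  cell <- as.numeric(sub(".*cell_km=([0-9.eE+-]+).*", "\\1", first))
  dens <- as.matrix(utils::read.table(path, sep = ",", skip = 1, header = FALSE))
  dimnames(dens) <- NULL
  structure(
    list(width_km = ncol(dens) * cell, height_km = nrow(dens) * cell,
         cell_km = cell, density = dens,
         total_population = sum(dens) * cell^2),
    class = "region"
  )
}

geojson_feature <- function(geometry_type, coords, properties) {
  list(type = "Feature",
       geometry = list(type = geometry_type, coordinates = coords),
       properties = properties)
}

write_feature_collection <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Write stations, events or the road network as GeoJSON
#'
#' Planar coordinates in km are written as GeoJSON positions as-is (the
#' synthetic geography has no CRS). Stations become Point features with a
#' `service` property; events Point features with `cell`, `local_density` and
#' any response columns present; network edges LineString features with a
#' `speed_kmh` property.
#'
#' @param stations,events,network,records Pipeline objects.
#' @param path Output file.
#' @name geojson-output
NULL

#' @rdname geojson-output
#' @export
write_stations_geojson <- function(stations, path) {
  feats <- lapply(seq_len(nrow(stations)), function(i) {
    geojson_feature("Point", c(stations$x_km[i], stations$y_km[i]),
                    list(id = stations$id[i], service = stations$service[i],
                         node = stations$node[i],
                         snap_distance_km = stations$snap_distance_km[i]))
  })
  write_feature_collection(feats, path)
}

#' @rdname geojson-output
#' @export
read_stations_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  rows <- lapply(fc$features, function(f) {
    data.frame(
      id = f$properties$id, service = f$properties$service,
      x_km = f$geometry$coordinates[[1]], y_km = f$geometry$coordinates[[2]],
      node = f$properties$node %||% NA_integer_,
      snap_distance_km = f$properties$snap_distance_km %||% NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("station_set", "data.frame")
  out
}

#' @rdname geojson-output
#' @export
write_network_geojson <- function(network, path) {
  nx <- network$nodes$x_km; ny <- network$nodes$y_km
  feats <- lapply(seq_len(nrow(network$edges)), function(i) {
    e <- network$edges[i, ]
    geojson_feature(
      "LineString",
      list(c(nx[e$from], ny[e$from]), c(nx[e$to], ny[e$to])),
      list(from = e$from, to = e$to, length_km = e$length_km,
           speed_kmh = e$speed_kmh, class = e$class %||% NA_character_)
    )
  })
  write_feature_collection(feats, path)
}

#' @rdname geojson-output
#' @export
write_events_geojson <- function(events, path, records = NULL) {
  rec <- NULL
  if (!is.null(records)) rec <- records[match(events$id, records$event_id), ]
  feats <- lapply(seq_len(nrow(events)), function(i) {
    props <- list(id = events$id[i],
                  cell = c(events$cell_i[i], events$cell_j[i]),
                  local_density = events$local_density[i])
    if (!is.null(rec)) {
      props$ems_response_min <- rec$ems_response_min[i]
      props$fire_response_min <- rec$fire_response_min[i]
      props$dual_response_min <- rec$dual_response_min[i]
      props$first_arriver <- rec$first_arriver[i]
    }
    geojson_feature("Point", c(events$x_km[i], events$y_km[i]), props)
  })
  write_feature_collection(feats, path)
}

#' Snap externally supplied stations to a network (real-data adapter)
#'
#' Adapter for station sets read from GeoJSON that carry coordinates but no
#' network node: fills `node` and `snap_distance_km` by Euclidean-nearest
#' node lookup (shared nodes allowed; external data fidelity beats the
#' synthetic generator's exclusivity rule).
#'
#' @param stations A `station_set` (possibly with `node` missing).
#' @param network A `road_network`.
#' @return The station set with `node` and `snap_distance_km` filled.
#' @export
snap_stations <- function(stations, network) {
  snap <- nearest_node_index(stations$x_km, stations$y_km, network$nodes)
  stations$node <- network$nodes$id[snap$index]
  stations$snap_distance_km <- snap$distance_km
  stations
}
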