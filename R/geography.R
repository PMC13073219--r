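#' Configuration for the synthetic study region
#'
#' Bundles every parameter of the synthetic-geography generator: region
#' dimensions and raster resolution, the population-density model (rural
#' background plus a mixture of Gaussian settlement clusters), the road-network
#' generator (node count, nearest-neighbour scaffold, highway fraction, speed
#' classes), station counts for both services, and the master seed.
#'
#' Defaults describe a Lower-Austria-like region: roughly 19,000 km² with
#' 1.73 million inhabitants, sparse rural background plus dense peri-urban
#' clusters, 121 EMS stations and 1590 volunteer fire stations (about a 13:1
#' fire-to-EMS ratio).
#'
#' @param width_km,height_km Region dimensions in km.
#' @param cell_km Raster cell edge length in km.
#' @param total_population Total population mass of the density raster.
#' @param n_population_clusters Number of Gaussian settlement clusters.
#' @param cluster_sd_range Range (km) the per-cluster spatial spread is drawn
#'   from (uniform).
#' @param cluster_mass_share Fraction of the population placed in clusters
#'   before renormalisation; the remainder is rural background.
#' @param rural_background_density Background density, inhabitants per km².
#' @param n_ems,n_fire Station counts per service; `n_fire >= n_ems`.
#' @param n_nodes Road-network node count.
#' @param knn Nearest-neighbour edges proposed per node in the road scaffold.
#' @param highway_fraction Fraction of scaffold edge count added as long-range
#'   highway edges at the fastest speed class.
#' @param highway_min_km Minimum Euclidean length of a highway edge.
#' @param speeds_kmh Named numeric vector with speed classes `urban`, `rural`,
#'   `highway` (km/h).
#' @param urban_density_threshold Density (inhabitants/km²) at or above which a
#'   road segment is classed as urban.
#' @param seed Master seed; stage seeds are derived as `seed` (region),
#'   `seed + 1` (network), `seed + 2` (stations).
#' @return An object of class `geography_config` (a validated list).
#' @examples
#' cfg <- geography_config(width_km = 40, height_km = 40, n_nodes = 300,
#'                         n_ems = 4, n_fire = 30)
#' @export
geography_config <- function(width_km = 160,
                             height_km = 120,
                             cell_km = 2,
                             total_population = 1.73e6,
                             n_population_clusters = 80,
                             cluster_sd_range = c(1.5, 5),
                             cluster_mass_share = 0.7,
                             rural_background_density = 10,
                             n_ems = 121,
                             n_fire = 1590,
                             n_nodes = 2000,
                             knn = 4,
                             highway_fraction = 0.05,
                             highway_min_km = 20,
                             speeds_kmh = c(urban = 40, rural = 70, highway = 100),
                             urban_density_threshold = 300,
                             seed = 42) {
  cfg <- list(
    width_km = width_km, height_km = height_km, cell_km = cell_km,
    total_population = total_population,
    n_population_clusters = n_population_clusters,
    cluster_sd_range = cluster_sd_range,
    cluster_mass_share = cluster_mass_share,
    rural_background_density = rural_background_density,
    n_ems = n_ems, n_fire = n_fire,
    n_nodes = n_nodes, knn = knn,
    highway_fraction = highway_fraction, highway_min_km = highway_min_km,
    speeds_kmh = speeds_kmh,
    urban_density_threshold = urban_density_threshold,
    seed = seed
  )
  validate_geography_config(cfg)
  class(cfg) <- "geography_config"
  cfg
}

validate_geography_config <- function(cfg) {
  for (f in c("width_km", "height_km", "cell_km", "total_population")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop_config("geography_config: '%s' must be a positive scalar", f)
    }
  }
  if (cfg$n_population_clusters < 0) {
    stop_config("geography_config: 'n_population_clusters' must be >= 0")
  }
  if (cfg$rural_background_density < 0) {
    stop_config("geography_config: 'rural_background_density' must be >= 0")
  }
  if (cfg$n_population_clusters == 0 && cfg$rural_background_density <= 0) {
    stop_config("geography_config: density surface would be identically zero")
  }
  for (f in c("n_ems", "n_fire", "n_nodes", "knn")) {
    if (cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]])) {
      stop_config("geography_config: '%s' must be a positive integer", f)
    }
  }
  if (cfg$n_fire < cfg$n_ems) {
    stop_config("geography_config: 'n_fire' must be >= 'n_ems'")
  }
  if (!all(c("urban", "rural", "highway") %in% names(cfg$speeds_kmh)) ||
      any(cfg$speeds_kmh <= 0)) {
    stop_config("geography_config: 'speeds_kmh' needs positive urban/rural/highway entries")
  }
  if (cfg$cluster_mass_share < 0 || cfg$cluster_mass_share > 1) {
    stop_config("geography_config: 'cluster_mass_share' must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Generate a synthetic population-density raster
#'
#' The density surface is a rural background plus a mixture of Gaussian
#' settlement clusters. Cluster centres are uniform over the region; each
#' cluster's spatial spread is drawn from `cluster_sd_range` and its mass share
#' from a gamma weight. The raster is then renormalised so that
#' `sum(density) * cell_km^2` equals `total_population` exactly (up to float
#' rounding), which makes the all-background case exactly uniform.
#'
#' @param config A [geography_config()].
#' @return An object of class `region`: list with `width_km`, `height_km`,
#'   `cell_km`, `density` (matrix, rows = y cells, cols = x cells, inhabitants
#'   per km²) and `total_population`.
#' @examples
#' r <- generate_region(geography_config(width_km = 40, height_km = 40))
#' sum(r$density) * r$cell_km^2  # == total_population
#' @export
generate_region <- function(config) {
  validate_geography_config(config)
  nx <- ceiling(config$width_km / config$cell_km)
  ny <- ceiling(config$height_km / config$cell_km)
  cx <- (seq_len(nx) - 0.5) * config$cell_km  # cell centre x
  cy <- (seq_len(ny) - 0.5) * config$cell_km  # cell centre y

  density <- matrix(config$rural_background_density, nrow = ny, ncol = nx)
  k <- config$n_population_clusters
  if (k > 0) {
    clusters <- with_seed(config$seed, {
      data.frame(
        x = stats::runif(k, 0, config$width_km),
        y = stats::runif(k, 0, config$height_km),
        sd = stats::runif(k, config$cluster_sd_range[1], config$cluster_sd_range[2]),
        w = stats::rgamma(k, shape = 2, rate = 1)
      )
    })
    clusters$mass <- config$total_population * config$cluster_mass_share *
      clusters$w / sum(clusters$w)
    for (j in seq_len(k)) {
      gx <- stats::dnorm(cx, clusters$x[j], clusters$sd[j])
      gy <- stats::dnorm(cy, clusters$y[j], clusters$sd[j])
      density <- density + clusters$mass[j] * outer(gy, gx)
    }
  }
  # renormalise raster mass to the configured population
  mass <- sum(density) * config$cell_km^2
  density <- density * (config$total_population / mass)

  structure(
    list(width_km = config$width_km, height_km = config$height_km,
         cell_km = config$cell_km, density = density,
         total_population = config$total_population),
    class = "region"
  )
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf(
    "<region> %.0f x %.0f km (%.0f km^2), cell %.2g km, grid %d x %d, population %.4g\n",
    x$width_km, x$height_km, x$width_km * x$height_km, x$cell_km,
    nrow(x$density), ncol(x$density), x$total_population))
  invisible(x)
}

# Raster cell (i = row / y, j = col / x) containing a point; clamped to grid.
region_cell <- function(region, x, y) {
  j <- pmin(pmax(ceiling(x / region$cell_km), 1L), ncol(region$density))
  i <- pmin(pmax(ceiling(y / region$cell_km), 1L), nrow(region$density))
  cbind(i = as.integer(i), j = as.integer(j))
}

region_density_at <- function(region, x, y) {
  ij <- region_cell(region, x, y)
  region$density[ij]
}

# Population per cell (density * cell area), as a matrix.
region_cell_population <- function(region) {
  region$density * region$cell_km^2
}

#' Construct a road network from node and edge tables
#'
#' Lower-level constructor used by [generate_road_network()] and by adapters
#' reading external networks. Edges are undirected; travel time per edge is
#' `60 * length_km / speed_kmh` minutes.
#'
#' @param nodes Data frame with columns `id` (1..n integers), `x_km`, `y_km`.
#' @param edges Data frame with columns `from`, `to` (node ids), `length_km`,
#'   `speed_kmh`, and optionally `class`.
#' @param require_connected Error if the graph is not a single component.
#' @return Object of class `road_network`: list with `nodes`, `edges`
#'   (including `travel_time_min`), and an igraph `graph`.
#' @export
road_network <- function(nodes, edges, require_connected = TRUE) {
  stopifnot(all(c("id", "x_km", "y_km") %in% names(nodes)),
            all(c("from", "to", "length_km", "speed_kmh") %in% names(edges)))
  if (nrow(nodes) < 2) stop_config("road_network: need at least 2 nodes")
  if (any(edges$length_km <= 0)) stop_config("road_network: edge lengths must be > 0")
  if (any(edges$speed_kmh <= 0)) stop_config("road_network: edge speeds must be > 0")
  edges$travel_time_min <- 60 * edges$length_km / edges$speed_kmh
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = nodes$id)
  )
  if (require_connected && igraph::count_components(g) != 1L) {
    stop_config("road_network: graph must be a single connected component")
  }
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d edges, mean degree %.2f\n",
              nrow(x$nodes), nrow(x$edges), 2 * nrow(x$edges) / nrow(x$nodes)))
  invisible(x)
}

#' Generate a synthetic road network over a region
#'
#' Nodes are sampled with probability increasing in local population density
#' (with a rural floor so the countryside keeps roads). Edges come from a
#' k-nearest-neighbour scaffold; components are then bridged by their closest
#' node pairs, which guarantees a single connected component; finally a
#' configured fraction of long-range highway edges is added at the fastest
#' speed class. Non-highway segments are classed urban or rural by the density
#' at their midpoint.
#'
#' @param region A [generate_region()] result.
#' @param config The same [geography_config()].
#' @return A `road_network`; its `edges$class` records the speed class.
#' @export
generate_road_network <- function(region, config) {
  validate_geography_config(config)
  n <- config$n_nodes
  if (n < 2) stop_config("generate_road_network: need at least 2 nodes")

  pop <- region_cell_population(region)
  # density-responsive node placement with a rural floor (10% of mean mass)
  w <- as.vector(pop) + 0.1 * mean(pop)
  nxc <- ncol(region$density)

  with_seed(config$seed + 1, {
    cells <- sample.int(length(w), n, replace = TRUE, prob = w)
    i <- ((cells - 1L) %% nrow(region$density)) + 1L
    j <- ((cells - 1L) %/% nrow(region$density)) + 1L
    x <- (j - stats::runif(n)) * region$cell_km
    y <- (i - stats::runif(n)) * region$cell_km
    nodes <- data.frame(id = seq_len(n), x_km = x, y_km = y)

    # k-nearest-neighbour scaffold
    D <- as.matrix(stats::dist(cbind(x, y)))
    diag(D) <- Inf
    k <- min(config$knn, n - 1L)
    nn <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
    ef <- rep(seq_len(n), k)
    et <- as.vector(nn)
    keep <- ef < et
    pairs <- unique(data.frame(from = pmin(ef, et), to = pmax(ef, et)))[, 1:2]

    # bridge components via closest node pairs -> single component
    g0 <- igraph::graph_from_data_frame(pairs, directed = FALSE,
                                        vertices = data.frame(name = seq_len(n)))
    comp <- igraph::components(g0)$membership
    while (length(unique(comp)) > 1L) {
      main <- which(comp == comp[1])
      rest <- which(comp != comp[1])
      sub <- D[main, rest, drop = FALSE]
      hit <- arrayInd(which.min(sub), dim(sub))
      a <- main[hit[1]]; b <- rest[hit[2]]
      pairs <- rbind(pairs, data.frame(from = min(a, b), to = max(a, b)))
      comp[comp == comp[b]] <- comp[1]
    }
    pairs <- unique(pairs)
    pairs$class <- "local"

    # long-range highway edges at the fastest class
    n_high <- round(config$highway_fraction * nrow(pairs))
    if (n_high > 0) {
      got <- 0L; tries <- 0L
      hw <- matrix(integer(0), ncol = 2)
      while (got < n_high && tries < 100 * n_high) {
        ab <- sample.int(n, 2)
        tries <- tries + 1L
        if (D[ab[1], ab[2]] >= config$highway_min_km) {
          hw <- rbind(hw, c(min(ab), max(ab)))
          got <- got + 1L
        }
      }
      if (nrow(hw) > 0) {
        hwdf <- data.frame(from = hw[, 1], to = hw[, 2], class = "highway")
        pairs <- rbind(pairs, hwdf)
        dup <- duplicated(pairs[, c("from", "to")])
        pairs <- pairs[!dup, ]
      }
    }

    len <- sqrt((x[pairs$from] - x[pairs$to])^2 + (y[pairs$from] - y[pairs$to])^2)
    midx <- (x[pairs$from] + x[pairs$to]) / 2
    midy <- (y[pairs$from] + y[pairs$to]) / 2
    middens <- region_density_at(region, midx, midy)
    cls <- ifelse(pairs$class == "highway", "highway",
                  ifelse(middens >= config$urban_density_threshold, "urban", "rural"))
    edges <- data.frame(
      from = pairs$from, to = pairs$to,
      length_km = len,
      speed_kmh = unname(config$speeds_kmh[cls]),
      class = cls
    )
    edges <- edges[edges$length_km > 0, ]
    road_network(nodes, edges)
  })
}

#' Place EMS and fire stations on the network
#'
#' EMS stations are placed by population-weighted sampling of raster cells
#' without replacement (demand-driven placement); fire stations by an equal
#' blend of population weighting and uniform sampling over settled cells
#' (municipal-level ubiquity). Each station gets a uniform position inside its
#' cell and is snapped to the nearest network node not already holding a
#' station of the same service.
#'
#' @param region A `region`.
#' @param network A `road_network`.
#' @param config The same [geography_config()]; uses `n_ems`, `n_fire`.
#' @return Object of class `station_set`: data frame with columns `id`,
#'   `service` ("EMS"/"FIRE"), `x_km`, `y_km`, `node`, `snap_distance_km`.
#' @export
place_stations <- function(region, network, config) {
  validate_geography_config(config)
  n_nodes <- nrow(network$nodes)
  if (config$n_ems + config$n_fire > n_nodes) {
    stop_config("place_stations: n_ems + n_fire (%d) exceeds network nodes (%d)",
                config$n_ems + config$n_fire, n_nodes)
  }
  pop <- as.vector(region_cell_population(region))
  settled <- as.numeric(pop > 0)
  if (sum(pop) <= 0) stop_config("place_stations: region has no population")
  w_ems <- pop / sum(pop)
  w_fire <- 0.5 * pop / sum(pop) + 0.5 * settled / sum(settled)

  with_seed(config$seed + 2, {
    ems <- sample_station_cells(region, network, config$n_ems, w_ems, "EMS", "E")
    fire <- sample_station_cells(region, network, config$n_fire, w_fire, "FIRE", "F")
    out <- rbind(ems, fire)
    rownames(out) <- NULL
    class(out) <- c("station_set", "data.frame")
    out
  })
}

# Draw n station cells without replacement under weight w, position uniformly
# within each cell, snap greedily to nearest unused node (per service).
sample_station_cells <- function(region, network, n, w, service, prefix) {
  ncells <- length(w)
  if (sum(w > 0) < n) {
    stop_config("place_stations: only %d cells have positive weight, need %d",
                sum(w > 0), n)
  }
  cells <- sample.int(ncells, n, replace = FALSE, prob = w)
  ny <- nrow(region$density)
  i <- ((cells - 1L) %% ny) + 1L
  j <- ((cells - 1L) %/% ny) + 1L
  x <- (j - stats::runif(n)) * region$cell_km
  y <- (i - stats::runif(n)) * region$cell_km

  taken <- rep(FALSE, nrow(network$nodes))
  node <- integer(n); snapd <- numeric(n)
  for (s in seq_len(n)) {
    d <- dist_to(x[s], y[s], network$nodes$x_km, network$nodes$y_km)
    d[taken] <- Inf
    jbest <- which.min(d)
    if (!is.finite(d[jbest])) stop_config("place_stations: ran out of free nodes")
    node[s] <- network$nodes$id[jbest]
    snapd[s] <- d[jbest]
    taken[jbest] <- TRUE
  }
  data.frame(
    id = sprintf("%s%0*d", prefix, nchar(n), seq_len(n)),
    service = service, x_km = x, y_km = y,
    node = node, snap_distance_km = snapd,
    stringsAsFactors = FALSE
  )
}

#' @export
print.station_set <- function(x, ...) {
  tab <- table(x$service)
  cat(sprintf("<station_set> %s\n",
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
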