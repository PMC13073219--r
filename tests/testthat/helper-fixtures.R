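# Shared fixtures (memoised: expensive instances are built once per test run)
# and independent oracles used against the package's own implementations.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# Small region: quick unit-test substrate.
tiny_config <- function(seed = 7, ...) {
  geography_config(
    width_km = 40, height_km = 30, cell_km = 2, total_population = 4e4,
    n_population_clusters = 5, cluster_sd_range = c(1, 3),
    rural_background_density = 5,
    n_ems = 3, n_fire = 30, n_nodes = 250, seed = seed, ...
  )
}

tiny_instance <- function() {
  memo("tiny", function() {
    cfg <- tiny_config()
    region <- generate_region(cfg)
    network <- generate_road_network(region, cfg)
    stations <- place_stations(region, network, cfg)
    events <- sample_events(region, network, n = 150, seed = cfg$seed + 3)
    travel <- compute_travel_times(events, stations, network, k = 10)
    list(config = cfg, region = region, network = network,
         stations = stations, events = events, travel = travel)
  })
}

# Mid-sized instance for exhaustive routing audits.
mid_instance <- function() {
  memo("mid", function() {
    cfg <- geography_config(
      width_km = 90, height_km = 60, cell_km = 2, total_population = 3e5,
      n_population_clusters = 20, cluster_sd_range = c(1, 4),
      rural_background_density = 8,
      n_ems = 10, n_fire = 130, n_nodes = 800, seed = 11
    )
    region <- generate_region(cfg)
    network <- generate_road_network(region, cfg)
    stations <- place_stations(region, network, cfg)
    events <- sample_events(region, network, n = 400, seed = cfg$seed + 3)
    list(config = cfg, region = region, network = network,
         stations = stations, events = events)
  })
}

# Full Lower-Austria-like default instance (the study conditions).
default_instance <- function() {
  memo("default", function() {
    cfg <- geography_config()  # seed 42
    region <- generate_region(cfg)
    network <- generate_road_network(region, cfg)
    stations <- place_stations(region, network, cfg)
    events <- sample_events(region, network, n = 1000, seed = cfg$seed + 3)
    travel <- compute_travel_times(events, stations, network, k = 10)
    list(config = cfg, region = region, network = network,
         stations = stations, events = events, travel = travel)
  })
}

# A hand-built region (bypasses the generator) for degenerate-weight tests.
manual_region <- function(density, cell_km = 1) {
  structure(
    list(width_km = ncol(density) * cell_km,
         height_km = nrow(density) * cell_km,
         cell_km = cell_km, density = density,
         total_population = sum(density) * cell_km^2),
    class = "region"
  )
}

# A hand-built line network with unit-speed edges.
manual_line_network <- function(xs, speed_kmh = 60) {
  n <- length(xs)
  nodes <- data.frame(id = seq_len(n), x_km = xs, y_km = 0)
  edges <- data.frame(from = seq_len(n - 1), to = 2:n,
                      length_km = diff(xs), speed_kmh = speed_kmh)
  road_network(nodes, edges)
}

# Independent shortest-path oracle: Bellman-Ford by repeated edge relaxation
# (both directions, since the network is undirected). Deliberately naive.
bellman_ford <- function(network, source_id) {
  n <- nrow(network$nodes)
  src <- match(source_id, network$nodes$id)
  d <- rep(Inf, n)
  d[src] <- 0
  ef <- match(network$edges$from, network$nodes$id)
  et <- match(network$edges$to, network$nodes$id)
  w <- network$edges$travel_time_min
  for (iter in seq_len(n)) {
    cand1 <- d[ef] + w
    cand2 <- d[et] + w
    new <- d
    upd1 <- cand1 < new[et]
    if (any(upd1)) for (i in which(upd1)) new[et[i]] <- min(new[et[i]], cand1[i])
    upd2 <- cand2 < new[ef]
    if (any(upd2)) for (i in which(upd2)) new[ef[i]] <- min(new[ef[i]], cand2[i])
    if (identical(new, d)) break
    d <- new
  }
  stats::setNames(d, network$nodes$id)
}

# Records with a prescribed ems - dual difference vector, for test oracles.
records_from_differences <- function(d, base = 10) {
  out <- data.frame(
    event_id = sprintf("e%02d", seq_along(d)),
    local_density = seq_along(d),
    ems_travel_min = base + d - 2,
    fire_travel_min = base - 5,
    ems_response_min = base + d,
    fire_response_min = base,
    dual_response_min = base,
    first_arriver = ifelse(d > 0, "FIRE", "EMS"),
    stringsAsFactors = FALSE
  )
  out$dual_response_min <- out$ems_response_min - d
  class(out) <- c("response_records", "data.frame")
  out
}
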