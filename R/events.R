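#' Sample population-weighted cardiac-arrest locations
#'
#' Hypothetical out-of-hospital cardiac arrests are allocated at random but
#' weighted by population: a raster cell is drawn with probability
#' proportional to its population (density times cell area), the event
#' position is uniform within the chosen cell, and the event is snapped to the
#' Euclidean-nearest road-network node (events may share nodes). Cells with
#' zero density can never receive an event.
#'
#' @param region A `region` from [generate_region()].
#' @param network A `road_network`; events are snapped to its nodes.
#' @param n Number of events (default 1000, the annual case load the
#'   simulation mirrors).
#' @param seed RNG seed; sampling is deterministic given `seed`.
#' @return Object of class `event_set`: data frame with `id`, `x_km`, `y_km`,
#'   `cell_i`, `cell_j`, `node`, `local_density` (inhabitants/km² of the
#'   event's cell, the regression covariate downstream).
#' @examples
#' cfg <- geography_config(width_km = 30, height_km = 30, n_nodes = 100,
#'                         n_ems = 2, n_fire = 10, n_population_clusters = 3)
#' reg <- generate_region(cfg)
#' net <- generate_road_network(reg, cfg)
#' ev <- sample_events(reg, net, n = 20, seed = 1)
#' @export
sample_events <- function(region, network, n = 1000, seed = 1) {
  if (n < 1 || n != round(n)) stop_config("sample_events: 'n' must be a positive integer")
  pop <- as.vector(region_cell_population(region))
  if (!any(pop > 0)) stop_config("sample_events: density raster is all zero")
  ny <- nrow(region$density)

  with_seed(seed, {
    cells <- sample.int(length(pop), n, replace = TRUE, prob = pop)
    i <- ((cells - 1L) %% ny) + 1L
    j <- ((cells - 1L) %/% ny) + 1L
    x <- (j - stats::runif(n)) * region$cell_km
    y <- (i - stats::runif(n)) * region$cell_km
    snap <- nearest_node_index(x, y, network$nodes)
    out <- data.frame(
      id = sprintf("ev%0*d", nchar(n), seq_len(n)),
      x_km = x, y_km = y,
      cell_i = i, cell_j = j,
      node = network$nodes$id[snap$index],
      local_density = region$density[cbind(i, j)],
      stringsAsFactors = FALSE
    )
    class(out) <- c("event_set", "data.frame")
    out
  })
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d events, median local density %.1f /km^2\n",
              nrow(x), stats::median(x$local_density)))
  invisible(x)
}
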