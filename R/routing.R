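#' Fastest-route travel time between two network nodes
#'
#' Minimum total edge travel time (minutes) over all paths, i.e. a shortest
#' path with edge weight `60 * length_km / speed_kmh`. Edges are undirected,
#' so the result is symmetric in origin and destination.
#'
#' @param network A `road_network`.
#' @param origin_node,dest_node Node ids.
#' @return Travel time in minutes (0 when origin equals destination).
#' @export
fastest_route_time <- function(network, origin_node, dest_node) {
  ids <- network$nodes$id
  if (!(origin_node %in% ids) || !(dest_node %in% ids)) {
    stop_config("fastest_route_time: unknown node id")
  }
  if (origin_node == dest_node) return(0)
  d <- igraph::distances(
    network$graph,
    v = as.character(origin_node), to = as.character(dest_node),
    weights = network$edges$travel_time_min, algorithm = "dijkstra"
  )[1, 1]
  if (!is.finite(d)) {
    stop_config("fastest_route_time: node %s unreachable from %s",
                dest_node, origin_node)
  }
  d
}

# Travel-time matrix (minutes) from a set of origin nodes to a set of
# destination nodes; rows/cols named by node id. Errors on unreachable pairs.
route_time_matrix <- function(network, from_nodes, to_nodes) {
  m <- igraph::distances(
    network$graph,
    v = as.character(from_nodes), to = as.character(to_nodes),
    weights = network$edges$travel_time_min, algorithm = "dijkstra"
  )
  if (any(!is.finite(m))) {
    stop_config("route_time_matrix: some node pairs are unreachable")
  }
  m
}

#' Euclidean k-nearest station candidates for an event
#'
#' Prefilter used before routing: the `min(k, available)` stations of the
#' requested service closest to the event by straight-line distance, ordered
#' by distance with ties broken by station id (ascending).
#'
#' @param event One row of an `event_set` (or any list with `x_km`, `y_km`).
#' @param stations A `station_set`.
#' @param service "EMS" or "FIRE".
#' @param k Number of candidates (default 10).
#' @return The candidate subset of `stations`, ordered.
#' @export
k_nearest_candidates <- function(event, stations, service, k = 10) {
  if (k < 1) stop_config("k_nearest_candidates: 'k' must be >= 1")
  sub <- stations[stations$service == service, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop_config("k_nearest_candidates: no stations of service '%s'", service)
  }
  d <- dist_to(event$x_km, event$y_km, sub$x_km, sub$y_km)
  ord <- order(d, sub$id)
  sub[ord[seq_len(min(k, nrow(sub)))], , drop = FALSE]
}

#' Best (shortest) routed travel time from an event to one service
#'
#' Routes the event's network node to each of the k Euclidean-nearest
#' candidate stations and keeps the minimum travel time; ties on routed time
#' are broken by station id (ascending).
#'
#' @inheritParams k_nearest_candidates
#' @param network A `road_network`.
#' @return List with `event_id`, `service`, `best_station_id`,
#'   `best_travel_min`, `candidate_count`.
#' @export
best_travel_time <- function(event, stations, network, service, k = 10) {
  cand <- k_nearest_candidates(event, stations, service, k)
  tt <- route_time_matrix(network, event$node, cand$node)[1, ]
  best <- min(tt)
  pick <- which(tt == best)
  pick <- pick[order(cand$id[pick])][1]
  list(
    event_id = event$id, service = service,
    best_station_id = cand$id[pick],
    best_travel_min = unname(best),
    candidate_count = nrow(cand)
  )
}

#' Best travel times for all events and both services
#'
#' Vectorised version of [best_travel_time()]: selects the k
#' Euclidean-nearest candidates per event and service, routes all unique
#' event nodes to all unique candidate nodes in one shortest-path sweep, and
#' keeps the per-event minimum. Travel times do not depend on turnout times,
#' so this table is computed once and reused across turnout scenarios.
#'
#' @param events An `event_set`.
#' @param stations A `station_set` containing both services.
#' @param network A `road_network`.
#' @param k Candidate count per service; `Inf` (or any k >= station count)
#'   gives the exact minimum over all stations.
#' @return Data frame (class `travel_times`) with one row per event:
#'   `event_id`, `ems_travel_min`, `ems_station_id`, `fire_travel_min`,
#'   `fire_station_id`.
#' @export
compute_travel_times <- function(events, stations, network, k = 10) {
  res <- data.frame(event_id = events$id, stringsAsFactors = FALSE)
  for (service in c("EMS", "FIRE")) {
    sub <- stations[stations$service == service, , drop = FALSE]
    if (nrow(sub) == 0) {
      stop_config("compute_travel_times: no stations of service '%s'", service)
    }
    kk <- min(k, nrow(sub))
    # k nearest candidate stations per event (Euclidean, id tie-break)
    cand <- matrix(NA_integer_, nrow = nrow(events), ncol = kk)
    for (e in seq_len(nrow(events))) {
      d <- dist_to(events$x_km[e], events$y_km[e], sub$x_km, sub$y_km)
      ord <- order(d, sub$id)
      cand[e, ] <- ord[seq_len(kk)]
    }
    un <- sort(unique(events$node))
    uc <- sort(unique(sub$node[as.vector(cand)]))
    tt <- route_time_matrix(network, un, uc)
    ei <- match(events$node, un)
    best <- numeric(nrow(events))
    bid <- character(nrow(events))
    for (e in seq_len(nrow(events))) {
      ct <- tt[ei[e], match(sub$node[cand[e, ]], uc)]
      m <- min(ct)
      pick <- which(ct == m)
      pick <- pick[order(sub$id[cand[e, pick]])][1]
      best[e] <- m
      bid[e] <- sub$id[cand[e, pick]]
    }
    pre <- if (service == "EMS") "ems" else "fire"
    res[[paste0(pre, "_travel_min")]] <- best
    res[[paste0(pre, "_station_id")]] <- bid
  }
  class(res) <- c("travel_times", "data.frame")
  res
}
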