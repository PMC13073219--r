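test_that("route time to self is zero and unknown nodes error", {
  net <- tiny_instance()$network
  expect_equal(fastest_route_time(net, net$nodes$id[1], net$nodes$id[1]), 0)
  expect_error(fastest_route_time(net, -99, net$nodes$id[1]), "unknown")
})

test_that("a two-edge path sums its edge times", {
  # A--B--C with 6 km and 4 km edges at 60 km/h: 6 + 4 minutes
  net <- manual_line_network(c(0, 6, 10), speed_kmh = 60)
  expect_equal(fastest_route_time(net, 1, 3), 10)
  expect_equal(fastest_route_time(net, 1, 2), 6)
})

test_that("route times match an exhaustive Bellman-Ford oracle", {
  for (seed in c(2, 31)) {
    cfg <- geography_config(width_km = 30, height_km = 30, cell_km = 2,
                            total_population = 2e4,
                            n_population_clusters = 3,
                            n_ems = 1, n_fire = 2, n_nodes = 50, seed = seed)
    reg <- generate_region(cfg)
    net <- generate_road_network(reg, cfg)
    set.seed(seed)
    origins <- sample(net$nodes$id, 10)
    for (o in origins) {
      oracle <- bellman_ford(net, o)
      dests <- sample(net$nodes$id, 5)
      for (d in dests) {
        expect_equal(fastest_route_time(net, o, d), unname(oracle[as.character(d)]))
      }
    }
  }
})

test_that("route times are symmetric and non-negative", {
  net <- tiny_instance()$network
  set.seed(8)
  for (i in 1:20) {
    ab <- sample(net$nodes$id, 2)
    t1 <- fastest_route_time(net, ab[1], ab[2])
    t2 <- fastest_route_time(net, ab[2], ab[1])
    expect_equal(t1, t2)
    expect_gte(t1, 0)
  }
})

test_that("candidate prefilter truncates, orders by distance and breaks ties by id", {
  st <- data.frame(
    id = c("F1", "F2", "F3", "F4"),
    service = "FIRE",
    x_km = c(1, 2, 3, 1), y_km = c(0, 0, 0, 0),
    node = 1:4, snap_distance_km = 0
  )
  ev <- list(x_km = 0, y_km = 0)
  got <- k_nearest_candidates(ev, st, "FIRE", k = 10)
  expect_equal(nrow(got), 4)  # truncation to available
  expect_equal(got$id, c("F1", "F4", "F2", "F3"))  # 1,1,2,3 km; tie F1 < F4
  got2 <- k_nearest_candidates(ev, st, "FIRE", k = 2)
  expect_equal(got2$id, c("F1", "F4"))
  expect_error(k_nearest_candidates(ev, st, "EMS", k = 2), "no stations")
})

test_that("best travel time is the minimum over candidates", {
  inst <- tiny_instance()
  ev <- inst$events[3, ]
  res <- best_travel_time(ev, inst$stations, inst$network, "FIRE", k = 5)
  cand <- k_nearest_candidates(ev, inst$stations, "FIRE", k = 5)
  times <- vapply(cand$node, function(nd) {
    fastest_route_time(inst$network, ev$node, nd)
  }, numeric(1))
  expect_equal(res$best_travel_min, min(times))
  expect_equal(res$candidate_count, 5)
})

test_that("best travel is pointwise non-increasing in k", {
  inst <- tiny_instance()
  ev <- inst$events[seq_len(25), ]
  prev <- rep(Inf, nrow(ev))
  for (k in c(1, 3, 5, 30)) {
    tr <- compute_travel_times(ev, inst$stations, inst$network, k = k)
    expect_true(all(tr$fire_travel_min <= prev + 1e-12))
    prev <- tr$fire_travel_min
  }
})

test_that("k = all equals the brute-force minimum over every station", {
  inst <- tiny_instance()
  tr <- compute_travel_times(inst$events, inst$stations, inst$network, k = Inf)
  g <- inst$network$graph
  for (service in c("EMS", "FIRE")) {
    st <- inst$stations[inst$stations$service == service, ]
    full <- igraph::distances(g, v = as.character(inst$events$node),
                              to = as.character(st$node),
                              weights = inst$network$edges$travel_time_min)
    brute <- apply(full, 1, min)
    col <- if (service == "EMS") "ems_travel_min" else "fire_travel_min"
    expect_equal(unname(tr[[col]]), unname(brute))
  }
})

test_that("routed time respects the Euclidean / max-speed lower bound", {
  inst <- tiny_instance()
  tr <- inst$travel
  nodes <- inst$network$nodes
  st <- inst$stations
  vmax <- max(inst$config$speeds_kmh)
  for (service in c("ems", "fire")) {
    sid <- tr[[paste0(service, "_station_id")]]
    snode <- st$node[match(sid, st$id)]
    enode <- inst$events$node
    eucl <- sqrt((nodes$x_km[enode] - nodes$x_km[snode])^2 +
                   (nodes$y_km[enode] - nodes$y_km[snode])^2)
    expect_true(all(tr[[paste0(service, "_travel_min")]] >=
                      60 * eucl / vmax - 1e-9))
  }
})
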