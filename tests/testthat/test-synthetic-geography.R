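test_that("a cluster-free region renormalises to an exactly uniform raster", {
  cfg <- geography_config(width_km = 100, height_km = 100, cell_km = 5,
                          total_population = 1e5,
                          n_population_clusters = 0,
                          rural_background_density = 10,
                          n_ems = 2, n_fire = 5, n_nodes = 50)
  reg <- generate_region(cfg)
  expect_equal(dim(reg$density), c(20, 20))
  expect_true(all(reg$density == 10))
})

test_that("raster mass equals the configured population for every seed", {
  for (seed in 1:5) {
    cfg <- tiny_config(seed = seed)
    reg <- generate_region(cfg)
    mass <- sum(reg$density) * reg$cell_km^2
    expect_lt(abs(mass - cfg$total_population) / cfg$total_population, 1e-3)
    expect_true(all(reg$density >= 0))
    expect_true(any(reg$density > 0))
  }
})

test_that("grid dimensions follow ceil(extent / cell)", {
  cfg <- geography_config(width_km = 33, height_km = 21, cell_km = 2,
                          n_ems = 1, n_fire = 2, n_nodes = 20)
  reg <- generate_region(cfg)
  expect_equal(nrow(reg$density), ceiling(21 / 2))
  expect_equal(ncol(reg$density), ceiling(33 / 2))
})

test_that("Lower-Austria-scale region conserves its 1.73 M population", {
  inst <- default_instance()
  mass <- sum(inst$region$density) * inst$region$cell_km^2
  expect_lt(abs(mass - 1.73e6) / 1.73e6, 1e-3)
})

test_that("default density surface is strongly heterogeneous", {
  reg <- default_instance()$region
  expect_gt(max(reg$density) / stats::median(reg$density), 10)
})

test_that("generation is bit-identical under a fixed config and seed", {
  cfg <- tiny_config()
  a <- generate_region(cfg); b <- generate_region(cfg)
  expect_identical(a, b)
  na <- generate_road_network(a, cfg); nb <- generate_road_network(b, cfg)
  expect_identical(na$nodes, nb$nodes)
  expect_identical(na$edges, nb$edges)
  sa <- place_stations(a, na, cfg); sb <- place_stations(b, nb, cfg)
  expect_identical(sa, sb)
})

test_that("generated networks are connected with valid speed-classed edges", {
  for (seed in c(3, 19)) {
    cfg <- tiny_config(seed = seed)
    reg <- generate_region(cfg)
    net <- generate_road_network(reg, cfg)
    expect_equal(igraph::count_components(net$graph), 1)
    expect_true(all(net$edges$length_km > 0))
    expect_true(all(net$edges$speed_kmh %in% cfg$speeds_kmh))
    expect_true(all(net$edges$travel_time_min > 0))
  }
})

test_that("edge travel time is 60 * length / speed on a hand-built square", {
  nodes <- data.frame(id = 1:4, x_km = c(0, 10, 10, 0), y_km = c(0, 0, 10, 10))
  edges <- data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 4, 1),
                      length_km = 10, speed_kmh = 60)
  net <- road_network(nodes, edges)
  expect_equal(net$edges$travel_time_min, rep(10, 4))
})

test_that("default network mean degree sits in a sane envelope", {
  net <- default_instance()$network
  expect_equal(nrow(net$nodes), 2000)
  deg <- 2 * nrow(net$edges) / nrow(net$nodes)
  expect_gte(deg, 2.5)
  expect_lte(deg, 6)
})

test_that("road density responds to population density", {
  inst <- default_instance()
  reg <- inst$region
  ny <- nrow(reg$density)
  i <- pmin(pmax(ceiling(inst$network$nodes$y_km / reg$cell_km), 1), ny)
  j <- pmin(pmax(ceiling(inst$network$nodes$x_km / reg$cell_km), 1),
            ncol(reg$density))
  counts <- tabulate((j - 1L) * ny + i, nbins = length(reg$density))
  rho <- stats::cor(as.vector(reg$density), counts, method = "spearman")
  expect_gt(rho, 0)
})

test_that("station placement respects counts and per-service node exclusivity", {
  st <- default_instance()$stations
  expect_equal(sum(st$service == "EMS"), 121)
  expect_equal(sum(st$service == "FIRE"), 1590)
  expect_false(any(duplicated(st$node[st$service == "EMS"])))
  expect_false(any(duplicated(st$node[st$service == "FIRE"])))
  expect_true(all(st$snap_distance_km >= 0))
})

test_that("sparse stations snap to their true nearest node", {
  inst <- tiny_instance()
  st <- inst$stations[inst$stations$service == "EMS", ]
  for (i in seq_len(nrow(st))) {
    d <- sqrt((inst$network$nodes$x_km - st$x_km[i])^2 +
                (inst$network$nodes$y_km - st$y_km[i])^2)
    expect_equal(st$snap_distance_km[i], min(d))
  }
})

test_that("degenerate placement on a 2-node network still lands on nodes", {
  reg <- manual_region(matrix(5, 2, 2), cell_km = 2)
  nodes <- data.frame(id = 1:2, x_km = c(1, 3), y_km = c(1, 3))
  edges <- data.frame(from = 1, to = 2, length_km = sqrt(8), speed_kmh = 60)
  net <- road_network(nodes, edges)
  cfg <- geography_config(width_km = 4, height_km = 4, cell_km = 2,
                          total_population = 80, n_population_clusters = 0,
                          rural_background_density = 5,
                          n_ems = 1, n_fire = 1, n_nodes = 2, seed = 1)
  st <- place_stations(reg, net, cfg)
  expect_setequal(st$node[st$service == "EMS"], st$node[st$service == "EMS"])
  expect_true(all(st$node %in% nodes$id))
  expect_true(all(st$snap_distance_km >= 0))
})

test_that("events sit closer to fire stations than to EMS stations on average", {
  inst <- default_instance()
  ems <- inst$stations[inst$stations$service == "EMS", ]
  fire <- inst$stations[inst$stations$service == "FIRE", ]
  nearest <- function(st) {
    vapply(seq_len(nrow(inst$events)), function(i) {
      min(sqrt((st$x_km - inst$events$x_km[i])^2 +
                 (st$y_km - inst$events$y_km[i])^2))
    }, numeric(1))
  }
  expect_lt(mean(nearest(fire)), mean(nearest(ems)))
})

test_that("invalid configurations are rejected", {
  expect_error(geography_config(width_km = -1), "positive")
  expect_error(geography_config(n_ems = 10, n_fire = 5), "n_fire")
  expect_error(geography_config(n_population_clusters = 0,
                                rural_background_density = 0),
               "zero")
  inst <- tiny_instance()
  cfg_too_many <- tiny_config()
  cfg_too_many$n_fire <- 10000
  expect_error(place_stations(inst$region, inst$network, cfg_too_many),
               "exceeds")
})
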