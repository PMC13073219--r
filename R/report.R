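# Run persistence and reporting: every number in a report is recomputed from
# the persisted per-event CSVs, so regenerating a report from a run directory
# is idempotent and the report carries no state of its own.

summary_to_list <- function(s) {
  out <- list(
    strategy = s$strategy, n = s$n,
    mean_min = s$mean_min, sd_min = s$sd_min,
    percentiles = as.list(s$percentiles),
    frac_within = as.list(s$frac_within)
  )
  if (!is.null(s$frac_fire_first)) out$frac_fire_first <- s$frac_fire_first
  out
}

comparison_to_list <- function(cmp) {
  list(mean_difference_min = cmp$mean_difference_min,
       t_statistic = cmp$t_statistic,
       p_value = cmp$p_value,
       test_kind = cmp$test_kind)
}

#' Persist a simulation run as plain-text files
#'
#' Writes the full state of a [run_dual_dispatch()] result into a directory:
#' `config.json`, the density raster (`density.csv`, `density.asc`), the
#' network and stations (GeoJSON), events (CSV + GeoJSON), the cached travel
#' times (`travel.csv`) and one `records_<scenario>.csv` per turnout
#' scenario.
#'
#' @param run A `dual_dispatch_run` from [run_dual_dispatch()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  cfg <- unclass(run$config)
  cfg$speeds_kmh <- as.list(cfg$speeds_kmh)
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_density_csv(run$region, p("density.csv"))
  write_ascii_grid(run$region, p("density.asc"))
  write_network_geojson(run$network, p("network.geojson"))
  write_stations_geojson(run$stations, p("stations.geojson"))
  utils::write.csv(run$events, p("events.csv"), row.names = FALSE)
  write_events_geojson(run$events, p("events.geojson"),
                       records = run$records[[1]])
  utils::write.csv(run$travel, p("travel.csv"), row.names = FALSE)
  for (nm in names(run$records)) {
    utils::write.csv(run$records[[nm]], p(sprintf("records_%s.csv", nm)),
                     row.names = FALSE)
  }
  invisible(dir)
}

read_records_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("response_records", "data.frame")
  out
}

#' Build the run report from a persisted run directory
#'
#' Re-reads the persisted CSVs, recomputes all summary statistics, strategy
#' comparisons, the fire-turnout sweep (from the cached travel table) and the
#' density-by-strategy regression, and writes `report.json` plus the
#' distribution and first-arriver-map figures. Turnout values per scenario
#' are derived from the records themselves (response minus travel), so the
#' report never trusts numbers it cannot recompute.
#'
#' @param run_dir Directory written by [write_run()].
#' @param thresholds Coverage thresholds in minutes.
#' @param alpha Significance level for the sweep threshold.
#' @param sweep_grid Fire-turnout grid for the sweep.
#' @param figures Also render `fig_distributions.png` and `fig_map.png`.
#' @param write Write `report.json` into `run_dir`.
#' @return The report, a plain nested list (JSON-serialisable).
#' @export
build_report <- function(run_dir, thresholds = 10, alpha = 0.05,
                         sweep_grid = 2:25, figures = TRUE, write = TRUE) {
  required <- c("config.json", "events.csv", "travel.csv")
  missing <- required[!file.exists(file.path(run_dir, required))]
  rec_files <- list.files(run_dir, pattern = "^records_.*\\.csv$")
  if (length(rec_files) == 0) missing <- c(missing, "records_<scenario>.csv")
  if (length(missing) > 0) {
    stop_config("build_report: missing inputs in '%s': %s",
                run_dir, paste(missing, collapse = ", "))
  }
  config <- jsonlite::read_json(file.path(run_dir, "config.json"),
                                simplifyVector = TRUE)
  events <- utils::read.csv(file.path(run_dir, "events.csv"),
                            stringsAsFactors = FALSE)
  class(events) <- c("event_set", "data.frame")
  travel <- utils::read.csv(file.path(run_dir, "travel.csv"),
                            stringsAsFactors = FALSE)
  class(travel) <- c("travel_times", "data.frame")

  scenarios <- list()
  records_list <- list()
  for (f in sort(rec_files)) {
    nm <- sub("^records_(.*)\\.csv$", "\\1", f)
    rec <- read_records_csv(file.path(run_dir, f))
    records_list[[nm]] <- rec
    turnout <- list(
      ems_turnout_min = rec$ems_response_min[1] - rec$ems_travel_min[1],
      fire_turnout_min = rec$fire_response_min[1] - rec$fire_travel_min[1]
    )
    scenarios[[nm]] <- list(
      turnout = turnout,
      ems_only = summary_to_list(
        summarize_strategy(rec, "ems_only", thresholds = thresholds)),
      dual = summary_to_list(
        summarize_strategy(rec, "dual", thresholds = thresholds)),
      comparison = comparison_to_list(compare_strategies(rec))
    )
  }

  ems_turnout <- scenarios[[1]]$turnout$ems_turnout_min
  sweep <- turnout_sweep(events, turnout_grid = sweep_grid, alpha = alpha,
                         ems_turnout_min = ems_turnout, travel = travel)
  sweep_out <- c(
    list(alpha = alpha, reached = !is.na(sweep$threshold_turnout)),
    as.list(sweep$table)
  )
  if (!is.na(sweep$threshold_turnout)) {
    sweep_out$threshold_turnout <- sweep$threshold_turnout
  }

  glm <- fit_density_glm(records_list[[1]])
  report <- list(
    schema_version = "1.0",
    config = config,
    scenarios = scenarios,
    sweep = sweep_out,
    glm = list(
      coefficients = as.list(glm$coefficients),
      se = as.list(glm$se),
      p_values = as.list(glm$p_values),
      r_squared = glm$r_squared,
      n_obs = glm$n_obs
    ),
    manifest = sort(list.files(run_dir))
  )
  if (write) write_report(report, file.path(run_dir, "report.json"))
  if (figures) {
    region <- read_density_csv(file.path(run_dir, "density.csv"))
    gg <- plot_response_distributions(records_list)
    ggplot2::ggsave(file.path(run_dir, "fig_distributions.png"), gg,
                    width = 6, height = 4, dpi = 150)
    gg2 <- plot_first_arriver_map(region, events, records_list[[1]])
    ggplot2::ggsave(file.path(run_dir, "fig_map.png"), gg2,
                    width = 7, height = 5.5, dpi = 150)
  }
  report
}

#' Write / read a report as JSON
#'
#' @param report A report list from [build_report()].
#' @param path JSON file path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Boxplots of response-time distributions by strategy
#'
#' One panel per turnout scenario, boxplots (median and interquartile range)
#' of EMS-only versus dual-dispatch response times.
#'
#' @param records_list Named list of `response_records` (one per scenario).
#' @return A ggplot object.
#' @export
plot_response_distributions <- function(records_list) {
  if (inherits(records_list, "data.frame")) {
    records_list <- list(run = records_list)
  }
  long <- do.call(rbind, lapply(names(records_list), function(nm) {
    rec <- records_list[[nm]]
    data.frame(
      scenario = nm,
      strategy = rep(c("EMS only", "Dual dispatch"), each = nrow(rec)),
      response_min = c(rec$ems_response_min, rec$dual_response_min)
    )
  }))
  long$strategy <- factor(long$strategy, c("EMS only", "Dual dispatch"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$strategy,
                                     y = .data$response_min,
                                     fill = .data$strategy)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = NULL, y = "Response time (min)") +
    ggplot2::theme_minimal()
}

#' Map of events coloured by first arriver over density shading
#'
#' Events where EMS arrived first are drawn red, events where the dual
#' dispatch (fire service) was faster green, over the population density
#' shaded on a log10(1 + d) scale.
#'
#' @param region A `region`.
#' @param events An `event_set`.
#' @param records Matching `response_records`.
#' @return A ggplot object.
#' @export
plot_first_arriver_map <- function(region, events, records) {
  dens <- region$density
  grid <- expand.grid(
    x = (seq_len(ncol(dens)) - 0.5) * region$cell_km,
    y = (seq_len(nrow(dens)) - 0.5) * region$cell_km
  )
  grid$logd <- log10(1 + as.vector(t(dens)))
  pts <- data.frame(
    x = events$x_km, y = events$y_km,
    first = records$first_arriver[match(events$id, records$event_id)]
  )
  pts$first <- factor(ifelse(pts$first == "EMS", "EMS first", "Dual faster"),
                      c("EMS first", "Dual faster"))
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = grid,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$logd)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue4",
                                 name = "log10(1+density)") +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$first),
                        size = 0.8, alpha = 0.8) +
    ggplot2::scale_colour_manual(
      values = c("EMS first" = "red3", "Dual faster" = "green4"),
      name = NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "km", y = "km") +
    ggplot2::theme_minimal()
}
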