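#' Summarise response times for one dispatch strategy
#'
#' Computes mean, sample SD (n-1), linearly interpolated percentiles, the
#' fraction of events reached within each threshold (inclusive), and — for
#' the dual strategy — the fraction of events where the fire service arrived
#' strictly first.
#'
#' @param records A `response_records` data frame.
#' @param strategy "ems_only" or "dual".
#' @param thresholds Response-time thresholds in minutes (default 10, the
#'   clinically motivated cutoff).
#' @param probs Percentile probabilities to report.
#' @return Object of class `strategy_summary`: list with `strategy`, `n`,
#'   `mean_min`, `sd_min`, `percentiles`, `frac_within`, and
#'   `frac_fire_first` (dual only).
#' @export
summarize_strategy <- function(records, strategy = c("ems_only", "dual"),
                               thresholds = 10,
                               probs = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
  strategy <- match.arg(strategy)
  if (nrow(records) == 0) stop_config("summarize_strategy: no records")
  x <- if (strategy == "ems_only") records$ems_response_min else records$dual_response_min
  pct <- stats::quantile(x, probs = probs, type = 7, names = TRUE)
  frac <- vapply(thresholds, function(t) mean(x <= t), numeric(1))
  names(frac) <- as.character(thresholds)
  out <- list(
    strategy = strategy,
    n = length(x),
    mean_min = mean(x),
    sd_min = stats::sd(x),
    percentiles = pct,
    frac_within = frac
  )
  if (strategy == "dual") {
    out$frac_fire_first <- mean(records$first_arriver == "FIRE")
  }
  class(out) <- "strategy_summary"
  out
}

#' @export
print.strategy_summary <- function(x, ...) {
  p90 <- if ("90%" %in% names(x$percentiles)) x$percentiles[["90%"]] else NA
  cat(sprintf("<strategy_summary> %s: n=%d mean=%.2f min sd=%.2f p90=%.2f\n",
              x$strategy, x$n, x$mean_min, x$sd_min, p90))
  for (t in names(x$frac_within)) {
    cat(sprintf("  within %s min: %.1f%%\n", t, 100 * x$frac_within[[t]]))
  }
  if (!is.null(x$frac_fire_first)) {
    cat(sprintf("  fire first: %.1f%%\n", 100 * x$frac_fire_first))
  }
  invisible(x)
}

#' Compare EMS-only and dual dispatch response times
#'
#' Tests the per-event difference `ems_response - dual_response`. The design
#' is intrinsically paired (both strategies are evaluated on the same events),
#' so the default is a paired two-sided t-test; a Welch two-sample variant is
#' available for comparison. When every paired difference is exactly zero
#' (e.g. an infinite fire turnout) the degenerate result t = 0, p = 1 is
#' returned.
#'
#' @param records A `response_records` data frame with at least 2 rows.
#' @param paired Use the paired test (default) or Welch's two-sample test.
#' @return Object of class `comparison_result`: list with
#'   `mean_difference_min`, `t_statistic`, `p_value`, `test_kind`.
#' @export
compare_strategies <- function(records, paired = TRUE) {
  if (nrow(records) < 2) stop_config("compare_strategies: need at least 2 records")
  d <- records$ems_response_min - records$dual_response_min
  if (paired) {
    if (all(d == 0)) {
      res <- list(mean_difference_min = 0, t_statistic = 0, p_value = 1,
                  test_kind = "paired two-sided t-test")
    } else {
      tt <- stats::t.test(d, alternative = "two.sided")
      res <- list(mean_difference_min = mean(d),
                  t_statistic = unname(tt$statistic),
                  p_value = tt$p.value,
                  test_kind = "paired two-sided t-test")
    }
  } else {
    if (stats::sd(records$ems_response_min) == 0 &&
        stats::sd(records$dual_response_min) == 0 &&
        mean(d) == 0) {
      res <- list(mean_difference_min = 0, t_statistic = 0, p_value = 1,
                  test_kind = "Welch two-sample t-test")
    } else {
      tt <- stats::t.test(records$ems_response_min, records$dual_response_min,
                          alternative = "two.sided", var.equal = FALSE)
      res <- list(mean_difference_min = mean(d),
                  t_statistic = unname(tt$statistic),
                  p_value = tt$p.value,
                  test_kind = "Welch two-sample t-test")
    }
  }
  class(res) <- "comparison_result"
  res
}

#' Fire-turnout sensitivity sweep
#'
#' Re-evaluates the strategy comparison over a grid of fire-service turnout
#' times. Travel times are turnout-independent, so they are computed once
#' (or supplied pre-computed) and only the dispatch and test stages are
#' re-run per grid value. The threshold turnout is the smallest grid value at
#' which the test is no longer significant (p >= alpha); no multiple-testing
#' correction is applied — the sweep is exploratory.
#'
#' The sweep asks a between-group question — at what turnout do the two
#' strategies' arrival-time distributions stop being distinguishable — so it
#' defaults to the Welch two-sample test. The paired test is available via
#' `test = "paired"`, but paired differences are non-negative by construction
#' (dual dispatch can never be slower), so a paired test only loses
#' significance when the strategies coincide almost exactly.
#'
#' @param events,stations,network Pipeline inputs (ignored when `travel`
#'   is supplied together with `events`).
#' @param turnout_grid Ascending fire-turnout values in minutes.
#' @param alpha Significance level for the threshold (default 0.05).
#' @param ems_turnout_min EMS turnout held fixed across the sweep.
#' @param k Candidate count for routing.
#' @param travel Optional pre-computed `travel_times` table.
#' @param test "welch" (default) or "paired"; see Details.
#' @return Object of class `sweep_result`: list with `table` (one row per
#'   grid value: turnout, mean/sd of dual response, fire-first fraction, mean
#'   difference, t, p), `alpha`, `threshold_turnout` (NA if never reached).
#' @export
turnout_sweep <- function(events, stations = NULL, network = NULL,
                          turnout_grid = 2:25, alpha = 0.05,
                          ems_turnout_min = 2, k = 10, travel = NULL,
                          test = c("welch", "paired")) {
  test <- match.arg(test)
  if (length(turnout_grid) == 0) stop_config("turnout_sweep: empty grid")
  if (is.unsorted(turnout_grid, strictly = FALSE)) {
    stop_config("turnout_sweep: grid must be sorted ascending")
  }
  if (is.null(travel)) {
    travel <- compute_travel_times(events, stations, network, k = k)
  }
  rows <- lapply(turnout_grid, function(g) {
    rec <- dispatch_responses(travel, events,
                              turnout_config(ems_turnout_min, g))
    cmp <- compare_strategies(rec, paired = (test == "paired"))
    data.frame(
      fire_turnout_min = g,
      mean_dual_min = mean(rec$dual_response_min),
      sd_dual_min = stats::sd(rec$dual_response_min),
      frac_fire_first = mean(rec$first_arriver == "FIRE"),
      mean_difference_min = cmp$mean_difference_min,
      t_statistic = cmp$t_statistic,
      p_value = cmp$p_value
    )
  })
  tab <- do.call(rbind, rows)
  hit <- which(tab$p_value >= alpha)
  res <- list(
    table = tab,
    alpha = alpha,
    test = test,
    threshold_turnout = if (length(hit)) tab$fire_turnout_min[min(hit)] else NA_real_
  )
  class(res) <- "sweep_result"
  res
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d turnout values, alpha=%.2g, threshold=%s min\n",
              nrow(x$table), x$alpha,
              ifelse(is.na(x$threshold_turnout), "not reached",
                     format(x$threshold_turnout))))
  invisible(x)
}

#' Gaussian GLM of response time on density, strategy and their interaction
#'
#' Fits `response ~ density + strategy + density:strategy` with a Gaussian
#' family and identity link on the long-format records (two rows per event:
#' strategy 0 = EMS-only, 1 = dual). A negative density coefficient means
#' denser areas are reached faster; a positive interaction means the dual
#' dispatch advantage shrinks as density grows. Density enters untransformed,
#' in inhabitants per km².
#'
#' @param records A `response_records` data frame (>= 2 events).
#' @return Object of class `density_glm`: list with `coefficients` (named
#'   intercept/density/strategy/interaction), `se`, `p_values`, `r_squared`,
#'   `n_obs`, and the underlying `fit`.
#' @export
fit_density_glm <- function(records) {
  if (nrow(records) < 2) stop_config("fit_density_glm: need at least 2 events")
  long <- data.frame(
    response = c(records$ems_response_min, records$dual_response_min),
    density = rep(records$local_density, 2),
    strategy = rep(c(0, 1), each = nrow(records))
  )
  if (stats::sd(long$density) == 0) {
    stop_config("fit_density_glm: design is rank deficient ('density' is constant)")
  }
  fit <- stats::glm(response ~ density * strategy, family = stats::gaussian(),
                    data = long)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_config("fit_density_glm: design is rank deficient (collinear: %s)",
                paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  nm <- c("intercept", "density", "strategy", "interaction")
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((long$response - mean(long$response))^2)
  res <- list(
    coefficients = stats::setNames(co[, "Estimate"], nm),
    se = stats::setNames(co[, "Std. Error"], nm),
    p_values = stats::setNames(co[, "Pr(>|t|)"], nm),
    r_squared = 1 - rss / tss,
    n_obs = nrow(long),
    fit = fit
  )
  class(res) <- "density_glm"
  res
}

#' @export
print.density_glm <- function(x, ...) {
  cat(sprintf(
    "<density_glm> n=%d R^2=%.3f\n  beta: intercept=%.4g density=%.4g strategy=%.4g interaction=%.4g\n",
    x$n_obs, x$r_squared, x$coefficients["intercept"], x$coefficients["density"],
    x$coefficients["strategy"], x$coefficients["interaction"]))
  invisible(x)
}

#' Predict response time from a fitted density-strategy model
#'
#' @param glm A `density_glm` fit.
#' @param density Population density, inhabitants per km².
#' @param strategy 0/1 indicator or "ems_only"/"dual".
#' @return Predicted response time in minutes.
#' @export
predict_response <- function(glm, density, strategy) {
  if (!inherits(glm, "density_glm")) {
    stop_config("predict_response: 'glm' must be a density_glm fit")
  }
  if (is.character(strategy)) {
    strategy <- match.arg(strategy, c("ems_only", "dual"))
    strategy <- as.numeric(strategy == "dual")
  }
  b <- glm$coefficients
  unname(b["intercept"] + b["density"] * density + b["strategy"] * strategy +
           b["interaction"] * density * strategy)
}
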