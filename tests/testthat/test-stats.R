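test_that("summary of a constant sample is degenerate", {
  rec <- records_from_differences(rep(0, 5), base = 7)
  s <- summarize_strategy(rec, "ems_only")
  expect_equal(s$mean_min, 7)
  expect_equal(s$sd_min, 0)
  expect_true(all(s$percentiles == 7))
})

test_that("coverage fraction counts events at or below the threshold", {
  rec <- records_from_differences(c(0, 0, 0), base = 10)
  rec$ems_response_min <- c(4, 8, 12)
  s <- summarize_strategy(rec, "ems_only", thresholds = c(10, Inf))
  expect_equal(unname(s$frac_within[["10"]]), 2 / 3)
  expect_equal(unname(s$frac_within[["Inf"]]), 1)
  expect_gte(s$percentiles[["90%"]], s$percentiles[["50%"]])
  expect_gte(s$percentiles[["50%"]], s$percentiles[["10%"]])
})

test_that("paired t-test matches the closed-form hand computation", {
  d <- c(3.2, 1.1, 0.0, 4.5, 2.2, 0.0, 1.8, 3.9, 0.4, 2.6,
         0.0, 1.2, 5.1, 2.8, 0.0, 3.3, 1.7, 0.9, 2.4, 4.0)
  cmp <- compare_strategies(records_from_differences(d))
  # frozen closed-form values: t = mean(d) / (sd(d)/sqrt(20)), p from t_19
  expect_equal(cmp$mean_difference_min, 2.055)
  expect_equal(cmp$t_statistic, 5.71754142956, tolerance = 1e-10)
  expect_equal(cmp$p_value, 1.64351411195e-05, tolerance = 1e-9)
  expect_match(cmp$test_kind, "paired")
})

test_that("identical strategies give the degenerate t = 0, p = 1", {
  rec <- records_from_differences(rep(0, 30))
  cmp <- compare_strategies(rec)
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)
  cmpw <- compare_strategies(rec, paired = FALSE)
  expect_equal(cmpw$p_value, 1)
})

test_that("a clearly separated difference is overwhelmingly significant", {
  set.seed(1)
  d <- 3 + stats::rnorm(50, sd = 0.01)
  cmp <- compare_strategies(records_from_differences(d))
  expect_lt(cmp$p_value, 1e-3)
})

test_that("tiny inputs are rejected", {
  rec <- records_from_differences(1)
  expect_error(compare_strategies(rec), "at least 2")
  expect_error(summarize_strategy(rec[0, ], "dual"), "no records")
})

test_that("noiseless data recovers the generating coefficients exactly", {
  d <- seq(0, 5000, length.out = 400)
  rec <- data.frame(
    event_id = sprintf("e%03d", seq_along(d)),
    local_density = d,
    ems_travel_min = 0, fire_travel_min = 0,
    ems_response_min = 12 - 0.001 * d,
    fire_response_min = 0,
    dual_response_min = (12 - 4) + (-0.001 + 0.0005) * d,
    first_arriver = "FIRE", stringsAsFactors = FALSE
  )
  fit <- fit_density_glm(rec)
  expect_equal(unname(fit$coefficients),
               c(12, -0.001, -4, 0.0005), tolerance = 1e-7)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("a constant density column is reported as rank deficient", {
  rec <- records_from_differences(c(1, 2, 3))
  rec$local_density <- 50
  expect_error(fit_density_glm(rec), "density")
})

test_that("prediction is the linear combination of the coefficients", {
  fit <- structure(list(coefficients = c(intercept = 12, density = -0.001,
                                         strategy = -4, interaction = 0.0005)),
                   class = "density_glm")
  expect_equal(predict_response(fit, 1000, 1), 7.5)
  expect_equal(predict_response(fit, 1000, "dual"), 7.5)
  flat <- structure(list(coefficients = c(intercept = 10, density = 0,
                                          strategy = 0, interaction = 0)),
                    class = "density_glm")
  expect_equal(predict_response(flat, 123, 0), 10)
  expect_equal(predict_response(flat, 9999, 1), 10)
})

test_that("a positive interaction shrinks the dual advantage with density", {
  fit <- structure(list(coefficients = c(intercept = 12, density = -0.001,
                                         strategy = -4, interaction = 0.0005)),
                   class = "density_glm")
  adv <- function(d) predict_response(fit, d, 0) - predict_response(fit, d, 1)
  expect_gt(adv(100), adv(10000))
})

test_that("sweep output is monotone and degenerates at huge turnout", {
  inst <- tiny_instance()
  sw <- turnout_sweep(inst$events, travel = inst$travel,
                      turnout_grid = c(5, 8, 11, 14, 17, 20, 1e6))
  tab <- sw$table
  expect_true(all(diff(tab$mean_dual_min) >= -1e-12))
  expect_true(all(diff(tab$frac_fire_first) <= 1e-12))
  expect_true(all(diff(tab$mean_difference_min) <= 1e-12))
  expect_equal(tab$p_value[nrow(tab)], 1)
})

test_that("sweep rejects unsorted or empty grids", {
  inst <- tiny_instance()
  expect_error(turnout_sweep(inst$events, travel = inst$travel,
                             turnout_grid = c(5, 3)), "ascending")
  expect_error(turnout_sweep(inst$events, travel = inst$travel,
                             turnout_grid = numeric(0)), "empty")
})

test_that("fire-first share exceeds half at a low turnout with dense coverage", {
  inst <- default_instance()
  rec <- dispatch_responses(inst$travel, inst$events, turnout_config(2, 2))
  expect_gt(mean(rec$first_arriver == "FIRE"), 0.5)
})
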