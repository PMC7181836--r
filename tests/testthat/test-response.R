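coef_tbl <- function(...) {
  vals <- c(...)
  tibble::tibble(term = names(vals), estimate = unname(vals))
}

test_that("CO2 turning point: first-order condition, degenerate cases", {
  # symmetric case: no linear term puts the vertex at zero
  tp0 <- co2_turning_point(coef_tbl(co2 = 0, co2_sq = 0.01))
  expect_equal(tp0$location, 0)
  expect_identical(tp0$direction, "minimum")

  # no quadratic term: an explicit no-turning-point result, not a number
  tp_lin <- co2_turning_point(coef_tbl(co2 = 0.5))
  expect_true(is.na(tp_lin$location))
  expect_identical(tp_lin$direction, "none")

  # negative curvature flips the direction
  tp_max <- co2_turning_point(coef_tbl(co2 = 4, co2_sq = -0.005))
  expect_identical(tp_max$direction, "maximum")
  expect_equal(tp_max$location, 400)

  expect_error(co2_turning_point(coef_tbl(pbgs = 1)), "CO2")
})

test_that("turning point agrees with a dense grid search on a fitted model", {
  sim <- simulate_panel(sim_config("corn", co2_effect = "quadratic",
                                   n_counties = 4, years = 1995:2013,
                                   noise_sd = 5, seed = 8))
  fit <- fit_becyr(sim$panel, model_spec("corn", "quadratic"))
  tp <- co2_turning_point(fit)
  cf <- coef(fit)
  grid <- seq(tp$location - 100, tp$location + 100, by = 0.01)
  curve <- cf["co2"] * grid + cf["co2_sq"] * grid^2
  oracle <- if (tp$direction == "minimum") {
    grid[which.min(curve)]
  } else {
    grid[which.max(curve)]
  }
  expect_equal(tp$location, oracle, tolerance = 0.011)
  # invariant to county effects: recompute from the coefficient table alone
  tp2 <- co2_turning_point(tidy(fit))
  expect_equal(tp2$location, tp$location)
})

test_that("peak levels: closed form at the mean, linear in the conditioning level", {
  cf <- coef_tbl(preci = 0.1697, preci_sq = -0.0001595,
                 dd = 0.1867, dd_sq = -0.00006496, preci_x_dd = 0.0002265)
  means <- c(preci = 450, dd = 1175)

  pk <- peak_level(cf, "preci", means = means)
  expect_equal(pk$location, 0.1697 / (2 * 0.0001595))
  expect_identical(pk$direction, "maximum")

  # conditioning shifts the peak linearly with slope -theta / (2 gamma)
  at1 <- peak_level(cf, "preci", at = 1275, means = means)$location
  at2 <- peak_level(cf, "preci", at = 1375, means = means)$location
  slope <- (at2 - at1) / 100
  expect_equal(slope, -0.0002265 / (2 * -0.0001595), tolerance = 1e-10)

  # theta = 0 decouples the variables
  cf0 <- coef_tbl(preci = 0.2, preci_sq = -0.0002, dd = 0.1,
                  dd_sq = -0.00005, preci_x_dd = 0)
  p1 <- peak_level(cf0, "preci", at = 1000, means = means)$location
  p2 <- peak_level(cf0, "preci", at = 2000, means = means)$location
  expect_equal(p1, p2)
  expect_equal(p1, 0.2 / (2 * 0.0002))

  # zero curvature: explicit no-peak result
  flat <- peak_level(coef_tbl(preci = 0.1, preci_sq = 0, dd = 0.1,
                              dd_sq = -1e-5, preci_x_dd = 1e-5),
                     "preci", means = means)
  expect_identical(flat$direction, "none")
})

test_that("linear CO2 effect scales the coefficient by mean yield", {
  cf <- tibble::tibble(term = c("co2", "pbgs"), estimate = c(0, 0.1),
                       std_error = c(0.4, 0.01))
  expect_equal(linear_co2_effect(cf, mean_yield = 90)$pct_per_ppm, 0)

  cf2 <- tibble::tibble(term = "co2", estimate = 0.04453, std_error = 0.4454)
  eff <- linear_co2_effect(cf2, mean_yield = 100)
  expect_equal(eff$pct_per_ppm, 0.04453 / 100 * 100)
  # CI width is definitional: 2 * 1.96 * SE * 100 / mean yield
  expect_equal(eff$conf_high - eff$conf_low, 2 * 1.96 * 0.4454 * 100 / 100)

  quad <- ontario_reference_coefficients("corn", "quadratic")
  expect_error(linear_co2_effect(quad, mean_yield = 100), "turning")
})

test_that("attribution: zero for constant variables, closed form for pure drift", {
  sim <- simulate_panel(tiny_config(n_counties = 4, years = 1995:2013,
                                    noise_sd = 0, seed = 14))
  fit <- suppressWarnings(fit_becyr(sim$panel, model_spec("corn", "linear")))
  att <- attribution(fit)
  expect_identical(
    att$variable,
    c("pbgs", "preci+dd", "price_lag", "pf", "trend", "co2")
  )
  expect_true(all(is.finite(att$pct_of_base_yield)))

  # a variable with no drift over time contributes nothing: replace pf by a
  # fluctuation residualized against year (OLS slope exactly zero)
  frozen <- sim$panel
  eps <- sin(seq_len(nrow(frozen)))
  eps <- unname(resid(lm(eps ~ frozen$year)))
  frozen$pf <- 1.2 + 0.05 * eps / max(abs(eps))
  fit_f <- suppressWarnings(fit_becyr(frozen, model_spec("corn", "linear")))
  att_f <- attribution(fit_f)
  expect_equal(att_f$pct_of_base_yield[att_f$variable == "pf"], 0,
               tolerance = 1e-8)

  # linear drift of exactly 0.01/year in pf plus a year-orthogonal
  # fluctuation (a purely linear pf would be collinear with the trend):
  # contribution = marginal effect x drift, verified by hand
  drifted <- sim$panel
  ey <- sin(sort(unique(drifted$year)))
  ey <- unname(resid(lm(ey ~ sort(unique(drifted$year)))))
  names(ey) <- sort(unique(drifted$year))
  drifted$pf <- 1 + 0.01 * (drifted$year - min(drifted$year)) +
    0.05 * ey[as.character(drifted$year)]
  fit_d <- suppressWarnings(fit_becyr(drifted, model_spec("corn", "linear")))
  cf <- coef(fit_d)
  expected <- (cf["pf"] + 2 * cf["pf_sq"] * mean(drifted$pf)) * 0.01
  base <- mean(predict(fit_d, drifted |> dplyr::filter(year == 1995)))
  got <- attribution(fit_d)
  expect_equal(got$pct_of_base_yield[got$variable == "pf"],
               unname(100 * expected / base), tolerance = 1e-8)

  # trend always drifts by one per year
  expect_equal(att$drift_per_year[att$variable == "trend"], 1, tolerance = 1e-10)

  expect_error(attribution(fit, base_year = 1800), "absent")
})

test_that("attribution signs on study-scale synthetic data match expectations", {
  # real crop prices decline and CO2 rises under the default generator, so
  # with positive price and CO2 marginal effects the price-lag entry is
  # negative, the trend and CO2 entries positive
  sim <- simulate_panel(sim_config("corn", seed = 6))
  fit_lin <- fit_becyr(sim$panel, model_spec("corn", "linear"))
  att_lin <- attribution(fit_lin)
  expect_lt(att_lin$pct_of_base_yield[att_lin$variable == "price_lag"], 0)
  # trend and CO2 both drift upward and are near-collinear, so their split
  # is unstable under the linear-CO2 model; their joint contribution is the
  # stable positive quantity, and the no-CO2 model pins the trend sign
  joint <- sum(att_lin$pct_of_base_yield[att_lin$variable %in% c("trend", "co2")])
  expect_gt(joint, 0)
  fit_none <- fit_becyr(sim$panel, model_spec("corn", "none"))
  att_none <- attribution(fit_none)
  expect_gt(att_none$pct_of_base_yield[att_none$variable == "trend"], 0)
  expect_lt(att_none$pct_of_base_yield[att_none$variable == "price_lag"], 0)
})
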