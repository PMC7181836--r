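#' Configuration for a full synthetic yield study
#'
#' Bundles everything [simulate_panel()] needs to generate a complete,
#' truth-known dataset: the generating coefficients of the quadratic
#' fixed-effects yield model, the county intercepts, the yield-noise
#' process, the weather climatology, and the unbalancedness pattern for
#' soybeans. Defaults reproduce the Ontario study conditions: 29 counties,
#' 1959-2013, generating coefficients equal to the reference linear-CO2
#' estimates so synthetic yields are realistic in scale.
#'
#' @param crop `"corn"` or `"soybean"`.
#' @param n_counties Number of counties (>= 2).
#' @param years Panel years (span >= 3). Weather, prices and CPI are
#'   generated for one extra leading year so the lagged price and
#'   pre-season precipitation exist for the first panel year.
#' @param co2_effect Generating CO2 specification.
#' @param coefficients Named vector of generating coefficients on the
#'   design terms (see [ontario_reference_coefficients()], the default).
#'   Must be complete for the chosen `co2_effect`.
#' @param alpha County intercepts (length `n_counties`, bushels/acre);
#'   default an evenly spaced spread chosen so mean yields are crop-typical.
#' @param noise_sd Yield error standard deviation (bushels/acre, >= 0).
#'   Defaults (16 corn, 7 soybean) put the refit adjusted R-squared near
#'   the reference values (0.79 / 0.65).
#' @param noise_model `"iid"` (default), `"ar1_by_county"` (AR(1) across
#'   years within county, persistence `noise_ar1`), or `"heteroskedastic"`
#'   (sd proportional to the noiseless yield).
#' @param noise_ar1 AR(1) persistence for `"ar1_by_county"`.
#' @param seed Integer seed; identical configs give bit-identical datasets.
#' @param soybean_missingness Fraction of soybean county-years before
#'   `missing_before` dropped at random (the early-period sparsity
#'   pattern). Ignored for corn.
#' @param missing_before First year from which the soybean record is
#'   complete.
#' @param pest_year Outbreak year receiving the dummy shift (soybeans).
#' @param pest_effect Yield shift (bushels/acre) in `pest_year`; overrides
#'   the `pest` entry of `coefficients`. `NULL` keeps the coefficient set's
#'   value.
#' @param co2_observed_from First year of the *returned* observed target
#'   CO2 series. `NULL` (default) returns the full series; setting e.g.
#'   2005 truncates the observed record so that downstream analysis must
#'   reconstruct earlier years through the proxy model, as with real data.
#' @param climatology A [weather_climatology()].
#' @return An object of class `becyr_sim_config`.
#' @export
sim_config <- function(crop = c("corn", "soybean"),
                       n_counties = 29,
                       years = 1959:2013,
                       co2_effect = c("linear", "none", "quadratic"),
                       coefficients = NULL,
                       alpha = NULL,
                       noise_sd = NULL,
                       noise_model = c("iid", "ar1_by_county", "heteroskedastic"),
                       noise_ar1 = 0.5,
                       seed = 1L,
                       soybean_missingness = 0.3,
                       missing_before = 1996,
                       pest_year = 2001,
                       pest_effect = NULL,
                       co2_observed_from = NULL,
                       climatology = weather_climatology()) {
  crop <- match.arg(crop)
  co2_effect <- match.arg(co2_effect)
  noise_model <- match.arg(noise_model)
  years <- seq(min(years), max(years))
  if (n_counties < 2) abort("`n_counties` must be >= 2.")
  if (length(years) < 3) abort("`years` must span at least 3 years.")

  if (is.null(coefficients)) {
    ref <- ontario_reference_coefficients(crop, co2_effect)
    coefficients <- setNames(ref$estimate, ref$term)
  }
  required <- c("pbgs", "preci", "dd", "price_lag", "pf", "trend",
                "pbgs_sq", "preci_sq", "dd_sq", "price_lag_sq", "pf_sq",
                "trend_sq", "preci_x_dd")
  if (co2_effect != "none") required <- c(required, "co2")
  if (co2_effect == "quadratic") required <- c(required, "co2_sq")
  absent <- setdiff(required, names(coefficients))
  if (length(absent) > 0) {
    abort(paste0("Coefficient set incomplete for co2_effect = '", co2_effect,
                 "'; missing: ", paste(absent, collapse = ", ")))
  }
  if (crop == "soybean" && !is.null(pest_effect)) {
    coefficients["pest"] <- pest_effect
  }

  if (is.null(alpha)) {
    alpha <- if (crop == "corn") {
      seq(-110, -80, length.out = n_counties)
    } else {
      seq(-62, -44, length.out = n_counties)
    }
  }
  if (length(alpha) != n_counties) {
    abort("`alpha` must have one intercept per county.")
  }
  if (is.null(noise_sd)) noise_sd <- if (crop == "corn") 16 else 7
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")

  structure(
    list(crop = crop, n_counties = n_counties, years = years,
         co2_effect = co2_effect, coefficients = coefficients, alpha = alpha,
         noise_sd = noise_sd, noise_model = noise_model, noise_ar1 = noise_ar1,
         seed = as.integer(seed), soybean_missingness = soybean_missingness,
         missing_before = missing_before, pest_year = pest_year,
         co2_observed_from = co2_observed_from, climatology = climatology),
    class = "becyr_sim_config"
  )
}

#' @export
print.becyr_sim_config <- function(x, ...) {
  cat(sprintf("<becyr_sim_config> %s, %d counties x %d years (%d-%d)\n",
              x$crop, x$n_counties, length(x$years), min(x$years), max(x$years)))
  cat(sprintf("  CO2 effect: %s; noise: %s sd %.1f bu/ac; seed %d\n",
              x$co2_effect, x$noise_model, x$noise_sd, x$seed))
  invisible(x)
}

# Economic series emulation: a slowly declining real crop price and real
# fertilizer index (with a 1970s-style bump) under steadily rising CPI.
# Units: real price in hundreds of base-2002 dollars per tonne, fertilizer
# index real level / 100 -- the scales behind the reference coefficients.
#' @noRd
simulate_economics <- function(crop, years_ext, seed) {
  withr::local_seed(seed)
  n <- length(years_ext)
  cpi <- tibble(year = years_ext, cpi = 100 * 1.039^(years_ext - 2002))

  start_real <- if (crop == "corn") 4.2 else 3.6
  end_real <- if (crop == "corn") 2.2 else 2.1
  trend_path <- seq(start_real, end_real, length.out = n)
  ar <- as.numeric(stats::filter(rnorm(n, 0, 0.22 * sqrt(1 - 0.6^2)),
                                 0.6, method = "recursive"))
  real_price <- pmax(0.5, trend_path + ar)
  nominal_annual <- real_price * cpi$cpi / 100 * 100  # back to $/tonne-like level
  prices <- tidyr::expand_grid(year = years_ext, month = 1:12) |>
    left_join(tibble(year = years_ext, annual = nominal_annual), by = "year") |>
    group_by(.data$year) |>
    mutate(dev = {
      d <- rnorm(dplyr::n(), 0, 0.04 * .data$annual[1])
      d - mean(d)
    }) |>
    ungroup() |>
    transmute(.data$year, .data$month, price = .data$annual + .data$dev)

  pf_trend <- seq(1.55, 0.95, length.out = n)
  bump <- 0.35 * exp(-((years_ext - 1975) / 4)^2)
  pf_ar <- as.numeric(stats::filter(rnorm(n, 0, 0.05 * sqrt(1 - 0.6^2)),
                                    0.6, method = "recursive"))
  real_pf <- pmax(0.4, pf_trend + bump + pf_ar)
  pf_nominal_annual <- real_pf * cpi$cpi
  fertilizer <- tidyr::expand_grid(year = years_ext, quarter = 1:4) |>
    left_join(tibble(year = years_ext, annual = pf_nominal_annual), by = "year") |>
    group_by(.data$year) |>
    mutate(dev = {
      d <- rnorm(dplyr::n(), 0, 0.015 * .data$annual[1])
      d - mean(d)
    }) |>
    ungroup() |>
    transmute(.data$year, .data$quarter, index = .data$annual + .data$dev)

  list(prices = prices, cpi = cpi, fertilizer = fertilizer)
}

#' @noRd
simulate_yield_noise <- function(config, panel, noiseless) {
  n <- nrow(panel)
  if (config$noise_sd == 0) return(numeric(n))
  switch(config$noise_model,
    iid = rnorm(n, 0, config$noise_sd),
    ar1_by_county = {
      rho <- config$noise_ar1
      panel |>
        mutate(.row = dplyr::row_number()) |>
        group_by(.data$county) |>
        arrange(.data$year, .by_group = TRUE) |>
        mutate(.e = as.numeric(stats::filter(
          rnorm(dplyr::n(), 0, config$noise_sd * sqrt(1 - rho^2)),
          rho, method = "recursive"))) |>
        ungroup() |>
        arrange(.data$.row) |>
        dplyr::pull(".e")
    },
    heteroskedastic = {
      scale <- abs(noiseless) / mean(abs(noiseless))
      rnorm(n, 0, config$noise_sd * scale)
    }
  )
}

#' Generate a complete synthetic yield study
#'
#' Simulates every input the analysis pipeline consumes -- daily county
#' weather, a reference/target monthly CO2 pair, monthly prices, CPI, a
#' quarterly fertilizer index, and county-year yields with harvest areas --
#' and also returns the assembled estimation panel and the generating
#' truth. Yields are computed exactly from the quadratic fixed-effects
#' model applied to the realized regressors (interaction centered at the
#' realized sample means of the returned panel), plus the configured noise;
#' the soybean variant applies the early-period missingness pattern and the
#' pest-year shift.
#'
#' @param config A [sim_config()].
#' @return An object of class `becyr_simulation`: a list with tibbles
#'   `weather`, `co2_reference`, `co2_target` (observed record, possibly
#'   truncated per `co2_observed_from`), `prices`, `cpi`, `fertilizer`,
#'   `yields`, `features`, `panel`, and `truth` (generating coefficients
#'   including county intercepts, centering means, the full CO2 target
#'   series, and the config).
#' @examples
#' sim <- simulate_panel(sim_config(n_counties = 3, years = 2000:2006,
#'                                  noise_sd = 0, seed = 7))
#' fit_becyr(sim$panel, model_spec("corn", "linear"))
#' @export
simulate_panel <- function(config) {
  if (!inherits(config, "becyr_sim_config")) {
    abort("`config` must come from sim_config().")
  }
  withr::local_seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1, config$n_counties + 4)

  years <- config$years
  years_ext <- c(min(years) - 1L, years)
  county_ids <- sprintf("C%02d", seq_len(config$n_counties))

  weather <- purrr::map2(county_ids, seeds[seq_len(config$n_counties)],
    function(id, s) {
      simulate_daily_weather(config$climatology, id, years_ext, seed = s)
    }) |>
    purrr::list_rbind()

  co2 <- simulate_co2_pair(years, seed = seeds[config$n_counties + 1])
  econ <- simulate_economics(config$crop, years_ext,
                             seed = seeds[config$n_counties + 2])

  features <- suppressWarnings(climate_features(weather, years = years))
  co2_year <- season_co2(co2$target, provincial_season(features))

  # harvest areas; soybeans scale up over time with sparse small-area
  # counties early on
  withr::local_seed(seeds[config$n_counties + 3])
  area_grid <- tidyr::expand_grid(county = county_ids, year = years)
  if (config$crop == "corn") {
    base_area <- setNames(runif(config$n_counties, 15000, 60000), county_ids)
    area_grid$area <- base_area[area_grid$county] *
      exp(rnorm(nrow(area_grid), 0, 0.08))
  } else {
    base_area <- setNames(runif(config$n_counties, 4000, 30000), county_ids)
    ramp <- 1 / (1 + exp(-(area_grid$year - 1985) / 8))
    area_grid$area <- pmax(300, base_area[area_grid$county] * ramp *
                             exp(rnorm(nrow(area_grid), 0, 0.15)))
  }

  yields0 <- area_grid |>
    mutate(crop = config$crop, yield = 0) |>
    select("county", "year", "crop", "yield", "area")

  if (config$crop == "soybean" && config$soybean_missingness > 0) {
    early <- yields0$year < config$missing_before
    drop <- early & runif(nrow(yields0)) < config$soybean_missingness
    yields0 <- yields0[!drop, ]
  }

  pest_in_truth <- "pest" %in% names(config$coefficients)
  panel0 <- assemble_panel(
    features, co2_year, econ$prices, econ$cpi, econ$fertilizer, yields0,
    crop = config$crop,
    pest_year = if (pest_in_truth) config$pest_year else NULL
  )

  gen_spec <- model_spec(config$crop, config$co2_effect,
                         pest_dummy = pest_in_truth)
  design <- build_design(panel0, gen_spec)
  means <- attr(design, "means")
  terms <- setdiff(names(design), "county")
  cf <- config$coefficients[terms]
  alpha <- setNames(config$alpha, county_ids)
  noiseless <- unname(alpha[as.character(panel0$county)]) +
    as.numeric(as.matrix(design[terms]) %*% cf)

  withr::local_seed(seeds[config$n_counties + 4])
  noise <- simulate_yield_noise(config, panel0, noiseless)
  panel <- panel0
  panel$yield <- noiseless + noise

  yields <- panel |>
    select("county", "year", "crop", "yield", "area") |>
    as_tibble()

  co2_target_obs <- co2$target
  if (!is.null(config$co2_observed_from)) {
    co2_target_obs <- co2_target_obs |>
      filter(.data$year >= config$co2_observed_from)
  }

  structure(
    list(
      weather = weather,
      co2_reference = co2$reference,
      co2_target = co2_target_obs,
      prices = econ$prices,
      cpi = econ$cpi,
      fertilizer = econ$fertilizer,
      yields = yields,
      features = features,
      panel = panel,
      truth = list(
        coefficients = cf,
        alpha = alpha,
        means = means,
        noise_sd = config$noise_sd,
        co2_full = co2$target,
        co2_pair_truth = co2$truth,
        config = config
      )
    ),
    class = "becyr_simulation"
  )
}

#' @export
print.becyr_simulation <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("<becyr_simulation> %s, %d counties, %d-%d\n",
              cfg$crop, cfg$n_counties, min(cfg$years), max(cfg$years)))
  cat(sprintf("  panel rows: %d; weather days: %d; noise sd %.1f (%s)\n",
              nrow(x$panel), nrow(x$weather), cfg$noise_sd, cfg$noise_model))
  invisible(x)
}
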