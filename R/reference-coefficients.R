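#' Reference BECYR coefficient sets for Ontario corn and soybeans, 1959-2013
#'
#' Returns the reference estimates of the county fixed-effects quadratic
#' yield response model for Ontario grain corn and soybeans over 1959-2013,
#' under one of three CO2 specifications (no CO2 term, linear CO2 term, or
#' linear plus quadratic CO2 terms). These are the canonical published
#' estimates for this model; the package uses them in two roles:
#'
#' * as the default generating coefficients of [simulate_panel()], so that
#'   synthetic panels are realistic in scale, and
#' * as direct inputs to the response analyses ([co2_turning_point()],
#'   [peak_level()], [linear_co2_effect()]), which are closed forms in the
#'   coefficients alone.
#'
#' Units behind the coefficients: yields in bushels/acre; `pbgs` and `preci`
#' in mm; `dd` in degree-days above 10 degrees C; `price_lag` the one-year
#' lagged real crop price in hundreds of 2002 dollars per tonne; `pf` the
#' real fertilizer price index divided by 100 (2002 dollars); `trend` the
#' integers 1..55; `co2` growing-season CO2 in ppm. The soybean model also
#' carries `pest`, a 0/1 indicator for the 2001 aphid outbreak year.
#'
#' @param crop `"corn"` or `"soybean"`.
#' @param co2_effect `"none"`, `"linear"`, or `"quadratic"`.
#'
#' @return A tibble with columns `term`, `label`, `estimate`, `std_error`.
#'   Terms use the package's design-column names (`pbgs`, `preci`, `dd`,
#'   `price_lag`, `pf`, `trend`, `co2`, their `_sq` squares, the centered
#'   interaction `preci_x_dd`, and `pest` for soybeans).
#' @examples
#' ontario_reference_coefficients("corn", "quadratic") |>
#'   co2_turning_point()
#' @export
ontario_reference_coefficients <- function(crop = c("corn", "soybean"),
                                           co2_effect = c("linear", "none", "quadratic")) {
  crop <- match.arg(crop)
  co2_effect <- match.arg(co2_effect)

  labels <- c(
    pest         = "Dummy of 2001",
    pbgs         = "Precipitation Before Growing Season",
    preci        = "Precipitation During Growing Season",
    dd           = "Degree Days During Growing Season",
    price_lag    = "Crop Price Lagged One-Year",
    pf           = "Fertilizer Price Index",
    trend        = "Trend",
    co2          = "Local CO2 During Growing Season",
    pbgs_sq      = "Square of Precipitation Before Growing Season",
    preci_sq     = "Square of Precipitation During Growing Season",
    dd_sq        = "Square of Degree Days During Growing Season",
    price_lag_sq = "Square of Crop Price Lagged One-Year",
    pf_sq        = "Square of Fertilizer Price Index",
    trend_sq     = "Square of Trend",
    co2_sq       = "Square of Local CO2 During Growing Season",
    preci_x_dd   = "Interaction of Precipitation and Degree Days"
  )

  corn <- list(
    none = c(
      pbgs = -0.1091, preci = 0.1697, dd = 0.1869, price_lag = 25.70,
      pf = -71.29, trend = 0.2906,
      pbgs_sq = 0.0002489, preci_sq = -0.0001594, dd_sq = -0.00006497,
      price_lag_sq = -4.002, pf_sq = 22.59, trend_sq = 0.02325,
      preci_x_dd = 0.0002266
    ),
    linear = c(
      pbgs = -0.1088, preci = 0.1697, dd = 0.1867, price_lag = 25.71,
      pf = -71.33, trend = 0.2563, co2 = 0.04453,
      pbgs_sq = 0.0002483, preci_sq = -0.0001595, dd_sq = -0.00006496,
      price_lag_sq = -4.000, pf_sq = 22.60, trend_sq = 0.02275,
      preci_x_dd = 0.0002265
    ),
    quadratic = c(
      pbgs = -0.08372, preci = 0.1631, dd = 0.1866, price_lag = 21.82,
      pf = -92.88, trend = 2.737, co2 = -16.35,
      pbgs_sq = 0.0001937, preci_sq = -0.0001517, dd_sq = -0.00006460,
      price_lag_sq = -3.589, pf_sq = 28.90, trend_sq = -0.01624,
      co2_sq = 0.02315, preci_x_dd = 0.0002201
    )
  )
  corn_se <- list(
    none = c(
      pbgs = 0.04055, preci = 0.01649, dd = 0.02179, price_lag = 2.057,
      pf = 8.952, trend = 0.1691,
      pbgs_sq = 0.00008557, preci_sq = 0.00001669, dd_sq = 0.000009012,
      price_lag_sq = 0.3407, pf_sq = 2.755, trend_sq = 0.002395,
      preci_x_dd = 0.00002119
    ),
    linear = c(
      pbgs = 0.04156, preci = 0.01646, dd = 0.02210, price_lag = 2.05,
      pf = 8.789, trend = 0.3211, co2 = 0.4454,
      pbgs_sq = 0.00008762, preci_sq = 0.00001668, dd_sq = 0.000009010,
      price_lag_sq = 0.3424, pf_sq = 2.723, trend_sq = 0.006010,
      preci_x_dd = 0.00002121
    ),
    quadratic = c(
      pbgs = 0.04095, preci = 0.01645, dd = 0.02160, price_lag = 1.958,
      pf = 9.069, trend = 0.4153, co2 = 1.77,
      pbgs_sq = 0.00008565, preci_sq = 0.00001733, dd_sq = 0.000008757,
      price_lag_sq = 0.3330, pf_sq = 2.821, trend_sq = 0.007021,
      co2_sq = 0.002384, preci_x_dd = 0.00002066
    )
  )

  soy <- list(
    none = c(
      pest = -11.53, pbgs = 0.03554, preci = 0.07197, dd = 0.05434,
      price_lag = 7.582, pf = -50.25, trend = 0.03450,
      pbgs_sq = -0.00005486, preci_sq = -0.00005729, dd_sq = -0.00001680,
      price_lag_sq = -0.5621, pf_sq = 15.24, trend_sq = 0.006238,
      preci_x_dd = 0.00003381
    ),
    linear = c(
      pest = -11.36, pbgs = 0.03759, preci = 0.07143, dd = 0.05310,
      price_lag = 7.607, pf = -50.55, trend = -0.05598, co2 = 0.1208,
      pbgs_sq = -0.00005929, preci_sq = -0.00005694, dd_sq = -0.00001649,
      price_lag_sq = -0.5635, pf_sq = 15.34, trend_sq = 0.004846,
      preci_x_dd = 0.00003385
    ),
    quadratic = c(
      pest = -11.09, pbgs = 0.04349, preci = 0.07058, dd = 0.05020,
      price_lag = 7.405, pf = -53.39, trend = 0.6310, co2 = -3.352,
      pbgs_sq = -0.00007115, preci_sq = -0.00005612, dd_sq = -0.00001522,
      price_lag_sq = -0.5658, pf_sq = 16.12, trend_sq = -0.001959,
      co2_sq = 0.004658, preci_x_dd = 0.00003522
    )
  )
  soy_se <- list(
    none = c(
      pest = 0.9217, pbgs = 0.02401, preci = 0.01073, dd = 0.007541,
      price_lag = 0.6085, pf = 4.79, trend = 0.07523,
      pbgs_sq = 0.00005219, preci_sq = 0.000009761, dd_sq = 0.000002806,
      price_lag_sq = 0.05585, pf_sq = 1.515, trend_sq = 0.001078,
      preci_x_dd = 0.000008023
    ),
    linear = c(
      pest = 1.000, pbgs = 0.02498, preci = 0.01047, dd = 0.008941,
      price_lag = 0.6106, pf = 4.635, trend = 0.1765, co2 = 0.2431,
      pbgs_sq = 0.00005418, preci_sq = 0.000009549, dd_sq = 0.000003148,
      price_lag_sq = 0.05606, pf_sq = 1.466, trend_sq = 0.003289,
      preci_x_dd = 0.000008022
    ),
    quadratic = c(
      pest = 0.9876, pbgs = 0.02545, preci = 0.01048, dd = 0.009281,
      price_lag = 0.6094, pf = 4.623, trend = 0.2175, co2 = 0.7144,
      pbgs_sq = 0.0000553, preci_sq = 0.000009665, dd_sq = 0.000003289,
      price_lag_sq = 0.05649, pf_sq = 1.461, trend_sq = 0.003687,
      co2_sq = 0.0009189, preci_x_dd = 0.000008045
    )
  )

  est <- if (crop == "corn") corn[[co2_effect]] else soy[[co2_effect]]
  se <- if (crop == "corn") corn_se[[co2_effect]] else soy_se[[co2_effect]]

  tibble(
    term = names(est),
    label = unname(labels[names(est)]),
    estimate = unname(est),
    std_error = unname(se[names(est)])
  )
}

#' Model-level reference statistics for the Ontario yield models
#'
#' Companion to [ontario_reference_coefficients()]: sample size, adjusted
#' R-squared and F statistic reported for each crop and CO2 specification.
#'
#' @inheritParams ontario_reference_coefficients
#' @return A one-row tibble with columns `crop`, `co2_effect`, `n`,
#'   `adj_r_squared`, `f_statistic`.
#' @export
ontario_reference_stats <- function(crop = c("corn", "soybean"),
                                    co2_effect = c("linear", "none", "quadratic")) {
  crop <- match.arg(crop)
  co2_effect <- match.arg(co2_effect)
  stats <- list(
    corn = list(
      none = c(n = 1594, adj_r_squared = 0.7869, f_statistic = 503.0),
      linear = c(n = 1594, adj_r_squared = 0.7864, f_statistic = 466.7),
      quadratic = c(n = 1594, adj_r_squared = 0.7919, f_statistic = 453.4)
    ),
    soybean = list(
      none = c(n = 829, adj_r_squared = 0.6529, f_statistic = 124.2),
      linear = c(n = 829, adj_r_squared = 0.6522, f_statistic = 115.8),
      quadratic = c(n = 829, adj_r_squared = 0.6535, f_statistic = 109.6)
    )
  )
  s <- stats[[crop]][[co2_effect]]
  tibble(crop = crop, co2_effect = co2_effect,
         n = unname(s["n"]),
         adj_r_squared = unname(s["adj_r_squared"]),
         f_statistic = unname(s["f_statistic"]))
}
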