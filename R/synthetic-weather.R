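#' Weather climatology for the synthetic daily generator
#'
#' Bundles the parameters of the stochastic daily-weather process used by
#' [simulate_daily_weather()]. Daily mean temperature is an AR(1) anomaly
#' around a sinusoidal annual cycle; daily minimum temperature sits a fixed
#' offset below the mean plus its own noise; precipitation is a
#' Bernoulli-gamma mixture (wet/dry day, gamma amounts on wet days). The
#' defaults are tuned to a southern-Ontario-like climate: frost-free seasons
#' (last/first occurrence of -2.2 degrees C on daily minima) that start in
#' late April and end in mid October on average, growing-season
#' precipitation of roughly 400-600 mm, and 1100-1600 degree-days above
#' 10 degrees C.
#'
#' @param mean_temp Annual mean of daily mean temperature (degrees C).
#' @param amplitude Seasonal amplitude of the sinusoid (degrees C, >= 0).
#' @param phase_doy Day of year at which the sinusoid crosses its annual
#'   mean going up; the seasonal peak falls a quarter cycle later.
#' @param warming_per_decade Linear drift of `mean_temp` (degrees C per
#'   decade), producing a slow lengthening of the frost-free season.
#' @param ar1 AR(1) persistence of daily temperature anomalies, in \[0, 1).
#' @param anomaly_sd Marginal standard deviation of daily anomalies
#'   (degrees C).
#' @param tmin_offset Mean gap between daily mean and daily minimum
#'   temperature (degrees C, >= 0).
#' @param tmin_sd Standard deviation of the extra daily-minimum noise
#'   (degrees C).
#' @param wet_prob Probability a day is wet, in \[0, 1\].
#' @param precip_shape,precip_scale Gamma shape and scale (mm) of wet-day
#'   precipitation amounts.
#' @return An object of class `becyr_climatology` (a named list).
#' @examples
#' clim <- weather_climatology()
#' simulate_daily_weather(clim, "C01", 2000:2001, seed = 1)
#' @export
weather_climatology <- function(mean_temp = 6.5,
                                amplitude = 14,
                                phase_doy = 110,
                                warming_per_decade = 0.15,
                                ar1 = 0.7,
                                anomaly_sd = 3.8,
                                tmin_offset = 5,
                                tmin_sd = 1.5,
                                wet_prob = 0.4,
                                precip_shape = 0.8,
                                precip_scale = 9) {
  stopifnot(
    is.numeric(amplitude), length(amplitude) == 1, amplitude >= 0,
    is.numeric(wet_prob), wet_prob >= 0, wet_prob <= 1,
    ar1 >= 0, ar1 < 1,
    anomaly_sd >= 0, tmin_sd >= 0, tmin_offset >= 0,
    precip_shape > 0, precip_scale >= 0
  )
  structure(
    list(
      mean_temp = mean_temp, amplitude = amplitude, phase_doy = phase_doy,
      warming_per_decade = warming_per_decade, ar1 = ar1,
      anomaly_sd = anomaly_sd, tmin_offset = tmin_offset, tmin_sd = tmin_sd,
      wet_prob = wet_prob, precip_shape = precip_shape,
      precip_scale = precip_scale
    ),
    class = "becyr_climatology"
  )
}

#' @export
print.becyr_climatology <- function(x, ...) {
  cat("<becyr_climatology>\n")
  cat(sprintf("  tmean: %.1f C +/- %.1f C seasonal, AR(1) %.2f, anomaly sd %.1f C\n",
              x$mean_temp, x$amplitude, x$ar1, x$anomaly_sd))
  cat(sprintf("  tmin offset: %.1f C (sd %.1f); warming %.2f C/decade\n",
              x$tmin_offset, x$tmin_sd, x$warming_per_decade))
  cat(sprintf("  precip: wet prob %.2f, gamma(shape %.2f, scale %.1f mm)\n",
              x$wet_prob, x$precip_shape, x$precip_scale))
  invisible(x)
}

#' Simulate a daily county weather series
#'
#' Generates one record per calendar day (leap days included) for the given
#' years, with columns `county`, `date`, `tmin`, `tmean`, `precip`. The
#' process is described in [weather_climatology()]. `tmin <= tmean` holds on
#' every day and `precip >= 0`.
#'
#' @param climatology A [weather_climatology()] object.
#' @param county_id Identifier stored in the `county` column.
#' @param years Integer vector of calendar years (need not start the panel;
#'   the pipeline typically simulates one extra leading year so that
#'   pre-season precipitation is available for the first panel year).
#' @param seed Integer seed; identical seeds give byte-identical series.
#' @return A tibble of daily records.
#' @export
simulate_daily_weather <- function(climatology, county_id, years, seed = 1L) {
  if (!inherits(climatology, "becyr_climatology")) {
    abort("`climatology` must be a weather_climatology() object.")
  }
  years <- as.integer(years)
  if (length(years) == 0 || anyNA(years)) {
    abort("`years` must be a non-empty vector of calendar years.")
  }
  years <- seq(min(years), max(years))
  withr::local_seed(as.integer(seed))
  dates <- seq(make_date(min(years), 1, 1), make_date(max(years), 12, 31), by = "day")
  n <- length(dates)
  doy <- yday(dates)
  yr <- year(dates)

  base <- climatology$mean_temp +
    climatology$warming_per_decade * (yr - years[1]) / 10 +
    climatology$amplitude * sin(2 * pi * (doy - climatology$phase_doy) / 365.25)

  if (climatology$anomaly_sd > 0) {
    innov_sd <- climatology$anomaly_sd * sqrt(1 - climatology$ar1^2)
    anom <- as.numeric(stats::filter(rnorm(n, 0, innov_sd),
                                     climatology$ar1, method = "recursive"))
  } else {
    anom <- numeric(n)
  }
  tmean <- base + anom
  tmin <- tmean - climatology$tmin_offset +
    (if (climatology$tmin_sd > 0) rnorm(n, 0, climatology$tmin_sd) else 0)
  tmin <- pmin(tmin, tmean)

  wet <- if (climatology$wet_prob > 0) rbinom(n, 1, climatology$wet_prob) else integer(n)
  precip <- numeric(n)
  nw <- sum(wet)
  if (nw > 0 && climatology$precip_scale > 0) {
    precip[wet == 1] <- rgamma(nw, shape = climatology$precip_shape,
                               scale = climatology$precip_scale)
  }

  tibble(
    county = as.character(county_id),
    date = dates,
    tmin = tmin,
    tmean = tmean,
    precip = precip
  )
}
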