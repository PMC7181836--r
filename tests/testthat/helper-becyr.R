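# Fixture builders and independent brute-force oracles shared across tests.

# A fully specified daily series from explicit vectors (recycled), one
# county, covering `years` completely.
make_weather <- function(years, tmin = -10, tmean = NULL, precip = 0,
                         county = "C01") {
  dates <- seq(lubridate::make_date(min(years), 1, 1),
               lubridate::make_date(max(years), 12, 31), by = "day")
  n <- length(dates)
  if (is.null(tmean)) tmean <- tmin + 5
  tibble::tibble(
    county = county,
    date = dates,
    tmin = rep_len(tmin, n),
    tmean = rep_len(tmean, n),
    precip = rep_len(precip, n)
  )
}

# Random short weather series (complete coverage of one year).
random_weather <- function(year = 2000, county = "C01") {
  w <- make_weather(year, county = county)
  n <- nrow(w)
  w$tmean <- runif(n, -5, 28)
  w$tmin <- w$tmean - runif(n, 0, 8)
  w$precip <- ifelse(runif(n) < 0.4, rgamma(n, 0.8, scale = 8), 0)
  w
}

one_season <- function(year, start_doy, end_doy, county = "C01") {
  tibble::tibble(
    county = county, year = year,
    start = lubridate::make_date(year, 1, 1) + (start_doy - 1),
    end = lubridate::make_date(year, 1, 1) + (end_doy - 1)
  )
}

# --- independent oracles (plain loops / closed forms) ---

oracle_window_sum <- function(weather, start, end, f) {
  total <- 0
  for (i in seq_len(nrow(weather))) {
    d <- weather$date[i]
    if (d >= start && d <= end) {
      total <- total + f(weather$tmean[i], weather$precip[i])
    }
  }
  total
}

oracle_dd <- function(weather, start, end, base = 10) {
  oracle_window_sum(weather, start, end,
                    function(tm, pr) max(0, tm - base))
}

oracle_precip <- function(weather, start, end) {
  oracle_window_sum(weather, start, end, function(tm, pr) pr)
}

# Normal-equations least squares, independent of lm. Columns are scaled to
# unit norm first so the explicit solve stays well conditioned on raw
# regressors spanning many orders of magnitude.
oracle_ols <- function(X, y) {
  s <- sqrt(colSums(X^2))
  Xs <- sweep(X, 2, s, "/")
  b <- drop(solve(t(Xs) %*% Xs, t(Xs) %*% y))
  b / s
}

# Area-weighted merge by explicit loop.
oracle_merge <- function(yields, areas) {
  sum(yields * areas) / sum(areas)
}

# Small, fast simulation config for pipeline tests.
tiny_config <- function(..., crop = "corn", n_counties = 4,
                        years = 2000:2009, seed = 42) {
  sim_config(crop = crop, n_counties = n_counties, years = years,
             seed = seed, ...)
}
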