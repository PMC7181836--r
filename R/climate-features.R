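#' @noRd
check_weather_frame <- function(weather) {
  needed <- c("county", "date", "tmin", "tmean", "precip")
  missing <- setdiff(needed, names(weather))
  if (length(missing) > 0) {
    abort(paste0("`weather` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(weather)
}

# Complete each county's calendar and linearly interpolate short gaps.
# More than `max_missing` absent or NA days in any county-year is an error:
# frost-date detection is unreliable on sparse records.
#' @noRd
complete_daily_weather <- function(weather, max_missing = 5) {
  check_weather_frame(weather)
  wx <- weather |>
    mutate(date = as.Date(.data$date)) |>
    arrange(.data$county, .data$date)
  # fast path: per-county contiguous daily coverage with no NAs needs no work
  spans <- wx |>
    summarise(n = dplyr::n(),
              expected = as.integer(max(.data$date) - min(.data$date)) + 1L,
              .by = "county")
  if (all(spans$n == spans$expected) &&
      !anyNA(wx$tmin) && !anyNA(wx$tmean) && !anyNA(wx$precip)) {
    return(wx)
  }

  out <- wx |>
    group_by(.data$county) |>
    tidyr::complete(date = seq(make_date(min(year(.data$date)), 1, 1),
                               make_date(max(year(.data$date)), 12, 31),
                               by = "day")) |>
    arrange(.data$date, .by_group = TRUE) |>
    mutate(missing = !complete.cases(.data$tmin, .data$tmean, .data$precip)) |>
    ungroup()

  gaps <- out |>
    group_by(.data$county, year = year(.data$date)) |>
    summarise(n_missing = sum(.data$missing), .groups = "drop") |>
    filter(.data$n_missing > max_missing)
  if (nrow(gaps) > 0) {
    abort(paste0(
      "Too many missing daily records (> ", max_missing, "/year) for: ",
      paste(sprintf("%s %d (%d missing)", gaps$county, gaps$year, gaps$n_missing),
            collapse = "; ")
    ))
  }

  out |>
    group_by(.data$county) |>
    mutate(across(c("tmin", "tmean", "precip"), function(v) {
      if (!anyNA(v)) return(v)
      approx(x = as.numeric(date)[!is.na(v)], y = v[!is.na(v)],
             xout = as.numeric(date), rule = 2)$y
    })) |>
    ungroup() |>
    select(-"missing")
}

#' Detect frost-free growing seasons from daily minimum temperature
#'
#' The growing season of a year starts on the day after the last spring
#' occurrence of daily minimum temperature at or below `frost_threshold`,
#' and ends on the day before the first fall occurrence. "Spring" is the
#' window before `split_doy` (day-of-year, default July 1) and "fall" the
#' window from `split_doy` onward. If no spring frost occurs the season
#' starts January 1; if no fall frost occurs it ends December 31.
#'
#' The frost test is applied to `tmin`: a -2.2 degree C event is
#' conventionally a daily-minimum (frost) event. Up to `max_missing` absent
#' or NA days per county-year are filled by linear interpolation; more is an
#' error.
#'
#' @param weather Daily weather tibble with columns `county`, `date`,
#'   `tmin`, `tmean`, `precip` (see [simulate_daily_weather()]).
#' @param years Optional integer vector restricting which years to detect;
#'   default all fully covered years in `weather`. Requesting a year absent
#'   from the series is an error.
#' @param frost_threshold Frost temperature (degrees C), default -2.2.
#' @param split_doy Day-of-year separating the spring and fall search
#'   windows (default 183, July 1 in non-leap years).
#' @param max_missing Maximum interpolatable missing days per county-year.
#' @return A tibble with one row per county-year: `county`, `year`,
#'   `start`, `end` (dates), `length` (days, `end - start + 1`).
#' @examples
#' w <- simulate_daily_weather(weather_climatology(), "C01", 2000:2002, seed = 3)
#' detect_growing_season(w)
#' @export
detect_growing_season <- function(weather, years = NULL,
                                  frost_threshold = -2.2, split_doy = 183,
                                  max_missing = 5) {
  wx <- complete_daily_weather(weather, max_missing = max_missing)
  lt <- as.POSIXlt(wx$date)
  wx$year <- lt$year + 1900L
  wx$doy <- lt$yday + 1L
  covered <- wx |>
    summarise(n = dplyr::n(), .by = c("county", "year")) |>
    filter(.data$n >= 365)
  if (!is.null(years)) {
    years <- as.integer(years)
    bad <- setdiff(years, unique(covered$year))
    if (length(bad) > 0) {
      abort(paste0("Year(s) not covered by `weather`: ", paste(bad, collapse = ", ")))
    }
    covered <- covered |> filter(.data$year %in% years)
  }
  frosty <- wx |>
    filter(.data$tmin <= frost_threshold) |>
    select("county", "year", "doy")
  summarise_frost <- function(data, fn, out) {
    if (nrow(data) == 0) {
      return(tibble(county = character(), year = integer(),
                    "{out}" := integer()))
    }
    data |>
      summarise("{out}" := fn(.data$doy), .by = c("county", "year"))
  }
  spring <- frosty |>
    filter(.data$doy < split_doy) |>
    summarise_frost(max, "last_spring")
  fall <- frosty |>
    filter(.data$doy >= split_doy) |>
    summarise_frost(min, "first_fall")
  covered |>
    select("county", "year") |>
    left_join(spring, by = c("county", "year")) |>
    left_join(fall, by = c("county", "year")) |>
    mutate(
      start = make_date(.data$year, 1, 1) +
        dplyr::coalesce(.data$last_spring, 0L),
      end = dplyr::if_else(
        is.na(.data$first_fall),
        make_date(.data$year, 12, 31),
        make_date(.data$year, 1, 1) + (.data$first_fall - 2L)
      ),
      length = as.integer(.data$end - .data$start) + 1L
    ) |>
    select("county", "year", "start", "end", "length") |>
    arrange(.data$county, .data$year)
}

#' @noRd
check_seasons_frame <- function(seasons) {
  needed <- c("county", "year", "start", "end")
  missing <- setdiff(needed, names(seasons))
  if (length(missing) > 0) {
    abort(paste0("`seasons` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(seasons$end < seasons$start)) abort("Empty season: `end` before `start`.")
  invisible(seasons)
}

# Sum f(day) over [start, end] per season row, erroring when the series
# does not fully cover the window. Uses per-county cumulative sums with a
# keyed date lookup: linear in the data, not in seasons x days.
#' @noRd
accumulate_over_seasons <- function(weather, seasons, value_fun, out_name) {
  check_weather_frame(weather)
  check_seasons_frame(seasons)
  wx <- weather |>
    mutate(date = as.Date(.data$date)) |>
    arrange(.data$county, .data$date)
  counties <- unique(wx$county)
  cid <- match(wx$county, counties)
  dint <- as.integer(wx$date)
  # composite numeric key; dates span far less than 1e7 distinct days
  key <- cid * 1e7 + (dint - min(dint))
  if (anyDuplicated(key)) {
    abort("`weather` has duplicate (county, date) records.")
  }
  val <- value_fun(wx$tmean, wx$precip)
  cs <- cumsum(val)  # windows never straddle counties (keys carry county)

  s_cid <- match(seasons$county, counties)
  i0 <- match(s_cid * 1e7 + (as.integer(as.Date(seasons$start)) - min(dint)), key)
  i1 <- match(s_cid * 1e7 + (as.integer(as.Date(seasons$end)) - min(dint)), key)
  expected <- as.integer(as.Date(seasons$end) - as.Date(seasons$start)) + 1L
  # i1 - i0 + 1 == expected rules out interior gaps, since dates are sorted
  # and unique within county
  ok <- !is.na(i0) & !is.na(i1) & (i1 - i0 + 1L) == expected
  if (any(!ok)) {
    bad <- seasons[!ok, ]
    abort(paste0(
      "Season window(s) not fully covered by `weather`: ",
      paste(sprintf("%s %d", bad$county, bad$year), collapse = "; ")
    ))
  }
  tibble(
    county = seasons$county,
    year = seasons$year,
    value = cs[i1] - cs[i0] + val[i0]
  ) |>
    rlang::set_names(c("county", "year", out_name))
}

#' Growing-degree-day accumulation over detected seasons
#'
#' Sums `max(0, tmean - base)` over every day of each season window: the
#' standard heat-supply index with daily mean temperature and a fixed base
#' (default 10 degrees C, the corn/soybean convention).
#'
#' @inheritParams detect_growing_season
#' @param seasons Season tibble from [detect_growing_season()] (columns
#'   `county`, `year`, `start`, `end`).
#' @param base Base temperature (degrees C).
#' @return A tibble `county`, `year`, `dd` (degree-days, >= 0).
#' @export
degree_days <- function(weather, seasons, base = 10) {
  accumulate_over_seasons(
    weather, seasons,
    function(tmean, precip) pmax(0, tmean - base),
    "dd"
  )
}

#' Total precipitation over detected seasons
#'
#' @inheritParams degree_days
#' @return A tibble `county`, `year`, `preci` (mm).
#' @export
season_precip <- function(weather, seasons) {
  accumulate_over_seasons(
    weather, seasons,
    function(tmean, precip) precip,
    "preci"
  )
}

#' Pre-season precipitation (the three months before season start)
#'
#' Sums daily precipitation over the window ending the day before each
#' season's start. By default the window is `window_days` days long
#' (92, approximately three months); with `calendar_months = TRUE` it is
#' instead the three whole calendar months preceding the start month. The
#' window may reach into the previous calendar year, so series coverage of
#' the year before the first season is required (else an error names the
#' affected county-years).
#'
#' @inheritParams degree_days
#' @param window_days Window length in days (used when
#'   `calendar_months = FALSE`).
#' @param calendar_months If `TRUE`, use the three whole calendar months
#'   before the season's start month.
#' @return A tibble `county`, `year`, `pbgs` (mm).
#' @export
pre_season_precip <- function(weather, seasons, window_days = 92,
                              calendar_months = FALSE) {
  check_seasons_frame(seasons)
  windows <- seasons |>
    mutate(
      end = .data$start - 1,
      start = if (calendar_months) {
        # first day of the month three calendar months before the start month
        mi <- year(.data$start) * 12L + (month(.data$start) - 1L) - 3L
        make_date(mi %/% 12L, mi %% 12L + 1L, 1L)
      } else {
        .data$start - window_days
      }
    )
  accumulate_over_seasons(
    weather, windows,
    function(tmean, precip) precip,
    "pbgs"
  )
}

#' Per-county-year climate regressors from daily weather
#'
#' One-call wrapper producing, for every county-year the series fully
#' covers, the three climate regressors of the yield model: pre-season
#' precipitation (`pbgs`, mm), growing-season precipitation (`preci`, mm)
#' and growing-season degree days (`dd`, degree-days above `base`), plus the
#' detected season window. Years whose pre-season window is not covered
#' (typically the first simulated year, whose window reaches into an
#' unsimulated prior year) get `pbgs = NA` with a warning; downstream
#' assembly drops and logs such rows.
#'
#' @inheritParams detect_growing_season
#' @inheritParams degree_days
#' @inheritParams pre_season_precip
#' @return A tibble `county`, `year`, `season_start`, `season_end`,
#'   `season_length`, `pbgs`, `preci`, `dd`.
#' @examples
#' w <- simulate_daily_weather(weather_climatology(), "C01", 1999:2002, seed = 9)
#' climate_features(w, years = 2000:2002)
#' @export
climate_features <- function(weather, years = NULL,
                             frost_threshold = -2.2, split_doy = 183,
                             base = 10, window_days = 92,
                             calendar_months = FALSE, max_missing = 5) {
  wx <- complete_daily_weather(weather, max_missing = max_missing)
  seasons <- detect_growing_season(wx, years = years,
                                   frost_threshold = frost_threshold,
                                   split_doy = split_doy,
                                   max_missing = max_missing)
  dd <- degree_days(wx, seasons, base = base)
  pr <- season_precip(wx, seasons)
  pb <- tryCatch(
    pre_season_precip(wx, seasons, window_days = window_days,
                      calendar_months = calendar_months),
    error = function(e) NULL
  )
  if (is.null(pb)) {
    # recompute per-year so only uncovered years are flagged
    pb <- seasons |>
      group_by(.data$year) |>
      group_map(function(rows, key) {
        tryCatch(
          pre_season_precip(wx, mutate(rows, year = key$year),
                            window_days = window_days,
                            calendar_months = calendar_months),
          error = function(e) {
            tibble(county = rows$county, year = key$year, pbgs = NA_real_)
          }
        )
      }) |>
      purrr::list_rbind()
    if (anyNA(pb$pbgs)) {
      warn(paste0(
        "Pre-season window not covered for year(s) ",
        paste(sort(unique(pb$year[is.na(pb$pbgs)])), collapse = ", "),
        "; `pbgs` set to NA there."
      ))
    }
  }
  seasons |>
    rename(season_start = "start", season_end = "end",
           season_length = "length") |>
    left_join(pb, by = c("county", "year")) |>
    left_join(pr, by = c("county", "year")) |>
    left_join(dd, by = c("county", "year"))
}

#' Linear trend in growing-season length
#'
#' Ordinary least-squares slope of season length on year, reported in days
#' per decade -- the standard way season-lengthening is quoted.
#'
#' @param seasons Output of [detect_growing_season()] or
#'   [climate_features()] (needs `year` and `length` or `season_length`).
#' @return A one-row tibble with `slope_days_per_decade`, `std_error`, `n`.
#' @export
season_length_trend <- function(seasons) {
  len <- seasons[["length"]] %||% seasons[["season_length"]]
  if (is.null(len)) abort("`seasons` needs a `length` or `season_length` column.")
  fit <- lm(len ~ year, data = tibble(len = len, year = seasons$year))
  sm <- summary(fit)$coefficients
  tibble(
    slope_days_per_decade = unname(coef(fit)["year"]) * 10,
    std_error = unname(sm["year", "Std. Error"]) * 10,
    n = length(len)
  )
}
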