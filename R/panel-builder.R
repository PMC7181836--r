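#' Harmonize yields across historical county boundary changes
#'
#' Counties whose boundaries merged during the study period are combined
#' retroactively: for each merged group and year, the harmonized yield is
#' the harvest-area-weighted average of the member yields,
#' `sum(yield_k * area_k) / sum(area_k)`, and the harmonized area is the
#' summed area. Counties not listed in the map pass through unchanged.
#' Total production (yield x area) is conserved exactly.
#'
#' @param yields Tibble with columns `county`, `year`, `crop`, `yield`,
#'   `area`.
#' @param boundary_map Tibble with columns `county` (historical identifier)
#'   and `merged` (the harmonized identifier). One-member groups act as
#'   renames.
#' @return A tibble with the same columns as `yields`, on harmonized
#'   county identifiers.
#' @examples
#' y <- tibble::tibble(county = c("A", "B"), year = 2000, crop = "corn",
#'                     yield = c(100, 80), area = c(300, 100))
#' merge_boundary_counties(y, tibble::tibble(county = c("A", "B"), merged = "AB"))
#' @export
merge_boundary_counties <- function(yields, boundary_map) {
  needed <- c("county", "year", "crop", "yield", "area")
  missing <- setdiff(needed, names(yields))
  if (length(missing) > 0) {
    abort(paste0("`yields` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!all(c("county", "merged") %in% names(boundary_map))) {
    abort("`boundary_map` needs columns `county` and `merged`.")
  }
  if (any(yields$area < 0, na.rm = TRUE)) abort("Harvest areas must be >= 0.")
  mapped <- yields |>
    left_join(boundary_map, by = "county") |>
    mutate(merged = dplyr::coalesce(.data$merged, .data$county))
  zero <- mapped |>
    group_by(.data$merged, .data$year, .data$crop) |>
    summarise(total_area = sum(.data$area), .groups = "drop") |>
    filter(.data$total_area <= 0)
  if (nrow(zero) > 0) {
    abort(paste0(
      "All harvest areas are zero in merged group/year: ",
      paste(sprintf("%s %d", zero$merged, zero$year), collapse = "; ")
    ))
  }
  mapped |>
    group_by(county = .data$merged, .data$year, .data$crop) |>
    summarise(
      yield = sum(.data$yield * .data$area) / sum(.data$area),
      area = sum(.data$area),
      .groups = "drop"
    )
}

#' Deflate a nominal annual series by a consumer price index
#'
#' Converts nominal values to real terms of a base year:
#' `real_t = nominal_t * CPI(base) / CPI(t)` (CPI base 2002 = 100 in the
#' Ontario analysis). A series year missing from the CPI table is an error.
#'
#' @param data Tibble with a `year` column and the nominal value column.
#' @param cpi Tibble with columns `year` and `cpi`.
#' @param col Name (tidy-eval) of the nominal column to deflate in place.
#' @param base_year Base year of the real scale.
#' @return `data` with `col` replaced by its real (deflated) values.
#' @export
deflate <- function(data, cpi, col, base_year = 2002) {
  if (!all(c("year", "cpi") %in% names(cpi))) {
    abort("`cpi` needs columns `year` and `cpi`.")
  }
  base_cpi <- cpi$cpi[match(base_year, cpi$year)]
  if (is.na(base_cpi) || base_cpi <= 0) {
    abort(paste0("CPI for base year ", base_year, " is missing or non-positive."))
  }
  missing_years <- setdiff(unique(data$year), cpi$year)
  if (length(missing_years) > 0) {
    abort(paste0("CPI missing for year(s): ", paste(sort(missing_years), collapse = ", ")))
  }
  col <- rlang::ensym(col)
  data |>
    left_join(cpi, by = "year") |>
    mutate(!!col := !!col * base_cpi / .data$cpi) |>
    select(-"cpi")
}

#' Apply the soybean harvest-area and continuity filters
#'
#' Two filters motivated by the sparse early soybean record: (1) drop any
#' county-year with harvest area below `min_area` acres; (2) with
#' `continuity = TRUE`, drop each county's leading years up to its last
#' gap, so every retained county is gap-free from its first retained year
#' through its last observed year. Every removed row is logged in the
#' `exclusions` attribute with a reason; a county removed entirely raises a
#' warning.
#'
#' Applying the filters twice gives the same panel as applying them once.
#'
#' @param yields Tibble with columns `county`, `year`, `yield`, `area`.
#' @param min_area Minimum harvest area (acres).
#' @param continuity Enforce the gap-free-suffix rule.
#' @return The filtered tibble, with attribute `exclusions` (a tibble
#'   `county`, `year`, `reason`).
#' @export
apply_soybean_filters <- function(yields, min_area = 1500, continuity = TRUE) {
  needed <- c("county", "year", "area")
  missing <- setdiff(needed, names(yields))
  if (length(missing) > 0) {
    abort(paste0("`yields` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  area_excl <- yields |>
    filter(.data$area < min_area) |>
    transmute(.data$county, .data$year,
              reason = sprintf("area %.0f < %.0f acres", .data$area, min_area))
  kept <- yields |> filter(.data$area >= min_area)

  cont_excl <- tibble(county = character(), year = integer(), reason = character())
  if (continuity && nrow(kept) > 0) {
    starts <- kept |>
      group_by(.data$county) |>
      summarise(
        first_ok = {
          yrs <- sort(.data$year)
          full <- seq(min(yrs), max(yrs))
          gaps <- setdiff(full, yrs)
          if (length(gaps)) max(gaps) + 1L else min(yrs)
        },
        .groups = "drop"
      )
    kept2 <- kept |> left_join(starts, by = "county")
    cont_excl <- kept2 |>
      filter(.data$year < .data$first_ok) |>
      transmute(.data$county, .data$year,
                reason = sprintf("before last gap (retained span starts %d)", .data$first_ok))
    kept <- kept2 |>
      filter(.data$year >= .data$first_ok) |>
      select(-"first_ok")
  }

  dropped_counties <- setdiff(unique(yields$county), unique(kept$county))
  if (length(dropped_counties) > 0) {
    warn(paste0("Filter removed entire count(y/ies): ",
                paste(dropped_counties, collapse = ", ")))
  }
  exclusions <- bind_rows(area_excl, cont_excl) |>
    arrange(.data$county, .data$year)
  attr(kept, "exclusions") <- exclusions
  kept
}

#' Assemble the county-year estimation panel
#'
#' Joins the regression inputs into one row per (county, year): yields,
#' climate features, growing-season CO2, the one-year-lagged real crop
#' price, the real fertilizer price index, an integer trend, and a pest
#' dummy. Aggregation and scaling conventions:
#'
#' * monthly nominal prices are averaged to annual, deflated by CPI to
#'   `base_year` dollars, divided by `price_scale`, then lagged one year
#'   (planting-time expectations are last year's price);
#' * the quarterly nominal fertilizer index is averaged to annual, deflated,
#'   and divided by `fertilizer_scale`;
#' * `trend = year - first panel year + 1` (1..55 for 1959-2013);
#' * `pest = 1` in `pest_year` (if given), else 0.
#'
#' The default scales (100) put prices in hundreds of base-year dollars per
#' tonne and the fertilizer index on a base-year-=-1 scale, matching the
#' units behind [ontario_reference_coefficients()].
#'
#' Rows whose pre-season precipitation is `NA` (first year without
#' prior-year weather) are dropped and logged in the `dropped` attribute;
#' any other join miss is an error listing the offending keys.
#'
#' @param features Climate features from [climate_features()].
#' @param co2 Per-year growing-season CO2 from [season_co2()] (`year`, `co2`).
#' @param prices Monthly nominal prices (`year`, `month`, `price`).
#' @param cpi CPI table (`year`, `cpi`), base `base_year` = 100.
#' @param fertilizer Quarterly nominal fertilizer index (`year`, `quarter`,
#'   `index`).
#' @param yields Yield records (`county`, `year`, `crop`, `yield`, `area`).
#' @param crop Crop to select from `yields`.
#' @param pest_year Year flagged by the pest dummy (e.g. 2001 for the
#'   soybean aphid outbreak), or `NULL` for none.
#' @param base_year CPI base year.
#' @param price_scale,fertilizer_scale Divisors applied after deflation.
#' @return A `becyr_panel` tibble: `county`, `year`, `crop`, `yield`,
#'   `area`, `pbgs`, `preci`, `dd`, `price_lag`, `pf`, `trend`, `co2`,
#'   `pest`.
#' @export
assemble_panel <- function(features, co2, prices, cpi, fertilizer, yields,
                           crop = c("corn", "soybean"), pest_year = NULL,
                           base_year = 2002, price_scale = 100,
                           fertilizer_scale = 100) {
  crop <- match.arg(crop)
  yd <- yields |> filter(.data$crop == !!crop)
  if (nrow(yd) == 0) abort(paste0("No yield rows for crop '", crop, "'."))
  first_year <- min(yd$year)

  price_annual <- prices |>
    group_by(.data$year) |>
    summarise(price = mean(.data$price), .groups = "drop") |>
    deflate(cpi, price, base_year = base_year) |>
    mutate(price = .data$price / price_scale)
  price_lagged <- price_annual |>
    mutate(year = .data$year + 1L) |>
    rename(price_lag = "price")

  pf_annual <- fertilizer |>
    group_by(.data$year) |>
    summarise(pf = mean(.data$index), .groups = "drop") |>
    deflate(cpi, pf, base_year = base_year) |>
    mutate(pf = .data$pf / fertilizer_scale)

  panel <- yd |>
    inner_join(features, by = c("county", "year")) |>
    left_join(co2, by = "year") |>
    left_join(price_lagged, by = "year") |>
    left_join(pf_annual, by = "year") |>
    mutate(
      trend = .data$year - first_year + 1L,
      pest = if (is.null(pest_year)) 0L else as.integer(.data$year %in% pest_year)
    )

  feature_miss <- yd |> anti_join(features, by = c("county", "year"))
  if (nrow(feature_miss) > 0) {
    abort(paste0(
      "No climate features for yield row(s): ",
      paste(sprintf("%s %d", feature_miss$county, feature_miss$year), collapse = "; ")
    ))
  }
  misses <- panel |>
    filter(is.na(.data$co2) | is.na(.data$price_lag) | is.na(.data$pf)) |>
    select("county", "year")
  if (nrow(misses) > 0) {
    abort(paste0(
      "Missing CO2/price/fertilizer for: ",
      paste(sprintf("%s %d", misses$county, misses$year), collapse = "; ")
    ))
  }

  dropped <- panel |> filter(is.na(.data$pbgs)) |> select("county", "year")
  if (nrow(dropped) > 0) {
    inform(paste0(
      nrow(dropped), " row(s) dropped for missing pre-season precipitation (",
      paste(sort(unique(dropped$year)), collapse = ", "), ")."
    ))
    panel <- panel |> filter(!is.na(.data$pbgs))
  }

  out <- panel |>
    select("county", "year", "crop", "yield", "area", "pbgs", "preci", "dd",
           "price_lag", "pf", "trend", "co2", "pest") |>
    arrange(.data$county, .data$year)
  attr(out, "dropped") <- dropped
  attr(out, "first_year") <- first_year
  class(out) <- c("becyr_panel", class(out))
  out
}
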