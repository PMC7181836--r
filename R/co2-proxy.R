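#' @noRd
check_monthly_co2 <- function(x, arg = "series") {
  needed <- c("year", "month", "ppm")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(paste0("`", arg, "` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(x$ppm <= 0, na.rm = TRUE)) abort(paste0("`", arg, "` has non-positive ppm values."))
  if (anyDuplicated(x[c("year", "month")])) {
    abort(paste0("`", arg, "` has duplicate (year, month) records."))
  }
  invisible(x)
}

#' Per-month correlation screening of two monthly CO2 series
#'
#' For each calendar month, the Pearson correlation between reference-site
#' and target-site concentrations over the years both series cover. This is
#' the screening step before fitting a proxy model: consistently high
#' correlations in every month justify a single-slope monthly-intercept
#' regression. Months with fewer than three overlapping years are flagged
#' (`ok = FALSE`) rather than dropped.
#'
#' @param reference,target Monthly CO2 tibbles with columns `year`, `month`,
#'   `ppm`.
#' @param years Optional integer vector restricting the overlap period.
#' @return A tibble `month`, `n`, `r`, `ok`.
#' @export
monthly_correlations <- function(reference, target, years = NULL) {
  check_monthly_co2(reference, "reference")
  check_monthly_co2(target, "target")
  joined <- inner_join(reference, target, by = c("year", "month"),
                       suffix = c("_ref", "_tgt"))
  if (!is.null(years)) joined <- filter(joined, .data$year %in% years)
  tibble(month = 1:12) |>
    left_join(
      joined |>
        group_by(.data$month) |>
        summarise(
          n = sum(complete.cases(.data$ppm_ref, .data$ppm_tgt)),
          r = if (n >= 3) cor(.data$ppm_ref, .data$ppm_tgt, use = "complete.obs") else NA_real_,
          .groups = "drop"
        ),
      by = "month"
    ) |>
    mutate(n = tidyr::replace_na(.data$n, 0L),
           ok = !is.na(.data$r) & .data$n >= 3)
}

#' Fit a monthly fixed-effects CO2 proxy model
#'
#' Least-squares fit of `target ~ slope * reference + intercept[month]`:
#' one shared slope on the reference-site concentration plus twelve
#' month-specific intercepts and no global intercept. This captures a
#' target site whose seasonal cycle has a different phase and amplitude
#' than the reference site while sharing its long-run trend.
#'
#' @inheritParams monthly_correlations
#' @return An object of class `becyr_proxy` with elements `slope`,
#'   `intercepts` (length 12), `model` (the underlying `lm`), `residuals`,
#'   `data` (the overlap rows used), `adj_r_squared`.
#' @examples
#' pair <- simulate_co2_pair(2005:2016, seed = 1)
#' fit_proxy_model(pair$reference, pair$target)
#' @export
fit_proxy_model <- function(reference, target, years = NULL) {
  check_monthly_co2(reference, "reference")
  check_monthly_co2(target, "target")
  joined <- inner_join(reference, target, by = c("year", "month"),
                       suffix = c("_ref", "_tgt")) |>
    filter(complete.cases(.data$ppm_ref, .data$ppm_tgt))
  if (!is.null(years)) joined <- filter(joined, .data$year %in% years)
  counts <- joined |> count(.data$month)
  short <- setdiff(1:12, counts$month[counts$n >= 2])
  if (length(short) > 0) {
    abort(paste0(
      "Too few overlapping observations (need >= 2) for month(s): ",
      paste(short, collapse = ", ")
    ))
  }
  joined <- joined |> mutate(month_f = factor(.data$month, levels = 1:12))
  model <- lm(ppm_tgt ~ 0 + month_f + ppm_ref, data = joined)
  cf <- coef(model)
  res <- resid(model)
  y <- joined$ppm_tgt
  n <- length(y)
  p <- length(cf)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(
    list(
      slope = unname(cf["ppm_ref"]),
      intercepts = unname(cf[paste0("month_f", 1:12)]),
      model = model,
      residuals = unname(res),
      data = joined |> select("year", "month", "ppm_ref", "ppm_tgt"),
      adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - p)
    ),
    class = "becyr_proxy"
  )
}

#' @export
print.becyr_proxy <- function(x, ...) {
  cat("<becyr_proxy> monthly fixed-effects CO2 proxy\n")
  cat(sprintf("  slope on reference ppm: %.4f\n", x$slope))
  cat(sprintf("  monthly intercepts: %.1f to %.1f ppm\n",
              min(x$intercepts), max(x$intercepts)))
  cat(sprintf("  overlap n = %d, adjusted R^2 = %.4f\n",
              nrow(x$data), x$adj_r_squared))
  invisible(x)
}

#' @export
tidy.becyr_proxy <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(
    term = c(paste0("month_", 1:12), "slope"),
    estimate = c(x$intercepts, x$slope),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @export
glance.becyr_proxy <- function(x, ...) {
  tibble(
    adj.r.squared = x$adj_r_squared,
    sigma = sqrt(sum(x$residuals^2) / (nrow(x$data) - 13)),
    nobs = nrow(x$data)
  )
}

#' Predict a proxy CO2 history from the reference series
#'
#' Applies a fitted [fit_proxy_model()] to reference-site records:
#' `ppm = slope * reference + intercept[month]`, flagged
#' `provenance = "proxy"`. Reference months absent from the input are simply
#' absent from the output (missingness propagates).
#'
#' @param model A `becyr_proxy` object.
#' @param reference Monthly CO2 tibble (`year`, `month`, `ppm`).
#' @param years Optional years to predict for (default: all reference rows).
#' @return A tibble `year`, `month`, `ppm`, `provenance`.
#' @export
predict_proxy <- function(model, reference, years = NULL) {
  if (!inherits(model, "becyr_proxy")) abort("`model` must be a becyr_proxy object.")
  check_monthly_co2(reference, "reference")
  out <- reference
  if (!is.null(years)) out <- filter(out, .data$year %in% years)
  out |>
    filter(!is.na(.data$ppm)) |>
    transmute(
      year = .data$year, month = .data$month,
      ppm = model$slope * .data$ppm + model$intercepts[.data$month],
      provenance = "proxy"
    )
}

#' Splice observed and proxy monthly CO2 series
#'
#' Combines a proxy reconstruction with directly observed records, with
#' observations taking precedence wherever both exist. Records carry a
#' `provenance` flag (`"observed"` or `"proxy"`).
#'
#' @param proxy Proxy series, e.g. from [predict_proxy()].
#' @param observed Observed series (`year`, `month`, `ppm`).
#' @return A tibble `year`, `month`, `ppm`, `provenance`, sorted by date.
#' @export
splice_co2 <- function(proxy, observed) {
  check_monthly_co2(proxy, "proxy")
  check_monthly_co2(observed, "observed")
  obs <- observed |>
    filter(!is.na(.data$ppm)) |>
    transmute(.data$year, .data$month, .data$ppm, provenance = "observed")
  prx <- proxy |>
    filter(!is.na(.data$ppm)) |>
    mutate(provenance = if ("provenance" %in% names(proxy)) .data$provenance else "proxy") |>
    anti_join(obs, by = c("year", "month")) |>
    select("year", "month", "ppm", "provenance")
  bind_rows(obs, prx) |> arrange(.data$year, .data$month)
}

#' Day-weighted growing-season CO2 averages
#'
#' For each year's season window, the mean of the monthly concentrations
#' over the months the season intersects, weighted by the number of days of
#' each month falling inside the season. A season month missing from the
#' series is an error naming every missing (year, month).
#'
#' @param monthly Monthly CO2 tibble (`year`, `month`, `ppm`), e.g. from
#'   [splice_co2()].
#' @param seasons Tibble with one row per year: `year`, `start`, `end`
#'   (dates). See [provincial_season()] for collapsing county-level seasons.
#' @return A tibble `year`, `co2` (ppm).
#' @export
season_co2 <- function(monthly, seasons) {
  check_monthly_co2(monthly, "monthly")
  if (!all(c("year", "start", "end") %in% names(seasons))) {
    abort("`seasons` needs columns year, start, end.")
  }
  if (anyDuplicated(seasons$year)) abort("`seasons` must have one row per year.")
  spans <- seasons |>
    mutate(start = as.Date(.data$start), end = as.Date(.data$end)) |>
    mutate(day = purrr::map2(.data$start, .data$end, seq, by = "day")) |>
    select("year", "day") |>
    tidyr::unnest("day") |>
    mutate(month = month(.data$day)) |>
    count(.data$year, .data$month, name = "weight")
  joined <- spans |> left_join(monthly, by = c("year", "month"))
  missing <- joined |> filter(is.na(.data$ppm))
  if (nrow(missing) > 0) {
    abort(paste0(
      "Monthly CO2 missing for season month(s): ",
      paste(sprintf("%d-%02d", missing$year, missing$month), collapse = ", ")
    ))
  }
  joined |>
    group_by(.data$year) |>
    summarise(co2 = sum(.data$ppm * .data$weight) / sum(.data$weight),
              .groups = "drop")
}

#' Collapse county-level seasons to one provincial window per year
#'
#' The yield model's CO2 regressor is a single province-level series, while
#' growing seasons are detected per county. This helper averages the county
#' start/end dates (rounded to whole days) to give one representative
#' window per year for [season_co2()].
#'
#' @param seasons County-level seasons (`county`, `year`, `start`/`season_start`,
#'   `end`/`season_end`).
#' @return A tibble `year`, `start`, `end`.
#' @export
provincial_season <- function(seasons) {
  start <- seasons[["start"]] %||% seasons[["season_start"]]
  end <- seasons[["end"]] %||% seasons[["season_end"]]
  if (is.null(start) || is.null(end)) {
    abort("`seasons` needs start/end (or season_start/season_end) columns.")
  }
  tibble(year = seasons$year, start = as.Date(start), end = as.Date(end)) |>
    group_by(.data$year) |>
    summarise(
      start = as.Date(round(mean(as.numeric(.data$start))), origin = "1970-01-01"),
      end = as.Date(round(mean(as.numeric(.data$end))), origin = "1970-01-01"),
      .groups = "drop"
    )
}
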