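# Extract a named coefficient vector from a becyr_fit or a coefficient
# tibble (term/estimate), so response quantities can be computed either
# from a fresh fit or from a published coefficient set.
#' @noRd
coef_lookup <- function(x) {
  if (inherits(x, "becyr_fit")) {
    cf <- coef(x)
    return(cf[!grepl("^county", names(cf))])
  }
  if (is.data.frame(x)) {
    if (!all(c("term", "estimate") %in% names(x))) {
      abort("Coefficient data frames need `term` and `estimate` columns.")
    }
    return(setNames(x$estimate, x$term))
  }
  abort("`x` must be a becyr_fit or a coefficient data frame.")
}

#' CO2 turning point of a quadratic-CO2 yield model
#'
#' Solves the first-order condition of fitted yield with respect to CO2:
#' the turning point sits at `-beta_co2 / (2 * gamma_co2)` ppm, a fitted
#' minimum when the quadratic coefficient is positive and a maximum when it
#' is negative. For a model without a quadratic CO2 term the result is an
#' explicit no-turning-point row (`location = NA`), not a number.
#'
#' @param x A `becyr_fit` estimated with `co2_effect = "quadratic"`, or a
#'   coefficient tibble (`term`, `estimate`) containing `co2` and `co2_sq`
#'   rows, e.g. from [ontario_reference_coefficients()].
#' @return A one-row tibble: `variable`, `location` (ppm), `direction`
#'   (`"minimum"`, `"maximum"`, or `"none"`), `beta`, `gamma`.
#' @examples
#' ontario_reference_coefficients("corn", "quadratic") |> co2_turning_point()
#' @export
co2_turning_point <- function(x) {
  cf <- coef_lookup(x)
  beta <- unname(cf["co2"])
  gamma <- unname(cf["co2_sq"])
  if (is.na(beta)) abort("No CO2 term: the model was fit without a CO2 effect.")
  if (is.na(gamma) || gamma == 0) {
    return(tibble(variable = "co2", location = NA_real_, direction = "none",
                  beta = beta, gamma = if (is.na(gamma)) NA_real_ else gamma))
  }
  tibble(
    variable = "co2",
    location = -beta / (2 * gamma),
    direction = if (gamma > 0) "minimum" else "maximum",
    beta = beta, gamma = gamma
  )
}

#' Peak-yield level of growing-season precipitation or degree days
#'
#' The yield response to season precipitation (`preci`) and degree days
#' (`dd`) is quadratic with a centered interaction, so the level at which
#' yield peaks with respect to one variable depends (linearly) on the level
#' of the other. For precipitation conditioned on degree days at level `d`:
#' `-(beta_preci + theta * (d - dd_bar)) / (2 * gamma_preci)`, and
#' symmetrically for degree days. At the grand mean of the conditioning
#' variable this reduces to `-beta / (2 * gamma)`.
#'
#' @param x A `becyr_fit`, or a coefficient tibble (`term`, `estimate`).
#' @param variable `"preci"` or `"dd"`.
#' @param at Conditioning level of the *other* variable (mm for `dd` peaks,
#'   degree-days for `preci` peaks). Default: the stored grand mean, giving
#'   the neutral `-beta/(2*gamma)` form. To mirror a recent-window analysis,
#'   pass e.g. the 2009-2013 mean of the conditioning variable.
#' @param means Named numeric with elements `preci` and `dd`: the grand
#'   means used for centering. Taken from the fit when `x` is a
#'   `becyr_fit`; required for coefficient tibbles when `at` is supplied.
#' @return A one-row tibble: `variable`, `location`, `direction`,
#'   `conditioning_variable`, `conditioning_level`, `beta`, `gamma`,
#'   `theta`.
#' @export
peak_level <- function(x, variable = c("preci", "dd"), at = NULL, means = NULL) {
  variable <- match.arg(variable)
  other <- if (variable == "preci") "dd" else "preci"
  cf <- coef_lookup(x)
  if (inherits(x, "becyr_fit")) means <- means %||% x$means
  beta <- unname(cf[variable])
  gamma <- unname(cf[paste0(variable, "_sq")])
  theta <- unname(cf["preci_x_dd"])
  if (anyNA(c(beta, gamma, theta))) {
    abort("Model must include the linear, squared and interaction terms.")
  }
  if (gamma == 0) {
    return(tibble(variable = variable, location = NA_real_, direction = "none",
                  conditioning_variable = other, conditioning_level = NA_real_,
                  beta = beta, gamma = gamma, theta = theta))
  }
  if (is.null(at)) {
    shift <- 0
    at_level <- if (!is.null(means)) unname(means[other]) else NA_real_
  } else {
    if (is.null(means)) {
      abort("Supply `means` (grand means of preci and dd) to condition away from the mean.")
    }
    shift <- theta * (at - unname(means[other]))
    at_level <- at
  }
  tibble(
    variable = variable,
    location = -(beta + shift) / (2 * gamma),
    direction = if (gamma > 0) "minimum" else "maximum",
    conditioning_variable = other,
    conditioning_level = at_level,
    beta = beta, gamma = gamma, theta = theta
  )
}

#' Linear CO2 effect as percent yield change per ppm
#'
#' For a linear-CO2 model, scales the CO2 coefficient by the mean yield:
#' `100 * beta_co2 / mean_yield` percent per ppm, with a 95% confidence
#' interval from the (robust) standard error scaled identically. Models
#' with a quadratic CO2 term have a turning point instead -- use
#' [co2_turning_point()].
#'
#' @param x A `becyr_fit` with `co2_effect = "linear"`, or a coefficient
#'   tibble with `term`, `estimate` and (for the CI) `std_error` columns.
#' @param mean_yield Mean crop yield over the study period (bushels/acre);
#'   defaults to the fitting panel's mean yield when `x` is a fit.
#' @return A one-row tibble: `pct_per_ppm`, `conf_low`, `conf_high`,
#'   `mean_yield`.
#' @export
linear_co2_effect <- function(x, mean_yield = NULL) {
  cf <- coef_lookup(x)
  if ("co2_sq" %in% names(cf)) {
    abort("Model has a quadratic CO2 term; use co2_turning_point() instead.")
  }
  if (!"co2" %in% names(cf)) abort("Model has no CO2 term.")
  if (inherits(x, "becyr_fit")) {
    mean_yield <- mean_yield %||% mean(x$panel$yield)
    se <- x$coefficients$std_error[x$coefficients$term == "co2"]
  } else {
    se <- if ("std_error" %in% names(x)) x$std_error[x$term == "co2"] else NA_real_
  }
  if (is.null(mean_yield) || is.na(mean_yield) || mean_yield <= 0) {
    abort("`mean_yield` must be a positive number.")
  }
  eff <- 100 * unname(cf["co2"]) / mean_yield
  half <- 1.96 * 100 * se / mean_yield
  tibble(pct_per_ppm = eff, conf_low = eff - half, conf_high = eff + half,
         mean_yield = mean_yield)
}

#' Per-variable attribution of average annual yield change
#'
#' Decomposes the average per-year change in fitted yield into the
#' contributions of each time-variant regressor, expressed as a percentage
#' of the fitted yield in the first panel year. For each variable the
#' contribution is (marginal effect at the sample means) times (average
#' annual drift), where the drift is the OLS slope of the variable's annual
#' panel mean on year. Precipitation and degree days are reported jointly,
#' including the interaction term's own drift, because the centered
#' interaction ties their marginal effects together.
#'
#' @param fit A `becyr_fit`.
#' @param panel Panel to measure drifts on; defaults to the fitting panel.
#' @param base_year Year whose fitted yield is the denominator; defaults to
#'   the panel's first year. An error is raised if it is absent.
#' @param method `"marginal"` (default: marginal effect x average drift) or
#'   `"finite-difference"` (average of year-on-year changes in the fitted
#'   contribution of each variable).
#' @return A tibble `variable`, `drift_per_year`, `marginal_effect`,
#'   `pct_of_base_yield`.
#' @export
attribution <- function(fit, panel = NULL,
                        base_year = NULL,
                        method = c("marginal", "finite-difference")) {
  method <- match.arg(method)
  if (!inherits(fit, "becyr_fit")) abort("`fit` must be a becyr_fit.")
  panel <- panel %||% fit$panel
  base_year <- base_year %||% min(panel$year)
  if (!base_year %in% panel$year) {
    abort(paste0("Base year ", base_year, " is absent from the panel."))
  }
  cf <- coef_lookup(fit)
  means <- vapply(spec_linear_terms(fit$spec), function(v) mean(panel[[v]]),
                  numeric(1))
  preci_bar <- unname(fit$means["preci"])
  dd_bar <- unname(fit$means["dd"])
  theta <- unname(cf["preci_x_dd"])

  base_fitted <- mean(predict(fit, panel |> filter(.data$year == base_year)))

  annual <- panel |>
    group_by(.data$year) |>
    summarise(
      across(all_of(spec_linear_terms(fit$spec)), mean),
      inter = mean((.data$preci - preci_bar) * (.data$dd - dd_bar)),
      .groups = "drop"
    )
  drift <- function(col) unname(coef(lm(annual[[col]] ~ annual$year))[2])
  gamma_of <- function(v) {
    g <- cf[paste0(v, "_sq")]
    if (is.na(g)) 0 else unname(g)
  }
  marginal <- function(v) unname(cf[v]) + 2 * gamma_of(v) * unname(means[v])

  vars <- setdiff(spec_linear_terms(fit$spec), c("preci", "dd"))
  rows <- purrr::map(vars, function(v) {
    contribution <- switch(method,
      marginal = marginal(v) * drift(v),
      `finite-difference` = mean(diff(
        unname(cf[v]) * annual[[v]] + gamma_of(v) * annual[[v]]^2
      ))
    )
    tibble(variable = v, drift_per_year = drift(v),
           marginal_effect = marginal(v),
           pct_of_base_yield = 100 * contribution / base_fitted)
  })

  joint_contribution <- switch(method,
    marginal = marginal("preci") * drift("preci") +
      marginal("dd") * drift("dd") + theta * drift("inter"),
    `finite-difference` = mean(diff(
      cf["preci"] * annual$preci + cf["preci_sq"] * annual$preci^2 +
        cf["dd"] * annual$dd + cf["dd_sq"] * annual$dd^2 +
        theta * annual$inter
    ))
  )
  joint <- tibble(
    variable = "preci+dd",
    drift_per_year = NA_real_,
    marginal_effect = NA_real_,
    pct_of_base_yield = 100 * joint_contribution / base_fitted
  )

  order_vars <- c("pbgs", "preci+dd", "price_lag", "pf", "trend", "co2")
  bind_rows(c(rows, list(joint))) |>
    mutate(variable = factor(.data$variable, levels = order_vars)) |>
    arrange(.data$variable) |>
    mutate(variable = as.character(.data$variable))
}
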