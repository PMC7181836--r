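#' Coefficient plot for a fitted yield model
#'
#' Dot-and-whisker plot of the non-indicator coefficients with robust 95%
#' intervals. County fixed effects are omitted (they are nuisance
#' intercepts).
#'
#' @param object A `becyr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.becyr_fit <- function(object, ...) {
  dat <- object$coefficients |>
    filter(.data$role == "regressor") |>
    mutate(
      conf_low = .data$estimate - 1.96 * .data$std_error,
      conf_high = .data$estimate + 1.96 * .data$std_error,
      term = factor(.data$term, levels = rev(.data$term))
    )
  ggplot(dat, aes(x = .data$estimate, y = .data$term)) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$conf_low, xmax = .data$conf_high),
                   height = 0.2) +
    geom_point() +
    labs(
      x = "Estimate (robust 95% interval)", y = NULL,
      title = sprintf("%s yield model, CO2 effect: %s",
                      object$spec$crop, object$spec$co2_effect)
    )
}

#' Observed, fitted and residual view of a CO2 proxy model
#'
#' @param object A `becyr_proxy` from [fit_proxy_model()].
#' @param ... Unused.
#' @return A ggplot object showing target observations and in-sample fit
#'   over the overlap period.
#' @export
autoplot.becyr_proxy <- function(object, ...) {
  dat <- object$data |>
    mutate(
      date = make_date(.data$year, .data$month, 15),
      fitted = .data$ppm_tgt - object$residuals
    )
  ggplot(dat, aes(x = .data$date)) +
    geom_line(aes(y = .data$ppm_tgt, colour = "observed")) +
    geom_line(aes(y = .data$fitted, colour = "fitted"), linetype = "dashed") +
    scale_colour_manual(values = c(observed = "black", fitted = "firebrick"),
                        name = NULL) +
    labs(x = NULL, y = "CO2 (ppm)",
         title = "Monthly fixed-effects CO2 proxy: overlap fit")
}

#' Fitted yield response curve in one variable
#'
#' Plots fitted yield against one regressor, holding all other regressors
#' at their panel means (and the county effect at its average), with the
#' panel's observed range shaded. Useful for reading turning points
#' directly off the quadratic response.
#'
#' @param fit A `becyr_fit`.
#' @param variable One of the model's linear terms (e.g. `"preci"`,
#'   `"dd"`, `"co2"`).
#' @param n Grid resolution.
#' @return A ggplot object.
#' @export
plot_response_curve <- function(fit, variable = "preci", n = 200) {
  lin <- spec_linear_terms(fit$spec)
  if (!variable %in% lin) {
    abort(paste0("`variable` must be one of: ", paste(lin, collapse = ", ")))
  }
  cf <- coef(fit)
  alpha_bar <- mean(cf[grepl("^county", names(cf))])
  means <- vapply(lin, function(v) mean(fit$panel[[v]]), numeric(1))
  xs <- seq(min(fit$panel[[variable]]), max(fit$panel[[variable]]),
            length.out = n)
  yhat <- alpha_bar
  for (v in lin) {
    vals <- if (v == variable) xs else means[v]
    yhat <- yhat + cf[v] * vals
    sq <- paste0(v, "_sq")
    if (sq %in% names(cf)) yhat <- yhat + cf[sq] * vals^2
  }
  preci_v <- if (variable == "preci") xs else means["preci"]
  dd_v <- if (variable == "dd") xs else means["dd"]
  yhat <- yhat + cf["preci_x_dd"] *
    (preci_v - fit$means["preci"]) * (dd_v - fit$means["dd"])
  ggplot(tibble(x = xs, yield = unname(yhat)), aes(.data$x, .data$yield)) +
    geom_line() +
    labs(x = variable, y = "Fitted yield (bu/ac)",
         title = sprintf("Fitted response to %s at panel means", variable))
}
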