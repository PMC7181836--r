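#' Hold-out validation of a yield model
#'
#' Fits the model on the panel minus a held-out set of years or counties,
#' predicts the held-out rows, and reports out-of-sample accuracy. Held-out
#' counties have no estimated fixed effect, so their predictions use the
#' mean county effect and are flagged as such in the report.
#'
#' @param panel A panel tibble from [assemble_panel()] or
#'   [simulate_panel()].
#' @param spec A [model_spec()].
#' @param holdout_years Integer years to hold out (exclusive with
#'   `holdout_counties`). Default: the last five panel years.
#' @param holdout_counties County identifiers to hold out.
#' @return A one-row tibble of class `becyr_validation`: `scheme`,
#'   `n_train`, `n_test`, `rmse`, `mean_error` (bushels/acre),
#'   `mean_county_effect_used`, plus a `predictions` attribute with the
#'   per-row held-out predictions.
#' @export
holdout_validate <- function(panel, spec = model_spec(),
                             holdout_years = NULL, holdout_counties = NULL) {
  if (!is.null(holdout_years) && !is.null(holdout_counties)) {
    abort("Hold out either years or counties, not both.")
  }
  if (is.null(holdout_years) && is.null(holdout_counties)) {
    holdout_years <- sort(unique(panel$year), decreasing = TRUE)[1:5]
  }
  if (!is.null(holdout_years)) {
    test_idx <- panel$year %in% holdout_years
    scheme <- "holdout-years"
  } else {
    test_idx <- panel$county %in% holdout_counties
    scheme <- "holdout-counties"
  }
  if (!any(test_idx)) abort("Hold-out set is empty.")
  if (all(test_idx)) abort("Hold-out set leaves no training rows.")

  train <- panel[!test_idx, ]
  test <- panel[test_idx, ]
  fit <- fit_becyr(train, spec)
  pred <- predict(fit, test,
                  new_county = if (scheme == "holdout-counties") "mean" else "error")
  err <- test$yield - pred

  out <- tibble(
    scheme = scheme,
    n_train = nrow(train),
    n_test = nrow(test),
    rmse = sqrt(mean(err^2)),
    mean_error = mean(err),
    mean_county_effect_used = scheme == "holdout-counties"
  )
  attr(out, "predictions") <- tibble(
    county = test$county, year = test$year,
    observed = test$yield, predicted = pred, error = err
  )
  class(out) <- c("becyr_validation", class(out))
  out
}

#' Parameter-recovery study over repeated synthetic panels
#'
#' Repeatedly simulates a full dataset with known coefficients
#' ([simulate_panel()]), refits the model on each simulated panel, and
#' summarises per-coefficient bias and nominal-95% confidence-interval
#' coverage (intervals use the fit's robust standard errors). A replicate
#' whose fit fails is recorded and skipped, not fatal.
#'
#' @param config A [sim_config()]; its seed anchors the whole study
#'   (replicate seeds are derived from it deterministically).
#' @param spec A [model_spec()] matching the generating specification.
#' @param replicates Number of replicates (>= 2).
#' @return A tibble of class `becyr_recovery`, one row per non-indicator
#'   coefficient: `term`, `true`, `mean_estimate`, `bias`, `sd_estimate`,
#'   `rmse`, `coverage_95`; attributes `replicates`, `failures`, `seed`.
#' @export
recovery_study <- function(config, spec = NULL, replicates = 200) {
  if (!inherits(config, "becyr_sim_config")) {
    abort("`config` must come from sim_config().")
  }
  if (replicates < 2) abort("`replicates` must be >= 2.")
  if (is.null(spec)) {
    spec <- model_spec(config$crop, config$co2_effect,
                       pest_dummy = "pest" %in% names(config$coefficients))
  }
  withr::local_seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, replicates)

  truth <- config$coefficients
  failures <- 0L
  draws <- purrr::map(seq_len(replicates), function(r) {
    cfg_r <- config
    cfg_r$seed <- rep_seeds[r]
    res <- tryCatch({
      sim <- simulate_panel(cfg_r)
      fit <- fit_becyr(sim$panel, spec)
      fit$coefficients |>
        filter(.data$role == "regressor") |>
        mutate(replicate = r)
    }, error = function(e) NULL)
    res
  })
  failures <- sum(vapply(draws, is.null, logical(1)))
  draws <- purrr::list_rbind(purrr::compact(draws))
  if (nrow(draws) == 0) abort("Every replicate failed to fit.")

  out <- draws |>
    mutate(true = unname(truth[.data$term])) |>
    group_by(.data$term) |>
    summarise(
      true = .data$true[1],
      mean_estimate = mean(.data$estimate),
      bias = mean(.data$estimate - .data$true),
      sd_estimate = sd(.data$estimate),
      rmse = sqrt(mean((.data$estimate - .data$true)^2)),
      coverage_95 = mean(abs(.data$estimate - .data$true) <= 1.96 * .data$std_error),
      .groups = "drop"
    )
  attr(out, "replicates") <- replicates
  attr(out, "failures") <- failures
  attr(out, "seed") <- config$seed
  class(out) <- c("becyr_recovery", class(out))
  out
}
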