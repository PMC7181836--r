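#' Specify a yield-model variant
#'
#' Describes which variant of the quadratic county fixed-effects yield model
#' to estimate: the crop, the CO2 specification (absent, linear, or linear +
#' quadratic), whether the pest-year dummy enters (on by default for
#' soybeans), the robust covariance estimator, and whether the
#' precipitation-by-degree-days interaction is centered at the grand means.
#'
#' @param crop `"corn"` or `"soybean"`.
#' @param co2_effect `"none"`, `"linear"`, or `"quadratic"` (quadratic
#'   always includes the linear term).
#' @param pest_dummy Include the pest-year dummy; default `TRUE` for
#'   soybeans, `FALSE` for corn.
#' @param covariance `"cluster"` (county-cluster robust, HC1 small-sample
#'   correction; the default), `"newey-west"` (panel Newey-West kernel
#'   with `lag` lags), or `"classical"`.
#' @param lag Lag order for the Newey-West kernel.
#' @param center Center the interaction term at the grand means of `preci`
#'   and `dd` (default). Turning it off spans the same column space (the
#'   county indicators absorb the constant shift), changing coefficient
#'   interpretation but not fitted values.
#' @return An object of class `becyr_spec`.
#' @export
model_spec <- function(crop = c("corn", "soybean"),
                       co2_effect = c("linear", "none", "quadratic"),
                       pest_dummy = NULL,
                       covariance = c("cluster", "newey-west", "classical"),
                       lag = 2, center = TRUE) {
  crop <- match.arg(crop)
  co2_effect <- match.arg(co2_effect)
  covariance <- match.arg(covariance)
  if (is.null(pest_dummy)) pest_dummy <- crop == "soybean"
  structure(
    list(crop = crop, co2_effect = co2_effect, pest_dummy = pest_dummy,
         covariance = covariance, lag = lag, center = center),
    class = "becyr_spec"
  )
}

#' @export
print.becyr_spec <- function(x, ...) {
  cat(sprintf("<becyr_spec> %s, CO2 effect: %s, pest dummy: %s, covariance: %s%s\n",
              x$crop, x$co2_effect, x$pest_dummy, x$covariance,
              if (x$center) "" else ", uncentered interaction"))
  invisible(x)
}

#' @noRd
spec_linear_terms <- function(spec) {
  base <- c("pbgs", "preci", "dd", "price_lag", "pf", "trend")
  if (spec$co2_effect != "none") base <- c(base, "co2")
  base
}

#' @noRd
spec_square_terms <- function(spec) {
  base <- c("pbgs_sq", "preci_sq", "dd_sq", "price_lag_sq", "pf_sq", "trend_sq")
  if (spec$co2_effect == "quadratic") base <- c(base, "co2_sq")
  base
}

#' Build the yield-model design columns
#'
#' Expands a panel into the regression design of the quadratic fixed-effects
#' model: one indicator per county (no global intercept), linear and squared
#' terms for pre-season precipitation, season precipitation, degree days,
#' lagged real price, fertilizer index, trend and (per the spec) CO2,
#' the interaction of precipitation and degree days centered at their grand
#' means over all counties and years, and optionally the pest dummy.
#' Squares are of the raw (uncentered) variables; only the interaction is
#' centered.
#'
#' @param panel A panel tibble from [assemble_panel()] (or any tibble with
#'   the same columns).
#' @param spec A [model_spec()].
#' @return A tibble of design columns (`county` as a factor plus numeric
#'   regressors), with attributes `ledger` (a tibble mapping every design
#'   column to its role and human-readable label) and `means` (the stored
#'   grand means of `preci` and `dd` used for centering).
#' @export
build_design <- function(panel, spec = model_spec()) {
  if (!inherits(spec, "becyr_spec")) abort("`spec` must come from model_spec().")
  lin <- spec_linear_terms(spec)
  missing <- setdiff(c("county", lin), names(panel))
  if (length(missing) > 0) {
    abort(paste0("`panel` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (spec$pest_dummy && !"pest" %in% names(panel)) {
    abort("`panel` is missing the `pest` column required by the spec.")
  }

  means <- c(preci = mean(panel$preci), dd = mean(panel$dd))
  design <- tibble(county = factor(panel$county))
  for (v in lin) design[[v]] <- panel[[v]]
  for (sq in spec_square_terms(spec)) {
    design[[sq]] <- panel[[sub("_sq$", "", sq)]]^2
  }
  if (spec$center) {
    design$preci_x_dd <- (panel$preci - means["preci"]) * (panel$dd - means["dd"])
  } else {
    design$preci_x_dd <- panel$preci * panel$dd
  }
  if (spec$pest_dummy) design$pest <- as.numeric(panel$pest)

  numeric_cols <- setdiff(names(design), "county")
  zero_var <- numeric_cols[vapply(design[numeric_cols], function(v) var(v) == 0,
                                  logical(1))]
  if (length(zero_var) > 0) {
    abort(paste0("Constant (zero-variance) design column(s): ",
                 paste(zero_var, collapse = ", ")))
  }

  labels <- c(
    pbgs = "Precipitation Before Growing Season",
    preci = "Precipitation During Growing Season",
    dd = "Degree Days During Growing Season",
    price_lag = "Crop Price Lagged One-Year",
    pf = "Fertilizer Price Index",
    trend = "Trend",
    co2 = "Local CO2 During Growing Season",
    pest = "Pest-Year Dummy",
    preci_x_dd = "Interaction of Precipitation and Degree Days"
  )
  label_of <- function(term) {
    if (term %in% names(labels)) return(unname(labels[term]))
    stem <- sub("_sq$", "", term)
    if (stem %in% names(labels)) return(paste("Square of", unname(labels[stem])))
    term
  }
  ledger <- bind_rows(
    tibble(column = paste0("county", levels(design$county)),
           role = "indicator",
           label = paste("County indicator:", levels(design$county))),
    tibble(column = numeric_cols,
           role = ifelse(numeric_cols %in% lin, "linear",
                         ifelse(grepl("_sq$", numeric_cols), "square",
                                ifelse(numeric_cols == "pest", "dummy", "interaction"))),
           label = vapply(numeric_cols, label_of, character(1)))
  )
  attr(design, "ledger") <- ledger
  attr(design, "means") <- means
  attr(design, "spec") <- spec
  design
}

#' Fit the quadratic county fixed-effects yield model
#'
#' Ordinary least squares on the design of [build_design()], with robust
#' covariance per the spec (default: county-cluster robust with HC1
#' small-sample correction; panel Newey-West and classical covariance are
#' alternatives). Reports adjusted R-squared about the grand mean (so values
#' are comparable across parameterizations even though the model carries no
#' global intercept), and an F statistic for the joint significance of all
#' non-indicator regressors (classical, from the residual-sum-of-squares
#' comparison against the county-indicators-only model).
#'
#' @inheritParams build_design
#' @return An object of class `becyr_fit`: see Details. Methods:
#'   [predict.becyr_fit()], `tidy()`, `glance()`, `autoplot()`, `print()`.
#' @details The returned object stores the underlying `lm` fit (`model`),
#'   the robust covariance (`vcov`), the coefficient table with robust
#'   standard errors (`coefficients`), the centering means (`means`), the
#'   column ledger, residuals, and the panel used.
#' @examples
#' sim <- simulate_panel(sim_config(n_counties = 4, years = 2000:2010, seed = 1))
#' fit <- fit_becyr(sim$panel, model_spec("corn", "linear"))
#' glance(fit)
#' @export
fit_becyr <- function(panel, spec = model_spec()) {
  design <- build_design(panel, spec)
  if (!"yield" %in% names(panel)) abort("`panel` needs a `yield` column.")
  dat <- design
  dat$yield <- panel$yield
  terms <- setdiff(names(design), "county")
  fml <- stats::as.formula(
    paste("yield ~ 0 + county +", paste(terms, collapse = " + "))
  )
  model <- lm(fml, data = dat)

  cf <- coef(model)
  if (anyNA(cf)) {
    abort(paste0("Design is rank deficient; offending column(s): ",
                 paste(names(cf)[is.na(cf)], collapse = ", ")))
  }

  cluster <- factor(panel$county)
  if (spec$covariance == "cluster" && any(table(cluster) == 1)) {
    warn("Cluster(s) of size 1 under cluster-robust covariance.")
  }
  V <- switch(spec$covariance,
    cluster = sandwich::vcovCL(model, cluster = cluster, type = "HC1"),
    `newey-west` = sandwich::vcovPL(model, cluster = cluster,
                                    lag = spec$lag, adjust = TRUE),
    classical = stats::vcov(model)
  )
  se <- sqrt(diag(V))

  y <- dat$yield
  res <- resid(model)
  n <- length(y)
  p <- length(cf)
  df_resid <- n - p
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p)

  fe_only <- lm(yield ~ 0 + county, data = dat)
  rss0 <- sum(resid(fe_only)^2)
  q <- length(terms)
  f_stat <- ((rss0 - rss) / q) / (rss / df_resid)
  f_p <- stats::pf(f_stat, q, df_resid, lower.tail = FALSE)

  est <- tibble(
    term = names(cf),
    estimate = unname(cf),
    std_error = unname(se[names(cf)]),
    statistic = unname(cf / se[names(cf)]),
    p_value = 2 * stats::pt(abs(unname(cf / se[names(cf)])), df_resid,
                            lower.tail = FALSE),
    role = ifelse(grepl("^county", names(cf)), "indicator", "regressor")
  )

  structure(
    list(
      model = model, spec = spec, coefficients = est, vcov = V,
      ledger = attr(design, "ledger"), means = attr(design, "means"),
      residuals = unname(res), fitted = unname(fitted(model)),
      adj_r_squared = adj_r2, r_squared = r2,
      f_statistic = f_stat, f_df = c(q, df_resid), f_p_value = f_p,
      n = n, df_residual = df_resid, sigma = sqrt(rss / df_resid),
      panel = panel, cluster = cluster
    ),
    class = "becyr_fit"
  )
}

#' @export
print.becyr_fit <- function(x, ...) {
  cat(sprintf("<becyr_fit> %s yield model, CO2 effect: %s\n",
              x$spec$crop, x$spec$co2_effect))
  cat(sprintf("  n = %d, counties = %d, adjusted R^2 = %.4f, F(%d, %d) = %.1f\n",
              x$n, nlevels(x$cluster), x$adj_r_squared, x$f_df[1], x$f_df[2],
              x$f_statistic))
  cat(sprintf("  covariance: %s; residual sd = %.2f bu/ac\n",
              x$spec$covariance, x$sigma))
  cat("\nRegressors (robust SEs):\n")
  reg <- x$coefficients |> filter(.data$role == "regressor")
  print(as.data.frame(reg[c("term", "estimate", "std_error", "p_value")]),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.becyr_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
vcov.becyr_fit <- function(object, ...) object$vcov

#' @rdname fit_becyr
#' @param x A `becyr_fit` object.
#' @param ... Unused.
#' @export
tidy.becyr_fit <- function(x, ...) {
  x$coefficients |>
    rename(std.error = "std_error", p.value = "p_value")
}

#' @rdname fit_becyr
#' @export
glance.becyr_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared,
    adj.r.squared = x$adj_r_squared,
    sigma = x$sigma,
    statistic = x$f_statistic,
    p.value = x$f_p_value,
    df = x$f_df[1],
    df.residual = x$df_residual,
    nobs = x$n
  )
}

#' Predict yields from a fitted model
#'
#' Rebuilds the design columns of `newdata` using the fit's stored centering
#' means and multiplies through the estimates. In-sample, fitted values plus
#' residuals reproduce the observed yields exactly.
#'
#' @param object A `becyr_fit`.
#' @param newdata A panel tibble; defaults to the fitting panel.
#' @param new_county What to do for counties without an estimated
#'   indicator: `"error"` (default) or `"mean"` (use the average county
#'   effect, appropriate for held-out-county validation).
#' @param ... Unused.
#' @return A numeric vector of predicted yields (bushels/acre).
#' @export
predict.becyr_fit <- function(object, newdata = NULL,
                              new_county = c("error", "mean"), ...) {
  new_county <- match.arg(new_county)
  panel <- newdata %||% object$panel
  spec <- object$spec
  lin <- spec_linear_terms(spec)
  cf <- coef(object)

  alpha_terms <- grep("^county", names(cf), value = TRUE)
  alphas <- setNames(cf[alpha_terms], sub("^county", "", alpha_terms))
  county <- as.character(panel$county)
  unknown <- setdiff(unique(county), names(alphas))
  if (length(unknown) > 0) {
    if (new_county == "error") {
      abort(paste0("No estimated county effect for: ",
                   paste(unknown, collapse = ", ")))
    }
    alphas <- c(alphas, setNames(rep(mean(alphas), length(unknown)), unknown))
  }

  yhat <- unname(alphas[county])
  for (v in lin) {
    yhat <- yhat + cf[v] * panel[[v]]
    sq <- paste0(v, "_sq")
    if (sq %in% names(cf)) yhat <- yhat + cf[sq] * panel[[v]]^2
  }
  inter <- if (spec$center) {
    (panel$preci - object$means["preci"]) * (panel$dd - object$means["dd"])
  } else {
    panel$preci * panel$dd
  }
  yhat <- yhat + cf["preci_x_dd"] * inter
  if (spec$pest_dummy) yhat <- yhat + cf["pest"] * as.numeric(panel$pest)
  unname(yhat)
}

#' Variance inflation factors on within-transformed linear terms
#'
#' Computes, for each linear regressor of the model, the variance inflation
#' factor `1 / (1 - R^2_j)` from regressing that term on the other linear
#' terms after subtracting county means (the within transformation, so the
#' diagnostics condition on the fixed effects, as the panel estimator does).
#' Perfect collinearity is reported as `Inf` and flagged.
#'
#' @param x A `becyr_fit`, or a data frame of linear regressors with an
#'   optional `county` column for the within transformation.
#' @param ... Passed between methods.
#' @return A tibble `term`, `vif`, `collinear`.
#' @export
becyr_vif <- function(x, ...) UseMethod("becyr_vif")

#' @rdname becyr_vif
#' @export
becyr_vif.becyr_fit <- function(x, ...) {
  lin <- spec_linear_terms(x$spec)
  df <- x$panel[c("county", lin)]
  becyr_vif(as_tibble(df), ...)
}

#' @rdname becyr_vif
#' @export
becyr_vif.data.frame <- function(x, ...) {
  vars <- setdiff(names(x), "county")
  num <- vars[vapply(x[vars], is.numeric, logical(1))]
  if (length(num) < 3) abort("Need at least 3 regressors for VIFs.")
  demeaned <- x[num]
  if ("county" %in% names(x)) {
    demeaned <- as_tibble(x) |>
      group_by(.data$county) |>
      mutate(across(all_of(num), function(v) v - mean(v))) |>
      ungroup() |>
      select(all_of(num))
  }
  vifs <- vapply(num, function(j) {
    others <- setdiff(num, j)
    fit <- lm(stats::reformulate(others, response = j), data = demeaned)
    yj <- demeaned[[j]]
    r2 <- 1 - sum(resid(fit)^2) / sum((yj - mean(yj))^2)
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble(term = num, vif = unname(vifs), collinear = !is.finite(vifs))
}
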