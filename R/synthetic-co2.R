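#' Simulate a reference/target pair of monthly CO2 series
#'
#' Generates two seasonally varying monthly CO2 series mimicking a tropical
#' reference station and a mid-latitude target station:
#'
#' * the **reference** series is a linear trend plus an annual harmonic
#'   peaking in `ref_peak_month` (default May);
#' * the **target** series is `intercept + slope * reference` plus twelve
#'   month-specific offsets and Gaussian noise. The default offsets give the
#'   target a larger seasonal range than the reference, with a high plateau
#'   from late fall through spring and a mid-summer trough -- the signature
#'   of a site where photosynthetic drawdown is confined to a short warm
#'   season.
#'
#' The generating relationship is exactly the form the proxy regression
#' ([fit_proxy_model()]) estimates, so the generator doubles as a
#' truth-known test bed for proxy reconstruction.
#'
#' @param years Integer vector of calendar years.
#' @param seed Integer seed.
#' @param base Reference concentration in the first year (ppm).
#' @param trend Reference trend (ppm per year).
#' @param ref_amplitude Amplitude of the reference annual harmonic (ppm).
#' @param ref_peak_month Month (1-12) at which the reference harmonic peaks.
#' @param slope,intercept Affine map from reference to target.
#' @param offsets Length-12 numeric, target monthly offsets (ppm).
#' @param noise_sd Standard deviation of target noise (ppm).
#' @return A list with tibbles `reference` and `target` (columns `year`,
#'   `month`, `ppm`) and the generating parameters in `truth`.
#' @examples
#' pair <- simulate_co2_pair(2005:2016, seed = 42)
#' monthly_correlations(pair$reference, pair$target)
#' @export
simulate_co2_pair <- function(years, seed = 1L,
                              base = 315, trend = 1.55,
                              ref_amplitude = 3, ref_peak_month = 5,
                              slope = 1, intercept = 0,
                              offsets = c(8, 8, 7.5, 6, 2, -4, -9, -9, -5, 1, 6, 8),
                              noise_sd = 0.8) {
  years <- as.integer(years)
  if (length(years) == 0 || anyNA(years)) abort("`years` must be non-empty.")
  years <- seq(min(years), max(years))
  if (length(offsets) != 12) abort("`offsets` must have length 12.")
  stopifnot(noise_sd >= 0)
  withr::local_seed(as.integer(seed))

  grid <- tidyr::expand_grid(year = years, month = 1:12)
  t_frac <- (grid$year - years[1]) + (grid$month - 0.5) / 12
  ref_ppm <- base + trend * t_frac +
    ref_amplitude * cos(2 * pi * (grid$month - ref_peak_month) / 12)
  tgt_ppm <- intercept + slope * ref_ppm + offsets[grid$month] +
    (if (noise_sd > 0) rnorm(nrow(grid), 0, noise_sd) else 0)
  if (any(ref_ppm <= 0) || any(tgt_ppm <= 0)) {
    abort("Generated CO2 values must be positive; adjust base/trend/offsets.")
  }

  list(
    reference = tibble(year = grid$year, month = grid$month, ppm = ref_ppm),
    target = tibble(year = grid$year, month = grid$month, ppm = tgt_ppm),
    truth = list(slope = slope, intercept = intercept, offsets = offsets,
                 noise_sd = noise_sd)
  )
}
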