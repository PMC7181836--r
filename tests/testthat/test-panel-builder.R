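test_that("area-weighted boundary merge: worked example, symmetry, identity", {
  y <- tibble::tibble(county = c("A", "B"), year = 2000L, crop = "corn",
                      yield = c(100, 80), area = c(300, 100))
  map <- tibble::tibble(county = c("A", "B"), merged = "AB")
  out <- merge_boundary_counties(y, map)
  expect_equal(out$yield, 95)           # (100*300 + 80*100) / 400
  expect_equal(oracle_merge(c(100, 80), c(300, 100)), 95)

  y_eq <- y |> dplyr::mutate(area = 200)
  expect_equal(merge_boundary_counties(y_eq, map)$yield, 90)  # simple average

  solo <- merge_boundary_counties(y[1, ], tibble::tibble(county = "A", merged = "A2"))
  expect_equal(solo$yield, 100)
  expect_equal(solo$area, 300)

  y0 <- y |> dplyr::mutate(area = 0)
  expect_error(merge_boundary_counties(y0, map), "zero")
})

test_that("merge output is bounded by member yields and conserves production", {
  withr::with_seed(41, {
    for (i in 1:20) {
      k <- sample(2:5, 1)
      y <- tibble::tibble(
        county = paste0("X", 1:k), year = 2000L, crop = "corn",
        yield = runif(k, 20, 150), area = runif(k, 100, 5000)
      )
      map <- tibble::tibble(county = y$county, merged = "M")
      out <- merge_boundary_counties(y, map)
      expect_gte(out$yield, min(y$yield))
      expect_lte(out$yield, max(y$yield))
      expect_equal(out$yield * out$area, sum(y$yield * y$area))
    }
  })
})

test_that("deflation: identity, doubling, and round trip", {
  cpi <- tibble::tibble(year = c(1990L, 2002L), cpi = c(100, 100))
  d <- tibble::tibble(year = 1990L, price = 200)
  expect_equal(deflate(d, cpi, price)$price, 200)

  cpi2 <- tibble::tibble(year = c(1990L, 2002L), cpi = c(50, 100))
  expect_equal(deflate(d, cpi2, price)$price, 400)

  # deflate then re-inflate recovers the original
  real <- deflate(d, cpi2, price)
  nominal_again <- real |>
    dplyr::left_join(cpi2, by = "year") |>
    dplyr::mutate(price = price * cpi / 100)
  expect_equal(nominal_again$price, d$price)

  expect_error(deflate(tibble::tibble(year = 1980L, price = 1), cpi2, price),
               "1980")
  # within-year ordering preserved (positive scalar transform)
  multi <- tibble::tibble(year = 1990L, price = c(10, 30, 20))
  expect_equal(order(deflate(multi, cpi2, price)$price), order(multi$price))
})

test_that("soybean filters: area rule, continuity rule, logging, idempotence", {
  y <- tibble::tibble(
    county = "A", year = c(1960L, 1961L, 1962L),
    yield = 30, area = c(900, 2000, 2000)
  )
  f <- apply_soybean_filters(y)
  expect_identical(f$year, c(1961L, 1962L))
  excl <- attr(f, "exclusions")
  expect_identical(excl$year, 1960L)
  expect_match(excl$reason, "area")

  # gap at 1966: retained span starts 1967
  y2 <- tibble::tibble(
    county = "B", year = c(1960:1965, 1967:1980), yield = 30, area = 2000
  )
  f2 <- apply_soybean_filters(y2)
  expect_identical(min(f2$year), 1967L)
  expect_identical(nrow(attr(f2, "exclusions")), 6L)

  # idempotence
  f2_again <- apply_soybean_filters(f2)
  expect_identical(nrow(attr(f2_again, "exclusions")), 0L)
  expect_equal(f2_again$year, f2$year)

  # a county filtered out entirely warns
  y3 <- tibble::tibble(county = "C", year = 1960L, yield = 30, area = 100)
  expect_warning(apply_soybean_filters(y3), "entire")
})

test_that("filtered synthetic soybean panels have no internal gaps", {
  sim <- simulate_panel(tiny_config(crop = "soybean", n_counties = 6,
                                    years = 1985:2005,
                                    soybean_missingness = 0.4,
                                    missing_before = 1996, seed = 77))
  filtered <- suppressWarnings(apply_soybean_filters(sim$yields))
  # exhaustive scan: every county's retained years are consecutive
  gaps <- filtered |>
    dplyr::summarise(
      gapfree = identical(sort(year), seq(min(year), max(year))),
      .by = county
    )
  expect_true(all(gaps$gapfree))
})

test_that("panel assembly: lag contract, trend sequence, row counting", {
  sim <- simulate_panel(tiny_config(n_counties = 3, years = 2000:2004))

  # lag contract: the panel's lagged price equals the prior year's deflated,
  # scaled annual mean price
  cpi <- sim$cpi
  p1999 <- sim$prices |>
    dplyr::filter(year == 1999) |>
    dplyr::summarise(p = mean(price)) |>
    dplyr::pull(p)
  real1999 <- p1999 * 100 / cpi$cpi[cpi$year == 1999] / 100
  got <- unique(sim$panel$price_lag[sim$panel$year == 2000])
  expect_equal(got, real1999, tolerance = 1e-10)

  expect_identical(sort(unique(sim$panel$trend)), 1L:5L)
  expect_identical(nrow(sim$panel), 15L)

  # full-length panels run trend 1..55 and 29 x 55 rows with the leading
  # year supplied
  cfg <- sim_config("corn", seed = 4)
  sim_full <- simulate_panel(cfg)
  expect_identical(sort(unique(sim_full$panel$trend)), 1L:55L)
  expect_identical(nrow(sim_full$panel), 29L * 55L)

  # edge rule: when the pre-season window reaches into an uncovered prior
  # year, that county-year row is dropped and logged (frost-free years have
  # Jan 1 starts, so the window sits wholly in the prior year)
  w_ff <- make_weather(2000:2001, tmin = 5, tmean = 14, precip = 1)
  feats <- suppressWarnings(climate_features(w_ff, years = 2000:2001))
  expect_true(is.na(feats$pbgs[feats$year == 2000]))
  co2_tbl <- tidyr::expand_grid(year = 2000:2001, month = 1:12) |>
    dplyr::mutate(ppm = 370)
  co2_year <- season_co2(co2_tbl, provincial_season(feats))
  y_small <- tibble::tibble(county = "C01", year = 2000:2001, crop = "corn",
                            yield = 100, area = 30000)
  cpi_small <- tibble::tibble(year = c(1999:2001, 2002L), cpi = c(92, 95, 97, 100))
  prices_small <- tidyr::expand_grid(year = 1999:2001, month = 1:12) |>
    dplyr::mutate(price = 300)
  fert_small <- tidyr::expand_grid(year = 1999:2001, quarter = 1:4) |>
    dplyr::mutate(index = 110)
  panel2 <- suppressMessages(assemble_panel(
    feats, co2_year, prices_small, cpi_small, fert_small, y_small,
    crop = "corn"
  ))
  expect_identical(nrow(panel2), 1L)
  expect_identical(attr(panel2, "dropped")$year, 2000L)

  # join misses error with keys listed
  expect_error(
    assemble_panel(feats, co2_year |> dplyr::filter(year > 2000),
                   prices_small, cpi_small, fert_small, y_small,
                   crop = "corn"),
    "Missing CO2"
  )
})
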