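make_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_panel(tiny_config(n_counties = 5, years = 1995:2010,
                                        noise_sd = 6, seed = 12))
      cache <<- list(sim = sim,
                     fit = fit_becyr(sim$panel, model_spec("corn", "linear")))
    }
    cache
  }
})

test_that("design columns follow the spec: counts, variants, centering", {
  sim <- make_fit()$sim
  d_quad <- build_design(sim$panel, model_spec("corn", "quadratic"))
  ledger <- attr(d_quad, "ledger")
  expect_identical(nrow(ledger), 5L + 15L)   # counties + 7 lin + 7 sq + inter
  # at 29 counties this is the 29 + 14 + 1 = 44 column quadratic design
  expect_identical(sum(ledger$role != "indicator"), 15L)

  d_none <- build_design(sim$panel, model_spec("corn", "none"))
  expect_false(any(grepl("co2", names(d_none))))
  d_lin <- build_design(sim$panel, model_spec("corn", "linear"))
  expect_true("co2" %in% names(d_lin))
  expect_false("co2_sq" %in% names(d_lin))

  # stored centering means equal the panel grand means
  means <- attr(d_lin, "means")
  expect_equal(unname(means["preci"]), mean(sim$panel$preci))
  expect_equal(unname(means["dd"]), mean(sim$panel$dd))

  # constant column rejected
  p_bad <- sim$panel
  p_bad$pf <- 1
  expect_error(build_design(p_bad, model_spec("corn", "linear")), "pf")
})

test_that("OLS estimates equal a pseudo-inverse oracle on a small instance", {
  sim <- simulate_panel(tiny_config(n_counties = 2, years = 2000:2012,
                                    noise_sd = 5, seed = 3))
  panel <- sim$panel[1:26, ]
  fit <- fit_becyr(panel, model_spec("corn", "linear"))
  design <- build_design(panel, model_spec("corn", "linear"))
  X <- cbind(stats::model.matrix(~ 0 + county, design),
             as.matrix(design[setdiff(names(design), "county")]))
  est <- oracle_ols(X, panel$yield)
  expect_equal(unname(coef(fit)[colnames(X)]), unname(est), tolerance = 1e-8)
})

test_that("OLS identities hold: residual orthogonality and in-sample prediction", {
  f <- make_fit()$fit
  design <- build_design(f$panel, f$spec)
  X <- cbind(stats::model.matrix(~ 0 + county, design),
             as.matrix(design[setdiff(names(design), "county")]))
  # residuals orthogonal to every design column
  expect_lt(max(abs(t(X) %*% f$residuals)) / nrow(X), 1e-7)
  # prediction + residuals = observed
  expect_equal(predict(f) + f$residuals, f$panel$yield, tolerance = 1e-8)
})

test_that("fitted values and R2 are invariant to interaction centering", {
  sim <- make_fit()$sim
  f_c <- fit_becyr(sim$panel, model_spec("corn", "linear", center = TRUE))
  f_r <- fit_becyr(sim$panel, model_spec("corn", "linear", center = FALSE))
  expect_equal(f_c$fitted, f_r$fitted, tolerance = 1e-8)
  expect_equal(f_c$residuals, f_r$residuals, tolerance = 1e-8)
  expect_equal(f_c$adj_r_squared, f_r$adj_r_squared, tolerance = 1e-10)
  # interaction coefficient itself is identical; linear terms shift
  expect_equal(unname(coef(f_c)["preci_x_dd"]), unname(coef(f_r)["preci_x_dd"]),
               tolerance = 1e-8)
})

test_that("adding a constant to one county's yields shifts only its intercept", {
  sim <- make_fit()$sim
  panel2 <- sim$panel
  bump <- panel2$county == "C02"
  panel2$yield[bump] <- panel2$yield[bump] + 12
  f1 <- make_fit()$fit
  f2 <- fit_becyr(panel2, f1$spec)
  c1 <- coef(f1); c2 <- coef(f2)
  expect_equal(unname(c2["countyC02"] - c1["countyC02"]), 12, tolerance = 1e-7)
  others <- setdiff(names(c1), "countyC02")
  expect_lt(max(abs(c2[others] - c1[others])), 1e-7)
})

test_that("robust and classical standard errors agree under iid errors at scale", {
  # homoskedastic independent noise: cluster-robust SEs should approach the
  # classical ones as the panel grows
  sim <- simulate_panel(tiny_config(n_counties = 20, years = 1970:2013,
                                    noise_sd = 10, seed = 31))
  f_cl <- fit_becyr(sim$panel, model_spec("corn", "linear", covariance = "cluster"))
  f_cls <- fit_becyr(sim$panel, model_spec("corn", "linear", covariance = "classical"))
  ratio <- f_cl$coefficients$std_error / f_cls$coefficients$std_error
  reg <- f_cl$coefficients$role == "regressor"
  expect_true(all(ratio[reg] > 0.5 & ratio[reg] < 2))
})

test_that("prediction contracts: excluded CO2 is inert, unknown counties error", {
  sim <- make_fit()$sim
  f_none <- fit_becyr(sim$panel, model_spec("corn", "none"))
  shifted <- sim$panel
  shifted$co2 <- shifted$co2 + 100
  expect_equal(predict(f_none, shifted), predict(f_none), tolerance = 1e-10)

  stranger <- sim$panel |> dplyr::mutate(county = "Z99")
  expect_error(predict(make_fit()$fit, stranger), "Z99")
  expect_silent(predict(make_fit()$fit, stranger, new_county = "mean"))
})

test_that("VIFs: orthogonal limit, closed form at r = 0.99, duplicated column", {
  withr::with_seed(19, {
    n <- 4000
    ortho <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    v <- becyr_vif(ortho)
    expect_true(all(abs(v$vif - 1) < 0.05))

    # two regressors with correlation 0.99: VIF ~ 1/(1 - 0.99^2) ~ 50.25
    x <- rnorm(n)
    y <- 0.99 * x + sqrt(1 - 0.99^2) * rnorm(n)
    z <- rnorm(n)
    v2 <- becyr_vif(tibble::tibble(x = x, y = y, z = z))
    expect_equal(v2$vif[v2$term == "x"], 1 / (1 - cor(x, y)^2), tolerance = 0.02)
    expect_equal(v2$vif[v2$term == "x"], 50.25, tolerance = 0.15 * 50.25)

    dup <- tibble::tibble(a = rnorm(n))
    dup$b <- dup$a
    dup$c <- rnorm(n)
    v3 <- becyr_vif(dup)
    expect_true(all(is.infinite(v3$vif[v3$term %in% c("a", "b")])))
    expect_true(all(v3$collinear[v3$term %in% c("a", "b")]))
  })
  # and on a fit: within-transformed linear terms
  v4 <- becyr_vif(make_fit()$fit)
  expect_identical(nrow(v4), 7L)
  expect_true(all(v4$vif >= 1))
})

test_that("tidy and glance present the fit in broom shape", {
  f <- make_fit()$fit
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(f)
  expect_identical(gl$nobs, f$n)
  expect_true(gl$adj.r.squared <= 1 && gl$adj.r.squared > 0)
})
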