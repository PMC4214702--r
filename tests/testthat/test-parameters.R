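test_that("scenario presets load, validate, and differ only in tumor IL-35 production", {
  expect_s3_class(p_il35, "il35_params")
  diff_names <- names(p_il35)[unlist(p_il35) != unlist(p_ctrl)]
  expect_identical(diff_names, "lambda_rho_c")
  expect_gt(p_il35$lambda_rho_c, p_ctrl$lambda_rho_c)
  # idempotent reload
  expect_identical(unlist(il35_params("J558-IL-35")), unlist(p_il35))
  expect_error(load_scenario("J558-XYZ"), "unknown scenario")
  expect_error(il35_params("J558-IL-35", nonsense = 1), "unknown parameter")
  expect_error(il35_params("J558-IL-35", d_M = -1), "non-positive")
})

test_that("validation rejects broken threshold ordering and baseline ratios", {
  p <- p_il35
  p$w_hyp <- p$w_nec / 2
  expect_error(validate_params(p), "w_nec < w_hyp")
  p <- p_il35
  p$eps_c <- 1.5
  expect_error(validate_params(p), "eps_c")
  p <- p_il35
  p$w_star <- 2 * p$w_normal
  expect_error(validate_params(p), "w_star")
})

test_that("nondimensionalization round trip is the identity", {
  s <- default_scaling()
  pn <- nondimensionalize(p_il35, s)
  pr <- redimensionalize(pn, s)
  expect_lt(max(abs(unlist(pr) / unlist(p_il35) - 1)), 1e-12)

  # identity scaling leaves values unchanged
  ones <- as.list(stats::setNames(rep(1, 15), names(unclass(default_scaling()))))
  s1 <- do.call(default_scaling, ones)
  pn1 <- nondimensionalize(p_il35, s1)
  expect_equal(unlist(pn1), unlist(p_il35)[names(pn1)], tolerance = 1e-14,
               ignore_attr = TRUE)

  # property: 100 random strictly positive parameter vectors round-trip
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    p <- p_il35
    p[] <- lapply(p, function(v) v * stats::runif(1, 0.5, 2))
    pr <- redimensionalize(nondimensionalize(p, s), s)
    worst <- max(worst, max(abs(unlist(pr) / unlist(p) - 1)))
  }
  expect_lt(worst, 1e-12)
})

test_that("parameters with identical scaling rules map consistently", {
  tab <- parameter_table()
  s <- default_scaling()
  pn <- nondimensionalize(p_il35, s)
  # two pure rates (1/day): dimensionless ratio equals dimensional ratio
  expect_equal(pn$d_M / pn$d_T, p_il35$d_M / p_il35$d_T)
  expect_equal(pn$D_c / pn$D_w, p_il35$D_c / p_il35$D_w)
})

test_that("stored dimensionless column is consistent with the declared scaling", {
  tab <- parameter_table()
  env <- list2env(unclass(default_scaling()))
  fac <- vapply(tab$nd_scale, function(e) eval(parse(text = e), envir = env),
                numeric(1))
  expect_lt(max(abs(tab$value * fac / tab$nd_value - 1)), 1e-12)
})

test_that("scaling system rejects non-positive factors and unknown names", {
  expect_error(default_scaling(L = -1), "positive")
  expect_error(default_scaling(bogus = 2), "unknown scale factor")
})

test_that("IL-35 production calibration inverts the saturating exponential", {
  d_rho <- 1.38; c_bar <- 0.4
  # steady-state limit
  lam_inf <- calibrate_il35_production(1e-10, c_bar, d_rho, Inf)
  expect_equal(lam_inf, d_rho * 1e-10 / c_bar)
  # forward consistency
  lam <- calibrate_il35_production(8e-11, c_bar, d_rho, 10)
  rho_fwd <- (lam * c_bar / d_rho) * (1 - exp(-d_rho * 10))
  expect_lt(abs(rho_fwd / 8e-11 - 1), 1e-10)
  # brute-force root-finding oracle on 50 random inputs
  set.seed(7)
  for (i in 1:50) {
    tgt <- stats::runif(1, 1e-12, 1e-9)
    cb <- stats::runif(1, 0.05, 0.5)
    dr <- stats::runif(1, 0.2, 5)
    tt <- stats::runif(1, 0.5, 30)
    lam <- calibrate_il35_production(tgt, cb, dr, tt)
    oracle <- stats::uniroot(
      function(l) (l * cb / dr) * (1 - exp(-dr * tt)) - tgt,
      interval = c(1e-16, 1), tol = 1e-15)$root
    expect_lt(abs(lam / oracle - 1), 1e-6)
  }
  expect_error(calibrate_il35_production(1e-10, 0.4, 1.38, -1), "positive")
  expect_error(calibrate_il35_production(Inf, 0.4, 1.38, 1), "finite")
})

test_that("MDSC production calibration matches the simplified two-ODE system", {
  expect_equal(calibrate_mdsc_production(1, d_M = 0.1, horizon = 14), 0)
  # monotone in the observed ratio
  est <- vapply(seq(1, 3, by = 0.25), function(r)
    calibrate_mdsc_production(r, 0.1, 14), numeric(1))
  expect_true(all(diff(est) > 0))
  # ODE oracle: integrate both simplified balances from M(0) = 0 and check
  # the horizon-time ratio implied by the closed-form estimate
  s_M <- 1e-4; d_M <- 0.1; horizon <- 14; sat <- 0.5; ratio_obs <- 2
  lam <- calibrate_mdsc_production(ratio_obs, d_M, horizon,
                                   s_M = s_M, saturation = sat)
  rhs <- function(t, y, L) list(c(s_M - d_M * y[1], s_M + L - d_M * y[2]))
  sol <- deSolve::lsoda(c(0, 0), c(0, horizon), rhs, lam * sat,
                        rtol = 1e-10, atol = 1e-14)
  expect_lt(abs(sol[2, 3] / sol[2, 2] - ratio_obs), 1e-6)
  expect_error(calibrate_mdsc_production(0.5, 0.1, 14), ">= 1")
})

test_that("symbol map covers every transcribed constant", {
  expect_setequal(symbol_map()$name, parameter_table()$name)
})
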