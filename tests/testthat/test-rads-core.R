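test_that("weighted dose combines gamma and RBE-weighted neutron components", {
  expect_equal(weighted_dose(0.1, 0.01, 10), 0.2)
  expect_equal(weighted_dose(0.35, 0), 0.35)
  expect_equal(weighted_dose(0, 0.05, 1), 0.05)
  expect_error(weighted_dose(-0.1, 0), class = "radsmmi_domain_error")
  expect_error(weighted_dose(0.1, 0.1, rbe = 0), class = "radsmmi_domain_error")
})

test_that("excess hazard combines transfer terms and divides by DDREF", {
  s <- rads_settings()
  expect_equal(excess_hazard(0, 0, 0.05, s), 0)
  # (0.5*1*0.01 + 0.5*100/1e4) / 2
  expect_equal(excess_hazard(1, 100, 0.01, s), 0.005)
  # pure multiplicative transfer, no dose-rate reduction
  s2 <- rads_settings(ddref = 1, transfer_weight_err = 1,
                      transfer_weight_ear = 0)
  expect_equal(excess_hazard(1, 0, 0.02, s2), 0.02)
  # EAR-only DDREF scope leaves the multiplicative term undivided
  s3 <- rads_settings(ddref = 2, ddref_scope = "ear_only")
  expect_equal(excess_hazard(1, 100, 0.01, s3), 0.5 * 0.01 + 0.5 * 0.01 / 2)
  expect_error(excess_hazard(1, 1, -0.1, s), class = "radsmmi_domain_error")
})

test_that("cumulative hazard integrates exactly on constant and linear integrands", {
  bl <- flat_baseline()
  s <- rads_settings(ddref = 1, latency = 5,
                     transfer_weight_err = 0, transfer_weight_ear = 1)
  # constant h = 0.01 over [45, 65]: EAR = 100 per 1e4 PY
  p <- exposure_profile(1, 40, 65, "male")
  H <- cumulative_hazard(function(a) list(err = 0 * a, ear = rep(100, length(a))),
                         bl, p, s)
  expect_equal(H, 0.2, tolerance = 1e-12)

  # linear h(u) = c*u over [40, 60]: trapezoid is exact, H = c*(60^2-40^2)/2
  c0 <- 0.001
  p2 <- exposure_profile(1, 35, 60, "male")
  H2 <- cumulative_hazard(function(a) list(err = 0 * a, ear = 1e4 * c0 * a),
                          bl, p2, s)
  expect_equal(H2, c0 * (60^2 - 40^2) / 2, tolerance = 1e-12)

  # empty integration range
  p3 <- exposure_profile(1, 40, 44, "male")
  expect_equal(cumulative_hazard(function(a) list(err = a, ear = a), bl, p3, s), 0)
})

test_that("quadrature agrees with an independent trapezoid implementation", {
  skip_if_not_installed("pracma")
  bl <- flat_baseline(0.004)
  s <- rads_settings(grid_step = 0.5)
  p <- ref_profile(0.5)
  prov <- function(a) list(err = 0.4 * exp(-0.05 * (a - 45)),
                           ear = 30 * (a / 70)^2)
  H <- cumulative_hazard(prov, bl, p, s)
  grid <- seq(45, 65, by = 0.5)
  er <- prov(grid)
  h <- (0.5 * er$err * 0.004 + 0.5 * er$ear / 1e4) / 2
  expect_equal(H, pracma::trapz(grid, h), tolerance = 1e-12)
})

test_that("cumulative hazard is additive over abutting age intervals", {
  bl <- flat_baseline(0.005)
  s <- rads_settings()
  prov <- function(a) list(err = 0.3 + 0.01 * a, ear = 20 + 0.5 * a)
  H_full <- cumulative_hazard(prov, bl, exposure_profile(1, 40, 65, "male"), s)
  # split at 53.5, off the unit grid; exact because h is linear in age here
  s8 <- rads_settings(latency = 0)
  H_a <- cumulative_hazard(prov, bl, exposure_profile(1, 45, 53.5, "male"), s8)
  H_b <- cumulative_hazard(prov, bl, exposure_profile(1, 53.5, 65, "male"), s8)
  expect_equal(H_a + H_b, H_full, tolerance = 1e-12)
})

test_that("halving the grid step barely moves RADS on smooth configurations", {
  cfg <- synth_config()
  reg <- synth_model_registry(cfg)
  bl <- synth_baseline(cfg)
  ws <- synth_weight_sets()[["AIC/original"]]
  p <- ref_profile(0.17)
  r1 <- rads_point(reg, ws, bl, p, rads_settings(grid_step = 1))
  r2 <- rads_point(reg, ws, bl, p, rads_settings(grid_step = 0.5))
  expect_lt(abs(r1 - r2), 1e-6)
})

test_that("a baseline coverage gap raises a data error naming the ages", {
  bl <- baseline_rate_table(
    tidyr::expand_grid(age = 50:60, sex = c("male", "female")) |>
      dplyr::mutate(rate = 0.01))
  p <- exposure_profile(1, 40, 65, "male")
  expect_error(
    cumulative_hazard(function(a) list(err = a, ear = a), bl, p,
                      rads_settings()),
    "45", class = "radsmmi_data_error")
})

test_that("the RADS transform is bounded, monotone and exact at oracles", {
  expect_equal(rads_from_hazard(0), 0)
  expect_equal(rads_from_hazard(0.0247), 1 - exp(-0.0247))
  expect_equal(round(rads_from_hazard(0.0247), 5), 0.0244)
  expect_error(rads_from_hazard(-0.01), class = "radsmmi_domain_error")
  H <- c(0, 1e-6, 0.01, 0.5, 5, 30)
  r <- rads_from_hazard(H)
  expect_true(all(r >= 0 & r < 1))
  expect_true(all(diff(r) > 0))
  # small-hazard limit: |RADS - H| <= H^2/2
  expect_true(all(abs(r - H) <= H^2 / 2 + 1e-15))
})

test_that("RADS point estimate composes the full stack", {
  # single linear model tuned so h is constant: ERR-only transfer,
  # alpha*D*0.5*m/DDREF = 0.001 over a 20-year window -> RADS = 1-exp(-0.02)
  m_rate <- 0.01
  s <- rads_settings(ddref = 2, transfer_weight_err = 1,
                     transfer_weight_ear = 0, latency = 5)
  alpha <- 0.001 * s$ddref / m_rate # with D = 1 and all modifiers off
  reg <- single_err_registry(grant_model(alpha = alpha))
  p <- exposure_profile(1, 35, 60, "male")
  r <- rads_point(reg, single_model_weights("GRANT_L"), flat_baseline(m_rate),
                  p, s)
  expect_equal(r, 1 - exp(-0.02), tolerance = 1e-12)

  # zero dose coefficient -> zero risk everywhere
  reg0 <- single_err_registry(grant_model(alpha = 0))
  expect_equal(rads_point(reg0, single_model_weights("GRANT_L"),
                          flat_baseline(), ref_profile(), rads_settings()), 0)
})

test_that("RADS increases monotonically with dose for linear models", {
  cfg <- synth_config()
  reg <- synth_model_registry(cfg)
  bl <- synth_baseline(cfg)
  ws <- synth_weight_sets()[["BIC/original"]]
  doses <- c(0.1, 0.3, 0.6, 1)
  r <- vapply(doses, function(d)
    rads_point(reg, ws, bl, ref_profile(d, "female"), rads_settings()),
    numeric(1))
  expect_true(all(diff(r) > 0))
})
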