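test_that("coefficient sampling matches its asymptotic normal distribution", {
  # degenerate: zero covariance returns the mean in every draw
  m0 <- grant_model(alpha = 0.5, tau = -0.2)
  d0 <- sample_coefficients(m0, 50, seed = 1)
  expect_equal(dim(d0), c(50, 5))
  expect_true(all(d0[, "alpha"] == 0.5))
  expect_true(all(d0[, "tau"] == -0.2))

  # moment check: 1-D variance within 5% at 10,000 draws
  v <- 0.04
  cov1 <- diag(c(v, 0, 0, 0, 0))
  m1 <- grant_model(alpha = 0.5, covariance = cov1)
  d1 <- sample_coefficients(m1, 10000, seed = 2)
  expect_equal(var(d1[, "alpha"]), v, tolerance = 0.05)
  expect_equal(mean(d1[, "alpha"]), 0.5, tolerance = 3 * sqrt(v / 10000) / 0.5)

  # determinism contract
  expect_identical(sample_coefficients(m1, 100, seed = 7),
                   sample_coefficients(m1, 100, seed = 7))
})

test_that("baseline Poisson resampling has the right moments and support", {
  bl <- flat_baseline(0.01)
  # zero rates stay exactly zero
  bl0 <- flat_baseline(0)
  expect_equal(sample_baseline(bl0, 1e5, seed = 1)$rate, bl0$rate)

  # large person-year limit: relative error O(1/sqrt(lambda)), ~1% at 1e6
  big <- sample_baseline(bl, 1e8, seed = 2) # lambda = 1e6 per cell
  expect_equal(big$rate, bl$rate, tolerance = 0.01)

  # one cell resampled repeatedly: mean within 3 standard errors
  one <- baseline_rate_table(
    tidyr::expand_grid(age = c(50, 51), sex = c("male", "female")) |>
      dplyr::mutate(rate = 0.02))
  set.seed(3)
  draws <- replicate(10000, sample_baseline(one, 1e4)$rate[1])
  se <- sqrt(0.02 / 1e4) / sqrt(10000)
  expect_lt(abs(mean(draws) - 0.02), 3 * se)
  expect_true(all(draws >= 0))
})

test_that("with no uncertainty sources the Monte Carlo CI collapses to the point", {
  reg <- single_err_registry(grant_model(alpha = 0.4))
  bl <- flat_baseline()
  s <- fast_settings(baseline_sampling = FALSE)
  est <- rads_ci(reg, single_model_weights("GRANT_L"), bl, ref_profile(), s)
  expect_equal(est$ci_low, est$point)
  expect_equal(est$ci_high, est$point)
  expect_true(all(est$realisations == est$point))
})

test_that("Monte Carlo estimates are reproducible and bounded", {
  cfg <- synth_config()
  reg <- synth_model_registry(cfg)
  bl <- synth_baseline(cfg)
  ws <- synth_weight_sets()[["AIC/original"]]
  s <- fast_settings()
  e1 <- rads_ci(reg, ws, bl, ref_profile(0.17), s)
  e2 <- rads_ci(reg, ws, bl, ref_profile(0.17), s)
  expect_identical(e1, e2)
  expect_true(all(e1$realisations >= 0 & e1$realisations < 1))
  expect_lte(e1$ci_low, e1$ci_high)
})

test_that("percentile CI matches the closed-form normal quantiles on a linear toy", {
  # RADS ~ 1 - exp(-alpha*C) ~ alpha*C for small C: percentile bounds at
  # 10,000 realisations should sit near C*(mu +/- 1.96*sd)
  mu <- 0.5; sdev <- 0.05
  cov1 <- matrix(0, 5, 5); cov1[1, 1] <- sdev^2
  reg <- single_err_registry(grant_model(alpha = mu, covariance = cov1))
  m_rate <- 0.001
  bl <- flat_baseline(m_rate)
  s <- rads_settings(n_realisations = 10000, seed = 9,
                     baseline_sampling = FALSE, transfer_weight_err = 1,
                     transfer_weight_ear = 0, ddref = 1)
  p <- ref_profile()
  est <- rads_ci(reg, single_model_weights("GRANT_L"), bl, p, s)
  C <- m_rate * 20 # flat hazard over [45, 65] per unit alpha
  expect_equal(est$point, 1 - exp(-mu * C), tolerance = 1e-12)
  expect_equal(est$ci_low, 1 - exp(-(mu - 1.96 * sdev) * C), tolerance = 0.01)
  expect_equal(est$ci_high, 1 - exp(-(mu + 1.96 * sdev) * C), tolerance = 0.01)
})

test_that("CI width shrinks as the coefficient covariance is scaled down", {
  base_cov <- matrix(0, 5, 5); base_cov[1, 1] <- 0.04
  bl <- flat_baseline(0.005)
  widths <- sapply(c(1, 0.25, 0), function(scale) {
    mean(sapply(1:20, function(k) {
      reg <- single_err_registry(
        grant_model(alpha = 0.5, covariance = base_cov * scale))
      s <- rads_settings(n_realisations = 400, seed = 100 + k,
                         baseline_sampling = FALSE)
      est <- rads_ci(reg, single_model_weights("GRANT_L"), bl, ref_profile(), s)
      est$ci_high - est$ci_low
    }))
  })
  expect_true(widths[1] > widths[2])
  expect_true(widths[2] > widths[3])
  expect_equal(widths[3], 0)
})

test_that("negative coefficient draws are floored in the hazard and logged", {
  # mean near zero with sizeable variance forces negative excess hazards
  cov1 <- matrix(0, 5, 5); cov1[1, 1] <- 1
  reg <- single_err_registry(grant_model(alpha = 0.01, covariance = cov1))
  s <- fast_settings(baseline_sampling = FALSE)
  est <- rads_ci(reg, single_model_weights("GRANT_L"), flat_baseline(),
                 ref_profile(), s)
  expect_gt(est$floor_rate, 0.3)
  expect_true(all(est$realisations >= 0))
  expect_message(
    rads_ci(reg, single_model_weights("GRANT_L"), flat_baseline(),
            ref_profile(), fast_settings(baseline_sampling = FALSE,
                                         verbose = TRUE)),
    "Floored")
})

test_that("tidy and glance summarise a RADS estimate", {
  reg <- single_err_registry(grant_model(alpha = 0.4))
  est <- rads_ci(reg, single_model_weights("GRANT_L"), flat_baseline(),
                 ref_profile(), fast_settings())
  td <- tidy(est)
  expect_named(td, c("method", "point", "ci_low", "ci_high"))
  expect_equal(td$point, est$point)
  gl <- glance(est)
  expect_equal(gl$n_realisations, 200L)
  expect_equal(gl$mc_sd, sd(est$realisations))
})
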