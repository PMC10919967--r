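test_that("BEIR VII age-at-exposure transform follows its piecewise form", {
  expect_equal(beir_age_transform(20), -1)
  expect_equal(beir_age_transform(30), 0)
  expect_equal(beir_age_transform(45), 0)
  expect_equal(beir_age_transform(c(10, 25, 29.999)),
               c(-2, -0.5, (29.999 - 30) / 10))
  expect_error(beir_age_transform(0), class = "radsmmi_domain_error")
  expect_error(beir_age_transform(-5), class = "radsmmi_domain_error")
})

test_that("INWORKS attained-age coefficient selects left-closed categories", {
  expect_equal(inworks_age_coefficient(59.9, 0.1, 0.2, 0.3), 0.1)
  expect_equal(inworks_age_coefficient(60, 0.1, 0.2, 0.3), 0.2)
  expect_equal(inworks_age_coefficient(80, 0.1, 0.2, 0.3), 0.3)
  expect_equal(inworks_age_coefficient(c(30, 70, 95), 1, 2, 3), c(1, 2, 3))
})

test_that("model constructor validates coefficient sets and covariance", {
  expect_error(risk_model("GRANT_L", "ERR", c(alpha = 1)),
               class = "radsmmi_config_error")
  # beta only for linear-quadratic families
  expect_error(
    risk_model("GRANT_L", "ERR",
               c(alpha = 1, beta = 1, tau = 0, nu = 0, phi = 0, sigma = 0)),
    class = "radsmmi_config_error")
  cf <- c(alpha = 1, tau = 0, nu = 0, phi = 0, sigma = 0)
  asym <- matrix(0, 5, 5); asym[1, 2] <- 1
  expect_error(risk_model("GRANT_L", "ERR", cf, asym),
               class = "radsmmi_config_error")
  neg <- diag(c(-1, 1, 1, 1, 1))
  expect_error(risk_model("GRANT_L", "ERR", cf, neg),
               class = "radsmmi_config_error")
  # valid PSD covariance accepted and reordered to canonical names
  m <- risk_model("GRANT_L", "ERR", cf[c(3, 1, 2, 4, 5)], diag(5) * 0.01)
  expect_named(m$coefficients, c("alpha", "tau", "nu", "phi", "sigma"))
})

test_that("the printed model forms evaluate correctly at scalar oracles", {
  p_neutral <- exposure_profile(1, 30, 70, "male")
  m <- grant_model(alpha = 1)
  expect_equal(evaluate_risk_model(m, p_neutral), 1) # all modifiers collapse

  # direct scalar arithmetic: 0.5 * exp(-0.3 * (40-30)/10)
  m2 <- grant_model(alpha = 0.5, tau = -0.3)
  p2 <- exposure_profile(1, 40, 70, "male")
  expect_equal(evaluate_risk_model(m2, p2), 0.5 * exp(-0.3))

  # linear-quadratic: 0.1*2 + 0.05*4
  lq <- risk_model("GRANT_LQ", "ERR",
                   c(alpha = 0.1, beta = 0.05, tau = 0, nu = 0,
                     phi = 0, sigma = 0))
  expect_equal(evaluate_risk_model(lq, exposure_profile(2, 30, 70, "male")),
               0.1 * 2 + 0.05 * 4)
})

test_that("zero dose yields zero excess risk for every family", {
  cfg <- synth_config()
  reg <- synth_model_registry(cfg)
  p0 <- exposure_profile(0, 40, 65, "female")
  er <- excess_risk(reg, p0)
  expect_equal(er$excess_risk, rep(0, nrow(reg)))
})

test_that("linear families are linear in dose; LQ reduces to L at beta = 0", {
  cfg <- synth_config()
  reg <- synth_model_registry(cfg)
  lin <- reg[grepl("_L$|BEIR7", reg$family), ]
  p1 <- ref_profile(0.4, "female")
  p2 <- ref_profile(0.8, "female")
  expect_equal(excess_risk(lin, p2)$excess_risk,
               2 * excess_risk(lin, p1)$excess_risk)

  for (fam in c("GRANT", "INWORKS", "UNSCEAR")) {
    l <- reg$model[[which(reg$family == paste0(fam, "_L") &
                            reg$endpoint == "ERR")]]
    lq <- reg$model[[which(reg$family == paste0(fam, "_LQ") &
                             reg$endpoint == "ERR")]]
    over <- as.list(l$coefficients)
    over$beta <- 0
    expect_equal(
      evaluate_risk_model(lq, p1, coefficients = over[names(lq$coefficients)]),
      evaluate_risk_model(l, p1))
  }
})

test_that("attained-age response is continuous except at INWORKS breaks", {
  cfg <- synth_config()
  reg <- synth_model_registry(cfg)
  p <- ref_profile()
  eps <- 1e-9
  for (i in seq_len(nrow(reg))) {
    m <- reg$model[[i]]
    a_test <- c(55, 60, 80) # includes the INWORKS category boundaries
    for (a in a_test) {
      left <- evaluate_risk_model(m, p, attained_age = a - eps)
      right <- evaluate_risk_model(m, p, attained_age = a + eps)
      if (grepl("INWORKS", m$family) && a %in% c(60, 80)) next
      expect_equal(left, right, tolerance = 1e-6)
    }
  }
})

test_that("UNSCEAR models reject non-positive time since exposure", {
  cfg <- synth_config()
  reg <- synth_model_registry(cfg)
  u <- reg$model[[which(reg$family == "UNSCEAR_L" & reg$endpoint == "ERR")]]
  p <- ref_profile()
  expect_error(evaluate_risk_model(u, p, attained_age = 40),
               class = "radsmmi_domain_error")
})

test_that("coefficient overrides are the MC entry point; unknown names rejected", {
  m <- grant_model(alpha = 1)
  p <- ref_profile()
  expect_equal(evaluate_risk_model(m, p, coefficients = c(alpha = 2)),
               2 * evaluate_risk_model(m, p))
  expect_error(evaluate_risk_model(m, p, coefficients = c(gamma = 1)),
               class = "radsmmi_config_error")
  # vectorised overrides broadcast across realisations
  out <- evaluate_risk_model(m, p, coefficients = list(alpha = c(1, 2, 3)))
  expect_equal(out, c(1, 2, 3) * evaluate_risk_model(m, p))
})

test_that("model registry round-trips losslessly through YAML", {
  reg <- synth_model_registry(synth_config())
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_registry(reg, path)
  back <- read_model_registry(path)
  expect_equal(back$family, reg$family)
  expect_equal(back$endpoint, reg$endpoint)
  for (i in seq_len(nrow(reg))) {
    expect_equal(back$model[[i]]$coefficients, reg$model[[i]]$coefficients,
                 tolerance = 1e-15)
    expect_equal(back$model[[i]]$covariance, reg$model[[i]]$covariance,
                 tolerance = 1e-15)
  }
})

test_that("exposure profile enforces its invariants", {
  expect_error(exposure_profile(-0.1, 40, 65, "male"),
               class = "radsmmi_domain_error")
  expect_error(exposure_profile(1, 65, 40, "male"),
               class = "radsmmi_domain_error")
  expect_error(exposure_profile(1, 40, 65, "male", shielded_kerma = -1),
               class = "radsmmi_domain_error")
})
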