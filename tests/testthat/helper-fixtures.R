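# shared fixture builders; everything is generated in code

# a GRANT_L model with chosen coefficients, zero covariance unless given
grant_model <- function(endpoint = "ERR", alpha = 0.5, tau = 0, nu = 0,
                        phi = 0, sigma = 0, covariance = NULL) {
  risk_model("GRANT_L", endpoint,
             c(alpha = alpha, tau = tau, nu = nu, phi = phi, sigma = sigma),
             covariance)
}

# registry holding one ERR model plus a silent (all-zero) EAR counterpart,
# so both endpoints resolve during model averaging
single_err_registry <- function(err_model) {
  ear <- risk_model(err_model$family, "EAR",
                    setNames(rep(0, length(err_model$coefficients)),
                             names(err_model$coefficients)))
  tibble::tibble(family = err_model$family, endpoint = c("ERR", "EAR"),
                 model = list(err_model, ear))
}

# flat baseline: constant per-person-year rate at all ages 0..100, both sexes
flat_baseline <- function(rate = 0.01) {
  baseline_rate_table(
    tidyr::expand_grid(age = 0:100, sex = c("male", "female")) |>
      dplyr::mutate(rate = rate))
}

fast_settings <- function(n_realisations = 200, seed = 42L, ...) {
  rads_settings(n_realisations = n_realisations, seed = seed, ...)
}

ref_profile <- function(dose = 1, sex = "male") {
  exposure_profile(dose, age_at_exposure = 40, attained_age = 65, sex = sex)
}
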