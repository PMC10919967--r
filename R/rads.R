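#' Excess hazard from ERR and EAR contributions
#'
#' The age-specific radiation-attributed excess incidence rate combining
#' multiplicative and additive risk transfer:
#' \deqn{h(a) = \frac{w_{ERR}\,ERR\,m(a) + w_{EAR}\,EAR/10000}{DDREF}}
#' with `m(a)` the baseline incidence rate (per person-year) and EAR in
#' cases per 10,000 person-years. With `ddref_scope = "ear_only"` the
#' DDREF divides only the additive term.
#'
#' @param err Excess relative risk (dimensionless; vectorised).
#' @param ear Excess absolute risk per 10,000 person-years (vectorised).
#' @param baseline_rate Baseline incidence rate per person-year.
#' @param settings A [rads_settings()].
#' @return Excess hazard per person-year.
#' @examples
#' excess_hazard(1, 100, 0.01, rads_settings()) # 0.005
#' @export
excess_hazard <- function(err, ear, baseline_rate, settings = rads_settings()) {
  if (any(baseline_rate < 0)) {
    rlang::abort("`baseline_rate` must be non-negative.",
                 class = "radsmmi_domain_error")
  }
  w_err <- settings$transfer_weight_err
  w_ear <- settings$transfer_weight_ear
  if (settings$ddref_scope == "total") {
    (w_err * err * baseline_rate + w_ear * ear / 1e4) / settings$ddref
  } else {
    w_err * err * baseline_rate + (w_ear * ear / 1e4) / settings$ddref
  }
}

# uniform age grid over [lo, hi] with step `by`, endpoint always included
hazard_grid <- function(lo, hi, by) {
  g <- seq(lo, hi, by = by)
  if (g[length(g)] < hi) g <- c(g, hi)
  g
}

# composite trapezoid weights for a (possibly non-uniform) grid
trapezoid_weights <- function(grid) {
  n <- length(grid)
  if (n == 1L) return(0)
  d <- diff(grid)
  c(d[1] / 2, (d[-length(d)] + d[-1]) / 2, d[length(d)] / 2)
}

#' Cumulative excess hazard
#'
#' Integrates the excess hazard from age at exposure plus latency up to
#' the attained age,
#' \eqn{H(a) = \int_{e+l}^{a} h(u)\,du}, by the trapezoidal rule on a
#' uniform age grid (exact for piecewise-linear integrands). ERR and EAR
#' are evaluated at attained age `u` with dose, age at exposure and sex
#' fixed. When the attained age does not exceed `e + l` the integral is
#' empty and `H = 0`.
#'
#' @param er_provider Function of an attained-age vector returning a list
#'   with elements `err` and `ear` (vectors of matching length).
#' @param baseline A [baseline_rate_table()] covering `[e + l, a]` for the
#'   profile's sex.
#' @param profile An [exposure_profile()].
#' @param settings A [rads_settings()].
#' @return The dimensionless cumulative hazard `H` (non-negative; negative
#'   excess hazards are floored at 0 per age step).
#' @export
cumulative_hazard <- function(er_provider, baseline, profile,
                              settings = rads_settings()) {
  lo <- profile$age_at_exposure + settings$latency
  hi <- profile$attained_age
  if (hi <= lo) return(0)
  check_baseline_coverage(baseline, profile$sex, lo, hi)
  grid <- hazard_grid(lo, hi, settings$grid_step)
  er <- er_provider(grid)
  design <- baseline_interp_design(baseline, profile$sex, grid)
  m <- interp_rates(baseline$rate, design)
  h <- excess_hazard(er$err, er$ear, m, settings)
  sum(trapezoid_weights(grid) * pmax(h, 0))
}

#' Radiation attributed decrease of survival from a cumulative hazard
#'
#' \eqn{RADS = 1 - \exp(-H)}: the cumulative probability of a
#' radiation-attributed cancer, conditional on survival to the attained
#' age. Strictly increasing in `H`, zero iff `H = 0`, and bounded in
#' `[0, 1)`; for small hazards `RADS` is within `H^2/2` of `H` itself.
#'
#' @param H Non-negative cumulative hazard (vectorised).
#' @return RADS as a fraction in `[0, 1)`.
#' @examples
#' rads_from_hazard(0.0247)
#' @export
rads_from_hazard <- function(H) {
  if (any(H < 0)) {
    rlang::abort("Cumulative hazard must be non-negative.",
                 class = "radsmmi_domain_error")
  }
  1 - exp(-H)
}

# model-averaged (ERR, EAR) provider over an age grid
mmi_er_provider <- function(registry, weight_set, profile,
                            overrides_err = NULL, overrides_ear = NULL) {
  function(a) {
    list(
      err = averaged_excess_risk(registry, weight_set, "ERR", profile,
                                 attained_age = a, overrides = overrides_err),
      ear = averaged_excess_risk(registry, weight_set, "EAR", profile,
                                 attained_age = a, overrides = overrides_ear))
  }
}

#' RADS point estimate for one exposure profile
#'
#' Composes the model-averaged excess risks (both endpoints, per age-grid
#' point), the excess hazard, its cumulative integral and the RADS
#' transform, at the models' mean coefficient values and the unperturbed
#' baseline.
#'
#' @inheritParams averaged_excess_risk
#' @param baseline A [baseline_rate_table()].
#' @param settings A [rads_settings()].
#' @return RADS as a fraction in `[0, 1)`.
#' @export
rads_point <- function(registry, weight_set, baseline, profile,
                       settings = rads_settings()) {
  H <- cumulative_hazard(mmi_er_provider(registry, weight_set, profile),
                         baseline, profile, settings)
  rads_from_hazard(H)
}
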