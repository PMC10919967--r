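#' RADS estimate object
#'
#' Bundles a RADS point estimate, its Monte Carlo 95% percentile
#' confidence interval and (optionally) the realisation vector behind it.
#' The point is the plug-in value at mean coefficients, so it need not sit
#' at the centre of the percentile interval, but `ci_low <= ci_high`
#' always and all values lie in `[0, 1)`.
#'
#' @param point Plug-in RADS point estimate (fraction).
#' @param ci_low,ci_high 2.5th/97.5th percentile bounds (fractions).
#' @param realisations Optional numeric vector of Monte Carlo RADS
#'   realisations.
#' @param method_label Label of the producing method, e.g. `"AIC/original"`,
#'   `"single-model"` or `"m4i"`.
#' @param floor_rate Fraction of (realisation, age-step) excess-hazard
#'   evaluations floored at zero.
#' @param mc_sd Monte Carlo standard deviation of the realisations;
#'   retained even when the realisation vector itself is dropped.
#' @return An object of class `rads_estimate`.
#' @export
rads_estimate <- function(point, ci_low, ci_high, realisations = NULL,
                          method_label = "single-model", floor_rate = 0,
                          mc_sd = NULL) {
  stopifnot(ci_low <= ci_high,
            point >= 0, point < 1, ci_low >= 0, ci_high < 1)
  if (is.null(mc_sd) && !is.null(realisations)) mc_sd <- stats::sd(realisations)
  structure(
    list(point = point, ci_low = ci_low, ci_high = ci_high,
         realisations = realisations, method_label = method_label,
         floor_rate = floor_rate, mc_sd = mc_sd),
    class = "rads_estimate")
}

#' @export
print.rads_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("<rads_estimate> %s: %.*f%% (95%% CI %.*f%%; %.*f%%)\n",
              x$method_label,
              digits, 100 * x$point, digits, 100 * x$ci_low,
              digits, 100 * x$ci_high))
  if (!is.null(x$realisations)) {
    cat("  ", length(x$realisations), " Monte Carlo realisations\n", sep = "")
  }
  invisible(x)
}

#' Tidy a RADS estimate
#'
#' @param x A [rads_estimate()].
#' @param ... Unused.
#' @return One-row tibble with `method`, `point`, `ci_low`, `ci_high`
#'   (fractions).
#' @export
tidy.rads_estimate <- function(x, ...) {
  tibble::tibble(method = x$method_label, point = x$point,
                 ci_low = x$ci_low, ci_high = x$ci_high)
}

#' Glance at a RADS estimate
#'
#' @inheritParams tidy.rads_estimate
#' @return One-row tibble with realisation count, Monte Carlo standard
#'   deviation, CI width and hazard-flooring rate.
#' @export
glance.rads_estimate <- function(x, ...) {
  tibble::tibble(
    method = x$method_label,
    n_realisations = if (is.null(x$realisations)) 0L else length(x$realisations),
    mc_sd = if (is.null(x$mc_sd)) NA_real_ else x$mc_sd,
    ci_width = x$ci_high - x$ci_low,
    floor_rate = x$floor_rate)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Sample coefficient sets from a model's asymptotic normal distribution
#'
#' Draws from the multivariate normal centred at the model's fitted
#' coefficients with the model's covariance matrix — the asymptotic joint
#' distribution of the maximum-likelihood estimators. A zero covariance
#' returns the mean coefficients in every draw.
#'
#' @param model A [risk_model()].
#' @param n Number of draws.
#' @param seed Optional integer seed; omit when calling inside an already
#'   seeded stream.
#' @return An `n` x p matrix with coefficient names as columns.
#' @export
sample_coefficients <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "risk_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- MASS::mvrnorm(n, mu = model$coefficients, Sigma = model$covariance,
                         tol = 1e-8)
  if (n == 1L) draws <- matrix(draws, nrow = 1,
                               dimnames = list(NULL, names(model$coefficients)))
  draws
}

#' Poisson-resample a baseline rate table
#'
#' Each cell's expected event count `lambda = rate * person_years` is
#' replaced by a Poisson(lambda) draw divided by `person_years`,
#' emulating the sampling noise of registry incidence rates. Zero rates
#' stay exactly zero. Cells are drawn in table order: age-major, male
#' before female.
#'
#' @param baseline A [baseline_rate_table()].
#' @param person_years Person-year denominator per cell (> 0).
#' @param seed Optional integer seed.
#' @return A resampled [baseline_rate_table()].
#' @export
sample_baseline <- function(baseline, person_years = 1e5, seed = NULL) {
  stopifnot(person_years > 0)
  if (!is.null(seed)) set.seed(seed)
  lambda <- baseline$rate * person_years
  out <- baseline
  out$rate <- stats::rpois(length(lambda), lambda) / person_years
  out
}

# draw coefficient override lists for every registry row, in registry
# order; returns list(err = list(family -> list(coef -> n-vector)), ear = ...)
draw_overrides <- function(registry, n) {
  ov <- list(ERR = list(), EAR = list())
  for (i in seq_len(nrow(registry))) {
    model <- registry$model[[i]]
    draws <- sample_coefficients(model, n)
    ov[[model$endpoint]][[model$family]] <-
      purrr::map(stats::setNames(colnames(draws), colnames(draws)),
                 ~ draws[, .x])
  }
  ov
}

#' RADS with a Monte Carlo 95% confidence interval
#'
#' Computes the plug-in RADS point estimate and propagates coefficient and
#' baseline-rate uncertainty by Monte Carlo: each realisation jointly
#' resamples every model's coefficients from its asymptotic normal
#' distribution (models independently of one another; ERR and EAR
#' variants of a family independently, as no joint covariance is
#' published) and Poisson-resamples the baseline rates, then recomputes
#' RADS. The 95% CI is the 2.5th/97.5th percentile of the realisations.
#' A single pseudo-random stream is seeded from `settings$seed`, with
#' coefficients drawn first (registry order), then baseline cells
#' (age-major, male before female; realisation-major).
#'
#' Negative excess hazards from negative coefficient draws are floored at
#' zero per age step; the flooring rate is recorded on the estimate (and
#' reported when `settings$verbose`).
#'
#' @inheritParams rads_point
#' @param method_label Label stored on the returned estimate; defaults to
#'   `criterion/baseline_method` of the weight set.
#' @return A [rads_estimate()] carrying the realisation vector.
#' @export
rads_ci <- function(registry, weight_set, baseline, profile,
                    settings = rads_settings(), method_label = NULL) {
  check_registry(registry)
  if (is.null(method_label)) {
    method_label <- if (inherits(weight_set, "mmi_weight_set")) {
      paste0(attr(weight_set, "criterion"), "/", attr(weight_set, "baseline_method"))
    } else "single-model"
  }
  point <- rads_point(registry, weight_set, baseline, profile, settings)

  n <- settings$n_realisations
  lo <- profile$age_at_exposure + settings$latency
  hi <- profile$attained_age
  if (hi <= lo) {
    return(rads_estimate(0, 0, 0, realisations = rep(0, n),
                         method_label = method_label))
  }
  check_baseline_coverage(baseline, profile$sex, lo, hi)

  set.seed(settings$seed)
  ov <- draw_overrides(registry, n)
  grid <- hazard_grid(lo, hi, settings$grid_step)
  wq <- trapezoid_weights(grid)
  design <- baseline_interp_design(baseline, profile$sex, grid)

  if (settings$baseline_sampling) {
    lambda <- baseline$rate * settings$person_years
    rates <- matrix(stats::rpois(length(lambda) * n, lambda),
                    nrow = length(lambda)) / settings$person_years
  } else {
    rates <- matrix(baseline$rate, nrow = length(baseline$rate), ncol = 1)
  }

  H <- numeric(n)
  n_floored <- 0L
  for (j in seq_along(grid)) {
    err_j <- averaged_excess_risk(registry, weight_set, "ERR", profile,
                                  attained_age = grid[j], overrides = ov$ERR)
    ear_j <- averaged_excess_risk(registry, weight_set, "EAR", profile,
                                  attained_age = grid[j], overrides = ov$EAR)
    m_j <- rates[design$rows[design$lo[j]], ] * (1 - design$frac[j]) +
      rates[design$rows[design$hi[j]], ] * design$frac[j]
    h_j <- excess_hazard(err_j, ear_j, m_j, settings)
    n_floored <- n_floored + sum(h_j < 0)
    H <- H + wq[j] * pmax(h_j, 0)
  }
  floor_rate <- n_floored / (n * length(grid))
  if (settings$verbose && floor_rate > 0) {
    rlang::inform(sprintf("Floored %.2f%% of excess-hazard evaluations at 0.",
                          100 * floor_rate))
  }
  realisations <- rads_from_hazard(H)
  ci <- unname(stats::quantile(realisations, c(0.025, 0.975)))
  rads_estimate(point, ci[1], ci[2],
                realisations = if (settings$keep_realisations) realisations,
                method_label = method_label, floor_rate = floor_rate,
                mc_sd = stats::sd(realisations))
}
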