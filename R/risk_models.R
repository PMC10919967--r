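#' @importFrom rlang abort inform .data
#' @importFrom stats approx quantile rpois setNames sd
NULL

# canonical coefficient sets per model family; beta present iff *_LQ,
# nu1..nu3 present iff INWORKS_*
fam_coefs <- list(
  BEIR7      = c("alpha_male", "alpha_female", "tau", "nu"),
  GRANT_L    = c("alpha", "tau", "nu", "phi", "sigma"),
  GRANT_LQ   = c("alpha", "beta", "tau", "nu", "phi", "sigma"),
  PRESTON_L  = c("alpha", "tau", "nu", "phi", "sigma"),
  INWORKS_L  = c("alpha", "tau", "nu1", "nu2", "nu3", "sigma"),
  INWORKS_LQ = c("alpha", "beta", "tau", "nu1", "nu2", "nu3", "sigma"),
  UNSCEAR_L  = c("alpha", "sigma", "epsilon", "nu"),
  UNSCEAR_LQ = c("alpha", "beta", "sigma", "epsilon", "nu")
)

#' Model families available in the registry
#'
#' The eight all-solid-cancer excess-risk model families: BEIR VII, the
#' Grant et al. linear and linear-quadratic models, the Preston et al.
#' linear model, the INWORKS-Leuraud linear and linear-quadratic models,
#' and the UNSCEAR linear and linear-quadratic models. Each family exists
#' in an ERR (excess relative risk, dimensionless) and an EAR (excess
#' absolute risk, cases per 10,000 person-years) variant with its own
#' coefficients.
#'
#' @return Character vector of family names.
#' @export
model_families <- function() names(fam_coefs)

#' Construct a single excess-risk model specification
#'
#' Holds one model family's fitted risk coefficients and their covariance
#' matrix for one endpoint. Coefficient names must be exactly the set the
#' family uses (e.g. `beta` only for linear-quadratic families, `nu1`..`nu3`
#' only for INWORKS). The covariance matrix drives multivariate-normal
#' resampling in the Monte Carlo uncertainty propagation; a zero matrix
#' (the default) makes the model deterministic.
#'
#' @param family One of [model_families()].
#' @param endpoint `"ERR"` or `"EAR"`.
#' @param coefficients Named numeric vector with exactly the family's
#'   coefficient names.
#' @param covariance Symmetric positive semi-definite matrix over the same
#'   coefficients (row/column order taken to match the canonical order);
#'   defaults to a zero matrix.
#'
#' @return An object of class `risk_model`.
#' @examples
#' risk_model("GRANT_L", "ERR",
#'            c(alpha = 0.4, tau = -0.2, nu = -1.5, phi = 0, sigma = 0.15))
#' @export
risk_model <- function(family, endpoint, coefficients, covariance = NULL) {
  family <- match.arg(family, model_families())
  endpoint <- match.arg(endpoint, c("ERR", "EAR"))
  need <- fam_coefs[[family]]
  if (is.null(names(coefficients)) ||
      !setequal(names(coefficients), need)) {
    rlang::abort(
      paste0("`coefficients` for ", family, " must be named exactly {",
             paste(need, collapse = ", "), "}."),
      class = "radsmmi_config_error")
  }
  coefficients <- as.numeric(coefficients[need]) |> stats::setNames(need)
  p <- length(need)
  if (is.null(covariance)) covariance <- matrix(0, p, p)
  covariance <- as.matrix(covariance)
  if (!all(dim(covariance) == p)) {
    rlang::abort("`covariance` dimension does not match the coefficients.",
                 class = "radsmmi_config_error")
  }
  if (max(abs(covariance - t(covariance))) > 1e-8 * max(1, max(abs(covariance)))) {
    rlang::abort("`covariance` must be symmetric.",
                 class = "radsmmi_config_error")
  }
  if (any(diag(covariance) < 0)) {
    rlang::abort("`covariance` must have non-negative diagonal.",
                 class = "radsmmi_config_error")
  }
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(1, max(abs(ev)))) {
    rlang::abort("`covariance` is not positive semi-definite within tolerance.",
                 class = "radsmmi_config_error")
  }
  dimnames(covariance) <- list(need, need)
  structure(
    list(family = family, endpoint = endpoint,
         coefficients = coefficients, covariance = covariance),
    class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> ", x$family, " [", x$endpoint, "]\n", sep = "")
  print(x$coefficients)
  if (any(x$covariance != 0)) cat("with non-zero covariance\n")
  invisible(x)
}

#' BEIR VII age-at-exposure transform
#'
#' The BEIR VII model modifies risk by age at exposure only below 30 years:
#' the transform returns `(e - 30)/10` for `e < 30` and 0 otherwise.
#'
#' @param age_at_exposure Age at exposure in years (vectorised, positive).
#' @return Dimensionless transformed exposure age.
#' @examples
#' beir_age_transform(c(20, 30, 45)) # -1, 0, 0
#' @export
beir_age_transform <- function(age_at_exposure) {
  if (any(!is.finite(age_at_exposure)) || any(age_at_exposure <= 0)) {
    rlang::abort("`age_at_exposure` must be positive.",
                 class = "radsmmi_domain_error")
  }
  ifelse(age_at_exposure < 30, (age_at_exposure - 30) / 10, 0)
}

#' INWORKS piecewise attained-age coefficient
#'
#' The INWORKS models use a step function of attained age for the age
#' modifier: `nu1` below 60 years, `nu2` from 60 to just under 80, and
#' `nu3` from 80 upward (intervals closed on the left).
#'
#' @param attained_age Attained age in years (vectorised, positive).
#' @param nu1,nu2,nu3 Coefficients for the three age categories.
#' @return The coefficient applying at each attained age.
#' @examples
#' inworks_age_coefficient(c(59.9, 60, 80), 0.1, 0.2, 0.3)
#' @export
inworks_age_coefficient <- function(attained_age, nu1, nu2, nu3) {
  if (any(!is.finite(attained_age)) || any(attained_age <= 0)) {
    rlang::abort("`attained_age` must be positive.",
                 class = "radsmmi_domain_error")
  }
  ifelse(attained_age < 60, nu1, ifelse(attained_age < 80, nu2, nu3))
}

# Core vectorised evaluator. `cf` is a named list whose elements are numeric
# vectors of length 1 or n (n = Monte Carlo realisations); `a` may likewise
# be a vector (age grid). Standard R recycling applies, so exactly one of
# the two may have length > 1 per call.
eval_er_form <- function(family, cf, dose, e, a, s_code, kerma) {
  switch(family,
    BEIR7 = {
      alpha <- if (s_code < 0) cf$alpha_male else cf$alpha_female
      alpha * dose * exp(cf$tau * beir_age_transform(e)) * (a / 70)^cf$nu
    },
    GRANT_L = ,
    PRESTON_L = {
      mod <- exp(cf$tau * (e - 30) / 10 + cf$nu * log(a / 70) +
                   cf$phi * (kerma > 4)) * (1 + cf$sigma * s_code)
      cf$alpha * dose * mod
    },
    GRANT_LQ = {
      mod <- exp(cf$tau * (e - 30) / 10 + cf$nu * log(a / 70) +
                   cf$phi * (kerma > 4)) * (1 + cf$sigma * s_code)
      (cf$alpha * dose + cf$beta * dose^2) * mod
    },
    INWORKS_L = {
      nu_a <- inworks_age_coefficient(a, cf$nu1, cf$nu2, cf$nu3)
      cf$alpha * dose * exp(cf$tau * (e - 30) / 10 + nu_a * (a - 70) / 10) *
        (1 + cf$sigma * s_code)
    },
    INWORKS_LQ = {
      nu_a <- inworks_age_coefficient(a, cf$nu1, cf$nu2, cf$nu3)
      (cf$alpha * dose + cf$beta * dose^2) *
        exp(cf$tau * (e - 30) / 10 + nu_a * (a - 70) / 10) *
        (1 + cf$sigma * s_code)
    },
    UNSCEAR_L = ,
    UNSCEAR_LQ = {
      if (any(a - e <= 0)) {
        rlang::abort(
          "UNSCEAR models require attained age > age at exposure (log of time since exposure).",
          class = "radsmmi_domain_error")
      }
      mod <- exp(cf$sigma * s_code + cf$epsilon * log((a - e) / 40) +
                   cf$nu * log(a / 70))
      if (family == "UNSCEAR_L") cf$alpha * dose * mod
      else (cf$alpha * dose + cf$beta * dose^2) * mod
    },
    rlang::abort(paste0("Unknown model family: ", family),
                 class = "radsmmi_config_error")
  )
}

#' Evaluate a single excess-risk model
#'
#' Evaluates the model family's printed mathematical form at the covariates
#' of an exposure profile. Attained age may be a vector (for evaluation
#' along an age grid) and `coefficients` may override any subset of the
#' model's coefficients — the single entry point used by the Monte Carlo
#' resampler, which keeps evaluation pure and stateless.
#'
#' @param model A [risk_model()].
#' @param profile An [exposure_profile()].
#' @param attained_age Optional vector of attained ages overriding the
#'   profile's single value.
#' @param coefficients Optional named vector/list overriding a subset of the
#'   model's coefficients; unknown names are rejected.
#'
#' @return Numeric vector of excess risk: dimensionless for ERR, cases per
#'   10,000 person-years for EAR. Zero dose always yields zero.
#' @examples
#' m <- risk_model("GRANT_L", "ERR",
#'                 c(alpha = 0.5, tau = -0.3, nu = 0, phi = 0, sigma = 0))
#' p <- exposure_profile(1, 40, 70, "male")
#' evaluate_risk_model(m, p) # 0.5 * exp(-0.3)
#' @export
evaluate_risk_model <- function(model, profile, attained_age = NULL,
                                coefficients = NULL) {
  stopifnot(inherits(model, "risk_model"), inherits(profile, "exposure_profile"))
  cf <- as.list(model$coefficients)
  if (!is.null(coefficients)) {
    bad <- setdiff(names(coefficients), names(cf))
    if (length(bad)) {
      rlang::abort(paste0("Unknown coefficient override(s): ",
                          paste(bad, collapse = ", ")),
                   class = "radsmmi_config_error")
    }
    cf[names(coefficients)] <- coefficients
  }
  a <- if (is.null(attained_age)) profile$attained_age else attained_age
  eval_er_form(model$family, cf,
               dose = profile$dose, e = profile$age_at_exposure, a = a,
               s_code = sex_code(profile$sex), kerma = profile$shielded_kerma)
}

#' Evaluate all models of a registry at one exposure profile
#'
#' @param registry A model registry tibble (see [read_model_registry()] or
#'   [synth_model_registry()]) with columns `family`, `endpoint`, `model`.
#' @param profile An [exposure_profile()].
#' @return A tibble with one row per model and an `excess_risk` column.
#' @export
excess_risk <- function(registry, profile) {
  check_registry(registry)
  registry |>
    dplyr::mutate(excess_risk = purrr::map_dbl(
      .data$model, evaluate_risk_model, profile = profile)) |>
    dplyr::select("family", "endpoint", "excess_risk")
}

check_registry <- function(registry) {
  if (!is.data.frame(registry) ||
      !all(c("family", "endpoint", "model") %in% names(registry))) {
    rlang::abort(
      "`registry` must be a tibble with columns family, endpoint, model.",
      class = "radsmmi_config_error")
  }
  invisible(registry)
}

as_registry <- function(models) {
  tibble::tibble(
    family = purrr::map_chr(models, "family"),
    endpoint = purrr::map_chr(models, "endpoint"),
    model = models
  )
}

#' Read or write a model registry
#'
#' The registry file is YAML: one document entry per model with fields
#' `family`, `endpoint`, `coefficients` (name/value map) and `covariance`
#' (full square matrix as a list of rows, in the canonical coefficient
#' order). The round trip is lossless; unknown coefficient names are
#' rejected at read time by the [risk_model()] validator.
#'
#' @param path File path.
#' @return `read_model_registry()` returns the registry tibble;
#'   `write_model_registry()` returns `path` invisibly.
#' @export
read_model_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  models <- purrr::map(raw, function(entry) {
    risk_model(entry$family, entry$endpoint,
               unlist(entry$coefficients),
               do.call(rbind, entry$covariance))
  })
  as_registry(models)
}

#' @rdname read_model_registry
#' @param registry Registry tibble to serialise.
#' @export
write_model_registry <- function(registry, path) {
  check_registry(registry)
  out <- purrr::map(registry$model, function(m) {
    list(family = m$family, endpoint = m$endpoint,
         coefficients = as.list(m$coefficients),
         covariance = apply(m$covariance, 1, as.numeric, simplify = FALSE))
  })
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}
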