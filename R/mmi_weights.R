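#' Information-criterion model weights
#'
#' Standard Akaike-type weights from AIC or BIC values across candidate
#' models: \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_i = IC_i - \min_j IC_j}. Weights are non-negative, sum to
#' one, are invariant under adding a constant to every IC value, and
#' decrease strictly in a model's own IC value.
#'
#' @param ic Data frame with columns `family` and `ic` (finite
#'   information-criterion values), or a named numeric vector.
#' @return A tibble with columns `family` and `weight`.
#' @examples
#' ic_weights(c(m1 = 0, m2 = 2)) # 0.731, 0.269
#' @export
ic_weights <- function(ic) {
  if (is.numeric(ic)) {
    ic <- tibble::tibble(family = names(ic), ic = as.numeric(ic))
  }
  if (nrow(ic) == 0L) {
    rlang::abort("At least one model is required.",
                 class = "radsmmi_config_error")
  }
  if (any(!is.finite(ic$ic))) {
    rlang::abort("IC values must be finite.", class = "radsmmi_config_error")
  }
  delta <- ic$ic - min(ic$ic)
  w <- exp(-delta / 2)
  tibble::tibble(family = ic$family, weight = w / sum(w))
}

#' Construct an MMI weight set
#'
#' One weight set corresponds to one (criterion, baseline-method) pair and
#' carries, per endpoint, the per-family model weights used for model
#' averaging. `baseline_method` distinguishes whether the candidate models
#' were fitted with their originally published baselines ("original") or
#' refitted on a common parametric baseline ("same") — stratified baselines
#' carry many nuisance parameters, so the two choices penalise models very
#' differently in the IC weights.
#'
#' @param criterion `"AIC"` or `"BIC"`.
#' @param baseline_method `"original"` or `"same"`.
#' @param weights Data frame with columns `endpoint`, `family`, `weight`.
#'   Families absent for an endpoint carry weight 0. Per endpoint the
#'   weights must be non-negative and sum to 1 within `tol`; sums within
#'   tolerance are renormalised exactly (with a message when off by more
#'   than 1e-9).
#' @param tol Renormalisation tolerance on the per-endpoint weight sum.
#' @return A tibble of class `mmi_weight_set` with attributes `criterion`
#'   and `baseline_method`.
#' @export
mmi_weight_set <- function(criterion, baseline_method, weights, tol = 1e-6) {
  criterion <- match.arg(criterion, c("AIC", "BIC"))
  baseline_method <- match.arg(baseline_method, c("original", "same"))
  stopifnot(all(c("endpoint", "family", "weight") %in% names(weights)))
  if (any(weights$weight < 0)) {
    rlang::abort("Model weights must be non-negative.",
                 class = "radsmmi_config_error")
  }
  bad_fam <- setdiff(weights$family, model_families())
  if (length(bad_fam)) {
    rlang::abort(paste0("Unknown model families in weight set: ",
                        paste(bad_fam, collapse = ", ")),
                 class = "radsmmi_config_error")
  }
  weights <- weights |>
    dplyr::group_by(.data$endpoint) |>
    dplyr::group_modify(function(df, key) {
      s <- sum(df$weight)
      if (abs(s - 1) > tol) {
        rlang::abort(
          paste0("Weights for endpoint ", key$endpoint, " sum to ",
                 format(s), ", outside tolerance ", format(tol), "."),
          class = "radsmmi_config_error")
      }
      if (abs(s - 1) > 1e-9) {
        rlang::inform(paste0("Renormalising ", key$endpoint,
                             " weights (sum ", format(s), ")."))
      }
      df$weight <- df$weight / s
      df
    }) |>
    dplyr::ungroup()
  structure(
    tibble::as_tibble(weights[c("endpoint", "family", "weight")]),
    criterion = criterion, baseline_method = baseline_method,
    class = c("mmi_weight_set", class(tibble::tibble())))
}

#' @export
print.mmi_weight_set <- function(x, ...) {
  cat("<mmi_weight_set> ", attr(x, "criterion"), " / ",
      attr(x, "baseline_method"), " baseline\n", sep = "")
  NextMethod()
}

#' Read or write an MMI weight-set configuration
#'
#' YAML with fields `criterion`, `baseline_method` and `weights`, the
#' latter a map endpoint -> (family -> weight). The loader enforces the
#' sum-to-one invariant via [mmi_weight_set()].
#'
#' @param path File path.
#' @param tol Renormalisation tolerance passed to [mmi_weight_set()].
#' @return The weight set, or (for write) `path` invisibly.
#' @export
read_weight_set <- function(path, tol = 1e-6) {
  raw <- yaml::read_yaml(path)
  w <- purrr::imap(raw$weights, function(fams, ep) {
    tibble::tibble(endpoint = ep, family = names(fams),
                   weight = as.numeric(unlist(fams)))
  }) |> purrr::list_rbind()
  mmi_weight_set(raw$criterion, raw$baseline_method, w, tol = tol)
}

#' @rdname read_weight_set
#' @param weight_set An `mmi_weight_set`.
#' @export
write_weight_set <- function(weight_set, path) {
  w <- split(weight_set, weight_set$endpoint)
  yaml::write_yaml(
    list(criterion = attr(weight_set, "criterion"),
         baseline_method = attr(weight_set, "baseline_method"),
         weights = purrr::map(w, ~ as.list(stats::setNames(.x$weight, .x$family)))),
    path, precision = 17)
  invisible(path)
}

# weights for one endpoint joined against the registry, validating that
# every positively weighted family has a spec of the matching endpoint
endpoint_weights <- function(weight_set, endpoint, registry) {
  w <- weight_set[weight_set$endpoint == endpoint & weight_set$weight > 0, ]
  have <- registry$family[registry$endpoint == endpoint]
  missing <- setdiff(w$family, have)
  if (length(missing)) {
    rlang::abort(paste0("Weight > 0 for ", endpoint, " model(s) without a spec: ",
                        paste(missing, collapse = ", ")),
                 class = "radsmmi_config_error")
  }
  w
}

#' Model-averaged excess risk
#'
#' The multi-model-inference estimate: the weighted sum of the candidate
#' models' excess risks at a given exposure profile,
#' \eqn{\sum_i w_i \, ER_i}. Averaging happens on the excess-risk scale,
#' per evaluation point; combining across weighting methods on the RADS
#' scale is done separately by [m4i()].
#'
#' @param registry Model registry tibble.
#' @param weight_set An [mmi_weight_set()].
#' @param endpoint `"ERR"` or `"EAR"`.
#' @param profile An [exposure_profile()].
#' @param attained_age Optional attained-age vector (age grid) overriding
#'   the profile's value.
#' @param overrides Optional named list (by family) of coefficient
#'   overrides, as produced by the Monte Carlo sampler.
#' @return Numeric vector of the averaged excess risk.
#' @export
averaged_excess_risk <- function(registry, weight_set, endpoint, profile,
                                 attained_age = NULL, overrides = NULL) {
  check_registry(registry)
  endpoint <- match.arg(endpoint, c("ERR", "EAR"))
  w <- endpoint_weights(weight_set, endpoint, registry)
  a <- if (is.null(attained_age)) profile$attained_age else attained_age
  acc <- 0
  for (i in seq_len(nrow(w))) {
    fam <- w$family[i]
    model <- registry$model[[which(registry$family == fam &
                                     registry$endpoint == endpoint)[1]]]
    er <- evaluate_risk_model(model, profile, attained_age = a,
                              coefficients = overrides[[fam]])
    acc <- acc + w$weight[i] * er
  }
  acc
}
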