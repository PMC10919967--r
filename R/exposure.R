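#' Exposure profile
#'
#' Bundles the covariates at which the excess-risk models are evaluated:
#' weighted colon dose `D` (Gy), age at exposure `e` (years), attained age
#' `a` (years), sex, and total shielded kerma `K` (Gy). `K` defaults to 0,
#' which is appropriate for mission predictions: the kerma indicator in the
#' Grant/Preston model forms only activates above 4 Gy and exists to
#' down-weight high-kerma atomic-bomb survivors during fitting.
#'
#' @param dose Weighted colon dose in Gy (gamma plus RBE-weighted neutron);
#'   must be non-negative.
#' @param age_at_exposure Age at exposure in years, strictly positive and
#'   strictly below `attained_age`.
#' @param attained_age Attained age in years.
#' @param sex `"male"` or `"female"`.
#' @param shielded_kerma Total shielded kerma in Gy, non-negative.
#'
#' @return A one-row tibble of class `exposure_profile`.
#' @examples
#' exposure_profile(0.17, age_at_exposure = 40, attained_age = 65, sex = "male")
#' @export
exposure_profile <- function(dose, age_at_exposure, attained_age, sex,
                             shielded_kerma = 0) {
  sex <- match.arg(sex, c("male", "female"))
  stopifnot(is.numeric(dose), length(dose) == 1L, is.finite(dose))
  if (dose < 0) {
    rlang::abort("`dose` must be non-negative.", class = "radsmmi_domain_error")
  }
  if (!is.finite(age_at_exposure) || age_at_exposure <= 0) {
    rlang::abort("`age_at_exposure` must be a positive number of years.",
                 class = "radsmmi_domain_error")
  }
  if (!is.finite(attained_age) || attained_age <= age_at_exposure) {
    rlang::abort("`attained_age` must exceed `age_at_exposure`.",
                 class = "radsmmi_domain_error")
  }
  if (!is.finite(shielded_kerma) || shielded_kerma < 0) {
    rlang::abort("`shielded_kerma` must be non-negative.",
                 class = "radsmmi_domain_error")
  }
  out <- tibble::tibble(
    dose = as.numeric(dose),
    age_at_exposure = as.numeric(age_at_exposure),
    attained_age = as.numeric(attained_age),
    sex = sex,
    shielded_kerma = as.numeric(shielded_kerma)
  )
  class(out) <- c("exposure_profile", class(out))
  out
}

#' Weighted colon dose from gamma and neutron components
#'
#' The all-solid-cancer dose metric of the Life Span Study: gamma dose plus
#' the neutron dose weighted by a relative biological effectiveness (RBE),
#' conventionally 10 for the LSS neutron field.
#'
#' @param gamma_dose Gamma dose in Gy (non-negative; vectorised).
#' @param neutron_dose Neutron dose in Gy (non-negative; vectorised).
#' @param rbe Neutron relative biological effectiveness, positive scalar.
#'
#' @return `gamma_dose + rbe * neutron_dose`, in Gy.
#' @examples
#' weighted_dose(0.1, 0.01) # 0.2 Gy
#' @export
weighted_dose <- function(gamma_dose, neutron_dose, rbe = 10) {
  if (any(gamma_dose < 0) || any(neutron_dose < 0)) {
    rlang::abort("Dose components must be non-negative.",
                 class = "radsmmi_domain_error")
  }
  if (length(rbe) != 1L || !is.finite(rbe) || rbe <= 0) {
    rlang::abort("`rbe` must be a positive scalar.",
                 class = "radsmmi_domain_error")
  }
  gamma_dose + rbe * neutron_dose
}

# sex -> symmetric code used inside (1 + sigma*s) and exp(sigma*s) modifiers;
# -1 male / +1 female (LSS convention; BEIR VII instead uses sex-specific alphas)
sex_code <- function(sex) {
  unname(c(male = -1, female = 1)[sex])
}
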