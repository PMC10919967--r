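#' Settings for the RADS calculation
#'
#' Collects the fixed radiological-protection parameters and the numerical
#' controls of the pipeline.
#'
#' @param ddref Dose and dose-rate effectiveness factor dividing the
#'   acute-exposure excess risks for chronic/low-dose-rate application.
#'   Default 2, the conventional protection value.
#' @param latency Latency period `l` in years between exposure and the
#'   start of excess-risk accumulation in the hazard integral. Default 5
#'   years, the conventional solid-cancer choice; this value is an
#'   assumption of the method, not a fitted quantity, and materially
#'   shifts short-follow-up results — review it for any serious use.
#' @param transfer_weight_err,transfer_weight_ear Weights of the
#'   multiplicative (ERR-based) and additive (EAR-based) risk-transfer
#'   contributions to the excess hazard; 0.5/0.5 per ICRP (2007) for all
#'   solid cancer.
#' @param neutron_rbe Relative biological effectiveness applied to the
#'   neutron dose component when forming the weighted colon dose
#'   (Life Span Study convention: 10).
#' @param grid_step Age step (years) of the uniform trapezoidal
#'   integration grid. Default 1 year.
#' @param n_realisations Monte Carlo realisations for confidence
#'   intervals. Default 1000.
#' @param seed Integer seed for the single pseudo-random stream of a run.
#' @param person_years Person-year denominator per baseline table cell used
#'   in Poisson resampling of baseline rates. Default 100,000.
#' @param ddref_scope Whether DDREF divides the whole excess hazard
#'   (`"total"`, default) or only the additive EAR term (`"ear_only"`).
#'   The published formula's grouping is typographically ambiguous; the
#'   whole-sum reading is the default.
#' @param baseline_sampling Logical; Poisson-resample the baseline rates
#'   inside the Monte Carlo loop (default `TRUE`). Disable to decompose
#'   uncertainty sources.
#' @param keep_realisations Logical; store the realisation vector on the
#'   returned estimate (default `TRUE`).
#' @param verbose Logical; emit messages about hazard flooring etc.
#'
#' @return A list of class `rads_settings`.
#' @export
rads_settings <- function(ddref = 2, latency = 5,
                          transfer_weight_err = 0.5, transfer_weight_ear = 0.5,
                          neutron_rbe = 10, grid_step = 1,
                          n_realisations = 1000, seed = 1L,
                          person_years = 1e5,
                          ddref_scope = c("total", "ear_only"),
                          baseline_sampling = TRUE,
                          keep_realisations = TRUE,
                          verbose = FALSE) {
  ddref_scope <- match.arg(ddref_scope)
  stopifnot(ddref > 0, latency >= 0,
            transfer_weight_err >= 0, transfer_weight_ear >= 0,
            neutron_rbe > 0, grid_step > 0, n_realisations >= 1,
            person_years > 0)
  structure(
    list(ddref = ddref, latency = latency,
         transfer_weight_err = transfer_weight_err,
         transfer_weight_ear = transfer_weight_ear,
         neutron_rbe = neutron_rbe, grid_step = grid_step,
         n_realisations = as.integer(n_realisations),
         seed = as.integer(seed), person_years = person_years,
         ddref_scope = ddref_scope,
         baseline_sampling = isTRUE(baseline_sampling),
         keep_realisations = isTRUE(keep_realisations),
         verbose = isTRUE(verbose)),
    class = "rads_settings")
}
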