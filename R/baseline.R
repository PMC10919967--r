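#' Baseline incidence rate table
#'
#' Age- and sex-specific all-solid-cancer incidence rates of the reference
#' population, the `m(a)` entering the multiplicative (ERR) part of the
#' excess hazard. Files carry rates per 100,000 person-years; internally
#' all arithmetic uses per-person-year fractions, and the conversion
#' happens exactly once, at load. Age bands are interpreted as
#' `[start, next start)`; rates are attached to band midpoints and
#' linearly interpolated between them, held flat beyond the table edges.
#'
#' @param df Data frame with columns `age` (band start, years), `sex`
#'   (`"male"`/`"female"`) and `rate` (incidence per person-year).
#' @return A tibble of class `baseline_rate_table`.
#' @export
baseline_rate_table <- function(df) {
  stopifnot(all(c("age", "sex", "rate") %in% names(df)))
  if (!setequal(unique(df$sex), c("male", "female"))) {
    rlang::abort("Baseline table must cover both sexes.",
                 class = "radsmmi_data_error")
  }
  if (any(df$rate < 0)) {
    rlang::abort("Baseline rates must be non-negative.",
                 class = "radsmmi_data_error")
  }
  df <- df |>
    dplyr::mutate(sex = factor(.data$sex, c("male", "female"))) |>
    dplyr::arrange(.data$age, .data$sex) |>
    dplyr::mutate(sex = as.character(.data$sex))
  for (s in c("male", "female")) {
    ages <- df$age[df$sex == s]
    if (any(diff(ages) <= 0)) {
      rlang::abort(paste0("Age bands for ", s,
                          " must be strictly increasing and non-overlapping."),
                   class = "radsmmi_data_error")
    }
  }
  structure(tibble::as_tibble(df[c("age", "sex", "rate")]),
            class = c("baseline_rate_table", class(tibble::tibble())))
}

#' Read or write a baseline rate table CSV
#'
#' CSV with header `age,sex,rate_per_100000`, UTF-8, comma-separated; sex
#' coded `male`/`female`. Rates are converted to per-person-year fractions
#' on read and back to per-100,000 on write.
#'
#' @param path File path.
#' @return The [baseline_rate_table()] (read) or `path`, invisibly (write).
#' @export
read_baseline <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    age = readr::col_double(), sex = readr::col_character(),
    rate_per_100000 = readr::col_double()))
  baseline_rate_table(
    dplyr::transmute(df, age = .data$age, sex = .data$sex,
                     rate = .data$rate_per_100000 / 1e5))
}

#' @rdname read_baseline
#' @param baseline A [baseline_rate_table()].
#' @export
write_baseline <- function(baseline, path) {
  baseline |>
    dplyr::transmute(.data$age, .data$sex,
                     rate_per_100000 = .data$rate * 1e5) |>
    readr::write_csv(path)
  invisible(path)
}

# band midpoints for one sex: [start_i, start_{i+1}) midpoints, last band
# assumed as wide as its predecessor
band_midpoints <- function(ages) {
  widths <- diff(ages)
  widths <- c(widths, widths[length(widths)])
  ages + widths / 2
}

# check the table nominally spans [lo, hi] for a sex, else data error
check_baseline_coverage <- function(baseline, sex, lo, hi) {
  ages <- baseline$age[baseline$sex == sex]
  widths <- diff(ages)
  span_hi <- max(ages) + widths[length(widths)]
  if (min(ages) > lo || span_hi < hi) {
    rlang::abort(sprintf(
      "Baseline table for %s covers [%g, %g) but ages [%g, %g] are required.",
      sex, min(ages), span_hi, lo, hi), class = "radsmmi_data_error")
  }
  invisible(TRUE)
}

# linear-interpolation design for a fixed age grid: indices into the sex's
# rate vector plus fractional weights, so resampled rate vectors can be
# interpolated by indexing (vectorised across Monte Carlo realisations)
baseline_interp_design <- function(baseline, sex, grid) {
  rows <- which(baseline$sex == sex)
  mid <- band_midpoints(baseline$age[rows])
  g <- pmin(pmax(grid, mid[1]), mid[length(mid)]) # flat beyond edges
  lo <- findInterval(g, mid, rightmost.closed = TRUE)
  lo <- pmin(pmax(lo, 1L), length(mid) - 1L)
  frac <- (g - mid[lo]) / (mid[lo + 1L] - mid[lo])
  frac <- pmin(pmax(frac, 0), 1)
  list(rows = rows, lo = lo, hi = lo + 1L, frac = frac)
}

# m(a) on a grid for one sex, from (possibly resampled) per-person-year rates
interp_rates <- function(rates, design) {
  r <- rates[design$rows]
  r[design$lo] * (1 - design$frac) + r[design$hi] * design$frac
}
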