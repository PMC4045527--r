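# Dose-to-risk conversion under the linear no-threshold model, and the
# clinical "1 in N" rendering convention.
#
# The convention: the risk is rounded HALF-UP to one significant figure,
# d x 10^k with d in 1..9; the denominator N is the reciprocal rounded onto
# the one-significant-figure reciprocal grid via the mantissa map
#   d:  1    2  3    4    5  6    7    8     9
#   M: 10    5  3.3  2.5  2  1.7  1.4  1.25  1.1
# giving N = M(d) x 10^(-k-1). So 2e-3 -> "1 in 500", 8e-5 -> "1 in 12500",
# 3e-4 -> "1 in 3300": the familiar denominators of clinical risk tables,
# not generic two-significant-figure reciprocals (which would print 13000
# where the convention prints 12500).

ONE_IN_N_MANTISSA <- c(10, 5, 3.3, 2.5, 2, 1.7, 1.4, 1.25, 1.1)

ENDPOINTS <- c("childhood_cancer", "hereditary", "iq_decline",
               "severe_mental_retardation")

#' Risk coefficients for the four foetal endpoints
#'
#' Defaults are the standard prenatal-exposure coefficients: childhood
#' cancer induction 8.0e-5 per mGy, hereditary effects 0.5e-5 per mGy,
#' IQ decline 25e-3 IQ points per mGy, severe mental retardation 43e-5 per
#' mGy. All are user-overridable.
#'
#' @param childhood_cancer,hereditary,severe_mental_retardation Probability
#'   per mGy.
#' @param iq_decline IQ points lost per mGy (not a probability).
#' @return A named list of class `risk_coefficients`.
#' @export
risk_coefficients <- function(childhood_cancer = 8.0e-5,
                              hereditary = 0.5e-5,
                              iq_decline = 25e-3,
                              severe_mental_retardation = 43e-5) {
  vals <- c(childhood_cancer = childhood_cancer, hereditary = hereditary,
            iq_decline = iq_decline,
            severe_mental_retardation = severe_mental_retardation)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("risk coefficients must be non-negative", call. = FALSE)
  }
  structure(as.list(vals), class = "risk_coefficients")
}

match_endpoint <- function(endpoint) {
  aliases <- c(cancer = "childhood_cancer", smr = "severe_mental_retardation",
               iq = "iq_decline")
  endpoint <- tolower(endpoint)
  if (endpoint %in% names(aliases)) endpoint <- aliases[[endpoint]]
  if (!endpoint %in% ENDPOINTS) {
    stop("unknown endpoint '", endpoint, "'; use one of ",
         paste(ENDPOINTS, collapse = ", "), call. = FALSE)
  }
  endpoint
}

#' Stochastic risk for a foetal absorbed dose
#'
#' Linear no-threshold: `R = D_f x RC`. For `iq_decline` the return value is
#' IQ points lost, not a probability.
#'
#' @param dose_mgy Foetal absorbed dose(s), mGy.
#' @param endpoint One of `"childhood_cancer"`, `"hereditary"`,
#'   `"iq_decline"`, `"severe_mental_retardation"` (aliases `cancer`, `iq`,
#'   `smr` accepted).
#' @param coeffs A [risk_coefficients()] object.
#' @return Numeric vector of risks (probabilities, or IQ points for
#'   `iq_decline`).
#' @export
fetal_risk <- function(dose_mgy, endpoint = "childhood_cancer",
                       coeffs = risk_coefficients()) {
  if (any(dose_mgy < 0, na.rm = TRUE)) {
    stop("dose must be non-negative", call. = FALSE)
  }
  endpoint <- match_endpoint(endpoint)
  dose_mgy * coeffs[[endpoint]]
}

# half-up rounding to one significant figure; returns list(d, k) with
# value = d x 10^k, d in 1..9
round_1sf <- function(r) {
  k <- floor(log10(r))
  m <- r / 10^k
  # guard against floating-point drift in log10/division
  if (m >= 10) { m <- m / 10; k <- k + 1 }
  if (m < 1)  { m <- m * 10; k <- k - 1 }
  d <- floor(m + 0.5)
  if (d >= 10) { d <- 1L; k <- k + 1 }
  list(d = as.integer(d), k = as.integer(k))
}

#' "1 in N" denominator for a risk
#'
#' The numeric denominator underlying [format_one_in_n()]: the risk is
#' rounded half-up to one significant figure `d x 10^k` and mapped to
#' `N = M(d) x 10^(-k-1)` with the mantissa map `{10, 5, 3.3, 2.5, 2, 1.7,
#' 1.4, 1.25, 1.1}` for leading digits 1-9.
#'
#' @param risk Risk(s) in (0, 1].
#' @return Numeric denominator(s) N.
#' @export
one_in_n_denominator <- function(risk) {
  vapply(risk, function(r) {
    if (is.na(r)) return(NA_real_)
    if (r <= 0 || r > 1) stop("risk must lie in (0, 1]", call. = FALSE)
    sf <- round_1sf(r)
    round(ONE_IN_N_MANTISSA[sf$d] * 10^(-sf$k - 1))
  }, numeric(1))
}

#' Format a risk as a "1 in N" string
#'
#' @param risk Risk(s) in `[0, 1]`.
#' @param negligible_below Risks below this threshold (default 1e-9),
#'   including exactly zero, render as the sentinel
#'   `"negligible (< 1 in 1e+09)"`.
#' @return Character vector of `"1 in N"` strings.
#' @examples
#' format_one_in_n(fetal_risk(21.9, "cancer"))   # "1 in 500"
#' format_one_in_n(fetal_risk(0.001, "hereditary"))  # "1 in 200000000"
#' @export
format_one_in_n <- function(risk, negligible_below = 1e-9) {
  vapply(risk, function(r) {
    if (is.na(r)) return(NA_character_)
    if (r < 0 || r > 1) stop("risk must lie in [0, 1]", call. = FALSE)
    if (r < negligible_below) {
      return(sprintf("negligible (< 1 in %g)", 1 / negligible_below))
    }
    sprintf("1 in %.0f", one_in_n_denominator(r))
  }, character(1))
}

#' Parse a "1 in N" string back to a probability
#'
#' Convenience for round-trip checks: `"1 in 500"` -> 1/500.
#'
#' @param x Character vector of `"1 in N"` strings.
#' @return Numeric probabilities.
#' @export
parse_one_in_n <- function(x) {
  n <- suppressWarnings(as.numeric(sub("^\\s*<?\\s*1 in\\s*", "", x)))
  1 / n
}

#' Risk range string for a dose interval
#'
#' Renders the two endpoint doses as `"1 in N_lo-1 in N_hi"` (en dash), the
#' layout of clinical per-examination risk tables: the lower dose gives the
#' larger denominator and comes first.
#'
#' @param dose_lo,dose_hi Dose endpoints, mGy.
#' @param endpoint,coeffs As in [fetal_risk()].
#' @return A single formatted string.
#' @examples
#' risk_range(0.05, 3.74, "cancer")  # "1 in 250000–1 in 3300"
#' @export
risk_range <- function(dose_lo, dose_hi, endpoint = "childhood_cancer",
                       coeffs = risk_coefficients()) {
  lo <- format_one_in_n(fetal_risk(dose_lo, endpoint, coeffs))
  hi <- format_one_in_n(fetal_risk(dose_hi, endpoint, coeffs))
  if (identical(dose_lo, dose_hi)) return(lo)
  paste0(lo, "–", hi)
}

#' Full consequence report for a foetal dose
#'
#' Presents the consequence of a foetal exposure in the four conventional
#' ways: (1) risk per endpoint, (2) safety (1 - risk), (3) the equivalent
#' number of chest X-rays, and (4) the equivalent period of natural
#' background exposure; plus a deterministic-effect advisory that trips at
#' the 100 mGy threshold below which no deterministic effects of practical
#' significance are expected.
#'
#' @param dose_mgy Foetal absorbed dose, mGy (single value).
#' @param coeffs A [risk_coefficients()] object.
#' @param chest_dose_mgy Reference foetal dose per chest examination, mGy
#'   (default 0.001, the mean AP-chest foetal dose).
#' @param background_mgy_per_year Annual natural background dose, mGy/year
#'   (default 2.4).
#' @param deterministic_threshold_mgy Advisory threshold, mGy (default 100).
#' @return A `risk_report`: a tibble with one row per endpoint (`endpoint`,
#'   `coefficient`, `risk`, `risk_1sf`, `one_in_n`, `safety`) carrying the
#'   equivalence attributes (`chest_xray_equivalents`, `background_period`,
#'   `background_years`, `deterministic_advisory`, `dose_mgy`).
#' @export
consequence_report <- function(dose_mgy, coeffs = risk_coefficients(),
                               chest_dose_mgy = 0.001,
                               background_mgy_per_year = 2.4,
                               deterministic_threshold_mgy = 100) {
  if (length(dose_mgy) != 1 || !is.finite(dose_mgy) || dose_mgy < 0) {
    stop("dose_mgy must be a single non-negative number", call. = FALSE)
  }
  rows <- purrr::map(ENDPOINTS, function(ep) {
    r <- fetal_risk(dose_mgy, ep, coeffs)
    prob <- ep != "iq_decline"
    tibble::tibble(
      endpoint = ep,
      coefficient = coeffs[[ep]],
      risk = r,
      risk_1sf = if (r > 0) {
        sf <- round_1sf(r); sf$d * 10^sf$k
      } else 0,
      one_in_n = if (prob) format_one_in_n(r) else NA_character_,
      safety = if (prob) 1 - r else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  years <- dose_mgy / background_mgy_per_year
  attr(out, "dose_mgy") <- dose_mgy
  attr(out, "chest_xray_equivalents") <- dose_mgy / chest_dose_mgy
  attr(out, "background_years") <- years
  attr(out, "background_period") <- format_background_period(years)
  attr(out, "deterministic_advisory") <- dose_mgy >= deterministic_threshold_mgy
  class(out) <- c("risk_report", class(out))
  out
}

format_background_period <- function(years) {
  if (years >= 1) {
    sprintf("%.1f years", years)
  } else if (years * 365.25 >= 14) {
    sprintf("%.1f weeks", years * 365.25 / 7)
  } else {
    sprintf("%.1f days", years * 365.25)
  }
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf("<risk_report> foetal dose %.6g mGy\n", attr(x, "dose_mgy")))
  if (isTRUE(attr(x, "deterministic_advisory"))) {
    cat("  ** dose at or above the 100 mGy deterministic-effect threshold **\n")
  }
  cat(sprintf("  equivalent chest X-rays: %.3g; background period: %s\n",
              attr(x, "chest_xray_equivalents"), attr(x, "background_period")))
  NextMethod()
}

#' Tidy a risk report
#'
#' @param x A `risk_report`.
#' @param ... Unused.
#' @return The per-endpoint tibble.
#' @export
tidy.risk_report <- function(x, ...) {
  out <- x
  for (a in c("dose_mgy", "chest_xray_equivalents", "background_years",
              "background_period", "deterministic_advisory")) {
    attr(out, a) <- NULL
  }
  class(out) <- setdiff(class(out), "risk_report")
  out
}

#' Glance at a risk report
#'
#' @param x A `risk_report`.
#' @param ... Unused.
#' @return One-row tibble with the dose and the equivalence presentations.
#' @export
glance.risk_report <- function(x, ...) {
  tibble::tibble(
    dose_mgy = attr(x, "dose_mgy"),
    chest_xray_equivalents = attr(x, "chest_xray_equivalents"),
    background_years = attr(x, "background_years"),
    background_period = attr(x, "background_period"),
    deterministic_advisory = attr(x, "deterministic_advisory")
  )
}
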