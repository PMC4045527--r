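# Entrance-surface-dose reconstruction from QA tube-output calibration, and
# the exposure-record CSV schema (one row per radiograph / screening run /
# DAP entry / CT acquisition).

EXPOSURE_COLUMNS <- c(
  "patient_id", "record_type", "projection", "view", "kvp", "fsd_cm",
  "mas", "ma", "time_min", "esd_mgy", "dap_gycm2", "scanner_model",
  "ctdi_air", "pitch", "scan_start_mm", "scan_end_mm",
  "ga_weeks", "fetal_depth_cm", "maternal_ap_cm"
)
RECORD_TYPES <- c("radiograph", "screening", "dap", "ct")

#' QA tube-output calibration
#'
#' The conditions under which the X-ray tube output was measured during
#' quality assurance: `output` is the free-in-air dose per unit tube loading
#' (mGy/mAs) at `fsd_cm` and `kvp`; `output_rate` is the fluoroscopic
#' equivalent (mGy per minute per mA), measured at the same geometry.
#'
#' @param kvp Tube potential at calibration, kV.
#' @param fsd_cm Focus-to-surface distance at calibration, cm.
#' @param output Tube output, mGy per mAs (radiographic pathway).
#' @param output_rate Output rate, mGy per minute per mA (screening pathway).
#' @return A one-row tibble of class `qa_calibration`.
#' @export
qa_calibration <- function(kvp, fsd_cm, output = NA_real_, output_rate = NA_real_) {
  vals <- c(kvp = kvp, fsd_cm = fsd_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("kvp and fsd_cm must be positive", call. = FALSE)
  }
  if (!is.na(output) && output <= 0) stop("output must be positive", call. = FALSE)
  if (!is.na(output_rate) && output_rate <= 0) {
    stop("output_rate must be positive", call. = FALSE)
  }
  out <- tibble::tibble(kvp = kvp, fsd_cm = fsd_cm,
                        output = output, output_rate = output_rate)
  class(out) <- c("qa_calibration", class(out))
  out
}

# shared distance/beam-quality correction: [(FSD_QA/FSD_EX)(kVp_EX/kVp_QA)]^2
exposure_correction <- function(kvp_ex, fsd_ex, cal) {
  if (any(!is.finite(fsd_ex)) || any(fsd_ex <= 0)) {
    stop("FSD at exposure must be positive", call. = FALSE)
  }
  if (any(!is.finite(kvp_ex)) || any(kvp_ex <= 0)) {
    stop("kVp at exposure must be positive", call. = FALSE)
  }
  big_gap <- abs(kvp_ex - cal$kvp) > 30
  if (any(big_gap)) {
    warning(sprintf(
      "kVp at exposure differs from calibration by > 30 kV (%s vs %g); the quadratic output scaling is approximate over such gaps",
      paste(kvp_ex[big_gap], collapse = ", "), cal$kvp), call. = FALSE)
  }
  ((cal$fsd_cm / fsd_ex) * (kvp_ex / cal$kvp))^2
}

#' Reconstruct entrance surface dose for a radiograph
#'
#' Scales the calibrated tube output to the exposure conditions with the
#' inverse-square distance correction and the quadratic kVp correction, then
#' multiplies by the tube loading:
#' `ESD = [(FSD_QA/FSD_EX) * (kVp_EX/kVp_QA)]^2 * output * mAs`.
#' At calibration conditions this reduces to `output * mAs` exactly.
#'
#' @param cal A [qa_calibration()] with `output` set.
#' @param kvp_ex Tube potential used for the exposure, kV.
#' @param fsd_ex Focus-to-skin distance at exposure, cm.
#' @param mas Tube loading, mAs.
#' @return Free-in-air entrance surface dose, mGy. Vectorized over the
#'   exposure arguments.
#' @export
esd_radiograph <- function(cal, kvp_ex, fsd_ex, mas) {
  stopifnot(inherits(cal, "qa_calibration"))
  if (is.na(cal$output)) {
    stop("calibration has no radiographic output (mGy/mAs)", call. = FALSE)
  }
  exposure_correction(kvp_ex, fsd_ex, cal) * cal$output * mas
}

#' Reconstruct entrance surface dose for a fluoroscopic screening run
#'
#' Same distance and kVp corrections as [esd_radiograph()], with
#' `output_rate * mA * time` (minutes) replacing `output * mAs`.
#'
#' @param cal A [qa_calibration()] with `output_rate` set.
#' @param kvp_ex Tube potential during screening, kV.
#' @param fsd_ex Focus-to-skin distance, cm.
#' @param ma Tube current, mA.
#' @param time_min Screening time, minutes.
#' @return Entrance surface dose, mGy.
#' @export
esd_screening <- function(cal, kvp_ex, fsd_ex, ma, time_min) {
  stopifnot(inherits(cal, "qa_calibration"))
  if (is.na(cal$output_rate)) {
    stop("calibration has no fluoroscopic output_rate (mGy/min/mA)", call. = FALSE)
  }
  if (any(ma <= 0) || any(time_min <= 0)) {
    stop("mA and screening time must be positive", call. = FALSE)
  }
  exposure_correction(kvp_ex, fsd_ex, cal) * cal$output_rate * ma * time_min
}

#' Convert free-in-air CTDI to soft tissue
#'
#' Applies the air-to-ICRU-muscle conversion `CTDI_soft = CTDI_air * 1.07`,
#' the standard approximation for dose to soft tissue within the body.
#'
#' @param ctdi_air CTDI measured free-in-air, mGy per 100 mAs.
#' @return Soft-tissue CTDI, mGy per 100 mAs.
#' @export
ctdi_soft_tissue <- function(ctdi_air) {
  if (any(ctdi_air < 0)) stop("CTDI_air must be non-negative", call. = FALSE)
  ctdi_air * 1.07
}

#' Read an exposure-record CSV
#'
#' One row per radiograph, screening run, DAP entry or CT acquisition;
#' `record_type` is one of `radiograph`, `screening`, `dap`, `ct`. Missing
#' optional columns are added as `NA` so downstream code sees a uniform
#' schema.
#'
#' @param path CSV path.
#' @return A tibble with the full exposure-record schema.
#' @export
read_exposures <- function(path) {
  if (!file.exists(path)) stop("exposure file not found: ", path, call. = FALSE)
  recs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("patient_id", "record_type")
  miss <- setdiff(need, names(recs))
  if (length(miss)) {
    stop("exposure file missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(recs$record_type), RECORD_TYPES)
  if (length(bad)) {
    stop("unknown record_type value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(EXPOSURE_COLUMNS, names(recs))) {
    recs[[col]] <- if (col %in% c("projection", "view", "scanner_model")) {
      NA_character_
    } else {
      NA_real_
    }
  }
  recs$patient_id <- as.character(recs$patient_id)
  dplyr::select(recs, dplyr::all_of(EXPOSURE_COLUMNS),
                dplyr::everything())
}

# Which dose pathway does a record row resolve? Measured ESD wins over DAP,
# DAP over QA reconstruction; NA when nothing resolves.
resolve_pathway <- function(rec, cal = NULL) {
  type <- rec$record_type
  if (type == "ct") {
    ok <- !is.na(rec$scanner_model) && !is.na(rec$ctdi_air) && rec$ctdi_air > 0 &&
      !is.na(rec$pitch) && rec$pitch > 0 && !is.na(rec$mas) &&
      !is.na(rec$scan_start_mm) && !is.na(rec$scan_end_mm) &&
      rec$scan_start_mm < rec$scan_end_mm
    return(if (ok) "ct" else NA_character_)
  }
  if (type == "screening") {
    ok <- !is.null(cal) && !is.na(cal$output_rate) &&
      !is.na(rec$kvp) && !is.na(rec$fsd_cm) &&
      !is.na(rec$ma) && !is.na(rec$time_min) && rec$ma > 0 && rec$time_min > 0
    return(if (ok) "screening" else NA_character_)
  }
  # radiograph / dap rows
  if (!is.na(rec$esd_mgy)) {
    if (!is.null(cal) && !is.na(cal$output) &&
        !is.na(rec$kvp) && !is.na(rec$fsd_cm) && !is.na(rec$mas)) {
      message(sprintf(
        "record for '%s/%s' carries both measured ESD and QA technique data; using measured ESD",
        rec$projection %||% "?", rec$view %||% "?"))
    }
    return("esd")
  }
  if (!is.na(rec$dap_gycm2)) return("dap")
  if (!is.null(cal) && !is.na(cal$output) &&
      !is.na(rec$kvp) && !is.na(rec$fsd_cm) && !is.na(rec$mas)) {
    return("qa")
  }
  NA_character_
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
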