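# The dose engine: foetal absorbed dose per exposure record and per foetus.
#
# Radiographic series:   D_f = sum_i NUD_ESD(d) * ESD_i * SF_i
# Fluoroscopic series:   spot films as above + screening runs with
#                        ESD = output_rate * mA * time (distance/kVp corrected)
# DAP series:            D_f = sum_i DAP_i * NUD_DAP(d) * SF_i
# CT acquisition:        D_f = NUD_V * CTDI_soft * (mAs/100) / pitch
#                        (no size factor: the slab coefficients already
#                        describe uterus dose in the whole-body phantom)
#
# Doses are never rounded here; presentation rounding lives in the risk and
# cohort layers.

new_dose_result <- function(contributions, rejects = NULL) {
  out <- tibble::as_tibble(contributions)
  attr(out, "rejects") <- rejects %|||% tibble::tibble(
    patient_id = character(), record_type = character(), reason = character()
  )
  class(out) <- c("fetal_dose_result", class(out))
  out
}

`%|||%` <- function(a, b) if (is.null(a)) b else a
# distinct name: %||% in exposure.R also treats length-1 NA as empty

audit_row <- function(rec, pathway, esd_mgy = NA_real_, dap_gycm2 = NA_real_,
                      nud = NA_real_, sf = NA_real_, dose_mgy) {
  tibble::tibble(
    patient_id = as.character(rec$patient_id %||% NA_character_),
    record_type = rec$record_type,
    projection = rec$projection %||% NA_character_,
    view = rec$view %||% NA_character_,
    pathway = pathway,
    esd_mgy = esd_mgy,
    dap_gycm2 = dap_gycm2,
    nud = nud,
    sf = sf,
    dose_mgy = dose_mgy
  )
}

context_for <- function(rec, context) {
  if (!is.null(context)) return(context)
  ga <- rec$ga_weeks %||% NA_real_
  if (is.na(ga)) {
    stop("record carries no ga_weeks and no context was supplied", call. = FALSE)
  }
  patient_context(ga,
                  fetal_depth_cm = rec$fetal_depth_cm %||% NA_real_,
                  maternal_ap_cm = rec$maternal_ap_cm %||% NA_real_)
}

dose_one_record <- function(rec, store, cal, context) {
  pathway <- resolve_pathway(rec, cal)
  if (is.na(pathway)) {
    return(list(row = NULL,
                reject = tibble::tibble(
                  patient_id = as.character(rec$patient_id %||% NA_character_),
                  record_type = rec$record_type,
                  reason = "no resolvable dose pathway (missing technique, DAP, ESD or calibration data)")))
  }
  ctx <- context_for(rec, context)

  if (pathway == "ct") {
    nud_v <- slab_sum(store, rec$scanner_model, rec$scan_start_mm, rec$scan_end_mm)
    dose <- nud_v * ctdi_soft_tissue(rec$ctdi_air) * (rec$mas / 100) / rec$pitch
    return(list(row = audit_row(rec, "ct", nud = nud_v, dose_mgy = dose)))
  }

  sf <- size_factor(store, ctx$ga_weeks)
  if (pathway == "dap") {
    nud <- nud_at_depth(store, rec$projection, rec$view, ctx$fetal_depth_cm,
                        kvp = rec$kvp %||% NULL, quantity = "dap")
    dose <- rec$dap_gycm2 * nud * sf
    return(list(row = audit_row(rec, "dap", dap_gycm2 = rec$dap_gycm2,
                                nud = nud, sf = sf, dose_mgy = dose)))
  }

  esd <- switch(pathway,
    esd = rec$esd_mgy,
    qa = esd_radiograph(cal, rec$kvp, rec$fsd_cm, rec$mas),
    screening = esd_screening(cal, rec$kvp, rec$fsd_cm, rec$ma, rec$time_min)
  )
  nud <- nud_at_depth(store, rec$projection, rec$view, ctx$fetal_depth_cm,
                      kvp = rec$kvp %||% NULL, quantity = "esd")
  dose <- nud * esd * sf
  list(row = audit_row(rec, pathway, esd_mgy = esd, nud = nud, sf = sf,
                       dose_mgy = dose))
}

#' Foetal absorbed dose for a set of exposure records
#'
#' The workhorse: resolves each record's dose pathway (measured ESD, DAP,
#' QA-reconstructed ESD, screening, or CT), looks up the normalized uterus
#' dose at the patient's foetal depth and the size factor at her gestational
#' age, and returns one audit row per record with the factors used and the
#' dose contribution in mGy. Records with no resolvable pathway are skipped
#' with a warning and reported in `attr(result, "rejects")`.
#'
#' @param records Exposure-record tibble (see [read_exposures()] for the
#'   schema). Data-frame-first so calls pipe.
#' @param store A [coefficient_store()].
#' @param cal Optional [qa_calibration()], needed for the QA-reconstruction
#'   and screening pathways.
#' @param context Optional [patient_context()] applied to every record;
#'   default takes gestational age / depths from the record columns.
#' @return A `fetal_dose_result`: a tibble of per-record contributions with
#'   columns `patient_id`, `record_type`, `projection`, `view`, `pathway`,
#'   `esd_mgy`, `dap_gycm2`, `nud`, `sf`, `dose_mgy`.
#' @examples
#' store <- simulate_coefficient_tables(seed = 1)
#' recs <- tibble::tibble(
#'   patient_id = "p1", record_type = "dap", projection = "abdomen",
#'   view = "AP", kvp = 75, dap_gycm2 = 2.0, ga_weeks = 20,
#'   fetal_depth_cm = NA, maternal_ap_cm = NA
#' )
#' fetal_dose(recs, store)
#' @export
fetal_dose <- function(records, store, cal = NULL, context = NULL) {
  stopifnot(inherits(store, "coefficient_store"))
  records <- normalize_records(tibble::as_tibble(records))
  if (!nrow(records)) return(new_dose_result(empty_contributions()))
  pieces <- purrr::map(seq_len(nrow(records)), function(i) {
    dose_one_record(as.list(records[i, ]), store, cal, context)
  })
  rows <- dplyr::bind_rows(purrr::map(pieces, "row"))
  rejects <- dplyr::bind_rows(purrr::map(pieces, "reject"))
  if (nrow(rejects)) {
    warning(sprintf("%d record(s) skipped: no resolvable dose pathway",
                    nrow(rejects)), call. = FALSE)
  }
  if (!nrow(rows)) rows <- empty_contributions()
  new_dose_result(rows, rejects)
}

# fill any missing schema columns with NA so per-record dispatch can rely on
# a uniform shape
normalize_records <- function(records) {
  if (!"record_type" %in% names(records)) {
    stop("records must have a 'record_type' column", call. = FALSE)
  }
  bad <- setdiff(unique(records$record_type), RECORD_TYPES)
  if (length(bad)) {
    stop("unknown record_type value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(EXPOSURE_COLUMNS, names(records))) {
    records[[col]] <- if (col %in% c("patient_id", "projection", "view",
                                     "scanner_model")) {
      NA_character_
    } else {
      NA_real_
    }
  }
  records$patient_id <- as.character(records$patient_id)
  records
}

empty_contributions <- function() {
  tibble::tibble(
    patient_id = character(), record_type = character(),
    projection = character(), view = character(), pathway = character(),
    esd_mgy = double(), dap_gycm2 = double(), nud = double(),
    sf = double(), dose_mgy = double()
  )
}

#' @describeIn fetal_dose Dose from a radiographic series only (records must
#'   be radiograph/DAP-free rows using the ESD or QA pathway).
#' @export
dose_radiographic <- function(records, store, cal = NULL, context = NULL) {
  records <- dplyr::filter(tibble::as_tibble(records),
                           .data$record_type == "radiograph")
  fetal_dose(records, store, cal = cal, context = context)
}

#' Dose from a complete fluoroscopic examination
#'
#' Sums the contributions of the spot films (radiograph records) and the
#' screening runs; with an empty screening list this reduces exactly to the
#' radiographic series dose.
#'
#' @param spots Radiograph records (spot films).
#' @param screenings Screening records.
#' @inheritParams fetal_dose
#' @return A `fetal_dose_result` over both parts.
#' @export
dose_fluoroscopic <- function(spots, screenings, store, cal = NULL, context = NULL) {
  both <- dplyr::bind_rows(tibble::as_tibble(spots), tibble::as_tibble(screenings))
  fetal_dose(both, store, cal = cal, context = context)
}

#' @describeIn fetal_dose Dose from dose-area-product records only.
#' @export
dose_dap <- function(records, store, context = NULL) {
  records <- tibble::as_tibble(records)
  records <- dplyr::filter(records, !is.na(.data$dap_gycm2))
  records$record_type <- "dap"
  fetal_dose(records, store, context = context)
}

#' @describeIn fetal_dose Dose from CT acquisitions only.
#' @export
dose_ct <- function(records, store, context = NULL) {
  records <- dplyr::filter(tibble::as_tibble(records), .data$record_type == "ct")
  fetal_dose(records, store, context = context)
}

#' Total dose per foetus
#'
#' Arithmetic sum of per-record contributions grouped by `patient_id`,
#' covering multiple and repeat examinations of the same patient.
#'
#' @param result A `fetal_dose_result` (or any tibble with `patient_id` and
#'   `dose_mgy`).
#' @return Tibble with one row per foetus: `patient_id`, `n_records`,
#'   `dose_mgy`.
#' @export
total_per_foetus <- function(result) {
  tibble::as_tibble(result) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_records = dplyr::n(),
                     dose_mgy = sum(.data$dose_mgy), .groups = "drop")
}

#' @export
print.fetal_dose_result <- function(x, ...) {
  cat(sprintf("<fetal_dose_result> %d contribution(s), total %.6g mGy\n",
              nrow(x), sum(x$dose_mgy)))
  rej <- attr(x, "rejects")
  if (!is.null(rej) && nrow(rej)) {
    cat(sprintf("  (%d record(s) rejected; see attr(, \"rejects\"))\n", nrow(rej)))
  }
  NextMethod()
}

#' Tidy a foetal dose result
#'
#' @param x A `fetal_dose_result`.
#' @param ... Unused.
#' @return The per-record audit tibble.
#' @export
tidy.fetal_dose_result <- function(x, ...) {
  out <- x
  attr(out, "rejects") <- NULL
  class(out) <- setdiff(class(out), "fetal_dose_result")
  out
}

#' Glance at a foetal dose result
#'
#' @param x A `fetal_dose_result`.
#' @param ... Unused.
#' @return One-row tibble: total dose (mGy), number of contributions and of
#'   rejected records, number of distinct foetuses.
#' @export
glance.fetal_dose_result <- function(x, ...) {
  tibble::tibble(
    total_dose_mgy = sum(x$dose_mgy),
    n_records = nrow(x),
    n_rejected = nrow(attr(x, "rejects") %|||% tibble::tibble()),
    n_foetuses = dplyr::n_distinct(x$patient_id)
  )
}
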