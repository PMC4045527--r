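# Cohort batch layer: per-foetus totals over an exposure CSV, dose-interval
# and gestational-age histograms, per-projection summary tables, risk-band
# tables, and a deterministic synthetic-cohort generator.

DOSE_BIN_EDGES <- c(0, 0.1, 1, 10, 50)
DOSE_BIN_LABELS <- c("<0.1", "0.1–<1", "1–<10", "10–<50")
OVERFLOW_LABEL <- "≥50"

# half-open [lo, hi) binning; doses >= 50 go to an overflow bin
dose_bin <- function(dose) {
  lab <- character(length(dose))
  for (i in seq_along(DOSE_BIN_LABELS)) {
    lab[dose >= DOSE_BIN_EDGES[i] & dose < DOSE_BIN_EDGES[i + 1]] <- DOSE_BIN_LABELS[i]
  }
  lab[dose >= DOSE_BIN_EDGES[length(DOSE_BIN_EDGES)]] <- OVERFLOW_LABEL
  factor(lab, levels = c(DOSE_BIN_LABELS, OVERFLOW_LABEL))
}

#' Summarize foetal doses over a cohort of exposure records
#'
#' Computes one dose total per `patient_id` through the dose engine, then
#' the study-style products: a dose-interval histogram on the half-open
#' bins `[0, 0.1) / [0.1, 1) / [1, 10) / [10, 50)` mGy (doses of 50 mGy or
#' more land in an overflow bin with a warning), a gestational-age
#' histogram, and per-projection dose range/mean tables aggregated per
#' examination. Records with no resolvable dose pathway are skipped, logged
#' and counted in the rejects table.
#'
#' @param records Exposure-record tibble or CSV path (see
#'   [read_exposures()]).
#' @param store A [coefficient_store()].
#' @param cal Optional [qa_calibration()] for QA/screening pathways.
#' @param ga_break_weeks Bin width of the gestational-age histogram, weeks.
#' @return A `cohort_summary`: list with `per_foetus`, `dose_histogram`,
#'   `ga_histogram`, `per_projection`, `rejects`, `n_foetuses`.
#' @export
summarize_cohort <- function(records, store, cal = NULL, ga_break_weeks = 4) {
  if (is.character(records)) records <- read_exposures(records)
  result <- fetal_dose(records, store, cal = cal)
  per_foetus <- total_per_foetus(result)

  if (nrow(per_foetus)) {
    per_foetus$dose_bin <- dose_bin(per_foetus$dose_mgy)
    if (any(per_foetus$dose_bin == OVERFLOW_LABEL)) {
      warning("cohort contains foetal doses >= 50 mGy (overflow bin)", call. = FALSE)
    }
  } else {
    per_foetus$dose_bin <- factor(character(), levels = c(DOSE_BIN_LABELS, OVERFLOW_LABEL))
  }

  dose_histogram <- per_foetus |>
    dplyr::count(.data$dose_bin, .drop = FALSE, name = "n_foetuses") |>
    dplyr::rename(bin = "dose_bin") |>
    dplyr::mutate(
      lo_mgy = c(DOSE_BIN_EDGES[-length(DOSE_BIN_EDGES)], DOSE_BIN_EDGES[length(DOSE_BIN_EDGES)]),
      hi_mgy = c(DOSE_BIN_EDGES[-1], Inf)
    )

  ga <- records |>
    tibble::as_tibble() |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE) |>
    dplyr::filter(!is.na(.data$ga_weeks))
  ga_histogram <- if (nrow(ga)) {
    breaks <- seq(0, ceiling(max(ga$ga_weeks) / ga_break_weeks) * ga_break_weeks,
                  by = ga_break_weeks)
    ga |>
      dplyr::mutate(ga_interval = cut(.data$ga_weeks, breaks = breaks,
                                      right = FALSE, include.lowest = FALSE)) |>
      dplyr::count(.data$ga_interval, .drop = FALSE, name = "n_foetuses")
  } else {
    tibble::tibble(ga_interval = factor(), n_foetuses = integer())
  }

  with_proj <- result |>
    tibble::as_tibble() |>
    dplyr::filter(!is.na(.data$projection))
  per_projection <- if (!nrow(with_proj)) {
    tibble::tibble(
      projection = character(), view = character(), n = integer(),
      esd_min = double(), esd_max = double(), esd_mean = double(),
      dose_min = double(), dose_max = double(), dose_mean = double()
    )
  } else {
    with_proj |>
    dplyr::group_by(.data$projection, .data$view) |>
    dplyr::summarise(
      n = dplyr::n(),
      esd_min = min(.data$esd_mgy, na.rm = TRUE) |> suppressWarnings(),
      esd_max = max(.data$esd_mgy, na.rm = TRUE) |> suppressWarnings(),
      esd_mean = mean(.data$esd_mgy, na.rm = TRUE),
      dose_min = min(.data$dose_mgy),
      dose_max = max(.data$dose_mgy),
      dose_mean = mean(.data$dose_mgy),
      .groups = "drop"
    ) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ replace(.x, is.infinite(.x), NA_real_)))
  }

  structure(
    list(
      per_foetus = per_foetus,
      dose_histogram = dose_histogram,
      ga_histogram = ga_histogram,
      per_projection = per_projection,
      rejects = attr(result, "rejects"),
      n_foetuses = nrow(per_foetus)
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d foetus(es)\n", x$n_foetuses))
  if (x$n_foetuses) {
    sub1 <- sum(x$dose_histogram$n_foetuses[x$dose_histogram$hi_mgy <= 1])
    over10 <- sum(x$dose_histogram$n_foetuses[x$dose_histogram$lo_mgy >= 10])
    cat(sprintf("  %d%% received < 1 mGy; %d%% received >= 10 mGy\n",
                round(100 * sub1 / x$n_foetuses),
                round(100 * over10 / x$n_foetuses)))
  }
  if (nrow(x$rejects)) cat(sprintf("  %d record(s) rejected\n", nrow(x$rejects)))
  print(x$dose_histogram)
  invisible(x)
}

#' Tidy a cohort summary
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return The per-foetus tibble (`patient_id`, `n_records`, `dose_mgy`,
#'   `dose_bin`).
#' @export
tidy.cohort_summary <- function(x, ...) x$per_foetus

#' Glance at a cohort summary
#'
#' Headline shares are reported as integer percentages of the cohort, the
#' way survey results are quoted ("78% received less than 1 mGy").
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return One-row tibble: cohort size, share below 1 mGy (%), share at or
#'   above 10 mGy (%), rejected record count.
#' @export
glance.cohort_summary <- function(x, ...) {
  n <- x$n_foetuses
  sub1 <- sum(x$dose_histogram$n_foetuses[x$dose_histogram$hi_mgy <= 1])
  over10 <- sum(x$dose_histogram$n_foetuses[x$dose_histogram$lo_mgy >= 10])
  tibble::tibble(
    n_foetuses = n,
    pct_below_1_mgy = if (n) round(100 * sub1 / n) else NA_real_,
    pct_at_least_10_mgy = if (n) round(100 * over10 / n) else NA_real_,
    n_rejected = nrow(x$rejects)
  )
}

#' Risk-band table for cohort dose bins
#'
#' For each dose bin `[lo, hi)` renders the childhood-cancer and hereditary
#' risk bands from the bin edges: the lowest bin as `"<1 in N(hi)"`, the
#' others as `"1 in N(lo)-<1 in N(hi)"` (the upper edge is excluded from the
#' bin, so its risk is a strict bound).
#'
#' @param summary A `cohort_summary`, or `NULL` to tabulate the canonical
#'   bins without counts.
#' @param coeffs A [risk_coefficients()] object.
#' @return Tibble with `bin`, `n_foetuses` (NA without a summary),
#'   `childhood_cancer`, `hereditary`.
#' @export
risk_band_table <- function(summary = NULL, coeffs = risk_coefficients()) {
  hist <- if (!is.null(summary)) {
    stopifnot(inherits(summary, "cohort_summary"))
    dplyr::filter(summary$dose_histogram, is.finite(.data$hi_mgy))
  } else {
    tibble::tibble(
      bin = factor(DOSE_BIN_LABELS, levels = DOSE_BIN_LABELS),
      n_foetuses = NA_integer_,
      lo_mgy = DOSE_BIN_EDGES[-length(DOSE_BIN_EDGES)],
      hi_mgy = DOSE_BIN_EDGES[-1]
    )
  }
  band <- function(lo, hi, endpoint) {
    hi_str <- paste0("<", format_one_in_n(fetal_risk(hi, endpoint, coeffs)))
    if (lo <= 0) return(hi_str)
    paste0(format_one_in_n(fetal_risk(lo, endpoint, coeffs)), "–", hi_str)
  }
  hist |>
    dplyr::rowwise() |>
    dplyr::mutate(
      childhood_cancer = band(.data$lo_mgy, .data$hi_mgy, "childhood_cancer"),
      hereditary = band(.data$lo_mgy, .data$hi_mgy, "hereditary")
    ) |>
    dplyr::ungroup() |>
    dplyr::select("bin", "n_foetuses", "childhood_cancer", "hereditary")
}

#' Simulate a synthetic exposure cohort
#'
#' Deterministic under `seed`. Emulates the structure of a multinational
#' foetal-dose referral cohort: gestational ages 2-38 weeks, foetal depths
#' 4.9-9.3 cm, maternal AP thicknesses 16.5-31.0 cm; a mix of plain
#' radiographs (measured-ESD, DAP and QA-reconstruction pathways),
#' fluoroscopic examinations with spot films plus screening runs, and CT
#' acquisitions; a minority of patients have multiple (2-4) or repeat (2-3)
#' examinations. Projections and scanner models are drawn from `store` so
#' every generated row resolves a dose pathway end to end.
#'
#' @param seed Integer seed.
#' @param n_patients Number of pregnant patients (one foetus each).
#' @param store A [coefficient_store()] supplying projection and scanner
#'   keys.
#' @param cal The [qa_calibration()] the QA/screening rows are generated
#'   against (pass the same one to [summarize_cohort()]).
#' @param p_multiple Probability a patient has a multi-examination workup.
#' @param p_ct Probability an examination is a CT acquisition.
#' @return An exposure-record tibble in the [read_exposures()] schema.
#' @export
simulate_cohort <- function(seed, n_patients, store,
                            cal = qa_calibration(80, 100, output = 0.05, output_rate = 10),
                            p_multiple = 0.25, p_ct = 0.12) {
  stopifnot(inherits(store, "coefficient_store"), n_patients >= 0)
  set.seed(as.integer(seed))
  if (!n_patients) return(read_exposures_schema_empty())

  projections <- dplyr::distinct(store$nud_esd, .data$projection, .data$view)
  scanners <- unique(store$ct_slab$scanner_model)

  one_patient <- function(i) {
    id <- sprintf("p%04d", i)
    ga <- stats::runif(1, 2, 38)
    depth <- stats::runif(1, 4.9, 9.3)
    ap <- stats::runif(1, max(16.5, depth + 2), 31.0)
    n_exams <- if (stats::runif(1) < p_multiple) sample(2:4, 1) else 1L
    exams <- purrr::map(seq_len(n_exams), function(e) {
      n_repeat <- if (stats::runif(1) < 0.1) sample(2:3, 1) else 1L
      kind <- if (stats::runif(1) < p_ct) "ct" else
        sample(c("radiograph_qa", "radiograph_esd", "dap", "fluoro"), 1,
               prob = c(0.4, 0.25, 0.25, 0.1))
      base <- tibble::tibble(
        patient_id = id, ga_weeks = ga,
        fetal_depth_cm = depth, maternal_ap_cm = ap
      )
      rows <- if (kind == "ct") {
        start <- stats::runif(1, 150, 280)
        tibble::tibble(
          base,
          record_type = "ct",
          scanner_model = sample(scanners, 1),
          kvp = 120,
          ctdi_air = stats::runif(1, 5, 25),
          mas = stats::runif(1, 100, 300),
          pitch = stats::runif(1, 1, 1.5),
          scan_start_mm = start,
          scan_end_mm = start + stats::runif(1, 100, 400)
        )
      } else {
        pr <- projections[sample(nrow(projections), 1), ]
        kvp <- stats::runif(1, 60, 110)
        common <- tibble::tibble(
          base, projection = pr$projection, view = pr$view, kvp = kvp
        )
        switch(kind,
          radiograph_qa = tibble::tibble(
            common, record_type = "radiograph",
            fsd_cm = stats::runif(1, 80, 110),
            mas = stats::runif(1, 5, 80)
          ),
          radiograph_esd = tibble::tibble(
            common, record_type = "radiograph",
            esd_mgy = stats::rlnorm(1, log(1.5), 0.9)
          ),
          dap = tibble::tibble(
            common, record_type = "dap",
            dap_gycm2 = stats::rlnorm(1, log(2), 0.8)
          ),
          fluoro = dplyr::bind_rows(
            tibble::tibble(
              common, record_type = "radiograph",
              fsd_cm = stats::runif(1, 80, 110),
              mas = stats::runif(1, 5, 40)
            ),
            tibble::tibble(
              common, record_type = "screening",
              fsd_cm = stats::runif(1, 80, 110),
              ma = stats::runif(1, 1, 4),
              time_min = stats::runif(1, 0.5, 5)
            )
          )
        )
      }
      dplyr::bind_rows(replicate(n_repeat, rows, simplify = FALSE))
    })
    dplyr::bind_rows(exams)
  }

  out <- dplyr::bind_rows(purrr::map(seq_len(n_patients), one_patient))
  for (col in setdiff(EXPOSURE_COLUMNS, names(out))) out[[col]] <- NA_real_
  dplyr::select(out, dplyr::all_of(EXPOSURE_COLUMNS))
}

read_exposures_schema_empty <- function() {
  out <- tibble::tibble(patient_id = character(), record_type = character())
  for (col in setdiff(EXPOSURE_COLUMNS, names(out))) {
    out[[col]] <- if (col %in% c("projection", "view", "scanner_model")) {
      character()
    } else {
      double()
    }
  }
  dplyr::select(out, dplyr::all_of(EXPOSURE_COLUMNS))
}

#' Plot a cohort summary
#'
#' @param object A `cohort_summary`.
#' @param type `"dose"` for the dose-interval histogram, `"ga"` for the
#'   gestational-age histogram.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_summary <- function(object, type = c("dose", "ga"), ...) {
  type <- match.arg(type)
  if (type == "dose") {
    ggplot2::ggplot(object$dose_histogram,
                    ggplot2::aes(x = .data$bin, y = .data$n_foetuses)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "Foetal absorbed dose interval (mGy)",
                    y = "Number of foetuses") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$ga_histogram,
                    ggplot2::aes(x = .data$ga_interval, y = .data$n_foetuses)) +
      ggplot2::geom_col(fill = "darkseagreen4") +
      ggplot2::labs(x = "Gestational age interval (weeks)",
                    y = "Number of foetuses") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  }
}

#' @rdname autoplot.cohort_summary
#' @param x A `cohort_summary`.
#' @param y Unused.
#' @export
plot.cohort_summary <- function(x, y, ...) print(autoplot.cohort_summary(x, ...))
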