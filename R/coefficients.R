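# Coefficient tables: normalized uterus dose (NUD) per unit entrance surface
# dose or per unit dose-area product, per-slab CT tables, and foetal size
# factors. One CSV dialect holds all four table types, keyed by `table_type`.

N_SLABS <- 208L
SLAB_WIDTH_MM <- 5
PHANTOM_LENGTH_MM <- N_SLABS * SLAB_WIDTH_MM

#' Bundle validated coefficient tables into a store
#'
#' A coefficient store holds the four lookup tables the dose engine needs:
#' radiographic NUD (mGy uterus dose per mGy free-in-air entrance surface
#' dose), DAP-normalized NUD (mGy per Gy cm^2), per-slab CT NUD profiles
#' (one value per contiguous 5 mm slab of the 208-slab reference phantom,
#' per mGy soft-tissue CTDI per 100 mAs), and foetal size factors (uterus to
#' foetus dose conversion, by gestational age).
#'
#' @param nud_esd Tibble with columns `projection`, `view`, `kvp_min`,
#'   `kvp_max`, `depth_cm`, `nud`.
#' @param nud_dap Tibble with the same columns as `nud_esd`; `nud` is in
#'   mGy per Gy cm^2.
#' @param ct_slab Tibble with columns `scanner_model`, `slab_index` (0-207),
#'   `nud`.
#' @param size_factor Tibble with columns `ga_weeks`, `sf`. May be `NULL`,
#'   in which case a size factor of 1 is used everywhere (with a warning at
#'   lookup time).
#' @return An object of class `coefficient_store`.
#' @seealso [read_coefficients()], [simulate_coefficient_tables()]
#' @export
coefficient_store <- function(nud_esd = NULL, nud_dap = NULL, ct_slab = NULL,
                              size_factor = NULL) {
  store <- structure(
    list(
      nud_esd = if (!is.null(nud_esd)) tibble::as_tibble(nud_esd),
      nud_dap = if (!is.null(nud_dap)) tibble::as_tibble(nud_dap),
      ct_slab = if (!is.null(ct_slab)) tibble::as_tibble(ct_slab),
      size_factor = if (!is.null(size_factor)) tibble::as_tibble(size_factor)
    ),
    class = "coefficient_store"
  )
  validate_coefficient_store(store)
  store
}

#' @export
print.coefficient_store <- function(x, ...) {
  cat("<coefficient_store>\n")
  n_proj <- function(tbl) {
    if (is.null(tbl)) 0L else nrow(dplyr::distinct(tbl, .data$projection, .data$view))
  }
  cat("  nud_esd:     ", n_proj(x$nud_esd), "projection/view table(s)\n")
  cat("  nud_dap:     ", n_proj(x$nud_dap), "projection/view table(s)\n")
  cat("  ct_slab:     ",
      if (is.null(x$ct_slab)) 0L else dplyr::n_distinct(x$ct_slab$scanner_model),
      "scanner model(s)\n")
  cat("  size_factor: ",
      if (is.null(x$size_factor)) "absent (SF = 1 fallback)"
      else paste0(nrow(x$size_factor), " gestational ages"), "\n")
  invisible(x)
}

validate_coefficient_store <- function(store) {
  for (kind in c("nud_esd", "nud_dap")) {
    tbl <- store[[kind]]
    if (is.null(tbl)) next
    need <- c("projection", "view", "kvp_min", "kvp_max", "depth_cm", "nud")
    miss <- setdiff(need, names(tbl))
    if (length(miss)) {
      stop(sprintf("%s table is missing required column(s): %s",
                   kind, paste(miss, collapse = ", ")), call. = FALSE)
    }
    if (any(tbl$nud <= 0)) {
      bad <- which(tbl$nud <= 0)[1]
      stop(sprintf("%s table: NUD must be strictly positive (row %d)", kind, bad),
           call. = FALSE)
    }
    check <- tbl |>
      dplyr::group_by(.data$projection, .data$view, .data$kvp_min, .data$kvp_max) |>
      dplyr::summarise(
        depth_increasing = !is.unsorted(.data$depth_cm, strictly = TRUE),
        nud_nonincreasing = all(diff(.data$nud) <= 0),
        .groups = "drop"
      )
    bad_depth <- dplyr::filter(check, !.data$depth_increasing)
    if (nrow(bad_depth)) {
      stop(sprintf("%s table: depth grid not strictly increasing for projection '%s/%s'",
                   kind, bad_depth$projection[1], bad_depth$view[1]), call. = FALSE)
    }
    bad_mono <- dplyr::filter(check, !.data$nud_nonincreasing)
    if (nrow(bad_mono)) {
      stop(sprintf("%s table: NUD must be non-increasing with foetal depth for projection '%s/%s'",
                   kind, bad_mono$projection[1], bad_mono$view[1]), call. = FALSE)
    }
  }

  tbl <- store$ct_slab
  if (!is.null(tbl)) {
    need <- c("scanner_model", "slab_index", "nud")
    miss <- setdiff(need, names(tbl))
    if (length(miss)) {
      stop(sprintf("ct_slab table is missing required column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    counts <- dplyr::count(tbl, .data$scanner_model)
    bad <- dplyr::filter(counts, .data$n != N_SLABS)
    if (nrow(bad)) {
      stop(sprintf("ct_slab table for scanner '%s': expected %d slabs, got %d",
                   bad$scanner_model[1], N_SLABS, bad$n[1]), call. = FALSE)
    }
    by_scanner <- split(tbl, tbl$scanner_model)
    for (sc in names(by_scanner)) {
      s <- by_scanner[[sc]][order(by_scanner[[sc]]$slab_index), ]
      if (!identical(as.integer(s$slab_index), 0:(N_SLABS - 1L))) {
        stop(sprintf("ct_slab table for scanner '%s': slab_index must cover 0..%d exactly",
                     sc, N_SLABS - 1L), call. = FALSE)
      }
      if (any(s$nud < 0)) {
        stop(sprintf("ct_slab table for scanner '%s': negative NUD entries", sc),
             call. = FALSE)
      }
      # profile shape is a fixture-generator guarantee; real scatter can break
      # strict unimodality, so this is advisory only
      if (!is_unimodal_or_flat(s$nud)) {
        warning(sprintf("ct_slab profile for scanner '%s' is not unimodal; check the table",
                        sc), call. = FALSE)
      }
    }
  }

  tbl <- store$size_factor
  if (!is.null(tbl)) {
    miss <- setdiff(c("ga_weeks", "sf"), names(tbl))
    if (length(miss)) {
      stop(sprintf("size_factor table is missing required column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    if (is.unsorted(tbl$ga_weeks, strictly = TRUE)) {
      stop("size_factor table: gestational ages must be strictly increasing",
           call. = FALSE)
    }
    if (any(tbl$sf <= 0)) stop("size_factor table: SF must be positive", call. = FALSE)
  }
  invisible(store)
}

is_unimodal_or_flat <- function(x, tol = 1e-12) {
  d <- diff(x)
  sign_changes <- rle(sign(d[abs(d) > tol]))
  up_down <- sign_changes$values
  length(up_down) <= 1 ||
    (length(up_down) == 2 && up_down[1] == 1 && up_down[2] == -1)
}

#' Read a coefficient file into a store
#'
#' The file is UTF-8 CSV with a `table_type` column taking values `nud_esd`,
#' `nud_dap`, `ct_slab` or `size_factor`; the remaining columns depend on the
#' section (see [coefficient_store()]). Validation failures name the
#' offending table and projection.
#'
#' @param path Path to the coefficient CSV.
#' @return A `coefficient_store`.
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) stop("coefficient file not found: ", path, call. = FALSE)
  # base parser: strtod is correctly rounded, so write -> read -> lookup
  # round-trips coefficient values bit-identically
  raw <- tibble::as_tibble(utils::read.csv(path, na.strings = ""))
  if (!"table_type" %in% names(raw)) {
    stop("coefficient file must have a 'table_type' column", call. = FALSE)
  }
  known <- c("nud_esd", "nud_dap", "ct_slab", "size_factor")
  unknown <- setdiff(unique(raw$table_type), known)
  if (length(unknown)) {
    stop("unknown table_type value(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  section <- function(type, cols) {
    part <- dplyr::filter(raw, .data$table_type == type)
    if (!nrow(part)) return(NULL)
    miss <- setdiff(cols, names(part))
    if (length(miss)) {
      stop(sprintf("%s section missing required column(s): %s",
                   type, paste(miss, collapse = ", ")), call. = FALSE)
    }
    dplyr::select(part, dplyr::all_of(cols))
  }
  coefficient_store(
    nud_esd = section("nud_esd",
                      c("projection", "view", "kvp_min", "kvp_max", "depth_cm", "nud")),
    nud_dap = section("nud_dap",
                      c("projection", "view", "kvp_min", "kvp_max", "depth_cm", "nud")),
    ct_slab = section("ct_slab", c("scanner_model", "slab_index", "nud")),
    size_factor = section("size_factor", c("ga_weeks", "sf"))
  )
}

#' Write a coefficient store (or coefficient tibble) to the CSV dialect
#'
#' Output is deterministic: the same store always yields a byte-identical
#' file.
#'
#' @param store A `coefficient_store`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(store, path) {
  stopifnot(inherits(store, "coefficient_store"))
  pieces <- list()
  for (kind in c("nud_esd", "nud_dap")) {
    tbl <- store[[kind]]
    if (is.null(tbl)) next
    pieces[[kind]] <- tibble::tibble(
      table_type = kind,
      projection = tbl$projection, view = tbl$view,
      kvp_min = tbl$kvp_min, kvp_max = tbl$kvp_max,
      depth_cm = tbl$depth_cm, nud = tbl$nud,
      scanner_model = NA_character_, slab_index = NA_integer_,
      ga_weeks = NA_real_, sf = NA_real_
    )
  }
  if (!is.null(store$ct_slab)) {
    tbl <- store$ct_slab
    pieces$ct_slab <- tibble::tibble(
      table_type = "ct_slab",
      projection = NA_character_, view = NA_character_,
      kvp_min = NA_real_, kvp_max = NA_real_,
      depth_cm = NA_real_, nud = tbl$nud,
      scanner_model = tbl$scanner_model, slab_index = as.integer(tbl$slab_index),
      ga_weeks = NA_real_, sf = NA_real_
    )
  }
  if (!is.null(store$size_factor)) {
    tbl <- store$size_factor
    pieces$size_factor <- tibble::tibble(
      table_type = "size_factor",
      projection = NA_character_, view = NA_character_,
      kvp_min = NA_real_, kvp_max = NA_real_,
      depth_cm = NA_real_, nud = NA_real_,
      scanner_model = NA_character_, slab_index = NA_integer_,
      ga_weeks = tbl$ga_weeks, sf = tbl$sf
    )
  }
  out <- dplyr::bind_rows(pieces)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

# Select the table whose kVp band contains kvp; ties toward the lower band.
select_band <- function(tbl, projection, view, kvp, kind) {
  cand <- dplyr::filter(tbl, .data$projection == !!projection, .data$view == !!view)
  if (!nrow(cand)) {
    stop(sprintf("no %s table for projection '%s/%s'", kind, projection, view),
         call. = FALSE)
  }
  if (!is.null(kvp) && !is.na(kvp)) {
    hit <- dplyr::filter(cand, .data$kvp_min <= !!kvp, !!kvp <= .data$kvp_max)
    if (nrow(hit)) {
      lo <- min(hit$kvp_min)
      return(dplyr::filter(hit, .data$kvp_min == lo))
    }
    # fall back to the nearest band rather than refusing the record
    bands <- dplyr::distinct(cand, .data$kvp_min, .data$kvp_max)
    mid <- (bands$kvp_min + bands$kvp_max) / 2
    pick <- bands[which.min(abs(mid - kvp)), ]
    warning(sprintf("kVp %.0f outside all bands for '%s/%s'; using band [%g, %g]",
                    kvp, projection, view, pick$kvp_min, pick$kvp_max),
            call. = FALSE)
    return(dplyr::filter(cand, .data$kvp_min == pick$kvp_min,
                         .data$kvp_max == pick$kvp_max))
  }
  lo <- min(cand$kvp_min)
  dplyr::filter(cand, .data$kvp_min == lo)
}

interp_clamped <- function(grid_x, grid_y, x, what) {
  if (!length(grid_x)) stop("empty ", what, " table", call. = FALSE)
  if (length(grid_x) == 1) return(rep(grid_y, length(x)))
  out_of_range <- x < min(grid_x) | x > max(grid_x)
  if (any(out_of_range)) {
    warning(sprintf("%s %s outside table grid [%g, %g]; clamped to nearest endpoint",
                    what, paste(signif(x[out_of_range], 4), collapse = ", "),
                    min(grid_x), max(grid_x)), call. = FALSE)
  }
  stats::approx(grid_x, grid_y, xout = x, method = "linear", rule = 2)$y
}

#' Normalized uterus dose at a foetal depth
#'
#' Piecewise-linear interpolation on the depth grid of the matching
#' projection/view table; exact at grid points, clamped (with a warning)
#' outside the grid. The beam-quality band is chosen as the kVp band
#' containing `kvp`, ties broken toward the lower band.
#'
#' @param store A `coefficient_store`.
#' @param projection,view Projection key, e.g. `"abdomen"`, `"AP"`.
#' @param depth_cm Foetal depth(s) in cm.
#' @param kvp Tube potential of the exposure, used for band selection; `NULL`
#'   selects the lowest band.
#' @param quantity `"esd"` for NUD per mGy entrance surface dose, `"dap"` for
#'   NUD per Gy cm^2 of dose-area product.
#' @return Numeric vector of NUD values, one per `depth_cm`.
#' @export
nud_at_depth <- function(store, projection, view, depth_cm, kvp = NULL,
                         quantity = c("esd", "dap")) {
  stopifnot(inherits(store, "coefficient_store"))
  quantity <- match.arg(quantity)
  kind <- paste0("nud_", quantity)
  tbl <- store[[kind]]
  if (is.null(tbl)) stop("store has no ", kind, " table", call. = FALSE)
  band <- select_band(tbl, projection, view, kvp, kind)
  band <- band[order(band$depth_cm), ]
  interp_clamped(band$depth_cm, band$nud, depth_cm, "foetal depth")
}

#' Sum of per-slab normalized doses over a CT scan volume
#'
#' A slab belongs to the scan volume iff its midpoint lies in the half-open
#' interval `[scan_start_mm, scan_end_mm)`. This makes the sum additive over
#' abutting ranges. Slab `i` spans `[5i, 5(i+1))` mm from the phantom origin
#' (slab 0's lower edge, increasing toward the head); the phantom is
#' 208 x 5 mm = 1040 mm long.
#'
#' @param store A `coefficient_store`.
#' @param scanner_model Scanner model key; must match a table exactly.
#' @param scan_start_mm,scan_end_mm Scan range in the phantom frame, mm.
#' @return The summed normalized uterus dose `NUD_V` (per mGy soft-tissue
#'   CTDI per 100 mAs).
#' @export
slab_sum <- function(store, scanner_model, scan_start_mm, scan_end_mm) {
  stopifnot(inherits(store, "coefficient_store"))
  if (is.null(store$ct_slab)) stop("store has no ct_slab table", call. = FALSE)
  if (scan_start_mm >= scan_end_mm) {
    stop("scan_start_mm must be < scan_end_mm", call. = FALSE)
  }
  if (scan_start_mm < 0 || scan_end_mm > PHANTOM_LENGTH_MM) {
    stop(sprintf("scan range must lie within [0, %d] mm", PHANTOM_LENGTH_MM),
         call. = FALSE)
  }
  tbl <- dplyr::filter(store$ct_slab, .data$scanner_model == !!scanner_model)
  if (!nrow(tbl)) {
    stop(sprintf("no ct_slab table for scanner model '%s'", scanner_model),
         call. = FALSE)
  }
  tbl <- tbl[order(tbl$slab_index), ]
  mid <- (tbl$slab_index + 0.5) * SLAB_WIDTH_MM
  inside <- mid >= scan_start_mm & mid < scan_end_mm
  if (!any(inside)) {
    warning("scan range contains no slab midpoints; NUD_V = 0", call. = FALSE)
    return(0)
  }
  sum(tbl$nud[inside])
}

#' Foetal size factor at a gestational age
#'
#' Uterus-to-foetus dose conversion factor, linearly interpolated on the
#' gestational-age grid and clamped (with a warning) outside it. When the
#' store carries no size-factor table, 1.0 is returned with a warning.
#'
#' @param store A `coefficient_store`.
#' @param ga_weeks Gestational age(s), weeks.
#' @return Numeric vector of size factors.
#' @export
size_factor <- function(store, ga_weeks) {
  stopifnot(inherits(store, "coefficient_store"))
  tbl <- store$size_factor
  if (is.null(tbl)) {
    warning("no size_factor table in store; using SF = 1", call. = FALSE)
    return(rep(1, length(ga_weeks)))
  }
  interp_clamped(tbl$ga_weeks, tbl$sf, ga_weeks, "gestational age")
}

#' Patient context for a foetal dose estimate
#'
#' Gestational age is required; foetal depth and maternal AP thickness
#' default to the population means used in clinical practice when the
#' measurements are not available: 9 cm and 25 cm respectively.
#'
#' @param ga_weeks Gestational age, weeks, in (0, 45].
#' @param fetal_depth_cm Foetal depth, cm; defaults to 9 when `NULL`/`NA`.
#' @param maternal_ap_cm Maternal anteroposterior thickness, cm; defaults to
#'   25 when `NULL`/`NA`.
#' @return A one-row tibble of class `patient_context`.
#' @export
patient_context <- function(ga_weeks, fetal_depth_cm = NULL, maternal_ap_cm = NULL) {
  if (!is.numeric(ga_weeks) || length(ga_weeks) != 1 ||
      is.na(ga_weeks) || ga_weeks <= 0 || ga_weeks > 45) {
    stop("ga_weeks must be a single number in (0, 45]", call. = FALSE)
  }
  if (is.null(maternal_ap_cm) || is.na(maternal_ap_cm)) maternal_ap_cm <- 25
  if (is.null(fetal_depth_cm) || is.na(fetal_depth_cm)) fetal_depth_cm <- 9
  if (fetal_depth_cm <= 0 || fetal_depth_cm >= maternal_ap_cm) {
    stop("fetal_depth_cm must lie in (0, maternal_ap_cm)", call. = FALSE)
  }
  out <- tibble::tibble(
    ga_weeks = ga_weeks,
    fetal_depth_cm = fetal_depth_cm,
    maternal_ap_cm = maternal_ap_cm
  )
  class(out) <- c("patient_context", class(out))
  out
}
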