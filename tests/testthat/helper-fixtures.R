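# Shared fixtures, all built in code.

fixture_store <- function(seed = 42, ...) {
  simulate_coefficient_tables(seed, ...)
}

fixture_cal <- function() {
  qa_calibration(kvp = 80, fsd_cm = 100, output = 0.05, output_rate = 10)
}

# Hand-sized store with known values, for exact-arithmetic dose checks.
# abdomen/AP: NUD(5) = 0.2, NUD(9) = 0.1, NUD(13) = 0.05 per mGy ESD;
# DAP-normalized NUD(9) = 0.5 mGy per Gy.cm2; SF = 1 at every age.
manual_store <- function() {
  nud_esd <- tibble::tibble(
    projection = "abdomen", view = "AP", kvp_min = 50, kvp_max = 120,
    depth_cm = c(5, 9, 13), nud = c(0.2, 0.1, 0.05)
  )
  nud_dap <- tibble::tibble(
    projection = "abdomen", view = "AP", kvp_min = 50, kvp_max = 120,
    depth_cm = c(5, 9, 13), nud = c(1.0, 0.5, 0.25)
  )
  # flat-topped profile: slabs 40-49 carry 0.05 each (sum 0.5), rest zero
  ct <- tibble::tibble(
    scanner_model = "ct_unit", slab_index = 0:207,
    nud = ifelse(0:207 %in% 40:49, 0.05, 0)
  )
  sf <- tibble::tibble(ga_weeks = c(2, 20, 40), sf = c(1, 1, 1))
  coefficient_store(nud_esd = nud_esd, nud_dap = nud_dap,
                    ct_slab = ct, size_factor = sf)
}

# One ESD-pathway record row; dose = nud * esd * sf with the manual store.
esd_record <- function(patient_id = "p1", esd_mgy = 2.0, ga_weeks = 20,
                       fetal_depth_cm = 9, projection = "abdomen", view = "AP") {
  tibble::tibble(
    patient_id = patient_id, record_type = "radiograph",
    projection = projection, view = view, kvp = 80,
    esd_mgy = esd_mgy, ga_weeks = ga_weeks,
    fetal_depth_cm = fetal_depth_cm, maternal_ap_cm = 25
  )
}

# Independent piecewise-linear oracle (no stats::approx): clamp, bracket,
# interpolate by hand.
polyline_oracle <- function(grid_x, grid_y, x) {
  vapply(x, function(xi) {
    if (xi <= grid_x[1]) return(grid_y[1])
    n <- length(grid_x)
    if (xi >= grid_x[n]) return(grid_y[n])
    i <- max(which(grid_x <= xi))
    if (grid_x[i] == xi) return(grid_y[i])
    grid_y[i] + (grid_y[i + 1] - grid_y[i]) * (xi - grid_x[i]) /
      (grid_x[i + 1] - grid_x[i])
  }, numeric(1))
}

# Brute-force slab-sum oracle: explicit loop over all 208 midpoints.
slab_sum_oracle <- function(slab_tbl, start, end) {
  total <- 0
  for (i in 0:207) {
    mid <- (i + 0.5) * 5
    if (mid >= start && mid < end) {
      total <- total + slab_tbl$nud[slab_tbl$slab_index == i]
    }
  }
  total
}
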