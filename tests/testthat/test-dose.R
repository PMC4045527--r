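test_that("a single radiographic record gives NUD * ESD * SF", {
  store <- manual_store()
  # NUD 0.1 at depth 9, ESD 2.0 mGy, SF 1.0 -> 0.2 mGy
  res <- fetal_dose(esd_record(esd_mgy = 2.0), store)
  expect_equal(res$dose_mgy, 0.2)
  expect_equal(res$nud, 0.1)
  expect_equal(res$sf, 1.0)
  expect_equal(res$pathway, "esd")
  expect_equal(glance(res)$total_dose_mgy, 0.2)
})

test_that("duplicating a record doubles the total (linearity of the sum)", {
  store <- manual_store()
  one <- fetal_dose(esd_record(), store)
  two <- fetal_dose(dplyr::bind_rows(esd_record(), esd_record()), store)
  expect_equal(glance(two)$total_dose_mgy, 2 * glance(one)$total_dose_mgy)
})

test_that("a radiographic series matches term-by-term oracle summation", {
  store <- fixture_store(seed = 31)
  cal <- fixture_cal()
  set.seed(505)
  recs <- tibble::tibble(
    patient_id = "p1", record_type = "radiograph",
    projection = "abdomen", view = "AP",
    kvp = runif(5, 60, 100), fsd_cm = runif(5, 80, 120),
    mas = runif(5, 5, 60),
    ga_weeks = 18, fetal_depth_cm = 7.5, maternal_ap_cm = 24
  )
  res <- fetal_dose(recs, store, cal = cal)
  oracle <- 0
  for (i in 1:5) {
    esd_i <- ((100 / recs$fsd_cm[i]) * (recs$kvp[i] / 80))^2 * 0.05 * recs$mas[i]
    nud_i <- nud_at_depth(store, "abdomen", "AP", 7.5, kvp = recs$kvp[i])
    sf_i <- size_factor(store, 18)
    oracle <- oracle + nud_i * esd_i * sf_i
  }
  expect_equal(glance(res)$total_dose_mgy, oracle, tolerance = 1e-12)
})

test_that("the total equals the sum of contributions and all contributions are non-negative", {
  store <- fixture_store(seed = 32)
  recs <- simulate_cohort(8, 30, store)
  res <- suppressWarnings(fetal_dose(recs, store, cal = fixture_cal()))
  expect_equal(glance(res)$total_dose_mgy, sum(res$dose_mgy), tolerance = 1e-9)
  expect_true(all(res$dose_mgy >= 0))
})

test_that("fluoroscopic dose sums spot films and screening runs, degenerating correctly", {
  store <- manual_store()
  cal <- fixture_cal()
  spots <- esd_record(esd_mgy = 1.5)
  screenings <- tibble::tibble(
    patient_id = "p1", record_type = "screening",
    projection = "abdomen", view = "AP",
    kvp = 80, fsd_cm = 100, ma = 2, time_min = 1.5,
    ga_weeks = 20, fetal_depth_cm = 9, maternal_ap_cm = 25
  )
  # empty screening list reduces to the radiographic dose
  fl_spots_only <- dose_fluoroscopic(spots, screenings[0, ], store, cal = cal)
  expect_equal(glance(fl_spots_only)$total_dose_mgy,
               glance(fetal_dose(spots, store, cal = cal))$total_dose_mgy)
  # empty spot list is the pure screening sum: ESD 30 mGy * NUD 0.1 * SF 1
  fl_screen_only <- dose_fluoroscopic(spots[0, ], screenings, store, cal = cal)
  expect_equal(glance(fl_screen_only)$total_dose_mgy, 3.0)
  # mixed series adds the two parts
  fl <- dose_fluoroscopic(spots, screenings, store, cal = cal)
  expect_equal(glance(fl)$total_dose_mgy,
               glance(fl_spots_only)$total_dose_mgy + 3.0)
})

test_that("DAP dose is DAP * NUD_DAP * SF with a zero-DAP record contributing zero", {
  store <- manual_store()
  rec <- tibble::tibble(
    patient_id = "p1", record_type = "dap", projection = "abdomen", view = "AP",
    kvp = 80, dap_gycm2 = 2.0, ga_weeks = 20, fetal_depth_cm = 9,
    maternal_ap_cm = 25
  )
  # DAP 2.0 Gy.cm2 * NUD_DAP 0.5 * SF 1 -> 1.0 mGy
  expect_equal(fetal_dose(rec, store)$dose_mgy, 1.0)
  rec$dap_gycm2 <- 0
  expect_equal(fetal_dose(rec, store)$dose_mgy, 0)
})

test_that("CT dose follows NUD_V * CTDI_soft * (mAs/100) / pitch", {
  store <- manual_store()  # slabs 40-49 at 0.05 each: NUD_V = 0.5 over [200, 250)
  ct <- tibble::tibble(
    patient_id = "p1", record_type = "ct", scanner_model = "ct_unit",
    ctdi_air = 10, mas = 200, pitch = 1,
    scan_start_mm = 200, scan_end_mm = 250, ga_weeks = 20
  )
  res <- fetal_dose(ct, store)
  # 0.5 * 10.7 * 2.0 / 1 = 10.7 mGy
  expect_equal(res$dose_mgy, 10.7)
  expect_equal(res$nud, 0.5)
  # pitch 2 halves the dose
  ct$pitch <- 2
  expect_equal(fetal_dose(ct, store)$dose_mgy, 5.35)
  # a scan range with no slab midpoints gives 0 with a warning
  ct$pitch <- 1
  ct$scan_start_mm <- 600.5
  ct$scan_end_mm <- 602
  expect_warning(res0 <- fetal_dose(ct, store), "no slab midpoints")
  expect_equal(res0$dose_mgy, 0)
})

test_that("dose scales linearly in mAs, DAP and screening time", {
  store <- fixture_store(seed = 33)
  cal <- fixture_cal()
  base <- tibble::tibble(
    patient_id = "p1", record_type = "radiograph", projection = "pelvis",
    view = "AP", kvp = 75, fsd_cm = 95, mas = 10,
    ga_weeks = 22, fetal_depth_cm = 8, maternal_ap_cm = 26
  )
  for (k in c(0.5, 2, 7)) {
    scaled <- base
    scaled$mas <- base$mas * k
    expect_equal(glance(fetal_dose(scaled, store, cal = cal))$total_dose_mgy,
                 k * glance(fetal_dose(base, store, cal = cal))$total_dose_mgy,
                 tolerance = 1e-12)
  }
})

test_that("increasing foetal depth never increases the dose", {
  store <- fixture_store(seed = 34)
  depths <- seq(4.9, 9.3, by = 0.4)
  doses <- vapply(depths, function(d) {
    rec <- esd_record(fetal_depth_cm = d)
    glance(fetal_dose(rec, store))$total_dose_mgy
  }, numeric(1))
  expect_true(all(diff(doses) <= 1e-12))
})

test_that("measured ESD wins over the QA pathway, with a log message", {
  store <- manual_store()
  rec <- esd_record(esd_mgy = 2.0)
  rec$fsd_cm <- 100
  rec$mas <- 1000  # QA pathway would give a much larger ESD
  expect_message(res <- fetal_dose(rec, store, cal = fixture_cal()),
                 "measured ESD")
  expect_equal(res$dose_mgy, 0.2)
  expect_equal(res$pathway, "esd")
})

test_that("unknown projection keys and scanner models are named in lookup errors", {
  store <- manual_store()
  rec <- esd_record(projection = "skull", view = "LAT")
  expect_error(fetal_dose(rec, store), "skull/LAT")
  ct <- tibble::tibble(
    patient_id = "p1", record_type = "ct", scanner_model = "mystery",
    ctdi_air = 10, mas = 100, pitch = 1, scan_start_mm = 100,
    scan_end_mm = 300, ga_weeks = 20
  )
  expect_error(fetal_dose(ct, store), "mystery")
})

test_that("records with no resolvable pathway are skipped and reported", {
  store <- manual_store()
  recs <- dplyr::bind_rows(
    esd_record(),
    tibble::tibble(patient_id = "p2", record_type = "radiograph",
                   projection = "abdomen", view = "AP", ga_weeks = 20)
  )
  expect_warning(res <- fetal_dose(recs, store), "skipped")
  expect_equal(nrow(res), 1)
  rejects <- attr(res, "rejects")
  expect_equal(rejects$patient_id, "p2")
  expect_match(rejects$reason, "pathway")
})

test_that("per-foetus totals sum per patient and are permutation invariant", {
  store <- fixture_store(seed = 35)
  recs <- simulate_cohort(12, 25, store)
  res <- suppressWarnings(fetal_dose(recs, store, cal = fixture_cal()))
  totals <- total_per_foetus(res)
  # oracle: explicit per-patient accumulation
  oracle <- tapply(res$dose_mgy, res$patient_id, sum)
  expect_equal(totals$dose_mgy, as.numeric(oracle[totals$patient_id]))
  shuffled <- res[sample(nrow(res)), ]
  totals2 <- total_per_foetus(shuffled)
  expect_equal(dplyr::arrange(totals, .data$patient_id),
               dplyr::arrange(totals2, .data$patient_id))
  # single-exam identity
  one <- total_per_foetus(fetal_dose(esd_record(), manual_store()))
  expect_equal(one$dose_mgy, 0.2)
})
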