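test_that("a well-formed fixture file round-trips through load with every table type", {
  store <- fixture_store()
  path <- withr::local_tempfile(fileext = ".csv")
  write_coefficients(store, path)
  loaded <- read_coefficients(path)
  expect_s3_class(loaded, "coefficient_store")
  for (kind in c("nud_esd", "nud_dap", "ct_slab", "size_factor")) {
    expect_gt(nrow(loaded[[kind]]), 0)
  }
  # write -> read -> lookup is bit-identical
  expect_identical(
    nud_at_depth(loaded, "abdomen", "AP", 7.31, kvp = 75),
    nud_at_depth(store, "abdomen", "AP", 7.31, kvp = 75)
  )
  expect_identical(size_factor(loaded, 17.2), size_factor(store, 17.2))
  expect_identical(slab_sum(loaded, "scanner_01", 123, 654),
                   slab_sum(store, "scanner_01", 123, 654))
})

test_that("validation rejects non-monotone depth grids, naming the projection", {
  bad <- tibble::tibble(
    projection = "abdomen", view = "AP", kvp_min = 50, kvp_max = 120,
    depth_cm = c(9, 7, 8), nud = c(0.1, 0.2, 0.15)
  )
  expect_error(coefficient_store(nud_esd = bad), "abdomen/AP")
  expect_error(coefficient_store(nud_esd = bad), "strictly increasing")
})

test_that("validation rejects NUD that increases with depth or is non-positive", {
  increasing <- tibble::tibble(
    projection = "pelvis", view = "AP", kvp_min = 50, kvp_max = 120,
    depth_cm = c(5, 9), nud = c(0.1, 0.2)
  )
  expect_error(coefficient_store(nud_esd = increasing), "non-increasing")
  nonpos <- tibble::tibble(
    projection = "pelvis", view = "AP", kvp_min = 50, kvp_max = 120,
    depth_cm = c(5, 9), nud = c(0.2, 0)
  )
  expect_error(coefficient_store(nud_esd = nonpos), "positive")
})

test_that("a CT table must have exactly 208 slabs", {
  short <- tibble::tibble(scanner_model = "s", slab_index = 0:206,
                          nud = rep(0.01, 207))
  expect_error(coefficient_store(ct_slab = short), "expected 208 slabs")
  long <- tibble::tibble(scanner_model = "s", slab_index = 0:208,
                         nud = rep(0.01, 209))
  expect_error(coefficient_store(ct_slab = long), "expected 208 slabs")
})

test_that("missing required columns raise a schema error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("table_type,projection,depth_cm,nud",
               "nud_esd,abdomen,5,0.2"), path)
  expect_error(read_coefficients(path), "missing required column")
})

test_that("depth interpolation is exact at grid points and linear between them", {
  store <- manual_store()
  expect_equal(nud_at_depth(store, "abdomen", "AP", 9, kvp = 80), 0.1)
  expect_equal(nud_at_depth(store, "abdomen", "AP", 5, kvp = 80), 0.2)
  # midway between values 0.2 and 0.1 -> 0.15
  expect_equal(nud_at_depth(store, "abdomen", "AP", 7, kvp = 80), 0.15)
})

test_that("interpolation agrees with an independent polyline oracle and never overshoots", {
  store <- fixture_store(seed = 11)
  band <- store$nud_esd[store$nud_esd$projection == "abdomen" &
                          store$nud_esd$view == "AP" &
                          store$nud_esd$kvp_min == 70, ]
  band <- band[order(band$depth_cm), ]
  set.seed(202)
  depths <- runif(100, min(band$depth_cm), max(band$depth_cm))
  got <- nud_at_depth(store, "abdomen", "AP", depths, kvp = 75)
  want <- polyline_oracle(band$depth_cm, band$nud, depths)
  expect_equal(got, want, tolerance = 1e-12)
  # bounded by neighbouring grid values (no overshoot)
  expect_true(all(got <= max(band$nud) & got >= min(band$nud)))
})

test_that("lookups outside the grid clamp to the nearest endpoint with a warning", {
  store <- manual_store()
  expect_warning(lo <- nud_at_depth(store, "abdomen", "AP", 1, kvp = 80), "clamped")
  expect_equal(lo, 0.2)
  expect_warning(hi <- nud_at_depth(store, "abdomen", "AP", 30, kvp = 80), "clamped")
  expect_equal(hi, 0.05)
  expect_warning(sf0 <- size_factor(store, 0.5), "clamped")
  expect_equal(sf0, 1)
})

test_that("size factor interpolates on the gestational-age grid and defaults to 1 without a table", {
  store <- fixture_store(seed = 9)
  tbl <- store$size_factor
  expect_equal(size_factor(store, tbl$ga_weeks[3]), tbl$sf[3])
  set.seed(303)
  ages <- runif(50, min(tbl$ga_weeks), max(tbl$ga_weeks))
  expect_equal(size_factor(store, ages),
               polyline_oracle(tbl$ga_weeks, tbl$sf, ages), tolerance = 1e-12)
  no_sf <- coefficient_store(nud_esd = store$nud_esd)
  expect_warning(sf <- size_factor(no_sf, 20), "SF = 1")
  expect_equal(sf, 1)
})

test_that("slab_sum matches a brute-force midpoint scan and is additive", {
  store <- fixture_store(seed = 13)
  slabs <- store$ct_slab[store$ct_slab$scanner_model == "scanner_01", ]
  # full phantom = sum of all 208 entries
  expect_equal(slab_sum(store, "scanner_01", 0, 1040), sum(slabs$nud))
  # a range covering exactly one midpoint returns that slab's value
  expect_equal(slab_sum(store, "scanner_01", 301, 304),
               slabs$nud[slabs$slab_index == 60])
  set.seed(404)
  for (i in 1:25) {
    ab <- sort(runif(2, 0, 1040))
    expect_equal(slab_sum(store, "scanner_01", ab[1], ab[2]),
                 slab_sum_oracle(slabs, ab[1], ab[2]))
  }
  # additivity over a midpoint-aligned split
  for (i in 1:10) {
    pts <- sort(c(runif(2, 0, 1040), sample(0:207, 1) * 5))
    expect_equal(
      slab_sum(store, "scanner_01", pts[1], pts[2]) +
        slab_sum(store, "scanner_01", pts[2], pts[3]),
      slab_sum(store, "scanner_01", pts[1], pts[3])
    )
  }
})

test_that("slab_sum rejects inverted or out-of-phantom ranges", {
  store <- manual_store()
  expect_error(slab_sum(store, "ct_unit", 500, 100), "scan_start")
  expect_error(slab_sum(store, "ct_unit", -10, 100), "within")
  expect_error(slab_sum(store, "ct_unit", 900, 1100), "within")
  expect_error(slab_sum(store, "unknown", 100, 200), "unknown")
})

test_that("beam-quality band selection contains the exposure kVp with ties to the lower band", {
  store <- fixture_store(seed = 21)
  tbl <- store$nud_esd
  band_of <- function(kvp) {
    hit <- nud_at_depth(store, "abdomen", "AP", 9, kvp = kvp)
    sub <- tbl[tbl$projection == "abdomen" & tbl$view == "AP", ]
    sub$kvp_min[sapply(seq_len(nrow(sub)), function(i) {
      band <- sub[sub$kvp_min == sub$kvp_min[i], ]
      isTRUE(all.equal(polyline_oracle(band$depth_cm[order(band$depth_cm)],
                                       band$nud[order(band$depth_cm)], 9), hit))
    })][1]
  }
  expect_equal(band_of(60), 50)
  expect_equal(band_of(75), 70)
  expect_equal(band_of(70), 50)   # shared edge resolves to the lower band
  expect_equal(band_of(110), 90)
})

test_that("patient context applies the documented defaults and bounds", {
  ctx <- patient_context(20)
  expect_equal(ctx$fetal_depth_cm, 9)
  expect_equal(ctx$maternal_ap_cm, 25)
  ctx2 <- patient_context(12, fetal_depth_cm = 6.5, maternal_ap_cm = 22)
  expect_equal(ctx2$fetal_depth_cm, 6.5)
  expect_error(patient_context(0), "ga_weeks")
  expect_error(patient_context(46), "ga_weeks")
  expect_error(patient_context(20, fetal_depth_cm = 26, maternal_ap_cm = 25),
               "fetal_depth_cm")
})
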