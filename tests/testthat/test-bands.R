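test_that("allometric band construction reproduces the published ABC/3TC table", {
  tab <- build_allometric_bands(abc_model(), abc3tc_formulary())
  expect_s3_class(tab, "weight_band_table")
  expect_equal(tab$upper_kg, c(8.2, 14.1, 20.6, 27.8, 35.4, Inf))
  expect_equal(tab$lower_kg, c(0, 8.3, 14.2, 20.7, 27.9, 35.5))
  expect_equal(tab$dose_mg, c(120, 180, 240, 300, 360, 600))
  expect_equal(tab$label, c("1", "1.5", "2", "2.5", "3", "adult"))
  # field-for-field against the packaged reference fixture
  ref <- allometric_reference_table()
  expect_equal(as.data.frame(tab), as.data.frame(ref))
  expect_identical(attr(tab, "resolution_kg"), attr(ref, "resolution_kg"))
})

test_that("band construction handles small formularies and other exponents", {
  # two steps: single finite edge at 70*(1/2)^(4/3), frozen from
  # arbitrary-precision evaluation
  f2 <- formulary(c(300, 600), c("half", "adult"), unit_strength_mg = 120)
  tab <- build_allometric_bands(abc_model(), f2)
  expect_equal(tab$upper_kg[1], 27.8)
  expect_equal(weight_for_dose(abc_model(), 300), 27.77951840944349,
               tolerance = 1e-12)
  expect_equal(tab$lower_kg, c(0, 27.9))
  # linear scaling: half dose at half the reference weight
  tab1 <- build_allometric_bands(scaling_model(600, 70, 1), f2)
  expect_equal(tab1$upper_kg[1], 35.0)
  expect_error(build_allometric_bands(abc_model(),
                                      formulary(600, "adult")),
               "at least two steps")
})

test_that("WHO chart lookup returns the published tablet counts", {
  who <- who_band_table()
  hit <- lookup_dose(who, c(5, 8, 12, 17, 22, 25, 30))
  expect_equal(hit$label, c("1", "1.5", "2", "2.5", "3", "adult", "adult"))
  expect_equal(hit$dose_mg, c(120, 180, 240, 300, 360, 600, 600))
  expect_false(any(hit$below_minimum))
})

test_that("lookup quantises weights to the table resolution before banding", {
  tab <- build_allometric_bands(abc_model(), abc3tc_formulary())
  # upper edges are inclusive
  expect_equal(lookup_dose(tab, 8.2)$dose_mg, 120)
  expect_equal(lookup_dose(tab, 35.4)$dose_mg, 360)
  expect_equal(lookup_dose(tab, 35.5)$dose_mg, 600)
  # recorded half-way weights round up into the next band
  expect_equal(lookup_dose(tab, 14.15)$dose_mg, 240)
  expect_equal(lookup_dose(tab, 14.14)$dose_mg, 180)
  # below the WHO chart minimum: first band with a flag
  who <- who_band_table()
  expect_warning(hit <- lookup_dose(who, 2.5), "below the table minimum")
  expect_true(hit$below_minimum)
  expect_equal(hit$dose_mg, 120)
})

test_that("every weight falls in exactly one band on both packaged tables", {
  tabs <- list(who_band_table(),
               build_allometric_bands(abc_model(), abc3tc_formulary()))
  set.seed(3)
  w <- runif(10000, 0.5, 120)
  for (tab in tabs) {
    hit <- suppressWarnings(lookup_dose(tab, w))
    expect_equal(nrow(hit), length(w))
    expect_true(all(hit$dose_mg %in% tab$dose_mg))
    # quantised weight sits inside the single band it was assigned
    wq <- floor(w / 0.1 + 0.5 + 1e-9) * 0.1
    idx <- match(hit$dose_mg, tab$dose_mg)
    ok <- hit$below_minimum |
      (wq >= tab$lower_kg[idx] - 1e-9 & wq <= tab$upper_kg[idx] + 1e-9)
    expect_true(all(ok))
  }
})

test_that("banded doses never trail the exact allometric dose by more than one step", {
  m <- abc_model()
  f <- abc3tc_formulary()
  tab <- build_allometric_bands(m, f)
  set.seed(5)
  w <- runif(2000, 0.5, 120)
  hit <- lookup_dose(tab, w)
  exact <- allometric_dose(m, w)
  # slack of one step spacing: edge rounding to 0.1 kg can pull a band's
  # upper edge slightly below the weight at which its dose is exact
  step_below <- vapply(hit$dose_mg, function(d) {
    i <- match(d, f$steps$dose_mg)
    if (i == 1L) f$steps$dose_mg[2L] - d else d - f$steps$dose_mg[i - 1L]
  }, numeric(1))
  expect_true(all(hit$dose_mg >= exact - step_below - 1e-9))
})

test_that("band table JSON round trip is lossless and parsing validates", {
  path <- withr::local_tempfile(fileext = ".json")
  for (tab in list(who_band_table(), allometric_reference_table())) {
    write_band_table(tab, path)
    back <- read_band_table(path)
    expect_equal(as.data.frame(back), as.data.frame(tab))
    expect_identical(attr(back, "source"), attr(tab, "source"))
  }
  expect_equal(nrow(allometric_reference_table()), 6L)
  # overlapping bands
  expect_error(weight_band_table(data.frame(
    lower_kg = c(0, 8.0), upper_kg = c(8.2, 14.1),
    dose_mg = c(120, 180), label = c("1", "1.5"))),
    "resolution step")
  # gap wider than the resolution
  expect_error(weight_band_table(data.frame(
    lower_kg = c(0, 9.0), upper_kg = c(8.2, 14.1),
    dose_mg = c(120, 180), label = c("1", "1.5"))),
    "rows 1-2")
  # decreasing doses
  expect_error(weight_band_table(data.frame(
    lower_kg = c(0, 8.3), upper_kg = c(8.2, 14.1),
    dose_mg = c(180, 120), label = c("1.5", "1"))),
    "non-decreasing")
  # inverted edges
  expect_error(weight_band_table(data.frame(
    lower_kg = 5, upper_kg = 4, dose_mg = 120, label = "1")),
    "lower_kg")
})
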