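test_that("place-frequency map is monotone, invertible and matches its closed form", {
  pf <- place_frequency_map()
  expect_gt(place_to_cf(pf, 0), place_to_cf(pf, 12))
  x <- seq(0, 12, by = 0.25)
  cf <- place_to_cf(pf, x)
  expect_true(all(diff(cf) < 0))
  # round trip to within 0.1%
  cf_probe <- c(0.2, 0.5, 1, 2, 4.5, 10, 30, 60)
  back <- place_to_cf(pf, cf_to_place(pf, cf_probe))
  expect_true(all(abs(back / cf_probe - 1) < 1e-3))
  # closed-form place of the 4.5-kHz CF: d% from apex = log10(f/A + k)/alpha
  d <- log10(4.5 / 0.398 + 0.631) / 0.022
  x45 <- 12 * (1 - d / 100)
  expect_equal(cf_to_place(pf, 4.5), x45, tolerance = 1e-10)
  expect_gt(x45, 3); expect_lt(x45, 9)
})

test_that("map and geometry inputs are validated", {
  pf <- place_frequency_map()
  expect_error(place_to_cf(pf, 13), "within")
  expect_error(cf_to_place(pf, 1e4), "within")
  expect_error(cochlear_geometry(length_mm = -1), "positive")
  expect_error(cochlear_geometry(corti_height_um = -5), "positive")
})
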