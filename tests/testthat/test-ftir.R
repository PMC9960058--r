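wn_grid <- seq(1300, 1800, by = 4)

test_that("spectrum constructors validate their inputs", {
  expect_s3_class(spectrum(wn_grid, rep(0.1, length(wn_grid))), "spectrum")
  expect_error(spectrum(c(1, 1, 2), c(0, 0, 0)),
               class = "casekin_invalid_parameter")
  expect_error(spectrum(wn_grid, c(NA, rep(0, length(wn_grid) - 1))),
               class = "casekin_invalid_parameter")
  expect_error(spectrum_series(wn_grid, matrix(0, length(wn_grid), 2),
                               t_min = c(5, 1)),
               class = "casekin_invalid_parameter")
  # descending acquisition order is normalized to an ascending grid
  s <- spectrum(rev(wn_grid), seq_along(wn_grid))
  expect_true(all(diff(s$wavenumber) > 0))
})

test_that("reference subtraction is pointwise and refuses mismatched grids", {
  a <- spectrum(wn_grid, gaussian_band(wn_grid, 1633, 12) + 0.05)
  ref <- spectrum(wn_grid, rep(0.05, length(wn_grid)), label = "enzyme")
  out <- subtract_reference(a, ref)
  expect_equal(out$absorbance, gaussian_band(wn_grid, 1633, 12))
  expect_identical(attr(out, "reference"), "enzyme")
  expect_equal(subtract_reference(a, a)$absorbance,
               rep(0, length(wn_grid)))
  zero <- spectrum(wn_grid, rep(0, length(wn_grid)))
  expect_equal(subtract_reference(a, zero)$absorbance, a$absorbance)
  other <- spectrum(seq(1302, 1798, by = 4), rep(0, 125))
  expect_error(subtract_reference(a, other), class = "casekin_grid_mismatch")
  # regridding the reference explicitly resolves the mismatch
  expect_s3_class(subtract_reference(
    spectrum(seq(1302, 1798, by = 4), rep(0.1, 125)),
    regrid(ref, seq(1302, 1798, by = 4))), "spectrum")
})

test_that("baseline correction zeroes the anchors and removes linear ramps", {
  ramp <- spectrum(wn_grid, 0.3 + 2e-4 * wn_grid)
  out <- baseline_correct(ramp)
  expect_lt(max(abs(out$absorbance)), 1e-12)
  expect_setequal(range(out$wavenumber), c(1375, 1725))

  # Gaussian band on a ramp: result equals the band minus the line
  # through its own anchor values (closed-form construction)
  band <- function(x) gaussian_band(x, 1633, 15)
  s <- spectrum(wn_grid, band(wn_grid) + 0.1 + 3e-4 * wn_grid)
  out <- baseline_correct(s)
  line <- function(x) {
    y1 <- band(1375); y2 <- band(1725)
    y1 + (x - 1375) * (y2 - y1) / (1725 - 1375)
  }
  # anchor values are read off the 4 cm^-1 grid by linear interpolation,
  # so the analytic construction agrees to interpolation accuracy
  expect_lt(max(abs(out$absorbance -
                    (band(out$wavenumber) - line(out$wavenumber)))), 1e-8)
  expect_lt(max(abs(out$absorbance[out$wavenumber %in% c(1375, 1725)])),
            1e-12)
  expect_error(baseline_correct(s, anchors = c(1200, 1725)),
               class = "casekin_out_of_range")
})

test_that("area normalization hits the target and is scale invariant", {
  # boxcar of height 2 over 1500-1600 cm^-1 sampled on the 4 cm^-1 grid:
  # trapezoidal area is 2 * 100 plus two edge triangles of 4 each = 208,
  # so unit-area normalization maps the height 2 to 2/208
  box <- as.numeric(wn_grid >= 1500 & wn_grid <= 1600) * 2
  s <- spectrum(wn_grid, box)
  out <- normalize_area(s)
  expect_equal(max(out$absorbance), 2 / 208, tolerance = 1e-10)
  sel <- out$wavenumber >= 1375 & out$wavenumber <= 1725
  area <- sum(diff(out$wavenumber[sel]) *
              (head(out$absorbance[sel], -1) + tail(out$absorbance[sel], -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-10)

  out2 <- normalize_area(spectrum(wn_grid, box * 37.5))
  expect_equal(out2$absorbance, out$absorbance, tolerance = 1e-12)
  expect_equal(normalize_area(out)$absorbance, out$absorbance,
               tolerance = 1e-12)
  expect_error(normalize_area(spectrum(wn_grid, -box)),
               class = "casekin_normalization_impossible")
})

test_that("difference series vanish at the first time and for static series", {
  A <- sapply(1:5, function(i) gaussian_band(wn_grid, 1633, 12, 0.1 * i))
  ser <- spectrum_series(wn_grid, A, t_min = c(1, 5, 10, 20, 30))
  d <- difference_series(ser)
  expect_true(all(d$absorbance[, 1] == 0))
  expect_equal(d$absorbance[, 3],
               gaussian_band(wn_grid, 1633, 12, 0.3) -
               gaussian_band(wn_grid, 1633, 12, 0.1))
  static <- spectrum_series(wn_grid, A[, c(2, 2, 2)], t_min = c(1, 2, 3))
  expect_true(all(difference_series(static)$absorbance == 0))
  expect_error(difference_series(list()), class = "casekin_empty_input")
})

test_that("band read-off interpolates linearly and respects the window", {
  A <- sapply(1:4, function(i) 0.01 * i * (wn_grid - 1300))
  ser <- spectrum_series(wn_grid, A, t_min = 1:4)
  d <- difference_series(ser)
  tr <- band_timecourse(d, 1632)  # on-grid point
  expect_equal(tr$delta_abs, (0:3) * 0.01 * (1632 - 1300))
  tr2 <- band_timecourse(d, 1633)  # between grid points, linear ramp
  expect_equal(tr2$delta_abs, (0:3) * 0.01 * (1633 - 1300))
  flat <- difference_series(
    spectrum_series(wn_grid, A[, c(1, 1)], t_min = 1:2))
  expect_true(all(band_timecourse(flat, 1650)$delta_abs == 0))
  expect_error(band_timecourse(d, 900), class = "casekin_out_of_range")
})

test_that("preprocessing is linear in absorbance (except normalization)", {
  set.seed(5)
  for (i in 1:5) {
    y1 <- stats::runif(length(wn_grid)); y2 <- stats::runif(length(wn_grid))
    al <- stats::rnorm(1); be <- stats::rnorm(1)
    comb <- spectrum(wn_grid, al * y1 + be * y2)
    s1 <- spectrum(wn_grid, y1); s2 <- spectrum(wn_grid, y2)
    ref <- spectrum(wn_grid, stats::runif(length(wn_grid)))
    expect_equal(subtract_reference(comb, ref)$absorbance,
                 al * subtract_reference(s1, ref)$absorbance +
                 be * subtract_reference(s2, ref)$absorbance +
                 (1 - al - be) * -ref$absorbance,
                 tolerance = 1e-12)
    expect_equal(baseline_correct(comb)$absorbance,
                 al * baseline_correct(s1)$absorbance +
                 be * baseline_correct(s2)$absorbance,
                 tolerance = 1e-10)
  }
})

test_that("the full processing chain enforces its stage order", {
  tr <- trajectory(paper_model(), seq(0, 6000, by = 20))
  gen <- gen_ftir_series(tr, times_min = c(1, seq(10, 90, 10)),
                         noise_sd = 0, seed = 1)
  out <- process_reaction_series(gen$series, gen$enzyme)
  expect_named(out$traces, c("1633", "1650", "1593"))
  # normalized series: every spectrum has identical window area
  areas <- apply(out$processed$absorbance, 2, function(a) {
    x <- out$processed$wavenumber
    sum(diff(x) * (head(a, -1) + tail(a, -1)) / 2)
  })
  expect_lt(diff(range(areas)) / mean(areas), 1e-10)
  # anchor points of every processed spectrum are zero
  anchor_rows <- out$processed$wavenumber %in% c(1375, 1725)
  expect_lt(max(abs(out$processed$absorbance[anchor_rows, ])), 1e-12)

  # swapping normalization and baseline correction changes the result
  swapped <- baseline_correct(
    normalize_area(subtract_reference(gen$series, gen$enzyme),
                   window = c(1375, 1725)))
  expect_gt(max(abs(swapped$absorbance - out$processed$absorbance)), 1e-6)

  # identity series (no evolution) gives all-zero traces
  static <- spectrum_series(gen$series$wavenumber,
                            gen$series$absorbance[, c(1, 1, 1)],
                            t_min = c(1, 2, 3))
  out0 <- process_reaction_series(static, gen$enzyme)
  for (trc in out0$traces) expect_true(all(trc$delta_abs == 0))

  # stage failures carry the stage name
  bad_ref <- spectrum(seq(1302, 1798, 4), rep(0, 125))
  expect_error(process_reaction_series(gen$series, bad_ref),
               "subtract_reference")
})
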