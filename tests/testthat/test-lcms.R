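test_that("zero amounts and zero noise give flat traces at baseline", {
  ch <- make_chromatogram(c(linamarin = 0, lotaustralin = 0), 0, noise_sd = 0)
  expect_true(all(apply(ch$traces, 2, stats::sd) == 0))
  seg <- extract_eic(ch, 270, 2.6, 1)
  expect_equal(integrate_peak(seg), 0)
})

test_that("peak areas equal amount times response factor to quadrature accuracy", {
  cmp <- lcms_compounds()
  ch <- make_chromatogram(c(linamarin = 12, lotaustralin = 7), 10, noise_sd = 0)
  for (i in 1:3) {
    amount <- c(12, 7, 10)[i]
    seg <- extract_eic(ch, cmp$mz[i], cmp$rt_min[i], 1.2)
    expect_equal(integrate_peak(seg), amount * cmp$response_factor[i],
                 tolerance = 0.01)
  }
})

test_that("the analyte/IS area ratio is invariant to instrument drift", {
  amounts <- c(linamarin = 8, lotaustralin = 3)
  ratios <- sapply(c(0.5, 1, 2.7), function(drift) {
    ch <- make_chromatogram(amounts, 10, drift = drift, noise_sd = 0)
    a270 <- integrate_peak(extract_eic(ch, 270, 2.6, 0.6))
    a480 <- integrate_peak(extract_eic(ch, 480, 6.6, 0.6))
    a270 / a480
  })
  expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-9)
})

test_that("EIC extraction windows behave and locate the apex", {
  ch <- make_chromatogram(c(linamarin = 5, lotaustralin = 5), 10, noise_sd = 0)
  full <- extract_eic(ch, 270, 8.5, 17)
  expect_equal(nrow(full), length(ch$time_min))
  seg <- extract_eic(ch, 270, 2.6, 1.0)
  expect_lt(abs(seg$time_min[which.max(seg$intensity)] - 2.6), 0.05)
  expect_error(extract_eic(ch, 999, 2.6, 1), "not present")
  expect_error(extract_eic(ch, 270, 30, 0.1), "empty")
})

test_that("peak integration subtracts the endpoint baseline", {
  t <- seq(0, 1, by = 0.01)
  flat <- data.frame(time_min = t, intensity = rep(5, length(t)))
  expect_equal(integrate_peak(flat), 0)
  peak <- data.frame(time_min = t,
                     intensity = 40 * exp(-0.5 * ((t - 0.5) / 0.05)^2))
  shifted <- peak
  shifted$intensity <- shifted$intensity + 123
  expect_equal(integrate_peak(shifted), integrate_peak(peak), tolerance = 1e-9)
  expect_equal(integrate_peak(peak), 40 * 0.05 * sqrt(2 * pi), tolerance = 0.01)
  expect_error(integrate_peak(peak[1:2, ]), "too short")
})

test_that("calibration fitting is exact on exact-linear standards", {
  curves <- simulate_calibration_curves(seed = 5)
  cmp <- lcms_compounds()
  for (compound in c("linamarin", "lotaustralin")) {
    cv <- curves[[compound]]
    rf <- cmp$response_factor[cmp$compound == compound]
    rf_is <- cmp$response_factor[cmp$compound == "amygdalin"]
    expect_equal(cv$r_squared, 1, tolerance = 1e-9)
    # slope reflects the response-factor ratio; endpoint baseline clipping of
    # the wider lotaustralin peak costs a reproducible fraction of a percent
    expect_equal(cv$slope, rf / (rf_is * 10), tolerance = 0.005)
  }
  expect_error(fit_calibration(c(5, 5, 5), c(1, 1.1, 0.9)), "zero variance")
  expect_error(fit_calibration(c(1, 2), c(0.1, 0.2)), "at least 3")
  o <- order(c(3, 1, 2))
  a <- fit_calibration(c(1, 5, 10), c(0.1, 0.52, 1.01))
  b <- fit_calibration(c(1, 5, 10)[o], c(0.1, 0.52, 1.01)[o])
  expect_equal(a$slope, b$slope, tolerance = 1e-12)
})

test_that("specimen quantification recovers spiked amounts and cancels drift", {
  curves <- simulate_calibration_curves(seed = 5)
  ch <- make_chromatogram(c(linamarin = 10, lotaustralin = 5), 10,
                          drift = 1.4, noise_sd = 0)
  res <- quantify_specimen(ch, curves, mass_mg = 50)
  expect_equal(res$linamarin_nmol, 10, tolerance = 0.02)
  expect_equal(res$lotaustralin_nmol, 5, tolerance = 0.02)
  expect_equal(res$total_nmol, res$linamarin_nmol + res$lotaustralin_nmol)
  expect_equal(res$concentration_nmol_per_mg, res$total_nmol / 50)

  doubled <- quantify_specimen(
    make_chromatogram(c(linamarin = 20, lotaustralin = 10), 10,
                      drift = 1.4, noise_sd = 0), curves, 50)
  expect_equal(doubled$total_nmol, 2 * res$total_nmol, tolerance = 1e-6)

  halved_drift <- quantify_specimen(
    make_chromatogram(c(linamarin = 10, lotaustralin = 5), 10,
                      drift = 0.7, noise_sd = 0), curves, 50)
  expect_equal(halved_drift$total_nmol, res$total_nmol, tolerance = 1e-9)

  no_is <- make_chromatogram(c(linamarin = 10, lotaustralin = 5), 0, noise_sd = 0)
  expect_error(quantify_specimen(no_is, curves, 50), "internal-standard")
  expect_error(quantify_specimen(ch, curves, 0), "mass")
})

test_that("negative amounts and drift are rejected", {
  expect_error(make_chromatogram(c(linamarin = -1, lotaustralin = 0), 10),
               "non-negative")
  expect_error(make_chromatogram(c(linamarin = 1, lotaustralin = 0), 10,
                                 drift = 0), "positive")
})

test_that("chromatograms survive a long-form CSV round trip", {
  ch <- make_chromatogram(c(linamarin = 4, lotaustralin = 2), 10,
                          noise_sd = 0.5, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_chromatogram_csv(ch, path)
  back <- read_chromatogram_csv(path)
  expect_equal(back$time_min, ch$time_min, tolerance = 1e-9)
  expect_equal(unname(back$traces), unname(ch$traces), tolerance = 1e-6)
})
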