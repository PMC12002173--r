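test_that("calibration fitting recovers exact lines and guards bad input", {
  x <- c(0, 1, 2, 3, 4)
  exact <- data.frame(amount = x, absorbance = 2 * x + 0.01)
  cal <- fit_calibration(exact)
  expect_equal(cal$slope, 2)
  expect_equal(cal$intercept, 0.01)
  expect_equal(cal$r_squared, 1)

  # two points define the interpolating line exactly
  two <- data.frame(amount = c(1, 3), absorbance = c(5, 11))
  cal2 <- fit_calibration(two)
  expect_equal(cal2$slope, 3)
  expect_equal(cal2$r_squared, 1)

  expect_error(fit_calibration(data.frame(amount = c(1, 1, 1),
                                          absorbance = c(1, 2, 3))), "distinct")
  noisy <- data.frame(amount = x, absorbance = c(0, 5, 1, 9, 2))
  expect_error(fit_calibration(noisy), "force")
  expect_silent(fit_calibration(noisy, force = TRUE))
})

test_that("calibration slope is recovered within 2% under realistic noise", {
  errs <- vapply(1:50, function(s) {
    sa <- sim_assay(0, noise_sd = 0.002, seed = s)
    cal <- fit_calibration(sa$standards)
    abs(cal$slope - sa$truth$calib_slope) / sa$truth$calib_slope
  }, numeric(1))
  expect_true(all(errs < 0.02))
})

test_that("endpoint rates invert the generator and flag detectability", {
  sa <- sim_assay(c(0, 2e-11), contaminant_rate = 0, noise_sd = 0, seed = 1)
  cal <- fit_calibration(sa$standards)

  # absorbance at blank level: zero rate, not detectable
  r0 <- endpoint_rate(mean(sa$blanks), sa$blanks, cal, 60)
  expect_equal(r0$rate, 0)
  expect_false(r0$detectable)

  # noiseless inversion is exact
  a <- sa$endpoints$absorbance[sa$endpoints$rate_id == "r02" &
                                 sa$endpoints$treatment == "untreated"]
  expect_equal(endpoint_rate(a, sa$blanks, cal, sa$incubation_time)$rate, 2e-11,
               tolerance = 1e-12)

  expect_error(endpoint_rate(0.5, sa$blanks, cal, 0), "positive")

  # the 3-sigma rule keeps zero-rate wells below detection almost always
  n_detect <- sum(vapply(1:1000, function(s) {
    z <- sim_assay(0, noise_sd = 0.002, seed = s)
    zcal <- list(slope = z$truth$calib_slope, intercept = 0, r_squared = 1)
    a0 <- z$endpoints$absorbance[z$endpoints$treatment == "untreated"]
    endpoint_rate(a0, z$blanks, zcal, z$incubation_time)$detectable
  }, logical(1)))
  expect_lte(n_detect / 1000, 0.01)
})

test_that("time-course slopes use the longest linear initial window", {
  times <- seq(0, 600, by = 30)
  # perfectly linear
  lin <- 0.05 + 0.004 * (times / 60)
  r <- timecourse_rate(times, lin, conversion_factor = 2)
  expect_equal(r$rate, 0.004 * 2, tolerance = 1e-10)
  expect_false(r$low_linearity)
  expect_equal(r$window_points, length(times))

  # linear then saturating: plateau is excluded, initial slope recovered
  sat <- ifelse(times <= 300, 0.05 + 0.004 * (times / 60),
                0.05 + 0.004 * 5 + 0.0001 * ((times - 300) / 60))
  rs <- timecourse_rate(times, sat, conversion_factor = 1)
  expect_lt(rs$window_points, length(times))
  expect_lt(abs(rs$rate - 0.004) / 0.004, 0.05)

  # flat course: rate 0, treated as perfectly linear
  flat <- rep(0.05, length(times))
  expect_equal(timecourse_rate(times, flat, 1)$rate, 0)

  # jagged course falls back to full fit with a warning flag
  set.seed(3)
  jag <- 0.05 + cumsum(rnorm(length(times), 0, 0.05))
  expect_true(timecourse_rate(times, jag, 1)$low_linearity)

  expect_error(timecourse_rate(times[1:3], lin[1:3], 1), "5 points")
  expect_error(timecourse_rate(rev(times), lin, 1), "increasing")
})

test_that("okadaic-acid attribution verdicts follow the inhibited fraction", {
  # all activity lost, enzyme in molar excess over inhibitor: contaminant
  att <- oa_attribution(1e-11, 0, enzyme_conc = 100e-9, inhibitor_conc = 12.5e-9)
  expect_equal(att$verdict, "contaminant_attributed")
  expect_equal(att$inhibited_fraction, 1)

  # untouched activity: the target
  expect_equal(oa_attribution(1e-11, 1e-11, 100e-9, 12.5e-9)$verdict,
               "target_attributed")
  # partial inhibition: indeterminate
  expect_equal(oa_attribution(1e-11, 5e-12, 100e-9, 12.5e-9)$verdict,
               "indeterminate")
  # full inhibition without molar excess is not contaminant-attributable
  expect_equal(oa_attribution(1e-11, 0, 1e-9, 12.5e-9)$verdict, "indeterminate")
  # undetectable untreated rate: f = 0 by convention
  expect_equal(oa_attribution(0, 0, 100e-9, 12.5e-9,
                              untreated_detectable = FALSE)$inhibited_fraction, 0)

  # scale invariance
  for (c in c(10, 100)) {
    expect_equal(oa_attribution(1e-11 * c, 2e-13 * c, 100e-9, 12.5e-9)$verdict,
                 oa_attribution(1e-11, 2e-13, 100e-9, 12.5e-9)$verdict)
  }
})

test_that("alkylation ratios classify buried and exposed cysteines", {
  tab <- data.frame(
    residue = c(467L, 690L, 1200L, 1300L, 799L),
    intensity_IAA = c(100, 50, 90000, 80000, 200),
    intensity_MMTS = c(90000, 80000, 120, 60, 70000)
  )
  calls <- alkylation_accessibility(tab)
  expect_equal(calls$call[calls$residue %in% c(467L, 690L, 799L)],
               rep("buried", 3))
  expect_equal(calls$call[calls$residue %in% c(1200L, 1300L)],
               rep("exposed", 2))

  # with intensities far above the pseudocount, row-wise scaling leaves the
  # log2 ratio essentially unchanged and the calls identical
  big <- tab
  big$intensity_IAA <- big$intensity_IAA * 1e6
  big$intensity_MMTS <- big$intensity_MMTS * 1e6
  ref <- alkylation_accessibility(big)
  for (c in c(10, 100)) {
    scaled <- big
    scaled$intensity_IAA <- scaled$intensity_IAA * c
    scaled$intensity_MMTS <- scaled$intensity_MMTS * c
    calls2 <- alkylation_accessibility(scaled)
    expect_identical(calls2$call, ref$call)
    expect_equal(calls2$log2_ratio, ref$log2_ratio, tolerance = 1e-6)
  }

  expect_error(alkylation_accessibility(tab, pseudocount = 0), "pseudocount")
  dup <- tab; dup$residue[2] <- 467L
  expect_error(alkylation_accessibility(dup), "unique")
})
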