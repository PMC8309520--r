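test_that("1 s block means form the rhythm, honoring validity", {
  r <- resample_rhythm(constant_trace(300, 35))
  expect_equal(nrow(r), 10)
  expect_true(all(r$diameter_px == 35))

  # a window with 10 invalid samples still averages its valid 20
  valid <- rep(TRUE, 60); valid[11:20] <- FALSE
  tr <- constant_trace(60, 40, valid = valid)
  r2 <- resample_rhythm(tr)
  expect_equal(r2$diameter_px, c(40, 40))
  expect_equal(r2$valid_fraction, c(2 / 3, 1))

  expect_error(resample_rhythm(constant_trace(30)), "at least 2 seconds")
  expect_error(resample_rhythm(constant_trace(90, valid = rep(FALSE, 90))),
               "no valid samples")
})

test_that("an all-invalid second is filled by linear interpolation", {
  d <- c(rep(35, 30), rep(0, 30), rep(37, 30))
  valid <- c(rep(TRUE, 30), rep(FALSE, 30), rep(TRUE, 30))
  tr <- constant_trace(90, valid = valid)
  tr$diameter_px <- ifelse(valid, d, NA)
  r <- resample_rhythm(tr)
  expect_equal(r$diameter_px, c(35, 36, 37))
  # edge windows take the nearest defined value
  valid2 <- c(rep(FALSE, 30), rep(TRUE, 60))
  tr2 <- constant_trace(90, 41, valid = valid2)
  expect_equal(resample_rhythm(tr2)$diameter_px, c(41, 41, 41))
})

test_that("mPD/sPD are the mean and sample standard deviation", {
  expect_equal(rhythm_mean_sd(rhythm_from_values(c(35, 35, 35))),
               tibble::tibble(mPD = 35, sPD = 0))
  ms <- rhythm_mean_sd(rhythm_from_values(c(34, 36)))
  expect_equal(ms$mPD, 35)
  expect_equal(ms$sPD, sqrt(2))
  expect_error(rhythm_mean_sd(rhythm_from_values(35)), "at least 2")
  # streaming two-pass oracle agreement on random rhythms
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(200, 40, 2)
    ms <- rhythm_mean_sd(rhythm_from_values(x))
    o <- oracle_mean_sd(x)
    expect_equal(ms$mPD, o$mean, tolerance = 1e-10)
    expect_equal(ms$sPD, o$sd, tolerance = 1e-10)
  }
})

test_that("preset traces land on their generator anchor values", {
  post <- features_from_trace(simulate_trace("postHMD", seed = 3))
  expect_lt(abs(post$mPD - 43), 0.5)
  expect_lt(abs(post$sPD - 2.5), 0.5)
  pre <- features_from_trace(simulate_trace("pre2D", seed = 4))
  expect_lt(abs(pre$mPD - 35), 0.5)
  expect_lt(abs(pre$sPD - 1.3), 0.5)
})

test_that("spectrum finds a sinusoid's frequency and kills DC", {
  t <- 0:299
  spec <- rhythm_spectrum(rhythm_from_values(40 + 2 * sin(2 * pi * 0.1 * t)))
  dom <- attr(spec, "dominant_bin")
  expect_lte(abs(spec$freq_hz[dom] - 0.1), 1 / 300)
  expect_true(all(spec$freq_hz > 0 & spec$freq_hz <= 0.5))
  flat <- rhythm_spectrum(rhythm_from_values(rep(35, 64)))
  expect_lt(attr(flat, "total_power"), 1e-20)
  expect_error(rhythm_spectrum(rhythm_from_values(rep(35, 5))), "at least 8")
})

test_that("white noise never concentrates in one bin", {
  set.seed(9)
  for (i in 1:5) {
    spec <- rhythm_spectrum(rhythm_from_values(rnorm(300)))
    expect_lt(attr(spec, "dominant_power") / attr(spec, "total_power"), 0.2)
  }
})

test_that("rectangular-window power satisfies Parseval's identity", {
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(250, 40, 2)
    spec <- rhythm_spectrum(rhythm_from_values(x), window = "rectangular")
    expect_equal(attr(spec, "total_power"), sum((x - mean(x))^2),
                 tolerance = 1e-8)
  }
})

test_that("PRC ratio closed forms hold on constructed spectra", {
  # K equal-power bins: single-bin ratio is 1/(K-1)
  expect_equal(prc_ratio(spectrum_from_powers(rep(3.7, 11))), 1 / 10)
  for (K in c(2, 5, 20, 151)) {
    expect_equal(prc_ratio(spectrum_from_powers(rep(1, K))), 1 / (K - 1))
  }
  # dominant share 0.595 of total
  p <- c(0.595, rep(0.405 / 9, 9))
  expect_equal(prc_ratio(spectrum_from_powers(p)), 0.595 / 0.405,
               tolerance = 1e-12)
  expect_error(prc_ratio(spectrum_from_powers(rep(0, 5))), "positive")
  expect_warning(r <- prc_ratio(spectrum_from_powers(c(1, 0, 0))),
                 "Degenerate")
  expect_identical(r, Inf)
})

test_that("PRC is scale-invariant and rewards concentration", {
  set.seed(12)
  x <- 40 + 1.5 * sin(2 * pi * 0.1 * (0:299)) + rnorm(300, 0, 1)
  s1 <- rhythm_spectrum(rhythm_from_values(x))
  s2 <- rhythm_spectrum(rhythm_from_values(3 * x))
  expect_equal(prc_ratio(s1), prc_ratio(s2), tolerance = 1e-10)
  # moving power from a non-dominant bin into the peak raises the ratio
  p <- c(5, 1, 1, 1, 1)
  p_moved <- c(5.5, 0.5, 1, 1, 1)
  expect_gt(prc_ratio(spectrum_from_powers(p_moved)),
            prc_ratio(spectrum_from_powers(p)))
})

test_that("an on-bin Hann-windowed sinusoid gives the three-bin leakage ratio", {
  # periodic Hann splits a bin-centered tone 0.5/0.25/0.25 in amplitude, so
  # the single-bin PRC ratio is 0.25^2/(2 * 0.125^2) ... = 2 exactly
  x <- 40 + 2 * sin(2 * pi * 0.1 * (0:299) + 0.7)
  spec <- rhythm_spectrum(rhythm_from_values(x))
  expect_equal(prc_ratio(spec), 2, tolerance = 0.05)
  # adding broadband noise can only lower it
  set.seed(21)
  noisy <- x + rnorm(300, 0, 2)
  expect_lt(prc_ratio(rhythm_spectrum(rhythm_from_values(noisy))),
            prc_ratio(spec))
  # with the halfwidth-1 band the leaked neighbours rejoin the peak and
  # essentially no power remains outside it
  expect_warning(r3 <- prc_ratio(spec, band_halfwidth = 1), "Degenerate")
  expect_gt(r3, 50)
})

test_that("feature composition matches presets and degenerates cleanly", {
  const <- features_from_trace(constant_trace(300, 35))
  expect_equal(const$mPD, 35)
  expect_equal(const$sPD, 0)
  expect_true(is.na(const$prc))
  pre_prc <- vapply(1:5, function(s) {
    features_from_trace(simulate_trace("pre2D", seed = s))$prc
  }, 0)
  expect_true(all(pre_prc > 0.3 & pre_prc < 0.8))
  post_prc <- vapply(1:5, function(s) {
    features_from_trace(simulate_trace("postHMD", seed = s))$prc
  }, 0)
  expect_true(all(post_prc < 0.2))
})

test_that("rhythm ordering across seeds matches the sickness signature", {
  pre <- t(vapply(1:20, function(s) {
    unlist(features_from_trace(simulate_trace("preHMD", duration = 120,
                                              seed = s)))
  }, c(mPD = 0, sPD = 0, prc = 0)))
  post <- t(vapply(1:20, function(s) {
    unlist(features_from_trace(simulate_trace("postHMD", duration = 120,
                                              seed = 100 + s)))
  }, c(mPD = 0, sPD = 0, prc = 0)))
  expect_gt(median(post[, "mPD"]), median(pre[, "mPD"]))
  expect_gt(median(post[, "sPD"]), median(pre[, "sPD"]))
  expect_lt(median(post[, "prc"]), median(pre[, "prc"]))
})
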