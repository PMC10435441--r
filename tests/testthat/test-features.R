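test_that("the 11 time-domain statistics behave on canonical windows", {
  fs <- 25
  td <- suppressWarnings(time_domain_features(rep(3.5, 100), fs))
  expect_named(td, c("mean", "median", "max", "min", "std", "var", "skew",
                     "kurtosis", "iqr", "mad", "slope"))
  expect_equal(unname(td[c("std", "var", "iqr", "mad", "slope")]),
               rep(0, 5))
  expect_warning(time_domain_features(rep(1, 10), fs), "degenerate")
  # symmetric window: integer periods of a sine -> skew 0
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  s <- sin(2 * pi * 2 * t)
  expect_lt(abs(time_domain_features(s, fs)[["skew"]]), 1e-10)
  # noiseless ramp a + b t -> slope b exactly, per second
  x <- 2 + 0.37 * t
  expect_equal(time_domain_features(x, fs)[["slope"]], 0.37, tolerance = 1e-10)
  # unbiased std/var convention
  x2 <- c(1, 2, 3, 6)
  expect_equal(time_domain_features(x2, fs)[["var"]], var(x2))
  expect_error(time_domain_features(c(1, 2, 3), fs), "at least 4")
})

test_that("Morse wavelet spectrum: peak channel, linearity, zero signal", {
  fs <- 25
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2.6 * t)
  sp <- wavelet_spectrum(x, fs)
  e <- rowMeans(sp$magnitude^2)
  best <- which.max(e)
  expect_equal(best, which.min(abs(sp$freqs_hz - 2.6)))
  # linearity: doubling amplitude doubles every magnitude
  sp2 <- wavelet_spectrum(2 * x, fs)
  expect_equal(sp2$magnitude, 2 * sp$magnitude, tolerance = 1e-12)
  # zero signal -> all-zero magnitudes
  expect_equal(max(wavelet_spectrum(numeric(300), fs)$magnitude), 0)
  # near-unit response at a channel center frequency (away from edges)
  fc <- sp$freqs_hz[best]
  xc <- sin(2 * pi * fc * t)
  mid <- wavelet_spectrum(xc, fs)$magnitude[best, 300:700]
  expect_close(median(mid), 1, 0.15)
  expect_error(wavelet_spectrum(x, fs = 0), "sampling rate")
  expect_error(wavelet_spectrum(x[1:10], fs), "64")
})

test_that("frequency-domain features: counting and constant channels", {
  sp <- wavelet_spectrum(sin(2 * pi * 2 * seq(0, 20, by = 0.04)), 25)
  fd <- suppressWarnings(frequency_domain_features(sp))
  expect_length(fd, 11 * length(sp$freqs_hz))
  expect_true(all(grepl("^[a-z]+_[0-9]+$", names(fd))))
})

test_that("feature names round-trip under the naming pattern", {
  nm <- make_feature_name(970, "fd", "median", 7)
  expect_identical(nm, "970_fd_median_7")
  p <- parse_feature_name(nm)
  expect_identical(p, list(wavelength = "970", domain = "fd", fun = "median",
                           channel = 7L))
  p2 <- parse_feature_name("1450_td_slope")
  expect_identical(p2$fun, "slope")
  expect_true(is.na(p2$channel))
  expect_error(parse_feature_name("970_zz_mean"), "does not match")
  expect_error(parse_feature_name("970_td_mean_3"), "does not match")
  expect_error(make_feature_name(970, "fd", "median"), "channel")
})

test_that("window feature extraction: counts, determinism, validation", {
  rec <- short_run()
  win <- window_spec(duration_s = 120, step_s = 20)
  v <- extract_window_features(rec, 0, win, wavelengths = c("970", "1450"))
  C <- 26
  expect_length(v, 11 * 2 * (1 + C))
  expect_true(all(vapply(names(v), function(n)
    is.list(parse_feature_name(n)), TRUE)))
  expect_true(all(is.finite(v)))
  # identical windows -> identical vectors; ordering stable
  v2 <- extract_window_features(rec, 0, win, wavelengths = c("970", "1450"))
  expect_identical(v, v2)
  # time-domain only
  vtd <- extract_window_features(rec, 0, win, wavelengths = "970",
                                 include_freq = FALSE)
  expect_length(vtd, 11)
  expect_error(extract_window_features(rec, 0, win, wavelengths = "800"),
               "unknown PPG channel")
  expect_error(extract_window_features(rec, 590, win), "does not fit")
})

test_that("an HR increase raises pulse-band median-magnitude features", {
  mk <- function(hr) generate_run(
    run_profile(duration_s = 300, hr_rest_bpm = hr, hr_peak_bpm = hr,
                motion_amp = 0, film_max_um = 0), seed = 9)
  win <- window_spec(duration_s = 210)
  lo <- extract_window_features(mk(70), 0, win, wavelengths = "970")
  hi <- extract_window_features(mk(150), 0, win, wavelengths = "970")
  sp <- wavelet_spectrum(numeric(210 * 25), 25)
  band <- which(sp$freqs_hz >= 2 & sp$freqs_hz <= 3)
  nms <- paste0("970_fd_median_", band)
  expect_gt(mean(hi[nms]), mean(lo[nms]))
})
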