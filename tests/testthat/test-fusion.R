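imu_matrix <- function(t, f_swing = 1.4, f_step = 2.8, amp = 1, noise = 0.02) {
  sw <- amp * sin(2 * pi * f_swing * t)
  st <- amp * sin(2 * pi * f_step * t + 1)
  cbind(acc_x = st + 0.3 * sw + rnorm(length(t), sd = noise),
        acc_y = 0.5 * st + rnorm(length(t), sd = noise),
        acc_z = 0.2 * st + rnorm(length(t), sd = noise),
        gyr_x = sw + rnorm(length(t), sd = noise),
        gyr_y = 0.8 * sw + rnorm(length(t), sd = noise),
        gyr_z = 0.3 * sw + rnorm(length(t), sd = noise))
}

test_that("motion frequencies are recovered within one bin", {
  fs <- 25
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  set.seed(3)
  prof <- identify_motion_frequencies(imu_matrix(t), fs = fs)
  bin <- fs / length(t)
  expect_true(any(abs(prof$freq_hz - 1.4) <= bin + 1e-9))
  expect_true(any(abs(prof$freq_hz - 2.8) <= bin + 1e-9))
  expect_true(all(prof$freq_hz > 0 & prof$freq_hz <= fs / 2))
  expect_true(all(prof$bandwidth_hz > 0))
})

test_that("rest and all-zero IMU give an empty profile", {
  fs <- 25
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  set.seed(4)
  rest <- matrix(rnorm(length(t) * 6, sd = 0.02), ncol = 6)
  expect_equal(nrow(identify_motion_frequencies(rest, fs = fs)), 0)
  zeros <- matrix(0, length(t), 6)
  expect_equal(nrow(identify_motion_frequencies(zeros, fs = fs)), 0)
  expect_error(identify_motion_frequencies(zeros[1:100, ], fs = fs), "30 s")
})

test_that("peak magnitudes scale linearly with IMU amplitude", {
  fs <- 25
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  set.seed(5)
  p1 <- identify_motion_frequencies(imu_matrix(t, amp = 1, noise = 0), fs = fs)
  set.seed(5)
  p3 <- identify_motion_frequencies(imu_matrix(t, amp = 3, noise = 0), fs = fs)
  m1 <- p1$magnitude[which.min(abs(p1$freq_hz - 1.4))]
  m3 <- p3$magnitude[which.min(abs(p3$freq_hz - 1.4))]
  expect_equal(m3 / m1, 3, tolerance = 0.05)
})

test_that("suppression removes motion bands and preserves the pulse", {
  fs <- 25
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  set.seed(6)
  ppg <- 1e4 + 100 * sin(2 * pi * 2.0 * t) + 120 * sin(2 * pi * 1.4 * t) +
    rnorm(length(t), sd = 5)
  prof <- identify_motion_frequencies(imu_matrix(t), fs = fs)
  out <- suppress_artifacts(ppg, prof, fs)
  expect_false(out$unusable)
  x <- out$signal - mean(out$signal)
  p <- Mod(fft(x))[2:(length(x) %/% 2)]
  fr <- (1:(length(x) %/% 2 - 1)) * fs / length(x)
  expect_close(fr[which.max(p)], 2.0, 0.05)
  # 1.4 Hz content (within the artifact band) is gone
  band14 <- fr > 1.3 & fr < 1.5
  band20 <- fr > 1.9 & fr < 2.1
  expect_lt(max(p[band14]), 0.02 * max(p[band20]))
  # energy never increases
  expect_lte(sum((out$signal - mean(out$signal))^2),
             sum((ppg - mean(ppg))^2) + 1e-6)
  # pulse band outside artifact bands changes by <= 5% in energy
  keep <- band20
  e_before <- sum(Mod(fft(ppg - mean(ppg)))[2:(length(x) %/% 2)][keep]^2)
  e_after <- sum(p[keep]^2)
  expect_close(e_after / e_before, 1, 0.05)
})

test_that("empty profile is identity; cardiac collision flags unusable", {
  fs <- 25
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  out <- suppress_artifacts(x, NULL, fs)
  expect_identical(out$signal, x)
  expect_false(out$unusable)
  # motion exactly at the cardiac frequency
  prof <- data.frame(freq_hz = 2.0, magnitude = 1, bandwidth_hz = 0.15,
                     harmonic = FALSE)
  out2 <- suppress_artifacts(x, prof, fs)
  expect_true(out2$unusable)
  expect_identical(out2$signal, x)
  # bands covering the whole pulse band
  prof3 <- data.frame(freq_hz = seq(0.8, 3.5, by = 0.2), magnitude = 1,
                      bandwidth_hz = 0.15, harmonic = FALSE)
  expect_true(suppress_artifacts(x, prof3, fs)$unusable)
})

test_that("fusion integrates with feature extraction on a recording", {
  rec <- short_run(seed = 30)
  prof <- identify_motion_frequencies(rec)
  expect_s3_class(prof, "artifact_profile")
  expect_gt(nrow(prof), 0)  # the generator embeds step and swing components
  v <- extract_window_features(rec, 0, window_spec(duration_s = 120),
                               wavelengths = "970", fuse_imu = TRUE)
  expect_true(all(is.finite(v)))
})
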