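#' Identify motion-artifact frequencies from the IMU channels
#'
#' Spectral peaks of the combined accelerometer and gyroscope magnitude
#' signals above a robust noise floor become artifact frequencies (cadence,
#' arm swing and their first harmonics) -- the frequencies that corrupt the
#' simultaneously recorded PPG.
#'
#' @param recording a `ppg_recording` (or a plain numeric matrix of IMU
#'   channels with `fs` supplied).
#' @param fs sampling rate, Hz (taken from the recording when given one).
#' @param floor_factor peaks must exceed `floor_factor` times the median
#'   periodogram power.
#' @param bandwidth_hz half-width assigned to each artifact band, Hz.
#' @param f_min ignore spectral content below this frequency (posture/drift).
#' @return object of class `"artifact_profile"`: data.frame with `freq_hz`,
#'   `magnitude`, `bandwidth_hz`, `harmonic` (TRUE for added first
#'   harmonics); empty for stationary or all-zero IMU.
#' @export
identify_motion_frequencies <- function(recording, fs = NULL,
                                        floor_factor = 30,
                                        bandwidth_hz = 0.15, f_min = 0.3) {
  if (inherits(recording, "ppg_recording")) {
    fs <- recording$fs
    imu <- as.matrix(recording$data[, c("acc_x", "acc_y", "acc_z",
                                        "gyr_x", "gyr_y", "gyr_z")])
  } else {
    imu <- as.matrix(recording)
    if (is.null(fs)) stop("fs must be supplied for a plain matrix")
  }
  n <- nrow(imu)
  if (n < 30 * fs) stop("need at least 30 s of IMU data")
  empty <- data.frame(freq_hz = numeric(0), magnitude = numeric(0),
                      bandwidth_hz = numeric(0), harmonic = logical(0))
  if (all(imu == 0))
    return(structure(empty, class = c("artifact_profile", "data.frame")))

  # combined detrended magnitude, Hann-windowed periodogram
  mag <- sqrt(rowSums(scale(imu, scale = FALSE)^2))
  mag <- mag - mean(mag)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  P <- Mod(fft(mag * w))^2
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs >= f_min & freqs <= fs / 2
  P <- P[keep]; freqs <- freqs[keep]
  floor_p <- median(P)
  if (floor_p <= 0)
    return(structure(empty, class = c("artifact_profile", "data.frame")))

  cand <- which(P > floor_factor * floor_p)
  peaks <- data.frame(freq_hz = numeric(0), magnitude = numeric(0))
  while (length(cand)) {                      # greedy peak extraction
    i <- cand[which.max(P[cand])]
    peaks <- rbind(peaks, data.frame(freq_hz = freqs[i],
                                     magnitude = sqrt(P[i])))
    cand <- cand[abs(freqs[cand] - freqs[i]) > 2 * bandwidth_hz]
  }
  if (!nrow(peaks))
    return(structure(empty, class = c("artifact_profile", "data.frame")))
  peaks$bandwidth_hz <- bandwidth_hz
  peaks$harmonic <- FALSE
  harm <- peaks[peaks$freq_hz * 2 <= fs / 2, , drop = FALSE]
  if (nrow(harm)) {
    harm$freq_hz <- harm$freq_hz * 2
    harm$magnitude <- harm$magnitude / 2
    harm$harmonic <- TRUE
    new <- vapply(harm$freq_hz, function(f)
      all(abs(peaks$freq_hz - f) > bandwidth_hz), TRUE)
    peaks <- rbind(peaks, harm[new, , drop = FALSE])
  }
  peaks <- peaks[order(peaks$freq_hz), ]
  rownames(peaks) <- NULL
  structure(peaks, class = c("artifact_profile", "data.frame"))
}

#' Suppress IMU-identified motion artifacts in a PPG channel
#'
#' Spectral content inside the artifact bands (peak +/- bandwidth, harmonics
#' included) is excluded before feature computation by zeroing the
#' corresponding Fourier components. If the dominant pulse-band peak of the
#' PPG itself falls inside an artifact band -- motion at the cardiac
#' frequency -- the channel is flagged unusable and returned unchanged rather
#' than silently cleaned.
#'
#' @param x numeric PPG channel.
#' @param profile an `artifact_profile` from the same recording.
#' @param fs sampling rate, Hz.
#' @param pulse_band plausible cardiac frequency range, Hz (default 0.8--3.5,
#'   i.e. 48--210 bpm).
#' @return list: `signal` (cleaned, or the input if unusable), `unusable`,
#'   `removed_energy` (fraction of AC energy removed), `bands` (matrix of
#'   excluded intervals).
#' @export
suppress_artifacts <- function(x, profile, fs = 25,
                               pulse_band = c(0.8, 3.5)) {
  if (is.null(profile) || nrow(profile) == 0)
    return(list(signal = x, unusable = FALSE, removed_energy = 0,
                bands = matrix(numeric(0), 0, 2)))
  bands <- cbind(profile$freq_hz - profile$bandwidth_hz,
                 profile$freq_hz + profile$bandwidth_hz)
  n <- length(x)
  X <- fft(x - mean(x))
  freqs <- (seq_len(n) - 1) * fs / n
  fmir <- pmin(freqs, fs - freqs)            # two-sided bin frequency
  in_band <- rep(FALSE, n)
  for (b in seq_len(nrow(bands)))
    in_band <- in_band | (fmir >= bands[b, 1] & fmir <= bands[b, 2])

  # is a credible cardiac line left outside the artifact bands? If the
  # pulse band is fully covered, or everything that survives outside the
  # bands is dwarfed by what sits inside them (motion on top of the cardiac
  # frequency), the channel cannot be cleaned honestly.
  pb <- fmir >= pulse_band[1] & fmir <= pulse_band[2]
  if (!any(pb & !in_band)) {
    return(list(signal = x, unusable = TRUE, removed_energy = 0,
                bands = bands))
  }
  amp <- Mod(X)
  out_max <- max(amp[pb & !in_band])
  in_max <- if (any(pb & in_band)) max(amp[pb & in_band]) else 0
  if (in_max > 0 && out_max < 0.2 * in_max)
    return(list(signal = x, unusable = TRUE, removed_energy = 0,
                bands = bands))

  total <- sum(Mod(X)^2)
  X[in_band] <- 0
  cleaned <- Re(fft(X, inverse = TRUE)) / n + mean(x)
  list(signal = cleaned, unusable = FALSE,
       removed_energy = if (total > 0) 1 - sum(Mod(X)^2) / total else 0,
       bands = bands)
}
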