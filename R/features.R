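FEATURE_FUNS <- c("mean", "median", "max", "min", "std", "var", "skew",
                  "kurtosis", "iqr", "mad", "slope")

#' Analysis window specification
#'
#' @param duration_s window duration, s (the classifier windows are 3.5 min).
#' @param step_s sweep step, s (windows move by 20 s steps).
#' @return object of class `"window_spec"`.
#' @export
window_spec <- function(duration_s = 210, step_s = 20) {
  if (duration_s <= 0 || step_s <= 0) stop("duration and step must be > 0")
  structure(list(duration_s = duration_s, step_s = step_s),
            class = "window_spec")
}

#' The 11 time-domain window statistics
#'
#' Mean, median, max, min, standard deviation and variance (unbiased, n-1),
#' skewness, excess kurtosis, interquartile range, median absolute deviation
#' (unscaled), and the least-squares trend slope per second. Computed on the
#' raw, unprocessed signal. For a degenerate (constant) window, skewness and
#' kurtosis are defined as 0 and a warning is logged.
#'
#' @param x numeric window, length >= 4.
#' @param fs sampling rate in Hz (for the slope's per-second units).
#' @return named numeric vector of length 11 (names are the field's
#'   lower-case function names used in feature naming).
#' @export
time_domain_features <- function(x, fs = 25) {
  n <- length(x)
  if (n < 4) stop("window must contain at least 4 samples")
  if (anyNA(x)) stop("window contains NA")
  m <- mean(x)
  cx <- x - m
  m2 <- mean(cx^2)
  if (m2 > 0) {
    skew <- mean(cx^3) / m2^1.5
    kurt <- mean(cx^4) / m2^2 - 3
  } else {
    warning("degenerate (constant) window: skewness and kurtosis set to 0")
    skew <- 0
    kurt <- 0
  }
  tt <- (seq_len(n) - 1) / fs
  tc <- tt - mean(tt)
  slope <- sum(tc * cx) / sum(tc^2)
  c(mean = m, median = median(x), max = max(x), min = min(x),
    std = sqrt(m2 * n / (n - 1)), var = m2 * n / (n - 1),
    skew = skew, kurtosis = kurt,
    iqr = unname(diff(quantile(x, c(0.25, 0.75), names = FALSE))),
    mad = median(abs(x - median(x))), slope = slope)
}

#' Generalized Morse wavelet transform of a signal window
#'
#' Continuous wavelet transform with the generalized Morse mother wavelet
#' (frequency-domain form `a_{beta,gamma} w^beta exp(-w^gamma)` for `w > 0`,
#' peak-normalized so a unit-amplitude sinusoid at a channel's center
#' frequency yields unit magnitude), evaluated by FFT over log-spaced scales.
#'
#' @param x numeric signal window, length >= 64.
#' @param fs sampling rate, Hz, > 0.
#' @param gamma,beta Morse shape parameters (defaults 3 and 20, the
#'   library-typical analytic-wavelet setting).
#' @param freqs_hz channel center frequencies in Hz; default 26 log-spaced
#'   channels covering 0.1 Hz to the 12.5 Hz Nyquist of the 25 Hz recording.
#' @return object of class `"wavelet_spectrum"`: `magnitude` (channels x
#'   samples), `freqs_hz`, `fs`, `gamma`, `beta`.
#' @export
wavelet_spectrum <- function(x, fs = 25, gamma = 3, beta = 20,
                             freqs_hz = NULL) {
  if (fs <= 0) stop("sampling rate must be > 0")
  n <- length(x)
  if (n < 64) stop("window must contain at least 64 samples")
  if (is.null(freqs_hz))
    freqs_hz <- exp(seq(log(0.1), log(min(12.5, fs / 2)), length.out = 26))
  nfft <- 2^ceiling(log2(n))
  X <- fft(c(x, numeric(nfft - n)))
  w <- 2 * pi * (0:(nfft - 1)) / nfft        # rad/sample, DFT bin frequencies
  pos <- w > 0 & seq_along(w) <= nfft / 2 + 1
  wp <- (beta / gamma)^(1 / gamma)           # Morse peak frequency
  log_a <- log(2) + (beta / gamma) * (1 + log(gamma / beta))
  mag <- matrix(0, length(freqs_hz), n)
  for (c_i in seq_along(freqs_hz)) {
    s <- wp / (2 * pi * freqs_hz[c_i] / fs)  # scale mapping peak -> f_c
    psi <- numeric(nfft)
    ws <- s * w[pos]
    psi[pos] <- exp(log_a + beta * log(ws) - ws^gamma)
    W <- fft(X * psi, inverse = TRUE) / nfft
    mag[c_i, ] <- Mod(W[seq_len(n)])  # psi-hat peak of 2 = analytic factor
  }
  structure(list(magnitude = mag, freqs_hz = freqs_hz, fs = fs,
                 gamma = gamma, beta = beta),
            class = "wavelet_spectrum")
}

#' Frequency-domain window statistics from a wavelet spectrum
#'
#' Applies the same 11 statistics as [time_domain_features()] to each wavelet
#' channel's magnitude time series; names carry the channel index.
#'
#' @param spectrum a [wavelet_spectrum()].
#' @return named numeric vector of length `11 * n_channels`, names
#'   `<function>_<channel>`.
#' @export
frequency_domain_features <- function(spectrum) {
  stopifnot(inherits(spectrum, "wavelet_spectrum"))
  out <- lapply(seq_len(nrow(spectrum$magnitude)), function(c_i) {
    v <- time_domain_features(spectrum$magnitude[c_i, ], spectrum$fs)
    names(v) <- paste0(names(v), "_", c_i)
    v
  })
  unlist(out)
}

#' Compose / parse feature names
#'
#' Feature names follow `<wavelength>_<domain>_<function>[_<channel>]`, e.g.
#' `970_td_skew` (time domain) or `1450_fd_median_7` (frequency domain,
#' wavelet channel 7).
#'
#' @param wavelength channel wavelength label.
#' @param domain `"td"` or `"fd"`.
#' @param fun one of the 11 statistic names.
#' @param channel wavelet channel index (frequency domain only).
#' @return `make_feature_name`: character name. `parse_feature_name`: list
#'   with fields `wavelength`, `domain`, `fun`, `channel` (NA for time
#'   domain).
#' @export
make_feature_name <- function(wavelength, domain, fun, channel = NULL) {
  if (!domain %in% c("td", "fd")) stop("domain must be 'td' or 'fd'")
  if (!fun %in% FEATURE_FUNS) stop("unknown statistic: ", fun)
  if (domain == "fd" && is.null(channel))
    stop("frequency-domain names require a channel index")
  paste(c(wavelength, domain, fun, channel), collapse = "_")
}

#' @rdname make_feature_name
#' @param name feature name to parse.
#' @export
parse_feature_name <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(parts) < 3 || length(parts) > 4 ||
      !parts[2] %in% c("td", "fd") || !parts[3] %in% FEATURE_FUNS ||
      (parts[2] == "td" && length(parts) != 3) ||
      (parts[2] == "fd" && length(parts) != 4))
    stop("feature name does not match <wavelength>_<domain>_<function>[_<channel>]: ",
         name)
  list(wavelength = parts[1], domain = parts[2], fun = parts[3],
       channel = if (length(parts) == 4) as.integer(parts[4]) else NA_integer_)
}

#' Extract the named feature vector of one analysis window
#'
#' Concatenates time-domain features (raw signal) and frequency-domain
#' features (Morse wavelet channels) for the configured wavelengths, in a
#' deterministic order. Optionally applies IMU-informed artifact suppression
#' ([suppress_artifacts()]) to each PPG channel first.
#'
#' @param recording a `ppg_recording`.
#' @param start_s window start time, s.
#' @param window a [window_spec()].
#' @param wavelengths channel wavelength labels (default 970 and 1450, the
#'   wavelengths the classification study focuses on).
#' @param include_freq include frequency-domain features (default TRUE).
#' @param fuse_imu logical; suppress IMU-identified motion artifacts first.
#' @param ... passed to [wavelet_spectrum()] (e.g. `freqs_hz`, `gamma`,
#'   `beta`).
#' @return named numeric vector of length `11 * W * (1 + C)` (W wavelengths,
#'   C wavelet channels) when `include_freq`, else `11 * W`.
#' @export
extract_window_features <- function(recording, start_s = 0,
                                    window = window_spec(),
                                    wavelengths = c("970", "1450"),
                                    include_freq = TRUE, fuse_imu = FALSE,
                                    ...) {
  fs <- recording$fs
  n_need <- floor(window$duration_s * fs)
  i0 <- round(start_s * fs) + 1L
  i1 <- i0 + n_need - 1L
  if (i0 < 1L || i1 > nrow(recording$data))
    stop("window [", start_s, ", ", start_s + window$duration_s,
         "] s does not fit inside the recording")
  profile <- if (fuse_imu) identify_motion_frequencies(recording) else NULL
  out <- lapply(wavelengths, function(w) {
    x <- ppg_channel(recording, w)[i0:i1]
    if (fuse_imu) x <- suppress_artifacts(x, profile, fs)$signal
    td <- time_domain_features(x, fs)
    names(td) <- vapply(names(td), function(f) make_feature_name(w, "td", f),
                        "")
    if (!include_freq) return(td)
    fd <- frequency_domain_features(wavelet_spectrum(x, fs, ...))
    names(fd) <- paste0(w, "_fd_", names(fd))
    c(td, fd)
  })
  v <- unlist(out)
  stopifnot(!anyDuplicated(names(v)))
  v
}
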