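#' Run profile: the stated world a synthetic recording is drawn from
#'
#' Describes a single treadmill run the way the study recordings look: heart
#' rate rising from rest to a plateau, cadence and arm swing switching on as
#' the run starts, and a sweat/water film appearing minutes in and growing as
#' a saturating ramp.
#'
#' @param duration_s run duration, seconds (study runs were ~20-35 min;
#'   default 22 min).
#' @param fs sampling rate, Hz (hardware records at 25 Hz).
#' @param hr_rest_bpm,hr_peak_bpm heart-rate trajectory endpoints; HR relaxes
#'   from rest toward the plateau with time constant `hr_tau_s`.
#' @param hr_tau_s heart-rate rise time constant, s.
#' @param cadence_spm steady running cadence, steps per minute.
#' @param arm_swing_hz arm-swing frequency, Hz (about cadence/120: one swing
#'   per two steps).
#' @param film_onset_s true film onset time t0, s.
#' @param film_max_um film thickness plateau, micrometers.
#' @param film_tau_s film growth time constant, s ("the film does not appear
#'   instantly"; ~5 min).
#' @param cardiac_amp relative cardiac (AC/DC) amplitude of the PPG.
#' @param motion_amp relative motion-artifact amplitude during running.
#' @param noise_sd relative white-noise level per PPG channel.
#' @param pink_sd relative pink (1/f) noise level per PPG channel.
#' @return object of class `"run_profile"`.
#' @export
run_profile <- function(duration_s = 1320, fs = 25,
                        hr_rest_bpm = 75, hr_peak_bpm = 155, hr_tau_s = 180,
                        cadence_spm = 170, arm_swing_hz = 1.4,
                        film_onset_s = 600, film_max_um = 300,
                        film_tau_s = 300,
                        cardiac_amp = 0.015, motion_amp = 0.012,
                        noise_sd = 0.002, pink_sd = 0.002) {
  if (duration_s <= 0) stop("duration must be > 0")
  if (hr_rest_bpm < 40 || hr_peak_bpm > 220)
    stop("heart rate must stay within [40, 220] bpm")
  if (film_onset_s < 0 || film_max_um < 0) stop("film parameters must be >= 0")
  structure(as.list(environment()), class = "run_profile")
}

# film thickness trajectory in um: 0 before onset, saturating ramp after
film_trajectory <- function(profile, t) {
  d <- numeric(length(t))
  after <- t >= profile$film_onset_s
  d[after] <- profile$film_max_um *
    (1 - exp(-(t[after] - profile$film_onset_s) / profile$film_tau_s))
  d
}

#' Default film-drift curves per wavelength
#'
#' Maps film thickness (um) to the relative PPG baseline change per channel.
#' The parametric fallback mirrors the simulated reflectance trends: an
#' uptrend at 970 nm and a distinct opposite downtrend at 1450 nm (the water
#' band), with saturating dependence on thickness; 535 and 940 nm respond
#' weakly. A list of functions from [wavelength_trend_curve()] output can be
#' supplied to [generate_run()] instead.
#'
#' @return named list of functions `thickness_um -> relative change`.
#' @export
default_trend_curves <- function() {
  list(
    `535` = function(d) 0.005 * (1 - exp(-d / 150)),
    `940` = function(d) 0.015 * (1 - exp(-d / 150)),
    `970` = function(d) 0.05 * (1 - exp(-d / 150)),
    `1450` = function(d) -0.15 * (1 - exp(-d / 150))
  )
}

# deterministic pink-ish noise: sum of a few seeded random-phase slow sines
pink_noise <- function(n, fs, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  t <- seq_len(n) / fs
  f <- c(0.003, 0.007, 0.013, 0.027, 0.053, 0.11)
  x <- numeric(n)
  for (fi in f) x <- x + runif(1, 0.5, 1) / sqrt(fi) *
      sin(2 * pi * fi * t + runif(1, 0, 2 * pi))
  x / sd(x) * sd_target
}

#' Generate a synthetic multi-wavelength PPG + IMU run recording
#'
#' Each PPG channel is baseline + cardiac pulse train (fundamental at HR/60 Hz
#' with three harmonics at fixed relative amplitudes) + motion artifact
#' (components at the step frequency and arm-swing frequency,
#' amplitude-coupled to the IMU channels) + film drift (the film trajectory
#' mapped through the per-wavelength trend curve) + white and pink noise.
#' The IMU channels contain the same motion frequencies. All randomness is
#' governed by `seed`; metadata records the profile and the true onset time.
#'
#' @param profile a [run_profile()].
#' @param trend named list of per-wavelength drift curves
#'   ([default_trend_curves()] by default).
#' @param seed integer seed; the same seed reproduces the recording exactly.
#' @param channel_alias optional renaming of the 940 nm channel to `"645"`
#'   (the hardware description lists 645 nm where the dataset description
#'   lists 940 nm).
#' @return object of class `"ppg_recording"`: `data` (data.frame with
#'   `time_s`, `ppg_*`, `acc_*`, `gyr_*`), `fs`, and `meta` (seed, profile,
#'   true onset `t0_s`).
#' @export
generate_run <- function(profile = run_profile(),
                         trend = default_trend_curves(), seed = 1,
                         channel_alias = c("940", "645")) {
  channel_alias <- match.arg(channel_alias)
  wl <- c("535", "940", "970", "1450")
  if (!all(wl %in% names(trend)))
    stop("trend curves must be named for channels ",
         paste(wl, collapse = ", "))
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 7))

  fs <- profile$fs
  n <- floor(profile$duration_s * fs) + 1L
  t <- (seq_len(n) - 1L) / fs

  hr <- profile$hr_rest_bpm + (profile$hr_peak_bpm - profile$hr_rest_bpm) *
    (1 - exp(-t / profile$hr_tau_s)) + 2 * sin(2 * pi * t / 90)
  phase <- cumsum(hr / 60) / fs
  harm <- c(1, 0.4, 0.15)
  pulse <- Reduce(`+`, lapply(seq_along(harm), function(h)
    harm[h] * sin(2 * pi * h * phase + (h - 1) * 0.8)))

  # cadence ramps in over the first minute of running
  envelope <- pmin(1, t / 60)
  f_step <- profile$cadence_spm / 60
  f_swing <- profile$arm_swing_hz
  ph_step <- runif(1, 0, 2 * pi); ph_swing <- runif(1, 0, 2 * pi)
  step_wave <- envelope * sin(2 * pi * f_step * t + ph_step)
  swing_wave <- envelope * sin(2 * pi * f_swing * t + ph_swing)

  film <- film_trajectory(profile, t)

  dat <- data.frame(time_s = t)
  for (w in wl) {
    drift <- trend[[w]](film)
    x <- 1 + drift +
      profile$cardiac_amp * pulse +
      profile$motion_amp * (step_wave + 0.7 * swing_wave) +
      rnorm(n, sd = profile$noise_sd) +
      pink_noise(n, fs, profile$pink_sd)
    nm <- if (w == "940" && channel_alias == "645") "645" else w
    dat[[paste0("ppg_", nm)]] <- x * 1e4  # arbitrary ADC counts
  }
  dat$acc_x <- 9.81 + 2.0 * step_wave + 0.5 * swing_wave + rnorm(n, sd = 0.05)
  dat$acc_y <- 1.5 * step_wave + 0.8 * swing_wave + rnorm(n, sd = 0.05)
  dat$acc_z <- 0.8 * step_wave + 0.3 * swing_wave + rnorm(n, sd = 0.05)
  dat$gyr_x <- 0.9 * swing_wave + 0.2 * step_wave + rnorm(n, sd = 0.02)
  dat$gyr_y <- 1.2 * swing_wave + 0.1 * step_wave + rnorm(n, sd = 0.02)
  dat$gyr_z <- 0.4 * swing_wave + rnorm(n, sd = 0.02)

  structure(list(
    data = dat, fs = fs,
    meta = list(seed = seed, t0_s = profile$film_onset_s,
                f_step_hz = f_step, f_swing_hz = f_swing,
                profile = unclass(profile))
  ), class = "ppg_recording")
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat(sprintf("<ppg_recording> %.1f min at %g Hz, %d channels (seed %s, t0 = %g s)\n",
              max(x$data$time_s) / 60, x$fs, ncol(x$data) - 1L,
              x$meta$seed %||% "?", x$meta$t0_s %||% NA))
  invisible(x)
}

#' Write / read a run recording (CSV + JSON sidecar)
#'
#' The channel table goes to `path` as plain CSV; metadata (seed, sampling
#' rate, true onset, profile) goes to `<path>.json`. The round trip is
#' lossless for all channels and metadata.
#'
#' @param recording a `ppg_recording`.
#' @param path CSV file path.
#' @return `write_recording`: `path`, invisibly. `read_recording`: the
#'   recording.
#' @export
write_recording <- function(recording, path) {
  write.csv(recording$data, path, row.names = FALSE)
  meta <- recording$meta
  meta$fs <- recording$fs
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dat <- read.csv(path, check.names = FALSE)
  required <- c("time_s", "acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
  missing_cols <- setdiff(required, names(dat))
  if (length(missing_cols))
    stop("recording is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!any(grepl("^ppg_", names(dat))))
    stop("recording is missing required column(s): ppg_*")
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  fs_data <- 1 / median(diff(dat$time_s))
  fs <- meta$fs %||% fs_data
  if (abs(fs - fs_data) > 1e-6 * fs)
    stop("sampling-rate mismatch: header says ", fs, " Hz, data spacing implies ",
         signif(fs_data, 6), " Hz")
  meta$fs <- NULL
  structure(list(data = dat, fs = fs, meta = meta), class = "ppg_recording")
}

#' PPG channel accessor
#'
#' @param recording a `ppg_recording`.
#' @param wavelength channel wavelength label (e.g. 1450).
#' @return numeric vector of samples.
#' @export
ppg_channel <- function(recording, wavelength) {
  nm <- paste0("ppg_", wavelength)
  if (!nm %in% names(recording$data))
    stop("unknown PPG channel: ", wavelength, " (have: ",
         paste(sub("^ppg_", "", grep("^ppg_", names(recording$data),
                                     value = TRUE)), collapse = ", "), ")")
  recording$data[[nm]]
}
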