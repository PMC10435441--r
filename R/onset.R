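#' Smoothed trend-slope series of a PPG channel
#'
#' Moving-average smoothing followed by a rolling least-squares slope, both
#' over the same window (the study found 2--5 min smoothing optimal; default
#' 3 min). The slope is reported in signal units per minute and additionally
#' normalized by its per-run robust scale (median absolute deviation), which
#' makes the onset rule invariant to affine rescaling of the channel.
#'
#' @param x numeric signal (raw PPG channel).
#' @param fs sampling rate, Hz.
#' @param smooth_s smoothing window, s (default 180, within the 120--300 s
#'   optimum).
#' @return object of class `"trend_series"`: `time_s` (trimmed to where the
#'   centered windows fit), `smoothed`, `slope` (units/min),
#'   `normalized_slope`, `smooth_s`, `fs`.
#' @export
trend_series <- function(x, fs = 25, smooth_s = 180) {
  n <- length(x)
  if (smooth_s <= 0) stop("smoothing window must be > 0")
  k <- round(smooth_s * fs)
  if (n <= 2 * k) stop("recording must be longer than twice the smoothing window")
  if (k %% 2 == 0) k <- k + 1L
  h <- (k - 1L) %/% 2L

  csum <- function(v) { s <- cumsum(v); c(s[k:n] - c(0, s[seq_len(n - k)])) }
  sm_full <- csum(x) / k                    # centers h+1 .. n-h of x
  m <- length(sm_full)
  # rolling LS slope of the smoothed series over the same k-sample window
  valid <- m - k + 1L                       # centers 2h+1 .. n-2h of x
  j <- seq_len(k) - (k + 1) / 2             # centered sample index
  denom <- sum(j^2)
  s1 <- cumsum(sm_full)
  s2 <- cumsum(sm_full * seq_len(m))
  win_sum <- s1[k:m] - c(0, s1[seq_len(m - k)])
  win_jsum <- s2[k:m] - c(0, s2[seq_len(m - k)])
  centers <- seq_len(valid) + h             # index into sm_full of window center
  # sum(j * y) with j centered: win_jsum - center_index * win_sum
  slope_per_sample <- (win_jsum - centers * win_sum) / denom
  slope <- slope_per_sample * fs * 60       # units per minute

  scale <- mad(slope)
  ns <- if (scale > 1e-12) (slope - 0) / scale else slope * 0
  idx <- seq_len(valid) + 2L * h            # original sample index of centers
  structure(list(time_s = (idx - 1L) / fs,
                 smoothed = sm_full[centers], slope = slope,
                 normalized_slope = ns, smooth_s = smooth_s, fs = fs),
            class = "trend_series")
}

#' @export
print.trend_series <- function(x, ...) {
  cat(sprintf("<trend_series> %d points, %.0f s smoothing, slope range [%.3g, %.3g] units/min\n",
              length(x$slope), x$smooth_s, min(x$slope), max(x$slope)))
  invisible(x)
}

#' Call the sweat-film onset from a trend-slope series
#'
#' Onset is the first time the normalized slope keeps the expected sign and
#' stays beyond the threshold for at least `sustain_s` seconds. The 1450 nm
#' channel is the intended input (best water-band SNR); its expected
#' direction under film formation is negative (reflectance downtrend).
#'
#' @param trend a [trend_series()].
#' @param direction expected sign of the sustained slope, `-1` or `+1`.
#' @param threshold normalized-slope magnitude that must be exceeded
#'   (robust-scale units; default 2).
#' @param sustain_s minimum time the exceedance must persist, s (default 60).
#' @return object of class `"onset_call"`: `onset_s` (or `NA` if never),
#'   `direction`, `confidence` (fraction of points beyond threshold within
#'   the sustained window).
#' @export
detect_onset <- function(trend, direction = -1, threshold = 2,
                         sustain_s = 60) {
  stopifnot(inherits(trend, "trend_series"))
  if (!direction %in% c(-1, 1)) stop("direction must be -1 or +1")
  ns <- trend$normalized_slope
  ok <- sign(ns) == direction & abs(ns) >= threshold
  need <- max(1L, round(sustain_s * trend$fs))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit))
    return(structure(list(onset_s = NA_real_, direction = direction,
                          confidence = 0, threshold = threshold,
                          sustain_s = sustain_s), class = "onset_call"))
  i0 <- starts[hit[1]]
  win <- i0:min(length(ns), i0 + max(need, round(trend$smooth_s * trend$fs)))
  structure(list(onset_s = trend$time_s[i0], direction = direction,
                 confidence = mean(ok[win]), threshold = threshold,
                 sustain_s = sustain_s), class = "onset_call")
}

#' @export
print.onset_call <- function(x, ...) {
  if (is.na(x$onset_s)) cat("<onset_call> no onset detected\n")
  else cat(sprintf("<onset_call> onset at %.0f s (direction %+d, confidence %.2f)\n",
                   x$onset_s, x$direction, x$confidence))
  invisible(x)
}

#' Cohort-aggregated trend-slope surface
#'
#' Time-binned mean normalized slope, averaged within groups of subjects
#' (the study averaged over 5-minute windows and groups of 5 subjects),
#' yielding a (group x time-bin) surface.
#'
#' @param trends list of [trend_series()] objects, one per trial.
#' @param bin_s averaging window, s (default 300).
#' @param per_group number of trials per subject group (default 5).
#' @return matrix (groups x time bins) of mean normalized slope; dimnames
#'   carry group indices and bin start times.
#' @export
aggregate_trials <- function(trends, bin_s = 300, per_group = 5) {
  if (!length(trends)) stop("need at least one trend series")
  groups <- split(seq_along(trends),
                  ceiling(seq_along(trends) / per_group))
  t_max <- max(vapply(trends, function(tr) max(tr$time_s), 0))
  breaks <- seq(0, t_max + bin_s, by = bin_s)
  nb <- length(breaks) - 1L
  surf <- matrix(NA_real_, length(groups), nb,
                 dimnames = list(paste0("group_", seq_along(groups)),
                                 paste0("t_", breaks[-length(breaks)], "s")))
  for (gi in seq_along(groups)) {
    members <- groups[[gi]]
    if (!length(members)) { warning("empty group ", gi, " skipped"); next }
    acc <- matrix(0, length(members), nb); cnt <- acc
    for (mi in seq_along(members)) {
      tr <- trends[[members[mi]]]
      bin <- findInterval(tr$time_s, breaks, rightmost.closed = TRUE)
      ok <- bin >= 1 & bin <= nb
      acc[mi, ] <- vapply(seq_len(nb), function(b)
        sum(tr$normalized_slope[ok & bin == b]), 0)
      cnt[mi, ] <- vapply(seq_len(nb), function(b) sum(ok & bin == b), 0)
    }
    tot <- colSums(cnt)
    surf[gi, tot > 0] <- colSums(acc)[tot > 0] / tot[tot > 0]
  }
  surf
}
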