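#' Euclidean norm of the triaxial acceleration signal
#'
#' The per-sample magnitude of the 3-axis acceleration vector. The norm is
#' invariant to sensor orientation, which is why all detectors in this
#' package operate on it rather than on individual axes: at the wrist the
#' axis orientations change constantly with free arm movement.
#'
#' @param recording a `gsd_recording`, or an N x 3 numeric matrix.
#' @return numeric vector of length N, in g.
#' @export
accel_norm <- function(recording) {
  acc <- if (inherits(recording, "gsd_recording")) recording$acc else as.matrix(recording)
  sqrt(rowSums(acc^2))
}

#' Zero-phase Butterworth-magnitude filter
#'
#' Filters a series in the frequency domain with the squared-magnitude
#' response of a Butterworth design, `|H(f)|^2 = 1 / (1 + (f/fc)^(2*order))`
#' for a low pass (high pass mirrored, band pass as a product of the two).
#' Because the response is applied with zero phase, event times are not
#' shifted: a symmetric pulse keeps its peak location. The series is
#' reflection-padded before the transform to suppress edge wrap-around.
#'
#' @param x numeric series.
#' @param fs sampling frequency in Hz.
#' @param kind one of `"lowpass"`, `"highpass"`, `"bandpass"`.
#' @param cutoff_hz one cutoff (low/high pass) or two (band pass); all must
#'   lie in (0, fs/2).
#' @param order filter order (>= 1), default 4.
#' @return filtered numeric series of the same length.
#' @export
filter_series <- function(x, fs, kind = c("lowpass", "highpass", "bandpass"),
                          cutoff_hz, order = 4L) {
  kind <- match.arg(kind)
  if (order < 1) stop("filter order must be >= 1")
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= fs / 2))
    stop("cutoffs must lie strictly between 0 and the Nyquist frequency")
  n_expect <- if (kind == "bandpass") 2L else 1L
  if (length(cutoff_hz) != n_expect)
    stop(sprintf("%s needs %d cutoff value(s)", kind, n_expect))
  n <- length(x)
  if (n < 4L) return(x)
  # reflection padding, capped so short series still work
  pad <- min(n - 1L, max(64L, ceiling(2 * fs / min(cutoff_hz))))
  xp <- c(rev(x[2L:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  m <- length(xp)
  f <- (seq_len(m) - 1L) / m * fs
  f <- pmin(f, fs - f)  # two-sided frequency axis
  resp <- switch(kind,
    lowpass  = 1 / sqrt(1 + (f / cutoff_hz)^(2 * order)),
    highpass = {
      r <- rep(0, m); nz <- f > 0
      r[nz] <- 1 / sqrt(1 + (cutoff_hz / f[nz])^(2 * order)); r
    },
    bandpass = {
      r <- rep(0, m); nz <- f > 0
      r[nz] <- 1 / sqrt(1 + (cutoff_hz[1L] / f[nz])^(2 * order)) /
        sqrt(1 + (f[nz] / cutoff_hz[2L])^(2 * order)); r
    })
  y <- Re(stats::fft(stats::fft(xp) * resp, inverse = TRUE)) / m
  y[(pad + 1L):(pad + n)]
}

#' Centered moving statistic
#'
#' Computes a centered moving mean, standard deviation or RMS over a window
#' of `window_s` seconds. At the edges the window shrinks so the output has
#' the same length as the input.
#'
#' @param x numeric series.
#' @param window_s window length in seconds (>= one sample).
#' @param fs sampling frequency in Hz.
#' @param stat one of `"mean"`, `"sd"`, `"rms"`.
#' @return numeric series of the same length as `x`.
#' @export
moving_stat <- function(x, window_s, fs, stat = c("mean", "sd", "rms")) {
  stat <- match.arg(stat)
  n <- length(x)
  w <- max(1L, round(window_s * fs))
  if (w < 1L) stop("window must span at least one sample")
  h_lo <- (w - 1L) %/% 2L
  h_hi <- w - 1L - h_lo
  i <- seq_len(n)
  lo <- pmax(1L, i - h_lo)
  hi <- pmin(n, i + h_hi)
  cnt <- hi - lo + 1L
  cs1 <- cumsum(c(0, x))
  s1 <- cs1[hi + 1L] - cs1[lo]
  if (stat == "mean") return(s1 / cnt)
  cs2 <- cumsum(c(0, x^2))
  s2 <- cs2[hi + 1L] - cs2[lo]
  if (stat == "rms") return(sqrt(pmax(0, s2 / cnt)))
  # unbiased sd; windows of one sample get 0
  v <- (s2 - s1^2 / cnt) / pmax(1L, cnt - 1L)
  v[cnt == 1L] <- 0
  sqrt(pmax(0, v))
}

#' Estimate the vertical (gravity-aligned) acceleration component
#'
#' Estimates the slowly varying gravity direction by low-pass filtering each
#' axis at `gravity_cutoff_hz` and projects the raw acceleration onto that
#' unit direction per sample. On a static recording this returns ~1 g
#' regardless of orientation.
#'
#' @param recording a `gsd_recording` of duration > `4 / gravity_cutoff_hz`.
#' @param gravity_cutoff_hz low-pass cutoff for the gravity estimate (Hz).
#' @return numeric vector of per-sample vertical acceleration in g.
#' @export
estimate_vertical <- function(recording, gravity_cutoff_hz = 0.25) {
  dur <- rec_duration(recording)
  if (dur <= 4 / gravity_cutoff_hz)
    stop(sprintf("recording too short for gravity estimation (need > %.1f s)",
                 4 / gravity_cutoff_hz))
  acc <- recording$acc
  g <- vapply(1:3, function(j)
    filter_series(acc[, j], recording$fs, "lowpass", gravity_cutoff_hz, order = 2L),
    numeric(nrow(acc)))
  gn <- sqrt(rowSums(g^2))
  gn[gn < 1e-9] <- 1e-9
  rowSums(acc * g) / gn
}

#' Resample a recording to a target sampling frequency
#'
#' Linear-interpolation resampling onto a uniform grid at `target_fs`, with a
#' zero-phase anti-aliasing low pass when downsampling. Detector parameters
#' in this package assume 100 Hz.
#'
#' @param recording a `gsd_recording`.
#' @param target_fs target sampling frequency in Hz.
#' @return a `gsd_recording` at `target_fs`.
#' @export
resample_recording <- function(recording, target_fs = 100) {
  if (abs(recording$fs - target_fs) < 1e-9) return(recording)
  acc <- recording$acc
  t_old <- rec_times(recording)
  if (target_fs < recording$fs) {
    cut <- 0.45 * target_fs
    acc <- vapply(1:3, function(j)
      filter_series(acc[, j], recording$fs, "lowpass", cut, order = 6L),
      numeric(nrow(acc)))
  }
  t_new <- seq(0, t_old[length(t_old)], by = 1 / target_fs)
  acc_new <- vapply(1:3, function(j)
    stats::approx(t_old, acc[, j], xout = t_new, rule = 2)$y, numeric(length(t_new)))
  new_recording(acc_new, target_fs, recording$subject_id, recording$group, recording$meta)
}

#' Per-epoch activity counts
#'
#' An open reconstruction of actigraphy-style activity counts: each axis is
#' band-pass filtered (0.29-1.63 Hz by default, the band used by the
#' published open count reconstruction; the vendor algorithm is proprietary),
#' rectified, dead-banded, clipped at a saturation level and accumulated over
#' epochs; the per-epoch vector magnitude across axes is returned.
#'
#' @param recording a `gsd_recording`.
#' @param epoch_s epoch length in seconds (>= one sample period).
#' @param band two band-pass cutoffs in Hz.
#' @param deadband_g rectified values below this are zeroed.
#' @param clip_g rectified values are clipped at this level.
#' @return non-negative numeric vector, one count value per epoch.
#' @export
activity_counts <- function(recording, epoch_s = 1.0,
                            band = c(0.29, 1.63), deadband_g = 0.002,
                            clip_g = 2.0) {
  fs <- recording$fs
  if (epoch_s < 1 / fs) stop("epoch_s must be at least one sample period")
  n <- nrow(recording$acc)
  ep <- floor((seq_len(n) - 1L) / (epoch_s * fs)) + 1L
  n_ep <- max(ep)
  per_axis <- vapply(1:3, function(j) {
    y <- filter_series(recording$acc[, j], fs, "bandpass", band, order = 4L)
    y <- abs(y)
    y[y < deadband_g] <- 0
    y <- pmin(y, clip_g)
    as.numeric(tapply(y, ep, sum))
  }, numeric(n_ep))
  sqrt(rowSums(per_axis^2))
}

#' Local maxima above a height threshold with a minimum separation
#'
#' Strict local maxima of `x` with `x > height`, thinned greedily by
#' descending height so that surviving peaks are at least `min_dist_s`
#' apart. Used by the peak-based detectors.
#'
#' @param x numeric series.
#' @param fs sampling frequency in Hz.
#' @param height minimum peak height (strict).
#' @param min_dist_s minimum separation between surviving peaks in seconds.
#' @return integer vector of peak sample indices (sorted).
#' @export
find_peaks <- function(x, fs, height = -Inf, min_dist_s = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  cand <- i[x[i] > x[i - 1L] & x[i] >= x[i + 1L] & x[i] > height]
  if (!length(cand) || min_dist_s <= 0) return(cand)
  min_gap <- min_dist_s * fs
  o <- cand[order(-x[cand])]
  keep <- logical(length(x))
  taken <- rep(FALSE, length(x))
  for (p in o) {
    lo <- max(1L, ceiling(p - min_gap)); hi <- min(n, floor(p + min_gap))
    if (!any(taken[lo:hi])) {
      keep[p] <- TRUE
      taken[p] <- TRUE
    }
  }
  which(keep)
}
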