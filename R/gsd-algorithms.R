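#' Gait detection from step peaks of the acceleration norm
#'
#' Step-based locomotion detection: the acceleration norm has gravity (1 g)
#' subtracted, is zero-phase low-pass filtered at `smooth_cutoff_hz`, and
#' local maxima higher than `th` with a minimum separation of 0.25 s are
#' taken as steps. Steps are assembled into gait sequences with the 3-second
#' rule. All thresholds are in g.
#'
#' @param recording a `gsd_recording`.
#' @param th step-peak threshold in g. The lower-back defaults are 0.1 and
#'   0.15; the wrist-optimized value is 0.35.
#' @param max_step_gap_s assembly gap (s).
#' @param min_steps minimum steps per gait sequence.
#' @param smooth_cutoff_hz low-pass cutoff (Hz).
#' @param min_peak_dist_s minimum separation between step peaks (s).
#' @return a `gs_list`.
#' @export
detect_paraschiv2019 <- function(recording, th = 0.1, max_step_gap_s = 3.0,
                                 min_steps = 3L, smooth_cutoff_hz = 3.5,
                                 min_peak_dist_s = 0.25) {
  if (th <= 0) stop("th must be > 0")
  x <- accel_norm(recording) - 1
  x <- filter_series(x, recording$fs, "lowpass", smooth_cutoff_hz)
  pk <- find_peaks(x, recording$fs, height = th, min_dist_s = min_peak_dist_s)
  if (!length(pk)) return(gs_list(source = "paraschiv2019"))
  assemble_gs_from_events(step_events((pk - 1L) / recording$fs),
                          max_gap_s = max_step_gap_s, min_events = min_steps,
                          source = "paraschiv2019")
}

#' Gait detection with iterative enhancement and a data-adaptive threshold
#'
#' Extension of the step-based detector: the detrended, low-pass filtered
#' norm passes `n_smooth_iters` rounds of moving-average smoothing followed
#' by an amplitude-normalized signed-square enhancement
#' (`sign(x) * x^2 / rms(x)`), which sharpens step peaks while preserving
#' scale. The step threshold is then set per recording as the
#' `adapt_quantile` quantile of the peak heights of a permissive pass,
#' floored at `adapt_floor_g` so a rest-only recording yields nothing.
#'
#' @inheritParams detect_paraschiv2019
#' @param n_smooth_iters smoothing/enhancement rounds (default 2).
#' @param adapt_quantile quantile of permissive-pass peak heights used as
#'   threshold (default 0.1).
#' @param adapt_floor_g lower bound of the adaptive threshold in g.
#' @param smooth_window_s moving-average window per round (s).
#' @return a `gs_list`.
#' @export
detect_paraschiv2020 <- function(recording, n_smooth_iters = 2L,
                                 adapt_quantile = 0.1, adapt_floor_g = 0.05,
                                 max_step_gap_s = 3.0, min_steps = 3L,
                                 smooth_cutoff_hz = 3.5, min_peak_dist_s = 0.25,
                                 smooth_window_s = 0.1) {
  if (adapt_quantile <= 0 || adapt_quantile >= 1)
    stop("adapt_quantile must be in (0, 1)")
  fs <- recording$fs
  x <- accel_norm(recording) - 1
  x <- filter_series(x, fs, "lowpass", smooth_cutoff_hz)
  for (i in seq_len(n_smooth_iters)) {
    x <- moving_stat(x, smooth_window_s, fs, "mean")
    r <- sqrt(mean(x^2))
    x <- sign(x) * x^2 / max(r, 1e-9)
  }
  pk_all <- find_peaks(x, fs, height = 0, min_dist_s = min_peak_dist_s)
  if (!length(pk_all)) return(gs_list(source = "paraschiv2020"))
  th <- max(adapt_floor_g,
            stats::quantile(x[pk_all], adapt_quantile, names = FALSE))
  pk <- pk_all[x[pk_all] > th]
  if (!length(pk)) return(gs_list(source = "paraschiv2020"))
  assemble_gs_from_events(step_events((pk - 1L) / fs),
                          max_gap_s = max_step_gap_s, min_events = min_steps,
                          source = "paraschiv2020")
}

#' Gait detection by convolution with a sinusoidal gait-cycle template
#'
#' The gravity-subtracted norm is convolved (raw inner product) with a
#' single-period sine template of duration `template_len`; local maxima of
#' the absolute convolution above `cm_norm_thres`, gated by a moving-variance
#' activity test, mark gait instants. Instants are assembled with the
#' 3-second rule and bouts shorter than `min_bout_length` are discarded.
#'
#' @param recording a `gsd_recording`.
#' @param activity_thres moving-variance gate in g^2 (default 0.01;
#'   wrist-optimized 0.04).
#' @param min_bout_length minimum bout duration in s (default 5; optimized 10).
#' @param template_len template duration in s (default 0.5; optimized 1).
#' @param cm_norm_thres convolution-maxima threshold (default 0.4;
#'   optimized 2.5).
#' @param max_gap_s assembly gap (s).
#' @return a `gs_list`.
#' @export
detect_iluz <- function(recording, activity_thres = 0.01, min_bout_length = 5,
                        template_len = 0.5, cm_norm_thres = 0.4,
                        max_gap_s = 3.0) {
  if (activity_thres <= 0 || min_bout_length <= 0 || template_len <= 0 ||
      cm_norm_thres <= 0)
    stop("all iluz parameters must be > 0")
  fs <- recording$fs
  x <- accel_norm(recording) - 1
  k <- max(4L, round(template_len * fs))
  tmpl <- sin(2 * pi * seq(0, 1, length.out = k))
  conv <- stats::filter(x, rev(tmpl), method = "convolution", sides = 2)
  conv[is.na(conv)] <- 0
  gate <- moving_stat(x, template_len, fs, "sd")^2 > activity_thres
  pk <- find_peaks(abs(as.numeric(conv)), fs, height = cm_norm_thres,
                   min_dist_s = template_len / 2)
  pk <- pk[gate[pk]]
  if (length(pk) < 2L) return(gs_list(source = "iluz"))
  gs <- assemble_gs_from_events(step_events((pk - 1L) / fs),
                                max_gap_s = max_gap_s, min_events = 2L,
                                source = "iluz")
  keep <- (gs$end_s - gs$start_s) >= min_bout_length
  gs_list(gs$start_s[keep], gs$end_s[keep], source = "iluz")
}

#' Gait detection from thresholded peaks of the acceleration norm
#'
#' Candidate peaks are the maxima of the norm within consecutive blocks of
#' `verisense_k` samples, debounced to a 0.25 s minimum separation. A
#' candidate is a step if (a) its magnitude exceeds `mag_thres`, (b) its
#' amplitude is similar to a neighboring candidate (negated absolute
#' difference in g at least `sim_thres`), and (c) it belongs to a run of at
#' least `cont_thres` consecutive candidates with plausible periodicity
#' (inter-peak intervals within 0.25-2.0 s). Steps are assembled with the
#' 3-second rule.
#'
#' @param recording a `gsd_recording`.
#' @param verisense_k candidate block length in samples (default 3;
#'   optimized 2).
#' @param sim_thres similarity threshold, negated absolute amplitude
#'   difference in g (default -0.5; optimized -0.8).
#' @param cont_thres minimum run length of periodic candidates (default 4).
#' @param mag_thres magnitude threshold on the raw norm in g (default 1.2).
#' @param period_range_s plausible inter-step interval range (s).
#' @param max_gap_s assembly gap (s).
#' @param min_steps minimum steps per gait sequence.
#' @return a `gs_list`.
#' @export
detect_gu <- function(recording, verisense_k = 3L, sim_thres = -0.5,
                      cont_thres = 4L, mag_thres = 1.2,
                      period_range_s = c(0.25, 2.0), max_gap_s = 3.0,
                      min_steps = 3L) {
  if (verisense_k < 1 || cont_thres < 1 || mag_thres <= 0)
    stop("invalid gu parameters")
  fs <- recording$fs
  x <- accel_norm(recording)
  n <- length(x)
  blk <- floor((seq_len(n) - 1L) / verisense_k)
  # index of the maximum within each block
  o <- order(blk, x)
  cand <- o[!duplicated(blk[o], fromLast = TRUE)]
  cand <- sort(cand)
  cand <- cand[x[cand] > mag_thres]
  # debounce: candidates closer than 0.25 s collapse to the strongest
  if (length(cand) > 1L) {
    keep <- logical(length(cand))
    cur <- 1L
    for (i in seq_along(cand)[-1L]) {
      if ((cand[i] - cand[cur]) / fs < period_range_s[1L]) {
        if (x[cand[i]] > x[cand[cur]]) cur <- i
      } else {
        keep[cur] <- TRUE; cur <- i
      }
    }
    keep[cur] <- TRUE
    cand <- cand[keep]
  }
  if (length(cand) < 2L) return(gs_list(source = "gu"))
  amp <- x[cand]
  d_prev <- c(Inf, abs(diff(amp)))
  d_next <- c(abs(diff(amp)), Inf)
  sim_ok <- (-d_prev >= sim_thres) | (-d_next >= sim_thres)
  cand <- cand[sim_ok]
  if (length(cand) < 2L) return(gs_list(source = "gu"))
  iv <- diff(cand) / fs
  periodic <- iv >= period_range_s[1L] & iv <= period_range_s[2L]
  run_id <- cumsum(c(0, as.numeric(!periodic)))
  steps <- numeric(0)
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    if (length(idx) >= cont_thres) steps <- c(steps, (cand[idx] - 1L) / fs)
  }
  if (length(steps) < 2L) return(gs_list(source = "gu"))
  out <- assemble_gs_from_events(step_events(steps), max_gap_s = max_gap_s,
                                 min_events = min_steps, source = "gu")
  attr(out, "steps") <- steps
  out
}

#' Stride templates for the template-matching detector
#'
#' Default templates: a one-period sine, and a sine mixed with a
#' step-frequency harmonic, both standardized to zero mean and unit
#' standard deviation at `len` samples.
#'
#' @param len template length in samples.
#' @return list of standardized numeric templates.
#' @export
karas_default_templates <- function(len = 100L) {
  th <- 2 * pi * seq(0, 1, length.out = len)
  lapply(list(sin(th), sin(th) + 0.8 * cos(2 * th)),
         function(x) (x - mean(x)) / stats::sd(x))
}

#' Template-matching stride detection (adaptive empirical pattern style)
#'
#' For each candidate duration on a grid over `[dur_MIN, dur_MAX]`, the
#' correlation between the rescaled template and the norm segment is
#' computed at every onset; non-overlapping strides with similarity at least
#' `sim_MIN` are accepted greedily (highest similarity first, earlier onset
#' on ties). Strides with peak-to-peak outside `[ptp_r_MIN, ptp_r_MAX]` are
#' rejected, and runs of consecutive strides whose mean absolute deviation
#' of per-stride median peak value, median trough value or duration exceeds
#' the corresponding bound are rejected. Surviving strides are assembled
#' with the 3-second rule.
#'
#' @param recording a `gsd_recording`.
#' @param sim_MIN minimum correlation (default 0.85; optimized 0.3).
#' @param dur_MIN,dur_MAX stride duration bounds in s (defaults 0.8/1.4;
#'   optimized 0.2/3.0).
#' @param ptp_r_MIN,ptp_r_MAX stride peak-to-peak bounds in g (defaults
#'   0.2/2.0; optimized 0.2/3.0).
#' @param mean_abs_diff_med_p_MAX,mean_abs_diff_med_t_MAX,mean_abs_diff_dur_MAX
#'   run-consistency bounds on median peak, median trough and duration
#'   (defaults 0.5/0.2/0.2; optimized all 0.5).
#' @param templates list of numeric stride patterns
#'   (default [karas_default_templates()]).
#' @param dur_step_s duration grid step in s (default 0.05).
#' @param smooth_window_s moving-average smoothing window applied to the
#'   norm before matching (s), as in the original adaptive empirical
#'   pattern method; suppresses impact transients so whole-stride
#'   correlations dominate.
#' @param max_gap_s assembly gap (s).
#' @return a `gs_list`; the accepted strides are attached as the
#'   `"strides"` attribute.
#' @export
detect_karas <- function(recording, sim_MIN = 0.85, dur_MIN = 0.8,
                         dur_MAX = 1.4, ptp_r_MIN = 0.2, ptp_r_MAX = 2.0,
                         mean_abs_diff_med_p_MAX = 0.5,
                         mean_abs_diff_med_t_MAX = 0.2,
                         mean_abs_diff_dur_MAX = 0.2,
                         templates = NULL, dur_step_s = 0.05,
                         smooth_window_s = 0.15, max_gap_s = 3.0) {
  if (dur_MIN >= dur_MAX) stop("dur_MIN must be < dur_MAX")
  if (ptp_r_MIN >= ptp_r_MAX) stop("ptp_r_MIN must be < ptp_r_MAX")
  if (sim_MIN < -1 || sim_MIN > 1) stop("sim_MIN must be in [-1, 1]")
  if (is.null(templates)) templates <- karas_default_templates()
  if (!length(templates)) stop("at least one template is required")
  fs <- recording$fs
  x <- accel_norm(recording) - 1
  if (smooth_window_s > 0) x <- moving_stat(x, smooth_window_s, fs, "mean")
  n <- length(x)
  durs <- seq(dur_MIN, dur_MAX, by = dur_step_s)
  # rolling mean/sd of x for every window length via cumsums
  cs1 <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  k_max <- min(n, round(max(durs) * fs))
  m_fft <- stats::nextn(n + k_max, 2)
  x_fft <- stats::fft(c(x, rep(0, m_fft - n)))
  cand_on <- integer(0); cand_len <- integer(0); cand_sim <- numeric(0)
  for (d in durs) {
    k <- round(d * fs)
    if (k < 4L || k > n) next
    n_on <- n - k + 1L
    on <- seq_len(n_on)
    s1 <- cs1[on + k] - cs1[on]
    s2 <- cs2[on + k] - cs2[on]
    sx <- sqrt(pmax(1e-18, (s2 - s1^2 / k) / (k - 1)))
    for (tm in templates) {
      tmk <- stats::approx(seq_along(tm), tm, n = k)$y
      tmk <- (tmk - mean(tmk)) / stats::sd(tmk)
      # rolling dot product as FFT cross-correlation; dp[i] is onset i
      t_fft <- stats::fft(c(rev(tmk), rep(0, m_fft - k)))
      dp_full <- Re(stats::fft(x_fft * t_fft, inverse = TRUE)) / m_fft
      dp <- dp_full[k:n]
      r <- dp / ((k - 1) * sx)
      # local maxima of similarity, thinned to half a stride
      pk <- find_peaks(r, fs, height = sim_MIN, min_dist_s = d / 2)
      if (length(pk)) {
        cand_on <- c(cand_on, pk)
        cand_len <- c(cand_len, rep(k, length(pk)))
        cand_sim <- c(cand_sim, r[pk])
      }
    }
  }
  if (!length(cand_on)) return(gs_list(source = "karas"))
  # greedy non-overlapping acceptance: highest similarity, then earlier onset
  o <- order(-cand_sim, cand_on)
  acc_s <- acc_e <- numeric(0)
  for (i in o) {
    s <- cand_on[i]; e <- cand_on[i] + cand_len[i] - 1L
    if (!length(acc_s) || !any(s <= acc_e & e >= acc_s)) {
      acc_s <- c(acc_s, s); acc_e <- c(acc_e, e)
    }
  }
  o2 <- order(acc_s)
  acc_s <- acc_s[o2]; acc_e <- acc_e[o2]
  # per-stride features
  med_p <- med_t <- ptp <- numeric(length(acc_s))
  for (i in seq_along(acc_s)) {
    seg <- x[acc_s[i]:acc_e[i]]
    med_p[i] <- max(seg); med_t[i] <- min(seg); ptp[i] <- max(seg) - min(seg)
  }
  ok <- ptp >= ptp_r_MIN & ptp <= ptp_r_MAX
  acc_s <- acc_s[ok]; acc_e <- acc_e[ok]
  med_p <- med_p[ok]; med_t <- med_t[ok]
  if (length(acc_s) < 2L) return(gs_list(source = "karas"))
  dur <- (acc_e - acc_s + 1L) / fs
  # runs of consecutive strides (gap <= max_gap_s) must be internally consistent
  gaps <- (acc_s[-1L] - acc_e[-length(acc_e)]) / fs
  run_id <- cumsum(c(0, as.numeric(gaps > max_gap_s)))
  keep <- logical(length(acc_s))
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    if (length(idx) < 2L) next
    mad_ <- function(v) mean(abs(v - mean(v)))
    if (mad_(med_p[idx]) <= mean_abs_diff_med_p_MAX &&
        mad_(med_t[idx]) <= mean_abs_diff_med_t_MAX &&
        mad_(dur[idx]) <= mean_abs_diff_dur_MAX)
      keep[idx] <- TRUE
  }
  acc_s <- acc_s[keep]; acc_e <- acc_e[keep]
  if (length(acc_s) < 2L) return(gs_list(source = "karas"))
  strides <- stride_intervals((acc_s - 1L) / fs, (acc_e - 1L) / fs)
  out <- assemble_gs_from_events(strides, max_gap_s = max_gap_s,
                                 min_events = 2L, source = "karas")
  attr(out, "strides") <- strides
  out
}

#' Gait detection from windowed movement and uprightness gates
#'
#' Non-overlapping windows of `window_s` are classified as moving when the
#' combined standard deviation of the three axes exceeds `ThresholdStill`,
#' and as upright when the mean estimated vertical acceleration minus 1 g
#' exceeds `ThresholdUpright` (the printed -0.5 g makes this a permissive
#' gate at the wrist, where "upright" is poorly defined). Gait windows are
#' those both moving and upright; adjacent gait windows are merged and the
#' 3-second gap rule applied.
#'
#' @param recording a `gsd_recording`.
#' @param ThresholdStill combined-SD threshold in g (default 0.2).
#' @param ThresholdUpright vertical-mean threshold in g relative to 1 g
#'   (default -0.5).
#' @param window_s window length in s (default 0.1).
#' @param max_gap_s assembly gap (s).
#' @return a `gs_list`.
#' @export
detect_hickey <- function(recording, ThresholdStill = 0.2,
                          ThresholdUpright = -0.5, window_s = 0.1,
                          max_gap_s = 3.0) {
  if (window_s <= 0) stop("window_s must be > 0")
  fs <- recording$fs
  n <- nrow(recording$acc)
  win <- floor((seq_len(n) - 1L) / (window_s * fs)) + 1L
  n_win <- max(win)
  v_axis <- vapply(1:3, function(j) {
    m <- as.numeric(tapply(recording$acc[, j], win, mean))
    s2 <- as.numeric(tapply(recording$acc[, j], win, stats::var))
    s2[is.na(s2)] <- 0
    s2
  }, numeric(n_win))
  comb_sd <- sqrt(rowSums(v_axis))
  vert <- estimate_vertical(recording)
  vert_win <- as.numeric(tapply(vert, win, mean))
  gait_win <- comb_sd > ThresholdStill & (vert_win - 1) > ThresholdUpright
  idx <- which(gait_win)
  if (length(idx) < 2L) return(gs_list(source = "hickey"))
  w_start <- (idx - 1L) * window_s
  w_end <- pmin(idx * window_s, rec_duration(recording))
  merged <- merge_overlapping(w_start, w_end)
  assemble_gs_from_events(stride_intervals(merged$start_s, merged$end_s),
                          max_gap_s = max_gap_s, min_events = 2L,
                          source = "hickey")
}

#' Gait detection from activity counts with an adaptive level
#'
#' Activity counts per `epoch_s` epoch are compared against an adaptive
#' level, the median of the recording's nonzero epoch counts. An epoch is
#' classified as walking when the fraction of epochs in its centered window
#' of `window_epochs` epochs above the level exceeds `walking_threshold`.
#' Walking epochs are merged into gait sequences with the 3-second rule.
#'
#' @param recording a `gsd_recording`.
#' @param walking_threshold fraction in (0, 1] (default 0.75;
#'   optimized 0.6).
#' @param epoch_s epoch length in s (default 1).
#' @param window_epochs sliding-window length in epochs (default 10).
#' @param max_gap_s assembly gap (s).
#' @return a `gs_list`.
#' @export
detect_kheirkhahan <- function(recording, walking_threshold = 0.75,
                               epoch_s = 1.0, window_epochs = 10L,
                               max_gap_s = 3.0) {
  if (walking_threshold <= 0 || walking_threshold > 1)
    stop("walking_threshold must be in (0, 1]")
  counts <- activity_counts(recording, epoch_s = epoch_s)
  nz <- counts[counts > 0]
  if (!length(nz)) return(gs_list(source = "kheirkhahan"))
  level <- stats::median(nz)
  above <- as.numeric(counts > level)
  frac <- moving_stat(above, window_epochs, 1, "mean")
  walking <- which(frac > walking_threshold)
  if (length(walking) < 2L) return(gs_list(source = "kheirkhahan"))
  w_start <- (walking - 1L) * epoch_s
  w_end <- walking * epoch_s
  dur <- rec_duration(recording)
  w_end <- pmin(w_end, dur)
  merged <- merge_overlapping(w_start, w_end)
  assemble_gs_from_events(stride_intervals(merged$start_s, merged$end_s),
                          max_gap_s = max_gap_s, min_events = 2L,
                          source = "kheirkhahan")
}
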