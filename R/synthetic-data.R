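#' Segment of a simulation schedule
#'
#' @param kind one of `"gait"`, `"rest"`, `"arm_activity"`.
#' @param duration_s segment duration in seconds (> 0).
#' @param step_freq_hz step frequency in Hz for gait segments (typical
#'   free-living range 1.4-2.3; the stride frequency is half of this).
#' @param swing_amp_g peak amplitude in g of the arm-swing oscillation for
#'   gait segments (typical 0.05-0.5).
#' @param noise_sd_g white-noise standard deviation per axis in g. Defaults
#'   by kind: 0.08 during gait (tissue vibration and jerk dominate real wrist
#'   signals during walking), 0.005 at rest, 0.02 during arm activity.
#' @param arm_amp_g RMS amplitude of the aperiodic arm-activity component.
#' @return a `sim_segment` list.
#' @export
sim_segment <- function(kind = c("gait", "rest", "arm_activity"), duration_s,
                        step_freq_hz = 1.9, swing_amp_g = 0.4,
                        noise_sd_g = NULL, arm_amp_g = 0.15) {
  kind <- match.arg(kind)
  if (duration_s <= 0) stop("segment duration must be > 0")
  if (swing_amp_g < 0) stop("swing amplitude must be >= 0")
  if (step_freq_hz <= 0) stop("step frequency must be > 0")
  if (is.null(noise_sd_g))
    noise_sd_g <- switch(kind, gait = 0.08, rest = 0.005, arm_activity = 0.02)
  structure(list(kind = kind, duration_s = duration_s,
                 step_freq_hz = step_freq_hz, swing_amp_g = swing_amp_g,
                 noise_sd_g = noise_sd_g, arm_amp_g = arm_amp_g),
            class = "sim_segment")
}

#' Simulation configuration
#'
#' Describes one synthetic wrist recording: a schedule of gait / rest /
#' arm-activity segments, an orientation drift rate, a walking-aid mode and
#' a seed. Generation is fully deterministic given the seed.
#'
#' @param schedule list of [sim_segment()] entries (non-empty).
#' @param fs sampling frequency in Hz (default 100).
#' @param drift_rate slow orientation drift of the gravity axis in rad/s
#'   (default 0.01): motivates norm-based (orientation-free) detection.
#' @param walking_aid_mode `"none"` or `"bilateral"`. Bilateral walking aids
#'   (rollators, walkers, two crutches) suppress arm swing; the mode
#'   multiplies the gait dynamic components by `suppression`.
#' @param suppression amplitude factor applied in bilateral mode (default 0.15).
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(schedule, fs = 100, drift_rate = 0.01,
                       walking_aid_mode = c("none", "bilateral"),
                       suppression = 0.15, seed = 1L) {
  walking_aid_mode <- match.arg(walking_aid_mode)
  if (!length(schedule)) stop("schedule must contain at least one segment")
  if (!all(vapply(schedule, inherits, logical(1), "sim_segment")))
    stop("schedule entries must be sim_segment objects")
  structure(list(schedule = schedule, fs = fs, drift_rate = drift_rate,
                 walking_aid_mode = walking_aid_mode,
                 suppression = suppression, seed = as.integer(seed)),
            class = "sim_config")
}

# Stride-cycle waveform: stride-frequency component plus a dominant
# step-frequency harmonic, normalized so the maximum is exactly +1 (reached
# twice per stride, once per step). theta is the stride phase in radians.
stride_waveform <- function(theta) {
  (0.6 * sin(theta) + 0.9 * cos(2 * theta)) / 0.95
}

# Stride phases (radians) of the two per-stride waveform peaks.
step_peak_phases <- function() {
  th <- asin(1 / 6)
  c(th, pi - th)
}

# Rotation of vector v about unit axis k by angle a (Rodrigues).
rotate_about <- function(v, k, a) {
  v * cos(a) + pracma_cross(k, v) * sin(a) + k * sum(k * v) * (1 - cos(a))
}

# Vectorized Rodrigues rotation: one fixed vector v, unit axis k, vector of
# angles. Returns length(a) x 3 matrix.
rotate_about_vec <- function(v, k, a) {
  kv <- pracma_cross(k, v)
  kd <- sum(k * v)
  outer(cos(a), v) + outer(sin(a), kv) + outer((1 - cos(a)) * kd, k)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Generate a synthetic annotated wrist recording
#'
#' Builds the acceleration signal segment by segment. During gait the signal
#' is a slowly rotating gravity unit vector plus an arm-swing oscillation at
#' stride frequency with a dominant step-frequency harmonic (combined peak
#' amplitude `swing_amp_g`, direction 20 degrees off the gravity axis),
#' heel-strike impact transients (raised-cosine pulses of width 0.12 s and
#' amplitude equal to the swing amplitude, centered at step times, directed
#' along gravity) and white noise. Rest is gravity plus noise; arm activity
#' adds band-limited (0.3-3 Hz) aperiodic bursts. In bilateral walking-aid
#' mode all gait dynamic components are multiplied by the suppression
#' factor. The exact gait schedule is returned as reference truth, and one
#' step event is recorded per step period.
#'
#' @param config a [sim_config()].
#' @return an `annotated_recording`: list with `recording`
#'   (a `gsd_recording`), `truth` (a `gs_list`, source `"reference"`) and
#'   `step_truth` (a `step_events` vector).
#' @export
generate_recording <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  fs <- config$fs
  set.seed(config$seed)
  supp <- if (config$walking_aid_mode == "bilateral") config$suppression else 1.0

  # draw order is fixed: per-recording geometry first, then per-segment draws
  drift_axis <- rnorm(3); drift_axis <- drift_axis / sqrt(sum(drift_axis^2))
  g0 <- c(0, 0, 1)
  swing_tilt_axis <- rnorm(3)

  seg_samples <- vapply(config$schedule, function(s) round(s$duration_s * fs), numeric(1))
  n <- as.integer(sum(seg_samples))
  t <- (seq_len(n) - 1L) / fs

  # slowly rotating gravity direction
  ang <- config$drift_rate * t
  ghat <- rotate_about_vec(g0, drift_axis, ang)

  acc <- ghat  # 1 g along the drifting gravity direction
  truth_s <- truth_e <- numeric(0)
  steps <- numeric(0)
  offset <- 0L
  for (si in seq_along(config$schedule)) {
    seg <- config$schedule[[si]]
    ns <- as.integer(seg_samples[si])
    idx <- offset + seq_len(ns)
    tseg <- (seq_len(ns) - 1L) / fs
    t0 <- offset / fs
    noise_sd <- seg$noise_sd_g
    if (seg$kind == "gait") {
      noise_sd <- max(0.005, noise_sd * supp)
      f_stride <- seg$step_freq_hz / 2
      theta <- 2 * pi * f_stride * tseg
      # per-stride amplitude jitter (cycle-to-cycle arm-swing variability)
      stride_id <- floor(theta / (2 * pi)) + 1L
      n_strides <- max(stride_id)
      jit <- pmin(1.5, pmax(0.5, 1 + 0.1 * rnorm(n_strides)))
      amp <- supp * seg$swing_amp_g * jit[stride_id]
      s_wave <- amp * stride_waveform(theta)
      # swing direction: gravity axis tilted by 20 degrees, drifting with it
      tilt_ax <- pracma_cross(drift_axis, g0)
      if (sum(tilt_ax^2) < 1e-12) tilt_ax <- pracma_cross(swing_tilt_axis, g0)
      tilt_ax <- tilt_ax / sqrt(sum(tilt_ax^2))
      u <- rotate_about_vec(rotate_about(g0, tilt_ax, 20 * pi / 180),
                            drift_axis, ang[idx])
      # step events: two waveform peaks per stride, inside the segment
      ph <- step_peak_phases()
      ev <- as.vector(outer(ph, 2 * pi * (seq_len(ceiling(ns / fs * f_stride) + 1L) - 1L), "+"))
      ev <- sort(ev) / (2 * pi * f_stride)
      ev <- ev[ev < ns / fs]
      # heel-strike impacts: raised-cosine pulses at step times, along gravity
      imp <- numeric(ns)
      w_imp <- 0.12
      imp_amp <- supp * seg$swing_amp_g
      for (e in ev) {
        k0 <- max(1L, ceiling((e - w_imp / 2) * fs) + 1L)
        k1 <- min(ns, floor((e + w_imp / 2) * fs) + 1L)
        if (k1 >= k0) {
          tk <- (k0:k1 - 1L) / fs
          imp[k0:k1] <- imp[k0:k1] + imp_amp * cos(pi * (tk - e) / w_imp)^2
        }
      }
      acc[idx, ] <- acc[idx, ] + u * s_wave + ghat[idx, ] * imp
      truth_s <- c(truth_s, t0)
      truth_e <- c(truth_e, t0 + ns / fs)
      steps <- c(steps, t0 + ev)
    } else if (seg$kind == "arm_activity") {
      # aperiodic band-limited bursts, comparable in magnitude to gait
      env <- filter_series(abs(rnorm(ns)), fs, "lowpass", 0.2, order = 2L)
      env <- pmax(0, env) / max(mean(env), 1e-9)
      burst <- vapply(1:3, function(j) {
        b <- filter_series(rnorm(ns), fs, "bandpass", c(0.3, 3.0), order = 4L)
        b / max(stats::sd(b), 1e-9)
      }, numeric(ns))
      acc[idx, ] <- acc[idx, ] + burst * (seg$arm_amp_g * env)
    }
    acc[idx, ] <- acc[idx, ] + matrix(rnorm(ns * 3L, sd = noise_sd), ncol = 3L)
    offset <- offset + ns
  }

  rec <- new_recording(acc, fs,
                       meta = list(walking_aid = if (supp < 1) "bilateral" else "none",
                                   seed = config$seed))
  # back-to-back gait segments form one continuous gait sequence
  truth <- if (length(truth_s)) merge_overlapping(truth_s, truth_e,
                                                  source = "reference")
           else gs_list(source = "reference")
  structure(list(recording = rec, truth = truth,
                 step_truth = step_events(steps)),
            class = "annotated_recording")
}

# Cohort profiles for the validation-style corpus. Amplitudes, cadences and
# bout structure mirror the qualitative cohort ordering seen in free-living
# studies: healthy older adults walk more, in longer and stronger bouts,
# hip-fracture patients least with weak fragmented bouts.
group_profiles <- function() {
  list(
    HA   = list(n_bouts = 8, bout_s = c(20, 90), swing = c(0.35, 0.50), step = c(1.8, 2.2)),
    COPD = list(n_bouts = 6, bout_s = c(15, 60), swing = c(0.30, 0.45), step = c(1.7, 2.0)),
    CHF  = list(n_bouts = 5, bout_s = c(15, 60), swing = c(0.30, 0.45), step = c(1.6, 1.9)),
    PD   = list(n_bouts = 4, bout_s = c(10, 50), swing = c(0.25, 0.40), step = c(1.5, 1.9)),
    MS   = list(n_bouts = 4, bout_s = c(10, 50), swing = c(0.25, 0.40), step = c(1.5, 1.9)),
    PFF  = list(n_bouts = 3, bout_s = c(8, 30),  swing = c(0.15, 0.30), step = c(1.4, 1.7))
  )
}

#' Build a random schedule for one synthetic subject
#'
#' Alternates rest, gait bouts (amplitude, cadence and duration drawn from
#' the cohort profile) and occasional non-gait arm activity until the target
#' duration is reached.
#'
#' @param group cohort label; one of `names(group_profiles())` (unknown
#'   labels fall back to the `"HA"` profile).
#' @param total_s target recording duration in seconds.
#' @param rng a `function(n)` returning uniform draws, used so callers
#'   control the stream.
#' @return list of [sim_segment()] entries.
#' @keywords internal
random_schedule <- function(group, total_s, rng = stats::runif) {
  prof <- group_profiles()[[group]]
  if (is.null(prof)) prof <- group_profiles()[["HA"]]
  scale <- total_s / 600
  n_bouts <- max(1L, round(prof$n_bouts * scale))
  segs <- list()
  used <- 0
  for (b in seq_len(n_bouts)) {
    # durations snapped to 10 ms so the 100 Hz sample grid realizes them exactly
    rest <- round(10 + rng(1) * 40, 2)
    if (rng(1) < 0.3) {
      arm <- round(10 + rng(1) * 20, 2)
      segs <- c(segs, list(sim_segment("arm_activity", arm)))
      used <- used + arm
    }
    segs <- c(segs, list(sim_segment("rest", rest)))
    used <- used + rest
    dur <- round(prof$bout_s[1] + rng(1) * diff(prof$bout_s), 2)
    swing <- prof$swing[1] + rng(1) * diff(prof$swing)
    stepf <- prof$step[1] + rng(1) * diff(prof$step)
    segs <- c(segs, list(sim_segment("gait", dur, step_freq_hz = stepf,
                                     swing_amp_g = swing)))
    used <- used + dur
  }
  if (used < total_s) segs <- c(segs, list(sim_segment("rest", round(total_s - used, 2))))
  segs
}

#' Generate a multi-group validation corpus
#'
#' Produces one annotated recording per subject with per-cohort parameter
#' distributions (see `group_profiles()`), deterministic given the seed.
#'
#' @param per_group named integer vector or list, cohort label -> number of
#'   subjects (each >= 1).
#' @param total_s duration of each recording in seconds (default 600).
#' @param seed integer seed for the corpus stream.
#' @param walking_aid_mode passed to every [sim_config()].
#' @return list of `annotated_recording` objects; each recording carries its
#'   `subject_id` and `group`.
#' @export
make_validation_corpus <- function(per_group = c(HA = 2, PFF = 2), total_s = 600,
                                   seed = 1L, walking_aid_mode = "none") {
  if (any(unlist(per_group) < 1)) stop("per-group counts must be >= 1")
  set.seed(seed)
  n_total <- sum(unlist(per_group))
  seeds <- matrix(sample.int(2^31 - 2L, 2L * n_total), ncol = 2L)
  out <- list()
  k <- 0L
  for (g in names(per_group)) {
    for (i in seq_len(per_group[[g]])) {
      k <- k + 1L
      set.seed(seeds[k, 1L])
      sched <- random_schedule(g, total_s)
      ar <- generate_recording(sim_config(sched, seed = seeds[k, 2L],
                                          walking_aid_mode = walking_aid_mode))
      ar$recording$subject_id <- sprintf("%s_%02d", g, i)
      ar$recording$group <- g
      out[[k]] <- ar
    }
  }
  out
}
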