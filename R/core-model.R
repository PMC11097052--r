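#' Construct a wrist accelerometer recording
#'
#' A recording is a uniformly sampled triaxial acceleration series in units of
#' g. Time starts at 0 s; the duration is `nrow(acc) / fs`.
#'
#' @param acc numeric matrix with N rows and 3 columns (x, y, z acceleration
#'   in g). All values must be finite.
#' @param fs sampling frequency in Hz (> 0). The detectors in this package
#'   were parameterized at 100 Hz.
#' @param subject_id opaque subject identifier.
#' @param group cohort label (free string, e.g. `"HA"`, `"PFF"`).
#' @param meta named list of annotations. The key `walking_aid` (one of
#'   `"none"`, `"unilateral"`, `"bilateral"`) is understood by the
#'   simulation and reporting layers.
#' @return an object of class `gsd_recording` with fields `acc`, `fs`,
#'   `subject_id`, `group`, `meta`.
#' @export
new_recording <- function(acc, fs, subject_id = "anon", group = "NA",
                          meta = list()) {
  acc <- as.matrix(acc)
  if (ncol(acc) != 3L) stop("`acc` must have exactly 3 columns (x, y, z)")
  if (nrow(acc) < 1L) stop("`acc` must have at least one sample")
  if (!is.numeric(acc) || !all(is.finite(acc)))
    stop("all acceleration values must be finite numbers")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  structure(
    list(acc = unname(acc), fs = as.numeric(fs),
         subject_id = as.character(subject_id), group = as.character(group),
         meta = meta),
    class = "gsd_recording"
  )
}

#' @export
print.gsd_recording <- function(x, ...) {
  cat(sprintf("<gsd_recording> subject=%s group=%s fs=%g Hz duration=%.1f s (%d samples)\n",
              x$subject_id, x$group, x$fs, rec_duration(x), nrow(x$acc)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording a `gsd_recording`.
#' @return duration in seconds (`N / fs`).
#' @export
rec_duration <- function(recording) nrow(recording$acc) / recording$fs

#' Sample times of a recording
#' @param recording a `gsd_recording`.
#' @return numeric vector of sample times in seconds, starting at 0.
#' @export
rec_times <- function(recording) (seq_len(nrow(recording$acc)) - 1L) / recording$fs

#' Construct a list of gait sequences
#'
#' Gait sequences (GSs) are half-open intervals `[start_s, end_s)` in seconds
#' from the start of the recording. A valid GS list is sorted by start, and
#' consecutive intervals are strictly separated (gap > 0).
#'
#' @param start_s,end_s numeric vectors of interval bounds in seconds.
#' @param source algorithm name, or `"reference"` for ground truth.
#' @return an object of class `gs_list`: a data.frame with columns `start_s`
#'   and `end_s` plus a `source` attribute.
#' @export
gs_list <- function(start_s = numeric(0), end_s = numeric(0), source = "unknown") {
  if (length(start_s) != length(end_s)) stop("start_s and end_s lengths differ")
  if (any(!is.finite(start_s)) || any(!is.finite(end_s)))
    stop("gait sequence bounds must be finite")
  if (any(end_s <= start_s)) stop("each gait sequence must satisfy end_s > start_s")
  if (any(start_s < 0)) stop("gait sequences cannot start before 0 s")
  o <- order(start_s)
  start_s <- start_s[o]; end_s <- end_s[o]
  if (length(start_s) > 1L && any(start_s[-1L] <= end_s[-length(end_s)]))
    stop("gait sequences must be non-overlapping and strictly separated")
  structure(
    data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s)),
    source = source, class = c("gs_list", "data.frame")
  )
}

#' @export
print.gs_list <- function(x, ...) {
  cat(sprintf("<gs_list> source=%s n=%d total=%.2f s\n",
              attr(x, "source"), nrow(x), gs_total_duration(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 20L))
  invisible(x)
}

#' Number of gait sequences
#' @param gs a `gs_list`.
#' @return integer count.
#' @export
gs_count <- function(gs) nrow(gs)

#' Total gait-sequence duration in seconds
#' @param gs a `gs_list`.
#' @return sum of interval lengths (0 for an empty list).
#' @export
gs_total_duration <- function(gs) if (nrow(gs)) sum(gs$end_s - gs$start_s) else 0

#' Construct step events
#'
#' @param times strictly increasing step-event timestamps in seconds.
#' @return object of class `step_events` (numeric vector).
#' @export
step_events <- function(times = numeric(0)) {
  times <- as.numeric(times)
  if (any(!is.finite(times))) stop("step times must be finite")
  if (is.unsorted(times, strictly = TRUE)) stop("step times must be strictly increasing")
  structure(times, class = "step_events")
}

#' Construct stride intervals
#'
#' @param start_s,end_s stride start/end times in seconds; starts strictly
#'   increasing, each end after its start.
#' @return object of class `stride_intervals` (2-column data.frame).
#' @export
stride_intervals <- function(start_s = numeric(0), end_s = numeric(0)) {
  if (length(start_s) != length(end_s)) stop("start_s and end_s lengths differ")
  if (is.unsorted(start_s, strictly = TRUE)) stop("stride starts must be strictly increasing")
  if (any(end_s <= start_s)) stop("each stride must satisfy end > start")
  structure(data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s)),
            class = c("stride_intervals", "data.frame"))
}

#' Assemble step events or strides into gait sequences
#'
#' Consecutive events are combined into one gait sequence when they are not
#' further apart than `max_gap_s` (3 s by default, the assembly rule shared by
#' all detectors). For strides the separation is end-to-next-start; for step
#' events it is time-to-time. Runs with fewer than `min_events` events are
#' discarded. A GS starts at the first event start and ends at the last event
#' end (for steps: at the last step time, no padding).
#'
#' @param events a `step_events` or `stride_intervals` object (a bare sorted
#'   numeric vector is accepted as step events).
#' @param max_gap_s maximum separation in seconds for two events to share a
#'   gait sequence (> 0).
#' @param min_events minimum number of events per gait sequence (>= 2);
#'   defaults to 3 for step events and 2 for strides. A stride contributes
#'   two events (its two boundary foot contacts), so a single stride already
#'   satisfies the stride default, while step runs need at least
#'   `min_events` step times.
#' @param source label recorded on the output.
#' @return a `gs_list`.
#' @export
assemble_gs_from_events <- function(events, max_gap_s = 3.0, min_events = NULL,
                                    source = "assembled") {
  if (!is.numeric(max_gap_s) || max_gap_s <= 0) stop("max_gap_s must be > 0")
  is_strides <- inherits(events, "stride_intervals")
  if (is_strides) {
    if (is.null(min_events)) min_events <- 2L
    starts <- events$start_s; ends <- events$end_s
  } else {
    if (is.null(min_events)) min_events <- 3L
    times <- as.numeric(events)
    if (is.unsorted(times, strictly = TRUE)) stop("step events must be strictly increasing")
    starts <- times; ends <- times
  }
  if (min_events < 2) stop("min_events must be >= 2")
  n <- length(starts)
  if (n == 0L) return(gs_list(source = source))
  # separation between event i and i+1: gap from end of i to start of i+1
  gaps <- starts[-1L] - ends[-n]
  run_id <- cumsum(c(0, as.numeric(gaps > max_gap_s)))
  ev_per <- if (is_strides) 2L else 1L
  keep_start <- keep_end <- numeric(0)
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    if (length(idx) * ev_per >= min_events) {
      keep_start <- c(keep_start, starts[idx[1L]])
      keep_end <- c(keep_end, ends[idx[length(idx)]])
    }
  }
  gs_list(keep_start, keep_end, source = source)
}

#' Merge overlapping or touching gait-sequence intervals
#'
#' Normalizes raw interval output into a valid `gs_list`: intervals are
#' sorted and their union taken, so overlapping or touching intervals become
#' one. Total covered time is preserved.
#'
#' @param start_s,end_s numeric interval bounds (unordered, possibly
#'   overlapping), or a 2-column data.frame passed as `start_s`.
#' @param source label recorded on the output.
#' @return a `gs_list`.
#' @export
merge_overlapping <- function(start_s, end_s = NULL, source = "merged") {
  if (is.data.frame(start_s)) {
    end_s <- start_s[[2L]]; start_s <- start_s[[1L]]
  }
  if (length(start_s) == 0L) return(gs_list(source = source))
  if (any(end_s <= start_s)) stop("each interval must satisfy end > start")
  o <- order(start_s)
  s <- start_s[o]; e <- end_s[o]
  out_s <- s[1L]; out_e <- e[1L]
  for (i in seq_along(s)[-1L]) {
    k <- length(out_s)
    if (s[i] <= out_e[k]) {
      out_e[k] <- max(out_e[k], e[i])
    } else {
      out_s <- c(out_s, s[i]); out_e <- c(out_e, e[i])
    }
  }
  gs_list(out_s, out_e, source = source)
}
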