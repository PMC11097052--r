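#' Rasterize gait sequences onto a fixed window grid
#'
#' The recording is segmented into windows of `window_s` seconds (0.1 s in
#' the validation protocol) on a fixed grid starting at 0. Window `i`
#' (interval `[i*w, (i+1)*w)`) is labeled gait iff its midpoint lies inside
#' any gait sequence.
#'
#' @param gs a `gs_list`; every interval must end within `duration_s`.
#' @param duration_s recording duration in seconds.
#' @param window_s window length in seconds (> 0).
#' @return logical vector of length `ceiling(duration_s / window_s)`.
#' @export
rasterize <- function(gs, duration_s, window_s = 0.1) {
  if (window_s <= 0) stop("window_s must be > 0")
  if (nrow(gs) && max(gs$end_s) > duration_s + 1e-9)
    stop("gait sequence exceeds the recording duration")
  n_win <- ceiling(duration_s / window_s)
  mid <- (seq_len(n_win) - 0.5) * window_s
  if (!nrow(gs)) return(rep(FALSE, n_win))
  bounds <- as.vector(rbind(gs$start_s, gs$end_s))
  findInterval(mid, bounds) %% 2L == 1L
}

#' Windowed confusion counts
#'
#' @param pred,ref logical label vectors of equal length (prediction and
#'   reference gait labels per window).
#' @return list with integer fields `tp`, `fp`, `tn`, `fn` (summing to the
#'   number of windows).
#' @export
confusion <- function(pred, ref) {
  if (length(pred) != length(ref))
    stop("prediction and reference label vectors differ in length")
  list(tp = sum(pred & ref), fp = sum(pred & !ref),
       tn = sum(!pred & !ref), fn = sum(!pred & ref))
}

#' Classification metrics from confusion counts
#'
#' Ratios with zero denominators are returned as `NA` and excluded from any
#' downstream aggregation.
#'
#' @param cc confusion counts from [confusion()].
#' @return named numeric vector: `sensitivity` (tp/(tp+fn)), `specificity`
#'   (tn/(tn+fp)), `ppv` (tp/(tp+fp)), `accuracy` ((tp+tn)/total).
#' @export
classification_metrics <- function(cc) {
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  total <- cc$tp + cc$fp + cc$tn + cc$fn
  c(sensitivity = safe_div(cc$tp, cc$tp + cc$fn),
    specificity = safe_div(cc$tn, cc$tn + cc$fp),
    ppv = safe_div(cc$tp, cc$tp + cc$fp),
    accuracy = safe_div(cc$tp + cc$tn, total))
}

#' Gait-sequence count and duration errors
#'
#' Relative (and relative absolute) errors of the number of detected gait
#' sequences and of the total gait-sequence duration, as a percentage of the
#' reference estimates.
#'
#' @param pred,ref `gs_list` objects; `ref` must be nonempty for defined
#'   errors.
#' @return named numeric vector (`NA` when the reference is empty):
#'   `gs_count_rel_err`, `gs_count_rel_abs_err`, `gs_dur_rel_err`,
#'   `gs_dur_rel_abs_err`, all in percent.
#' @export
gs_errors <- function(pred, ref) {
  if (!nrow(ref))
    return(c(gs_count_rel_err = NA_real_, gs_count_rel_abs_err = NA_real_,
             gs_dur_rel_err = NA_real_, gs_dur_rel_abs_err = NA_real_))
  ce <- 100 * (gs_count(pred) - gs_count(ref)) / gs_count(ref)
  de <- 100 * (gs_total_duration(pred) - gs_total_duration(ref)) /
    gs_total_duration(ref)
  c(gs_count_rel_err = ce, gs_count_rel_abs_err = abs(ce),
    gs_dur_rel_err = de, gs_dur_rel_abs_err = abs(de))
}

#' Per-recording validation metric panel
#'
#' Composes [rasterize()], [confusion()], [classification_metrics()] and
#' [gs_errors()] for one recording and attaches identifying metadata plus
#' the total predicted and reference gait durations (used for ICC).
#'
#' @param pred,ref `gs_list` objects (detected and reference).
#' @param duration_s recording duration in seconds.
#' @param window_s window length in seconds.
#' @param subject_id,group metadata carried into the panel.
#' @return one-row data.frame with the metric panel.
#' @export
evaluate_recording <- function(pred, ref, duration_s, window_s = 0.1,
                               subject_id = "anon", group = "NA") {
  cc <- confusion(rasterize(pred, duration_s, window_s),
                  rasterize(ref, duration_s, window_s))
  cm <- classification_metrics(cc)
  ge <- gs_errors(pred, ref)
  cbind(data.frame(subject_id = subject_id, group = group,
                   duration_s = duration_s),
        as.data.frame(t(c(cm, ge))),
        data.frame(dur_pred_s = gs_total_duration(pred),
                   dur_ref_s = gs_total_duration(ref),
                   n_pred = gs_count(pred), n_ref = gs_count(ref),
                   tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn))
}

#' Evaluate a detector over an annotated corpus
#'
#' @param corpus list of `annotated_recording` objects.
#' @param algorithm registry key.
#' @param bank parameter bank.
#' @param params_override named list of overrides.
#' @param window_s evaluation window in seconds.
#' @return data.frame of per-recording metric panels.
#' @export
evaluate_corpus <- function(corpus, algorithm, bank = "optimized",
                            params_override = list(), window_s = 0.1) {
  do.call(rbind, lapply(corpus, function(ar) {
    pred <- run_algorithm(algorithm, ar$recording, bank, params_override)
    evaluate_recording(pred, ar$truth, rec_duration(ar$recording), window_s,
                       subject_id = ar$recording$subject_id,
                       group = ar$recording$group)
  }))
}
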