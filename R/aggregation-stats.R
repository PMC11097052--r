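#' Two-way random-effects, absolute-agreement, single-measure ICC
#'
#' ICC(2,1) between two raters (here: a detector's and the reference
#' system's total gait duration per subject), computed from the two-way
#' ANOVA mean squares:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param values numeric matrix with n subjects as rows and k = 2 raters as
#'   columns (n >= 3).
#' @return list with `icc`, `category` (see [interpret_icc()]),
#'   `n_subjects`, and the ANOVA mean squares `ms_rows`, `ms_cols`,
#'   `ms_err`.
#' @export
icc_2_1 <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 3) stop("ICC(2,1) needs at least 3 subjects")
  if (any(!is.finite(values))) stop("ICC input must be finite")
  gm <- mean(values)
  rm_ <- rowMeans(values); cm_ <- colMeans(values)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm_ - gm)^2)
  sst <- sum((values - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- if (abs(denom) < 1e-300) NA_real_ else (msr - mse) / denom
  list(icc = icc, category = interpret_icc(icc), n_subjects = n,
       ms_rows = msr, ms_cols = msc, ms_err = mse)
}

#' Interpret an ICC estimate
#'
#' Reliability bands: poor below 0.50, moderate in \[0.50, 0.75), good in
#' \[0.75, 0.90), excellent at or above 0.90. Boundary values fall in the
#' higher category.
#'
#' @param icc numeric ICC estimate (or `NA`).
#' @return one of `"poor"`, `"moderate"`, `"good"`, `"excellent"` (or `NA`).
#' @export
interpret_icc <- function(icc) {
  if (is.na(icc)) return(NA_character_)
  if (icc < 0.50) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc < 0.90) "good"
  else "excellent"
}

#' Default performance-index weights
#'
#' Uniform weights over the seven metrics entering the index: five benefit
#' metrics (accuracy, sensitivity, specificity, PPV, ICC) and two cost
#' metrics (GS duration and GS count relative absolute errors, in percent,
#' capped at `cost_cap`). The published weighting scheme is not reproduced
#' here; any scheme in the same layout can be supplied instead.
#'
#' @param cost_cap cap in percent applied to cost metrics before
#'   normalization (default 100).
#' @return data.frame with columns `metric`, `weight`, `orientation`, plus a
#'   `cost_cap` attribute.
#' @export
default_perf_weights <- function(cost_cap = 100) {
  w <- data.frame(
    metric = c("accuracy", "sensitivity", "specificity", "ppv", "icc",
               "gs_dur_rel_abs_err", "gs_count_rel_abs_err"),
    weight = rep(1 / 7, 7),
    orientation = c(rep("benefit", 5), rep("cost", 2))
  )
  attr(w, "cost_cap") <- cost_cap
  w
}

#' Weighted performance index
#'
#' Combines group-level metrics into a single index in \[0, 1\] (0 worst, 1
#' best): benefit metrics enter directly, cost metrics are capped at
#' `cost_cap` percent, scaled to \[0, 1\] and inverted; the index is the
#' weighted sum.
#'
#' @param group_metrics named numeric vector containing every metric named
#'   in `weights`.
#' @param weights weight table from [default_perf_weights()] (weights must
#'   be non-negative and sum to 1).
#' @return numeric index in \[0, 1\].
#' @export
performance_index <- function(group_metrics, weights = default_perf_weights()) {
  if (any(weights$weight < 0) || abs(sum(weights$weight) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  cap <- attr(weights, "cost_cap") %||% 100
  missing <- setdiff(weights$metric, names(group_metrics))
  if (length(missing))
    stop(sprintf("missing metric(s) for performance index: %s",
                 paste(missing, collapse = ", ")))
  vals <- group_metrics[weights$metric]
  if (any(is.na(vals)))
    stop(sprintf("metric(s) undefined (NA) for performance index: %s",
                 paste(weights$metric[is.na(vals)], collapse = ", ")))
  b <- ifelse(weights$orientation == "benefit",
              pmin(1, pmax(0, vals)),
              1 - pmin(cap, pmax(0, vals)) / cap)
  sum(weights$weight * b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-sided paired t test for one metric
#'
#' Mean difference `a - b` with the textbook paired t statistic
#' `t = mean(d) / (sd(d) / sqrt(n))`. Zero-variance differences are flagged
#' degenerate: the p value is 0 for a nonzero constant shift
#' (degenerate-certain) and `NA` when the two vectors are identical.
#'
#' @param metric_a,metric_b paired per-participant metric values (equal
#'   length >= 3); pairs containing `NA` are dropped.
#' @param metric name carried into the result.
#' @return one-row data.frame: `metric`, `n`, `mean_difference`, `t_stat`,
#'   `p_value`, `degenerate`.
#' @export
paired_compare <- function(metric_a, metric_b, metric = "metric") {
  if (length(metric_a) != length(metric_b)) stop("inputs must be paired")
  ok <- is.finite(metric_a) & is.finite(metric_b)
  d <- metric_a[ok] - metric_b[ok]
  n <- length(d)
  if (n < 3) stop("need at least 3 complete pairs")
  md <- mean(d)
  sd_d <- stats::sd(d)
  # treat numerically-zero variance (e.g. an exact constant shift up to
  # floating-point residue) as degenerate
  if (sd_d <= 1e-10 * max(abs(md), 1e-12)) {
    return(data.frame(metric = metric, n = n, mean_difference = md,
                      t_stat = NA_real_,
                      p_value = if (md == 0) NA_real_ else 0,
                      degenerate = TRUE))
  }
  t_stat <- md / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  data.frame(metric = metric, n = n, mean_difference = md, t_stat = t_stat,
             p_value = p, degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment:
#' `adjusted_(i) = min over j >= i of (m * p_(j) / j)`, capped at 1,
#' returned in the original order.
#'
#' @param pvals numeric p values in \[0, 1\].
#' @return adjusted p values, same order as input.
#' @export
benjamini_hochberg <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals)
  ranked <- pvals[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(1, adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Compare two detectors' panels metric by metric
#'
#' Runs [paired_compare()] per metric on per-participant panels from
#' [evaluate_corpus()] and adjusts p values with [benjamini_hochberg()].
#'
#' @param panel_a,panel_b metric-panel data.frames with matching
#'   `subject_id` order.
#' @param metrics metric columns to compare.
#' @return data.frame in a three-column comparison-table layout: metric,
#'   mean difference, p value, adjusted p value.
#' @export
compare_panels <- function(panel_a, panel_b,
                           metrics = c("sensitivity", "specificity", "ppv",
                                       "accuracy", "gs_count_rel_err",
                                       "gs_dur_rel_err")) {
  if (!identical(panel_a$subject_id, panel_b$subject_id))
    stop("panels must cover the same subjects in the same order")
  res <- do.call(rbind, lapply(metrics, function(m)
    paired_compare(panel_a[[m]], panel_b[[m]], metric = m)))
  res$p_adjusted <- benjamini_hochberg(ifelse(is.na(res$p_value), 1, res$p_value))
  res$p_adjusted[is.na(res$p_value)] <- NA_real_
  res
}

#' Group-level summary: mean metrics, ICC and performance index
#'
#' Aggregates per-recording metric panels per cohort: metric means exclude
#' undefined (`NA`) entries; ICC(2,1) is computed between the detected and
#' reference total gait durations across the group's subjects (`NA` when
#' the group has fewer than 3 subjects); the performance index combines the
#' group means and the ICC.
#'
#' @param panels data.frame of per-recording panels
#'   (see [evaluate_recording()]).
#' @param weights performance-index weights.
#' @return data.frame, one row per group, with mean metrics, `icc`,
#'   `icc_category` and `performance_index`.
#' @export
summarize_group <- function(panels, weights = default_perf_weights()) {
  metric_cols <- c("sensitivity", "specificity", "ppv", "accuracy",
                   "gs_count_rel_err", "gs_count_rel_abs_err",
                   "gs_dur_rel_err", "gs_dur_rel_abs_err")
  groups <- unique(panels$group)
  out <- lapply(groups, function(g) {
    p <- panels[panels$group == g, , drop = FALSE]
    means <- vapply(metric_cols, function(m) mean(p[[m]], na.rm = TRUE),
                    numeric(1))
    means[is.nan(means)] <- NA_real_
    icc <- if (nrow(p) >= 3) icc_2_1(cbind(p$dur_pred_s, p$dur_ref_s))
           else list(icc = NA_real_, category = NA_character_)
    gm <- c(means, icc = icc$icc)
    pi_val <- tryCatch(performance_index(gm, weights), error = function(e) NA_real_)
    cbind(data.frame(group = g, n = nrow(p)), as.data.frame(t(means)),
          data.frame(icc = icc$icc, icc_category = icc$category,
                     performance_index = pi_val))
  })
  do.call(rbind, out)
}
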