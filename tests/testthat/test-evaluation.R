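test_that("rasterization follows the midpoint-in-interval rule", {
  g <- gs_list(0.25, 0.55)
  lab <- rasterize(g, 1.0, 0.1)
  expect_length(lab, 10L)
  expect_equal(sum(lab), 3L)  # midpoints 0.25, 0.35, 0.45
  expect_equal(which(lab), 3:5)
  expect_false(any(rasterize(gs_list(), 1.0, 0.1)))
  expect_error(rasterize(gs_list(0, 2), 1.0), "exceeds")

  # loop oracle on random GS lists
  set.seed(13)
  for (rep in 1:20) {
    s <- sort(runif(5, 0, 50)); e <- s + runif(5, 0.05, 3)
    g <- merge_overlapping(s, e)
    dur <- 60
    lab <- rasterize(g, dur, 0.1)
    mids <- (seq_len(ceiling(dur / 0.1)) - 0.5) * 0.1
    oracle <- vapply(mids, function(m)
      any(m >= g$start_s & m < g$end_s), logical(1))
    expect_identical(lab, oracle)
  }
})

test_that("confusion counts match the elementwise definition", {
  cc <- confusion(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(cc, list(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  lab <- c(TRUE, FALSE, TRUE)
  expect_equal(confusion(lab, lab)$fp + confusion(lab, lab)$fn, 0L)
  expect_error(confusion(c(TRUE), c(TRUE, FALSE)), "length")

  set.seed(14)
  pred <- runif(1e4) < 0.3
  ref <- runif(1e4) < 0.2
  cc <- confusion(pred, ref)
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] && ref[i]) tp <- tp + 1L
    else if (pred[i]) fp <- fp + 1L
    else if (ref[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  expect_equal(cc, list(tp = tp, fp = fp, tn = tn, fn = fn))
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 1e4L)
})

test_that("classification metrics follow their definitions and handle 0/0", {
  m <- classification_metrics(list(tp = 8, fn = 2, tn = 85, fp = 5))
  expect_equal(round(unname(m), 4), c(0.8, 0.9444, 0.6154, 0.93))
  perfect <- classification_metrics(list(tp = 10, fn = 0, tn = 90, fp = 0))
  expect_true(all(perfect == 1))
  none <- classification_metrics(list(tp = 0, fn = 0, tn = 100, fp = 0))
  expect_true(is.na(none["sensitivity"]))
  expect_true(is.na(none["ppv"]))
})

test_that("GS count and duration errors are relative to the reference", {
  pred <- gs_list(c(0, 10), c(4, 50))   # T = 44, n = 2
  ref <- gs_list(c(0, 10, 60, 70), c(5, 40, 65, 75))  # T = 45, n = 4
  e <- gs_errors(pred, ref)
  expect_equal(unname(e["gs_count_rel_err"]), 100 * (2 - 4) / 4)
  expect_equal(unname(e["gs_dur_rel_err"]), 100 * (44 - 45) / 45)
  expect_equal(unname(e["gs_dur_rel_abs_err"]), abs(100 * (44 - 45) / 45))
  # worked values: T_pred 80 vs T_ref 100 -> -20 % / 20 %; 6 vs 4 GSs -> +50 %
  e2 <- gs_errors(gs_list(0, 80), gs_list(0, 100))
  expect_equal(unname(e2[c("gs_dur_rel_err", "gs_dur_rel_abs_err")]), c(-20, 20))
  e3 <- gs_errors(gs_list(seq(0, 50, 10), seq(0, 50, 10) + 2),
                  gs_list(seq(0, 30, 10), seq(0, 30, 10) + 2))
  expect_equal(unname(e3["gs_count_rel_err"]), 50)
  expect_equal(unname(gs_errors(ref, ref)), rep(0, 4))
  expect_true(all(is.na(gs_errors(pred, gs_list()))))
})

test_that("evaluate_recording composes the metric pipeline", {
  ar <- fx_gait()
  panel <- evaluate_recording(ar$truth, ar$truth, rec_duration(ar$recording))
  expect_equal(panel$sensitivity, 1)
  expect_equal(panel$specificity, 1)
  expect_equal(panel$gs_dur_rel_abs_err, 0)

  pred <- gs_list(21, 48, source = "x")
  panel2 <- evaluate_recording(pred, ar$truth, 60)
  # compositional oracle
  cc <- confusion(rasterize(pred, 60), rasterize(ar$truth, 60))
  expect_equal(panel2$sensitivity,
               unname(classification_metrics(cc)["sensitivity"]))
  expect_equal(panel2$tp, cc$tp)
  # deterministic
  expect_identical(panel2, evaluate_recording(pred, ar$truth, 60))
})

test_that("metrics are invariant to GS order and stable under finer windows", {
  set.seed(15)
  s <- sort(runif(6, 0, 50)); e <- s + runif(6, 0.5, 4)
  g <- merge_overlapping(s, e)
  perm <- sample(nrow(g))
  g_perm <- gs_list(g$start_s[perm], g$end_s[perm])
  expect_equal(rasterize(g_perm, 60), rasterize(g, 60))

  ar <- fx_gait()
  pred <- run_algorithm("paraschiv2019", ar$recording, "optimized")
  dur <- rec_duration(ar$recording)
  for (w in c(0.1, 0.01)) {
    cc <- confusion(rasterize(pred, dur, w), rasterize(ar$truth, dur, w))
    assign(paste0("m", w * 100), classification_metrics(cc))
  }
  expect_lt(abs(m10["sensitivity"] - m1["sensitivity"]), 0.02)
  expect_lt(abs(m10["specificity"] - m1["specificity"]), 0.02)

  # exact identity: accuracy is the prevalence-weighted mix of sens and spec
  cc <- confusion(rasterize(pred, dur), rasterize(ar$truth, dur))
  m <- classification_metrics(cc)
  prev <- (cc$tp + cc$fn) / (cc$tp + cc$fn + cc$tn + cc$fp)
  expect_equal(unname(m["accuracy"]),
               unname(m["sensitivity"] * prev + m["specificity"] * (1 - prev)))
})
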