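test_that("ICC(2,1) matches the ANOVA oracle and known cases", {
  # perfect agreement with between-subject variance
  m <- cbind(c(10, 20, 30, 40), c(10, 20, 30, 40))
  r <- icc_2_1(m)
  expect_equal(r$icc, 1)
  expect_equal(r$category, "excellent")

  # a constant offset is penalized under absolute agreement
  m2 <- cbind(c(10, 20, 30, 40), c(10, 20, 30, 40) + 15)
  expect_lt(icc_2_1(m2)$icc, 1)

  expect_error(icc_2_1(cbind(1:2, 3:4)), "at least 3")

  # oracle: mean squares from stats::aov on the long layout
  set.seed(16)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    mm <- matrix(rnorm(2 * n, mean = 30, sd = 10), ncol = 2)
    r <- icc_2_1(mm)
    long <- data.frame(y = as.vector(mm),
                       subj = factor(rep(seq_len(n), 2)),
                       rater = factor(rep(1:2, each = n)))
    ms <- summary(stats::aov(y ~ subj + rater, data = long))[[1]][, "Mean Sq"]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    icc_oracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
    expect_lt(abs(r$icc - icc_oracle), 1e-10)
    # row permutation leaves the estimate unchanged
    expect_equal(icc_2_1(mm[sample(n), ])$icc, r$icc)
  }
})

test_that("ICC interpretation bands use the documented boundaries", {
  expect_equal(interpret_icc(0.49), "poor")
  expect_equal(interpret_icc(0.50), "moderate")
  expect_equal(interpret_icc(0.75), "good")
  expect_equal(interpret_icc(0.90), "excellent")
  expect_true(is.na(interpret_icc(NA_real_)))
})

test_that("the performance index respects its contract", {
  best <- c(accuracy = 1, sensitivity = 1, specificity = 1, ppv = 1, icc = 1,
            gs_dur_rel_abs_err = 0, gs_count_rel_abs_err = 0)
  worst <- c(accuracy = 0, sensitivity = 0, specificity = 0, ppv = 0, icc = 0,
             gs_dur_rel_abs_err = 100, gs_count_rel_abs_err = 150)
  expect_equal(performance_index(best), 1.0)
  expect_equal(performance_index(worst), 0.0)  # costs capped at 100 %

  mid <- c(accuracy = 0.8, sensitivity = 0.8, specificity = 0.8, ppv = 0.8,
           icc = 0.8, gs_dur_rel_abs_err = 20, gs_count_rel_abs_err = 20)
  expect_equal(performance_index(mid), 0.8)  # hand-computed weighted sum

  # monotone in every coordinate
  set.seed(17)
  for (rep in 1:20) {
    gm <- c(accuracy = runif(1), sensitivity = runif(1),
            specificity = runif(1), ppv = runif(1), icc = runif(1),
            gs_dur_rel_abs_err = runif(1, 0, 99),
            gs_count_rel_abs_err = runif(1, 0, 99))
    base <- performance_index(gm)
    expect_gte(base, 0); expect_lte(base, 1)
    for (b in c("accuracy", "sensitivity", "specificity", "ppv", "icc")) {
      up <- gm; up[b] <- min(1, up[b] + 0.05)
      expect_gte(performance_index(up), base)
    }
    for (cst in c("gs_dur_rel_abs_err", "gs_count_rel_abs_err")) {
      up <- gm; up[cst] <- up[cst] + 5
      expect_lte(performance_index(up), base)
    }
  }
  expect_error(performance_index(best[-3]), "specificity")
})

test_that("paired comparison matches the t-test oracle and flags degeneracy", {
  a <- c(1, 2, 3, 4, 5)
  r <- paired_compare(a, a)
  expect_true(r$degenerate)
  expect_true(is.na(r$p_value))

  r2 <- paired_compare(a + 0.7, a, metric = "x")
  expect_true(r2$degenerate)
  expect_equal(r2$mean_difference, 0.7)
  expect_lt(r2$p_value, 1e-6)  # degenerate-certain shift

  set.seed(18)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- paired_compare(x, y)
    tt <- stats::t.test(x, y, paired = TRUE)
    expect_equal(r$t_stat, unname(tt$statistic))
    expect_equal(r$p_value, tt$p.value)
    expect_equal(r$mean_difference, unname(tt$estimate))
  }
})

test_that("Benjamini-Hochberg matches the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")

  set.seed(19)
  for (rep in 1:20) {
    p <- runif(sample(2:30, 1))
    got <- benjamini_hochberg(p)
    expect_equal(got, stats::p.adjust(p, method = "BH"))
    expect_true(all(got >= p))
    sorted <- benjamini_hochberg(sort(p))
    expect_true(all(diff(sorted) >= -1e-15))
  }
})

test_that("group summaries aggregate panels, ICC and index per cohort", {
  mk_panel <- function(id, grp, sens, dp, dr) {
    data.frame(subject_id = id, group = grp, duration_s = 60,
               sensitivity = sens, specificity = 0.9, ppv = 0.8,
               accuracy = 0.9, gs_count_rel_err = 10,
               gs_count_rel_abs_err = 10, gs_dur_rel_err = -5,
               gs_dur_rel_abs_err = 5, dur_pred_s = dp, dur_ref_s = dr,
               n_pred = 3, n_ref = 3, tp = 1, fp = 1, tn = 1, fn = 1)
  }
  panels <- rbind(mk_panel("a", "G1", 0.8, 30, 31), mk_panel("b", "G1", 0.6, 40, 41),
                  mk_panel("c", "G1", 0.7, 50, 52), mk_panel("d", "G2", 0.5, 20, 22))
  s <- summarize_group(panels)
  g1 <- s[s$group == "G1", ]
  expect_equal(g1$sensitivity, mean(c(0.8, 0.6, 0.7)))
  expect_equal(g1$icc, icc_2_1(cbind(c(30, 40, 50), c(31, 41, 52)))$icc)
  expect_false(is.na(g1$performance_index))
  g2 <- s[s$group == "G2", ]
  expect_equal(g2$n, 1L)
  expect_equal(g2$sensitivity, 0.5)
  expect_true(is.na(g2$icc))  # fewer than 3 subjects

  # single-recording group mean equals the recording; NA metrics excluded
  panels$ppv[1] <- NA
  s2 <- summarize_group(panels)
  expect_equal(s2$ppv[s2$group == "G1"], mean(c(0.8, 0.8)))
})
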