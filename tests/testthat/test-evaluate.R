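test_that("segment metrics evaluate the confusion formulas in percent", {
  perfect <- segment_metrics(tp = 50, tn = 50, fp = 0, fn = 0)
  expect_equal(unname(perfect), rep(100, 4))
  m <- segment_metrics(tp = 96, tn = 97, fp = 3, fn = 4)
  expect_equal(unname(m["sensitivity"]), 96.0)
  expect_equal(unname(m["specificity"]), 97.0)
  expect_equal(unname(m["accuracy"]), 96.5)
  expect_equal(unname(m["precision"]), 100 * 96 / 99, tolerance = 1e-12)
  # undefined metrics are NA, not zero
  u <- segment_metrics(tp = 0, tn = 10, fp = 0, fn = 0)
  expect_true(is.na(u["sensitivity"]))
  expect_true(is.na(u["precision"]))
  expect_error(segment_metrics(0, 0, 0, 0), "zero")
  expect_error(segment_metrics(-1, 2, 3, 4), "nonnegative")
})

test_that("segment metrics are scale-free in the counts", {
  m1 <- segment_metrics(12, 30, 5, 3)
  m7 <- segment_metrics(12 * 7, 30 * 7, 5 * 7, 3 * 7)
  expect_equal(m1, m7)
})

test_that("confusion counts tally predictions against labels", {
  cc <- confusion_counts(pred = c(1, 0, 1, 1, 0), truth = c(1, 0, 0, 1, 1))
  expect_equal(unname(cc), c(2L, 1L, 1L, 1L))
})

test_that("AUC equals the pairwise-comparison statistic", {
  expect_equal(auc_score(c(.1, .4, .35, .8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_score(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  set.seed(51)
  for (i in 1:10) {
    sc <- round(runif(30), 1)              # rounded: forces ties
    lab <- rbinom(30, 1, .4)
    if (length(unique(lab)) < 2) next
    expect_equal(auc_score(sc, lab), auc_oracle(sc, lab))
  }
  # independent labels at large n give AUC near 1/2
  set.seed(52)
  sc <- runif(4000); lab <- rbinom(4000, 1, .5)
  expect_lt(abs(auc_score(sc, lab) - 0.5), 0.03)
  expect_error(auc_score(c(.1, .2), c(1, 1)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  sc <- c(rnorm(40), rnorm(40, 1))
  lab <- rep(0:1, each = 40)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE)))
  expect_equal(auc_score(sc, lab), ref, tolerance = 1e-12)
})

test_that("event scoring counts overlaps, latencies and false alarms", {
  es <- event_metrics(data.frame(start_s = 120, end_s = 180),
                      data.frame(start_s = 100, end_s = 160),
                      test_hours = 1)
  expect_equal(es$n_detected, 1L)
  expect_equal(es$latencies_s, 20)
  expect_equal(es$fdr_per_h, 0)
  # prediction preceding the onset clamps latency at zero
  es2 <- event_metrics(data.frame(start_s = 80, end_s = 130),
                       data.frame(start_s = 100, end_s = 160), 1)
  expect_equal(es2$latencies_s, 0)
  # no predictions: 0% sensitivity, 0/h FDR
  es3 <- event_metrics(NULL, data.frame(start_s = 10, end_s = 50), 2)
  expect_equal(es3$sensitivity_pct, 0)
  expect_equal(es3$fdr_per_h, 0)
  # 2 false events over 2 h -> FDR 1/h
  es4 <- event_metrics(data.frame(start_s = c(10, 300),
                                  end_s = c(50, 400)),
                       data.frame(start_s = 1000, end_s = 1100), 2)
  expect_equal(es4$fdr_per_h, 1)
  expect_equal(es4$sensitivity_pct, 0)
})

test_that("event-scoring conventions: one credit per seizure, both if spanned", {
  truth <- data.frame(start_s = c(100, 300), end_s = c(150, 360))
  # two predictions inside one annotation: one detection, earliest latency
  es <- event_metrics(data.frame(start_s = c(110, 130), end_s = c(120, 140)),
                      truth, 1)
  expect_equal(es$n_detected, 1L)
  expect_equal(es$latencies_s, 10)
  expect_equal(es$n_false_alarms, 0L)
  # a single prediction spanning both annotations credits both
  es2 <- event_metrics(data.frame(start_s = 90, end_s = 400), truth, 1)
  expect_equal(es2$n_detected, 2L)
  expect_equal(es2$sensitivity_pct, 100)
  # detected + missed fractions always cover every annotated seizure
  expect_equal(es$n_detected + (es$n_seizures - es$n_detected),
               nrow(truth))
  expect_error(event_metrics(data.frame(start_s = 5, end_s = 2), truth, 1),
               "end_s > start_s")
  expect_error(event_metrics(NULL, truth, 0), "positive")
})
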