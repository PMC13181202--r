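test_that("the printed sensitivity/specificity pin down a unique confusion matrix", {
  # 37 positives / 55 negatives; brute-force all matrices and keep those whose
  # rendered SEN/SPE match the reference 91.89 / 89.09
  hits <- list()
  for (tp in 0:37) for (tn in 0:55) {
    if (as_percent(tp / 37) == 91.89 && as_percent(tn / 55) == 89.09)
      hits[[length(hits) + 1]] <- c(tp, tn)
  }
  expect_length(hits, 1L)
  expect_equal(hits[[1]], c(34, 49))
})

test_that("the metric suite reproduces the reference worked example", {
  m <- compute_metrics(confusion_matrix(tp = 34, fn = 3, fp = 6, tn = 49))
  expect_equal(as_percent(m$acc), 90.22)
  expect_equal(as_percent(m$sen), 91.89)
  expect_equal(as_percent(m$spe), 89.09)
  expect_equal(as_percent(m$f1), 88.31)
  expect_equal(as_percent(m$gmean), 90.48)
  expect_equal(m$n, 92)
})

test_that("degenerate matrices hit the documented extremes", {
  perfect <- compute_metrics(confusion_matrix(10, 0, 0, 10))
  expect_true(all(unlist(perfect[c("acc", "spe", "sen", "pre", "f1", "gmean")]) == 1))
  worst <- compute_metrics(confusion_matrix(0, 10, 10, 0))
  expect_equal(worst$acc, 0)
  expect_equal(worst$gmean, 0)
})

test_that("zero denominators are flagged undefined, never silently zero", {
  m <- compute_metrics(confusion_matrix(0, 0, 3, 7))
  expect_true(is.na(m$sen))
  expect_true(all(c("sen", "f1", "gmean") %in% attr(m, "undefined")))
  expect_equal(m$pre, 0)                      # tp/(tp+fp) is defined here
  expect_false("spe" %in% attr(m, "undefined"))
  r <- compute_rates(confusion_matrix(0, 0, 3, 7))
  expect_true(is.na(r$tpr))
  expect_equal(r$fpr, 0.3)
})

test_that("rates reproduce the reference confusion-matrix example", {
  r <- compute_rates(confusion_matrix(tp = 31, fn = 5, fp = 3, tn = 53))
  expect_equal(as_percent(r$tpr), 86.11)
  expect_equal(as_percent(r$fnr), 13.89)
  expect_equal(as_percent(r$fpr), 5.36)
  expect_equal(as_percent(r$tnr), 94.64)
  sym <- compute_rates(confusion_matrix(5, 5, 5, 5))
  expect_true(all(unlist(sym) == 0.5))
})

test_that("metric identities and orderings hold on random matrices", {
  set.seed(14)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    t <- sample(0:1, n, replace = TRUE)
    p <- sample(0:1, n, replace = TRUE)
    cm <- confusion_from_predictions(t, p)
    expect_equal(cm$tp + cm$fn + cm$fp + cm$tn, n)
    m <- compute_metrics(cm)
    expect_equal(m$acc * m$n, cm$tp + cm$tn)
    # brute-force recomputation straight from the prediction vectors
    expect_equal(m$acc, mean(t == p))
    if (!is.na(m$sen)) expect_equal(m$sen, mean(p[t == 1] == 1))
    if (!is.na(m$spe)) expect_equal(m$spe, mean(p[t == 0] == 0))
    if (!is.na(m$pre)) expect_equal(m$pre, mean(t[p == 1] == 1))
    if (!is.na(m$f1)) {
      expect_gte(m$f1, min(m$pre, m$sen) - 1e-12)
      expect_lte(m$f1, max(m$pre, m$sen) + 1e-12)
    }
    if (!is.na(m$gmean)) {
      expect_lt(abs(m$gmean^2 - m$sen * m$spe), 1e-9)
      expect_lte(m$gmean, (m$sen + m$spe) / 2 + 1e-12)
    }
    r <- compute_rates(cm)
    if (!is.na(r$tpr)) expect_equal(r$tpr + r$fnr, 1)
    if (!is.na(r$fpr)) expect_equal(r$fpr + r$tnr, 1)
  }
})

test_that("confusion matrices come out of prediction vectors and validate", {
  cm <- confusion_from_predictions(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 1, fn = 1, fp = 1, tn = 1))
  lab <- confusion_from_predictions(c("malignant", "benign"),
                                    c("malignant", "benign"))
  expect_equal(lab$tp + lab$tn, 2)
  all_neg <- confusion_from_predictions(rep(1, 6), rep(0, 6))
  expect_equal(all_neg$tp, 0); expect_equal(all_neg$fn, 6)
  expect_error(confusion_from_predictions(1, c(1, 0)), "equal length")
  expect_error(confusion_matrix(-1, 0, 0, 1), "nonnegative")
})

test_that("reports serialize to JSON and one-line CSV with 2 dp percentages", {
  m <- compute_metrics(confusion_matrix(34, 3, 6, 49))
  js <- jsonlite::fromJSON(metrics_json(m))
  expect_equal(js$acc, 90.22)
  expect_equal(js$n, 92)
  row <- metrics_csv_row(m, label = "ckpt1")
  expect_match(row, "^ckpt1,90.22,89.09,91.89,85.00,88.31,90.48,92$")
})
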