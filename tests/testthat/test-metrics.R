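test_that("confusion counts match an element-wise tally", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c(cc$fp, cc$fn), c(0, 0))

  set.seed(3)
  p <- sample(0:1, 50, replace = TRUE)
  y <- sample(0:1, 50, replace = TRUE)
  cc <- confusion_counts(p, y)
  expect_equal(cc$tp, sum(p == 1 & y == 1))
  expect_equal(cc$tn, sum(p == 0 & y == 0))
  expect_equal(cc$fp, sum(p == 1 & y == 0))
  expect_equal(cc$fn, sum(p == 0 & y == 1))
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 50)

  # inverting predictions swaps tp<->fn and tn<->fp
  ci <- confusion_counts(1 - p, y)
  expect_equal(ci$tp, cc$fn)
  expect_equal(ci$tn, cc$fp)
  expect_error(confusion_counts(c(1, 0), c(1)), "equal length")
})

test_that("classification metrics follow the printed formulas exactly", {
  perfect <- confusion_counts(c(1, 0), c(1, 0))
  m <- classification_metrics(perfect, percent = FALSE)
  expect_equal(unlist(m[c("ac", "sn", "sp", "f1", "ccr", "mcc")]),
               c(ac = 1, sn = 1, sp = 1, f1 = 1, ccr = 1, mcc = 1))

  set.seed(11)
  for (k in 1:20) {
    tp <- sample(0:30, 1); tn <- sample(0:30, 1)
    fp <- sample(0:30, 1); fn <- sample(0:30, 1)
    if (tp + tn + fp + fn == 0) next
    cc <- structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
                    class = "confusion_counts")
    m <- classification_metrics(cc, percent = FALSE)
    # independent formula evaluation
    expect_equal(m$ac, (tp + tn) / (tp + tn + fp + fn), tolerance = 1e-12)
    if (tp + fn > 0) expect_equal(m$sn, tp / (tp + fn), tolerance = 1e-12)
    if (tn + fp > 0) expect_equal(m$sp, tn / (tn + fp), tolerance = 1e-12)
    if (tp + fp + fn > 0) {
      expect_equal(m$f1, tp / (tp + 0.5 * (fp + fn)), tolerance = 1e-12)
    }
    if (!is.na(m$ccr)) expect_equal(m$ccr, (m$sn + m$sp) / 2,
                                    tolerance = 1e-12)
    den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den > 0) {
      expect_equal(m$mcc, (as.numeric(tp) * tn - as.numeric(fp) * fn) /
                     sqrt(den), tolerance = 1e-12)
      expect_true(m$mcc >= -1 && m$mcc <= 1)
    } else {
      expect_equal(m$mcc, 0)
    }
  }
})

test_that("CCR reproduces the published benchmark rows from SN/SP", {
  expect_equal(ccr_from_rates(96.2, 82.8), 89.5)
  expect_equal(ccr_from_rates(86.2, 80.3), 83.25, tolerance = 1e-12)
})

test_that("rank-based AUC equals exhaustive pair counting", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1.0)
  set.seed(5)
  s <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.2)
  y <- c(1, 1, 0, 1, 0, 0)
  expect_equal(roc_auc(s, y), oracle_auc(s, y))
  for (k in 1:10) {
    s <- round(runif(20), 1)  # force some ties
    y <- sample(0:1, 20, replace = TRUE)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), oracle_auc(s, y))
  }
  # chance level under label shuffling
  s <- rnorm(10000)
  y <- rep(0:1, 5000)
  expect_equal(roc_auc(s, y), 0.5, tolerance = 0.02)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  s <- rnorm(100)
  y <- as.numeric(s + rnorm(100) > 0)
  a <- roc_auc(s, y)
  expect_equal(roc_auc(exp(s), y), a)
  expect_equal(roc_auc(2 * s + 7, y), a)
})

test_that("Pearson correlation matches direct computation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.5)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), num / den, tolerance = 1e-10)
  expect_error(pearson_r(x, rep(1, 5)), "zero variance")
})

test_that("label aggregation trims high outliers above the 95th percentile", {
  expect_equal(aggregate_labels(6.0), 6.0)
  expect_equal(aggregate_labels(c(5.0, 5.0, 5.0)), 5.0)
  vals <- c(5.0, 5.1, 4.9, 9.0)
  q <- quantile(vals, 0.95, names = FALSE)  # independent computation
  expect_equal(aggregate_labels(vals), mean(vals[vals <= q]))
  expect_equal(aggregate_labels(vals), 5.0, tolerance = 1e-6)
  expect_error(aggregate_labels(numeric(0)), "no replicate")
})
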