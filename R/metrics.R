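# Classification and regression evaluation: confusion-matrix metrics,
# rank-based ROC AUC, Pearson correlation, and the Y-randomization protocol.

#' Confusion counts from predicted and true binary labels
#'
#' @param predicted,truth Equal-length binary vectors (logical or 0/1);
#'   1/TRUE is the positive ("blocker") class.
#' @return An object of class `confusion_counts` with fields `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("'predicted' and 'truth' must have equal length")
  }
  p <- as.logical(predicted); y <- as.logical(truth)
  if (anyNA(p) || anyNA(y)) stop("labels must be binary with no NA")
  structure(list(tp = sum(p & y), tn = sum(!p & !y),
                 fp = sum(p & !y), fn = sum(!p & y)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("TP", x$tp, " TN", x$tn, " FP", x$fp, " FN", x$fn, "\n")
  invisible(x)
}

#' Binary classification metrics
#'
#' Computes accuracy, sensitivity, specificity, F1, correct classification
#' rate (the mean of sensitivity and specificity) and the Matthews
#' correlation coefficient from confusion counts. All metrics except MCC can
#' be requested as percentages (the reporting convention of the benchmark
#' tables, where MCC is also scaled by 100). Ratios with a zero denominator
#' are reported as `NA`; MCC is 0 when any marginal is zero.
#'
#' @param counts A `confusion_counts` object.
#' @param percent Report ac/sn/sp/f1/ccr (and mcc) scaled by 100?
#' @return An object of class `metric_report` with fields `ac`, `sn`, `sp`,
#'   `f1`, `ccr`, `mcc`.
#' @export
classification_metrics <- function(counts, percent = TRUE) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion counts")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  ac <- (tp + tn) / total
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  f1 <- safe_div(tp, tp + 0.5 * (fp + fn))
  ccr <- if (is.na(sn) || is.na(sp)) NA_real_ else (sn + sp) / 2
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  }
  s <- if (percent) 100 else 1
  structure(list(ac = ac * s, sn = sn * s, sp = sp * s, f1 = f1 * s,
                 ccr = ccr * s, mcc = mcc * s, percent = percent),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 1, ...) {
  u <- if (x$percent) "%" else ""
  cat(sprintf("AC %s%s  SN %s%s  SP %s%s  F1 %s%s  CCR %s%s  MCC %s\n",
              round(x$ac, digits), u, round(x$sn, digits), u,
              round(x$sp, digits), u, round(x$f1, digits), u,
              round(x$ccr, digits), u, round(x$mcc, digits + 1)))
  invisible(x)
}

#' Correct classification rate from sensitivity and specificity
#'
#' The mean of sensitivity and specificity, on whatever scale its inputs
#' are given (so percentages in, percentages out).
#'
#' @param sn,sp Sensitivity and specificity.
#' @return `(sn + sp) / 2`.
#' @export
ccr_from_rates <- function(sn, sp) (sn + sp) / 2

#' Fold change between two pIC50 values
#'
#' pIC50 is a negative log10 molar quantity, so a difference of d log units
#' is a 10^d-fold potency ratio.
#'
#' @param pic50_a,pic50_b pIC50 values (a relative to b).
#' @return `10^(pic50_a - pic50_b)`.
#' @export
pic50_fold_change <- function(pic50_a, pic50_b) 10^(pic50_a - pic50_b)

#' Rank-based ROC AUC
#'
#' Mann-Whitney estimate: the probability that a random positive scores
#' higher than a random negative, with ties counted half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  if (length(scores) != length(y)) stop("length mismatch")
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pearson correlation
#'
#' @param x,y Numeric vectors (n >= 2, nonzero variance).
#' @return Sample Pearson r.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("need two equal-length vectors with n >= 2")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Pearson correlation undefined for zero variance")
  }
  stats::cor(x, y)
}

#' Y-randomization test
#'
#' Re-trains a model on label-permuted copies of the data and compares the
#' true-label validation metric against the permuted-label distribution. A
#' real structure-activity signal should collapse to chance under
#' permutation.
#'
#' @param records Data.frame of training records (passed to `train_fn`).
#' @param train_fn Function `(records, seed)` returning a validation metric
#'   (higher = better) for a model trained on `records`.
#' @param label_col Name of the label column to permute.
#' @param n_permutations Number of label permutations.
#' @param seed Integer seed; fixing it fixes the permutation sequence.
#' @return An object of class `y_randomization` with the true metric and
#'   the permuted metrics.
#' @export
y_randomization <- function(records, train_fn, label_col = "pic50",
                            n_permutations = 5L, seed = 1L) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (!label_col %in% names(records)) {
    stop("no column '", label_col, "' in records")
  }
  rng <- rng_make(seed)
  true_metric <- train_fn(records, rng_child_seed(rng))
  permuted <- vapply(seq_len(n_permutations), function(k) {
    shuffled <- records
    shuffled[[label_col]] <-
      shuffled[[label_col]][rng_sample(rng, nrow(records), nrow(records))]
    train_fn(shuffled, rng_child_seed(rng))
  }, numeric(1))
  structure(list(true_metric = true_metric, permuted_metrics = permuted,
                 n_permutations = n_permutations),
            class = "y_randomization")
}

#' @export
print.y_randomization <- function(x, ...) {
  cat("Y-randomization:", x$n_permutations, "permutations\n")
  cat("  true-label metric:    ", round(x$true_metric, 4), "\n")
  cat("  permuted (mean, max): ", round(mean(x$permuted_metrics), 4), ",",
      round(max(x$permuted_metrics), 4), "\n")
  invisible(x)
}
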