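#' Confusion matrix for binary malignancy classification
#'
#' Positive class is malignant. Construct either from counts or from paired
#' truth/prediction vectors via [confusion_from_predictions()].
#'
#' @param tp,fn,fp,tn nonnegative integer counts.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(v < 0) || any(v != round(v)))
    stop("confusion-matrix counts must be nonnegative integers", call. = FALSE)
  structure(as.list(v), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L, byrow = TRUE,
              dimnames = list(truth = c("malignant", "benign"),
                              predicted = c("malignant", "benign")))
  print(m)
  invisible(x)
}

#' Confusion matrix from prediction vectors
#'
#' @param y_true,y_pred equal-length binary vectors (1/TRUE/"malignant" =
#'   positive).
#' @return a [confusion_matrix()].
#' @export
confusion_from_predictions <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L)
    stop("y_true and y_pred must be nonempty and of equal length", call. = FALSE)
  to_bin <- function(v) {
    if (is.character(v) || is.factor(v)) as.integer(as.character(v) == "malignant")
    else as.integer(as.logical(v))
  }
  t <- to_bin(y_true); p <- to_bin(y_pred)
  confusion_matrix(tp = sum(t == 1 & p == 1), fn = sum(t == 1 & p == 0),
                   fp = sum(t == 0 & p == 1), tn = sum(t == 0 & p == 0))
}

.safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Evaluation metric suite
#'
#' Accuracy, specificity, sensitivity, precision, F1 (harmonic mean of
#' precision and sensitivity) and G-mean (geometric mean of sensitivity and
#' specificity, robust to class imbalance). Metrics with a zero denominator
#' are reported as `NA` and listed in the `undefined` attribute - they are
#' undefined, not zero, and silent zeros would corrupt model selection.
#'
#' @param cm a [confusion_matrix()].
#' @return object of class `metrics_report`: list of proportions `acc, spe,
#'   sen, pre, f1, gmean` plus `n`, with attribute `undefined`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  acc <- (cm$tp + cm$tn) / n
  spe <- .safe_div(cm$tn, cm$tn + cm$fp)
  sen <- .safe_div(cm$tp, cm$tp + cm$fn)
  pre <- .safe_div(cm$tp, cm$tp + cm$fp)
  f1 <- if (is.na(pre) || is.na(sen) || pre + sen == 0) NA_real_
        else 2 * pre * sen / (pre + sen)
  gmean <- if (is.na(sen) || is.na(spe)) NA_real_ else sqrt(sen * spe)
  out <- list(acc = acc, spe = spe, sen = sen, pre = pre, f1 = f1,
              gmean = gmean, n = n)
  und <- names(out)[vapply(out, function(v) length(v) == 1 && is.na(v), logical(1))]
  structure(out, class = "metrics_report", undefined = und)
}

#' @export
print.metrics_report <- function(x, ...) {
  vals <- unlist(x[c("acc", "spe", "sen", "pre", "f1", "gmean")])
  cat(paste(sprintf("%s %.2f%%", toupper(names(vals)), 100 * vals),
            collapse = "  "), sprintf(" (n=%d)\n", x$n))
  if (length(attr(x, "undefined")))
    cat("undefined:", paste(attr(x, "undefined"), collapse = ", "), "\n")
  invisible(x)
}

#' True/false positive/negative rates
#'
#' @param cm a [confusion_matrix()].
#' @return object of class `rate_report`: list `tpr, fnr, fpr, tnr`
#'   (proportions, `NA` when a row sum is zero).
#' @export
compute_rates <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  pos <- cm$tp + cm$fn; neg <- cm$fp + cm$tn
  structure(list(tpr = .safe_div(cm$tp, pos), fnr = .safe_div(cm$fn, pos),
                 fpr = .safe_div(cm$fp, neg), tnr = .safe_div(cm$tn, neg)),
            class = "rate_report")
}

#' @export
print.rate_report <- function(x, ...) {
  cat(sprintf("TPR %.2f%%  FNR %.2f%%  FPR %.2f%%  TNR %.2f%%\n",
              100 * x$tpr, 100 * x$fnr, 100 * x$fpr, 100 * x$tnr))
  invisible(x)
}

#' Serialize a metrics report
#'
#' @param x a `metrics_report`.
#' @param path optional file; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
metrics_json <- function(x, path = NULL) {
  obj <- lapply(x[c("acc", "spe", "sen", "pre", "f1", "gmean")],
                function(v) if (is.na(v)) NULL else as_percent(v))
  obj$n <- x$n
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' One-line CSV rendering of a metrics report
#'
#' Percentages at 2 dp (half-up), for aggregation across checkpoints.
#'
#' @param x a `metrics_report`.
#' @param label row label (first field).
#' @return character scalar CSV row `label,acc,spe,sen,pre,f1,gmean,n`.
#' @export
metrics_csv_row <- function(x, label = "model") {
  vals <- vapply(x[c("acc", "spe", "sen", "pre", "f1", "gmean")],
                 function(v) if (is.na(v)) "" else sprintf("%.2f", as_percent(v)),
                 character(1))
  paste(c(label, vals, x$n), collapse = ",")
}
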