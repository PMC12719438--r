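#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Exact two-sided confidence interval for a binomial proportion from Beta
#' quantiles: the lower bound is `qbeta(alpha/2, x, n - x + 1)` (0 when
#' `x == 0`) and the upper bound is `qbeta(1 - alpha/2, x + 1, n - x)`
#' (1 when `x == n`). The interval is conservative: coverage is at least the
#' nominal level for every true proportion.
#'
#' @param x number of successes (0 <= x <= n).
#' @param n number of trials. `n = 0` yields an undefined estimate with the
#'   uninformative interval \[0, 1\] and `undefined = TRUE`.
#' @param level confidence level, default 0.95.
#' @return list with `estimate`, `lower`, `upper`, `undefined`.
#' @examples
#' exact_ci(12, 12)  # lower bound 0.74 at 2 dp
#' @export
exact_ci <- function(x, n, level = 0.95) {
  stopifnot(length(x) == 1, length(n) == 1, n >= 0, x >= 0, x <= max(n, 0))
  if (n == 0) {
    return(list(estimate = NA_real_, lower = 0, upper = 1, undefined = TRUE))
  }
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  list(estimate = x / n, lower = lower, upper = upper, undefined = FALSE)
}

#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return a `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), class = "confusion_counts")
}

#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth logical or 0/1 vectors; `TRUE`/1 is the positive
#'   (EC) class.
#' @export
confusion_from_labels <- function(predicted, truth) {
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  stopifnot(length(predicted) == length(truth), !anyNA(predicted), !anyNA(truth))
  confusion_counts(
    tp = sum(predicted & truth), fp = sum(predicted & !truth),
    tn = sum(!predicted & !truth), fn = sum(!predicted & truth)
  )
}

metric_block <- function(x, n, level) {
  ci <- exact_ci(x, n, level)
  list(estimate = ci$estimate, lower = ci$lower, upper = ci$upper,
       undefined = ci$undefined, x = x, n = n)
}

#' Diagnostic metrics with exact confidence intervals
#'
#' Sensitivity, specificity, PPV and NPV from a confusion table, each with an
#' exact binomial confidence interval on its own numerator/denominator. A
#' metric whose denominator is zero is flagged `undefined` and reported with
#' the uninformative interval \[0, 1\] (serialized as null/NaN), rather than
#' raising an error.
#'
#' @param counts a `confusion_counts` object.
#' @param level confidence level for the exact intervals.
#' @return a `metric_report` list of per-metric blocks.
#' @export
confusion_metrics <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, structure(list(
    sensitivity = metric_block(tp, tp + fn, level),
    specificity = metric_block(tn, tn + fp, level),
    ppv         = metric_block(tp, tp + fp, level),
    npv         = metric_block(tn, tn + fn, level),
    counts      = unclass(counts),
    level       = level
  ), class = "metric_report"))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a randomly chosen
#' positive sample receives a higher score than a randomly chosen negative
#' one, with tied scores contributing 1/2.
#'
#' @param probabilities numeric scores, higher = more likely positive.
#' @param labels logical or 0/1 truth; `TRUE`/1 positive.
#' @return AUROC in \[0, 1\], or `NA` (with a warning) if only one class is
#'   present.
#' @export
auroc <- function(probabilities, labels) {
  labels <- as.logical(labels)
  stopifnot(length(probabilities) == length(labels), !anyNA(probabilities))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    warning("AUROC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Assemble a full metric report from scores and truth
#'
#' @param probabilities predicted probabilities of the positive class.
#' @param truth logical or 0/1 truth labels.
#' @param threshold classification threshold; probability >= threshold is
#'   called positive.
#' @param level confidence level.
#' @export
metric_report <- function(probabilities, truth, threshold = 0.5, level = 0.95) {
  predicted <- probabilities >= threshold
  rep <- confusion_metrics(confusion_from_labels(predicted, truth), level)
  truth <- as.logical(truth)
  rep$auroc <- if (length(unique(truth)) == 2) {
    auroc(probabilities, truth)
  } else NA_real_
  rep$n <- length(truth)
  rep$threshold <- threshold
  rep
}

#' F1 score at a fixed classification threshold
#'
#' Harmonic mean of precision and recall. Returns 0 when there are no true
#' positives (the limit of the harmonic mean as precision or recall vanishes).
#'
#' @param probabilities predicted probabilities.
#' @param truth logical or 0/1 truth labels.
#' @param threshold classification threshold (>= is positive).
#' @export
f1_score <- function(probabilities, truth, threshold = 0.5) {
  predicted <- probabilities >= threshold
  truth <- as.logical(truth)
  tp <- sum(predicted & truth)
  if (tp == 0) return(0)
  precision <- tp / sum(predicted)
  recall <- tp / sum(truth)
  2 * precision * recall / (precision + recall)
}

#' Format a metric report as a one-row summary table
#'
#' Presentation mirrors the published style: point estimate with bracketed
#' exact 95% interval, `NaN [0, 1]` for undefined metrics.
#'
#' @param report a `metric_report`.
#' @param label row label for the model variant.
#' @export
format_metric_report <- function(report, label = "model") {
  fmt <- function(b) {
    est <- if (isTRUE(b$undefined)) "NaN" else sprintf("%.2f", b$estimate)
    sprintf("%s [%.2f, %.2f]", est, b$lower, b$upper)
  }
  data.frame(
    model = label,
    npv = fmt(report$npv), sensitivity = fmt(report$sensitivity),
    ppv = fmt(report$ppv), specificity = fmt(report$specificity),
    auroc = if (is.null(report$auroc) || is.na(report$auroc)) "NaN"
            else sprintf("%.2f", report$auroc),
    stringsAsFactors = FALSE
  )
}

#' Serialize a metric report to JSON
#'
#' Undefined metrics serialize with `estimate = null` and interval \[0, 1\].
#'
#' @param report a `metric_report`.
#' @param path output file path.
#' @export
write_metric_report <- function(report, path) {
  clean <- lapply(report, function(b) {
    if (is.list(b) && isTRUE(b$undefined)) b$estimate <- NULL
    b
  })
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
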