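#' Evaluate phage-contig predictions
#'
#' Confusion counts and the six summary metrics (sensitivity,
#' specificity, precision, F1, accuracy, MCC) under one of two weighting
#' schemes: with `weighting = "count"` every contig contributes 1; with
#' `weighting = "abundance"` every contig contributes its relative
#' abundance (the fraction of the sample's reads mapping to it), so the
#' metrics measure how much of the community's read mass is classified
#' correctly. Ambiguous and confident non-phage labels both count as the
#' negative class.
#'
#' Ratios with a zero denominator are reported as `NaN` and flagged in
#' the `undefined` attribute rather than silently zeroed.
#'
#' @param predicted character vector of calls, `"phage"`/`"non_phage"`,
#'   or logical (TRUE = phage).
#' @param labels character vector of true labels
#'   (`"phage"`/`"ambiguous"`/`"non_phage"`), parallel to `predicted`.
#' @param abundances numeric vector of relative abundances, required for
#'   `weighting = "abundance"`.
#' @param weighting `"count"` or `"abundance"`.
#' @return an object of class `perf_report`: a list with `weighting`,
#'   `TP`, `FP`, `TN`, `FN` and the six metrics; `undefined` attribute
#'   names any metric with a zero denominator.
#' @export
evaluate_predictions <- function(predicted, labels, abundances = NULL,
                                 weighting = c("count", "abundance")) {
  weighting <- match.arg(weighting)
  if (length(predicted) == 0L) stop("empty prediction set", call. = FALSE)
  if (length(predicted) != length(labels))
    stop("predicted and labels differ in length", call. = FALSE)
  pred <- if (is.logical(predicted)) predicted else predicted == "phage"
  if (anyNA(pred)) stop("NA in predictions", call. = FALSE)
  truth <- labels == "phage"  # ambiguous counted as non-phage
  if (weighting == "abundance") {
    if (is.null(abundances) || anyNA(abundances))
      stop("abundance weighting requires a relative abundance per contig",
           call. = FALSE)
    w <- abundances
  } else {
    w <- rep(1, length(pred))
  }
  conf <- c(TP = sum(w[pred & truth]), FP = sum(w[pred & !truth]),
            TN = sum(w[!pred & !truth]), FN = sum(w[!pred & truth]))
  .perf_report(conf, weighting)
}

.safe_div <- function(num, den) {
  if (is.nan(num) || is.nan(den) || den == 0) NaN else num / den
}

.perf_report <- function(conf, weighting) {
  TP <- conf[["TP"]]; FP <- conf[["FP"]]
  TN <- conf[["TN"]]; FN <- conf[["FN"]]
  sens <- .safe_div(TP, TP + FN)
  spec <- .safe_div(TN, TN + FP)
  prec <- .safe_div(TP, TP + FP)
  f1 <- .safe_div(2 * prec * sens, prec + sens)
  acc <- .safe_div(TP + TN, TP + TN + FP + FN)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) NaN else (TP * TN - FP * FN) / mcc_den
  rep <- list(weighting = weighting, TP = TP, FP = FP, TN = TN, FN = FN,
              sensitivity = sens, specificity = spec, precision = prec,
              f1 = f1, accuracy = acc, mcc = mcc)
  metrics <- c("sensitivity", "specificity", "precision", "f1",
               "accuracy", "mcc")
  attr(rep, "undefined") <- metrics[vapply(rep[metrics], is.nan, TRUE)]
  class(rep) <- "perf_report"
  rep
}

#' @export
print.perf_report <- function(x, ...) {
  cat(sprintf("Performance report (%s-weighted)\n", x$weighting))
  cat(sprintf("  TP=%.4g FP=%.4g TN=%.4g FN=%.4g\n", x$TP, x$FP, x$TN, x$FN))
  for (m in c("sensitivity", "specificity", "precision", "f1",
              "accuracy", "mcc"))
    cat(sprintf("  %-12s %.4f\n", m, x[[m]]))
  und <- attr(x, "undefined")
  if (length(und)) cat("  undefined:", paste(und, collapse = ", "), "\n")
  invisible(x)
}

#' Restrict an evaluation to high-abundance contigs
#'
#' Recomputes a performance report using only contigs whose relative
#' abundance exceeds `floor` (strict), the filter used when visualising
#' high-abundance true positives.
#'
#' @inheritParams evaluate_predictions
#' @param floor strict lower abundance bound, default 0.001.
#' @return a `perf_report`; `empty` attribute set if no contig passes.
#' @export
high_abundance_view <- function(predicted, labels, abundances,
                                weighting = c("count", "abundance"),
                                floor = 0.001) {
  weighting <- match.arg(weighting)
  keep <- abundances > floor
  if (!any(keep)) {
    rep <- .perf_report(c(TP = 0, FP = 0, TN = 0, FN = 0), weighting)
    attr(rep, "empty") <- TRUE
    return(rep)
  }
  evaluate_predictions(predicted[keep], labels[keep], abundances[keep],
                       weighting)
}

#' Aggregate performance reports across subjects
#'
#' Arithmetic mean and sample standard deviation of each metric over a
#' list of reports (e.g. one per held-out subject). `NaN` metric values
#' are skipped, with the number of contributing reports recorded.
#'
#' @param reports list of `perf_report` objects.
#' @return data.frame with columns `metric`, `mean`, `sd`, `n_used`.
#' @export
aggregate_reports <- function(reports) {
  if (!length(reports)) stop("no reports to aggregate", call. = FALSE)
  metrics <- c("sensitivity", "specificity", "precision", "f1",
               "accuracy", "mcc")
  rows <- lapply(metrics, function(m) {
    v <- vapply(reports, function(r) r[[m]], numeric(1))
    v <- v[!is.nan(v)]
    data.frame(metric = m,
               mean = if (length(v)) mean(v) else NaN,
               sd = if (length(v) > 1L) sd(v) else NaN,
               n_used = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
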