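#' Confusion matrix of binary calls against binary truth
#'
#' @param truth Character vector of `"P"`/`"B"` truth labels.
#' @param calls Character vector of `"P"`/`"B"` calls, same length.
#' @param drop_missing Drop pairs where either entry is `NA`
#'   (pairwise-complete evaluation, the default). With `FALSE`, missing
#'   entries are an error.
#' @return An object of class `"confusion_matrix"` with integer fields
#'   `tp`, `fp`, `tn`, `fn` and attribute `n_dropped`.
#' @export
#' @examples
#' confusion(c("P", "P", "B", "B"), c("P", "B", "B", "P"))
confusion <- function(truth, calls, drop_missing = TRUE) {
  if (length(truth) != length(calls)) {
    stop("truth and calls must have equal length", call. = FALSE)
  }
  ok_lab <- function(x) all(is.na(x) | x %in% c("P", "B"))
  if (!ok_lab(truth) || !ok_lab(calls)) {
    stop("labels must be 'P', 'B' or NA", call. = FALSE)
  }
  miss <- is.na(truth) | is.na(calls)
  if (any(miss)) {
    if (!drop_missing) stop("missing truth or call entries", call. = FALSE)
    truth <- truth[!miss]; calls <- calls[!miss]
  }
  out <- structure(list(tp = sum(truth == "P" & calls == "P"),
                        fp = sum(truth == "B" & calls == "P"),
                        tn = sum(truth == "B" & calls == "B"),
                        fn = sum(truth == "P" & calls == "B")),
                   class = "confusion_matrix")
  attr(out, "n_dropped") <- sum(miss)
  out
}

#' Construct a confusion matrix from its four cell counts
#'
#' @param tp,fp,tn,fn Non-negative integer cell counts.
#' @return An object of class `"confusion_matrix"`.
#' @export
#' @examples
#' confusion_matrix(tp = 14, fp = 46, tn = 94, fn = 7)
confusion_matrix <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != round(v))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(as.integer(v)) |> stats::setNames(names(v)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("P", "B"), call = c("P", "B")))
  print(m)
  invisible(x)
}

#' Performance statistics of a confusion matrix
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(FP+TN)`, accuracy
#' `(TP+TN)/total` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A statistic whose
#' denominator is zero is reported as `NA` (sensitivity/specificity) or 0 with
#' `mcc_degenerate = TRUE` (MCC; the conventional value for a constant
#' prediction).
#'
#' @param cm A `"confusion_matrix"`.
#' @return An object of class `"performance_report"` with fields `sens`,
#'   `spec`, `acc`, `mcc`, `mcc_degenerate`, `n`, and the source matrix.
#' @export
#' @examples
#' performance(confusion_matrix(tp = 14, fp = 46, tn = 94, fn = 7))
performance <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (fp + tn) else NA_real_
  acc <- (tp + tn) / total
  # products as doubles: counts up to 1e4 would overflow integer multiplication
  denom <- sqrt((tp + fp) * (tp + fn)) * sqrt(as.numeric(tn + fp) * (tn + fn))
  degen <- denom == 0
  mcc <- if (degen) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
  structure(list(sens = sens, spec = spec, acc = acc, mcc = mcc,
                 mcc_degenerate = degen, n = total, cm = cm),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, digits = 2, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else
    formatC(round_half_up(v, digits), format = "f", digits = digits)
  cat(sprintf("SENS %s  SPEC %s  ACC %s  MCC %s  (n = %d%s)\n",
              fmt(x$sens), fmt(x$spec), fmt(x$acc), fmt(x$mcc), x$n,
              if (x$mcc_degenerate) ", MCC degenerate" else ""))
  invisible(x)
}

#' Family-weighted counts of erroneous results
#'
#' Misclassifying a variant affects every family carrying it; these counts
#' weight each false call by the number of index families in the registry that
#' carry the variant, giving the number of families that would receive an
#' erroneous negative (false negative) or positive (false positive) test
#' result if diagnosis relied on the in silico call alone.
#'
#' @param variants Variant data frame with `truth_class` and `family_count`.
#' @param calls Character vector of `"P"`/`"B"` calls, one per variant (or a
#'   named vector indexed by `variant_id`).
#' @return List with `families_false_negative` and `families_false_positive`.
#' @export
impact_counts <- function(variants, calls) {
  stopifnot(is.data.frame(variants))
  if (!is.null(names(calls)) && all(variants$variant_id %in% names(calls))) {
    calls <- calls[as.character(variants$variant_id)]
  }
  if (length(calls) != nrow(variants)) {
    stop("need one call per variant", call. = FALSE)
  }
  if (any(is.na(calls))) {
    stop("missing call for: ",
         paste(variants$variant_id[is.na(calls)], collapse = ", "), call. = FALSE)
  }
  truth <- truth_call(variants$truth_class)
  fam <- as.numeric(variants$family_count)
  if (any(is.na(fam) | fam < 0)) {
    stop("every variant needs a non-negative family_count", call. = FALSE)
  }
  list(families_false_negative = sum(fam[truth %in% "P" & calls == "B"]),
       families_false_positive = sum(fam[truth %in% "B" & calls == "P"]))
}

#' Stand-alone performance of each predictor on a variant set
#'
#' @param variants Variant data frame with harmonized `*_call` columns (see
#'   [harmonize_calls()]) and `truth_class`.
#' @param tools Character vector of tools to evaluate.
#' @return Data frame with one row per tool: confusion cells, SENS, SPEC,
#'   ACC, MCC, the number of variants dropped for missing calls, and
#'   family-weighted false-negative/false-positive counts.
#' @export
evaluate_tools <- function(variants, tools = vusbench_tools()) {
  truth <- truth_call(variants$truth_class)
  rows <- lapply(tools, function(tool) {
    calls <- variants[[call_column(tool)]]
    cm <- confusion(truth, calls)
    perf <- performance(cm)
    keep <- !is.na(calls) & !is.na(truth)
    imp <- impact_counts(variants[keep, , drop = FALSE], calls[keep])
    data.frame(tool = tool, tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
               sens = perf$sens, spec = perf$spec, acc = perf$acc,
               mcc = perf$mcc, n_dropped = attr(cm, "n_dropped"),
               families_fn = imp$families_false_negative,
               families_fp = imp$families_false_positive,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
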