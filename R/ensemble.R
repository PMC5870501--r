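#' The four supported predictors
#'
#' @return Character vector of canonical tool names, in the order used
#'   throughout: `align_gvgd`, `sift`, `mutation_taster2`, `polyphen2`.
#' @export
vusbench_tools <- function() c("align_gvgd", "sift", "mutation_taster2", "polyphen2")

# harmonized-call column for a canonical tool name
call_column <- function(tool) {
  map <- c(align_gvgd = "agvgd_call", sift = "sift_call",
           mutation_taster2 = "mt2_call", polyphen2 = "pph2_call")
  unname(map[match(tool, names(map))])
}

#' Enumerate admissible m-of-n voting schemes
#'
#' A scheme votes over a subset of `n` tools and calls a variant pathogenic
#' when at least `m` of them do. Admissible schemes require a majority,
#' `m >= n/2`, and exclude the two-tool case entirely: for `n = 2` the only
#' candidate is the unanimous `m = 2`, which is excluded, so no two-tool
#' scheme exists. With four tools this yields 11 schemes: two per three-tool
#' subset (m in \{2, 3\}) and three for the full set (m in \{2, 3, 4\}).
#'
#' @param tools Character vector of distinct tool names (default all four).
#' @return List of `"ensemble_scheme"` objects, each with fields `tools`,
#'   `n` and `m`.
#' @export
admissible_schemes <- function(tools = vusbench_tools()) {
  stopifnot(!anyDuplicated(tools), length(tools) >= 2)
  schemes <- list()
  for (n in 2:length(tools)) {
    # n = 2 admits only the unanimous vote, which is excluded: skip entirely
    if (n == 2L) next
    subsets <- utils::combn(tools, n, simplify = FALSE)
    for (sub in subsets) {
      for (m in ceiling(n / 2):n) {
        schemes[[length(schemes) + 1L]] <- structure(
          list(tools = sub, n = n, m = as.integer(m)),
          class = "ensemble_scheme")
      }
    }
  }
  schemes
}

#' @export
print.ensemble_scheme <- function(x, ...) {
  cat(sprintf("%d-of-%d vote over {%s}\n", x$m, x$n,
              paste(x$tools, collapse = ", ")))
  invisible(x)
}

#' m-of-n majority vote over binary calls
#'
#' @param calls Character matrix or data frame of `"P"`/`"B"` calls, one
#'   column per tool, or a vector for a single variant.
#' @param m Vote threshold: pathogenic iff at least `m` tools call pathogenic.
#' @return Character vector of `"P"`/`"B"` combined calls.
#' @export
#' @examples
#' ensemble_call(c("P", "P", "B", "B"), m = 2)
ensemble_call <- function(calls, m) {
  if (is.data.frame(calls)) calls <- as.matrix(calls)
  if (!is.matrix(calls)) calls <- matrix(calls, nrow = 1L)
  n <- ncol(calls)
  if (!(m >= 1 && m <= n)) stop("m must lie in 1..n", call. = FALSE)
  if (anyNA(calls)) {
    stop("ensemble voting requires complete calls; drop incomplete variants upstream",
         call. = FALSE)
  }
  if (!all(calls %in% c("P", "B"))) stop("calls must be 'P' or 'B'", call. = FALSE)
  votes <- rowSums(calls == "P")
  ifelse(votes >= m, "P", "B")
}

#' Poisson-binomial probability mass function
#'
#' Distribution of the number of successes among independent Bernoulli trials
#' with distinct success probabilities, computed by iterative convolution
#' (exact up to floating point; O(n^2)).
#'
#' @param probs Vector of success probabilities in \[0, 1\].
#' @return Numeric vector of length `length(probs) + 1`: P(X = 0..n).
#' @export
poisson_binomial_pmf <- function(probs) {
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  pmf <- 1
  for (p in probs) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  pmf
}

#' Expected m-of-n performance under independent predictors
#'
#' Best-case model of a voting ensemble assuming the tools' calls are
#' mutually independent with the given marginals. The number of pathogenic
#' votes is then Poisson-binomial:
#' * sensitivity mode: per-tool success probabilities are the sensitivities
#'   and the expected combined sensitivity is `P(X >= m)` on pathogenic
#'   variants;
#' * specificity mode: success probabilities are the false-positive rates
#'   (1 - specificity) and the expected combined specificity is `P(Y < m)`
#'   on neutral variants.
#'
#' @param probs Per-tool sensitivities (sensitivity mode) or false-positive
#'   rates (specificity mode); length n >= 2.
#' @param m Vote threshold.
#' @param mode `"sensitivity"` or `"specificity"`.
#' @return The expected probability.
#' @export
#' @examples
#' expected_combined(c(1, 1, 0.90, 0.67), m = 4)            # 0.603
#' expected_combined(c(0.1, 0.2, 0.3), m = 2, "specificity") # 0.902
expected_combined <- function(probs, m, mode = c("sensitivity", "specificity")) {
  mode <- match.arg(mode)
  n <- length(probs)
  if (n < 2) stop("need at least two tools", call. = FALSE)
  if (!(m >= 1 && m <= n)) stop("m must lie in 1..n", call. = FALSE)
  pmf <- poisson_binomial_pmf(probs)
  tail_ge_m <- sum(pmf[(m + 1L):(n + 1L)])
  if (mode == "sensitivity") tail_ge_m else 1 - tail_ge_m
}

#' Consensus partition of variants by four-tool agreement
#'
#' @param calls Data frame or matrix of complete `"P"`/`"B"` calls with one
#'   column per tool (columns named by tool).
#' @return List with `counts` (named vector: `concordant_benign`,
#'   `concordant_pathogenic`, `discordant`), `category` (per-variant vector),
#'   and per-tool `exclusive_pathogenic` / `exclusive_benign` counts (variants
#'   where exactly one tool made that call).
#' @export
consensus_partition <- function(calls) {
  if (is.data.frame(calls)) calls <- as.matrix(calls)
  if (anyNA(calls)) stop("consensus partition requires complete calls", call. = FALSE)
  if (!all(calls %in% c("P", "B"))) stop("calls must be 'P' or 'B'", call. = FALSE)
  votes <- rowSums(calls == "P")
  n <- ncol(calls)
  category <- ifelse(votes == 0, "concordant_benign",
                     ifelse(votes == n, "concordant_pathogenic", "discordant"))
  excl_p <- colSums(calls == "P" & votes == 1)
  excl_b <- colSums(calls == "B" & votes == n - 1)
  list(counts = c(concordant_benign = sum(category == "concordant_benign"),
                  concordant_pathogenic = sum(category == "concordant_pathogenic"),
                  discordant = sum(category == "discordant")),
       category = category,
       exclusive_pathogenic = excl_p,
       exclusive_benign = excl_b)
}

#' Benignity screen: unanimous benign call by selected tools
#'
#' Screens variants for benignity: `TRUE` when every screening tool calls the
#' variant benign. The default screening pair is SIFT and MutationTaster2,
#' the two tools with no observed false-negative calls.
#'
#' @param calls Data frame/matrix of calls with columns named by tool.
#' @param screen_tools Tools whose unanimous benign call triggers the screen.
#' @return Logical vector.
#' @export
benignity_screen <- function(calls, screen_tools = c("sift", "mutation_taster2")) {
  if (is.data.frame(calls)) calls <- as.matrix(calls)
  missing_cols <- setdiff(screen_tools, colnames(calls))
  if (length(missing_cols)) {
    stop("calls missing for screen tools: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sub <- calls[, screen_tools, drop = FALSE]
  if (anyNA(sub)) stop("benignity screen requires complete calls", call. = FALSE)
  rowSums(sub == "B") == length(screen_tools)
}

#' Observed and independence-expected performance of voting schemes
#'
#' For each admissible scheme, computes the observed confusion matrix of the
#' m-of-n vote on the variant set, the expected sensitivity and specificity
#' under the independence model ([expected_combined()], using each member
#' tool's observed stand-alone marginals on the same variants), expected
#' accuracy and MCC derived from the expected cell counts at the observed
#' prevalence, and family-weighted false-call counts. Variants with any
#' missing member call are dropped from that scheme (count reported).
#'
#' @param variants Variant data frame with harmonized `*_call` columns and
#'   `truth_class` (and `family_count` for impact counts).
#' @param schemes List of schemes from [admissible_schemes()].
#' @return Data frame, one row per scheme.
#' @export
evaluate_ensembles <- function(variants, schemes = admissible_schemes()) {
  truth_all <- truth_call(variants$truth_class)
  has_fam <- "family_count" %in% names(variants) &&
    !anyNA(variants$family_count)
  rows <- lapply(schemes, function(s) {
    cols <- vapply(s$tools, call_column, character(1))
    call_mat <- as.matrix(variants[, cols, drop = FALSE])
    colnames(call_mat) <- s$tools
    complete <- stats::complete.cases(call_mat) & !is.na(truth_all)
    cm_mat <- call_mat[complete, , drop = FALSE]
    truth <- truth_all[complete]
    comb <- ensemble_call(cm_mat, s$m)
    perf <- performance(confusion(truth, comb))
    # member marginals measured on the same complete-case set
    sens_i <- vapply(s$tools, function(t) {
      performance(confusion(truth, cm_mat[, t]))$sens
    }, numeric(1))
    fpr_i <- vapply(s$tools, function(t) {
      1 - performance(confusion(truth, cm_mat[, t]))$spec
    }, numeric(1))
    e_sens <- if (anyNA(sens_i)) NA_real_ else
      expected_combined(sens_i, s$m, "sensitivity")
    e_spec <- if (anyNA(fpr_i)) NA_real_ else
      expected_combined(fpr_i, s$m, "specificity")
    n_p <- sum(truth == "P"); n_b <- sum(truth == "B")
    e_perf <- expected_performance_from_cells(e_sens, e_spec, n_p, n_b)
    fams <- if (has_fam) {
      imp <- impact_counts(variants[complete, , drop = FALSE], comb)
      c(imp$families_false_negative, imp$families_false_positive)
    } else c(NA_real_, NA_real_)
    data.frame(tools = paste(s$tools, collapse = "+"), n = s$n, m = s$m,
               tp = perf$cm$tp, fp = perf$cm$fp, tn = perf$cm$tn, fn = perf$cm$fn,
               sens = perf$sens, spec = perf$spec, acc = perf$acc, mcc = perf$mcc,
               expected_sens = e_sens, expected_spec = e_spec,
               expected_acc = e_perf$acc, expected_mcc = e_perf$mcc,
               n_dropped = sum(!complete),
               families_fn = fams[1], families_fp = fams[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# expected ACC/MCC from expected (fractional) cell counts at fixed prevalence;
# a package construction, not part of the independence model proper
expected_performance_from_cells <- function(e_sens, e_spec, n_p, n_b) {
  if (is.na(e_sens) || is.na(e_spec)) return(list(acc = NA_real_, mcc = NA_real_))
  tp <- n_p * e_sens; fn <- n_p - tp
  tn <- n_b * e_spec; fp <- n_b - tn
  acc <- (tp + tn) / (n_p + n_b)
  denom <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  list(acc = acc, mcc = mcc)
}
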