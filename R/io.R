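variant_table_columns <- function() {
  list(character = c("variant_id", "gene", "sift_label", "mt2_label",
                     "pph2_label", "agvgd_class"),
       numeric = c("product_of_lrs", af_columns, "sift_score"),
       integer = c("truth_class", "family_count"),
       logical = c("spliceogenic", "expert_override"))
}

mandatory_columns <- function() {
  c("variant_id", "gene", "truth_class", "product_of_lrs", af_columns,
    "spliceogenic", "expert_override", "family_count")
}

parse_numeric_col <- function(x, col) {
  raw <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & nzchar(raw) & is.na(out))
  if (length(bad)) {
    stop(sprintf("malformed numeric value '%s' in column '%s', row %d",
                 raw[bad[1]], col, bad[1]), call. = FALSE)
  }
  out
}

#' Read / write the tab-separated variant table
#'
#' The native exchange format is a TSV with one header row and one row per
#' variant. Mandatory columns: `variant_id`, `gene`, `truth_class`,
#' `product_of_lrs`, the six cohort allele frequencies `af_afr, af_eas,
#' af_sas, af_fin, af_nfe, af_amr`, `spliceogenic`, `expert_override`,
#' `family_count`. Raw predictor columns (`agvgd_class`, `sift_score`,
#' `sift_label`, `mt2_label`, `pph2_label`) and any further columns are
#' carried through unchanged. Empty cells are missing values; numbers use dot
#' decimals regardless of locale. Write-then-read round-trips all declared
#' columns losslessly.
#'
#' @param path File path.
#' @param variants Variant data frame to write.
#' @return `read_variant_table()` returns the variant data frame;
#'   `write_variant_table()` returns `path` invisibly.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = c("", "NA"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(mandatory_columns(), names(df))
  if (length(missing_cols)) {
    stop("variant table missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  types <- variant_table_columns()
  for (col in intersect(types$numeric, names(df))) {
    df[[col]] <- parse_numeric_col(df[[col]], col)
  }
  for (col in intersect(types$integer, names(df))) {
    v <- parse_numeric_col(df[[col]], col)
    if (any(!is.na(v) & v != round(v))) {
      stop("column '", col, "' must be integer-valued", call. = FALSE)
    }
    df[[col]] <- as.integer(v)
  }
  for (col in intersect(types$logical, names(df))) {
    df[[col]] <- isTRUE_vec(df[[col]], nrow(df))
  }
  df
}

#' @rdname read_variant_table
#' @export
write_variant_table <- function(variants, path) {
  stopifnot(is.data.frame(variants))
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full evaluation pipeline on a variant table
#'
#' Orchestrates curation (classified set, then the prior-independent
#' evaluation set), harmonization of raw predictor outputs, stand-alone
#' per-tool performance, m-of-n ensemble evaluation with independence
#' expectations, the four-tool consensus partition, the benignity screen, and
#' family-weighted impact counts. Deterministic given its inputs.
#'
#' @param variants Variant data frame or a path to a TSV readable by
#'   [read_variant_table()].
#' @param priors A [prior_config()].
#' @param thresholds A [plon_thresholds()].
#' @param af_max Allele-frequency cutoff for the classified set.
#' @param schemes Voting schemes (default [admissible_schemes()]).
#' @param on Which curated set to evaluate on: `"evaluation"` (default,
#'   circularity-free) or `"classified"`.
#' @return An object of class `"report_bundle"`: fields `curation`,
#'   `composition`, `tool_metrics`, `ensemble_metrics`, `consensus`,
#'   `benign_screen_fraction`, `exclusion_log`, `evaluated_set`.
#' @export
run_pipeline <- function(variants, priors = prior_config(),
                         thresholds = plon_thresholds(), af_max = 0.01,
                         schemes = admissible_schemes(),
                         on = c("evaluation", "classified")) {
  on <- match.arg(on)
  if (is.character(variants) && length(variants) == 1L) {
    variants <- read_variant_table(variants)
  }
  cur <- curate(variants, priors = priors, thresholds = thresholds,
                af_max = af_max)
  eval_set <- if (on == "evaluation") cur$evaluation_set else cur$classified_set
  eval_set <- harmonize_calls(eval_set)
  call_cols <- vapply(vusbench_tools(), call_column, character(1))
  call_mat <- as.matrix(eval_set[, call_cols, drop = FALSE])
  colnames(call_mat) <- vusbench_tools()
  complete <- stats::complete.cases(call_mat)
  consensus <- if (any(complete)) {
    consensus_partition(call_mat[complete, , drop = FALSE])
  } else NULL
  screen_frac <- if (any(complete)) {
    mean(benignity_screen(call_mat[complete, , drop = FALSE]))
  } else NA_real_
  structure(list(
    curation = cur,
    composition = set_composition(eval_set),
    tool_metrics = evaluate_tools(eval_set),
    ensemble_metrics = evaluate_ensembles(eval_set, schemes),
    consensus = consensus,
    benign_screen_fraction = screen_frac,
    exclusion_log = cur$exclusion_log,
    evaluated_set = eval_set),
    class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, digits = 2, ...) {
  cat("Variant-set evaluation report\n\n")
  print(x$curation)
  cat("\nComposition:\n")
  print(x$composition)
  cat("\nStand-alone tool performance:\n")
  tm <- x$tool_metrics
  for (col in c("sens", "spec", "acc", "mcc")) {
    tm[[col]] <- round_half_up(tm[[col]], digits)
  }
  print(tm[, c("tool", "tp", "fp", "tn", "fn", "sens", "spec", "acc", "mcc")])
  cat("\nTop voting schemes (by MCC):\n")
  em <- x$ensemble_metrics
  em <- em[order(-em$mcc), c("tools", "m", "n", "sens", "spec", "acc", "mcc",
                             "expected_sens", "expected_spec")]
  for (col in setdiff(names(em), c("tools", "m", "n"))) {
    em[[col]] <- round_half_up(em[[col]], digits)
  }
  print(utils::head(em, 5), row.names = FALSE)
  if (!is.null(x$consensus)) {
    cat("\nConsensus partition:\n")
    print(x$consensus$counts)
  }
  cat(sprintf("\nBenignity screen (SIFT & MutationTaster2 both benign): %.1f%%\n",
              100 * x$benign_screen_fraction))
  invisible(x)
}
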