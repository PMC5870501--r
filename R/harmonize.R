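#' @name harmonize
#' @title Harmonize raw predictor outputs to binary pathogenic/benign calls
#'
#' @description
#' Each supported predictor reports in its own vocabulary; these functions map
#' the raw output to a binary call, `"P"` (pathogenic) or `"B"` (benign):
#'
#' * Align-GVGD: seven ordinal grades C0-C65; pathogenic iff grade >= C35.
#' * SIFT: a score in \[0, 1\] (pathogenic iff strictly below 0.05) or the
#'   labels `AFFECT PROTEIN FUNCTION` / `TOLERATED`.
#' * MutationTaster2: `disease causing` (pathogenic) / `polymorphism` (benign).
#' * PolyPhen-2: `probably damaging` or `possibly damaging` (pathogenic) /
#'   `benign`.
#'
#' Labels are matched case-insensitively after collapsing whitespace and
#' underscores. Already-binary inputs (`"P"`/`"B"`, `"pathogenic"`/`"benign"`
#' where unambiguous) pass through unchanged, so harmonization is idempotent.
#' Missing raw values yield `NA` calls; anything outside a tool's vocabulary
#' is an error listing the accepted values.
#'
#' @param grade Character vector of Align-GVGD grades (`"C0"` ... `"C65"`).
#' @param raw For SIFT, a numeric score vector or a character label vector.
#' @param label Character label vector for MutationTaster2 / PolyPhen-2.
#' @return Character vector of `"P"`/`"B"` calls (`NA` where input missing).
NULL

# lowercase, collapse runs of whitespace/underscores to single spaces, trim
norm_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]_]+", " ", x)
}

# P/B passthrough shared by all tools; returns NA where not already binary
binary_passthrough <- function(x) {
  out <- rep(NA_character_, length(x))
  out[x %in% c("p", "pathogenic")] <- "P"
  out[x %in% c("b", "benign")] <- "B"
  out
}

harmonize_labels <- function(x, pathogenic, benign, tool) {
  nx <- norm_label(x)
  out <- rep(NA_character_, length(x))
  out[nx %in% pathogenic] <- "P"
  out[nx %in% benign] <- "B"
  pass <- binary_passthrough(nx)
  out[is.na(out) & !is.na(pass)] <- pass[is.na(out) & !is.na(pass)]
  bad <- !is.na(x) & nzchar(trimws(as.character(x))) & is.na(out)
  if (any(bad)) {
    stop(sprintf("unrecognized %s output %s; accepted: %s", tool,
                 paste(sQuote(unique(x[bad])), collapse = ", "),
                 paste(sQuote(c(pathogenic, benign)), collapse = ", ")),
         call. = FALSE)
  }
  out
}

#' @rdname harmonize
#' @export
#' @examples
#' harmonize_align_gvgd(c("C65", "C35", "C25"))
harmonize_align_gvgd <- function(grade) {
  nx <- norm_label(grade)
  out <- binary_passthrough(nx)
  valid <- paste0("c", c(0, 15, 25, 35, 45, 55, 65))
  is_grade <- nx %in% valid
  num <- suppressWarnings(as.numeric(sub("^c", "", nx[is_grade])))
  out[is_grade] <- ifelse(num >= 35, "P", "B")
  bad <- !is.na(grade) & nzchar(trimws(as.character(grade))) & is.na(out)
  if (any(bad)) {
    stop(sprintf("unrecognized Align-GVGD grade %s; accepted: %s",
                 paste(sQuote(unique(grade[bad])), collapse = ", "),
                 paste(sQuote(toupper(valid)), collapse = ", ")),
         call. = FALSE)
  }
  out
}

#' @rdname harmonize
#' @export
#' @examples
#' harmonize_sift(c(0.049, 0.05))
#' harmonize_sift(c("TOLERATED", "AFFECT PROTEIN FUNCTION"))
harmonize_sift <- function(raw) {
  if (is.numeric(raw)) {
    if (any(!is.na(raw) & (raw < 0 | raw > 1))) {
      stop("SIFT scores must lie in [0, 1]", call. = FALSE)
    }
    return(ifelse(is.na(raw), NA_character_, ifelse(raw < 0.05, "P", "B")))
  }
  harmonize_labels(raw,
                   pathogenic = "affect protein function",
                   benign = "tolerated",
                   tool = "SIFT")
}

#' @rdname harmonize
#' @export
#' @examples
#' harmonize_mt2(c("disease causing", "polymorphism"))
harmonize_mt2 <- function(label) {
  harmonize_labels(label,
                   pathogenic = c("disease causing", "disease causing (automatic)"),
                   benign = c("polymorphism", "polymorphism (automatic)"),
                   tool = "MutationTaster2")
}

#' @rdname harmonize
#' @export
#' @examples
#' harmonize_polyphen2(c("probably damaging", "benign"))
harmonize_polyphen2 <- function(label) {
  harmonize_labels(label,
                   pathogenic = c("probably damaging", "possibly damaging"),
                   benign = "benign",
                   tool = "PolyPhen-2")
}

#' Add harmonized binary call columns to a variant table
#'
#' Maps the raw predictor columns `agvgd_class`, `sift_score` (falling back to
#' `sift_label` where the score is missing), `mt2_label` and `pph2_label` to
#' binary call columns `agvgd_call`, `sift_call`, `mt2_call`, `pph2_call`
#' (`"P"`/`"B"`/`NA`). A variant with a missing raw output gets an `NA` call
#' for that tool; such variants are dropped pairwise from that tool's
#' confusion matrix and excluded from ensembles requiring completeness.
#'
#' @param variants A variant data frame (see [read_variant_table()]).
#' @return The input data frame with the four `*_call` columns added.
#' @export
harmonize_calls <- function(variants) {
  stopifnot(is.data.frame(variants))
  n <- nrow(variants)
  get <- function(col) if (col %in% names(variants)) variants[[col]] else rep(NA, n)
  variants$agvgd_call <- harmonize_align_gvgd(get("agvgd_class"))
  sift <- harmonize_sift(as.numeric(get("sift_score")))
  lab <- get("sift_label")
  if (!all(is.na(lab))) {
    fill <- is.na(sift)
    sift[fill] <- harmonize_sift(as.character(lab))[fill]
  }
  variants$sift_call <- sift
  variants$mt2_call <- harmonize_mt2(get("mt2_label"))
  variants$pph2_call <- harmonize_polyphen2(get("pph2_label"))
  variants
}
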