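#' @keywords internal
af_columns <- c("af_afr", "af_eas", "af_sas", "af_fin", "af_nfe", "af_amr")

#' Maximum per-population allele frequency of each variant
#'
#' The rarity filter uses the maximum allele frequency over the six reference
#' population cohorts (African, East Asian, South Asian, European Finnish,
#' European non-Finnish, Latino). A variant absent from the reference (all
#' cohort AFs missing) is treated as unobserved and its AF set to zero.
#'
#' @param variants Variant data frame with (any subset of) the columns
#'   `af_afr, af_eas, af_sas, af_fin, af_nfe, af_amr`.
#' @return Numeric vector of per-variant maximum AFs (0 where none observed).
#' @export
max_af <- function(variants) {
  stopifnot(is.data.frame(variants))
  cols <- intersect(af_columns, names(variants))
  if (length(cols) == 0L) return(rep(0, nrow(variants)))
  m <- as.matrix(as.data.frame(lapply(variants[cols], as.numeric)))
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  out <- apply(m, 1L, function(r) if (all(is.na(r))) 0 else max(r, na.rm = TRUE))
  as.numeric(out)
}

#' Binarize five-tier truth classes
#'
#' Classes 4 and 5 are (likely) pathogenic, classes 1 and 2 (likely) benign;
#' class 3 (uncertain) and missing classes map to `NA`.
#'
#' @param truth_class Integer vector of classes 1..5 (NA allowed).
#' @return Character vector of `"P"`/`"B"`/`NA`.
#' @export
truth_call <- function(truth_class) {
  out <- rep(NA_character_, length(truth_class))
  out[truth_class %in% c(4L, 5L)] <- "P"
  out[truth_class %in% c(1L, 2L)] <- "B"
  out
}

new_curation_result <- function(classified, evaluation, log) {
  structure(list(classified_set = classified,
                 evaluation_set = evaluation,
                 exclusion_log = log),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  cat("Curation result\n")
  cat("  classified set: ", nrow(x$classified_set), " variants\n", sep = "")
  if (!is.null(x$evaluation_set)) {
    cat("  evaluation set: ", nrow(x$evaluation_set), " variants\n", sep = "")
  }
  if (nrow(x$exclusion_log)) {
    tab <- table(x$exclusion_log$reason)
    cat("  exclusions:\n")
    for (r in names(tab)) cat("    ", r, ": ", tab[[r]], "\n", sep = "")
  }
  invisible(x)
}

#' Build the classified variant set
#'
#' Admission rules, applied as a conjunction (the logged reason is the first
#' failing rule, in the order given):
#' 1. truth class in \{1, 2, 4, 5\} — uncertain (class 3) and unclassified
#'    variants are excluded;
#' 2. maximum population allele frequency < `af_max` (default 0.01; common
#'    variants are benign by frequency alone and would trivialize evaluation);
#' 3. not spliceogenic (spliceogenic variants confound missense prediction
#'    with splice effects).
#'
#' @param variants Variant data frame (see [read_variant_table()]).
#' @param af_max Allele-frequency cutoff (exclusive). Default 0.01.
#' @return A `"curation_result"` with `classified_set` and `exclusion_log`
#'   (`evaluation_set` is `NULL` until [build_evaluation_set()] is run).
#' @export
build_classified_set <- function(variants, af_max = 0.01) {
  stopifnot(is.data.frame(variants), "variant_id" %in% names(variants))
  tc <- variants$truth_class
  afs <- max_af(variants)
  splice <- isTRUE_vec(variants$spliceogenic, nrow(variants))

  reason <- rep(NA_character_, nrow(variants))
  reason[is.na(reason) & is.na(tc)] <- "unclassified"
  reason[is.na(reason) & !(tc %in% c(1L, 2L, 4L, 5L))] <- "uncertain class"
  reason[is.na(reason) & afs >= af_max] <- sprintf("AF >= %g", af_max)
  reason[is.na(reason) & splice] <- "spliceogenic"

  keep <- is.na(reason)
  log <- data.frame(variant_id = variants$variant_id[!keep],
                    reason = reason[!keep],
                    stringsAsFactors = FALSE)
  new_curation_result(variants[keep, , drop = FALSE], NULL, log)
}

# coerce a possibly-missing logical-ish column to logical of length n
isTRUE_vec <- function(x, n) {
  if (is.null(x)) return(rep(FALSE, n))
  if (is.character(x)) x <- tolower(trimws(x)) %in% c("true", "t", "yes", "1")
  x <- as.logical(x)
  x[is.na(x)] <- FALSE
  x
}

#' Build the prior-independent evaluation variant set
#'
#' From a classified set, admits the variants whose five-tier classification
#' does not depend on the missense-prediction prior: either the expert panel
#' classified them on functional/published evidence (`expert_override`), or
#' their product of LRs clears the prior-independent pathogenic/neutral bound
#' (see [prior_independence()]). A variant admitted through an extreme LR must
#' have a truth class in the matching direction (4/5 for pathogenic, 1/2 for
#' neutral); a contradiction is a data-integrity error naming the variant.
#'
#' @param classified A `"curation_result"` from [build_classified_set()], or a
#'   classified variant data frame.
#' @param priors A [prior_config()] object.
#' @param thresholds A [plon_thresholds()] object.
#' @return A `"curation_result"` with `evaluation_set` populated and
#'   prior-dependent exclusions appended to the log.
#' @export
build_evaluation_set <- function(classified, priors = prior_config(),
                                 thresholds = plon_thresholds()) {
  prior_log <- data.frame(variant_id = character(), reason = character(),
                          stringsAsFactors = FALSE)
  if (inherits(classified, "curation_result")) {
    prior_log <- classified$exclusion_log
    classified <- classified$classified_set
  }
  stopifnot(is.data.frame(classified))
  n <- nrow(classified)
  expert <- isTRUE_vec(classified$expert_override, n)
  lr <- as.numeric(classified$product_of_lrs)
  if (any(!expert & is.na(lr))) {
    bad <- classified$variant_id[!expert & is.na(lr)]
    stop("classified variants without expert override must carry a product of LRs: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  status <- rep(NA_character_, n)
  status[!is.na(lr)] <- prior_independence(lr[!is.na(lr)], priors, thresholds)

  truth <- truth_call(classified$truth_class)
  contra <- (!is.na(status) & status == "independent_pathogenic" & !(truth %in% "P")) |
            (!is.na(status) & status == "independent_neutral" & !(truth %in% "B"))
  if (any(contra)) {
    stop("LR direction contradicts truth class for: ",
         paste(classified$variant_id[contra], collapse = ", "), call. = FALSE)
  }
  keep <- expert | (!is.na(status) & status != "prior_dependent")
  log <- rbind(prior_log,
               data.frame(variant_id = classified$variant_id[!keep],
                          reason = rep("prior-dependent", sum(!keep)),
                          stringsAsFactors = FALSE))
  new_curation_result(classified, classified[keep, , drop = FALSE], log)
}

#' Full curation cascade
#'
#' Runs [build_classified_set()] then [build_evaluation_set()].
#'
#' @inheritParams build_classified_set
#' @inheritParams build_evaluation_set
#' @param variants Variant data frame.
#' @return A `"curation_result"` with both sets and the complete exclusion log.
#' @export
curate <- function(variants, priors = prior_config(),
                   thresholds = plon_thresholds(), af_max = 0.01) {
  build_evaluation_set(build_classified_set(variants, af_max = af_max),
                       priors = priors, thresholds = thresholds)
}

#' Per-gene composition of a classified variant set
#'
#' @param variants Classified variant data frame (all truth classes present
#'   and in \{1, 2, 4, 5\}).
#' @return Data frame with one row per gene plus a `total` row, columns
#'   `gene`, `pathogenic`, `neutral`, `total`.
#' @export
set_composition <- function(variants) {
  stopifnot(is.data.frame(variants))
  truth <- truth_call(variants$truth_class)
  if (any(is.na(truth)) && nrow(variants) > 0) {
    stop("set_composition requires all variants classified into classes 1/2/4/5",
         call. = FALSE)
  }
  genes <- sort(unique(as.character(variants$gene)))
  rows <- lapply(genes, function(g) {
    sel <- variants$gene == g
    data.frame(gene = g,
               pathogenic = sum(truth[sel] == "P"),
               neutral = sum(truth[sel] == "B"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(gene = "total",
               pathogenic = sum(truth == "P"),
               neutral = sum(truth == "B"),
               stringsAsFactors = FALSE))))
  if (is.null(out)) {
    out <- data.frame(gene = "total", pathogenic = 0L, neutral = 0L,
                      stringsAsFactors = FALSE)
  }
  out$total <- out$pathogenic + out$neutral
  rownames(out) <- NULL
  out
}
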