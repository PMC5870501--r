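# Build a small variant table with sensible defaults; any field can be
# overridden by a vector recycled to length n.
make_variants <- function(n,
                          truth_class = 5L,
                          product_of_lrs = 1000,
                          gene = "BRCA1",
                          af = 0,
                          spliceogenic = FALSE,
                          expert_override = FALSE,
                          family_count = 1L,
                          agvgd_class = "C65",
                          sift_score = 0.01,
                          mt2_label = "disease causing",
                          pph2_label = "probably damaging") {
  rec <- function(x) rep_len(x, n)
  df <- data.frame(
    variant_id = sprintf("v%03d", seq_len(n)),
    gene = rec(gene),
    truth_class = rec(as.integer(truth_class)),
    product_of_lrs = rec(product_of_lrs),
    af_afr = rec(af), af_eas = rec(NA_real_), af_sas = rec(NA_real_),
    af_fin = rec(NA_real_), af_nfe = rec(NA_real_), af_amr = rec(NA_real_),
    spliceogenic = rec(spliceogenic),
    expert_override = rec(expert_override),
    family_count = rec(as.integer(family_count)),
    agvgd_class = rec(agvgd_class),
    sift_score = rec(sift_score),
    sift_label = rec(NA_character_),
    mt2_label = rec(mt2_label),
    pph2_label = rec(pph2_label),
    stringsAsFactors = FALSE)
  df
}

# Independent oracle for the expected m-of-n vote probability: exhaustive
# enumeration of all 2^n call patterns.
enum_expected <- function(probs, m, mode = c("sensitivity", "specificity")) {
  mode <- match.arg(mode)
  n <- length(probs)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  pattern_prob <- apply(grid, 1L, function(g) prod(ifelse(g == 1, probs, 1 - probs)))
  k <- rowSums(grid)
  if (mode == "sensitivity") sum(pattern_prob[k >= m]) else sum(pattern_prob[k < m])
}

# All admissible (n, m) pairs over subsets of size <= 4 (tool-agnostic)
admissible_nm <- function() {
  out <- list()
  for (n in 2:4) for (m in ceiling(n / 2):n) {
    if (m == 2 && n == 2) next
    out[[length(out) + 1L]] <- c(n = n, m = m)
  }
  out
}
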