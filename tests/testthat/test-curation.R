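test_that("max_af takes the maximum over observed cohorts, zero when absent", {
  v <- make_variants(3)
  v[1, c("af_afr", "af_amr")] <- c(0.002, 0.008)
  v[2, "af_nfe"] <- 0.012
  v[3, paste0("af_", c("afr", "eas", "sas", "fin", "nfe", "amr"))] <- NA_real_
  v$af_afr[3] <- NA_real_
  expect_equal(max_af(v), c(0.008, 0.012, 0))
  v$af_afr[1] <- 1.2
  expect_error(max_af(v), "\\[0, 1\\]")
})

test_that("classified-set admission is the stated conjunction with ordered reasons", {
  v <- make_variants(6, truth_class = c(3L, 5L, 2L, NA, 5L, 5L))
  v$af_afr[2] <- 0.02
  v$spliceogenic[5] <- TRUE
  v$af_afr[6] <- 0.02; v$spliceogenic[6] <- TRUE  # AF rule logged first
  res <- build_classified_set(v)
  expect_identical(res$classified_set$variant_id, "v003")
  log <- res$exclusion_log
  expect_identical(log$reason[log$variant_id == "v001"], "uncertain class")
  expect_identical(log$reason[log$variant_id == "v002"], "AF >= 0.01")
  expect_identical(log$reason[log$variant_id == "v004"], "unclassified")
  expect_identical(log$reason[log$variant_id == "v005"], "spliceogenic")
  expect_identical(log$reason[log$variant_id == "v006"], "AF >= 0.01")
  # every input lands in exactly one of classified set / log
  expect_setequal(c(res$classified_set$variant_id, log$variant_id), v$variant_id)
  expect_identical(anyDuplicated(c(res$classified_set$variant_id, log$variant_id)), 0L)
})

test_that("evaluation set admits expert overrides and prior-independent LRs only", {
  v <- make_variants(4, truth_class = c(5L, 1L, 1L, 5L),
                     product_of_lrs = c(1000, 0.5, 0.001, NA))
  v$expert_override[4] <- TRUE
  res <- build_evaluation_set(build_classified_set(v))
  expect_setequal(res$evaluation_set$variant_id, c("v001", "v003", "v004"))
  log <- res$exclusion_log
  expect_identical(log$reason[log$variant_id == "v002"], "prior-dependent")
  # subset relation
  expect_true(all(res$evaluation_set$variant_id %in% res$classified_set$variant_id))
})

test_that("LR direction contradicting the truth class is an integrity error", {
  v <- make_variants(1, truth_class = 1L, product_of_lrs = 1000)
  expect_error(build_evaluation_set(v), "contradicts.*v001")
  v2 <- make_variants(1, truth_class = 5L, product_of_lrs = 0.001)
  expect_error(build_evaluation_set(v2), "contradicts.*v001")
  # a non-expert variant without an LR violates the contract
  v3 <- make_variants(1, truth_class = 5L, product_of_lrs = NA)
  expect_error(build_evaluation_set(v3), "product of LRs")
})

test_that("set composition counts pathogenic/neutral per gene and in total", {
  v <- make_variants(3, truth_class = c(5L, 5L, 2L), gene = c("BRCA1", "BRCA1", "BRCA2"))
  comp <- set_composition(v)
  expect_equal(comp$pathogenic[comp$gene == "BRCA1"], 2)
  expect_equal(comp$neutral[comp$gene == "BRCA2"], 1)
  expect_equal(comp$total[comp$gene == "total"], 3)
  empty <- set_composition(make_variants(0))
  expect_equal(empty$total, 0)
  expect_error(set_composition(make_variants(1, truth_class = 3L)), "classes 1/2/4/5")
})

test_that("admission is order-insensitive: admitted iff the conjunction holds", {
  set.seed(21)
  v <- make_variants(200,
                     truth_class = sample(c(1:5, NA), 200, replace = TRUE),
                     product_of_lrs = exp(runif(200, -12, 12)))
  # keep LR direction consistent with truth to avoid integrity errors
  tr <- truth_call(v$truth_class)
  v$product_of_lrs[tr %in% "P"] <- exp(runif(sum(tr %in% "P"), 0, 12))
  v$product_of_lrs[tr %in% "B"] <- exp(runif(sum(tr %in% "B"), -12, 0))
  v$af_afr <- sample(c(0, 0.005, 0.02), 200, replace = TRUE)
  v$spliceogenic <- sample(c(TRUE, FALSE), 200, replace = TRUE, prob = c(0.2, 0.8))
  res <- curate(v)
  expected_classified <- !is.na(v$truth_class) & v$truth_class %in% c(1, 2, 4, 5) &
    max_af(v) < 0.01 & !v$spliceogenic
  expect_setequal(res$classified_set$variant_id, v$variant_id[expected_classified])
  status <- prior_independence(v$product_of_lrs)
  expected_eval <- expected_classified & status != "prior_dependent"
  expect_setequal(res$evaluation_set$variant_id, v$variant_id[expected_eval])
  # exact cover: classified set + exclusion log = input, once each
  ids <- c(res$classified_set$variant_id, res$exclusion_log$variant_id[
    res$exclusion_log$reason != "prior-dependent"])
  expect_setequal(ids, v$variant_id)
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("admitted fraction matches the generator's analytic admission probability", {
  cfg <- synthetic_config(n_pathogenic = 4000, n_neutral = 4000,
                          lr_sdlog = c(pathogenic = 2, neutral = 2), seed = 31)
  v <- generate_variants(cfg)
  res <- curate(v)
  p <- admission_probability(cfg)
  eval_truth <- truth_call(res$evaluation_set$truth_class)
  got_p <- sum(eval_truth == "P") / cfg$n_pathogenic
  got_b <- sum(eval_truth == "B") / cfg$n_neutral
  se <- function(prob, n) sqrt(prob * (1 - prob) / n)
  expect_lt(abs(got_p - p[["pathogenic"]]), 3 * se(p[["pathogenic"]], 4000))
  expect_lt(abs(got_b - p[["neutral"]]), 3 * se(p[["neutral"]], 4000))
})
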