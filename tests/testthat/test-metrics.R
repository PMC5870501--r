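test_that("confusion counts the four cells and handles missingness pairwise", {
  cm <- confusion(c("P", "P", "B", "B"), c("P", "B", "B", "P"))
  expect_equal(unclass(cm)[c("tp", "fn", "tn", "fp")],
               list(tp = 1L, fn = 1L, tn = 1L, fp = 1L))
  expect_error(confusion("P", c("P", "B")), "equal length")
  cm2 <- confusion(c("P", "B", "B"), c("P", NA, "B"))
  expect_equal(attr(cm2, "n_dropped"), 1L)
  expect_equal(cm2$tn, 1L)
  expect_error(confusion(c("P", "B"), c("P", NA), drop_missing = FALSE), "missing")
  all_right <- confusion(rep(c("P", "B"), 5), rep(c("P", "B"), 5))
  expect_equal(all_right$fp + all_right$fn, 0L)
})

test_that("performance reproduces published stand-alone tool statistics", {
  # a caller mislabelling 7 of 21 pathogenic and 46 of 140 neutral variants
  p <- performance(confusion_matrix(tp = 14, fp = 46, tn = 94, fn = 7))
  expect_equal(round_half_up(p$sens, 2), 0.67)
  expect_equal(round_half_up(p$spec, 2), 0.67)
  expect_equal(round_half_up(p$acc, 2), 0.67)
  expect_equal(round(p$mcc, 4), 0.2355)  # direct formula evaluation
  # 131 benign calls of which 2 were truly pathogenic, on 21 P / 140 B
  a <- performance(confusion_matrix(tp = 19, fp = 11, tn = 129, fn = 2))
  expect_equal(round_half_up(a$sens, 2), 0.90)
  expect_equal(round_half_up(a$spec, 2), 0.92)
  expect_equal(round_half_up(a$acc, 2), 0.92)
  # perfect prediction
  expect_equal(performance(confusion_matrix(10, 0, 20, 0))$mcc, 1)
  expect_error(performance(confusion_matrix(0, 0, 0, 0)), "empty")
})

test_that("degenerate marginals yield NA rates and a flagged zero MCC", {
  p <- performance(confusion_matrix(tp = 0, fp = 0, tn = 5, fn = 0))
  expect_true(is.na(p$sens))
  expect_equal(p$spec, 1)
  expect_equal(p$mcc, 0)
  expect_true(p$mcc_degenerate)
})

test_that("accuracy is the prevalence-weighted mix of sensitivity and specificity", {
  set.seed(51)
  for (i in 1:100) {
    cm <- confusion_matrix(tp = rpois(1, 20) + 1, fp = rpois(1, 10) + 1,
                           tn = rpois(1, 50) + 1, fn = rpois(1, 5) + 1)
    p <- performance(cm)
    prev <- (cm$tp + cm$fn) / p$n
    expect_equal(p$acc, prev * p$sens + (1 - prev) * p$spec)
    # MCC is symmetric under label swap
    swapped <- performance(confusion_matrix(tp = cm$tn, fp = cm$fn,
                                            tn = cm$tp, fn = cm$fp))
    expect_equal(swapped$mcc, p$mcc)
    expect_true(p$mcc >= -1 && p$mcc <= 1)
  }
})

test_that("MCC of truth-independent calls is centred on zero", {
  set.seed(52)
  mccs <- replicate(200, {
    truth <- sample(c("P", "B"), 400, replace = TRUE, prob = c(0.3, 0.7))
    calls <- sample(c("P", "B"), 400, replace = TRUE, prob = c(0.4, 0.6))
    performance(confusion(truth, calls))$mcc
  })
  expect_lt(abs(mean(mccs)), 3 / sqrt(400 * 200) * 5)
})

test_that("impact counts weight false calls by carrier families", {
  v <- make_variants(4, truth_class = c(5L, 1L, 1L, 1L),
                     family_count = c(368L, 3L, 5L, 7L))
  calls <- c("B", "P", "P", "B")  # founder missed; two neutral flagged
  imp <- impact_counts(v, calls)
  expect_equal(imp$families_false_negative, 368)
  expect_equal(imp$families_false_positive, 8)
  perfect <- impact_counts(v, c("P", "B", "B", "B"))
  expect_equal(unlist(perfect), c(families_false_negative = 0,
                                  families_false_positive = 0))
  expect_error(impact_counts(v, c("P", NA, "B", "B")), "missing call.*v002")
})

test_that("evaluate_tools reports per-tool matrices over harmonized calls", {
  v <- harmonize_calls(make_variants(
    6, truth_class = c(5L, 5L, 1L, 1L, 1L, 1L),
    agvgd_class = c("C65", "C0", "C0", "C0", "C65", "C0"),
    sift_score = c(0.01, 0.01, 0.5, 0.5, 0.5, 0.01),
    mt2_label = c("disease causing", "disease causing", "polymorphism",
                  "polymorphism", "polymorphism", "polymorphism"),
    pph2_label = "benign"))
  tm <- evaluate_tools(v)
  ag <- tm[tm$tool == "align_gvgd", ]
  expect_equal(c(ag$tp, ag$fp, ag$tn, ag$fn), c(1, 1, 3, 1))
  mt <- tm[tm$tool == "mutation_taster2", ]
  expect_equal(mt$sens, 1)
  expect_equal(mt$spec, 1)
  expect_equal(tm[tm$tool == "polyphen2", "sens"], 0)
})
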