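test_that("generation is reproducible and leaves the global RNG stream alone", {
  cfg <- synthetic_config(seed = 71)
  a <- generate_variants(cfg)
  set.seed(99); before <- runif(1)
  set.seed(99)
  b <- generate_variants(cfg)
  after <- runif(1)
  expect_identical(a, b)
  expect_identical(before, after)  # generator uses a private stream
  expect_false(identical(a, generate_variants(synthetic_config(seed = 72))))
})

test_that("perfect tools with zero correlation never miscall", {
  profiles <- lapply(default_tool_profiles(), function(p) c(sens = 1, spec = 1))
  v <- harmonize_calls(generate_variants(synthetic_config(
    n_pathogenic = 50, n_neutral = 200, tool_profiles = profiles, seed = 73)))
  truth <- truth_call(v$truth_class)
  for (col in c("agvgd_call", "sift_call", "mt2_call", "pph2_call")) {
    expect_identical(v[[col]], truth)
  }
})

test_that("harmonization recovers exactly the calls the generator intended", {
  v <- generate_variants(synthetic_config(n_pathogenic = 200, n_neutral = 200,
                                          correlation = 0.4, seed = 74))
  h <- harmonize_calls(v)
  # raw renderings are mutually consistent: score and label routes agree
  expect_identical(h$sift_call, harmonize_sift(v$sift_label))
  expect_identical(h$agvgd_call, ifelse(v$agvgd_class == "C65", "P", "B"))
  expect_identical(h$mt2_call, ifelse(v$mt2_label == "disease causing", "P", "B"))
  expect_identical(h$pph2_call, ifelse(v$pph2_label == "benign", "B", "P"))
})

test_that("empirical marginals match the profiles, with and without correlation", {
  for (rho in c(0, 0.6)) {
    v <- harmonize_calls(generate_variants(synthetic_config(
      n_pathogenic = 10000, n_neutral = 10000, correlation = rho,
      seed = 75 + round(10 * rho))))
    tm <- evaluate_tools(v)
    for (tool in vusbench_tools()) {
      prof <- default_tool_profiles()[[tool]]
      row <- tm[tm$tool == tool, ]
      se_s <- sqrt(prof[["sens"]] * (1 - prof[["sens"]]) / 10000)
      se_p <- sqrt(prof[["spec"]] * (1 - prof[["spec"]]) / 10000)
      expect_lt(abs(row$sens - prof[["sens"]]), max(3 * se_s, 1e-12))
      expect_lt(abs(row$spec - prof[["spec"]]), max(3 * se_p, 1e-12))
    }
  }
})

test_that("pairwise call concordance increases with the copula correlation", {
  concordance <- function(rho) {
    v <- harmonize_calls(generate_variants(synthetic_config(
      n_pathogenic = 0L + 1L, n_neutral = 6000,
      correlation = rho, seed = 76)))
    calls <- as.matrix(v[truth_call(v$truth_class) == "B",
                         c("agvgd_call", "sift_call", "mt2_call", "pph2_call")])
    pairs <- utils::combn(ncol(calls), 2)
    mean(apply(pairs, 2, function(ix) mean(calls[, ix[1]] == calls[, ix[2]])))
  }
  cc <- vapply(c(0, 0.3, 0.6, 0.9), concordance, numeric(1))
  expect_true(all(diff(cc) > 0))
})

test_that("LR products track the truth side and the analytic admission bounds", {
  cfg <- synthetic_config(seed = 77)
  with(list(), {
    set.seed(77)
    lr <- generate_lr_products(c(5L, 5L, 1L, 1L), cfg)
    expect_length(lr, 4)
    expect_true(all(lr > 0))
  })
  # near-degenerate spread: point mass above / at / below the bounds
  tight <- function(mu) synthetic_config(
    lr_meanlog = c(pathogenic = mu, neutral = mu),
    lr_sdlog = c(pathogenic = 1e-9, neutral = 1e-9), seed = 78)
  set.seed(78)
  lr_hi <- generate_lr_products(rep(5L, 100), tight(log(1000)))
  expect_true(all(prior_independence(lr_hi) == "independent_pathogenic"))
  set.seed(78)
  lr_one <- generate_lr_products(rep(5L, 100), tight(0))
  expect_true(all(prior_independence(lr_one) == "prior_dependent"))
  # median at the pathogenic bound: admission fraction near 1/2
  bound <- solve_lr_threshold(0.03, 0.95)
  cfg_med <- synthetic_config(lr_meanlog = c(pathogenic = log(bound),
                                             neutral = log(0.001)),
                              lr_sdlog = c(pathogenic = 1, neutral = 1))
  expect_equal(admission_probability(cfg_med)[["pathogenic"]], 0.5)
  set.seed(79)
  lr_med <- generate_lr_products(rep(5L, 10000), cfg_med)
  frac <- mean(lr_med > bound)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(generate_lr_products(5L, synthetic_config(
    lr_sdlog = c(pathogenic = -1, neutral = 1))))
})

test_that("composition of a generated set is fixed by the configuration", {
  v <- generate_variants(synthetic_config(n_pathogenic = 21, n_neutral = 140,
                                          seed = 80))
  comp <- set_composition(v)
  expect_equal(comp$pathogenic[comp$gene == "total"], 21)
  expect_equal(comp$neutral[comp$gene == "total"], 140)
})
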