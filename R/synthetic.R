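#' Default per-tool marginal call profiles
#'
#' Sensitivity/specificity pairs mirroring the stand-alone performance of the
#' four predictors on the curated evaluation set (21 pathogenic, 140 neutral
#' rare missense variants): Align-GVGD (0.90, 0.92), SIFT (1.00, 0.72),
#' MutationTaster2 (1.00, 0.79), PolyPhen-2 (0.67, 0.67).
#'
#' @return Named list of `c(sens, spec)` pairs.
#' @export
default_tool_profiles <- function() {
  list(align_gvgd = c(sens = 0.90, spec = 0.92),
       sift = c(sens = 1.00, spec = 0.72),
       mutation_taster2 = c(sens = 1.00, spec = 0.79),
       polyphen2 = c(sens = 0.67, spec = 0.67))
}

#' Configuration for the synthetic variant-table generator
#'
#' Describes the statistical world the generator draws from. Defaults mirror
#' the curated evaluation-set composition (21 pathogenic, 140 neutral) and
#' the four predictors' published marginals; the likelihood-ratio products
#' are log-normal per truth side, well separated so that most variants are
#' prior-independent; allele frequencies model a registry where most rare
#' variants are absent from the population reference.
#'
#' @param n_pathogenic,n_neutral Variant counts per truth side.
#' @param tool_profiles Named list of `c(sens, spec)` per tool
#'   ([default_tool_profiles()]).
#' @param correlation Exchangeable inter-tool correlation rho in \[0, 1):
#'   loading of the shared latent factor in the Gaussian copula. 0 =
#'   independent tools.
#' @param lr_meanlog,lr_sdlog Log-normal parameters (named `pathogenic`,
#'   `neutral`) for the product of LRs on each truth side.
#' @param af_unobserved Fraction of variants absent from the population
#'   reference (all cohort AFs missing; AF treated as zero downstream).
#' @param af_beta Beta(a, b) parameters for observed allele frequencies.
#' @param prop_common Fraction of neutral variants drawn as common
#'   (AF >= 0.01), exercising the frequency filter.
#' @param prop_spliceogenic Fraction of variants flagged spliceogenic.
#' @param family_zipf_exponent,family_max Power-law exponent and cap for
#'   per-variant family counts.
#' @param founder_families If positive, one pathogenic variant is designated
#'   a founder allele carried by this many families (default 368).
#' @param seed Integer seed; the generator is fully reproducible given the
#'   configuration.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_pathogenic = 21, n_neutral = 140,
                             tool_profiles = default_tool_profiles(),
                             correlation = 0,
                             lr_meanlog = c(pathogenic = log(5000), neutral = log(0.001)),
                             lr_sdlog = c(pathogenic = 1.5, neutral = 1.5),
                             af_unobserved = 0.644,
                             af_beta = c(0.5, 1000),
                             prop_common = 0,
                             prop_spliceogenic = 0,
                             family_zipf_exponent = 2,
                             family_max = 50,
                             founder_families = 0,
                             seed = 1L) {
  stopifnot(n_pathogenic > 0 || n_neutral > 0,
            correlation >= 0, correlation < 1,
            all(lr_sdlog > 0),
            af_unobserved >= 0, af_unobserved <= 1,
            prop_common >= 0, prop_common <= 1,
            prop_spliceogenic >= 0, prop_spliceogenic <= 1)
  if (!setequal(names(tool_profiles), vusbench_tools())) {
    stop("tool_profiles must be named by the four canonical tools: ",
         paste(vusbench_tools(), collapse = ", "), call. = FALSE)
  }
  tool_profiles <- tool_profiles[vusbench_tools()]
  for (p in tool_profiles) {
    if (any(p < 0 | p > 1)) stop("tool profiles must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_pathogenic = as.integer(n_pathogenic),
                 n_neutral = as.integer(n_neutral),
                 tool_profiles = tool_profiles,
                 correlation = correlation,
                 lr_meanlog = lr_meanlog, lr_sdlog = lr_sdlog,
                 af_unobserved = af_unobserved, af_beta = af_beta,
                 prop_common = prop_common,
                 prop_spliceogenic = prop_spliceogenic,
                 family_zipf_exponent = family_zipf_exponent,
                 family_max = as.integer(family_max),
                 founder_families = as.integer(founder_families),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("Synthetic variant world: %d pathogenic + %d neutral, rho = %g, seed = %d\n",
              x$n_pathogenic, x$n_neutral, x$correlation, x$seed))
  invisible(x)
}

# run expr with a private RNG stream seeded from `seed`, restoring any
# pre-existing global stream afterwards
with_private_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Draw products of likelihood ratios for given truth classes
#'
#' Pathogenic variants (classes 4/5) draw from the high log-normal component,
#' neutral variants (1/2) from the low one. The analytic probability that a
#' pathogenic draw clears the prior-independent pathogenic bound is
#' `1 - plnorm(bound, meanlog, sdlog)` (and `plnorm(bound, ...)` for the
#' neutral side), which tests use as the expected admission fraction.
#'
#' @param truth_class Integer vector of classes in \{1, 2, 4, 5\}.
#' @param config A [synthetic_config()].
#' @return Numeric vector of LR products.
#' @export
generate_lr_products <- function(truth_class, config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (any(config$lr_sdlog <= 0)) stop("lr_sdlog must be > 0", call. = FALSE)
  side <- ifelse(truth_class %in% c(4L, 5L), "pathogenic", "neutral")
  stats::rlnorm(length(truth_class),
                meanlog = config$lr_meanlog[side],
                sdlog = config$lr_sdlog[side])
}

# correlated binary calls via a single-factor Gaussian copula:
# indicator_i = 1[ sqrt(rho) z + sqrt(1-rho) e_i > qnorm(1 - p_i) ],
# marginal P(indicator_i) = p_i exactly, for any rho
copula_calls <- function(p_call, rho, n) {
  k <- length(p_call)
  z <- stats::rnorm(n)
  e <- matrix(stats::rnorm(n * k), n, k)
  latent <- sqrt(rho) * z + sqrt(1 - rho) * e
  thr <- stats::qnorm(1 - p_call) # p 0 -> +Inf (never call), p 1 -> -Inf (always)
  sweep(latent, 2L, thr, `>`)
}

#' Generate a synthetic annotated variant table
#'
#' Emulates a classified variant set: truth classes (pathogenic variants
#' split over classes 4/5, neutral over 1/2), genes (BRCA1/BRCA2), products
#' of LRs consistent with the truth side, per-cohort allele frequencies,
#' spliceogenic flags, family counts, and the four predictors' raw outputs.
#' Per-tool pathogenic-call indicators follow a single-factor Gaussian copula
#' with exchangeable correlation `rho`, calibrated so each tool's marginal
#' call probability equals its profile sensitivity (on pathogenic variants)
#' or one minus its specificity (on neutral variants). Raw outputs are
#' rendered in each tool's native vocabulary (grade C65/C0, SIFT score
#' straddling 0.05, native labels) so that [harmonize_calls()] recovers the
#' intended binary call exactly.
#'
#' @param config A [synthetic_config()].
#' @return Variant data frame in the standard column layout (see
#'   [read_variant_table()]), with raw tool columns filled.
#' @export
#' @examples
#' head(generate_variants(synthetic_config(seed = 42)))
generate_variants <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_private_seed(config$seed, {
    n_p <- config$n_pathogenic; n_b <- config$n_neutral
    n <- n_p + n_b
    truth <- c(sample(c(4L, 5L), n_p, replace = TRUE, prob = c(0.3, 0.7)),
               sample(c(1L, 2L), n_b, replace = TRUE, prob = c(0.4, 0.6)))
    gene <- sample(c("BRCA1", "BRCA2"), n, replace = TRUE, prob = c(0.55, 0.45))
    lr <- generate_lr_products(truth, config)

    # allele frequencies: most variants unobserved in the reference; a
    # configurable fraction of neutral variants made common to exercise the
    # frequency filter
    af <- matrix(NA_real_, n, length(af_columns),
                 dimnames = list(NULL, af_columns))
    observed <- stats::runif(n) > config$af_unobserved
    n_obs <- sum(observed)
    if (n_obs > 0) {
      k <- length(af_columns)
      draws <- matrix(stats::rbeta(n_obs * k, config$af_beta[1], config$af_beta[2]),
                      n_obs, k)
      seen <- matrix(stats::runif(n_obs * k) < 0.7, n_obs, k) # cohort coverage
      seen[cbind(seq_len(n_obs), sample.int(k, n_obs, replace = TRUE))] <- TRUE
      draws[!seen] <- NA_real_
      af[observed, ] <- draws
    }
    common <- truth %in% c(1L, 2L) & stats::runif(n) < config$prop_common
    af[common, "af_nfe"] <- stats::runif(sum(common), 0.01, 0.2)

    splice <- stats::runif(n) < config$prop_spliceogenic

    # family counts: discrete power law, optional founder allele
    ranks <- seq_len(config$family_max)
    pw <- ranks^(-config$family_zipf_exponent)
    fam <- sample(ranks, n, replace = TRUE, prob = pw / sum(pw))
    if (config$founder_families > 0 && n_p > 0) fam[1L] <- config$founder_families

    # per-tool call probabilities by truth side
    tools <- names(config$tool_profiles)
    p_call_p <- vapply(config$tool_profiles, `[[`, numeric(1), "sens")
    p_call_b <- 1 - vapply(config$tool_profiles, `[[`, numeric(1), "spec")
    calls <- matrix(NA, n, length(tools), dimnames = list(NULL, tools))
    if (n_p > 0) calls[seq_len(n_p), ] <- copula_calls(p_call_p, config$correlation, n_p)
    if (n_b > 0) calls[n_p + seq_len(n_b), ] <- copula_calls(p_call_b, config$correlation, n_b)

    render_score <- function(pathogenic) {
      ifelse(pathogenic, stats::runif(n, 0, 0.049), stats::runif(n, 0.05, 1))
    }
    df <- data.frame(
      variant_id = sprintf("%s:v%04d", gene, seq_len(n)),
      gene = gene,
      truth_class = truth,
      product_of_lrs = lr,
      stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(af))
    df$spliceogenic <- splice
    df$expert_override <- FALSE
    df$family_count <- fam
    df$agvgd_class <- ifelse(calls[, "align_gvgd"], "C65", "C0")
    df$sift_score <- render_score(calls[, "sift"])
    df$sift_label <- ifelse(calls[, "sift"], "AFFECT PROTEIN FUNCTION", "TOLERATED")
    df$mt2_label <- ifelse(calls[, "mutation_taster2"], "disease causing", "polymorphism")
    df$pph2_label <- ifelse(calls[, "polyphen2"],
                            sample(c("probably damaging", "possibly damaging"),
                                   n, replace = TRUE),
                            "benign")
    rownames(df) <- NULL
    df
  })
}

#' Analytic prior-independence admission probabilities of a generator world
#'
#' Closed-form probability that a generated variant's LR product clears the
#' prior-independent bound for its truth side, from the log-normal CDF.
#'
#' @param config A [synthetic_config()].
#' @param priors,thresholds Model configuration (defaults as in
#'   [prior_independence()]).
#' @return Named vector: `pathogenic` = P(LR > pathogenic bound),
#'   `neutral` = P(LR < neutral bound).
#' @export
admission_probability <- function(config = synthetic_config(),
                                  priors = prior_config(),
                                  thresholds = plon_thresholds()) {
  hi <- solve_lr_threshold(priors$prior_low, thresholds$c4_lower)
  lo <- solve_lr_threshold(priors$prior_high, thresholds$c2_upper)
  c(pathogenic = unname(1 - stats::plnorm(hi, config$lr_meanlog[["pathogenic"]],
                                          config$lr_sdlog[["pathogenic"]])),
    neutral = unname(stats::plnorm(lo, config$lr_meanlog[["neutral"]],
                                   config$lr_sdlog[["neutral"]])))
}
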