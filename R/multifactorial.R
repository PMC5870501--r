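#' Prior probabilities of pathogenicity for missense prediction extremes
#'
#' Container for the two prior probabilities attached to the extreme grades of
#' a missense prediction tool (conventionally Align-GVGD): the prior for the
#' least-damaging grade (C0) and the prior for the most-damaging grade (C65).
#' These are the two priors under which a variant's five-tier class must agree
#' for its classification to be independent of the in silico prediction.
#'
#' @param prior_low Prior probability of pathogenicity under the
#'   least-damaging missense prediction. Default 0.03.
#' @param prior_high Prior probability under the most-damaging prediction.
#'   Default 0.81.
#' @return An object of class `"prior_config"`.
#' @seealso [prior_independence()], [solve_lr_threshold()]
#' @export
#' @examples
#' prior_config()
prior_config <- function(prior_low = 0.03, prior_high = 0.81) {
  stopifnot(is.numeric(prior_low), is.numeric(prior_high),
            length(prior_low) == 1L, length(prior_high) == 1L)
  if (!(prior_low > 0 && prior_low < prior_high && prior_high < 1)) {
    stop("priors must satisfy 0 < prior_low < prior_high < 1", call. = FALSE)
  }
  structure(list(prior_low = prior_low, prior_high = prior_high),
            class = "prior_config")
}

#' @export
print.prior_config <- function(x, ...) {
  cat("Missense-prediction priors: low =", x$prior_low,
      ", high =", x$prior_high, "\n")
  invisible(x)
}

#' Posterior-probability boundaries of the five-tier classification
#'
#' Boundaries of the five-tier pathogenicity classes on the posterior
#' probability scale: class 1 (benign) below `c1_upper`, class 2 (likely
#' benign) up to `c2_upper`, class 3 (uncertain) in between, class 4 (likely
#' pathogenic) from `c4_lower`, class 5 (pathogenic) above `c5_lower`.
#' Boundary conventions: class 1 is strictly below `c1_upper`; class 2 is the
#' half-open interval `[c1_upper, c2_upper)`; class 4 is the closed interval
#' `[c4_lower, c5_lower]`; class 5 is strictly above `c5_lower`.
#'
#' @param c1_upper,c2_upper,c4_lower,c5_lower Class boundaries, strictly
#'   increasing probabilities. Defaults 0.001, 0.05, 0.95, 0.99.
#' @return An object of class `"plon_thresholds"`.
#' @export
#' @examples
#' plon_thresholds()
plon_thresholds <- function(c1_upper = 0.001, c2_upper = 0.05,
                            c4_lower = 0.95, c5_lower = 0.99) {
  v <- c(c1_upper, c2_upper, c4_lower, c5_lower)
  stopifnot(is.numeric(v), length(v) == 4L)
  if (!(all(v > 0) && all(v < 1) && all(diff(v) > 0))) {
    stop("thresholds must satisfy 0 < c1_upper < c2_upper < c4_lower < c5_lower < 1",
         call. = FALSE)
  }
  structure(list(c1_upper = c1_upper, c2_upper = c2_upper,
                 c4_lower = c4_lower, c5_lower = c5_lower),
            class = "plon_thresholds")
}

#' @export
print.plon_thresholds <- function(x, ...) {
  cat("Five-tier posterior boundaries:",
      sprintf("1 | %g | 2 | %g | 3 | %g | 4 | %g | 5",
              x$c1_upper, x$c2_upper, x$c4_lower, x$c5_lower), "\n")
  invisible(x)
}

#' Posterior probability of pathogenicity
#'
#' Combines a prior probability of pathogenicity with a product of likelihood
#' ratios (from segregation, co-occurrence, family history and pathology
#' evidence) on the odds scale:
#' posterior odds = LR x prior / (1 - prior), posterior = odds / (odds + 1).
#'
#' @param prior_p Prior probability, in (0, 1). Recycled against
#'   `product_of_lrs`.
#' @param product_of_lrs Combined likelihood ratio, finite and > 0.
#' @return Posterior probability in (0, 1), vectorized.
#' @export
#' @examples
#' posterior_probability(0.03, 614.33) # 0.95
posterior_probability <- function(prior_p, product_of_lrs) {
  if (!is.numeric(prior_p) || !is.numeric(product_of_lrs)) {
    stop("prior_p and product_of_lrs must be numeric", call. = FALSE)
  }
  ok_p <- is.na(prior_p) | (prior_p > 0 & prior_p < 1)
  if (!all(ok_p)) stop("prior_p must lie strictly in (0, 1)", call. = FALSE)
  ok_lr <- is.na(product_of_lrs) | (product_of_lrs > 0 & is.finite(product_of_lrs))
  if (!all(ok_lr)) stop("product_of_lrs must be finite and > 0", call. = FALSE)
  odds <- product_of_lrs * prior_p / (1 - prior_p)
  odds / (odds + 1)
}

#' Product-of-LRs threshold reaching a posterior target
#'
#' Inverts the posterior-probability relation: the likelihood-ratio product
#' `LR*` for which the posterior equals `posterior_target` given `prior_p`.
#' The closed form is `(t/(1-t)) * ((1-p)/p)`; a bisection solver on the
#' forward relation is available as a cross-check.
#'
#' @param prior_p Prior probability, in (0, 1).
#' @param posterior_target Target posterior probability, in (0, 1).
#' @param method `"closed_form"` (default) or `"bisection"`.
#' @param tol Convergence tolerance for the bisection solver.
#' @return The threshold LR (positive scalar; vectorized for closed form).
#' @export
#' @examples
#' solve_lr_threshold(0.03, 0.95) # 614.33...
#' solve_lr_threshold(0.81, 0.05) # 0.012346...
solve_lr_threshold <- function(prior_p, posterior_target,
                               method = c("closed_form", "bisection"),
                               tol = 1e-12) {
  method <- match.arg(method)
  if (!all(prior_p > 0 & prior_p < 1)) {
    stop("prior_p must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!all(posterior_target > 0 & posterior_target < 1)) {
    stop("posterior_target must lie strictly in (0, 1): targets 0 and 1 have no finite LR",
         call. = FALSE)
  }
  if (method == "closed_form") {
    return((posterior_target / (1 - posterior_target)) * ((1 - prior_p) / prior_p))
  }
  # bisection on log(LR); monotone forward map guarantees bracketing
  mapply(function(p, t) {
    lo <- -60; hi <- 60
    f <- function(loglr) posterior_probability(p, exp(loglr)) - t
    if (f(lo) > 0 || f(hi) < 0) stop("bisection bracket failed", call. = FALSE)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    exp((lo + hi) / 2)
  }, prior_p, posterior_target)
}

#' Assign the five-tier pathogenicity class from a posterior probability
#'
#' @param posterior_p Posterior probability, in (0, 1). Vectorized.
#' @param thresholds A [plon_thresholds()] object.
#' @return Integer vector of classes 1 to 5 (1 benign ... 5 pathogenic).
#' @export
#' @examples
#' assign_plon_class(c(0.0005, 0.5, 0.96))
assign_plon_class <- function(posterior_p, thresholds = plon_thresholds()) {
  stopifnot(inherits(thresholds, "plon_thresholds"))
  if (!all(is.na(posterior_p) | (posterior_p > 0 & posterior_p < 1))) {
    stop("posterior_p must lie strictly in (0, 1)", call. = FALSE)
  }
  out <- rep.int(3L, length(posterior_p))
  out[posterior_p < thresholds$c1_upper] <- 1L
  out[posterior_p >= thresholds$c1_upper & posterior_p < thresholds$c2_upper] <- 2L
  out[posterior_p >= thresholds$c4_lower & posterior_p <= thresholds$c5_lower] <- 4L
  out[posterior_p > thresholds$c5_lower] <- 5L
  out[is.na(posterior_p)] <- NA_integer_
  out
}

#' Prior-independent classification status of a likelihood-ratio product
#'
#' A variant's classification is independent of the missense-prediction prior
#' when its product of LRs is extreme enough that the five-tier class is
#' (likely) pathogenic even under the lowest prior, or (likely) benign even
#' under the highest prior. The boundaries used are exactly
#' `solve_lr_threshold(prior_low, c4_lower)` and
#' `solve_lr_threshold(prior_high, c2_upper)`; no constants are hard-coded.
#'
#' @param product_of_lrs Combined likelihood ratio(s), > 0.
#' @param priors A [prior_config()] object.
#' @param thresholds A [plon_thresholds()] object.
#' @return Character vector with levels `"independent_pathogenic"`,
#'   `"independent_neutral"`, `"prior_dependent"`.
#' @export
#' @examples
#' prior_independence(c(700, 0.005, 1))
prior_independence <- function(product_of_lrs, priors = prior_config(),
                               thresholds = plon_thresholds()) {
  stopifnot(inherits(priors, "prior_config"),
            inherits(thresholds, "plon_thresholds"))
  p_low <- posterior_probability(priors$prior_low, product_of_lrs)
  p_high <- posterior_probability(priors$prior_high, product_of_lrs)
  out <- rep("prior_dependent", length(product_of_lrs))
  out[p_low >= thresholds$c4_lower] <- "independent_pathogenic"
  out[p_high < thresholds$c2_upper] <- "independent_neutral"
  out[is.na(product_of_lrs)] <- NA_character_
  out
}

#' Round half away from zero for display
#'
#' Display rounding used throughout the reporting functions. R's `round()`
#' rounds half to even; printed performance values in the clinical literature
#' use conventional half-up rounding (0.905 -> 0.91, not 0.90).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.905, 2)
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}
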