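---
title: "Circularity-free benchmarking of missense pathogenicity predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circularity-free benchmarking of missense pathogenicity predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vusbench)
```

## The problem

Clinical interpretation of rare *BRCA1/2* missense variants rests on the
multifactorial likelihood model: quantitative evidence from segregation,
co-occurrence with known deleterious alleles, family history and tumour
pathology is combined into a product of likelihood ratios (LRs), which
updates a prior probability of pathogenicity into a posterior. The posterior
is mapped to the standard five-tier scheme (1 benign ... 5 pathogenic). The
catch for benchmarking: the *prior* is itself derived from in silico missense
prediction (conventionally Align-GVGD). Any "truth" label that depends on
that prior is partially an echo of the predictor one wants to evaluate, so
naive benchmarks overstate agreement — a circularity.

`vusbench` removes the circularity by inverting the posterior model. Writing
$p$ for the prior and $LR$ for the product of likelihood ratios,

$$\text{posterior odds} = LR \cdot \frac{p}{1-p}, \qquad
  \text{posterior} = \frac{\text{odds}}{\text{odds}+1},$$

the LR needed to reach a target posterior $t$ is the closed form
$LR^\*(p, t) = \frac{t}{1-t}\cdot\frac{1-p}{p}$. A variant whose LR product
exceeds $LR^\*(p_{\text{low}}, 0.95)$ is (likely) pathogenic even under the
*lowest* prior any missense prediction could assign; one whose LR product is
below $LR^\*(p_{\text{high}}, 0.05)$ is (likely) benign even under the
*highest*. Such variants are classified independently of the prior and are
legitimate benchmark truth. With the conventional prior extremes 0.03 and
0.81:

```{r thresholds}
solve_lr_threshold(0.03, 0.95)   # prior-independent pathogenic bound
solve_lr_threshold(0.81, 0.05)   # prior-independent neutral bound
```

The neutral bound, 0.012346, is conventionally quoted rounded to 0.01
(`round_half_up(x, 2)`); the exact solver is authoritative throughout and the
rounded figure is display only. The closed form is cross-checked against a
bisection solver on the forward relation to $10^{-9}$.

## Model parameters and conventions

* **Prior extremes** (`prior_config()`): 0.03 for the least-damaging and
  0.81 for the most-damaging missense grade. Priors for intermediate grades
  are not needed for the independence screen and are not defaulted.
* **Five-tier posterior boundaries** (`plon_thresholds()`): 0.001, 0.05,
  0.95, 0.99. Boundary conventions are not fixed by convention in the
  literature; here class 1 is strictly below 0.001, class 2 is
  `[0.001, 0.05)`, class 4 is `[0.95, 0.99]`, class 5 is strictly above
  0.99. This choice makes the 0.95 boundary reproduce the pathogenic LR
  bound 614.33 exactly, and makes the independence screen's boundary
  behaviour (closed at the pathogenic bound, open at the neutral bound)
  follow from the class boundaries rather than from separate constants.
  The class-2 upper boundary is taken as 0.05 (not 0.049); both round the
  derived neutral bound to the same displayed 0.01, and 0.05 is the stated
  tier boundary. All boundaries are user-configurable.
* **Curation** (`build_classified_set()`, `build_evaluation_set()`): admit
  truth classes {1, 2, 4, 5}; require maximum per-cohort allele frequency
  < 0.01 (the maximum over the six reference cohorts — the conservative
  reading, consistent with the class-1-by-frequency rule; variants absent
  from the reference count as AF 0); exclude spliceogenic variants; then
  keep prior-independent variants plus expert-panel overrides. Exclusion
  reasons are logged in that order. An extreme LR pointing against the
  recorded truth class is an integrity error, not a silent exclusion.
* **Harmonization**: Align-GVGD pathogenic iff grade ≥ C35; SIFT pathogenic
  iff score strictly below 0.05 (a score of exactly 0.05 is benign);
  PolyPhen-2 pathogenic for possibly/probably damaging; MutationTaster2
  pathogenic for disease causing. Labels are matched after lowercasing and
  collapsing whitespace/underscores. Missing raw output yields a missing
  call; such variants are dropped pairwise from that tool's confusion matrix
  and entirely from any ensemble that includes the tool (with a logged
  count). Pairwise-complete handling is this package's policy; the original
  study describes none.
* **Metrics**: SENS, SPEC, ACC and MCC from the confusion matrix. A zero MCC
  denominator is reported as 0 with a degeneracy flag. Display rounding is
  half-up to 2 decimals. Family-weighted impact counts sum registry family
  counts over false-negative and false-positive variants.
* **Ensembles**: m-of-n majority votes, `m >= n/2`, with the two-tool case
  excluded entirely (its only candidate, the unanimous 2-of-2, is excluded,
  and 1-of-2 is not a majority scheme in the admissible family), leaving 11
  schemes over four tools.

## The independence model

The expected best-case performance of a voting ensemble assumes the tools
err independently. The number of pathogenic votes among $n$ independent
tools with distinct marginals is Poisson-binomial; the expected combined
sensitivity is $P(X \ge m)$ with per-tool success probabilities equal to the
sensitivities, and the expected combined specificity is $P(Y < m)$ with
success probabilities equal to the false-positive rates. `expected_combined()`
computes the distribution by iterative convolution, which is exact (to
floating point) for any $n$; tests verify it against exhaustive $2^n$
enumeration. Expected ACC and MCC are derived from the expected confusion
cells at the observed prevalence — that derivation is this package's
construction, not part of the independence model proper, and is flagged as
such in `evaluate_ensembles()` output documentation.

```{r independence}
expected_combined(c(1, 1, 0.90, 0.67), m = 3)                  # sensitivity
expected_combined(1 - c(0.92, 0.72, 0.79, 0.67), m = 3, "specificity")
```

## What the synthetic generator emulates

`generate_variants()` draws a variant table with the statistical structure
the pipeline assumes: truth classes with a configurable pathogenic/neutral
balance (default 21/140, the curated evaluation-set composition), genes,
log-normal LR products per truth side, per-cohort allele frequencies with a
configurable fraction of reference-absent variants (default 0.644, the
registry's share of private variants), power-law family counts with an
optional founder allele (368 families, mirroring the *BRCA1* C61G skew), and
the four predictors' raw outputs.

Tool errors follow a single-factor Gaussian copula: for each variant a
shared latent factor $z$ and tool-specific noise $e_i$ give the indicator
$\mathbf 1[\sqrt\rho\, z + \sqrt{1-\rho}\, e_i > \Phi^{-1}(1-p_i)]$, where
$p_i$ is the tool's sensitivity (pathogenic variants) or false-positive rate
(neutral variants). Marginals are exact for any $\rho$, so one knob moves
inter-tool correlation without recalibration; a full correlation matrix
could be accepted later without interface change. Default marginals mirror
the published stand-alone performance: Align-GVGD (0.90, 0.92), SIFT
(1.00, 0.72), MutationTaster2 (1.00, 0.79), PolyPhen-2 (0.67, 0.67).
LR defaults place pathogenic variants at `meanlog = log(5000)` and neutral
ones at `meanlog = log(0.001)`, `sdlog = 1.5` — wide enough that a realistic
minority of variants is prior-dependent, while keeping the probability of an
LR contradicting its truth class negligible ($|z| > 8$).

What a green synthetic test does **not** establish: the generator renders
raw outputs only as far as harmonization consumes them (grade C65/C0, a
score straddling 0.05, native labels); it does not emulate real predictors'
score distributions, gene- or region-specific error structure, or the
non-exchangeable correlation of real tools. Agreement on synthetic data
validates the pipeline's arithmetic and calibration, not any claim about
real predictor performance.

```{r pipeline}
v <- generate_variants(synthetic_config(correlation = 0.5, seed = 7,
                                        founder_families = 368))
report <- run_pipeline(v)
report$tool_metrics[, c("tool", "sens", "spec", "acc", "mcc")]
```

With positive correlation, the observed specificity of unanimous (m = n)
schemes falls below the independence expectation — correlated tools repeat
each other's false positives, so unanimity filters less than independence
promises:

```{r gap}
em <- report$ensemble_metrics
em[em$m == em$n, c("tools", "m", "spec", "expected_spec")]
```

## Numerical choices and degenerate inputs

* The bisection solver brackets on `log(LR)` in ±60 (posteriors
  indistinguishable from 0/1 beyond that) and halves to `tol = 1e-12`.
* Posterior targets of exactly 0 or 1 have no finite LR and are domain
  errors, as are priors outside (0, 1) and non-positive or infinite LRs.
* Tool profiles of exactly 0 or 1 give ±Inf copula thresholds and
  deterministic calls for any correlation.
* An evaluation set with no pathogenic (or no neutral) variants reports the
  corresponding rate as `NA` and expected ensemble quantities as `NA`; the
  pipeline completes.
* Confusion-cell products are computed in double precision to avoid integer
  overflow on large synthetic sets.

## Known discrepancies in the source figures

The published counts are internally inconsistent in three places, which this
package reports rather than reconciles. First, the printed MCC values for
PolyPhen-2 (0.39) and Align-GVGD (0.73) are not reproducible from any
confusion matrix consistent with the printed error counts; direct evaluation
of the MCC formula on those counts gives 0.2355 and 0.7136. The formula
implementation is authoritative here, and the tests freeze the recomputed
values. Second, the evaluation-set composition (89 + 72 variants; 21
pathogenic, 140 neutral; 161 total) conflicts with a figure caption quoting
166 variants and a discussion figure of 25 pathogenic (15.1%); the 161/21/140
composition is used as authoritative. Third, the set arithmetic 236 − 151 −
10 leaves 75 prior-dependent variants, which no printed table itemizes; the
exclusion log makes the corresponding accounting explicit for any input this
package curates.

## Limitations

The package consumes predictor outputs and LR products; it does not run the
predictors, build alignments, call splice effects, or compute segregation /
co-occurrence likelihoods. The evaluation-set curation removes
prior-dependent variants, which shrinks the benchmark and can bias it toward
variants with abundant family data; that is the price of removing
circularity, not an artifact of the implementation.
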