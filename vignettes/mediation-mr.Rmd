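---
title: "Two-step mediation Mendelian randomization: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step mediation Mendelian randomization: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The scientific problem

Mendelian randomization (MR) uses genetic variants as instrumental variables
to estimate the causal effect of an exposure on an outcome from GWAS summary
statistics alone. A variant is a valid instrument when it (1) is robustly
associated with the exposure, (2) is independent of confounders of the
exposure-outcome relation, and (3) affects the outcome only through the
exposure. `mrmediate` implements the *two-step* (mediation) extension: with
an exposure X, a putative mediator M and an outcome Y, three univariable MR
fits give the total effect of X on Y, the effect of X on M (here called
direct effect A, or `beta1`), and the effect of M on Y (direct effect B,
`beta2`). The product of coefficients `beta1 * beta2` estimates the indirect
(mediated) effect, and its ratio to the total effect is the mediated
proportion.

The package grew out of drug-target applications, where the "exposure" is
genetically proxied inhibition of a drug target (for instance variants at a
transporter gene locus whose alleles lower the downstream biomarker the drug
moves), the mediator is a disease trait with its own GWAS (for instance
venous thromboembolism), and the outcome is a binary clinical endpoint. All
effects are on the log-odds scale for binary traits; odds ratios are
`exp(beta)`.

## The estimator panel

Five estimators run on each leg, all built from the per-variant Wald ratios
`beta_outcome / beta_exposure`:

* **IVW** — inverse-variance-weighted meta-analysis, equivalent to weighted
  least squares of outcome on exposure betas through the origin with weights
  `1/se_outcome^2`. The default is a multiplicative random-effects model: the
  fixed-effect standard error is inflated by `max(1, sqrt(Q/(J-1)))`, so it
  reduces to the fixed-effect model exactly when there is no excess
  heterogeneity. We default to random effects because it is conservative and
  is the common default in two-sample practice; `model = "fixed"` is a flag.
* **MR-Egger** — the same regression with a free intercept, after orienting
  every instrument to a positive exposure effect. The slope is robust to
  directional pleiotropy under the InSIDE assumption; the intercept estimates
  the average direct (pleiotropic) effect and its two-sided test is the
  pleiotropy diagnostic. Standard errors use the same never-deflate
  multiplicative scale.
* **Weighted median** — the interpolated 0.5-quantile of the ordered Wald
  ratios under normalized inverse-variance weights `(beta_x/se_y)^2`;
  consistent when at least half the weight comes from valid instruments.
* **Simple and weighted mode** — the argmax of a gaussian-kernel density of
  the ratios, unweighted or inverse-variance weighted; consistent when the
  largest group of instruments sharing a ratio is valid.

Standard errors for the median and mode estimators come from a parametric
bootstrap (resampling both betas from their sampling normals), 5,000 draws by
default, always seeded. P-values for all point estimators are two-sided
normal; Cochran's Q uses the upper chi-square tail. These reference choices
are stated rather than argued: they match the conventions of the estimators'
original descriptions.

## Sensitivity suite

`mr_sensitivity()` bundles Cochran's Q (first-order weights
`(beta_x/se_y)^2`, matching the IVW weighting; second-order weights were
considered and rejected to keep the Q consistent with the estimator it
tests), the Egger intercept test, leave-one-out IVW, and MR-PRESSO. Our
MR-PRESSO computes the weighted residual sum of squares of each outcome beta
around its leave-one-out IVW prediction, simulates both betas parametrically
under the no-pleiotropy model to get the global empirical p-value,
Bonferroni-adjusts the per-variant residual tails for the outlier test, and
compares the outlier-corrected estimate against random same-size removals
for the distortion test. The simulation count defaults to 5,000 (1,000 is
the enforced floor) and the seed is mandatory: two calls with the same seed
are bit-identical.

## Harmonization

Two-sample MR requires exposure and outcome effects on the same effect
allele. The convention implemented: align to the exposure's effect allele;
swapped alleles flip the outcome beta and complement its frequency; strand
complements (A/C reported as T/G) are resolved by complementing;
palindromic variants (A/T, C/G) cannot be resolved that way and follow an
explicit policy — `"drop"` (default) or `"infer"` by allele frequency with
an ambiguity window of 0.42-0.58 on either study's frequency, inside which
(or with a missing frequency) the variant is dropped. Irreconcilable allele
sets are always dropped and logged, never silently kept. Harmonization is
idempotent, and jointly flipping an allele's sign in both studies leaves
every downstream estimate unchanged; both properties are tested.

## Instrument selection

`select_instruments()` applies, in fixed order: a significance filter
(conventionally `5e-8` genome-wide; `1e-4` for locus-scale biomarker
validation of cis instruments), greedy LD clumping, the F-statistic
weak-instrument screen, and a confounder screen against a local
variant-to-trait annotation table (a desk replacement for web-service
lookups). Clumping repeatedly takes the smallest-p remaining variant and
discards everything with squared correlation above the threshold;
ties break on variant ID so the survivor set does not depend on input
order. Both thresholds seen in drug-target practice are supported: a
stringent `r^2 = 0.001` for genome-wide instruments and a permissive
`r^2 = 0.8` within a cis locus. We read "correlation coefficient"
thresholds as r-squared, the standard clumping convention; an explicit LD
matrix is required for clumping and, absent one, variants are treated as
uncorrelated. The per-variant F statistic defaults to the squared z-score
`(beta/se)^2`, which needs only printed columns; the
`(n-2) R^2/(1-R^2)` form is available when allele frequency and sample size
are known. F below 10 is the conventional weak-instrument flag.

## Colocalization gate

Before trusting cis instruments, the locus should show that the gene
expression (or target-engagement) signal and the biomarker signal share one
causal variant. `coloc_abf()` computes per-variant approximate Bayes factors
(`log ABF = 0.5 [log(1-r) + r z^2]` with `r = W^2/(W^2 + se^2)`) and
accumulates the five standard hypothesis sums in log space. Priors default
to `p1 = p2 = 1e-4`, `p12 = 1e-5`; the effect-scale prior W defaults to
0.15 (0.20 is conventional for binary traits). The binary call is
`PP(H4) > 0.70`, strictly greater. In `run_study()` a failed gate halts all
stages that would use the exposure instruments and the report records
"not colocalized"; the mediator leg is unaffected.

## Mediation arithmetic and intervals

The indirect effect is `beta1 * beta2`. Two interval constructions are
implemented. The delta method gives
`se = sqrt(beta1^2 se2^2 + beta2^2 se1^2)` with a symmetric normal CI. The
default is Monte-Carlo: draw both coefficients from independent normals and
take empirical percentiles of the product, which captures the asymmetry a
product of normals has when either coefficient is imprecise (real studies
print visibly asymmetric mediation CIs, which a delta interval cannot
produce). The mediated proportion is `100 * indirect / total`; its default
interval propagates draws of the numerator (as a product) and denominator,
because the delta method for a ratio is fragile when the total effect is
small. 100,000 draws by default, seeded. When both coefficients have
`|beta/se| > 3` the two constructions converge (tested to within 10% on the
interval width).

`beta2` comes from the univariable mediator-to-outcome fit with the
mediator's own instruments, mirroring the two-step design; this assumes the
exposure does not confound that leg (a multivariable "difference method" is
deliberately out of scope).

## The synthetic-data generator

`simulate_two_sample()` simulates directly at the summary level — normal
draws around true betas — rather than from individual-level genotypes. This
matches two-sample theory, keeps the truth exact, and makes replicate
studies cheap. Two variant classes mirror the two-step design: exposure
instruments with effects `gamma_j`, and mediator-specific instruments with
effects `delta_j` and no exposure effect (the mediator's own GWAS hits).
Observed betas are `N(mean, se^2)` with `se = 1/sqrt(2 maf (1-maf) n)`,
times `1/sqrt(v(1-v))` for the binary outcome with case fraction `v`.
Defaults are chosen once to mirror the motivating study's conditions:
sample sizes 344,182 (exposure biomarker), 484,598 (mediator), 361,194
(outcome; 1,597 cases), `theta_em = -0.05`, `theta_mo = 0.03`,
`theta_direct = -0.0155` (total about -0.017), effect magnitudes uniform on
0.03-0.08 with random signs so every instrument is strong (F far above 10),
minor-allele frequencies uniform on 0.05-0.5. Pleiotropy is optional
(balanced or directional normal direct effects on the outcome) and LD is
optional exchangeable-block correlation applied to the sampling noise.

What the generator does *not* emulate: realistic genome-wide LD, winner's
curse from discovery-stage selection, sample overlap between the two
samples, allele-frequency differences between studies, and multi-allelic or
strand-ambiguous messiness beyond what the harmonizer's unit fixtures
construct by hand. Passing recovery and calibration tests on this generator
therefore validates the estimators and the pipeline plumbing, not robustness
to those real-data pathologies.

`make_study_fixture()` is an engineered, deterministic study whose
selection pipeline lands on fixed instrument counts — 13
genome-wide-significant mediator variants of which 4 fall to stringent
clumping and 2 to confounder screening (7 survivors), and a cis locus
yielding exactly 6 instruments — so end-to-end tests can assert exact
structural outcomes. It is labelled synthetic everywhere; its numbers are
not estimates of anything real.

## Numerical choices and degenerate inputs

* Weighted-median interpolation uses midpoint cumulative weights
  (`cumsum(w) - w/2`), clamping to the extreme ratios outside the covered
  range.
* The mode bandwidth is `phi * 0.9 * min(sd, mad) * J^(-1/5)` (modified
  Silverman, `phi = 1` by default). When the MAD degenerates to zero (tied
  ratios) the exact weighted mode of the tied values is returned, which is
  what makes the estimator ignore a minority outlier. The density argmax is
  found on a 2,048-point grid and refined by local optimisation, so it is
  exact well beyond the bootstrap noise in its SE.
* A single instrument degrades IVW to the Wald ratio with a message; Egger,
  median and mode refuse to run below 3 instruments and MR-PRESSO below 4.
* Hypothesis sums in colocalization use log-sum-exp throughout; the H3
  cross-sum subtracts in log space with a guard against cancellation.
* Simulated p-values are floored at the smallest positive double so
  generated tables always satisfy the readers' `p > 0` invariant.
* Clumping, selection and harmonization are deterministic given their
  inputs; every stochastic routine (bootstraps, MR-PRESSO, Monte-Carlo
  intervals, the generator) takes a mandatory seed and is bit-reproducible.

## Problem sizes used in validation

The shipped validation suite uses problem sizes chosen to make the
statistical assertions sharp while staying desk-scale: oracle equivalence on
100 random fixtures (tolerance 1e-10); parameter recovery with J = 50
strong instruments over 200 replicates, asserting each estimator's mean is
within 3 Monte-Carlo standard errors of truth; null calibration over 500
replicates for IVW and the Egger intercept (rejection at 0.05 required to
lie in [0.02, 0.09]) and 200 replicates for the MR-PRESSO global test with
1,000 simulations each; planted +10-sigma outlier recovery over 100
repetitions (at least 95% flagged); and 100 seeded loci per arm for the
colocalization gate. Bootstrap SEs in tests use reduced draw counts where
only point estimates are asserted; the package defaults remain 5,000.

## Known limitations

* Univariable legs only: no multivariable MR, no Steiger filtering, no
  MR-RAPS/CAUSE-style likelihood methods.
* The mediated-proportion interval is undefined when the total effect is
  zero and unstable when it is near zero relative to its SE; the Monte-Carlo
  interval makes this visible (very wide) rather than hiding it.
* Colocalization assumes at most one causal variant per trait in the locus
  (no SuSiE-style multi-signal decomposition).
* LD handling is limited to a supplied correlation matrix; the package never
  estimates LD from genotypes.
* The exact interval construction behind published mediation CIs is often
  unstated; with only printed coefficients the package reproduces point
  estimates and proportions exactly, and interval reproduction is not
  claimed.
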