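---
title: "Structural models of bias in polygenic score studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural models of bias in polygenic score studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsbias)
```

## The problem

Polygenic scores (PGS) — weighted sums of trait-associated allele counts,
with weights taken from a genome-wide association study — are now routinely
used in psychiatric and behavioural research as predictors, covariates, and
mediator-model exposures. Their interpretation is harder than their
construction: a PGS is a *noisy indicator* of the latent additive genetic
factor it stands for, typically capturing well under half of the
SNP-heritability of its phenotype. This package treats the resulting
inferential problems in one coherent frame: standardized linear structural
models in which every observed variable (the score, a measured exposure, a
measured outcome) loads on a latent "true" counterpart, and every bias of
interest — attenuation, residual genetic confounding, inflated mediation,
collider-driven amplification, gene–environment correlation artefacts,
genetic nurture, assortative mating, population stratification — is either a
closed-form function of the path coefficients or a reproducible simulation
signature.

Three layers make each other checkable:

1. **Exact algebra.** `implied_correlations()` computes the model-implied
   correlation matrix of any acyclic standardized path model, and
   `partial_coefficients()` turns any such matrix into the coefficients a
   researcher would estimate by OLS in an infinite sample. Every closed-form
   bias expression in the package is tested to `1e-10` against this route.
2. **Monte Carlo.** `simulate_model()` draws Gaussian cohorts whose sample
   correlations converge to the implied matrix, so every analytic bias can
   be re-derived from data; the scenario registry (`run_scenario()`)
   automates the comparison with 4-standard-error pass bands.
3. **Genotypes.** For intergenerational questions the linear-model
   abstraction is not enough, so `simulate_parents()` /
   `mate_and_transmit()` simulate phased haplotypes, Mendelian
   transmission, and transmitted/non-transmitted half-scores directly.

## Model conventions

All models are standardized: every variable, latent or observed, has total
variance 1, and residual variances are *derived* (1 minus the
parent-explained variance), never user-set. This matches the convention in
which path coefficients, loadings, and correlations live on the same scale
and makes every formula directly interpretable. A loading `l` relates an
indicator to its latent variable; the *reliability* of the indicator is
`l^2`. Thus a polygenic score with reliability 0.10 enters the model with
loading `sqrt(0.10)`, and a genetic factor explaining 15% of exposure
variance enters with path coefficient `sqrt(0.15)`. The package validates
at construction time that the implied residual variance of every variable
lies in `[0, 1]`, so impossible parameter combinations are caught before
any algebra runs.

The implied-correlation solver walks the graph in topological order
(lexicographic tie-break, so output is deterministic across platforms),
accumulating covariances variable by variable; the reduced-form matrix
solution `(I - B)^-1 Psi (I - B)^-T` is kept as an internal cross-check
(`method = "matrix"`), and the test suite additionally verifies both
against a brute-force enumeration of directed path pairs — the reduced form
of Wright's tracing rules — on random models.

Residual correlations ("co-paths", e.g. between parental genetic factors
under assortative mating) are supported between exogenous variables only.
This restriction covers the use the models need while keeping the
sequential residual-variance solve exact.

## The bias formulas

With true effect `beta` of the latent genetic factor on the latent outcome,
score loading `l_G`, and outcome loading `l_Y`:

* **Attenuation** (`attenuated_pgs_effect`): the fitted simple coefficient
  is `l_Y * l_G * beta`. With reliabilities 0.80 and 0.10 and `beta = 0.9`
  the fitted value is 0.2546 (prints as 0.25) — a variance explained near
  6% for a phenotype whose latent heritability is 81%.
* **Score reliability** (`pgs_reliability`): `l_G^2 = R2_PGS / h2_SNP`, the
  ratio of the variance the score explains to the SNP-heritability. The
  ratio exceeding 1 flags inconsistent inputs rather than erroring, since
  both quantities arrive with sampling error.
* **Residual confounding** (`adjusted_exposure_effect`): adjusting an
  exposure–outcome regression for the *score* rather than the *factor*
  leaves `beta_GX * beta_GY * (1 - l_G^2) / (1 - l_G^2 * beta_GX^2)` of the
  genetic confounding in place. In the canonical null-exposure scenario
  (genes explain 15% of exposure and 30% of outcome variance, score
  reliability 0.10) the fitted exposure effect is 0.194 — "adjusted for
  genetics" yet entirely confounded.
* **Mediation inflation** (`fitted_mediated_effect`): the fitted indirect
  effect is `l_G * beta_M + l_G * beta_GX * Bias`, so the proportion of a
  genetic effect "mediated" by a risk factor is over- rather than
  under-estimated, and can be positive when the true mediation is null.
* **Collider amplification** (`collider_adjusted_effects`,
  `full_collider_fitted_bxy`): when the genetic factor affects only the
  exposure, adjusting for it shrinks the denominator `1 - beta_GX^2` under
  the confounder path and moves the exposure estimate *further* from the
  causal effect than no adjustment at all. The general expression with
  measurement error in all three indicators decomposes the fitted
  coefficient into causal, collider, and confounding terms; its denominator
  is `1 - l_G^2 * l_X^2 * beta_GX^2`, the form recovered by deriving the
  OLS solution on the implied matrix (the flattened rendering of the
  expression elsewhere drops the squares; the derived form is implemented
  and verified against the regression oracle, and reduces exactly to the
  simpler expression at unit loadings).

## The heritability-informed sensitivity analysis

`sensitivity_adjusted_effect()` answers: *what would the adjusted exposure
effect be had we measured a score capturing the full additive
heritability?* Given observed correlations `r_GX, r_GY, r_XY` and an
external heritability `h2` (SNP- or twin-based — both are legitimate
inputs; they answer different versions of the question and can be reported
side by side), the just-identified exposure model inverts in closed form:

    l_G  = r_GY / sqrt(h2)
    b_GX = r_GX / l_G
    b_XY = (r_XY - b_GX * sqrt(h2)) / (1 - b_GX^2)

`h2` is interpreted as the squared *total* genetic correlation with the
latent outcome, exposure-mediated paths included; this is what makes the
null-exposure worked example invert exactly to zero. A moment-based solve
was chosen over iterative SEM fitting deliberately: the model is
just-identified, so SEM machinery would add dependencies and iteration
without changing the estimate. `bootstrap_sensitivity()` supplies
percentile intervals by row resampling; resamples that leave the
identifiable region (`r_GY^2 > h2`, or an implied `|b_GX| >= 1`) are
dropped and counted, with a warning past a 20% drop rate. A bootstrap
coverage study (500 replicates of n = 5,000, B = 200) sits in the test
suite and lands near nominal 95%.

Two reporting conventions worth knowing: the naive PGS-adjusted OLS
coefficient is always returned alongside the corrected one (the two
coincide exactly when `h2 = r_GY^2`), and the correction is monotone in the
assumed `h2` — a larger external heritability implies a larger correction —
so a sensitivity *curve* over plausible `h2` values is one `sapply` away.

## What the simulators emulate — and what they do not

`simulate_model()` is a Gaussian structural simulator: linear effects,
Gaussian residuals, standardization exact in expectation. Dichotomization
(`dichotomize`) acts on realized values at exact empirical quantiles, and
selection (`apply_selection`) implements deterministic keep-if-any referral
over indicator columns. These choices keep every analytic target exact and
every selection story enumerable (the within-stratum association under
keep-if-either selection is checked against a three-cell multinomial
enumeration). Real phenotypes are not Gaussian, real referral is not
deterministic, and real selection acts on many correlated variables at
once; passing tests therefore demonstrate the *mechanisms*, not empirical
effect sizes in any cohort.

The genotype-level simulator draws unlinked biallelic loci with phased
haplotypes and no LD, mutation, or genome structure — the intergenerational
arguments it supports are about expectations over transmission, which
unlinked loci capture fully. Transmission is fair-coin per locus per
parent; the parental score splits exactly into transmitted plus
non-transmitted half-scores because scores are computed on the theoretical
scale (counts centered by `2f`, scaled by `sqrt(2f(1-f))`, weight-norm
standardized). Assortative mating is realized by noisy rank-matching on a
mating phenotype (the true score), with the matching-noise SD tuned by
bisection until the realized spousal correlation is within 0.02 of target —
the phenomenon is a named mechanism without a canonical generative model,
and rank-matching reaches any attainable target without committing to one.
GWAS weight error in `compute_pgs()` is a weight-vector perturbation drawn
orthogonal to the true weights and scaled so the population true–observed
squared correlation equals the requested reliability exactly.

The family phenotype model (`simulate_family_phenotypes`) standardizes each
generated variable against the empirical covariance of its inputs, so
configured paths are standardized coefficients under any mating regime; a
configuration whose systematic part exceeds unit variance is rejected as an
invalid variance decomposition.

## Scenario registry and defaults

Every named scenario (`list_scenarios()`) runs simulation plus estimators
plus the matching closed forms and reports `analytic`, `estimate`,
Monte-Carlo SE, and a z-statistic; any row with `|z| > 4` fails the
scenario, and `make_report()` aggregates to a table and an exit status for
scripted use. Default scenario size is n = 100,000 with 4-SE bands;
genotype-based scenarios scale the trio count down (a trio at 1,000 loci
costs roughly three orders of magnitude more than a Gaussian row). The test
suite exercises the registry at n = 20,000, the bias-formula oracle
equivalence at 1,000 random parameter draws, the trio invariants at 5,000
trios by 1,000 loci, and the sensitivity-recovery study at 200 cohorts of
n = 100,000 — sizes chosen so the whole suite documents the claims it
makes at interactive timescales.

Where the figure-level models needed numeric paths that are nowhere
specified, the registry's defaults are package choices, made once:
the nurture scenario uses individual effect 0.3, parental-genetics-to-
environment paths 0.5–0.6, nurture paths 0.3–0.4, a maternal evocative
path 0.2 and none on the paternal side (so the passive-only signature is
visible on that side); the stratification scenario shifts allele
frequencies by 0.1 between subpopulations with an outcome offset of 0.5
standard deviations and all-positive weights (a GWAS confounded in the
direction of the shift, which is what makes the classic spurious
association appear with a definite sign). These magnitudes were picked to
sit comfortably inside detectability at the default sizes while staying in
the range of effects this literature discusses; none is an empirical claim.

## Numerical choices and degenerate inputs

* Validation reports rather than raises; computation on an invalid model
  raises, naming the failed invariant.
* Residual variances within `[-1e-10, 0)` are clamped to 0 (saturated
  children of correlated parents produce exact zeros up to float error);
  anything lower is an error.
* Proportions mediated are undefined (`NA` plus a flag) when the total
  association is below `1e-12` in magnitude, rather than returning an
  arbitrary huge ratio.
* Quantile dichotomization breaks ties by row order and tops up to the
  exact target count, so the realized split is as close to the target as
  the sample allows; re-dichotomizing an indicator at 0.5 is the identity.
* All simulators take a single integer seed, generate columns in
  topological+lexicographic order, and restore the caller's RNG state on
  exit, so cohorts are bit-for-bit reproducible and composable.
* Analytic tolerance is `1e-10` throughout; stochastic checks use 3 (unit
  tests) or 4 (scenario registry) Monte-Carlo SEs.

## Known limitations

* Linear, Gaussian, acyclic models only; no estimation of general path
  models from data (only the sensitivity module estimates, and only its
  specific model). Residual distributions are nowhere specified by the
  underlying theory; Gaussianity is this package's explicit default, not a
  derived fact.
* The sensitivity correction inherits the exposure model's assumptions —
  in particular, no unmeasured *non-genetic* confounding and no reverse
  causation; it corrects the genetic-reliability problem only.
* Cross-trait assortative mating is demonstrable (two weight vectors) but
  not estimated; gene–environment interaction is out of scope entirely.
* Selection is modelled as deterministic stratification; probabilistic
  referral would interpolate the induced association toward zero but is not
  required for any of the demonstrated signatures.
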