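---
title: "Modelling polygenic modification of monogenic disease risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling polygenic modification of monogenic disease risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polypen)
```

## The scientific problem

Rare pathogenic variants in genes such as *LDLR* (familial
hypercholesterolemia), *BRCA1/2* (hereditary breast and ovarian cancer) and
the mismatch-repair genes (Lynch syndrome) confer several-fold increases in
disease risk, yet their penetrance is famously incomplete. A polygenic
score — a weighted sum of millions of common-variant dosages — measures an
independent, continuous axis of inherited risk. `polypen` implements the
joint analysis of these two axes: how much does polygenic background move
the absolute and relative risk of a monogenic variant carrier?

The package covers the full analysis chain: score computation and
ancestry correction, variant screening and carrier calling, stratified and
interaction logistic models, Cox cumulative incidence ("penetrance") by a
horizon age, and a retrospective power analysis for the carrier-by-score
interaction test. A synthetic-cohort generator with known ground truth
supports every stage, so the whole chain is testable end to end without
access to individual-level biobank data.

## Polygenic scores and ancestry correction

The raw score is `PS_i = sum_v w_v d_iv` over effect-allele dosages
`d in [0, 2]`. Missing dosages are imputed with the variant's mean dosage
over non-missing individuals (twice the effect-allele frequency), the
common default of genotype-score tooling; zero imputation is available.
Because allele frequencies differ across genetic ancestries, raw scores are
shifted between ancestry groups for reasons unrelated to disease risk. The
correction regresses the raw score on the leading principal components of
ancestry (`PS ~ PC1 + ... + PCK`, default `K = 4`) and keeps the residual.
Ordinary least squares makes the corrected score exactly orthogonal to each
PC and invariant to location shifts of the raw score.

Corrected scores are reported three ways:

* **z** — standardized against a reference distribution, using the sample
  (`n - 1`) standard deviation. Odds ratios "per SD" refer to this scale.
* **percentile** — `ceiling(100 * r / n_ref)` where `r` is the mean rank of
  the value in the reference distribution; ties get their average rank and
  out-of-reference values clamp to 1 or 100. The reference defaults to the
  analysis sample itself; any external reference vector can be supplied.
* **strata** — low (percentile 1–20), intermediate (21–80), high (81–100).

Two score-surgery sensitivity analyses are provided: removal of all score
variants within 1 Mb of the condition's genes (inclusive bounds, distance
measured from the gene footprint edges, `exclude_flanking_variants()`), and
residualization of the primary score on a secondary score plus the PCs
(`residualize_on_secondary_score()`), e.g. purging an LDL-cholesterol
signal from a coronary disease score.

## Variant screening and carrier status

Clinical variant classification (pathogenic / likely pathogenic / VUS /
likely benign / benign) is a human judgement and enters as an input label.
The screening that precedes it is mechanical and implemented:
`candidate_filter()` drops synonymous variants and variants with allele
frequency strictly above 0.005 in at least one (`mode = "any"`, default) or
every (`mode = "each"`) reference subpopulation; `region_quality_filter()`
drops variants in low-complexity regions or segmental duplications and
variants failing the quality random-forest flag. The two filters commute,
so their order is immaterial.

A carrier holds a dosage of at least 0.9 (tolerating imputed dosages) at
one or more surviving P/LP variant in the condition's genes (FH:
*LDLR/APOB/PCSK9*; HBOC: *BRCA1/BRCA2*; Lynch: *MLH1/MSH2/MSH6/PMS2*).
Heterozygous and homozygous carriers are treated alike — clinical cohorts
of these genes essentially never contain homozygotes. Two qualifying
variants in one individual are a data-quality violation, configurable as an
error or keep-first-with-warning. Per-gene associations use one adjusted
logistic fit per gene; with a handful of carriers these fits can separate,
in which case a Firth-type penalized fit (Jeffreys prior) is substituted
and labelled.

## Association models

All disease models are maximum-likelihood logistic regressions (IRLS,
deviance tolerance 1e-12, at most 100 iterations) with Wald tests and
intervals; two-sided alpha is 0.05 throughout and no multiple-testing
correction is applied. The fitted models are:

* **Six-level model** — a single fit with a 2 (carrier) x 3 (score
  stratum) indicator; noncarriers with intermediate score are the
  reference, pinned at odds ratio 1 with a degenerate interval.
* **Per-SD by stratum** — independent fits in carriers and noncarriers. In
  the covariate-free case these coincide exactly with the interaction
  model's stratum slopes (a property the tests assert).
* **Interaction test** — Wald test of the score-by-carrier product term.
* **Percentile curve** — from an additive fit in carrier status and z (the
  default; an interaction term is optional, but the additive model matches
  the approximately parallel carrier/noncarrier curves these data show),
  the predicted odds ratio at percentile `p` and carrier state `c` relative
  to a noncarrier at the median percentile is
  `exp(gamma c + beta (z_p - z_50))`, with covariates conditioned at their
  means. `z_p` is the empirical mean corrected score inside the percentile
  bin — robust to non-normal corrected scores — with empty bins linearly
  interpolated under a warning. Intervals use the delta method on the
  coefficient covariance; a bootstrap was considered and rejected as the
  curves are smooth functions of two or three coefficients.
* **Linearity check** — likelihood-ratio test of the linear score model
  against a cubic polynomial (2 df), plus a 20-bin observed-versus-expected
  calibration table over percentile bins of 5.

## Penetrance: cumulative incidence by age 75

Absolute risk uses a Cox proportional-hazards model with age as the
time-scale: the time-to-event is the age at first diagnosis for cases and
the age at last follow-up for censored individuals, with everyone at risk
from birth. Prevalent cases (diagnosed before enrollment) are pooled with
incident ones at their diagnosis age; this ignores left truncation at
enrollment, a simplification we expose by providing an `entry` argument for
left-truncated risk sets so the two analyses can be contrasted. Ties are
handled by the Breslow method (ages recorded in whole years tie heavily;
Efron is available), and the Breslow estimator supplies the baseline
cumulative hazard. Penetrance is `F(t) = 1 - S(t)` with
`S(t) = exp(-H0(t) exp(x beta))`, evaluated at `t = 75` for carriers and
noncarriers across score percentiles with the remaining covariates at their
means; intervals use the log(-log S) transform.

## The synthetic cohort generator

`generate_population()` emulates the statistical structure the estimators
assume, with every generating parameter recorded in `truth`:

* **Ancestry structure** — Balding–Nichols: ancestral frequencies uniform
  on (0.05, 0.95), per-component frequencies Beta-distributed around them
  with divergence `fst`, individuals admixed with Dirichlet(1) proportions.
  The admixture proportions (minus one redundant column) are exported as
  the PC covariates: they carry exactly the confounding the correction
  must remove, because the individual allele frequency — hence the expected
  raw score — is linear in them. Eigenvector computation would add
  machinery without changing that structure.
* **Scores** — weights are normal; dosages Binomial(2, p). Default 200
  variants: enough for an approximately normal score, far below biobank
  scale (linkage disequilibrium is deliberately not modelled).
* **Carriers** — Bernoulli with frequency 0.005 (the order observed for
  familial hypercholesterolemia variants), each carrier holding exactly one
  rare pathogenic variant; decoy variants failing each filter rule are
  included so the screen is exercised.
* **Prevalent disease** — logistic in carrier status (log OR log 3), true
  score (log 1.6 per SD), age and sex, with the intercept solved by
  root-finding so the marginal prevalence hits its target (default 5%).
* **Onset ages** — Weibull proportional hazards (default shape 4, scale
  135, roughly 10% cumulative incidence by age 75 at the baseline),
  independent uniform censoring ages between 55 and 80, enrollment between
  40 and 69 — middle-aged-cohort values.
* **Case-control sampling** — uniform within disease strata, without
  age-matching: age enters the models as a covariate, which is what the
  estimators require.

What passing tests on these cohorts do *not* show: robustness to linkage
disequilibrium between score variants, genotyping or imputation error,
ascertainment correlated with covariates, or real ancestry structure beyond
a few admixed components.

## Retrospective power with the case total fixed

The carrier-by-score interaction tests are underpowered in any realistic
carrier count, so the package quantifies exactly what effect sizes *were*
detectable. The design holds the observed study fixed: total size, case
count, carrier count, the noncarrier score effect, and the carrier-status
association with disease (the unadjusted odds ratio from the observed 2x2
carrier-by-case table — it sets the case fraction among carriers, which
controls the information available for the carrier slope). Only the
carrier score effect is varied.

Phenotypes are simulated *conditionally on the case total*: given
per-individual case probabilities `p_i` from the logistic model (intercept
calibrated by root-finding so `E[sum y] = n_cases`), the phenotype vector is
drawn from independent Bernoullis conditioned on their sum — the
conditional Bernoulli law, `P(y) ∝ prod r_i^{y_i}` with `r_i = p_i/(1-p_i)`.
Because conditioning absorbs any common odds factor, the calibrated
intercept is nearly irrelevant (a property the tests verify exactly through
the inclusion probabilities). Two exact samplers are implemented: a
backward dynamic-programming sampler over the Poisson-binomial recursion
(`O(n * n_cases)` table), and an exponential-tilting rejection sampler
(tilting leaves the conditional law invariant while making acceptance
`O(1/sd(sum))`), which is the default at biobank scale where the DP table
would hold ~10^8 entries. Both match brute-force enumeration in the tests.

Power at a carrier effect is the rejection rate of the two-sided Wald
interaction test over replicates (default 500 per grid point); replicates
with failed fits are excluded from the denominator and counted.
`detectable_or_bounds()` locates the 80%-power effect on each side of the
noncarrier null by monotone bisection on the log odds-ratio distance,
seeded by a deterministic Fisher-information approximation and stopped when
the bracket is narrower than 0.01 on the OR scale or narrower than the
Monte-Carlo positional uncertainty of the crossing, whichever comes first;
the crossing is then interpolated linearly inside the final bracket.

Carrier scores default to standard normal on the corrected scale. The
original analyses presumably used the observed carrier covariate values,
which are not reproducible from printed summaries; `carrier_score =
"supplied"` accepts real values when available, and the difference is
absorbed into the Monte-Carlo uncertainty of the bounds.

## Numerical choices and degenerate inputs

* Logistic fits refuse single-class outcomes and missing values; detected
  separation is flagged, never silently reported.
* The intercept calibration and exponential tilt use `uniroot` on a
  bracket of ±45 on the log-odds scale and fail explicitly outside it.
* Percentile bins with no observations are interpolated with a warning.
* A penetrance horizon beyond the observed follow-up warns and uses the
  last estimate; a horizon before the first event returns F = 0 with a
  zero-width interval.
* Chromosome-name dialects ("chr1" vs "1") are normalized with a warning;
  BED input is converted from 0-based half-open to the 1-based inclusive
  convention used internally.
* Seeds: every stochastic entry point takes a master seed and derives
  per-replicate (or per-evaluation) seeds from it, so runs are bit
  reproducible and individual replicates can be replayed.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at desk scale by design:
synthetic cohorts of 4,000–50,000 individuals with 30–200 score variants;
power scenarios at the published design sizes (12,852 and 19,264) with 500
replicates per grid point; property suites with 10^5 sampler draws and
100–1,000 model replicates. These sizes keep every Monte-Carlo tolerance
well above its sampling noise.

## Known limitations

* No linkage disequilibrium, haplotypes or sequencing reads in the
  generator; no competing-risk adjustment in the penetrance model; no
  family-history or time-varying effects.
* The default penetrance analysis pools prevalent and incident cases from
  birth; left truncation is available but not the default.
* ACMG/AMP classification is consumed, not computed.
* Published headline cohort estimates depend on individual-level biobank
  data; the package reproduces their *structure* on synthetic cohorts and
  their retrospective power bounds, which are functions of printed
  summaries only.
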