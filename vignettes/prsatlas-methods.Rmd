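---
title: "Methods: polygenic score scans and Mendelian randomization triage"
author: "prsatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic score scans and Mendelian randomization triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsatlas)
```

# The problem

A polygenic risk score (PRS) summarizes a person's genetic liability to a
trait as the weighted sum of trait-associated allele dosages, with weights
taken from an external GWAS. Scanning many scores against many phenotypes
in a biobank cohort (a phenome-wide scan) is a powerful way to surface
candidate causal relationships — but a score association is not a causal
effect. Horizontal pleiotropy (variants affecting the outcome through
pathways other than the scored trait) inflates false-positive rates of
PRS-based causal tests, which is why every scan hit here can be pushed
through a systematic two-sample Mendelian randomization (MR) triage.

`prsatlas` implements the full chain: synthetic data generation with known
ground truth, PRS construction (LD clumping, proxy substitution, allele
harmonization, scoring, standardization), the phenome scan across four
regression families, the summary-data MR estimators and sensitivity
analyses, the triage / bi-directional / mediation / multivariable MR
frameworks, and the simulation study contrasting the PRS association test
with the inverse-variance-weighted (IVW) MR estimator under pleiotropy.

# Models and estimators

## PRS construction

Scores use independent SNPs selected by greedy LD clumping: candidates at
`p <= p_threshold` are ranked by ascending p; the best is accepted and all
candidates within the window whose reference-panel `r^2` is at or above
`r2_threshold` are removed. Defaults are the lenient scoring threshold
`5e-5` with `r^2 < 0.001`; the genome-wide threshold `5e-8` is a
first-class alternative because both score sets matter (the lenient one
recovers sub-significant heritability, the strict one feeds MR). Ties in p
break by chromosome, position, then id — the clumping literature is silent
on tie-breaks, and determinism requires one. The 10,000 kb window is the
convention of the major summary-statistics platforms; only the `r^2`
threshold is intrinsic to the method.

Allele harmonization reflects weights for allele swaps, complements
strand flips, and drops palindromic SNPs (A/T, C/G) whose effect-allele
frequency lies in the ambiguity band `[0.42, 0.58]`; outside the band,
palindromic SNPs are aligned by frequency. The band and the
frequency-matching rule are conventions, not facts inherited from any one
cohort pipeline. Missing dosages contribute the SNP's cohort-mean dosage
(mean imputation keeps n constant across individuals; complete-case
scoring is available by flag). Raw scores are standardized to mean 0,
SD 1 (sample SD, n − 1) on the analysis sample, so every reported effect
is per SD of score. Unweighted scores (used when the source GWAS overlaps
the cohort and weights would overfit) carry the sign of the reported beta
only.

## Phenome scan

Each score–trait pair is fitted with the family-appropriate model: linear
(continuous), logistic (binary), proportional-odds (ordinal — with the
degenerate two-realized-level case handled as the logistic model it
mathematically is), multinomial logistic (categorical, whose headline
p-value is the likelihood-ratio test of the score and whose per-level
log-odds are reported against the reference level). Default adjustment is
age, sex, ten principal-component surrogates and genotyping chip;
sex-restricted traits drop the sex covariate and ineligible individuals.
Variance explained is the R² of the covariate-unadjusted score-only model
for continuous traits, and McFadden's pseudo-R²,
`1 − ln(L_m)/ln(L_0)`, for likelihood models — computed from the
score-only fit against the intercept-only fit.

Phenome-plot data are signed `−log10(p)` values (magnitude of evidence
signed by effect direction). Bonferroni flags default to the per-score
convention `0.05 / n_traits` (e.g. `0.05/551 = 9.07e-5`); an overall
`0.05 / n_tests` scope is available. Decile contrasts use type-7
empirical quantiles with boundary ties to the lower decile, reduce to the
2×2 contingency odds ratio when unadjusted, and apply the
Haldane–Anscombe 0.5 correction (flagged) to zero cells. AUC uses the
rank statistic (probability a random case outranks a random control, ties
half) and equals trapezoidal integration of the reported curve.

## Two-sample MR

For an instrument set of J SNPs with exposure effects γ and outcome
effects Γ (harmonized to the exposure's effect allele, exposure
`p < 5e-8`, clumped at `r^2 < 0.001`):

* **Wald ratio** (single SNP): `Γ/γ`, SE `se_Γ/|γ|`.
* **IVW**: weighted regression of Γ on γ through the origin, weights
  `1/se_Γ²`; Cochran's Q is the weighted sum of squared deviations of the
  per-SNP ratios from the pooled estimate. The default is multiplicative
  random effects: the fixed-effect SE is inflated by
  `max(1, sqrt(Q/(J−1)))`, so heterogeneity widens but never narrows
  intervals.
* **MR-Egger**: the same weighted regression with a free intercept after
  orienting every SNP to a non-negative exposure effect; the intercept
  estimates average directional pleiotropy; t-based p-values on J − 2 df
  with the same residual-scale floor.
* **Weighted median**: the 50% point of the inverse-variance-weighted
  cumulative distribution of Wald ratios, linearly interpolated;
  parametric-bootstrap SE (resampling γ and Γ from normals with their
  reported SEs; 1000 draws, seeded — the references do not pin these, so
  they are explicit configuration).
* **Weighted mode**: argmax of the weighted Gaussian-kernel density of
  the ratios, bandwidth `φ·0.9·min(sd, IQR/1.349)·J^{−1/5}`, maximized on
  a 512-point grid spanning the ratio range ± 3 bandwidths; same
  bootstrap.
* **Steiger directionality filter**: per SNP, variance explained is
  recovered from the t statistic, `r² = t²/(t² + n − 2)`, in each study;
  instruments explaining more outcome than exposure variance are removed.
  The t-based conversion is used for all trait types; the
  frequency-based binary-trait variant is a known limitation.
* **Leave-one-out**: IVW re-fitted dropping each SNP in turn; a SNP is
  flagged when its removal flips the estimate's sign or moves p across
  0.05.

`mr_fit()` bundles these behind a classed model object with `print`,
`summary`, `coef`, `confint`, `plot` and `residuals` methods.

## Triage, bi-directional, mediation, multivariable MR

The triage encodes the three-step screening logic: (1) IVW — weak
evidence (`p ≥ α`) ends the evaluation as `NOT_SUPPORTED`; (2) in the
presence of heterogeneity (`Q_p < α`) the weighted median **and** mode
must corroborate, otherwise `NOT_ROBUST` (when heterogeneity is absent
the two estimators can still be run, advisory only — both behaviours are
selectable); (3) the analysis is repeated on Steiger-filtered
instruments and the Egger intercept is tested; a nonzero intercept or a
reversal of the filtered conclusion yields `SENSITIVITY_FLAGGED`, else
`CAUSAL_CANDIDATE`. "Strong evidence" is nowhere quantified in the
screening tradition this encodes, so `α = 0.05` per step, configurable.

Bi-directional MR runs the triage in both orientations with
independently selected instruments. Mediation MR estimates each edge of
an ordered trait chain by IVW, multiplies the edges into the indirect
effect (delta-method SE), estimates the total effect directly, and
reports the proportion mediated as `indirect / total`. The alternative
reading of the proportion — `(total − indirect)/total` — is available
behind a flag, but the product-over-total form is the one consistent
with the worked example the method is known for (77% of a total effect
of 0.5 carried by edge estimates 0.7 × 0.5 × 1.1 = 0.385). A zero total
(undefined proportion) and opposite signs of indirect and total
("inconsistent mediation") are flagged rather than silently reported.
Note a terminology trap: in some published descriptions the *total*
exposure→outcome estimate is called the "direct effect"; this package
uses "total" in the standard mediation sense and computes the direct
component as total − indirect.

Multivariable MR regresses outcome effects on the matrix of exposure
effects (union of each exposure's clumped genome-wide-significant
instruments, complete-case across all studies with logged drops, no
intercept, weights `1/se_Γ²`) and reports conditional estimates plus an
attenuation ratio against each exposure's univariable IVW. Rank-deficient
exposure matrices error, naming the collinear exposures.

# The synthetic-data generator

The generator stands in for the inaccessible individual-level cohort and
the external GWAS catalogue, so its design is part of the package's
contract:

* **Genotypes** are additive dosages Binomial(2, p), p uniform on a
  configurable range (default 0.05–0.5), Hardy–Weinberg by construction.
  LD blocks copy a shared latent haplotype with probability
  `r2^(1/4)` per haplotype, giving the requested pairwise dosage r²
  in expectation and exact duplicates at r² = 1.
* **Two-sample GWAS pairs**: the exposure is `x = G b + e` with the
  genetic part scaled to a SNP heritability of 0.3 (a typical value for
  the anthropometric/metabolic traits this emulates; the source study
  does not print one). Causal SNPs contribute *equal* variance shares
  and are coded with the exposure-increasing allele as effect allele.
  Equal shares keep every instrument's expected association statistic
  well above the genome-wide threshold at the default n = 10,000 and
  m = 50, so instrument selection introduces no winner's-curse
  attenuation — a deliberate design choice so that estimator bias seen
  in tests reflects the estimators, not marginal-instrument artefacts.
  The outcome is `y = βx + Gα + e'` in a disjoint sample of the same
  size; a configurable fraction of SNPs receives direct effects
  `α ~ N(mean, sd²)` — directional when the mean is nonzero (default
  0.05 with SD 0.05), balanced when zero.
* **Cohorts** carry age, sex, ten PC surrogates and a chip indicator,
  plus traits of all four families generated from declared linear
  predictors (logistic link, proportional-odds latent variable,
  multinomial logits).
* **Mediation chains** wire exposure → mediator1 → mediator2 → outcome
  with a direct exposure → outcome path; each upstream trait has ten
  private equal-share instruments (h² = 0.3) and each of the four GWAS
  is run in its own disjoint sample over all SNPs. The generating
  proportion mediated, `(β₁β₂β₃)/(β₁β₂β₃ + direct)`, is recorded as
  truth. Because mediators causally inherit upstream variants, a
  mediator's GWAS legitimately reaches genome-wide significance at
  upstream SNPs; when the direct path is nonzero those inherited
  variants are mildly invalid instruments for the final edge. This is a
  property of mediation MR itself, not of the generator, and is why
  recovery is checked against Monte-Carlo error rather than exactly.

What the generator does **not** emulate: realistic human LD maps,
imputation uncertainty, case-control ascertainment, population structure
beyond independent confounder columns, or the correlated trait batteries
of a real biobank. Passing tests therefore demonstrate correctness of
the machinery and calibration under the stated model, not robustness to
every failure mode of real data.

# The simulation study

`run_comparison()` contrasts the PRS association test with IVW MR under
a causal model and a null model across pleiotropy levels (default grid
0–0.5 in steps of 0.1, directional or balanced). Settings follow the
printed experiment: 1000 replicates per cell, 10,000 individuals per
GWAS sample, 50 SNPs. The PRS arm is two-sample: weights from the
discovery (exposure) GWAS at `p < 5e-5`, scored and tested in the
disjoint outcome sample — mirroring the atlas pipeline. The IVW arm
instruments at `p < 5e-8`. The causal-model effect size is 0.1 (not
printed in the source; chosen so neither arm is fully saturated at the
study's sample size). The comparison scores the classical fixed-effect
IVW test: under the exact null with homogeneous instruments the
multiplicative random-effects variant is conservative (its SE floor only
ever widens), and the calibration/power contrast concerns the calibrated
test. The triage and `mr_fit()` keep the random-effects default, which
is the right robustness trade-off for real, heterogeneous instruments.

The qualitative outcome this reproduces: the PRS test has at least the
power of IVW when pleiotropy is absent, but its false-positive rate
under directional pleiotropy rises far above nominal, while the MR
toolkit at least signals the violation through the Egger intercept.

# Numerical choices and degenerate inputs

* All randomness flows from explicit seeds; identical configuration and
  seed give bit-identical outputs.
* Standardization refuses zero-variance scores by name; combining a
  score with its own negation therefore errors rather than returning
  noise.
* p-values are floored at 1e-300 so downstream `log10` transforms stay
  finite.
* Zero kernel bandwidth (all Wald ratios identical) returns the common
  ratio with SE 0 instead of failing.
* Non-converged regressions are flagged and retained so scan row counts
  remain auditable; pairs with fewer than 50 complete cases are skipped
  with a reason.
* Empty clumping results are a warning plus an empty definition (the
  scan must go on), but an empty *instrument* set is an error — MR
  without instruments is meaningless.

# Problem sizes used by the test suite

Module tests run at reduced scale (hundreds to a few thousand
individuals, tens to a few hundred replicates) — sizes chosen so each
property is decided by its stated Monte-Carlo tolerance, not by waiting.
The end-to-end calibration checks use the study's full settings: 1000
replicates at n = 10,000 and m = 50 for the null/pleiotropy cells and
the triage calibration, 25 replicates for causal-effect recovery, and 12
chains at n = 20,000 per GWAS for mediation recovery.

# Known limitations

* Steiger filtering uses the t-statistic variance conversion for binary
  traits too; liability-scale refinements are out of scope.
* LD handling assumes the reference panel's empirical correlations are
  the truth; no shrinkage is applied.
* The mediation delta-method SE ignores covariance between edges
  estimated from overlapping instrument sets.
* Correlated-instrument MR, outlier-removal estimators and
  contamination-mixture models are deliberately out of scope.
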