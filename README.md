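# prsatlas

Polygenic risk score (PRS) phenome scans with a Mendelian randomization
(MR) triage, plus the simulation machinery to study when each approach can
be trusted.

## The problem

Large GWAS make it possible to summarize anyone's genetic liability to a
trait as a PRS — the sum of effect-allele dosages weighted by reported
regression coefficients,

    PRS_i = sum_j w_j g_ij,   standardized to mean 0, SD 1,

built from independent SNPs (LD clumping at r² < 0.001, inclusion at
p < 5×10⁻⁵, or the conventional 5×10⁻⁸). Regressing hundreds of biobank
traits on hundreds of such scores (a phenome-wide scan) surfaces candidate
causal relationships — but a score association can be driven by horizontal
pleiotropy rather than a causal effect of the scored trait. Two-sample MR
provides the follow-up toolkit: with per-SNP exposure effects γ and
outcome effects Γ, the IVW estimate is

    β_IVW = Σ γΓ/se_Γ² / Σ γ²/se_Γ² ,

with Cochran's Q for heterogeneity, the MR-Egger intercept for directional
pleiotropy, weighted-median and weighted-mode estimators for robustness,
Steiger directionality filtering, leave-one-out, bi-directional MR,
mediation MR (proportion mediated = product of edge IVW estimates over the
total effect) and multivariable MR for joint exposures.

`prsatlas` implements the full pipeline for biostatisticians and genetic
epidemiologists: a synthetic-data module with known ground truth (so every
stage is testable without access-restricted biobank data), PRS
construction, the four-family phenome scan, the MR estimator suite behind
a classed `mr_fit()` model object, the decision frameworks, and the
power / false-positive simulation study comparing the PRS test against
IVW under horizontal pleiotropy.

## Worked example

Simulate a two-sample GWAS pair with a true causal effect of 0.25, build
instruments, and fit the MR estimators:

```r
library(prsatlas)

cfg  <- sim_config(n_individuals = 8000, n_snps = 20,
                   causal_effect = 0.25, seed = 42)
pair <- simulate_two_sample_gwas(cfg)
panel <- pair$samples$exposure$genotypes

instr <- harmonize_two_sample(pair$exposure_stats, pair$outcome_stats, panel)
fit <- mr_fit(instr, seed = 1)
summary(fit)
#> Two-sample MR: exposure -> outcome (17 instrument(s))
#>           method estimate      se         p
#>       ivw_random   0.2704 0.02558 4.021e-26
#>            egger   0.2578 0.17162 1.538e-01
#>  weighted_median   0.2802 0.03258 7.886e-18
#>    weighted_mode   0.2830 0.06397 9.686e-06
#> Heterogeneity: Q = 19.557 on 16 df (p = 0.241)
#> Egger intercept: 0.0025 (se 0.0334, p = 0.942)
```

All four estimators recover the simulated effect (truth 0.25 is inside
every interval), Q shows no excess heterogeneity, and the Egger intercept
is indistinguishable from zero — no sign of directional pleiotropy. The
three-step triage agrees:

```r
mr_triage(pair$exposure_stats, pair$outcome_stats, panel, seed = 1)
#> MR triage: exposure -> outcome
#>   Step 1 (IVW): estimate 0.2704, p = 4.02e-26, Q_p = 0.241
#>   Step 3: 17/17 retained by Steiger, Egger intercept p = 0.942
#>   Verdict: CAUSAL_CANDIDATE
```

The same objects feed the rest of the pipeline: `ld_clump()` +
`compute_score()` + `standardize_score()` build scores, `run_scan()`
produces the score-by-trait atlas table with signed −log10(p) and
Bonferroni flags, `mr_mediation()` / `mr_mvmr()` decompose multi-risk
pathways, and `run_comparison()` reproduces the PRS-versus-IVW power and
false-positive study. `run_pipeline()` chains simulate → score → scan →
triage → export end to end.

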