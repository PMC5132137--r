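# coffeemr

Mendelian randomization (MR) of coffee consumption and prostate cancer
risk and progression, re-implemented as a tested, reusable R package.

Observational studies have linked heavy coffee drinking to lower prostate
cancer risk, but coffee is confounded with smoking, alcohol and
socioeconomic position, and diagnosed men may change their habits. MR
uses genetic variants associated with caffeine intake as instruments:
because alleles are assigned at conception, a genetic proxy for coffee
consumption is immune to that confounding and to reverse causation.
`coffeemr` implements the whole analysis for a two-SNP instrument in a
multi-study case-control consortium, together with a synthetic consortium
generator so the pipeline is testable end to end (the real consortium's
individual-level data are not public). It is aimed at genetic
epidemiologists who want the estimators, the coding rules and the
power/scaling arithmetic of this design as working, verifiable code.

## The model

An additive genetic risk score is built from imputed allele dosages of
rs4410790 (*AHR*) and rs2472297 (*CYP1A1/2*), counting
coffee-consumption-increasing alleles:

    G_i = d_i1 + d_i2,   d ∈ [0, 2],  G ∈ [0, 4]

* **First stage** (per study s, HC1 robust errors, pooled by
  DerSimonian–Laird random effects):
  `cups_i = α_s + γ G_i + Σ_k δ_k PC_ki + ε_i`
* **Reduced form** (case status; and within cases, nonlocalised vs
  localised stage and high vs low Gleason grade), by IRLS logistic
  regression with cluster-robust (by study) sandwich errors:
  `logit P(Y_i = 1) = α + β G_i + Σ_k δ_k PC_ki + study_i`
* **Mortality**, by Cox regression on the age timescale with delayed
  entry at age at diagnosis and Efron tie handling:
  `λ_i(t) = λ_0(t) exp(β G_i + Σ_k δ_k PC_ki + study_i)`
* **Heterogeneity** across studies by fixed-effect meta-analysis
  (Cochran's Q, I²); **MR arithmetic** via the Wald ratio
  `β_reduced / γ` with delta-method SE, odds-ratio rescaling
  `exp(ln OR_ext · u/c)` between category contrasts and per-cup units,
  and the minimal detectable OR
  `exp(−(z_{1−α/2} + z_{pow}) / √(N φ(1−φ) σ²_G))`.

The logistic IRLS, clustered sandwich, left-truncated Efron Cox fitter,
DerSimonian–Laird pooling and Hardy–Weinberg test are implemented from
first principles in this package and are validated in the test suite
against independent oracles (likelihood-grid search, exhaustive partial
likelihood, exact HWE enumeration) and against `survival::coxph`,
`stats::glm` and `metafor::rma`.

## Worked example

Simulate a small 8-study consortium and run the full pipeline:

```r
library(coffeemr)
cfg <- sim_config(n_studies = 8, total_n = 12000, case_fraction = 0.5,
                  n_coffee_studies = 4, seed = 7)
rep <- run_analysis(cfg)
print(rep)
```

```
Mendelian randomization analysis report (seed 7 )

First stage (combined coffee+tea): 0.079 cups/allele (95% CI 0.034, 0.124), I2 = 0%

Risk, stage and grade (per coffee-increasing allele):
    exposure                   outcome     n    or ci_low ci_high      p   i2
 g_rs4410790       all_prostate_cancer 12000 0.995  0.950    1.04 0.8368  0.0
 g_rs2472297       all_prostate_cancer 12000 1.063  0.974    1.16 0.1689 50.3
         grs       all_prostate_cancer 12000 1.025  0.979    1.07 0.2911 16.3
 g_rs4410790 nonlocalised_vs_localised  5211 1.086  0.999    1.18 0.0520  0.0
 g_rs2472297 nonlocalised_vs_localised  5211 0.979  0.903    1.06 0.6044  0.0
         grs nonlocalised_vs_localised  5211 1.037  0.998    1.08 0.0634  0.0
 ...

Mortality (per coffee-increasing allele):
    exposure                  outcome    n n_deaths years_at_risk_1000s    hr ...
 g_rs4410790                all_cause 5835     1551                40.5 1.037
 ...

Scaling: extreme-category OR 0.96 equates to 0.9993 per 0.06 cups;
power: minimal detectable per-allele OR 0.946 (per cup 0.574) at this sample size
```

Reading the output: the first stage says each coffee-increasing allele
adds about 0.08 cups/day in this simulated draw (generative value 0.10);
the odds and hazard ratios are per allele of the score with their
cluster-robust 95% CIs and the between-study I²; `n` is always the count
of records that entered that model after the logged exclusions (the run
log at the end records QC results, studies dropped for having no
controls or no nonlocalised cases, and men excluded for unknown vital
status). The scaling block converts the published highest-vs-lowest
category OR of 0.96 to a per-0.06-cup OR (≈ 0.999) and reports the
smallest per-allele OR this design could detect at 80% power.

Individual estimators are available directly — `fit_logistic()`,
`fit_linear_robust()`, `fit_cox()` (all returning an `mrfit` object with
`print`/`summary`/`coef`/`vcov`/`confint` methods), `fixed_effect()`,
`random_effects_dl()`, `wald_ratio()`, `detectable_or()` — as are the
coding rules (`classify_stage()`, `classify_grade()`,
`resolve_mortality()`, `recode_cups()`, `study_eligibility()`) and
cohort I/O (`write_cohort()`/`read_cohort()`: VCF with a per-sample `DS`
dosage field plus a tab-delimited phenotype table).

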