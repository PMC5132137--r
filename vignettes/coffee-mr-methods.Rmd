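---
title: "Methods: genetic instruments for coffee consumption and prostate cancer"
author: "coffeemr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic instruments for coffee consumption and prostate cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coffeemr)
```

## The design

Observational studies have reported that heavy coffee drinkers have lower
prostate cancer risk, but coffee consumption is entangled with smoking,
alcohol and socioeconomic position, and diagnosed men may change their
habits. Mendelian randomization (MR) sidesteps both problems by using
genetic variants associated with caffeine intake as instruments: alleles
are assigned at conception, independently of lifestyle, and cannot be
altered by disease.

`coffeemr` implements the full analysis pipeline for a two-SNP instrument
in a multi-study case-control consortium:

1. an additive **genetic risk score** (GRS) built from imputed allele
   dosages of rs4410790 (*AHR*) and rs2472297 (*CYP1A1/2*), counting
   coffee-consumption-increasing alleles (the major allele of rs4410790,
   the minor allele of rs2472297);
2. a **first stage** relating the GRS to cups/day of coffee and tea,
   estimated per study by linear regression with heteroscedasticity-robust
   (HC1) errors and pooled by DerSimonian–Laird random effects;
3. **reduced-form** logistic models of case status and, within cases, of
   nonlocalised vs localised stage and high vs low grade, adjusted for
   eight genetic principal components and study, with cluster-robust
   (by-study sandwich) standard errors;
4. **left-truncated Cox models** of all-cause and prostate-cancer-specific
   mortality on the age timescale, entering at age at diagnosis, with the
   same adjustment and clustering;
5. fixed-effect meta-analysis of per-study estimates for between-study
   heterogeneity (Cochran's Q, I²);
6. MR-specific arithmetic: rescaling categorical odds ratios to a per-cup
   scale, the Wald ratio `beta_reduced / gamma` with its delta-method
   standard error, and the minimal detectable odds ratio of the design.

Because the consortium's individual-level data are not public, the package
ships a first-class synthetic-cohort generator with the causal and
confounding structure the analysis assumes, so every stage is exercised
end to end and the estimators' parameter recovery can be demonstrated at
the published sample sizes.

## The models

### Instrument and first stage

Imputed dosages $d \in [0,2]$ count a file's ALT allele; orientation maps
them onto the coffee-increasing allele ($d$ or $2-d$, fixed by
configuration, never re-derived from data) and the score is the additive
sum, $G = d_1 + d_2 \in [0,4]$. A missing dosage makes the score missing;
it is never imputed. The first stage is, per study $s$,

$$\text{cups}_i = \alpha_s + \gamma\, G_i + \sum_{k=1}^{8}\delta_k
\mathrm{PC}_{ki} + \varepsilon_i,$$

with HC1 sandwich errors because cups/day is right-skewed, and the
$\hat\gamma_s$ pooled by DerSimonian–Laird:
$Q=\sum w_s(\hat\gamma_s-\hat\gamma_{FE})^2$,
$\tau^2 = \max\{0, (Q-(k-1))/(\sum w_s - \sum w_s^2/\sum w_s)\}$,
weights $1/(\mathrm{SE}_s^2+\tau^2)$. The outcome heterogeneity check uses
fixed effects, exactly as the two pooling tasks are assigned in the
original analysis; $I^2 = \max\{0,(Q-(k-1))/Q\}\cdot 100$.

### Reduced-form logistic models

Case status (and, within cases, stage and grade) is modelled by maximum
likelihood logistic regression, written directly as IRLS on the score
equations. Convergence requires the largest score component below
$10^{-8}$ or a relative log-likelihood change below $10^{-10}$ (at most
50 iterations, with step-halving). Aliased columns are dropped by pivoted
QR before fitting; a diverging coefficient with a near-perfect likelihood
raises an explicit complete-separation error naming the term. The
clustered sandwich is $A^{-1}BA^{-1}$ with $A$ the observed information
and $B$ the sum over studies of outer products of within-study score
sums, scaled by $G/(G-1)$; with one observation per cluster this is HC0
times $G/(G-1)$.

### Survival models

Mortality is analysed on the *age* timescale with delayed entry: a man
enters the risk set at his age at diagnosis and leaves at death or last
follow-up, so the risk set at event age $t$ is
$\{i: \text{entry}_i < t \le \text{exit}_i\}$. The partial likelihood
uses the Efron correction for tied event ages (ages recorded in coarse
units tie heavily; the generator produces continuous ages, where Efron
and Breslow coincide). Newton iterations run until the score is below
$10^{-8}$. Risk-set sums are evaluated by two prefix-sum sweeps (one over
exit ages, one over entry ages), and the information folds the per-event
second-moment sums into per-subject cumulative weights, so a fit is
$O(nd + nd^2)$ per iteration without materializing any risk set. Records
with exit equal to entry are shifted by one day (1/365.25 y) with a
warning. Robust variance reuses the same clustered sandwich with
Breslow-form score residuals. The proportional-hazards diagnostic is a
Grambsch–Therneau-type score test of Schoenfeld residuals against event
age.

### Scaling and power

Under log-linearity in cups, an odds ratio $\mathrm{OR}_\text{ext}$
between consumption categories separated by $c$ cups/day equates to
$\exp(\ln \mathrm{OR}_\text{ext} \cdot u/c)$ per $u$ cups/day. The
package defaults to $c = 3.5$ (at least 4 cups vs under 1) and emits a
sensitivity table over $c \in [2.5, 6]$; the per-0.06-cup value stays
within half a rounding unit of 0.999 across that grid, though strictly it
rounds to 1.000 for contrasts above about 4.9 cups. The minimal
detectable per-allele odds ratio uses the case-control Wald
approximation $\mathrm{SE}(\hat\beta) \approx (N\phi(1-\phi)
\sigma^2_G)^{-1/2}$ with $\sigma^2_G = \sum_v 2f_v(1-f_v)$ derived from
the configured frequencies; because the original report does not name its
power method, the package reports the formula result (and the empirical
simulation check validates it) rather than asserting equality with the
published "region of".

## The synthetic consortium

`sim_config()` holds every generative parameter. The defaults encode the
study conditions:

* **25 studies, 46,687 men**, case fraction 0.4966 per study (case-only
  studies are expressed as `case_fraction = 1`).
* **Allele frequencies 0.63 / 0.26** for the coffee-increasing alleles.
  These are implementation defaults drawn from European reference panels
  — the consortium analysis never prints frequencies — and are fully
  configurable.
* **Imputation quality 0.95** per variant. Dosages are generated as
  posterior-mean-style blends, $d = 2f + r^2(g-2f) + e$ with
  $e \sim N(0, r^2(1-r^2)\,2f(1-f))$, clipped to $[0,2]$: the squared
  dosage–genotype correlation equals $r^2$ before clipping and the
  dosage variance is approximately $r^2 \cdot 2f(1-f)$, as for real
  imputed dosages.
* **First stage** $\gamma = 0.10$ cups/day per allele on combined
  coffee + tea, split evenly between the beverages; right-skewed
  gamma-distributed residuals (shape 2, scale 0.75 cups) capture the
  long upper tail of consumption; baseline 1.2 cups coffee / 0.8 cups
  tea plus a per-study offset (SD 0.2 cups). Only the first four studies
  carry beverage data, mirroring the subsample with questionnaires.
* **Confounding**: ever-smoking (prevalence 0.55) adds 0.5 cups/day and
  0.15 log-odds of case status, independent of genotype — the structure
  MR is designed to be immune to.
* **Reduced-form effects**: per-allele log odds `log(1.01)` on case
  status, `log(1.03)` on nonlocalised stage, `log(1.01)` on high grade;
  intercepts are tuned by root-finding so realized fractions match their
  targets in expectation, and an unattainable target raises an error
  rather than being clipped.
* **Stage and grade coding**: odd-numbered studies emit TNM token
  strings, even-numbered studies SEER labels, so both classifier paths
  are exercised; Gleason scores are drawn 2–6 (low) or 7–10 (high);
  13% / 16.7% missingness matches the published staged/graded counts.
* **Mortality**: two latent cause-specific Weibull times (shared shape
  1.2, increasing hazard) with the prostate-cancer share of the baseline
  hazard at 43% of deaths; the scale is solved analytically so the
  all-cause death probability by the administrative horizon (8 years)
  equals its target (0.2624). Ages at diagnosis are N(65, 8²) truncated
  to 40–90. Unknown vital status (2%) and unknown cause of death (5%)
  exercise the exclusion/assignment rules.
* **Reproducibility**: each study draws from its own RNG stream derived
  from the master seed, so appending a study never changes earlier
  studies' data, and a fixed seed reproduces the cohort byte for byte.

What the generator does *not* emulate: linkage disequilibrium (the two
loci are independent, as they are in reality on different chromosomes),
real population structure (the PCs are pure noise covariates, so PC
adjustment is exercised but cannot be shown to remove stratification),
between-study heterogeneity in true effects, and informative censoring.
Passing tests therefore demonstrate correctness of the estimators and
codings under the assumed generative model, not robustness to violations
of MR assumptions such as pleiotropy.

## Parameter-recovery experiments

`recovery_study()` re-estimates each published quantity from 200
simulated replicates at the published sample sizes: 4,722 men in 4
studies for the first stage; 45,755 in 23 studies for case-control;
19,758 staged cases in 21 studies; 14,010 cases with about 1,754
prostate-cancer deaths in 12 studies; 15,555 cases with about 4,081
deaths in 15 studies. Those replicate counts and sizes were chosen to
make the Monte-Carlo error of the median a small fraction of each
recovery tolerance. Counts are binomially random around their expected
values, as in any generative model; for the prostate-cancer mortality
design the baseline cause fraction is deflated by the mean per-allele
hazard multiplier so the expected death count sits at its design value.

## Numerical and coding decisions

* QC thresholds are applied inclusively (call rate $\ge 0.95$, HWE
  $p \ge 10^{-7}$ in controls, imputation $R^2 \ge 0.3$): the source
  states only the exclusion side, and boundary-inclusive acceptance is
  the conservative reading. The HWE test is the 1-df chi-square (the
  original's choice of test is unstated; chi-square is deterministic and
  is cross-checked against an exact-test oracle in the test suite). It
  needs hard calls, so it runs on rounded dosages only when $r^2 = 1$
  and is otherwise skipped with a warning.
* The TNM rule is "any nonlocalised token wins" (T3/T4/N1/M1), with
  NX/MX and absent N/M treated as localised-compatible; contradictory
  TNM/SEER double-coding becomes missing with a warning.
* The questionnaire category map (never = 0, <1 = 0.5, 1 = 1, 2–3 = 2.5,
  ≥4 = 5 cups/day with an open-category offset of 1 cup) is an explicit
  stand-in for per-study questionnaires that are not publicly available,
  and is overridable.
* Wald (not likelihood-ratio) inference throughout, with 95% CIs
  computed as $\exp(\hat\beta \pm 1.96\,\mathrm{SE})$, matching the
  OR + CI reporting style; per-SNP and GRS models are separate
  single-exposure models.
* The clustered sandwich uses the $G/(G-1)$ small-sample factor; no
  further small-$G$ refinement (such as $t_{G-1}$ quantiles) is applied,
  to stay on the reported normal-approximation scale. A known
  consequence, visible in the test suite's null-calibration check, is
  that with only 12–15 clusters the robust CIs undercover slightly
  (a few percentage points below nominal); the model-based CIs do not.
* Weak instruments are flagged at first-stage $|\gamma|/\mathrm{SE} <
  \sqrt{10}$ (F < 10) in the Wald ratio.

## Limitations

The estimators are validated against independent oracles and established
implementations, and parameter recovery holds at consortium scale, but
all of that is within the generator's assumptions. Real consortium data
would add platform differences, relatedness, cryptic stratification,
differential stage/grade coding quality between studies, and possibly
pleiotropic instrument effects — none of which the synthetic cohort
represents. The pipeline is therefore a faithful, testable
re-implementation of the analysis method, not evidence about coffee and
prostate cancer in new data.
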