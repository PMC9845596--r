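---
title: "Quantifying metabolic syndrome: scores, classification and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying metabolic syndrome: scores, classification and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simscore)
```

## The model

The IDF definition of metabolic syndrome (MS) is a binary rule: central
obesity (waist circumference ≥ 94 cm in men, ≥ 80 cm in women) plus at
least two of four further components — triglycerides ≥ 1.7 mmol/L or
lipid-lowering therapy; HDL < 1.03 (men) / < 1.29 (women) mmol/L or
therapy; SBP/DBP ≥ 135/85 mmHg or antihypertensive therapy; fasting
glucose ≥ 5.6 mmol/L or diagnosed type-2 diabetes. Patients who meet some
components but not the rule are *pre-MS*. The binary label is useless for
follow-up, which motivates the continuous siMS score

$$\mathrm{siMS} = \frac{2\,WC}{height} + \frac{Gly}{5.6} + \frac{Tg}{1.7}
  + \frac{SBP}{130} - \frac{HDL}{d}, \qquad
  d = \begin{cases}1.03 & \text{men}\\ 1.3 & \text{women}\end{cases}$$

Each term is a component divided by its diagnostic reference value, so a
subject at every threshold scores exactly 3 (the HDL term enters with a
negative sign because low HDL is the risk direction; at the threshold the
four positive terms contribute 4 and the HDL term −1). The glucose term
uses *fasting* (0-min) glucose: 5.6 mmol/L is the fasting criterion it
normalises by. Waist and height share a unit so their ratio is unitless.
Note two deliberate asymmetries carried over from the source conventions:
the blood-pressure *criterion* is 135/85 while the siMS denominator is
130, and the female HDL criterion is 1.29 while the siMS denominator is
1.3. Both pairs are kept as printed rather than reconciled.

Companion indices:

* **HOMA-IR** = insulin₀ (mIU/L) × glucose₀ (mmol/L) / 22.5 — insulin
  resistance.
* **FLI** — fatty liver index, the logistic transform of
  $z = 0.953\ln Tg + 0.139\,BMI + 0.718\ln GGT + 0.053\,WC - 15.745$,
  scaled to (0, 100). Triglycerides enter in mmol/L, matching how the
  cohort's lipids are recorded. The original FLI literature uses mg/dL;
  with mmol/L the $0.953\ln Tg$ term is smaller by
  $0.953\ln(88.5) \approx 4.3$, compressing the index so cohort medians
  sit near 5 instead of near 50. FLI values from this package are
  therefore internally consistent (and monotone in the same inputs) but
  not comparable against mg/dL-based cutoffs such as FLI ≥ 60.
* **Mean OGTT insulin** — the unweighted mean of the 0/30/120-min values;
  no weighting scheme is defined for the 3-point OGTT, and the unequal
  spacing is deliberately ignored.

Missing optional biomarkers yield partial score panels rather than
errors, because real cohort tables have varying per-column n; only `sex`
is hard-required (the HDL reference is sex-specific). Height may be
derived as $100\sqrt{weight/BMI}$ when only weight and BMI are recorded,
which round-trips with the BMI definition exactly.

## Classification choices

OGTT glycoregulation categories use standard WHO/ADA thresholds — IFG:
fasting 5.6–6.9 mmol/L; IGT: 2-h 7.8–11.0 mmol/L; DM: fasting ≥ 7.0 or
2-h ≥ 11.1 or prior diagnosis — with precedence DM > IGT > IFG so every
subject gets exactly one label. Obesity grading uses the strict
inequalities BMI > 25 (overweight) and BMI > 30 (obese); BMI ≤ 25 is
labelled `out_of_cohort` since the cohort definition starts above 25. A
subject meeting three or more non-waist criteria but not the waist
criterion is *not* MS (central obesity is mandatory) and is labelled
pre-MS. Lipid-lowering therapy triggers both the triglyceride and the HDL
component, reading "or applied therapy" as attached to each lipid
criterion. The blood-pressure thresholds are configurable
(`sbp_cutoff`, `dbp_cutoff`) for users who prefer the conventional IDF
130/85.

## What the synthetic cohorts emulate

No patient-level data are distributed, so the generator emulates the
*published summary structure* of an obese two-age-group cohort
(16–30, n = 167; 31–75, n = 284): every variable reported as mean ± SD
becomes a (floored) normal marginal; every variable reported as
median (Q1–Q3) — triglycerides, the three insulin time points, CRP,
microalbuminuria, ALT, AST, GGT — becomes a log-normal marginal with
$\mu = \ln(\text{median})$ and
$\sigma = (\ln Q3 - \ln Q1)/(2 z_{0.75})$. A two-parameter log-normal can
match the median and the quartile *ratio* exactly; when the printed
quartiles are not log-symmetric the individual quartiles are approximated,
which is the best a parametric inversion can do.

Dependence is a Gaussian copula: a latent multivariate normal vector with
a documented default correlation matrix is mapped coordinate-wise through
the marginal quantile functions. The summary table reports no
correlations, so the default matrix is an *assumption*: moderate
magnitudes (|ρ| 0.2–0.6) encoding the directions metabolic-syndrome
physiology asserts (adiposity, insulin resistance, glycaemia,
triglycerides, liver enzymes, CRP, PAI-1, uric acid positively coupled;
HDL negatively; the lipid fractions and OGTT time points internally
coherent). It is repaired to positive definiteness by eigenvalue clipping
and is fully overridable; no claim is made of matching the unpublished
study correlations. Rank (Spearman) correlations survive the marginal
transforms exactly, which is what the recovery tests check.

Numerical choices worth knowing:

* **Truncation floors** (physiologic minima, e.g. HDL ≥ 0.4 mmol/L,
  2-h glucose ≥ 2.0) are implemented as exact truncated-normal quantile
  mapping, not rejection sampling. This preserves rank dependence and
  makes the realised marginal an exact truncated normal, whose
  closed-form mean is what validation compares against — for the older
  group's 2-h glucose (5.4 ± 2.5) the floor shifts the mean upward by
  about 0.1 mmol/L, a real property of the sampled distribution rather
  than a bug.
* **Weight** is computed from generated BMI and height
  ($weight = BMI\,(height/100)^2$), so BMI, weight and height are always
  mutually consistent; FLI is never generated directly but always
  computed from generated Tg/BMI/GGT/WC, keeping the pipeline
  self-consistent.
* **Height** is not in the summary table; it is normal(173.1, 9) cm for
  the young group and normal(169.7, 9) for the older, the means implied
  by the printed weight and BMI means.
* **Age** is uniform over the group range; **sex** is an even Bernoulli
  mix; therapy flags are independent Bernoulli draws (5% lipid / 5%
  antihypertensive young, 15% / 20% older — plausible for obese outpatient
  cohorts of these ages; the source does not report therapy prevalence).
* **Determinism**: the config seed drives all sampling; identical configs
  give bit-identical cohorts.

### Induced glycoregulation subgroups

The printed category prevalences (young: 2.4% IFG, 4.8% IGT; older: 1.4%
IFG, 1.8% IGT, 5.7% newly detected DM) are mutually inconsistent with the
printed continuous glucose marginals: under any unimodal marginal with
mean 5.2 and SD 1.1, far more than 1.4% of values exceed the 5.6 mmol/L
IFG threshold. The generator resolves this by assigning subjects to
categories at the printed fractions first and then mapping each
subgroup's glucose coordinates through range-restricted marginals
(normal: fasting < 5.6 and 2-h < 7.8; IFG: fasting in [5.6, 7.0); IGT:
2-h in [7.8, 11.1) with fasting drawn from the high-normal overlap zone,
mean 5.8, since 2-h hyperglycaemia is clinically accompanied by elevated
fasting values; DM: fasting ≥ 7.0). Downstream OGTT classification then
recovers the configured prevalences exactly in expectation, at the cost
of mildly compressing the overall glucose marginal (the cohort mean
fasting glucose drops by ≈ 0.3 mmol/L in the older group). Setting the
three fractions to zero recovers the pure copula marginals.

What passing tests on these cohorts do **not** show: that the package
reproduces the real study's inter-variable dependence (unpublished), its
outlier structure, its missingness pattern (synthetic cohorts are
complete), assay measurement error, or any non-log-normal skewness in the
real biomarkers. Agreement on synthetic data validates the *machinery*,
not the epidemiology.

## The statistics stage

The comparison table maps each variable to its test as data
(`table1_spec()`): pooled-variance t test for mean ± SD rows ("independent
samples t test"; Welch by flag), Mann-Whitney for median rows, Fisher's
exact test for the 2 × 4 glycoregulation distribution, Pearson chi-square
without continuity correction for the obesity proportion. The
Mann-Whitney p-value is exact (full null enumeration semantics) when the
smaller group has ≤ 8 observations and no ties are present, and the
normal approximation with tie correction otherwise. Degenerate continuous
input — both groups constant and equal — reports statistic 0 and p = 1.
Correlation screens (`table2_spec()`) use Pearson for approximately
symmetric and log-transformed variables and Spearman for skewed raw ones;
pairs are dropped listwise per analysis. Raw p-values are reported, as in
the source; a Benjamini-Hochberg column is available (`adjust = "BH"`)
but off by default, and the 0.05 threshold only *annotates* rows — it
never filters them.

## Problem sizes used in validation

The test suite and acceptance script run: 20 seeded cohorts per age group
at the published group sizes for the mean-siMS check; single cohorts of
n = 10,000 for marginal (3 standard errors) and Spearman (±0.05) recovery;
two pooled cohorts of n = 4,000 for the glycoregulation ordering of siMS;
2,000 replicates of n = 50 + 50 for the t-test size check; and full
enumeration (≤ 252 labelings) for the small-sample Mann-Whitney oracle.
These sizes put Monte-Carlo noise well below each check's tolerance while
keeping the default run fast.

## Known limitations

* The siMS *risk* score (the age- and family-history-weighted companion
  score) is out of scope; its formula is not part of this package's
  sources.
* Inputs are contractually SI; there is no mg/dL auto-conversion.
* The generator produces cross-sectional cohorts only — no longitudinal
  trajectories or intervention effects.
* FLI on the mmol/L scale is not comparable to mg/dL-based published
  cutoffs (see above).
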