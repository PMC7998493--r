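---
title: "Reliability and biological variation of repeated biomarker measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliability and biological variation of repeated biomarker measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biovar)
```

## The problem

Epidemiological studies routinely characterise a subject's long-term
biomarker status from a single blood draw. Whether that is defensible
depends on how the biomarker's variance decomposes: if most variation lies
*between* subjects, one measurement ranks people reliably; if most lies
*within* subjects (day-to-day biology, cycle phase, diet, assay noise), a
single value is a poor surrogate and regression coefficients built on it are
attenuated towards zero. `biovar` implements the full analysis chain used in
short repeated-measures reliability panels — typically a few dozen subjects
measured at three roughly monthly visits — together with a synthetic-cohort
generator with known ground truth, so every stage of the chain is testable
without access to any particular study's data.

## Model and estimation

For subject $i$ at visit $j$, the working model is the random-intercept
decomposition

$$y_{ij} = x_{ij}^\top\beta + b_i + e_{ij}, \qquad
b_i \sim N(0,\sigma_b^2),\; e_{ij} \sim N(0,\sigma_w^2),$$

on the raw scale or after a natural-log transform. The crude model has only
an intercept in $x_{ij}$; the adjusted model adds fixed covariate effects
(cycle day, BMI, fasting and sleep duration, contraceptive use, serum
cholesterol, physical activity level, energy or nutrient intake — whatever
the design calls for). Both variance components are estimated by restricted
maximum likelihood. The implementation profiles the restricted likelihood
down to one dimension in the variance ratio $\lambda = \sigma_b^2/\sigma_w^2$
(generalized least squares gives $\beta$ and $\sigma_w^2$ in closed form at
each $\lambda$), maximizes by Brent search on $\log\lambda$, and then
sharpens the optimum by root-finding on the analytic profile score — Brent
alone is limited to about $\sqrt{\varepsilon}$ relative precision by the
flatness of any likelihood near its maximum, which is not enough to
guarantee agreement with the balanced-data ANOVA closed form at the $10^{-8}$
level the test-bench demands. The $\lambda = 0$ boundary is evaluated
exactly; a solution truncated there is flagged a *singular fit* and its ICC
is reported as 0 by convention.

The intraclass correlation coefficient is
$\mathrm{ICC} = \sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$, interpreted with
the conventional bands: $\ge 0.75$ very good, $0.51$–$0.74$ good,
$0.40$–$0.50$ fair, $< 0.40$ poor. Values falling in the unassigned gap
$(0.50, 0.51)$ are classified fair with a warning. Confidence intervals come
from a subject-level nonparametric bootstrap: subjects are resampled with
replacement (all visits travel together), the model is refitted per
replicate, and the percentile 2.5/97.5 bounds are taken with the classic
$(B{+}1)p$ order-statistic convention (quantile type 6) and clipped to
$[0,1]$. The default is $B = 2000$ replicates; a normal-approximation
interval is available behind a switch.

## Outlier screening

Before modelling, each biomarker is screened with the two classic
biological-variation rules:

* **Cochran's C** on the per-subject intra-individual variances,
  $C = \max_i s_i^2 / \sum_i s_i^2$, against the closed-form critical value
  $C_{\alpha} = \left[1 + (n-1)/F_{\alpha/n}(d, (n-1)d)\right]^{-1}$ with
  $d$ = visits − 1. The Bonferroni-style $\alpha/n$ form matches a
  200,000-draw Monte-Carlo null within a few thousandths across the design
  range, which the suite verifies. The scan removes the maximal-variance
  subject and repeats until clean (a single-pass switch exists).
* **Reed's criterion** on the per-subject means: an extreme is an outlier
  when its gap to the nearest value exceeds one third of the range, applied
  at both ends and re-applied after each removal. Recursion stops when three
  values remain — with exactly three, any asymmetric spacing would condemn
  an extreme, so the criterion carries no information there.

Both rules run on the biomarker's *analysis* scale. This ordering (decide
the transform, then screen) is deliberate: the intra-individual variance of
a lognormal biomarker grows with the subject's own level, so raw-scale
variances are heteroscedastic under a perfectly clean null and Cochran's
test would flag near half of clean synthetic cohorts; on the log scale the
per-scan false-positive rate sits at its nominal level.

The transform decision itself applies the Shapiro–Wilk test to pooled
within-subject-centered values on both scales and recommends the log when
raw normality is rejected but log normality is not; per-biomarker manual
overrides take precedence (raw-scale conventions for bilirubin, erythrocyte
catalase, glutathione and TEAC-type capacity assays are common even when
normality is imperfect).

## Closed-form biological-variation metrics

With $CV_T$ (total intra-individual) and $CV_G$ (inter-individual)
coefficients of variation — obtained from the variance components directly
on the raw scale, or through the lognormal relations
$\sigma = \sqrt{\ln(CV^2+1)}$ and $CV = \sqrt{e^{\sigma^2}-1}$ on the log
scale — the package computes:

* **Index of individuality** $II = CV_T/CV_G$; $II < 0.6$ marks strong
  individuality (reference change values beat population reference
  intervals), $II > 1.4$ low individuality. Undefined (rendered `/`) when
  $CV_G = 0$.
* **Reference change value**: symmetric $\pm Z\sqrt{2}\,CV_T$ on the raw
  scale; asymmetric $(e^{\pm Z\sqrt{2}\sigma}-1)\times 100$ under the
  lognormal model, with $Z = 1.96$ for the 95% level.
* **Attenuation-limiting measurement count**
  $n_\beta = [P/(1-P)]\,(\sigma_w^2/\sigma_b^2)$ with $P$ = 1 − allowed
  attenuation (defaults 10% and 20%). The count is rounded up only when it
  exceeds the lower integer by more than 0.20, floored at one measurement,
  and undefined when $\sigma_b^2 = 0$.
* **Sample size for detecting an ICC** by the Walter–Eliasziw–Donner
  Fisher-transform formula
  $n = 1 + 2k(z_\alpha + z_\beta)^2/[(k-1)(\ln C)^2]$,
  $C = (1+k\theta_1)/(1+k\theta_0)$, $\theta = \rho/(1-\rho)$, with
  multiplicative dropout inflation $\lceil n(1+r)\rceil$. A Monte-Carlo
  power check via the one-way ANOVA F test is bundled
  (`icc_power_sim()`).

```{r}
rcv_asymmetric(0.113)                  # lognormal RCV at CV_T = 11.3%
index_of_individuality(0.217, 0.617)$ii
n_measurements(1 - 0.515, 0.515, 0.10) # repeats to limit attenuation to 10%
icc_sample_size(rho1 = 0.30, k = 3, dropout = 0.20)[1:2]
```

## Sensitivity analyses and descriptive tests

Two sensitivity modes re-run the pipeline under stricter inclusion:

* **Residual mode** iteratively drops every *subject* with at least one
  standardized conditional residual beyond the cutoff (default 2.0) and
  refits until clean. The conditional convention — residuals after removing
  the empirical best linear unbiased predictor of the subject intercept,
  scaled by $\hat\sigma_w$ — is the default; marginal residuals are a
  switch. Subjects, not observations, are the exclusion unit.
* **Subgroup mode** excludes subjects flagged by binary condition columns
  (contraceptive use, medication, vaccination, cycle irregularities, health
  problems) or an inflammation marker above threshold (default 95 nmol/L
  for hs-CRP), re-screens, and reports crude-only metrics: with the
  halved sample size an adjusted model with many covariates is not
  meaningfully estimable, so the adjusted ICC is deliberately absent.

Visit effects are tested with the Friedman test; when significant, all
pairwise Wilcoxon signed-rank tests follow with Bonferroni multiplication by
the number of pairs, summarised as compact letters. Baseline interrelations
come as a Spearman correlation matrix with `autoplot()` support.

## The synthetic cohort

`synthetic_spec()` defines the generator the whole test-bench runs on:
44 subjects × 3 visits by default — the scale of a typical short
reliability panel — with a bundled 17-biomarker antioxidant panel
(`default_panel()`) whose means and CV magnitudes resemble published values
for healthy premenopausal women (between-subject CVs from 0 to ~0.62,
within-subject CVs from 0.06 to ~0.32, log-scale conventions for the plasma
micronutrients). Covariates draw from subject-level plus visit-level normal
components (or Bernoulli flags); effects enter on the analysis scale, so the
adjusted mixed model is correctly specified under simulation and
parameter-recovery tests are exact in expectation. Outlier injections
(variance inflation of a subject's deviations; mean shifts in units of the
between-subject SD) exercise the screening and sensitivity stages. One
master seed feeds deterministic per-biomarker and per-covariate substreams,
so extending the panel never perturbs existing columns.

What the generator does *not* emulate — menstrual-cycle periodicity, assay
drift, correlated biomarkers, non-lognormal skewness — bounds what passing
tests show: they certify the estimators and decision rules under the stated
variance structure, not robustness to every feature of real cohorts. For
raw-scale (normal) biomarkers with large CVs the generator redraws the rare
visit residual that would produce a non-positive concentration; this
truncation is negligible at the bundled panel's magnitudes.

## Numerical choices and problem sizes

Tolerances: the profile optimum is polished to near machine precision in
$\log\lambda$; balanced-data fits agree with the ANOVA method-of-moments
closed form to $10^{-8}$ relative, and the lognormal CV conversions invert
to $10^{-12}$. Degenerate inputs have defined behaviour: all-identical data
give a singular fit with ICC 0; zero within-subject scatter gives ICC 1;
single-visit-only designs are rejected as unidentifiable. The suite's
simulation sizes are chosen to keep the default run at desk scale while
leaving comfortable statistical margins: 500 cohorts per truth for ICC
recovery (|bias| < 0.05 at truths 0.3–0.875), 200 outer replicates at
B = 200 for bootstrap coverage (90–99% band at nominal 95%), 200,000 draws
for the Cochran Monte-Carlo null, 1000 null and 200 shifted cohorts for the
Friedman level/power checks.

## Limitations

The package fits a single random intercept — no crossed or nested random
factors, no Bayesian or small-sample (Kenward–Roger) machinery. $CV_T$ is
not decomposed into analytical and true intra-individual parts, so assay
imprecision is bundled into the within-subject component. Units are carried
as metadata and never converted. The Goldberg/Black energy-intake screen
(`screen_energy_reporting()`) computes the resting metabolic rate from a
configurable Müller-type linear equation and anchors its plausibility band
at the per-visit mean physical activity level; PAL is computed as total
energy expenditure over RMR (the time-weighted mean MET), the orientation
consistent with observed PAL values near 1.6.
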