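---
title: "Estimating storage decay of serum lipids and its impact on cardiovascular risk classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating storage decay of serum lipids and its impact on cardiovascular risk classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidecay)
```

## The problem

Biobanked serum from long-running cohorts is often the only source of
historical lipid measurements, but cholesterol degrades slowly in the
freezer. If samples drawn across 25 years are all assayed on one date,
measured levels confound three things: the patient's true lipid course
over follow-up, systematic differences between enrolment eras (period
effects: statin uptake, falling smoking rates), and storage decay itself.
This package implements an analysis that separates them, converts the
estimated decay into a correction factor, and asks the clinically
decisive question: does correcting change patients' cardiovascular risk
categories?

## The model

For lipid level $y_{ij}$ (mmol/L) of patient $i$ at occasion $j$:

$$y_{ij} = x_{ij}'\beta + \gamma_1 t_{f,ij} + \gamma_2 t_{f,ij}^2
  - \delta\, t_{s,ij} + b_i + \varepsilon_{ij}, \qquad
  b_i \sim N(0, \sigma_b^2),\;\; \varepsilon_{ij} \sim N(0, \sigma_e^2),$$

where $t_f$ is follow-up time (years since inclusion), $t_s$ is storage
time (years between sampling and assay), $x_{ij}$ collects covariates,
and the single random intercept $b_i$ carries the within-patient
correlation of repeated measures. The quadratic follow-up term reflects
the nonlinear course of cholesterol after disease onset. Two analyses
share this skeleton:

* the **period-effect analysis** replaces $\delta t_s$ with subcohort
  indicators and subcohort-by-follow-up interactions, and jointly tests
  the interactions (Wald chi-square on 4 df for five subcohorts);
* the **decay analysis** keeps storage time as the primary regressor;
  $-\hat\delta$ (a loss) becomes the correction factor, applied as
  $y_{\text{corrected}} = y_{\text{observed}} + \delta\, t_s$.

Confounders enter by the change-in-estimate rule: a candidate is kept if
adding it moves any monitored effect (the interactions for the period
analysis, the storage slope for the decay analysis) by more than 10%
relative. When a monitored base coefficient is exactly zero the change is
judged on an absolute scale (`zero_scale`, default 1 mmol/L) instead of a
relative one.

Downstream, corrected TC and HDL feed the TC:HDL ratio and the SCORE
two-cause Weibull model of 10-year fatal cardiovascular risk, and
patients are cross-tabulated by risk category (low < 10%, intermediate
10–20% inclusive, high > 20%) before and after correction.

## What the synthetic cohort emulates

No public data set with this design exists, so the generator is
first-class, tested code. Its defaults *are* the study conditions:

* five inclusion-period subcohorts (1985–1989 … 2005–2009), 30 patients
  each, inclusion dates uniform within each period;
* sampling at follow-up years {0, 1, 2, 3, 5, 7, 10}, all samples assayed
  January 2012 (decimal year 2012.0); samples whose date would exceed the
  analysis date are dropped, reproducing the staircase of truncated
  follow-up in recent subcohorts and storage times from under a year to
  about 27 years;
* per-subcohort covariate distributions with the secular trends such a
  cohort shows (statin use rising from 0% to 29%, smoking falling from
  47% to 29%, rising age at inclusion, DAS28 and rheumatoid-factor
  prevalence roughly stable);
* true decay rates $\delta_{TC} = 0.030$ and $\delta_{HDL} = 0.024$
  mmol/L per storage-year — the values the adjusted decay models report
  on such data — with fixed-effect truth for the intercepts, follow-up
  trend and covariate effects likewise taken from those adjusted-model
  estimates, so that the fitted functional form is the generative form
  and parameter recovery is a well-posed test;
* noise per lipid: $\sigma_b = 0.8$, $\sigma_e = 0.5$ mmol/L for TC
  (levels around 5 mmol/L) and $\sigma_b = 0.25$, $\sigma_e = 0.15$ for
  HDL-c (levels around 1.2 mmol/L). A single noise scale for both lipids
  would push a substantial share of simulated HDL values below zero; the
  positivity floor (0.1 mmol/L, resampled residuals) would then truncate
  old samples asymmetrically and bias decay recovery, so the HDL scale is
  set from the observed dispersion of HDL-c (SD ≈ 0.3 mmol/L) instead;
* systolic blood pressure Normal(135, 15) mmHg per patient — not part of
  the lipid model, but required by the risk score — and log-normal
  triglycerides (median ≈ 1.6 mmol/L) for Friedewald LDL.

One integer seed drives a single generator stream, so every cohort draw
is bit-reproducible.

What it deliberately does **not** emulate: freeze–thaw cycles, vial
types, the 2008 transfer from −20 °C to −80 °C storage, assay batch
effects, within-patient biological drift beyond the smooth trend, or
disease-activity dynamics (DAS28 and RF stay at baseline). Passing tests
therefore show that the estimators recover a linear decay under the
staircase design with Gaussian patient heterogeneity — not that real
serum decays linearly.

## Numerical choices

* The random-intercept likelihood is profiled over
  $\lambda = \sigma_b^2/\sigma_e^2$ using the closed-form
  compound-symmetry inverse
  $V_i^{-1} \propto I - \tfrac{\lambda}{1 + n_i\lambda} J$, so each
  evaluation is $O(Np + gp^2)$ for $N$ observations, $g$ patients and $p$
  fixed effects. The scalar optimiser works on $\log\lambda$ over
  $[-20, 20]$ (tolerance $10^{-12}$ after a local refinement), then an
  analytic-gradient root polish brings the optimum to near machine
  precision, and the $\sigma_b^2 = 0$ boundary is checked explicitly. On
  balanced layouts the REML estimates match the closed-form ANOVA
  estimators to about $10^{-14}$; the test suite also cross-checks
  estimates, standard errors, variance components and log-likelihoods
  against `lme4` on unbalanced cohorts.
* REML is the default for reported coefficients, ML for likelihood-ratio
  tests (the REML likelihood is not comparable across fixed-effect
  structures, and `lr_test()` refuses it). Either convention could be
  defended; this is the common one for mixed models.
* Joint tests are Wald chi-square rather than F with Satterthwaite
  degrees of freedom — simpler, and adequate at the design's size
  (150 patients, ~950 observations): under a null generator the
  period-effect test rejects at 5.2% (1000 replicates). At much smaller
  cohort sizes some anticonservatism should be expected.
* Confidence intervals are Wald, estimate ± 1.96 SE; p-values are
  two-sided normal.
* Subcohorts are indicator-coded with the oldest period as reference,
  matching the natural "oldest vs most recent" contrast.
* Rank-deficient designs are refused, naming the collinear columns;
  degenerate inputs (a subcohort observed at a single follow-up time,
  fewer than two subcohorts, negative storage times) raise named errors
  rather than producing silent nonsense.

## The type-I calibration uses a decay-free null

One finding worth recording: with decay switched **on**, the
period-effect test rejects at ~9–10% rather than 5%. This is not a test
defect. Inside the recent subcohorts, patients enrolled earlier have both
longer storage (hence lower measured lipids, via decay) and longer
uncensored follow-up; the censoring at the fixed assay date therefore
correlates patient-level lipid shifts with observed follow-up length and
induces genuine small subcohort-by-time mean differences. The test
correctly detects them — storage decay leaks into the period analysis
through the staircase design, which is precisely why the decay analysis
adjusts for follow-up and subcohort structure. The size calibration in
the acceptance suite therefore runs the generator with both decay rates
set to zero, which is the only configuration in which "no period effect"
is true of the data-generating mechanism.

## SCORE engine

The risk engine implements the published two-cause Weibull form: per
cause (coronary and non-coronary), baseline survival
$S_0(a) = \exp(-e^{\alpha}(a-20)^p)$ and 10-year conditional risk
$1 - \left(S_0(a+10)/S_0(a)\right)^{e^w}$ with
$w = \sum_k \beta_k (x_k - \mathrm{ref}_k)$, summed over causes. The
coefficients ship in a versioned, human-readable constants file
(`inst/extdata/score_coefficients_conroy2003.csv`) transcribed from the
published SCORE derivation (Conroy et al. 2003), never hard-coded; the
file documents which entries carry the strongest provenance (the
total-cholesterol variant) and which could not be re-audited against the
original tables when the file was assembled (the TC:HDL-ratio
cholesterol betas). The ratio variant is the default because the ratio
is the lipid input used for individual risk stratification here; the
region default is the low-risk calibration (a Dutch cohort). No
rheumatoid-arthritis risk multiplier is applied — the analysis evaluates
the score exactly as published. Ages outside the calibrated 20–85 range
raise an error unless clamping is requested explicitly; the pipeline
requests it, since an inception cohort legitimately contains patients
older than 85 at baseline. Category boundaries read "10–20%" as a closed
interval; both cut-offs are configurable.

The engine is verified three ways: an algebraic identity ($S_0(20) = 1$),
monotonicity sweeps in every risk factor, and agreement to $10^{-12}$
with an independently coded scalar implementation, plus a small frozen
grid of chart-style integer percentages derived with that oracle.

## Decay correction and its direction

Because the TC and HDL decay rates are similar in absolute terms
(0.030 vs 0.024) while HDL levels are about four times smaller, storage
inflates the observed TC:HDL ratio, and correction deflates it: for
decays $a, b > 0$ and storage $t > 0$,
$(TC + at)/(HDL + bt) < TC/HDL \iff TC/HDL > a/b = 1.25$, which holds
for every clinically plausible profile. Correction therefore lowers
computed risk and can only move patients toward lower categories — the
reclassification matrix is lower-triangular. This is asserted both
algebraically over randomized inputs and on full pipeline runs.

LDL is handled asymmetrically on purpose: no storage effect on LDL is
assumed (the decay analysis finds none), so corrected LDL is *recomputed*
by Friedewald from corrected TC and HDL with observed TG rather than
corrected directly. Friedewald's validity guard (TG ≤ 4.5 mmol/L) is the
only protection against its known fragility with non-fasting samples;
triglyceride decay is not modelled for lack of evidence.

## Problem sizes used by the tests

The acceptance suite fits 200 replicate default cohorts for decay
recovery (accepting the mean within two Monte-Carlo standard errors of
the true rates), runs 500 null replicates for the size of the
period-effect test (accepting the binomial 95% band around 5%), checks
the balanced-ANOVA and dense-GLS oracles at $10^{-8}$, and sweeps 10,000
randomized profiles for the ratio/category direction property. The whole
suite completes in well under a minute on one core; the power and
confounder-screen simulations in the unit tests use 25–30 replicates at
reduced cohort sizes, chosen so each check remains sharp without
dominating runtime.

## Known limitations

* The mixed model has a single random intercept — no random slopes, no
  serial correlation, no GEE alternative; that matches the target
  analysis but understates within-patient structure real data may have.
* Wald-based inference is asymptotic; no small-sample degree-of-freedom
  correction is offered.
* The change-in-estimate screen is stepwise-like and inherits the usual
  caveats of data-driven confounder selection.
* The synthetic cohort is a model of the *design*, not of serum
  chemistry; conclusions about real storage decay require real paired
  measurements.
* The SCORE constants are a transcription; users applying the package to
  actual clinical decisions should verify the coefficient file against
  the original publication for their region and variant.
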