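---
title: "Methods behind simscore: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind simscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simscore)
```

## The scoring model

The siMS score expresses each metabolic syndrome component as a fraction of
its diagnostic cutoff and sums the fractions:

$$\mathrm{siMS} = 2\frac{W}{H} + \frac{G}{G_{ref}} + \frac{T}{T_{ref}} +
\frac{P}{P_{ref}} - \frac{D}{D_{ref}(sex)}$$

with waist $W$ and height $H$ in cm, fasting glucose $G$ and triglycerides
$T$ and HDL $D$ in mmol/L, systolic pressure $P$ in mmHg. The waist term
uses the waist-to-height ratio (doubled so that the conventional "healthy"
ratio of 0.5 contributes 1 like the other components) rather than the raw
circumference, which removes most of the stature dependence and lets one
formula serve adults and children. HDL enters negatively because it is
protective. The default denominators are the 2009 joint-definition cutoffs
($G_{ref}=5.6$, $T_{ref}=1.7$, $P_{ref}=130$, $D_{ref}=1.02$ male / $1.28$
female); every one of them is a field of `sims_reference()` and can be
replaced by laboratory- or population-specific values. A subject at every
cutoff with $W/H = 0.5$ scores exactly 3, which makes the scale
interpretable across cohorts — the property the sample-specific scores
lack.

Two deliberate quirks are worth stating:

* The HDL *score denominators* (1.02/1.28) differ from the HDL *classifier
  cutoffs* (1.03/1.29). The continuous formula is conventionally written
  with the former; the dichotomous definition uses the latter. Both are
  separate config fields, so either convention can be forced everywhere.
* `tg_double_ref` divides the triglyceride term by $2T_{ref}$ instead of
  $T_{ref}$. This variant correlates marginally better with the
  sample-specific scores, but the single-reference form is kept as the
  default for simplicity; the flag exposes the variant.

The siMS risk score multiplies the (full-precision, never the rounded)
siMS score by $Age/45$ for men or $Age/50$ for women — reference ages near
the onset of elevated cardio/cerebro-vascular incidence, 50 chosen for
women as the average age of menopause — and by 1.2 when a positive family
history of cardio- or cerebro-vascular events is recorded (an average 20%
excess familial risk). Treatment flags are carried by the data model but do
not enter the continuous scores; they only matter to the dichotomous
classifier.

**Missing data.** Scores are complete-case per quantity: a score exists
for a subject exactly when all of its inputs do, and nothing is imputed. A
missing family history is *unknown*, not negative; `score_cohort(...,
assume_no_family_history = TRUE)` (or the CLI's
`--assume-no-family-history`) must be used deliberately to treat it as a
known negative.

**Units are fixed** (cm, kg, mmHg, mmol/L, mIU/L, years) and never
auto-converted. Silent unit mix-ups are the dominant failure mode for a
cutoff-normalized formula — a glucose of 100 mg/dL scored against a 5.6
mmol/L cutoff contributes 18 instead of 1 — so ingestion rejects files
whose glucose, HDL or triglycerides exceed physiological mmol/L ceilings
(30, 12 and 40 respectively) instead of guessing a conversion.

**Display rounding** is round-half-up at two decimals (`format_score()`),
applied only at presentation. Internally everything chains at full
precision; in particular the risk score multiplies the unrounded siMS
value.

## The dichotomous classifier

Adults (age ≥ 18) follow the 2009 harmonized definition: waist ≥ 94 cm
(men) / 80 cm (women), Tg ≥ 1.7, HDL < 1.03 / 1.29, SBP ≥ 130 and/or
DBP ≥ 85, glucose ≥ 5.6; at least 3 of 5 criteria ⇒ MS present. Inequality
directions are as quoted (HDL is the one strict `<`); drug treatment for a
component fulfils that criterion regardless of the measured value.

Children and adolescents use the IDF consensus structure: below 10 the
syndrome is not defined; from 10 to under 16 abdominal obesity (waist at or
above the population 90th percentile) is mandatory plus at least two of the
other four criteria at the fixed cutoffs above; from 16 the adult rule
applies. The cited consensus does not print universal waist percentiles —
they are population-specific — so `pediatric_reference()` takes a
percentile table as configuration. The shipped default table is a
**synthetic linear approximation** of school-age waist percentile growth,
adequate for simulation and testing; clinical use should substitute the
table for the population at hand.

Missing components make the diagnosis missing whenever the ≥3 decision is
ambiguous (e.g. 2 criteria present, 1 unknown), never imputed false: the
classification is the ground truth for ROC analysis downstream, and
imputation would bias measured prevalence and discrimination.

## The sample-specific comparators

Two families of classical continuous MS scores are implemented as
comparators, with the component set: waist circumference, blood pressure,
log triglycerides, HDL, and a glycemic variable (fasting glucose, log
fasting insulin, or log HOMA-IR).

**Sum of z-scores.** Each component is regressed by OLS on age and sex
(pooled, sex as an indicator — the coding is irrelevant to residuals and is
fixed at male = 1 for reproducible coefficients); residuals are
standardized (sample sd, $n-1$); the HDL z is sign-flipped; the score is
the sum of the five z's. Blood pressure enters as systolic. Right-skewed
variables (Tg, insulin, HOMA-IR) are log-transformed first; the natural log
is used — the base cancels in standardization. If a stratum has constant
age *and* sex the regression degenerates to centering, with a warning. A
component whose residual sd is numerically zero (below $10^{-10}$ relative
to the component scale — plain `== 0` would miss the ~1e-16 noise residuals
of a constant column) is an error naming the component. Two complete cases
are the mathematical minimum (the sample sd needs $n \ge 2$) and are
accepted.

**PCA factor scores.** The five components (blood pressure as mean
arterial pressure here) are standardized and the principal components of
their **correlation** matrix extracted — a covariance PCA would let the
incommensurate units set the loadings. "Factor analysis" is implemented as
unrotated PCA with the eigenvalue-greater-than-1 retention rule, the usual
convention when the two terms are used interchangeably and no rotation is
stated. Two score variants: the first-component score, and the two-factor
variance-weighted sum $(\lambda_1 PC_1 + \lambda_2 PC_2)/(\lambda_1 +
\lambda_2)$. The normalization by retained variance is one of several
defensible readings of "weighted for the variance explained"; it does not
affect correlations, which are the quantities compared. When only one
eigenvalue exceeds 1 — typical of age-homogeneous subsamples — the weighted
sum degrades to the first component with a warning. Eigenvectors are
oriented so the waist loading is non-negative (falling back to the Tg
loading if it is exactly zero), which makes repeated runs bit-identical.

Both comparators optionally run independently within age strata
(`age_strata_default()`: <18, 18–30, 31+), re-deriving the regressions or
components per stratum — which is precisely the sample-specificity that
motivates the siMS score.

Open points resolved as package policy: the z-score regressions pool both
sexes with a sex covariate (taking "adjusted for age and gender"
literally); the PCA's glucose variant log-transforms Tg but not glucose
(glucose is near-symmetric in clinical ranges; insulin and HOMA-IR are
logged in their variants).

## Validation layer

Pearson correlations (via `stats::cor.test`; two-sided p from the t
distribution with $n-2$ df) use pairwise complete cases per cell, which
maximizes the n of each comparison and matches per-score complete-case
accounting. Optional natural-log transforms handle right-skewed scores —
an externally supplied risk comparator (e.g. a published 10-year
cardiovascular risk algorithm, which this package deliberately does not
implement) is correlated on the log scale.

ROC AUC uses the Mann–Whitney construction with midrank ties:
$AUC = (R_+ - n_+(n_+{+}1)/2)/(n_+ n_-)$, the probability a random positive
outscores a random negative with ties counting ½. Orientation is fixed
(higher score ⇒ positive) and never auto-flipped, so anti-discrimination is
reported honestly as AUC < 0.5. The 95% CI uses the Hanley–McNeil standard
error with a normal approximation truncated to [0, 1] — the simplest
published estimator, chosen because the CI method behind typical
statistics-package output is rarely stated; the method is recorded in the
result (`ci_method`), and DeLong-type CIs are out of scope.

## The synthetic cohort generator

`generate_cohort()` exists so that the entire pipeline — ingestion,
scoring, classification, comparators, validation — is exercisable without
patient data. It emulates an obesity-enriched, mixed-age (7–77),
two-sex endocrinology-clinic population: 34.5% male; ages drawn from a
three-group mixture (weights 0.138/0.305/0.557, means 13.2/24.3/48.2 y,
sds 2.8/3.4/10.6). A standard-normal latent severity factor loads on every
component — the single-factor structure repeatedly reported for the
metabolic syndrome, and the reason z-sum and PCA scores correlate — plus a
second, lipid-specific factor coupling Tg and HDL beyond the severity
axis. With the default `lipid_axis_scale = 1` a whole-sample correlation
PCA extracts two factors ($\lambda_2 \approx 1.1$–$1.3$); setting it to 0
yields a pure single-factor population ($\lambda_2 \approx 0.67$) in which
the weighted-sum PCA falls back to one factor — the structure of
age-homogeneous subsamples.

Each component is mean + age slope + sex effect + loadings × factors +
independent Gaussian noise on its modelling scale, exponentiated for Tg and
insulin (hence strictly positive). Height is drawn by sex with a linear
growth curve reaching adult stature at 16; waist derives from a
severity-dependent waist-to-height ratio times height; weight from a
severity-dependent BMI; DBP is SBP minus a positive gap, so SBP > DBP
always. Treatment flags are all negative: the generator emulates an
untreated scoring population. Missingness, when configured, is applied
independently per field as the last step. Generation is fully deterministic
given the config (which includes the seed).

The component-level constants are **calibration artifacts**, chosen once
with `scripts/calibrate_synthetic.R` so that default cohorts have mean BMI
≈ 31 kg/m², MS prevalence ≈ 47%, and the factor structure above, and left
alone since. What the generator does *not* emulate: real measurement-error
structure, treated patients, informative missingness, assay floors/ceilings
other than simple clamps, or the exact joint distribution of any real
database. Tests passing on synthetic cohorts therefore demonstrate the
*machinery* (formulas, accounting, invariances, qualitative structure
recovery), not population-level agreement with any particular clinical
sample, whose exact correlations and AUCs can only be reproduced from that
sample itself.

## Problem sizes and numerical choices in the test suite

The suite runs at deliberately small scales — oracle comparisons on random
cohorts of n ≤ 50, structure-recovery checks on cohorts of 250–528, a
10-seed dispersion check at n = 4000 (the mean effect of severity loadings
flows only through log-normal convexity and needs that n to resolve) — all
chosen as the smallest sizes at which the checked properties are stable.
Exact oracles (normal-equations OLS, SVD-based PCA, brute-force
pair-counting AUC, the product-moment sum formula) are compared at
1e-10/1e-8/1e-12 as appropriate; stochastic properties use fixed seeds and
wide bands (e.g. prevalence within ±10 percentage points of 46.6%,
structure-recovery r > 0.7, AUC > 0.85).

## Known limitations

* The score's cross-population comparability is exactly as good as the
  agreed reference cutoffs; mixing configs across cohorts silently breaks
  it (configs are therefore explicit everywhere, and the CLI logs them).
* The risk score's age/heredity multipliers are heuristic, not calibrated
  to absolute event probabilities; without longitudinal outcomes no cutoff
  value is derivable, and none is offered.
* The pediatric classifier is only as good as the supplied waist
  percentile table; the shipped default is synthetic.
* Hanley–McNeil CIs undercover slightly for AUCs near 1 and small n; the
  point estimate, not the CI, is the supported comparison quantity.
* XLSX ingestion reads a single sheet through the same header contract as
  CSV and needs `readxl` installed; CSV is the first-class format.
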