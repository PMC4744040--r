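---
title: "Methods: Mendelian randomization of alcohol consumption on lipids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomization of alcohol consumption on lipids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrlipids)
```

## The design

`mrlipids` implements an instrumental-variable analysis of the causal
effect of alcohol consumption on nine lipid measures (TG, total
cholesterol, HDL-c, HDL2-c, HDL3-c, LDL-c, sdLDL-c, apoB, Lp(a)).
Variants in the alcohol-dehydrogenase genes alter acetaldehyde
accumulation and hence drinking behaviour; because alleles are assigned
at conception, they are — under the usual MR assumptions — independent of
the confounders that plague observational alcohol–lipid associations.

Three assumptions carry the design, and the package operationalizes each:

* **Relevance** — the instrument predicts the exposure. Checked by the
  first-stage F and partial R² of the allele score; F ≤ 10 flags a
  weak-instrument caveat on the affected outcome rows rather than
  aborting the analysis.
* **Exchangeability** — the instrument is independent of confounders.
  Screened by Pearson correlation (|r| > 0.1 fails) between each
  candidate dosage and smoking (coded 0/1/2 for never/former/current),
  BMI, waist-to-hip ratio and diabetes (0/1).
* **Exclusion restriction** — the instrument affects the outcome only
  through the exposure. Proxied by screening candidates for LD
  (r² > 0.2, computed as squared Pearson correlation of dosages) against
  user-supplied lipid-associated loci, so variants that tag lipid genes
  directly are excluded.

Redundant candidates (pairwise r² > 0.7) are pruned per connected
component of the LD graph, keeping the variant with the most functional
impact (exonic/splicing above everything else), then the largest source
sample size, then the lexicographically smallest rsID. The last
tie-break is this package's own addition: the upstream rules do not
specify one, and a total order is required for the screening to be
invariant to candidate order (a property the tests assert).

The surviving instruments are oriented so each dosage counts the
alcohol-raising allele (a fitted negative slope flips G to 2 − G) and
summed into an unweighted score. The score itself is then re-screened
with the same confounder/LD criteria; outcomes are stored as flags.

## Phenotype derivation

All derivations are deterministic and vectorized:

* grams of ethanol per week from beverage counts
  (wine 10.8 g / beer 13.2 g / liquor 15.1 g per unit);
* analysis exposure `ln(g/wk + 1)`, mapping abstention to 0;
* drinker categories: never and former pass through; current drinkers
  with < 1 drink/wk are *infrequent*; otherwise *heavy* above
  210 g/wk (men) / 105 g/wk (women) and *low-to-moderate* at or below
  the threshold (the boundary is inclusive on the low-to-moderate side);
* Friedewald LDL-c = TC − HDL-c − TG/5, undefined above TG 400 mg/dL;
* HDL2-c = HDL-c − HDL3-c;
* Lp(a) rescaled ×1.326 to an apo(a)-isoform-insensitive assay scale;
* natural-log companions for the six log-analyzed lipids (TG, HDL-c,
  HDL2-c, sdLDL-c, apoB, corrected Lp(a)). Non-positive inputs to a log
  transform are set missing with a warning instead of erroring: the
  exposure's +1 construction has no analogue for lipids, and a negative
  subtraction-derived HDL2-c is a data problem the analyst should see,
  not a crash.

One deliberate wrinkle: the "record 0 g/wk for infrequent drinkers"
convention is applied to category classification, but the derived
analysis exposure keeps the stored g/wk. Re-zeroing would make the
analysis exposure differ from the exposure the synthetic generator's
causal curves act on, breaking parameter-recovery testing; with real
interview data the zeroing happens upstream at recording time anyway.

## The estimator

The first stage is OLS of exposure on score plus covariates (sex, age,
PC1, PC2). The F reported is the nested-model F for adding the score,
and partial R² the proportional RSS reduction; the identity
`F = partialR²/(1 − partialR²)(n − k)` is asserted to 1e-8 on every fit.

The second stage cuts first-stage fitted values at their empirical
25/50/75 percentiles. Boundary ties go to the lower quartile — with a
discrete score plus continuous age exact ties are rare, but the rule is
fixed and documented. Cut-points are recomputed per outcome on that
outcome's complete-case set, since per-lipid missingness (and the
visit-4 subsampling of sdLDL-c and apoB) changes the analysis set; a
config-level alternative would be trivial to add but the per-model
choice matches reporting per-outcome n. Quartile boundaries are also
reported back-transformed to g/wk via `exp(x) − 1`; this is reporting
convention only.

Lipids are regressed on quartile indicators (q1 reference) plus
covariates; visit-4 outcomes use age at visit 4. Wald tests use the
large-sample normal/χ² reference — at n ~ 10⁴ the t/F distinction is
immaterial. The default covariance is heteroskedasticity-robust (HC1)
with a classical option: no closed-form generated-regressor correction
exists for quartiled fitted values, so the CIs are explicitly
conditional on the estimated quartile assignment. The overall test is
the 3-df quadratic form c'V⁻¹c over the three quartile coefficients.

`fit_linear_2sls()` is the continuous-exposure analogue used for oracle
checks: the two-step coefficient equals the closed-form IV solution
(asserted to 1e-8 on random designs), and its SE recomputes residuals
with the observed — not fitted — exposure, the standard 2SLS correction.

The ancestry-PC helper (`compute_pcs()`) is a plain SVD on dosages
centred at 2p and scaled by √(2p(1−p)), signs fixed by making each
component's largest-magnitude score positive. It is a functional
stand-in for dedicated stratification software, not a reimplementation
of it.

## The synthetic cohort generator

The generator exists so that every downstream stage has a testable
ground truth. It emulates:

* five independent instrument SNPs in Hardy–Weinberg equilibrium at
  MAFs 0.001, 0.172, 0.169, 0.409, 0.313 with marginal per-allele
  effects 0.33, 0.06, 0.07, 0.05, 0.07 on ln(g/wk + 1);
* drinking status never/former/current at 18.1/17.0/64.9%, independent
  of genotype and confounder by default (so the exclusion restriction
  holds exactly); an `abstention_follows_confounder` switch couples
  abstention odds to the confounder for reverse-causation stress tests;
* a single latent standard-normal confounder U acting on exposure
  (+0.3 per SD by default) and on each lipid, with observed proxies
  (smoking, BMI, waist-to-hip ratio, diabetes) generated as noisy
  functions of U so the screening step has something real to screen;
* a lipid panel on the measurement scale, with HDL-c stored as the sum
  of generated HDL2-c and HDL3-c (making the subtraction derivation
  exact), Friedewald-eligible TG/TC, and visit-4 subsampling of
  sdLDL-c/apoB via higher missingness (20%/24.5%).

Two generator choices deserve explanation:

**Marginal-effect rescaling.** Per-allele effects are specified as
whole-sample marginal slopes, because that is how instrument-discovery
studies report them. Internally the latent exposure model's
coefficients are divided by the attenuation factor
`P(current) · P(latent > 0)` so that zeroing non-drinkers and truncating
the latent at 0 leaves the configured marginal slope intact; a 200,000-
individual test recovers each configured slope within 3 SE.

**Weak-instrument calibration.** The exposure intercept (1.8) and
residual SD (2.45, with a 1,200 g/wk plausibility cap on reported
intake) are calibration constants, tuned once by simulation so that the
default score's first-stage partial R² is ~0.13% at n = 10,000 — the
regime in which the F ≈ 10 diagnostic is actually informative. The
upstream literature does not report the exposure's residual variance, so
these constants are this package's own; they trade off intake realism
(mean g/wk runs somewhat high) in favour of the calibration, which is
load-bearing for the diagnostics tests.

Default causal curves are J-shaped tents: benefit accumulating up to the
heavy-drinking threshold (ln 211 on the exposure scale) and reversing
three-fold faster beyond it, with amplitudes that produce quartile
effects of realistic magnitude (ln-TG effects in the −0.05 to −0.15
range).

## What the weak-instrument regime can and cannot show

A point that shaped the test design: with the score explaining ~0.1% of
exposure variance, the exposure's spread around its prediction is ~2.4
log-units. Averaging any causal curve over that spread is a Gaussian
convolution; curve components sharp enough to leave an interior peak
across the fitted-value range are suppressed by factors of order
exp(−ω²σ²/2) ≈ 10⁻⁶. Consequently the expected quartile profile under
the calibrated default is near-linear *whatever the true curve*, and no
replicate-stable q3-peaked pattern can be generated there — a genuine
limitation of quartile-shape inference with weak instruments that users
of this design should be aware of.

The package therefore separates two questions. Weak-instrument
*calibration* (partial R² in the 0.05–0.2% band, F near 10–14) is tested
under the default configuration. Nonlinear *shape recovery* — does the
quartiled second stage find |β_q3| ≥ |β_q4| when the causal curve peaks
in the third quartile of predicted exposure? — is tested under
`strong_instrument_config()`: per-allele effects scaled ×8 (the strength
of the strongest known alcohol-metabolism variants, ALDH2-class),
exposure noise 1.2, and a TG curve peaking at 2.7 ln-units, the centre
of the third predicted-exposure quartile under that configuration.
These settings were fixed from a design scan before being frozen into
the tests.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the sizes the properties
demand: 500 replicates of n = 10,000 for parameter recovery (mean 2SLS
within 2 Monte-Carlo SEs of the true −0.13 while OLS is ≥ 5 MC SEs off
in the confounded direction), 2,000 replicates of n = 2,000 for the
overall Wald test's type-I error (0.05 ± 0.015), 200 replicates of
n = 10,893 for the peak-shape fraction, 30 replicates of n = 10,000 for
the calibration band, and single cohorts of 4,000–10,893 elsewhere.

Numerical conventions: pairwise-complete observations for screening
correlations with a 50-individual overlap floor (below it the statistic
is undetermined and strict mode fails the screen conservatively); the
score is computed only for individuals with complete dosages (an
unweighted sum is biased by per-individual missingness, so there is no
imputation); SNPs monomorphic in a given sample skip orientation with a
warning (rs2066702 at MAF 0.001 has no carriers in ~2% of n = 2,000
draws); rank-deficient designs error naming the offending columns.

## Known limitations

* The generator has no LD among the five instruments (the screened
  default set is effectively independent; LD structure appears only in
  screening-test fixtures), no longitudinal visit structure beyond the
  visit-4 missingness pattern, and a single global confounder rather
  than a confounder hierarchy.
* CIs from the quartiled second stage are conditional on the estimated
  cut-points; no resampling correction is provided.
* Quartile-shape inference under genuinely weak instruments is
  uninformative (see above); the package reports the diagnostics that
  reveal this rather than pretending otherwise.
* Units are mg/dL throughout; there is no mmol/L layer.
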