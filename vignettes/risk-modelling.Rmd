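---
title: "Risk modelling for colorectal neoplasm screening with crcrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk modelling for colorectal neoplasm screening with crcrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcrisk)
```

## The modelling chain

crcrisk implements the risk-modelling chain used in risk-stratified
colorectal cancer (CRC) screening studies. Individual risk is summarized
by two weighted scores:

* a **lifestyle score** $LS = \sum_k \beta_k x_k$ over binary
  unfavorable-lifestyle indicators $x_k$ (elevated waist circumference,
  regular red meat intake, low fruit consumption, and — for men only —
  heavy smoking, defined as $\ge 15$ pack-years with the boundary
  included), with weights $\beta_k$ equal to the log odds ratios of each
  factor for colorectal neoplasm; and
* a **polygenic risk score** $PRS = \sum_k \beta_k g_k$ over risk-allele
  dosages $g_k \in \{0, 1, 2\}$ of SNPs that survive a Hardy–Weinberg
  equilibrium (HWE) quality filter, with per-allele log odds ratio
  weights.

Scores are categorized (lifestyle at the sex-specific median, PRS at the
90th percentile, optionally the top tertile), odds ratios for the four
combined lifestyle-by-PRS profiles are estimated by logistic regression
against three case–control contrasts (any neoplasm, non-advanced
adenoma, advanced neoplasm — each versus colonoscopy-negative controls),
10-year absolute risks are projected per profile with competing
mortality, and a risk-adapted screening strategy (risk triage to
colonoscopy or fecal immunochemical test, FIT) is evaluated by positive
predictive value (PPV) and the number of colonoscopies needed per lesion
detected (NNS).

All of this is exercised on synthetic cohorts: the generator produces
data with exactly the statistical structure the downstream stages
assume, so the chain is testable end to end without access to
individual-level trial data.

## The synthetic cohort generator

`simulate_subjects()` draws, per subject: sex (default 51.3% male,
matching the composition of a baseline colonoscopy cohort from a
population-based Chinese CRC screening trial), age uniform over the
screening eligibility window 50–74 years, binary unfavorable-lifestyle
indicators at sex-specific prevalences (defaults near that cohort's
margins), and SNP dosages from per-SNP genotype frequencies.

Genotypes follow the inbreeding-coefficient parameterization of HWE
departure: with risk-allele frequency $p$ and coefficient $f$, genotype
frequencies are

$$\big((1-p)^2 + fp(1-p),\; 2p(1-p)(1-f),\; p^2 + fp(1-p)\big),$$

so $f = 0$ is exact HWE and a single knob forces a quality failure.
`default_snp_panel()` uses this to build a 24-SNP candidate panel in
which 5 SNPs carry $f = 0.5$, reproducing the common situation where a
targeted genotyping panel loses a handful of assays to HWE failure.
`hwe_pattern_genotypes()` additionally provides a deterministic fixture
whose genotype counts equal the rounded expected counts per SNP: on it,
the HWE filter's pass/fail pattern reflects the panel design exactly
rather than sampling noise, which is the right fixture whenever a test
needs an exact retained-SNP count (a random draw of 19 null SNPs at
$\alpha = 0.05$ would flip at least one of them in roughly 62% of
seeds).

The outcome is generated in **two logistic stages**: any neoplasm given
covariates, then advanced given neoplasm. This mirrors the three-class
case–control structure while keeping each stage an ordinary logistic
model, and makes injected log odds ratios directly recoverable by the
association module. With all covariate effects zero, the default
intercepts reproduce the class margins 667/1880 (any neoplasm) and
203/667 (advanced among neoplasm).

FIT results are class-conditional: sensitivity 0.31 for advanced
neoplasm (a case mix of cancers at ~0.75 and advanced adenomas at
~0.25 sensitivity), 0.10 for non-advanced adenoma, specificity 0.92.
These are *plausible placeholders* for a one-round quantitative FIT at
the 100 ng Hb/ml cutoff, not estimates from any specific study — no
in-trial FIT accuracy was available to calibrate them. The optional
quantitative mode draws ng Hb/ml values consistent with the binary flag
under the $\ge 100$ positivity rule (boundary positive).

What the generator deliberately does **not** emulate: correlation (LD)
between SNPs, age- or sex-dependence of genotype frequencies,
confounding between lifestyle factors, colonoscopy quality or lesion
location, and longitudinal repeat screening. Passing tests therefore
demonstrate the statistical machinery is correct under the stated model,
not that real screening data meet the model's assumptions.

## Score construction choices

* **HWE test**: plain 1-df chi-square of observed genotype counts
  against $\hat p^2 / 2\hat p\hat q / \hat q^2$; monomorphic SNPs are a
  degenerate case (no test; excluded from the PRS with a message). The
  exclusion threshold defaults to $\alpha = 0.05$ and is exposed in the
  configuration, since published analyses rarely state it. An exact test
  would differ only at rare-allele SNPs and tiny samples.
* **Missing genotypes** exclude the subject from PRS scoring (mirroring
  the exclusion of samples with failed SNP detection); no imputation.
* **Quantile convention**: cutpoints use linear interpolation between
  order statistics (`quantile` type 7, R's default). Group membership at
  the boundary depends on this, so it is configurable
  (`quantile_type`). Ties at a cutpoint always go to the upper
  (unfavorable / higher) group because the categorization rules are
  inclusive ($\ge$ median, $\ge$ 90th percentile).
* **Lifestyle weights** come from a supplied `weight_vector()` or are
  estimated by sex-stratified logistic regression
  (`fit_lifestyle_weights()`); the univariate pre-screening of candidate
  factors at $p < 0.1$ is available as an optional helper
  (`screen_lifestyle_factors()`) but not hard-wired, since the factor
  set is usually fixed by design.

## Odds-ratio estimation

`fit_logistic()` wraps the binomial GLM (iteratively reweighted least
squares) with a deviance convergence tolerance of 1e-8 and at most 50
iterations, adding two guard rails: coefficients diverging beyond 15 in
absolute value trigger a separation warning naming the term, and
rank-deficient designs raise an aliasing error instead of silently
dropping columns. Intervals are Wald intervals throughout — the standard
reporting convention in this literature; profile-likelihood intervals
are out of scope. Crude 2x2 odds ratios apply the Haldane–Anscombe 0.5
continuity correction (with a warning) when a cell is zero.

The adjustment set behind published profile odds ratios is typically
unstated; `run_contrast_suite()` defaults to continuous age and makes
the set configurable. Its output deliberately reports the per-cell
case/control counts next to each OR so crude recomputations are always
possible. The lifestyle-by-PRS interaction model (product term on the
log-odds scale) is available as a sensitivity analysis.

## Absolute risk projection

The projection follows the classical absolute-risk (Gail-type)
construction. A composite age-banded incidence hazard $h(a)$ from
registry data is first calibrated to the risk-profile distribution:
with profile prevalences $P_g$ and relative risks $RR_g$,

$$h_1(a) = \frac{h(a)}{\sum_g P_g \, RR_g},$$

so that the prevalence-weighted profile hazards reproduce $h(a)$
exactly (the denominator is $1/(1 - AR)$ with $AR$ the attributable
risk). Both age-constant and age-banded $(P_g, RR_g)$ are supported;
with banded input the band's own parameters calibrate that band and the
profile's band-specific RR enters the projection.

The 10-year risk for a profile with relative risk $r$ is the
cause-specific cumulative incidence under competing mortality $m(a)$,
with all hazards piecewise constant over age bands. Each band $i$
intersecting the projection window contributes, in closed form,

$$S_i \cdot \frac{\lambda_i}{\lambda_i + \mu_i}
  \left(1 - e^{-(\lambda_i + \mu_i)\Delta_i}\right),
  \qquad \lambda_i = r\,h_1(a_i),\; \mu_i = m(a_i),$$

where $S_i$ is the probability of being alive and lesion-free at band
entry and $\Delta_i$ the within-window band width. There is no
quadrature error; the degenerate band $\lambda_i + \mu_i = 0$
contributes 0 (the $\lambda_i \Delta_i S_i$ limit). Bands are half-open
$[start, end)$, ages are exact reals, and tables published per 100,000
person-years are converted on read.

The test suite checks this band walk against two independent
integrators: pure forward Euler at $\Delta t = 10^{-3}$ years (which
carries its own $O(\Delta t)$ error of order $10^{-5}$ on realistic
hazards, so it is compared loosely and catches formula-level mistakes)
and a fine-grid integrator with exact exponential updates on a
boundary-aligned grid (agreement to $10^{-9}$, catching band-traversal
mistakes). A calibration identity — prevalence-weighted profile risks
equal the population projection — holds exactly for hazards and within
1% relative error for 10-year risks below 10%, where the cumulative
mapping is still nearly linear.

Confidence intervals use a **parametric bootstrap over the
relative-risk uncertainty**: each draw samples every profile's log RR
from a normal with its estimated mean and standard error, re-runs
calibration and projection, and the 2.5/97.5 percentiles over the draws
(default 2,000, seeded) form the interval. Registry-rate uncertainty is
ignored by default because registry denominators are large; with all
standard errors zero the interval collapses onto the point estimate.
Published absolute-risk tables built from national registry rate and
attributable-risk tables cannot be reproduced without those tables
(they are typically supplementary material and are consumed here as
user-supplied CSV inputs); the package instead guarantees the
calibration, ordering and oracle properties above on any valid rate
table.

## Risk-adapted screening yield

A triage rule is a truth table over the four combined lifestyle-by-PRS
cells (the exact high-risk predicate used in published risk-adapted
schemes is rarely printed, so the rule is configurable; presets
`either-high`, `both-high`, `LS-only`, `PRS-only`, plus the degenerate
`all-high`/`all-low`). High-risk subjects go straight to colonoscopy;
low-risk subjects are offered FIT, and FIT-positive subjects ($\ge$ 100
ng Hb/ml, boundary included) reflex to colonoscopy.

Detection is person-level: a colonoscopy detects the subject's true
most-advanced lesion class. PPV is detected target lesions over
colonoscopies performed; NNS is its reciprocal, so $NNS \times PPV = 1$
exactly at full precision. Values are rounded to one decimal only for
display. On a fixture cohort with the composition 203 advanced / 464
non-advanced / 1,213 controls ($N = 1880$), the colonoscopy-only
scenario gives PPV 10.8% and NNS 9.3 for advanced neoplasm and NNS 2.8
for any neoplasm.

## Numerical and design notes

* Deterministic contract: every simulator takes an explicit integer
  seed; a fixed seed and configuration give byte-identical output
  bundles, and every written table carries a provenance header (package
  version, seed, MD5 of the configuration file).
* Problem sizes in the test suite were chosen so statistical checks are
  decisive at desk scale: frequency-recovery checks at $n = 50{,}000$
  with ~3.5-SD binomial bounds, coverage of an injected combined-exposure
  OR of 3.0 over 200 replicates of $n = 5{,}000$ (expected coverage
  $\approx$ 95%, asserted $\ge 93\%$), HWE type-I calibration over
  2,000 SNPs of $n = 2{,}000$ within 2 binomial SD of $\alpha$.
* Coverage and null-calibration simulations generate the four-level
  exposure directly (`simulate_case_control()`) so the injected cell
  log-OR is exactly the estimand of the fitted model; routing the
  injection through simulated scores would change the true cell OR.
* Degenerate inputs fail loudly: all-tied scores (no cutpoint),
  monomorphic SNPs, empty exposure cells (flagged, OR omitted), zero
  colonoscopies (undefined yield), zero detections (infinite NNS,
  flagged), projection windows not covered by the rate table.

## Limitations

The generator's independence assumptions (no LD, independent lifestyle
factors) make recovery tests easier than real data would be; the
absolute-risk module's accuracy is bounded by the quality of the
supplied registry rates; and the screening-yield analysis is a
retrospective re-screening of a fixed cohort — it does not model
participation, adherence, repeat rounds, or cost.
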