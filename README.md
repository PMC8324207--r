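# crcrisk

Risk modelling for colorectal neoplasm screening: weighted lifestyle
scores, polygenic risk scores (PRS) with Hardy–Weinberg quality
filtering, case–control odds ratios for combined risk profiles,
Gail-type 10-year absolute risk projection with competing mortality, and
evaluation of risk-adapted screening strategies by positive predictive
value (PPV) and number of colonoscopies needed per lesion (NNS).

It is written for biostatisticians and screening-programme analysts who
want to reproduce, stress-test or extend this modelling chain. Because
individual-level screening-trial data are rarely distributable, the
package ships a synthetic cohort generator with exactly the statistical
structure the analysis assumes (two-stage logistic outcome model,
inbreeding-parameterized HWE departures, class-conditional FIT
results), so every stage is testable end to end.

## The models

**Scores.** Lifestyle score `LS = Σ βk·xk` over binary
unfavorable-lifestyle indicators (waist circumference, red meat intake,
low fruit consumption; plus ≥ 15 pack-years of smoking for men), and
`PRS = Σ βk·gk` over risk-allele dosages `gk ∈ {0,1,2}` of SNPs passing
a 1-df chi-square HWE filter; all weights are log odds ratios.
Lifestyle is dichotomized at the sex-specific median, the PRS at its
90th percentile (ties upward).

**Relative risk.** Logistic regression of each case–control contrast
(any neoplasm, non-advanced adenoma, advanced neoplasm vs controls) on
the four-level combined lifestyle-by-PRS exposure, stratified by sex,
Wald intervals, optional lifestyle×PRS product term.

**Absolute risk.** Baseline hazard calibration
`h1(a) = h(a) / Σg Pg·RRg` (attributable-risk adjustment), then
cause-specific cumulative incidence with competing mortality under
piecewise-constant hazards — per age band, in closed form,

```
S · λ/(λ+μ) · (1 − exp(−(λ+μ)Δ)),   λ = rr·h1(a), μ = m(a)
```

with parametric-bootstrap confidence intervals over the log-RR
uncertainty.

**Screening yield.** Triage rules over the four risk cells send
high-risk subjects to colonoscopy and low-risk subjects to FIT
(positive ≥ 100 ng Hb/ml reflexes to colonoscopy); scenarios are scored
by person-level PPV and NNS (`NNS × PPV = 1`).

## Worked example

```r
library(crcrisk)

panel  <- default_snp_panel()            # 24 candidate SNPs, 5 out of HWE
cohort <- simulate_subjects(cohort_config(5000, seed = 42,
  outcome_model = list(intercept_any = qlogis(0.25),
                       beta_any = c(waist = 0.5, red_meat = 0.35,
                                    low_fruit = 0.3, smoking = 0.4),
                       intercept_advanced = qlogis(0.3),
                       beta_advanced = numeric(0))), panel)

g <- as.matrix(cohort[, panel$snp_id]); rownames(g) <- cohort$subject_id
filt <- filter_snps(panel, g, alpha = 0.05)
cat("retained", nrow(filt$panel), "of", nrow(panel), "SNPs\n")
#> retained 18 of 24 SNPs
```

The five designed HWE failures are always removed; here one additional
SNP fell below α = 0.05 by chance, as expected for 19 null tests on a
random draw.

```r
prs <- polygenic_score(g, filt$panel)
w   <- fit_lifestyle_weights(cohort)
ls  <- lifestyle_score(cohort, w$male, w$female)
lg  <- categorize(ls, "sex_median", sex = cohort$sex)
pg  <- categorize(unname(prs), "percentile_90")

suite <- run_contrast_suite(cohort, lg, pg, contrasts = "any")
subset(suite, sex == "male")
#>    sex contrast           exposure n_cases n_controls    or ci_low ci_high
#>   male      any    favorable_lower     285        490 1.000     NA      NA
#>   male      any   favorable_higher      25         50 0.867  0.525    1.43
#>   male      any  unfavorable_lower     746        775 1.663  1.393    1.99
#>   male      any unfavorable_higher      73         89 1.391  0.987    1.96
```

Each row is one combined exposure cell with its case/control counts and
age-adjusted odds ratio versus the favorable-lifestyle/lower-PRS
reference.

```r
rt <- rate_table(seq(50, 70, 5), seq(55, 75, 5),
                 incidence = c(60, 90, 130, 180, 240),     # per 100k p-y
                 mortality = c(400, 700, 1200, 2100, 3600),
                 sex = "male", per100k = TRUE)
dist <- risk_distribution(
  c("favorable_lower", "favorable_higher",
    "unfavorable_lower", "unfavorable_higher"),
  prevalence = c(0.45, 0.05, 0.40, 0.10),
  rr = c(1, 2.0, 1.7, 2.9), se_log_rr = c(0, 0.30, 0.14, 0.29))

project_profile_table(50, 10, dist, rt, n_boot = 2000, seed = 42)
#>              profile  rr    risk  ci_low ci_high age_start horizon
#>     favorable_lower 1.0 0.00479 0.00397 0.00559        50      10
#>    favorable_higher 2.0 0.00956 0.00534 0.01684        50      10
#>   unfavorable_lower 1.7 0.00814 0.00650 0.00964        50      10
#>  unfavorable_higher 2.9 0.01384 0.00829 0.02124        50      10
```

Ten-year absolute risk of colorectal neoplasm for a 50-year-old in each
risk profile, given the supplied registry-style rate table: 0.48% in
the lowest profile rising to 1.38% in the highest, with bootstrap 95%
intervals reflecting the log-RR standard errors.

```r
compare_scenarios(cohort, lg, pg,
                  rules = list(triage_rule("either-high"),
                               triage_rule("both-high")))
#>          scenario n_screened n_colonoscopies detected_advanced detected_any
#>  colonoscopy-only       5000            5000               635         2104
#>       either-high       5000            3689               530         1696
#>         both-high       5000             855               232          460
#>  ppv_advanced ppv_any nns_advanced nns_any
#>         12.7%   42.1%          7.9     2.4
#>         14.4%   46.0%          7.0     2.2
#>         27.1%   53.8%          3.7     1.9
```

Restricting colonoscopy to risk-enriched cells raises the PPV for
advanced neoplasm (12.7% → 27.1% under `both-high`) and lowers the NNS
(7.9 → 3.7) at the cost of lesions missed in the FIT arm — the core
trade-off of risk-adapted screening.

`run_pipeline()` (and the thin CLI in `inst/cli/crcrisk.R`) chains the
stages from a YAML configuration and writes every table with a
provenance header; a fixed seed gives a byte-identical output bundle.

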