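# Weighted lifestyle score and polygenic risk score construction:
# Hardy-Weinberg quality filtering, factor dichotomization, weighted
# sums and score categorization.

#' Chi-square test for Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype
#' counts against the proportions `p^2, 2pq, q^2` expected at the sample
#' allele frequency. Used as a genotyping quality filter: SNPs departing
#' from HWE in controls usually indicate assay artefacts.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (AA = zero copies of the
#'   counted allele, aa = two copies). Alternatively pass a length-3
#'   vector as `n_AA`.
#' @return List with `chi_square`, `p_value`, `allele_freq` (sample
#'   frequency of the `a` allele), `n`, and `degenerate` (`TRUE` for a
#'   monomorphic SNP, where the test is undefined and `chi_square`/
#'   `p_value` are `NA`).
#' @export
#' @examples
#' test_hwe(25, 50, 25)  # exact HWE proportions: chi-square 0, p = 1
#' test_hwe(30, 40, 30)  # chi-square 4, p ~ 0.0455
test_hwe <- function(n_AA, n_Aa = NULL, n_aa = NULL) {
  if (is.null(n_Aa) && length(n_AA) == 3) {
    counts <- as.numeric(n_AA)
  } else {
    counts <- c(n_AA, n_Aa, n_aa)
  }
  if (length(counts) != 3 || any(counts < 0) || any(!is.finite(counts))) {
    stop("genotype counts must be three non-negative numbers",
         call. = FALSE)
  }
  n <- sum(counts)
  if (n <= 0) stop("total genotype count must be positive", call. = FALSE)
  p <- (counts[2] + 2 * counts[3]) / (2 * n)  # frequency of the 'a' allele
  if (p == 0 || p == 1) {
    return(list(chi_square = NA_real_, p_value = NA_real_,
                allele_freq = p, n = n, degenerate = TRUE))
  }
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi_square <- sum((counts - expected)^2 / expected)
  list(chi_square = chi_square,
       p_value = stats::pchisq(chi_square, df = 1, lower.tail = FALSE),
       allele_freq = p, n = n, degenerate = FALSE)
}

#' Exclude SNPs departing from Hardy-Weinberg equilibrium
#'
#' Runs [test_hwe()] per SNP on the genotype matrix and removes SNPs
#' with HWE p-value below `alpha`. Monomorphic SNPs cannot enter a PRS
#' (their dosage carries no information and the HWE test is undefined)
#' and are excluded with a message.
#'
#' @param panel a [snp_panel()].
#' @param genotypes dosage matrix (subjects x SNPs, values 0/1/2/`NA`)
#'   with columns matching `panel$snp_id`.
#' @param alpha significance level of the exclusion rule; `alpha = 0`
#'   excludes nothing.
#' @return List with `panel` (retained [snp_panel()]) and `report`, a
#'   `data.frame` with `snp_id`, `chi_square`, `p_value`, `excluded`,
#'   `reason`.
#' @export
filter_snps <- function(panel, genotypes, alpha = 0.05) {
  stopifnot(inherits(panel, "snp_panel"), nrow(panel) >= 1)
  if (!all(panel$snp_id %in% colnames(genotypes))) {
    stop("genotype matrix lacks columns for some panel SNPs",
         call. = FALSE)
  }
  report <- data.frame(snp_id = panel$snp_id,
                       chi_square = NA_real_, p_value = NA_real_,
                       excluded = FALSE, reason = "",
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(panel))) {
    d <- genotypes[, panel$snp_id[i]]
    counts <- c(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
                sum(d == 2, na.rm = TRUE))
    h <- test_hwe(counts)
    report$chi_square[i] <- h$chi_square
    report$p_value[i] <- h$p_value
    if (h$degenerate) {
      report$excluded[i] <- TRUE
      report$reason[i] <- "monomorphic"
    } else if (alpha > 0 && h$p_value < alpha) {
      report$excluded[i] <- TRUE
      report$reason[i] <- "HWE departure"
    }
  }
  if (any(report$reason == "monomorphic")) {
    message("excluding monomorphic SNP(s): ",
            paste(report$snp_id[report$reason == "monomorphic"],
                  collapse = ", "))
  }
  retained <- panel[!report$excluded, , drop = FALSE]
  class(retained) <- c("snp_panel", "data.frame")
  if (nrow(retained) == 0) {
    warning("no SNPs retained after HWE filtering", call. = FALSE)
  }
  list(panel = retained, report = report)
}

#' Sex-specific binary unfavorable-lifestyle indicators
#'
#' Dichotomizes the lifestyle information of each subject into
#' unfavorable-level indicators: elevated waist circumference, regular
#' red meat intake and low fruit consumption for everyone, plus heavy
#' smoking (>= 15 pack-years, boundary included) for men. Women's
#' lifestyle score has no smoking term, so their smoking indicator is
#' `NA` and is skipped by [lifestyle_score()].
#'
#' @param subjects `data.frame` with `sex` and the raw factor columns
#'   `waist`, `red_meat`, `low_fruit` (already 0/1) and `pack_years`.
#' @return `data.frame` (one row per subject) with integer columns
#'   `waist`, `red_meat`, `low_fruit`, `smoking`.
#' @export
dichotomize_lifestyle <- function(subjects) {
  needed <- c("sex", "waist", "red_meat", "low_fruit", "pack_years")
  miss <- setdiff(needed, names(subjects))
  if (length(miss)) {
    stop("missing covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (nm in needed) {
    if (anyNA(subjects[[nm]])) {
      stop("missing covariate values in: ", nm, call. = FALSE)
    }
  }
  male <- subjects$sex == "male"
  data.frame(waist = as.integer(subjects$waist > 0),
             red_meat = as.integer(subjects$red_meat > 0),
             low_fruit = as.integer(subjects$low_fruit > 0),
             smoking = ifelse(male,
                              as.integer(subjects$pack_years >= 15),
                              NA_integer_),
             row.names = NULL)
}

#' Named log odds ratio weight vector
#'
#' @param names unique factor or SNP identifiers.
#' @param betas finite log odds ratio weights, one per name.
#' @return Named numeric vector of class `weight_vector`.
#' @export
weight_vector <- function(names, betas) {
  if (length(names) != length(betas)) {
    stop("names and betas must have equal length", call. = FALSE)
  }
  if (anyDuplicated(names)) stop("weight names must be unique", call. = FALSE)
  if (any(!is.finite(betas))) stop("betas must be finite", call. = FALSE)
  structure(stats::setNames(as.numeric(betas), as.character(names)),
            class = "weight_vector")
}

#' Weighted score: sum of beta_k * x_k aligned by name
#'
#' Computes `sum(beta_k * x_k)` per subject, the common form of both the
#' weighted lifestyle score (x = binary unfavorable indicators) and the
#' weighted PRS (x = risk-allele dosages 0/1/2). Values are aligned to
#' the weights by name; a missing value reaching this function is a
#' contract violation (subjects with failed genotyping are dropped
#' upstream, see [polygenic_score()]).
#'
#' @param x named numeric vector, or matrix/data.frame (subjects x
#'   variables) with column names.
#' @param weights a [weight_vector()].
#' @return Numeric score (vector of length `nrow(x)` for matrix input).
#' @export
weighted_score <- function(x, weights) {
  stopifnot(inherits(weights, "weight_vector"))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (!all(names(weights) %in% colnames(x))) {
      stop("alignment error: x lacks columns ",
           paste(setdiff(names(weights), colnames(x)), collapse = ", "),
           call. = FALSE)
    }
    x <- x[, names(weights), drop = FALSE]
    if (anyNA(x)) {
      stop("missing values reached weighted_score; drop or impute upstream",
           call. = FALSE)
    }
    return(drop(x %*% unclass(weights)))
  }
  if (!all(names(weights) %in% names(x))) {
    stop("alignment error: x lacks entries ",
         paste(setdiff(names(weights), names(x)), collapse = ", "),
         call. = FALSE)
  }
  x <- x[names(weights)]
  if (anyNA(x)) {
    stop("missing values reached weighted_score; drop or impute upstream",
         call. = FALSE)
  }
  sum(unclass(weights) * as.numeric(x))
}

#' Weighted polygenic risk score from a dosage matrix
#'
#' PRS = sum over retained SNPs of (per-allele log-OR) x (risk-allele
#' dosage). Subjects with a missing dosage at any retained SNP receive
#' `NA` (they are excluded from scoring rather than imputed, matching
#' the exclusion of samples with failed SNP detection).
#'
#' @param genotypes dosage matrix (subjects x SNPs).
#' @param panel retained [snp_panel()] (after [filter_snps()]).
#' @return Named numeric vector of PRS values (`NA` where any dosage is
#'   missing), with an attribute `n_dropped`.
#' @export
polygenic_score <- function(genotypes, panel) {
  stopifnot(inherits(panel, "snp_panel"))
  w <- weight_vector(panel$snp_id, panel$weight)
  if (!all(names(w) %in% colnames(genotypes))) {
    stop("alignment error: genotype matrix lacks panel SNPs", call. = FALSE)
  }
  g <- genotypes[, names(w), drop = FALSE]
  complete <- !apply(g, 1, anyNA)
  score <- rep(NA_real_, nrow(g))
  if (any(complete)) {
    score[complete] <- drop(g[complete, , drop = FALSE] %*% unclass(w))
  }
  names(score) <- rownames(genotypes)
  attr(score, "n_dropped") <- sum(!complete)
  score
}

#' Sex-specific weighted lifestyle score
#'
#' Applies [dichotomize_lifestyle()] and computes the weighted sum with
#' sex-specific weights: four factors (including heavy smoking) for men,
#' three for women.
#'
#' @param subjects cohort `data.frame` (see [dichotomize_lifestyle()]).
#' @param weights_male [weight_vector()] over
#'   `waist`, `red_meat`, `low_fruit`, `smoking`.
#' @param weights_female [weight_vector()] over
#'   `waist`, `red_meat`, `low_fruit`.
#' @return Numeric vector of lifestyle scores.
#' @export
lifestyle_score <- function(subjects, weights_male, weights_female) {
  stopifnot(inherits(weights_male, "weight_vector"),
            inherits(weights_female, "weight_vector"))
  if (!setequal(names(weights_male),
                c("waist", "red_meat", "low_fruit", "smoking"))) {
    stop("male weights must cover waist, red_meat, low_fruit, smoking",
         call. = FALSE)
  }
  if (!setequal(names(weights_female),
                c("waist", "red_meat", "low_fruit"))) {
    stop("female weights must cover waist, red_meat, low_fruit",
         call. = FALSE)
  }
  ind <- dichotomize_lifestyle(subjects)
  score <- numeric(nrow(ind))
  male <- subjects$sex == "male"
  if (any(male)) {
    score[male] <- weighted_score(as.matrix(ind[male, , drop = FALSE]),
                                  weights_male)
  }
  if (any(!male)) {
    fem <- ind[!male, c("waist", "red_meat", "low_fruit"), drop = FALSE]
    score[!male] <- weighted_score(as.matrix(fem), weights_female)
  }
  score
}

#' Estimate lifestyle-score weights from a cohort
#'
#' Fits, separately by sex, a logistic regression of case status on the
#' binary unfavorable-lifestyle indicators and returns the fitted log
#' odds ratios as [weight_vector()]s - the usual way the weights of a
#' weighted lifestyle score are obtained when no external estimates are
#' available.
#'
#' @param subjects cohort with `outcome`.
#' @param contrast which case definition to regress:
#'   `"any"` (any neoplasm vs control), `"non_advanced"` or
#'   `"advanced"` (vs control).
#' @return List with `male` and `female` weight vectors.
#' @export
fit_lifestyle_weights <- function(subjects, contrast = "any") {
  y <- outcome_indicator(subjects$outcome, contrast)
  ind <- dichotomize_lifestyle(subjects)
  keep <- !is.na(y)
  fit_sex <- function(sel, cols) {
    df <- cbind(y = y[sel & keep], ind[sel & keep, cols, drop = FALSE])
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    weight_vector(cols, stats::coef(fit)[cols])
  }
  male <- subjects$sex == "male"
  list(male = fit_sex(male, c("waist", "red_meat", "low_fruit", "smoking")),
       female = fit_sex(!male, c("waist", "red_meat", "low_fruit")))
}

#' Screen lifestyle factors by univariate association
#'
#' Optional helper reproducing the usual factor pre-selection step:
#' univariate logistic regression of case status on each candidate
#' binary factor, keeping factors with p below a threshold (commonly
#' 0.1).
#'
#' @param subjects cohort with `outcome` and the candidate columns.
#' @param factors candidate column names.
#' @param contrast case definition, as in [fit_lifestyle_weights()].
#' @param p_threshold inclusion threshold on the Wald p-value.
#' @return `data.frame` with `factor`, `log_or`, `p_value`, `selected`.
#' @export
screen_lifestyle_factors <- function(subjects, factors,
                                     contrast = "any", p_threshold = 0.1) {
  y <- outcome_indicator(subjects$outcome, contrast)
  keep <- !is.na(y)
  out <- lapply(factors, function(f) {
    fit <- stats::glm(y[keep] ~ subjects[[f]][keep],
                      family = stats::binomial())
    s <- summary(fit)$coefficients
    data.frame(factor = f, log_or = s[2, 1], p_value = s[2, 4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$selected <- out$p_value < p_threshold
  out
}

#' Categorize scores into risk groups
#'
#' Three categorization schemes used for risk stratification:
#' \describe{
#'   \item{`sex_median`}{dichotomize at the sex-specific median;
#'     scores at or above the median are `unfavorable`.}
#'   \item{`percentile_90`}{dichotomize at the 90th percentile of the
#'     score distribution; scores at or above the cutpoint are
#'     `higher`.}
#'   \item{`tertile_top`}{`higher` = top tertile, `lower` = tertiles
#'     1-2.}
#' }
#' Cutpoints use linear interpolation between order statistics
#' (`quantile` type 7) by default; ties at the cutpoint go to the upper
#' group because the rules are inclusive (>=).
#'
#' @param scores numeric score vector.
#' @param scheme one of `"sex_median"`, `"percentile_90"`,
#'   `"tertile_top"`.
#' @param sex factor/character vector (required for `sex_median`).
#' @param quantile_type passed to [stats::quantile()]; default 7.
#' @return Factor of group labels: `favorable`/`unfavorable` for
#'   `sex_median`, `lower`/`higher` otherwise. Attribute `cutpoints`
#'   records the cutpoint(s) used.
#' @export
categorize <- function(scores, scheme = c("sex_median", "percentile_90",
                                          "tertile_top"),
                       sex = NULL, quantile_type = 7) {
  scheme <- match.arg(scheme)
  if (anyNA(scores)) {
    stop("scores contain missing values; drop unscored subjects first",
         call. = FALSE)
  }
  assert_spread <- function(x, label) {
    if (length(unique(x)) < 2) {
      stop("degenerate stratification: all scores tied in ", label,
           call. = FALSE)
    }
  }
  if (scheme == "sex_median") {
    if (is.null(sex)) {
      stop("sex is required for sex-specific median categorization",
           call. = FALSE)
    }
    group <- character(length(scores))
    cuts <- c()
    for (s in unique(as.character(sex))) {
      sel <- as.character(sex) == s
      assert_spread(scores[sel], paste("stratum", s))
      m <- stats::quantile(scores[sel], 0.5, type = quantile_type,
                           names = FALSE)
      group[sel] <- ifelse(scores[sel] >= m, "unfavorable", "favorable")
      cuts[s] <- m
    }
    out <- factor(group, levels = c("favorable", "unfavorable"))
  } else if (scheme == "percentile_90") {
    assert_spread(scores, "the cohort")
    q <- stats::quantile(scores, 0.9, type = quantile_type, names = FALSE)
    out <- factor(ifelse(scores >= q, "higher", "lower"),
                  levels = c("lower", "higher"))
    cuts <- c(p90 = q)
  } else {
    assert_spread(scores, "the cohort")
    q <- stats::quantile(scores, 2 / 3, type = quantile_type, names = FALSE)
    out <- factor(ifelse(scores >= q, "higher", "lower"),
                  levels = c("lower", "higher"))
    cuts <- c(tertile = q)
  }
  attr(out, "cutpoints") <- cuts
  out
}

# Binary case indicator for one of the three case-control contrasts.
# Returns NA for subjects outside the contrast (e.g. advanced cases in
# the non-advanced contrast) so they drop out of the model.
outcome_indicator <- function(outcome,
                              contrast = c("any", "non_advanced",
                                           "advanced")) {
  contrast <- match.arg(contrast)
  outcome <- as.character(outcome)
  switch(contrast,
         any = as.integer(outcome != "control"),
         non_advanced = ifelse(outcome == "advanced", NA_integer_,
                               as.integer(outcome == "non_advanced")),
         advanced = ifelse(outcome == "non_advanced", NA_integer_,
                           as.integer(outcome == "advanced")))
}
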