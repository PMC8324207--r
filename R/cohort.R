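# Synthetic screening cohorts: subject-level simulation with a two-stage
# outcome model and class-conditional FIT results.

#' Configuration for a synthetic screening cohort
#'
#' Bundles every knob of the subject-level simulator. The outcome is
#' generated in two stages: a logistic model for carrying any colorectal
#' neoplasm given covariates, then a logistic model for the neoplasm
#' being advanced given that a neoplasm is present. This mirrors the
#' three-class case-control structure (control / non-advanced adenoma /
#' advanced neoplasm) used in screening colonoscopy studies while
#' keeping each stage an ordinary logistic regression.
#'
#' Default lifestyle-factor prevalences follow the composition of a
#' baseline colonoscopy cohort from a population-based Chinese CRC
#' screening trial (about 94% of men and 91% of women consuming red
#' meat regularly, 39%/48% with low fruit intake, 48% of men with >= 15
#' pack-years, elevated waist circumference in roughly 40%). The default
#' outcome intercepts reproduce that cohort's class margins (any
#' neoplasm 667/1880, advanced among neoplasm 203/667) when all
#' covariate log odds ratios are zero.
#'
#' Default FIT operating characteristics (sensitivity 0.31 for advanced
#' neoplasm - a mix of cancers and advanced adenomas - 0.10 for
#' non-advanced adenoma, specificity 0.92) are plausible one-round
#' quantitative-FIT values at the 100 ng Hb/ml cutoff, not estimates
#' from any particular trial; set them explicitly when that matters.
#'
#' @param n_subjects number of subjects, at least 1.
#' @param sex_ratio fraction male in `[0, 1]`.
#' @param age_range integer bounds (years) of the uniform age draw;
#'   default 50-74, the usual screening eligibility window.
#' @param lifestyle_prevalences list with elements `male` and `female`,
#'   each a named probability vector over the binary unfavorable
#'   indicators `waist`, `red_meat`, `low_fruit` and (men only)
#'   `smoking` (>= 15 pack-years).
#' @param outcome_model list with `intercept_any`, `beta_any`,
#'   `intercept_advanced`, `beta_advanced`. The betas are named log odds
#'   ratio vectors; names refer to subject columns (`age`, `male`,
#'   `waist`, `red_meat`, `low_fruit`, `smoking`) or to SNP identifiers
#'   (per-allele effect on the dosage).
#' @param fit_model list with `sensitivity` (named vector over classes
#'   `non_advanced`, `advanced`), `specificity` (scalar), and `mode`
#'   (`"binary"` flag only, or `"quantitative"` ng Hb/ml values
#'   thresholded at 100).
#' @param missing_rate per-genotype missingness probability.
#' @param seed integer seed; fixed seed gives byte-identical cohorts.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects,
                          sex_ratio = 0.513,
                          age_range = c(50, 74),
                          lifestyle_prevalences = list(
                            male = c(waist = 0.40, red_meat = 0.935,
                                     low_fruit = 0.393, smoking = 0.481),
                            female = c(waist = 0.40, red_meat = 0.914,
                                       low_fruit = 0.479)),
                          outcome_model = list(
                            intercept_any = stats::qlogis(667 / 1880),
                            beta_any = numeric(0),
                            intercept_advanced = stats::qlogis(203 / 667),
                            beta_advanced = numeric(0)),
                          fit_model = list(
                            sensitivity = c(non_advanced = 0.10,
                                            advanced = 0.31),
                            specificity = 0.92,
                            mode = "binary"),
                          missing_rate = 0,
                          seed = 1L) {
  stopifnot(length(n_subjects) == 1, n_subjects >= 1)
  probs <- c(sex_ratio, missing_rate,
             unlist(lifestyle_prevalences, use.names = FALSE),
             fit_model$sensitivity, fit_model$specificity)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(age_range) == 2, age_range[1] <= age_range[2])
  for (nm in c("waist", "red_meat", "low_fruit", "smoking")) {
    if (!nm %in% names(lifestyle_prevalences$male)) {
      stop("male lifestyle_prevalences missing factor: ", nm, call. = FALSE)
    }
  }
  for (nm in c("waist", "red_meat", "low_fruit")) {
    if (!nm %in% names(lifestyle_prevalences$female)) {
      stop("female lifestyle_prevalences missing factor: ", nm, call. = FALSE)
    }
  }
  stopifnot(all(c("non_advanced", "advanced") %in%
                  names(fit_model$sensitivity)))
  fit_model$mode <- match.arg(fit_model$mode, c("binary", "quantitative"))
  structure(list(n_subjects = as.integer(n_subjects),
                 sex_ratio = sex_ratio,
                 age_range = as.integer(age_range),
                 lifestyle_prevalences = lifestyle_prevalences,
                 outcome_model = outcome_model,
                 fit_model = fit_model,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a synthetic screening cohort
#'
#' Draws sex, age and binary unfavorable-lifestyle indicators per the
#' configuration, simulates per-SNP risk-allele dosages from the panel,
#' assigns the three-class outcome from the two-stage logistic model
#' (linear predictor = intercept + sum of log-OR x covariate, including
#' per-SNP dosages), and generates a FIT result with class-specific
#' sensitivity and an overall specificity.
#'
#' Pack-years are generated consistently with the smoking indicator:
#' men flagged as heavy smokers receive >= 15 pack-years, other men a
#' value below 15 (possibly 0), women mostly 0.
#'
#' @param config a [cohort_config()].
#' @param panel a [snp_panel()], or `NULL` for a cohort without
#'   genotypes.
#' @return A `data.frame` of class `crc_cohort`: `subject_id`, `sex`,
#'   `age`, indicators `waist`/`red_meat`/`low_fruit`/`smoking`,
#'   `pack_years`, one dosage column per SNP, `outcome` (factor
#'   control/non_advanced/advanced), `fit_positive` and, in
#'   quantitative mode, `fit_value` (ng Hb/ml).
#' @export
simulate_subjects <- function(config, panel = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  local_rng(config$seed)
  n <- config$n_subjects
  sex <- factor(ifelse(stats::runif(n) < config$sex_ratio, "male", "female"),
                levels = c("male", "female"))
  age <- sample(seq(config$age_range[1], config$age_range[2]), n,
                replace = TRUE)
  male <- sex == "male"

  prev <- function(factor_name) {
    p <- ifelse(male,
                config$lifestyle_prevalences$male[factor_name],
                # women have no smoking term in the lifestyle score
                ifelse(rep(factor_name == "smoking", n), 0,
                       config$lifestyle_prevalences$female[factor_name]))
    as.integer(stats::runif(n) < p)
  }
  waist <- prev("waist")
  red_meat <- prev("red_meat")
  low_fruit <- prev("low_fruit")
  smoking <- prev("smoking")

  # pack-years consistent with the >= 15 pack-year indicator for men
  pack_years <- numeric(n)
  heavy <- male & smoking == 1
  pack_years[heavy] <- 15 + stats::rexp(sum(heavy), rate = 1 / 12)
  light_men <- male & smoking == 0
  ever_light <- stats::runif(sum(light_men)) < 0.4
  pack_years[light_men][ever_light] <-
    stats::runif(sum(ever_light), 0.5, 14.5)
  fem_ever <- !male & stats::runif(n) < 0.015
  pack_years[fem_ever] <- stats::runif(sum(fem_ever), 0.5, 10)

  subjects <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                         sex = sex, age = age,
                         waist = waist, red_meat = red_meat,
                         low_fruit = low_fruit, smoking = smoking,
                         pack_years = round(pack_years, 1),
                         stringsAsFactors = FALSE)

  if (!is.null(panel)) {
    freqs <- genotype_freqs(panel$raf, panel$inbreeding_f)
    freqs[freqs < 0] <- 0
    for (j in seq_len(nrow(panel))) {
      d <- sample(0:2, n, replace = TRUE, prob = freqs[j, ])
      if (config$missing_rate > 0) {
        d[stats::runif(n) < config$missing_rate] <- NA_integer_
      }
      subjects[[panel$snp_id[j]]] <- d
    }
  }

  lp <- function(intercept, beta) {
    eta <- rep(intercept, n)
    for (nm in names(beta)) {
      x <- switch(nm, male = as.numeric(male), subjects[[nm]])
      if (is.null(x)) {
        stop("outcome model names unknown covariate: ", nm, call. = FALSE)
      }
      xv <- as.numeric(x)
      xv[is.na(xv)] <- 0  # missing dosage contributes no genetic load
      eta <- eta + beta[[nm]] * xv
    }
    eta
  }
  om <- config$outcome_model
  p_any <- stats::plogis(lp(om$intercept_any, om$beta_any))
  p_adv <- stats::plogis(lp(om$intercept_advanced, om$beta_advanced))
  if (any(!is.finite(p_any)) || any(!is.finite(p_adv))) {
    stop("model specification error: outcome probabilities are not finite",
         call. = FALSE)
  }
  any_neo <- stats::runif(n) < p_any
  advanced <- any_neo & stats::runif(n) < p_adv
  outcome <- factor(ifelse(!any_neo, "control",
                           ifelse(advanced, "advanced", "non_advanced")),
                    levels = c("control", "non_advanced", "advanced"))
  subjects$outcome <- outcome

  fm <- config$fit_model
  p_pos <- ifelse(outcome == "control", 1 - fm$specificity,
                  fm$sensitivity[as.character(outcome)])
  fit_positive <- stats::runif(n) < p_pos
  subjects$fit_positive <- fit_positive
  if (fm$mode == "quantitative") {
    val <- numeric(n)
    val[fit_positive] <- 100 * (1 + stats::rexp(sum(fit_positive), 1.5))
    val[!fit_positive] <- stats::runif(sum(!fit_positive), 0, 99.9)
    subjects$fit_value <- round(val, 1)
  }
  class(subjects) <- c("crc_cohort", "data.frame")
  subjects
}

#' Deterministic cohort fixture matching a published sex-by-outcome table
#'
#' Expands printed cell counts of a baseline colonoscopy cohort (sex by
#' outcome class) into a subject-level `data.frame`. The default counts
#' reproduce the composition of the 1,880-subject analysis set of a
#' population-based Chinese CRC screening trial: 203 advanced neoplasms,
#' 464 non-advanced adenomas and 1,213 controls, 51.3% male. Useful for
#' yield calculations that depend only on the outcome composition.
#'
#' @param counts matrix (2 x 3) of subject counts with rownames
#'   `male`/`female` and colnames `control`/`non_advanced`/`advanced`.
#' @return A `data.frame` of class `crc_cohort` with `subject_id`,
#'   `sex`, `outcome`.
#' @export
study_composition_cohort <- function(counts = matrix(
    c(513, 306, 145,
      700, 158, 58),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("male", "female"),
                    c("control", "non_advanced", "advanced")))) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            identical(colnames(counts),
                      c("control", "non_advanced", "advanced")))
  rows <- expand.grid(sex = rownames(counts), outcome = colnames(counts),
                      stringsAsFactors = FALSE)
  sex <- rep(rows$sex, times = counts[cbind(rows$sex, rows$outcome)])
  outcome <- rep(rows$outcome, times = counts[cbind(rows$sex, rows$outcome)])
  n <- length(sex)
  structure(data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                       sex = factor(sex, levels = c("male", "female")),
                       outcome = factor(outcome,
                                        levels = c("control", "non_advanced",
                                                   "advanced")),
                       stringsAsFactors = FALSE),
            class = c("crc_cohort", "data.frame"))
}

#' Apply a stepwise sample-exclusion flow
#'
#' Walks an initial sample size through a sequence of named exclusions
#' (as in a study flow diagram) and reports the size remaining after
#' each step.
#'
#' @param n_initial subjects before any exclusion.
#' @param exclusions named integer vector; each element is removed in
#'   order.
#' @return `data.frame` with `step`, `n_excluded`, `n_remaining`; the
#'   final `n_remaining` is the analysis set size.
#' @export
#' @examples
#' flow <- sample_flow(3825, c(`no blood sample` = 94,
#'                             `ineligible DNA quality` = 1294,
#'                             `failed SNP detection` = 557))
#' tail(flow$n_remaining, 1)  # 1880
sample_flow <- function(n_initial, exclusions) {
  stopifnot(n_initial >= 0, all(exclusions >= 0),
            !is.null(names(exclusions)), all(nzchar(names(exclusions))))
  remaining <- n_initial - cumsum(as.numeric(exclusions))
  if (any(remaining < 0)) {
    stop("exclusions exceed the available sample", call. = FALSE)
  }
  data.frame(step = c("initial", names(exclusions)),
             n_excluded = c(0, as.numeric(exclusions)),
             n_remaining = c(n_initial, remaining),
             stringsAsFactors = FALSE)
}

#' Simulate a case-control study with a four-level combined exposure
#'
#' Direct generator for calibration studies of the association module:
#' subjects fall into one of four combined lifestyle-by-PRS exposure
#' cells with given prevalences, and case status follows a logistic
#' model with a log odds ratio per non-reference cell.
#'
#' @param n subjects.
#' @param cell_prev probabilities over the four cells (sum to 1), named
#'   `favorable_lower`, `favorable_higher`, `unfavorable_lower`,
#'   `unfavorable_higher`.
#' @param log_or log odds ratios for the three non-reference cells, in
#'   the same order (reference `favorable_lower` fixed at 0).
#' @param intercept baseline log-odds of being a case in the reference
#'   cell.
#' @param seed integer seed.
#' @return `data.frame` with `exposure` (factor, reference first) and
#'   `case` (0/1).
#' @export
simulate_case_control <- function(n,
                                  cell_prev = c(favorable_lower = 0.50,
                                                favorable_higher = 0.06,
                                                unfavorable_lower = 0.34,
                                                unfavorable_higher = 0.10),
                                  log_or = c(favorable_higher = 0,
                                             unfavorable_lower = 0,
                                             unfavorable_higher = 0),
                                  intercept = stats::qlogis(0.3),
                                  seed = 1L) {
  stopifnot(abs(sum(cell_prev) - 1) < 1e-9, length(cell_prev) == 4,
            length(log_or) == 3)
  local_rng(seed)
  lev <- names(cell_prev)
  exposure <- factor(sample(lev, n, replace = TRUE, prob = cell_prev),
                     levels = lev)
  eta <- intercept + c(0, log_or)[as.integer(exposure)]
  case <- as.integer(stats::runif(n) < stats::plogis(eta))
  data.frame(exposure = exposure, case = case)
}
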