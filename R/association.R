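# Odds ratios for risk profiles: crude 2x2 estimates, logistic model
# fits, and the sex-stratified contrast suite over combined
# lifestyle-by-PRS exposure categories.

#' Crude odds ratio from a 2x2 table
#'
#' OR = (a d) / (b c) with Wald 95% confidence interval
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is
#' zero, 0.5 is added to all four cells (Haldane-Anscombe continuity
#' correction) with a warning.
#'
#' @param exposed_cases,exposed_controls,unexposed_cases,unexposed_controls
#'   cell counts (a, b, c, d).
#' @return `data.frame` of class `or_result`: `estimate`, `ci_low`,
#'   `ci_high`, `log_or`, `se`, `corrected`.
#' @export
#' @examples
#' crude_or(38, 22, 166, 264)  # ~ 2.75
crude_or <- function(exposed_cases, exposed_controls,
                     unexposed_cases, unexposed_controls) {
  cells <- c(exposed_cases, exposed_controls,
             unexposed_cases, unexposed_controls)
  if (length(cells) != 4 || any(cells < 0) || any(!is.finite(cells))) {
    stop("all four cell counts must be non-negative numbers", call. = FALSE)
  }
  corrected <- any(cells == 0)
  if (corrected) {
    warning("zero cell: applying 0.5 continuity correction to all cells",
            call. = FALSE)
    cells <- cells + 0.5
  }
  log_or <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(0.975)
  structure(data.frame(estimate = exp(log_or),
                       ci_low = exp(log_or - z * se),
                       ci_high = exp(log_or + z * se),
                       log_or = log_or, se = se, corrected = corrected),
            class = c("or_result", "data.frame"))
}

#' Maximum-likelihood logistic regression fit
#'
#' Fits a binary logistic model by iteratively reweighted least squares
#' (via [stats::glm()] with a tight convergence tolerance of 1e-8 on the
#' deviance and at most 50 iterations) and returns coefficients, their
#' covariance (inverse observed information), and per-term odds ratios
#' with Wald 95% intervals.
#'
#' A coefficient diverging beyond 15 in absolute value is flagged as
#' probable complete/quasi-complete separation (warning naming the
#' term). Rank-deficient designs raise an error naming the aliased
#' columns rather than silently dropping them.
#'
#' @param design numeric covariate matrix (no intercept column;
#'   one is added).
#' @param outcome binary 0/1 vector, `length(outcome) == nrow(design)`.
#' @return List of class `logistic_fit`: `coefficients`, `vcov`,
#'   `or_table` (`data.frame` with term, estimate, se, or, ci_low,
#'   ci_high, z, p_value), `converged`, `n`.
#' @export
fit_logistic <- function(design, outcome) {
  design <- as.matrix(design)
  if (is.null(colnames(design)) && ncol(design) > 0) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  stopifnot(nrow(design) == length(outcome))
  if (!all(outcome %in% c(0, 1))) {
    stop("outcome must be binary 0/1", call. = FALSE)
  }
  if (nrow(design) <= ncol(design) + 1) {
    stop("need more observations than parameters", call. = FALSE)
  }
  df <- data.frame(.y = outcome, design, check.names = FALSE)
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 50))
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("aliasing error: rank-deficient design, aliased term(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  }
  big <- abs(beta) > 15
  if (any(big)) {
    warning("possible separation: coefficient(s) diverging for ",
            paste(names(beta)[big], collapse = ", "), call. = FALSE)
  }
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  z <- stats::qnorm(0.975)
  or_table <- data.frame(term = names(beta), estimate = unname(beta),
                         se = unname(se),
                         or = exp(unname(beta)),
                         ci_low = exp(unname(beta) - z * unname(se)),
                         ci_high = exp(unname(beta) + z * unname(se)),
                         z = unname(beta / se),
                         p_value = 2 * stats::pnorm(-abs(unname(beta / se))),
                         stringsAsFactors = FALSE)
  structure(list(coefficients = beta, vcov = V, or_table = or_table,
                 converged = fit$converged, n = length(outcome)),
            class = "logistic_fit")
}

#' Odds-ratio suite over combined lifestyle-by-PRS exposure categories
#'
#' For each sex stratum and each case-control contrast (any neoplasm,
#' non-advanced adenoma, advanced neoplasm - each vs controls), fits a
#' logistic model on the four-level combined exposure (favorable
#' lifestyle and lower PRS as reference) plus adjustment covariates, and
#' reports per-level odds ratios with Wald 95% intervals alongside the
#' case/control counts per cell. Optionally adds a lifestyle-by-PRS
#' product term as a sensitivity analysis.
#'
#' @param subjects cohort `data.frame` with `sex`, `outcome` and the
#'   adjustment columns.
#' @param lifestyle_group factor `favorable`/`unfavorable` per subject.
#' @param prs_group factor `lower`/`higher` per subject.
#' @param contrasts subset of `c("any", "non_advanced", "advanced")`.
#' @param adjust names of adjustment covariate columns; default
#'   `"age"` (continuous).
#' @param interaction if `TRUE`, fit the two main effects plus their
#'   product instead of the four-level factor, and report the product
#'   term.
#' @return `data.frame` with `sex`, `contrast`, `exposure`, `n_cases`,
#'   `n_controls`, `or`, `ci_low`, `ci_high` (reference rows carry
#'   `or = 1` and `NA` bounds; empty cells carry `NA` odds ratios and
#'   are flagged in `note`).
#' @export
run_contrast_suite <- function(subjects, lifestyle_group, prs_group,
                               contrasts = c("any", "non_advanced",
                                             "advanced"),
                               adjust = "age", interaction = FALSE) {
  stopifnot(nrow(subjects) == length(lifestyle_group),
            nrow(subjects) == length(prs_group))
  exposure <- combined_exposure(lifestyle_group, prs_group)
  out <- list()
  for (s in c("male", "female")) {
    sel_sex <- subjects$sex == s
    for (ct in contrasts) {
      y <- outcome_indicator(subjects$outcome, ct)
      keep <- sel_sex & !is.na(y)
      if (!any(keep)) next  # no subjects of this sex in the data
      rows <- fit_exposure_model(y[keep], exposure[keep],
                                 subjects[keep, adjust, drop = FALSE],
                                 interaction)
      rows$sex <- s
      rows$contrast <- ct
      out[[paste(s, ct)]] <- rows
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("sex", "contrast", "exposure", "n_cases", "n_controls",
          "or", "ci_low", "ci_high", "note")]
}

# Fit one sex-by-contrast stratum: four-level exposure (+ adjustment),
# or main effects + product term when interaction = TRUE.
fit_exposure_model <- function(y, exposure, adjust_df, interaction) {
  lev <- levels(exposure)
  counts <- table(exposure, factor(y, levels = 0:1))
  rows <- data.frame(exposure = lev,
                     n_cases = as.integer(counts[, "1"]),
                     n_controls = as.integer(counts[, "0"]),
                     or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     note = "", stringsAsFactors = FALSE)
  rows$or[1] <- 1
  rows$note[1] <- "reference"
  empty <- rows$n_cases + rows$n_controls == 0
  rows$note[empty] <- "empty cell"
  present <- lev[!empty]
  exposure <- factor(as.character(exposure), levels = present)

  if (interaction) {
    ls_un <- as.integer(grepl("^unfavorable", as.character(exposure)))
    prs_hi <- as.integer(grepl("higher$", as.character(exposure)))
    X <- cbind(unfavorable = ls_un, higher_prs = prs_hi,
               product = ls_un * prs_hi)
  } else {
    X <- stats::model.matrix(~exposure)[, -1, drop = FALSE]
    colnames(X) <- sub("^exposure", "", colnames(X))
  }
  if (ncol(adjust_df) > 0) {
    X <- cbind(X, as.matrix(data.frame(lapply(adjust_df, as.numeric))))
  }
  fit <- fit_logistic(X, y)
  tab <- fit$or_table
  if (interaction) {
    for (nm in c("unfavorable", "higher_prs", "product")) {
      r <- tab[tab$term == nm, ]
      rows <- rbind(rows,
                    data.frame(exposure = paste0("term:", nm),
                               n_cases = NA_integer_,
                               n_controls = NA_integer_,
                               or = r$or, ci_low = r$ci_low,
                               ci_high = r$ci_high, note = "model term",
                               stringsAsFactors = FALSE))
    }
  } else {
    for (l in present[-1]) {
      r <- tab[tab$term == l, ]
      if (nrow(r) == 1) {
        i <- match(l, rows$exposure)
        rows$or[i] <- r$or
        rows$ci_low[i] <- r$ci_low
        rows$ci_high[i] <- r$ci_high
      }
    }
  }
  rows
}

# Four-level combined exposure factor, reference = favorable & lower.
combined_exposure <- function(lifestyle_group, prs_group) {
  lg <- as.character(lifestyle_group)
  pg <- as.character(prs_group)
  stopifnot(all(lg %in% c("favorable", "unfavorable")),
            all(pg %in% c("lower", "higher")))
  factor(paste(lg, pg, sep = "_"),
         levels = c("favorable_lower", "favorable_higher",
                    "unfavorable_lower", "unfavorable_higher"))
}
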