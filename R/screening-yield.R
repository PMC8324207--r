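# Risk-adapted screening scenarios: triage on score groups, FIT reflex,
# and yield metrics (PPV, number of colonoscopies needed per lesion).

#' Triage rule over the four combined risk cells
#'
#' A triage rule maps each combined lifestyle-by-PRS cell to a first-line
#' screening modality: high-risk cells go straight to colonoscopy,
#' low-risk cells are offered FIT (with colonoscopy on a positive
#' result). Because the underlying risk-adapted scheme is defined on the
#' four cells, a rule is simply a truth table over them.
#'
#' Shipped presets:
#' \describe{
#'   \item{`either-high`}{high if lifestyle unfavorable or PRS higher.}
#'   \item{`both-high`}{high only if unfavorable and higher.}
#'   \item{`LS-only`}{high if lifestyle unfavorable.}
#'   \item{`PRS-only`}{high if PRS higher.}
#'   \item{`all-high`}{everyone to colonoscopy (the colonoscopy-only
#'     reference).}
#'   \item{`all-low`}{everyone to FIT.}
#' }
#'
#' @param preset a preset name, or `NULL` when `table` is given.
#' @param table named logical vector over the four cells
#'   (`favorable_lower`, `favorable_higher`, `unfavorable_lower`,
#'   `unfavorable_higher`); `TRUE` = high risk.
#' @param label scenario label; defaults to the preset name.
#' @return List of class `triage_rule` with `label` and `high` (named
#'   logical over the four cells).
#' @export
triage_rule <- function(preset = c("either-high", "both-high", "LS-only",
                                   "PRS-only", "all-high", "all-low"),
                        table = NULL, label = NULL) {
  cells <- c("favorable_lower", "favorable_higher",
             "unfavorable_lower", "unfavorable_higher")
  if (is.null(table)) {
    preset <- match.arg(preset)
    high <- switch(preset,
                   `either-high` = c(FALSE, TRUE, TRUE, TRUE),
                   `both-high` = c(FALSE, FALSE, FALSE, TRUE),
                   `LS-only` = c(FALSE, FALSE, TRUE, TRUE),
                   `PRS-only` = c(FALSE, TRUE, FALSE, TRUE),
                   `all-high` = c(TRUE, TRUE, TRUE, TRUE),
                   `all-low` = c(FALSE, FALSE, FALSE, FALSE))
    names(high) <- cells
    if (is.null(label)) label <- preset
  } else {
    if (!setequal(names(table), cells) || !is.logical(table)) {
      stop("table must be a logical vector naming all four cells",
           call. = FALSE)
    }
    high <- table[cells]
    if (is.null(label)) label <- "custom"
  }
  structure(list(label = label, high = high), class = "triage_rule")
}

#' Assign subjects to a first-line screening modality
#'
#' Deterministically maps every subject's combined lifestyle-by-PRS cell
#' through the triage rule.
#'
#' @param lifestyle_group factor `favorable`/`unfavorable`.
#' @param prs_group factor `lower`/`higher`.
#' @param rule a [triage_rule()].
#' @return Factor `colonoscopy`/`fit`, one per subject.
#' @export
triage <- function(lifestyle_group, prs_group, rule) {
  stopifnot(inherits(rule, "triage_rule"),
            length(lifestyle_group) == length(prs_group))
  if (anyNA(lifestyle_group) || anyNA(prs_group)) {
    bad <- which(is.na(lifestyle_group) | is.na(prs_group))
    stop("triage error: missing group label for subject(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (length(lifestyle_group) == 0) {
    return(factor(character(0), levels = c("colonoscopy", "fit")))
  }
  cell <- combined_exposure(lifestyle_group, prs_group)
  factor(ifelse(rule$high[as.character(cell)], "colonoscopy", "fit"),
         levels = c("colonoscopy", "fit"))
}

#' Resolve the FIT reflex into the final colonoscopy set
#'
#' High-risk subjects go to colonoscopy directly; low-risk subjects
#' undergo colonoscopy only on a positive FIT. FIT results may be given
#' as logical flags or as quantitative values in ng Hb/ml, thresholded
#' at >= 100 (boundary positive).
#'
#' @param assignment factor from [triage()].
#' @param fit_result logical positivity flags, or numeric ng Hb/ml
#'   values when `threshold` is used.
#' @param threshold positivity cutoff for numeric `fit_result`
#'   (default 100 ng Hb/ml).
#' @return Logical vector: `TRUE` where the subject undergoes
#'   colonoscopy.
#' @export
resolve_fit_reflex <- function(assignment, fit_result, threshold = 100) {
  stopifnot(length(assignment) == length(fit_result))
  if (is.numeric(fit_result)) {
    positive <- fit_result >= threshold
  } else {
    positive <- as.logical(fit_result)
  }
  in_fit_arm <- assignment == "fit"
  if (any(in_fit_arm & is.na(positive))) {
    stop("missing FIT result for subject(s) in the FIT arm", call. = FALSE)
  }
  as.logical(assignment == "colonoscopy" | (in_fit_arm & positive))
}

#' Yield and resource metrics of a screening scenario
#'
#' Positive predictive value = subjects with the lesion of interest
#' among those undergoing colonoscopy; number needed to scope (NNS) =
#' colonoscopies performed per lesion detected (the reciprocal of the
#' PPV at person level). Detection is person-level: a colonoscopy
#' detects the subject's true most-advanced lesion class.
#'
#' Full precision is kept internally; round only for display.
#'
#' @param colonoscopy logical vector, `TRUE` where colonoscopy was done.
#' @param outcome factor `control`/`non_advanced`/`advanced` per
#'   subject.
#' @param label scenario label.
#' @return One-row `data.frame` of class `yield_report`: `scenario`,
#'   `n_screened`, `n_colonoscopies`, `detected_advanced`,
#'   `detected_any`, `ppv_advanced`, `ppv_any`, `nns_advanced`,
#'   `nns_any` (`Inf` with zero detections).
#' @export
evaluate_yield <- function(colonoscopy, outcome, label = "scenario") {
  stopifnot(length(colonoscopy) == length(outcome))
  outcome <- factor(as.character(outcome),
                    levels = c("control", "non_advanced", "advanced"))
  if (any(colonoscopy & is.na(outcome))) {
    stop("outcome unknown for colonoscoped subject(s)", call. = FALSE)
  }
  n_col <- sum(colonoscopy)
  if (n_col == 0) {
    stop("undefined yield: no colonoscopies performed", call. = FALSE)
  }
  det_adv <- sum(colonoscopy & outcome == "advanced")
  det_any <- sum(colonoscopy & outcome != "control")
  structure(data.frame(scenario = label,
                       n_screened = length(colonoscopy),
                       n_colonoscopies = n_col,
                       detected_advanced = det_adv,
                       detected_any = det_any,
                       ppv_advanced = det_adv / n_col,
                       ppv_any = det_any / n_col,
                       nns_advanced = if (det_adv > 0) n_col / det_adv
                                      else Inf,
                       nns_any = if (det_any > 0) n_col / det_any else Inf,
                       stringsAsFactors = FALSE),
            class = c("yield_report", "data.frame"))
}

#' Compare screening scenarios on one cohort
#'
#' Evaluates a list of triage rules on the same cohort, resolving the
#' FIT reflex for each, and stacks the yield reports. The
#' colonoscopy-only approach (`all-high`) is always included first as
#' the reference.
#'
#' @param subjects cohort with `outcome` and a FIT result column
#'   (`fit_positive` flags or `fit_value` ng Hb/ml).
#' @param lifestyle_group,prs_group score group labels per subject.
#' @param rules list of [triage_rule()]s (labels must be unique).
#' @param fit_threshold positivity cutoff when `fit_value` is used.
#' @return `data.frame` of stacked [evaluate_yield()] rows.
#' @export
compare_scenarios <- function(subjects, lifestyle_group, prs_group,
                              rules = list(triage_rule("either-high"),
                                           triage_rule("both-high")),
                              fit_threshold = 100) {
  labels <- vapply(rules, `[[`, character(1), "label")
  if (anyDuplicated(c("colonoscopy-only", labels))) {
    stop("duplicate scenario labels", call. = FALSE)
  }
  fit_result <- if (!is.null(subjects$fit_value)) {
    subjects$fit_value
  } else subjects$fit_positive
  all_rules <- c(list(triage_rule("all-high", label = "colonoscopy-only")),
                 rules)
  reports <- lapply(all_rules, function(rule) {
    assignment <- triage(lifestyle_group, prs_group, rule)
    scoped <- resolve_fit_reflex(assignment, fit_result, fit_threshold)
    evaluate_yield(scoped, subjects$outcome, label = rule$label)
  })
  out <- do.call(rbind, reports)
  rownames(out) <- NULL
  out
}

#' Display formatting for a yield report
#'
#' @param x a `yield_report`.
#' @param ... unused.
#' @export
#' @method print yield_report
print.yield_report <- function(x, ...) {
  y <- as.data.frame(x)
  y$ppv_advanced <- sprintf("%.1f%%", 100 * y$ppv_advanced)
  y$ppv_any <- sprintf("%.1f%%", 100 * y$ppv_any)
  y$nns_advanced <- ifelse(is.finite(y$nns_advanced),
                           sprintf("%.1f", y$nns_advanced), "Inf")
  y$nns_any <- ifelse(is.finite(y$nns_any),
                      sprintf("%.1f", y$nns_any), "Inf")
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
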