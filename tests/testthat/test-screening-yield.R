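# Risk-adapted screening: triage truth tables, FIT reflex, yield
# metrics and scenario comparison.

make_groups <- function(n_per_cell = 1) {
  cells <- expand.grid(lg = c("favorable", "unfavorable"),
                       pg = c("lower", "higher"),
                       stringsAsFactors = FALSE)
  cells <- cells[rep(seq_len(4), each = n_per_cell), ]
  list(lg = factor(cells$lg, levels = c("favorable", "unfavorable")),
       pg = factor(cells$pg, levels = c("lower", "higher")))
}

test_that("triage presets implement their truth tables", {
  g <- make_groups()
  combos <- paste(g$lg, g$pg, sep = "_")
  assign_of <- function(preset) {
    as.character(triage(g$lg, g$pg, triage_rule(preset)))
  }
  expect_equal(assign_of("all-high"), rep("colonoscopy", 4))
  expect_equal(assign_of("all-low"), rep("fit", 4))
  # both-high sends exactly the unfavorable & higher cell to colonoscopy
  bh <- assign_of("both-high")
  expect_equal(bh[combos == "unfavorable_higher"], "colonoscopy")
  expect_equal(sum(bh == "colonoscopy"), 1)
  # either-high spares only the favorable & lower cell
  eh <- assign_of("either-high")
  expect_equal(sum(eh == "fit"), 1)
  expect_equal(eh[combos == "favorable_lower"], "fit")
  expect_equal(assign_of("LS-only"),
               ifelse(grepl("^unfavorable", combos), "colonoscopy", "fit"))
  expect_equal(assign_of("PRS-only"),
               ifelse(grepl("higher$", combos), "colonoscopy", "fit"))
})

test_that("custom rules and degenerate inputs are handled", {
  tab <- c(favorable_lower = FALSE, favorable_higher = TRUE,
           unfavorable_lower = FALSE, unfavorable_higher = TRUE)
  rule <- triage_rule(table = tab, label = "custom-prs")
  g <- make_groups()
  expect_equal(sum(triage(g$lg, g$pg, rule) == "colonoscopy"), 2)
  # empty cohort: empty assignment
  empty <- triage(factor(character(0), levels = c("favorable",
                                                  "unfavorable")),
                  factor(character(0), levels = c("lower", "higher")),
                  rule)
  expect_length(empty, 0)
  # missing group label names the subject
  lg <- factor(c("favorable", NA), levels = c("favorable", "unfavorable"))
  pg <- factor(c("lower", "lower"), levels = c("lower", "higher"))
  expect_error(triage(lg, pg, rule), "missing group")
})

test_that("FIT reflex unions the high arm with FIT positives", {
  assignment <- factor(c("colonoscopy", "fit", "fit", "fit"),
                       levels = c("colonoscopy", "fit"))
  # all FIT negative: colonoscopy set = high arm only
  expect_equal(resolve_fit_reflex(assignment, c(NA, FALSE, FALSE, FALSE)),
               c(TRUE, FALSE, FALSE, FALSE))
  # all FIT positive: full cohort
  expect_equal(resolve_fit_reflex(assignment, c(TRUE, TRUE, TRUE, TRUE)),
               rep(TRUE, 4))
  # quantitative threshold: 100 ng Hb/ml is positive (boundary included)
  expect_equal(resolve_fit_reflex(assignment, c(0, 100, 99.9, 250)),
               c(TRUE, TRUE, FALSE, TRUE))
  # missing FIT result in the FIT arm is an error
  expect_error(resolve_fit_reflex(assignment, c(TRUE, NA, TRUE, TRUE)),
               "missing FIT")
})

test_that("yield metrics reproduce the printed colonoscopy-only figures", {
  fix <- study_composition_cohort()
  y <- evaluate_yield(rep(TRUE, nrow(fix)), fix$outcome,
                      label = "colonoscopy-only")
  expect_equal(y$n_colonoscopies, 1880)
  expect_equal(round(100 * y$ppv_advanced, 1), 10.8)
  expect_equal(round(y$nns_advanced, 1), 9.3)
  expect_equal(round(y$nns_any, 1), 2.8)
})

test_that("yield report invariants hold", {
  fix <- study_composition_cohort()
  scoped <- rep(c(TRUE, FALSE), length.out = nrow(fix))
  y <- evaluate_yield(scoped, fix$outcome)
  # NNS * PPV = 1 exactly at full precision
  expect_equal(y$nns_advanced * y$ppv_advanced, 1, tolerance = 1e-12)
  expect_equal(y$nns_any * y$ppv_any, 1, tolerance = 1e-12)
  expect_lte(y$detected_advanced, y$n_colonoscopies)
  # invariant to subject ordering
  perm <- sample(nrow(fix))
  y2 <- evaluate_yield(scoped[perm], fix$outcome[perm])
  expect_equal(y2$ppv_advanced, y$ppv_advanced)
  # all-control colonoscopies: zero PPV, infinite NNS
  y0 <- evaluate_yield(fix$outcome == "control", fix$outcome)
  expect_equal(y0$ppv_advanced, 0)
  expect_true(is.infinite(y0$nns_advanced))
  # no colonoscopy at all is undefined
  expect_error(evaluate_yield(rep(FALSE, 10),
                              factor(rep("control", 10),
                                     levels = c("control", "non_advanced",
                                                "advanced"))),
               "undefined")
})

test_that("scenario comparison enriches PPV when risk groups enrich", {
  # cohort where the unfavorable/higher cells carry more disease
  cfg <- cohort_config(
    8000, seed = 23,
    outcome_model = list(intercept_any = stats::qlogis(0.25),
                         beta_any = c(waist = 0.7, red_meat = 0.4,
                                      low_fruit = 0.4, smoking = 0.5),
                         intercept_advanced = stats::qlogis(0.3),
                         beta_advanced = numeric(0)))
  s <- simulate_subjects(cfg, tiny_panel())
  w <- fit_lifestyle_weights(s)
  ls <- lifestyle_score(s, w$male, w$female)
  prs <- polygenic_score(as.matrix(s[, c("rs1", "rs2", "rs3")]),
                         tiny_panel())
  lg <- categorize(ls, "sex_median", sex = s$sex)
  pg <- categorize(unname(prs), "percentile_90")
  out <- compare_scenarios(s, lg, pg,
                           rules = list(triage_rule("either-high"),
                                        triage_rule("LS-only")))
  ref <- out[out$scenario == "colonoscopy-only", ]
  expect_equal(ref$n_colonoscopies, nrow(s))
  # partition conservation: every scenario scopes at most everyone
  expect_true(all(out$n_colonoscopies <= out$n_screened))
  # risk-enriched triage raises the advanced-neoplasm PPV over reference
  expect_gt(out$ppv_advanced[out$scenario == "LS-only"], ref$ppv_advanced)
  # an all-high triage reproduces the reference exactly
  same <- compare_scenarios(s, lg, pg,
                            rules = list(triage_rule("all-high",
                                                     label = "everyone")))
  expect_equal(same$ppv_advanced[2], ref$ppv_advanced)
  expect_equal(same$n_colonoscopies[2], ref$n_colonoscopies)
})

test_that("final colonoscopy count equals high arm plus FIT positives", {
  cfg <- cohort_config(3000, seed = 29)
  s <- simulate_subjects(cfg, tiny_panel())
  prs <- unname(polygenic_score(as.matrix(s[, c("rs1", "rs2", "rs3")]),
                                tiny_panel()))
  w <- fit_lifestyle_weights(s)
  lg <- categorize(lifestyle_score(s, w$male, w$female), "sex_median",
                   sex = s$sex)
  pg <- categorize(prs, "percentile_90")
  rule <- triage_rule("either-high")
  assignment <- triage(lg, pg, rule)
  scoped <- resolve_fit_reflex(assignment, s$fit_positive)
  expect_equal(sum(assignment == "colonoscopy") + sum(assignment == "fit"),
               nrow(s))
  expect_equal(sum(scoped),
               sum(assignment == "colonoscopy") +
                 sum(s$fit_positive[assignment == "fit"]))
})

test_that("duplicate scenario labels are rejected", {
  fix <- study_composition_cohort()
  fix$fit_positive <- FALSE
  lg <- factor(rep("favorable", nrow(fix)),
               levels = c("favorable", "unfavorable"))
  pg <- factor(rep("lower", nrow(fix)), levels = c("lower", "higher"))
  expect_error(compare_scenarios(fix, lg, pg,
                                 rules = list(triage_rule("both-high"),
                                              triage_rule("both-high"))),
               "duplicate")
})
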