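# Odds-ratio estimation: crude 2x2, logistic fits, contrast suite.

test_that("crude odds ratios match direct computation on printed counts", {
  expect_equal(crude_or(10, 10, 10, 10)$estimate, 1)
  # combined-exposure cells of the male any-neoplasm contrast
  expect_equal(crude_or(38, 22, 166, 264)$estimate, (38 * 264) / (22 * 166))
  expect_equal(round(crude_or(38, 22, 166, 264)$estimate, 2), 2.75)
  # female non-advanced contrast
  expect_equal(crude_or(17, 27, 40, 270)$estimate, 4.25)
  # Wald interval brackets the estimate
  r <- crude_or(38, 22, 166, 264)
  expect_lt(r$ci_low, r$estimate)
  expect_gt(r$ci_high, r$estimate)
})

test_that("zero cells trigger the 0.5 continuity correction", {
  expect_warning(r <- crude_or(0, 10, 10, 10), "continuity")
  expect_true(r$corrected)
  expect_equal(r$estimate, (0.5 * 10.5) / (10.5 * 10.5))
})

test_that("swapping case/control labels inverts the odds ratio exactly", {
  r <- crude_or(38, 22, 166, 264)
  inv <- crude_or(22, 38, 264, 166)
  expect_equal(inv$estimate, 1 / r$estimate)
  expect_equal(inv$se, r$se)
})

test_that("crude OR equals the exponentiated logistic coefficient", {
  # single binary covariate, no zero cells
  set.seed(4)
  x <- rbinom(600, 1, 0.4)
  y <- rbinom(600, 1, stats::plogis(-0.5 + 0.8 * x))
  tab <- table(x, y)
  cr <- crude_or(tab["1", "1"], tab["1", "0"], tab["0", "1"], tab["0", "0"])
  fit <- fit_logistic(cbind(x = x), y)
  expect_equal(cr$estimate, exp(fit$coefficients[["x"]]),
               tolerance = 1e-6)
  expect_equal(cr$se, fit$or_table$se[fit$or_table$term == "x"],
               tolerance = 1e-4)
})

test_that("intercept-only logistic fit returns logit of the prevalence", {
  y <- c(rep(1, 30), rep(0, 70))
  fit <- fit_logistic(matrix(numeric(0), nrow = 100, ncol = 0), y)
  expect_equal(unname(fit$coefficients[1]), stats::qlogis(0.3),
               tolerance = 1e-7)
})

test_that("fit_logistic flags separation and aliasing", {
  x <- c(rep(0, 50), rep(1, 50))
  y <- x  # complete separation
  expect_warning(fit_logistic(cbind(x = x), y), "separation")
  x2 <- cbind(a = x, b = x)  # aliased copy
  y2 <- rbinom(100, 1, 0.5)
  expect_error(fit_logistic(x2, y2), "alias")
  expect_error(fit_logistic(cbind(x = x), c(y[-1], 2)), "binary")
})

test_that("Wald CI width shrinks as 1/sqrt(n) on replicated data", {
  base_x <- rep(c(0, 1), each = 50)
  base_y <- rep(c(0, 1, 0, 1), c(35, 15, 20, 30))
  widths <- vapply(c(1, 4, 16), function(k) {
    fit <- fit_logistic(cbind(x = rep(base_x, k)), rep(base_y, k))
    r <- fit$or_table[fit$or_table$term == "x", ]
    log(r$ci_high) - log(r$ci_low)
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 1e-6)
  expect_equal(widths[2] / widths[3], 2, tolerance = 1e-6)
})

test_that("null covariates are calibrated (|z| < 3 almost always)", {
  hits <- vapply(1:150, function(i) {
    set.seed(3000 + i)
    x <- rbinom(4000, 1, 0.5)
    y <- rbinom(4000, 1, 0.35)
    fit <- fit_logistic(cbind(x = x), y)
    abs(fit$or_table$z[fit$or_table$term == "x"]) < 3
  }, logical(1))
  expect_gte(mean(hits), 0.985)
})

test_that("contrast suite reproduces cell counts and reference level", {
  d <- simulate_case_control(4000, log_or = c(favorable_higher = log(2),
                                              unfavorable_lower = log(1.7),
                                              unfavorable_higher = log(3)),
                             seed = 12)
  subjects <- data.frame(sex = factor(rep("male", nrow(d)),
                                      levels = c("male", "female")),
                         age = 60,
                         outcome = factor(ifelse(d$case == 1,
                                                 "advanced", "control"),
                                          levels = c("control",
                                                     "non_advanced",
                                                     "advanced")))
  lg <- factor(ifelse(grepl("^unfavorable", d$exposure),
                      "unfavorable", "favorable"),
               levels = c("favorable", "unfavorable"))
  pg <- factor(ifelse(grepl("higher$", d$exposure), "higher", "lower"),
               levels = c("lower", "higher"))
  suite <- run_contrast_suite(subjects, lg, pg, contrasts = "advanced",
                              adjust = character(0))
  male <- suite[suite$sex == "male", ]
  expect_equal(male$or[male$exposure == "favorable_lower"], 1)
  expect_equal(male$note[male$exposure == "favorable_lower"], "reference")
  expect_equal(sum(male$n_cases), sum(d$case))
  expect_equal(sum(male$n_cases + male$n_controls), nrow(d))
  # injected effects are recovered within the Wald interval
  row3 <- male[male$exposure == "unfavorable_higher", ]
  expect_gt(row3$ci_high, 3)
  expect_lt(row3$ci_low, 3 * 1.7)  # loose sanity bound on the low side
})

test_that("interaction mode reports main effects and product term", {
  d <- simulate_case_control(6000, log_or = c(favorable_higher = 0.4,
                                              unfavorable_lower = 0.5,
                                              unfavorable_higher = 0.9),
                             seed = 14)
  subjects <- data.frame(sex = factor(rep("female", nrow(d)),
                                      levels = c("male", "female")),
                         age = 60,
                         outcome = factor(ifelse(d$case == 1, "advanced",
                                                 "control"),
                                          levels = c("control",
                                                     "non_advanced",
                                                     "advanced")))
  lg <- ifelse(grepl("^unfavorable", d$exposure), "unfavorable", "favorable")
  pg <- ifelse(grepl("higher$", d$exposure), "higher", "lower")
  suite <- run_contrast_suite(subjects, lg, pg, contrasts = "advanced",
                              adjust = character(0), interaction = TRUE)
  fem <- suite[suite$sex == "female", ]
  terms <- fem[grepl("^term:", fem$exposure), ]
  expect_setequal(terms$exposure,
                  c("term:unfavorable", "term:higher_prs", "term:product"))
  # data were generated additively on the log-odds scale (0.4 + 0.5 = 0.9),
  # so the product term's CI should cover 1
  prod_row <- terms[terms$exposure == "term:product", ]
  expect_lt(prod_row$ci_low, 1)
  expect_gt(prod_row$ci_high, 1)
})

test_that("empty exposure cells are flagged and the suite still runs", {
  subjects <- data.frame(sex = factor(rep("male", 200),
                                      levels = c("male", "female")),
                         age = 55,
                         outcome = factor(rep(c("control", "advanced"), 100),
                                          levels = c("control",
                                                     "non_advanced",
                                                     "advanced")))
  lg <- rep("favorable", 200)
  pg <- rep(c("lower", "higher"), each = 100)
  suite <- run_contrast_suite(subjects, lg, pg, contrasts = "advanced",
                              adjust = character(0))
  male <- suite[suite$sex == "male", ]
  empty <- male[male$exposure == "unfavorable_higher", ]
  expect_equal(empty$note, "empty cell")
  expect_true(is.na(empty$or))
})
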