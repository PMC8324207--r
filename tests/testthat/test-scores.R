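# Score construction: HWE testing and filtering, lifestyle
# dichotomization, weighted sums, categorization schemes.

test_that("HWE chi-square matches hand-computed values", {
  h0 <- test_hwe(25, 50, 25)
  expect_equal(h0$chi_square, 0)
  expect_equal(h0$p_value, 1)

  h1 <- test_hwe(30, 40, 30)  # p-hat 0.5, expected (25, 50, 25)
  expect_equal(h1$chi_square, 4.0)
  expect_equal(h1$p_value, 0.0455, tolerance = 1e-3)

  # vector form agrees with the three-argument form
  expect_identical(test_hwe(c(30, 40, 30)), h1)
})

test_that("monomorphic SNPs signal degeneracy instead of a p-value", {
  h <- test_hwe(0, 0, 100)
  expect_true(h$degenerate)
  expect_true(is.na(h$p_value))
  expect_error(test_hwe(0, 0, 0), "positive")
  expect_error(test_hwe(-1, 5, 5), "non-negative")
})

test_that("filter_snps removes HWE failures and reports them", {
  panel <- default_snp_panel(n_snps = 24, n_hwe_fail = 5)
  g <- hwe_pattern_genotypes(panel, 2000)
  res <- filter_snps(panel, g, alpha = 0.05)
  expect_equal(nrow(res$panel), 19)
  expect_equal(sum(res$report$excluded), 5)
  expect_setequal(res$report$snp_id[res$report$excluded],
                  panel$snp_id[panel$inbreeding_f > 0])

  # alpha = 0 excludes nothing
  res0 <- filter_snps(panel, g, alpha = 0)
  expect_equal(nrow(res0$panel), 24)

  # monomorphic column is excluded with reason
  g2 <- g
  g2[, 1] <- 2L
  expect_message(res2 <- filter_snps(panel, g2, alpha = 0.05),
                 "monomorphic")
  expect_true(res2$report$excluded[1])
  expect_equal(res2$report$reason[1], "monomorphic")
})

test_that("null HWE exclusions occur near the nominal alpha rate", {
  # with all SNPs at HWE, expected exclusions per 24-SNP panel is 24 * alpha;
  # average over 200 seeded panels and allow a ~3 SD binomial band
  alpha <- 0.05
  n_panels <- 200
  panel <- default_snp_panel(n_snps = 24, n_hwe_fail = 0)
  excl <- vapply(seq_len(n_panels), function(i) {
    g <- simulate_genotypes(panel, 800, seed = 1000 + i)
    sum(filter_snps(panel, g, alpha = alpha)$report$excluded)
  }, numeric(1))
  rate <- mean(excl) / 24
  band <- 3 * sqrt(alpha * (1 - alpha) / (24 * n_panels))
  expect_gt(rate, alpha - band)
  expect_lt(rate, alpha + band)
})

test_that("lifestyle dichotomization is sex-specific with >= 15 pack-years", {
  subjects <- data.frame(
    sex = c("male", "male", "male", "female", "female"),
    waist = c(1, 0, 0, 1, 0),
    red_meat = c(1, 0, 1, 0, 0),
    low_fruit = c(0, 0, 1, 1, 0),
    pack_years = c(15, 14.9, 30, 20, 0))
  ind <- dichotomize_lifestyle(subjects)
  expect_equal(ind$smoking[1], 1L)  # boundary 15 included
  expect_equal(ind$smoking[2], 0L)
  expect_true(all(is.na(ind$smoking[4:5])))  # no smoking term for women
  # all-favorable man scores zero on every indicator
  expect_equal(unlist(ind[2, ]), c(waist = 0L, red_meat = 0L,
                                   low_fruit = 0L, smoking = 0L))
  expect_error(dichotomize_lifestyle(subjects[, -2]),
               "missing covariate.*waist")
})

test_that("weighted_score is the named, aligned sum of beta * x", {
  w <- weight_vector(c("a", "b", "c", "d"), c(0.3, 0.2, 0.1, 0.4))
  expect_equal(weighted_score(c(a = 1, b = 0, c = 1, d = 1), w), 0.8)
  expect_equal(weighted_score(c(a = 0, b = 0, c = 0, d = 0), w), 0)
  # bilinearity: doubled dosages with halved weights gives the same score
  w2 <- weight_vector(c("a", "b", "c", "d"), c(0.3, 0.2, 0.1, 0.4) / 2)
  x <- c(a = 2, b = 1, c = 0, d = 2)
  expect_equal(weighted_score(2 * x, w2), weighted_score(x, w))
  # alignment is by name, not position
  expect_equal(weighted_score(c(d = 1, a = 1, c = 1, b = 0), w), 0.8)
  expect_error(weighted_score(c(a = 1, b = 2), w), "alignment")
  expect_error(weighted_score(c(a = 1, b = NA, c = 0, d = 0), w), "missing")
})

test_that("PRS is invariant to SNP column order and drops missing", {
  panel <- tiny_panel()
  g <- simulate_genotypes(panel, 100, seed = 2)
  s1 <- polygenic_score(g, panel)
  s2 <- polygenic_score(g[, c(3, 1, 2)], panel)
  expect_equal(s1, s2)
  g[5, 2] <- NA
  s3 <- polygenic_score(g, panel)
  expect_true(is.na(s3[5]))
  expect_equal(attr(s3, "n_dropped"), 1)
})

test_that("filtering then scoring equals scoring the pre-filtered panel", {
  panel <- default_snp_panel(n_snps = 10, n_hwe_fail = 3)
  g <- hwe_pattern_genotypes(panel, 1000)
  res <- filter_snps(panel, g, alpha = 0.05)
  via_filter <- polygenic_score(g, res$panel)
  pre_filtered <- panel[panel$inbreeding_f == 0, ]
  class(pre_filtered) <- c("snp_panel", "data.frame")
  direct <- polygenic_score(g, pre_filtered)
  expect_equal(via_filter, direct)
})

test_that("categorize implements the three schemes with ties upward", {
  # 90th percentile by linear interpolation of 1..10 is 9.1: one subject
  sc <- 1:10
  g <- categorize(sc, "percentile_90")
  expect_equal(sum(g == "higher"), 1)
  expect_equal(unname(attr(g, "cutpoints")["p90"]), 9.1)

  # symmetric scores around the median: ties go to unfavorable
  scores <- c(1, 2, 2, 3)
  sex <- rep("male", 4)
  gm <- categorize(scores, "sex_median", sex = sex)
  expect_equal(as.character(gm), c("favorable", "unfavorable",
                                   "unfavorable", "unfavorable"))

  # sex-specific cutpoints differ between strata
  sc2 <- c(1, 2, 3, 4, 10, 20, 30, 40)
  sex2 <- rep(c("male", "female"), each = 4)
  gs <- categorize(sc2, "sex_median", sex = sex2)
  expect_equal(sum(gs == "unfavorable"), 4)

  # top tertile
  gt <- categorize(1:9, "tertile_top")
  expect_equal(sum(gt == "higher"), 3)

  # group sizes conserved; percentile_90 assigns at most 10% plus ties
  expect_equal(length(g), 10)
  expect_lte(sum(categorize(rnorm(1000), "percentile_90") == "higher"), 101)

  expect_error(categorize(rep(1, 5), "percentile_90"), "degenerate")
  expect_error(categorize(1:4, "sex_median"), "sex")
})

test_that("lifestyle weights are recovered from a simulated cohort", {
  cfg <- cohort_config(
    30000, seed = 5,
    outcome_model = list(intercept_any = stats::qlogis(0.25),
                         beta_any = c(waist = 0.5, red_meat = 0.3,
                                      low_fruit = 0.2, smoking = 0.4),
                         intercept_advanced = stats::qlogis(0.3),
                         beta_advanced = numeric(0)))
  s <- simulate_subjects(cfg)
  w <- fit_lifestyle_weights(s, contrast = "any")
  expect_equal(unname(unclass(w$male)[c("waist", "red_meat",
                                        "low_fruit", "smoking")]),
               c(0.5, 0.3, 0.2, 0.4), tolerance = 0.25)
  expect_length(w$female, 3)
  ls <- lifestyle_score(s, w$male, w$female)
  expect_length(ls, nrow(s))
  expect_true(all(is.finite(ls)))
})

test_that("univariate factor screening flags associated factors", {
  cfg <- cohort_config(
    20000, seed = 6,
    outcome_model = list(intercept_any = stats::qlogis(0.3),
                         beta_any = c(waist = 0.6),
                         intercept_advanced = stats::qlogis(0.3),
                         beta_advanced = numeric(0)))
  s <- simulate_subjects(cfg)
  scr <- screen_lifestyle_factors(s, c("waist", "red_meat", "low_fruit"))
  expect_true(scr$selected[scr$factor == "waist"])
  expect_equal(scr$log_or[scr$factor == "waist"], 0.6, tolerance = 0.2)
})
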