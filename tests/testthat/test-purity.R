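# Purity regression, outlier handling, fat adjustment, CI-overlap verdicts,
# grade and subtype contrasts, sample selection.

test_that("archetype criteria classify the documented example compositions", {
  cohort <- generate_cohort(seed = 1)[1:3, ]
  set_comp <- function(row, ...) {
    vals <- list(...)
    for (cl in TISSUE_CLASSES) row[[cl]] <- 0
    for (nm in names(vals)) row[[nm]] <- vals[[nm]]
    row
  }
  c1 <- set_comp(cohort[1, ], cancer = 45, fat = 5,
                 intratumoral_fibrosis = 50)
  expect_true(select_samples(c1, archetype_criteria()$C))
  c2 <- set_comp(cohort[1, ], intratumoral_fibrosis = 85, cancer = 10,
                 extratumoral_connective = 5)
  expect_true(select_samples(c2, archetype_criteria()$IF))
  # cancer 30 + fibrosis 45 = 75 <= 80: excluded from the regression subset
  c3 <- set_comp(cohort[1, ], cancer = 30, intratumoral_fibrosis = 45,
                 fat = 25)
  expect_false(select_samples(c3, "regression"))
  c4 <- set_comp(cohort[1, ], cancer = 40, intratumoral_fibrosis = 45,
                 fat = 15)
  expect_true(select_samples(c4, "regression"))
  expect_error(selection_criteria(bogus_min = 10), "unknown tissue class")
})

test_that("an exactly collinear purity relation is recovered exactly", {
  fit <- fit_purity_regression(c(2, 4, 6, 3, 5), c(0, 50, 100, 25, 75),
                               at = c(0, 60, 100))
  expect_equal(fit$slope, 0.04)
  expect_equal(fit$intercept, 2)
  expect_equal(fit$pearson_r, 1)
  expect_equal(fit$predictions$estimate, c(2, 4.4, 6))
  expect_true(all(fit$predictions$ci_lo <= fit$predictions$estimate &
                    fit$predictions$estimate <= fit$predictions$ci_hi))
  expect_equal(fit$purity_range, c(0, 100))
  expect_error(fit_purity_regression(1:5, rep(50, 5)), "constant")
  expect_error(fit_purity_regression(1:4, c(1, 2, 3, 4)), "at least 5")
})

test_that("purity-independent levels rarely show spurious correlation", {
  set.seed(20)
  rs <- replicate(200, {
    fit_purity_regression(rnorm(39, 3), runif(39, 5, 75))$pearson_r
  })
  # |r| < 0.32 corresponds to the 95% null band at n = 39
  expect_gte(mean(abs(rs) < 0.32), 0.93)
})

test_that("outliers are excluded only when both diagnostics are extreme", {
  set.seed(21)
  pur <- runif(39, 5, 75)
  lv <- 2 + 0.04 * pur + rnorm(39, sd = 0.1)
  clean <- flag_outliers(fit_purity_regression(lv, pur))
  expect_equal(nrow(clean$excluded_points), 0)
  # plant a gross outlier at high purity (high leverage + huge residual)
  lv2 <- lv; lv2[which.max(pur)] <- lv2[which.max(pur)] + 10 * 0.1 * 10
  fit2 <- fit_purity_regression(lv2, pur)
  expect_message(flagged <- flag_outliers(fit2), "excluded")
  expect_equal(nrow(flagged$excluded_points), 1)
  expect_equal(flagged$n, 38)
  # the refit slope is closer to the truth than the contaminated one
  expect_lt(abs(flagged$slope - 0.04), abs(fit2$slope - 0.04))
  # diagnostics like the documented excluded point (4.5, 2.6) are flagged
  expect_true(with(flagged$excluded_points,
                   abs(std_residual) > 3 & cooks_d > 1))
})

test_that("fat adjustment projects reference levels to zero fat", {
  # two-compartment (connective + fat) synthetic mixtures
  set.seed(22)
  s_conn <- 3; s_fat <- 0.5
  fat_cal <- runif(40, 20, 95)
  lv_cal <- (s_conn * (100 - fat_cal) + s_fat * fat_cal) / 100 +
    rnorm(40, sd = 0.05)
  fat_ref <- runif(10, 5, 40)
  lv_ref <- (s_conn * (100 - fat_ref) + s_fat * fat_ref) / 100 +
    rnorm(10, sd = 0.05)
  adj <- adjust_for_fat(lv_ref, fat_ref, lv_cal, fat_cal)
  se <- 2 * sd(adj) / sqrt(length(adj))
  expect_lt(abs(mean(adj) - s_conn), max(2 * se, 0.1))
  # zero fat means no change; zero slope means identity
  expect_equal(as.numeric(adjust_for_fat(lv_ref, rep(0, 10), lv_cal, fat_cal)),
               lv_ref)
  flat <- adjust_for_fat(lv_ref, fat_ref, rep(1, 40), fat_cal)
  expect_equal(as.numeric(flat), lv_ref, tolerance = 1e-12)
  expect_warning(adjust_for_fat(lv_ref, fat_ref, lv_cal[1:5],
                                rep(30, 5) + runif(5)),
                 "extrapolation unstable")
})

test_that("compartment verdicts follow the two-level CI overlap rule", {
  set.seed(23)
  pur <- runif(30, 5, 70)
  # stroma level 5 vs reference near 1: clearly significant
  fit <- fit_purity_regression(5 + 0.02 * pur + rnorm(30, sd = 0.2), pur)
  cmp <- compare_compartments(fit, rnorm(10, 1, 0.1))
  expect_equal(cmp$verdict, "significant")
  # identical distributions: almost always ns
  verdicts <- replicate(40, {
    p <- runif(30, 5, 70)
    f <- fit_purity_regression(2 + rnorm(30, sd = 0.3), p)
    compare_compartments(f, rnorm(10, 2, 0.3))$verdict
  })
  expect_gte(mean(verdicts == "ns"), 0.9)
  expect_error(compare_compartments(fit, c(1, 2)), "at least 3")
})

test_that("a trend verdict arises when only the 90% intervals separate", {
  # search a grid of reference means for a case where the 95% CIs overlap
  # but the 90% CIs do not; the verdict there must be "trend"
  set.seed(24)
  pur <- runif(30, 5, 70)
  fit <- fit_purity_regression(2 + 0.02 * pur + rnorm(30, sd = 0.3), pur)
  found <- FALSE
  for (delta in seq(0.2, 1.5, by = 0.005)) {
    ref <- 2 + delta + rnorm(10, 0, 0.25) - mean(rnorm(10, 0, 0.25))
    cmp <- compare_compartments(fit, ref)
    if (cmp$verdict == "trend") { found <- TRUE; break }
  }
  expect_true(found)
  # monotonicity: significant at 95% implies disjoint at 90% too
  cmp_sig <- compare_compartments(fit, rnorm(10, 20, 0.1))
  expect_equal(cmp_sig$verdict, "significant")
})

test_that("grade contrasts at 60% purity detect modifier effects", {
  set.seed(25)
  gen <- function(n, factor) {
    pur <- runif(n, 10, 75)
    lv <- (2 + 0.04 * pur * factor) * exp(rnorm(n, 0, 0.05))
    fit_purity_regression(lv, pur)
  }
  # modifier 1.5: significant in most replicates
  hits <- replicate(25, {
    grade_contrast(gen(25, 1), gen(25, 1.5))$verdict
  })
  expect_gte(mean(hits == "significant"), 0.8)
  # no effect: mostly ns
  nulls <- replicate(25, grade_contrast(gen(25, 1), gen(25, 1))$verdict)
  expect_gte(mean(nulls == "ns"), 0.8)
  # identical fits: exactly ns
  f <- gen(25, 1)
  expect_equal(grade_contrast(f, f)$verdict, "ns")
  # insufficient group size
  small <- list(n = 3)
  expect_equal(grade_contrast(small, f)$verdict, "insufficient")
})

test_that("homogeneity of slopes is a calibrated interaction F test", {
  set.seed(26)
  # equal slopes: duplicated data gives the p = 1 boundary
  pur <- runif(20, 5, 75)
  lv <- 2 + 0.04 * pur + rnorm(20, sd = 0.2)
  hs <- homogeneity_of_slopes(c(lv, lv), c(pur, pur), rep(c("a", "b"), each = 20))
  expect_gte(hs$p_value, 1 - 1e-9)
  # distinct slopes are detected with good power
  hits <- replicate(30, {
    p1 <- runif(20, 5, 75); p2 <- runif(20, 5, 75)
    l1 <- 2 + 0 * p1 + rnorm(20, sd = 0.15)
    l2 <- 2 + 0.04 * p2 + rnorm(20, sd = 0.15)
    homogeneity_of_slopes(c(l1, l2), c(p1, p2),
                          rep(c("a", "b"), each = 20))$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)
  expect_error(homogeneity_of_slopes(lv, pur, rep("a", 20)), "two groups")
  expect_error(homogeneity_of_slopes(lv, pur,
                                     c(rep("a", 17), rep("b", 3))),
               "at least 5")
})

test_that("PEG contamination flags gross outliers of the PEG region", {
  peg <- c(rep(1, 20), 12, 0.5)
  flagged <- suppressMessages(flag_peg_contamination(peg))
  expect_equal(which(flagged), 21)
  expect_false(any(flag_peg_contamination(rep(0, 10))))
})
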