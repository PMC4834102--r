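test_that("prevalence_ci matches hand-checked Wald arithmetic and clamps", {
  p <- prevalence_ci(93319, 441925)
  expect_equal(unlist(p[, .(percent, ci_low, ci_high)]),
               c(percent = 21.1, ci_low = 21.0, ci_high = 21.2))
  degenerate <- prevalence_ci(0, 100)
  expect_equal(unlist(degenerate[, .(percent, ci_low, ci_high)]),
               c(percent = 0, ci_low = 0, ci_high = 0))
  full <- prevalence_ci(100, 100)
  expect_equal(full$ci_high, 100)
  expect_error(prevalence_ci(1, 0), "denominator")
  expect_error(prevalence_ci(5, 4), "numerator")
  # Wilson interval stays inside [0,100] and differs from Wald at the edge
  w <- prevalence_ci(1, 100, method = "wilson")
  expect_gt(w$ci_low, 0)
  expect_lt(w$ci_high, 100)
})

test_that("rounding is half-up on the percent scale", {
  expect_equal(round_half_up(0.25 * 100, 1), 25)
  expect_equal(round_half_up(2.45, 1), 2.5)   # base round() would give 2.4
  expect_equal(round_half_up(46.646, 1), 46.6)
  expect_equal(round_half_up(-2.45, 1), -2.5)
})

test_that("pip_count_table partitions the any-PIP count", {
  prof <- data.table(patient_id = sprintf("p%d", 1:10),
                     any_pip = rep(c(TRUE, FALSE), c(6L, 4L)),
                     pip_category = factor(
                       c("1", "1", "1", "2", "2", "3+", rep("0", 4L)),
                       levels = c("0", "1", "2", "3+")),
                     any_duplication = rep(c(TRUE, FALSE), c(2L, 8L)))
  tab <- pip_count_table(prof)
  expect_equal(tab[row == "overall_pip", numerator], 6L)
  expect_equal(tab[row %in% c("pip_1", "pip_2", "pip_3plus"),
                   sum(numerator)],
               tab[row == "overall_pip", numerator])
  expect_equal(tab[row == "duplication", percent], 20)
  # inconsistent profiles trip the structural assertion
  broken <- copy(prof)[1L, any_pip := FALSE]
  expect_error(pip_count_table(broken), "partition")
  # all-zero profiles give all-zero rows
  zero <- copy(prof)[, `:=`(any_pip = FALSE,
                            pip_category = factor("0",
                                                  levels = c("0", "1", "2",
                                                             "3+")),
                            any_duplication = FALSE)]
  expect_true(all(pip_count_table(zero)$numerator == 0L))
})

test_that("univariate logistic OR equals the 2x2 cross-product ratio", {
  # constructed table: a=40 exposed cases, b=60, c=25, d=175
  tab <- data.table(
    y = rep(c(TRUE, FALSE, TRUE, FALSE), c(40L, 60L, 25L, 175L)),
    x = rep(c(TRUE, TRUE, FALSE, FALSE), c(40L, 60L, 25L, 175L)))
  fit <- fit_logistic(tab, outcome = "y", covariates = "x")
  or_hat <- fit[level == "TRUE", or_unadjusted]
  expect_equal(or_hat, (40 * 175) / (60 * 25), tolerance = 1e-7)
  expect_equal(fit[level == "TRUE", or_adjusted], or_hat, tolerance = 1e-7)
  expect_equal(fit[level == "FALSE", or_unadjusted], 1)
  expect_true(is.na(fit[level == "FALSE", ci_low_unadjusted]))
})

test_that("a covariate independent of the outcome has a CI covering 1", {
  withr::local_seed(31L)
  n <- 50000L
  dat <- data.table(y = runif(n) < 0.2, x = runif(n) < 0.5)
  fit <- fit_logistic(dat, outcome = "y", covariates = "x")
  expect_lt(fit[level == "TRUE", ci_low_unadjusted], 1)
  expect_gt(fit[level == "TRUE", ci_high_unadjusted], 1)
})

test_that("factor covariates report reference levels and adjusted ORs", {
  withr::local_seed(32L)
  n <- 20000L
  dat <- data.table(
    polypharmacy = runif(n) < 0.2,
    gender = factor(ifelse(runif(n) < 0.5, "female", "male"),
                    levels = c("male", "female")),
    age_group = factor(sample(c("45-49", "50-54", "55-59", "60-64"), n,
                              TRUE), levels = c("45-49", "50-54", "55-59",
                                                "60-64")))
  lp <- -2 + log(8) * dat$polypharmacy +
    log(1.5) * (dat$gender == "female") +
    log(1.1) * (as.integer(dat$age_group) - 1L)
  dat[, any_pip := runif(n) < plogis(lp)]
  fit <- fit_logistic(dat)
  expect_equal(nrow(fit), 8L)  # 2 + 2 + 4 levels
  expect_equal(fit[reference == TRUE, or_adjusted], rep(1, 3L))
  # point estimates land near the truth at this n
  expect_equal(fit[term == "polypharmacy" & level == "TRUE", or_adjusted],
               8, tolerance = 0.15)
  expect_equal(fit[term == "gender" & level == "female", or_adjusted],
               1.5, tolerance = 0.15)
})

test_that("perfect separation fails with an actionable message", {
  dat <- data.table(y = rep(c(TRUE, FALSE), each = 50L),
                    x = rep(c(TRUE, FALSE), each = 50L))
  expect_error(suppressWarnings(fit_logistic(dat, "y", "x")), "separation")
})
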