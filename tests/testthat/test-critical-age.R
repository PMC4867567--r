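test_that("Kruskal-Wallis H matches hand computation and stats::kruskal.test", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2) # mean ranks 2/5/8: H = 12/90 * 54
  expect_equal(kw$df, 2)
  # identical groups: H = 0, p = 1
  same <- kruskal_wallis(list(rep(2, 4), rep(2, 4)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  # agreement with the base-R implementation, with and without ties
  withr::with_seed(101, {
    for (i in 1:10) {
      g <- list(
        sample(1:8, 7, TRUE), sample(1:8, 5, TRUE), sample(1:8, 6, TRUE)
      )
      ref <- stats::kruskal.test(g)
      kw <- kruskal_wallis(g)
      expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(kw$p, ref$p.value, tolerance = 1e-12)
    }
  })
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("two-group Kruskal-Wallis agrees with the exhaustive rank-permutation null", {
  x <- c(1, 3, 5, 8)
  y <- c(2, 9, 10, 11)
  kw <- kruskal_wallis(list(x, y))
  expect_equal(kw$H, kw_H_oracle(list(x, y)), tolerance = 1e-12)
  p_exact <- perm_rankdiff_p(x, y)
  expect_lt(abs(kw$p - p_exact), 0.06)
  # a fully separated pair: both routes call it significant
  x <- 1:4
  y <- 11:14
  kw <- kruskal_wallis(list(x, y))
  expect_lt(kw$p, 0.05)
  expect_lte(perm_rankdiff_p(x, y), 0.05)
})

test_that("Dunn comparisons use the pooled tie term and Bonferroni over all pairs", {
  # identical groups: nothing significant, adjusted p = 1
  dn <- dunn_pairwise(list(a = rep(1, 5), b = rep(1, 5), c = rep(1, 5)))
  expect_true(all(dn$p_adjusted == 1))
  expect_false(any(dn$significant))
  # k = 2: a single comparison, so no multiplication
  dn2 <- dunn_pairwise(list(a = c(1, 2, 3), b = c(7, 8, 9)))
  expect_equal(dn2$p_adjusted, dn2$p_raw)
  # separated three-group case: extreme pair flagged at alpha = 0.05,
  # and the pairwise decision agrees with the exhaustive permutation oracle
  g <- list(a = c(1, 2, 3, 4), b = c(5, 6, 7, 8), c = c(21, 22, 23, 24))
  dn3 <- dunn_pairwise(g)
  ac <- dn3[dn3$group_a == "a" & dn3$group_b == "c", ]
  expect_true(ac$significant)
  expect_lte(perm_rankdiff_p(g$a, g$c), 0.05)
  # Bonferroni arithmetic
  expect_equal(dn3$p_adjusted, pmin(1, 3 * dn3$p_raw))
})

test_that("phase regressions reproduce the normal equations and degenerate cases", {
  ages <- c(41, 45, 50, 55, 60, 70)
  # noiseless line: exact slope, zero residuals
  fit <- fit_phase_regression(ages, 0.048 * ages)
  expect_equal(fit$slope, 0.048, tolerance = 1e-12)
  expect_lt(fit$p_slope, 1e-6)
  # constant response: slope 0, p = 1
  flat <- fit_phase_regression(ages, rep(0.3, 6))
  expect_equal(flat$slope, 0)
  expect_equal(flat$p_slope, 1)
  # closed-form agreement on noisy data
  withr::with_seed(7, {
    y <- 0.02 * ages + rnorm(6, sd = 0.3)
    fit <- fit_phase_regression(ages, y)
    or <- ols_oracle(ages, y)
    expect_equal(fit$slope, unname(or["slope"]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(or["intercept"]), tolerance = 1e-10)
    expect_true(fit$slope_ci_low <= fit$slope && fit$slope <= fit$slope_ci_high)
  })
  expect_error(fit_phase_regression(1:2, 1:2), "at least 3")
  expect_error(fit_phase_regression(rep(5, 4), 1:4), "zero variance")
})

test_that("noiseless biphasic data yields the exact break and segment slopes", {
  ages <- rep(1:80, 2)
  va <- ifelse(ages <= 40, 0.05, 0.05 + 0.048 * (ages - 40))
  co <- make_cohort(age = ages, va_od = va)
  res <- biphasic_report(co, "va")
  expect_equal(res$critical_age, 40)
  expect_equal(res$phase1$slope, 0, tolerance = 1e-12)
  expect_equal(res$phase2$slope, 0.048, tolerance = 1e-10)
  # trace grows monotonically and terminates within seven steps
  expect_lte(nrow(res$trace), 7)
  expect_true(all(diff(res$trace$n_pooled) > 0))
  expect_true(res$trace$significant[nrow(res$trace)])
  expect_false(any(res$trace$significant[-nrow(res$trace)]))
})

test_that("a flat cohort has no critical age and a single-phase fit", {
  co <- make_cohort(age = rep(c(5, 15, 25, 35, 45, 55), each = 6), va_od = 0.1)
  res <- find_critical_age(co, "va")
  expect_true(is.na(res$critical_age))
  expect_null(res$phase2)
  expect_equal(res$phase1$slope, 0)
  g <- glance(res)
  expect_true(is.na(g$critical_age))
  expect_error(find_critical_age(make_cohort(age = c(3, 5), va_od = c(0, 0.1)), "va"),
    "two non-empty decade bins"
  )
})

test_that("critical-age recovery on the default synthetic cohorts", {
  va <- find_critical_age(simulate_cohort(cohort_config(), seed = 2), "va")
  expect_equal(va$critical_age, 40)
  expect_true(!is.null(va$phase2))
  # reporting convention: field loss is a positive rate
  vf <- biphasic_report(simulate_cohort(vf_cohort_config(), seed = 42), "vf")
  if (!is.null(vf$phase2)) {
    expect_gt(glance(vf)$phase2_rate, 0)
  }
  # tidy/glance surface both phases
  td <- tidy(va)
  expect_setequal(td$phase, c("phase1", "phase2"))
  expect_s3_class(ggplot2::autoplot(va), "ggplot")
})

test_that("the protected comparison family keeps false critical ages rare under a true null", {
  cfg <- cohort_config(
    va_slope_post = 0, va_slope_pre = 0,
    va_noise_sd_by_decade = rep(0.15, 8)
  )
  hits <- vapply(1:100, function(s) {
    res <- find_critical_age(simulate_cohort(cfg, seed = s), "va",
      comparison_family = "all_pairs"
    )
    !is.na(res$critical_age)
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})
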