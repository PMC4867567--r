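test_that("the product-limit estimator matches hand computation", {
  cv <- km_curve(c(10, 10, 11, 12, 15, 20, 30))
  # events at 10 (x2), 11, 12: S(12) = (5/7)(4/5)(3/4) = 3/7
  expect_equal(km_survival_at(cv, 12), 3 / 7)
  expect_equal(cv$median, 12)
  expect_equal(km_survival_at(cv, 9), 1)
  # with no censoring the curve equals the empirical survivor function
  tt <- c(3, 7, 7, 9, 14)
  cv2 <- km_curve(tt)
  grid <- 0:15
  expect_equal(km_survival_at(cv2, grid), sapply(grid, function(t) mean(tt > t)))
  # single observed event: survival drops 1 -> 0
  one <- km_curve(8)
  expect_equal(km_survival_at(one, 8), 0)
  expect_equal(one$median, 8)
  # all censored: survival stays 1, median absent
  cens <- km_curve(c(5, 9, 12), observed = c(FALSE, FALSE, FALSE))
  expect_equal(km_survival_at(cens, 12), 1)
  expect_true(is.na(cens$median))
  expect_error(km_curve(numeric(0)), "no observations")
})

test_that("median conventions: first step at or below 0.5 vs midpoint interpolation", {
  # two events: S(10) = 0.5 exactly
  expect_equal(km_curve(c(10, 20))$median, 10)
  expect_equal(km_curve(c(10, 20), median_method = "midpoint")$median, 15)
  # when S jumps straight past 0.5 both conventions agree
  expect_equal(km_curve(c(10, 10, 20))$median, 10)
  expect_equal(km_curve(c(10, 10, 20), median_method = "midpoint")$median, 10)
})

test_that("group comparison is null on identical groups and flags separated ones", {
  d <- data.frame(
    time = rep(c(5, 8, 12, 20), 2), status = TRUE,
    group = rep(c("a", "b"), each = 4)
  )
  cmp <- compare_onset(d)
  expect_equal(cmp$statistic, 0, tolerance = 1e-12)
  expect_equal(cmp$p, 1)
  # fully separated groups: analytic p < 0.05, confirmed by the exhaustive
  # label-permutation oracle
  d2 <- data.frame(
    time = c(5, 6, 7, 8, 30, 31, 32, 33), status = TRUE,
    group = rep(c("a", "b"), each = 4)
  )
  cmp2 <- compare_onset(d2)
  expect_lt(cmp2$p, 0.05)
  expect_lte(perm_logrank_p(d2$time, d2$status, 4), 0.05)
  expect_equal(cmp2$df, 1)
  # the statistic is invariant to relabelling groups
  d3 <- d2[sample(nrow(d2)), ]
  expect_equal(compare_onset(d3)$statistic, cmp2$statistic, tolerance = 1e-10)
  expect_error(compare_onset(d2[d2$group == "a", ]), "two groups")
})

test_that("onset summaries report mean and SEM", {
  s <- onset_summary(c(10, 10, 20))
  expect_equal(s$mean, 40 / 3, tolerance = 1e-12)
  expect_equal(s$sem, sd(c(10, 10, 20)) / sqrt(3), tolerance = 1e-12)
  expect_equal(s$n, 3)
  expect_true(is.na(onset_summary(7)$sem))
  # synthetic onsets drawn at the configured mean land within 2 SEM
  co <- simulate_cohort(cohort_config(), seed = 31)
  obs <- co$onset_nyctalopia[!is.na(co$onset_nyctalopia)]
  s2 <- onset_summary(obs)
  expect_lt(abs(s2$mean - 12.6), 2 * s2$sem + 1) # +1 for onset>age censoring bias
})

test_that("cohort-level onset analysis censors asymptomatic subjects at assessment age", {
  co <- simulate_cohort(cohort_config(), seed = 3)
  ev <- onset_events(co, "nyctalopia")
  expect_equal(nrow(ev), nrow(co))
  miss <- is.na(co$onset_nyctalopia)
  expect_true(all(ev$time[miss] == co$age[miss]))
  expect_true(all(!ev$status[miss]))
  res <- onset_analysis(co, "nyctalopia")
  expect_true(all(names(res$curves) %in% c("missense", "rep1_absent", "other")))
  expect_true(res$comparison$p >= 0 && res$comparison$p <= 1)
})

test_that("Spearman intereye correlation uses midranks and drops incomplete pairs", {
  expect_equal(intereye_spearman(1:6, (1:6)^3)$rho, 1) # monotone
  expect_equal(intereye_spearman(1:6, -(1:6))$rho, -1) # reversed
  expect_equal(intereye_spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  # invariant under strictly monotone transforms of either eye
  withr::with_seed(5, {
    od <- rnorm(30)
    os <- od + rnorm(30)
    r0 <- intereye_spearman(od, os)$rho
    expect_equal(intereye_spearman(exp(od), os)$rho, r0)
    expect_equal(intereye_spearman(od, log(os - min(os) + 1))$rho, r0)
  })
  # incomplete pairs dropped from n
  r <- intereye_spearman(c(1, 2, 3, NA, 5), c(2, 1, 3, 4, NA))
  expect_equal(r$n, 3)
  expect_error(intereye_spearman(c(1, 2), c(2, 1)), "3 complete pairs")
})
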