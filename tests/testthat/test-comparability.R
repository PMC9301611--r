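test_that("estimated true score regresses toward the mean", {
  expect_equal(estimated_true_score(100, 0.3), 100)  # fixed point
  expect_equal(estimated_true_score(130, 0.9), 127)
  expect_equal(estimated_true_score(130, 1), 130)    # identity at r = 1
  expect_error(estimated_true_score(100, 0), "\\(0,1\\]")
})

test_that("true-score CIs use the standard error of estimate", {
  expect_equal(true_score_ci(130, 1), c(lower = 130, upper = 130))
  ci <- true_score_ci(130, 0.9)
  expect_equal(unname(ci),
               127 + c(-1, 1) * qnorm(0.975) * 15 * sqrt(0.9 * 0.1),
               tolerance = 1e-12)
  expect_equal(unname(round(ci, 2)), c(118.18, 135.82))
  # symmetric about 100 at the mean for any reliability
  for (r in c(0.5, 0.8, 0.95)) {
    ci <- true_score_ci(100, r)
    expect_equal(unname(ci[1] + ci[2]), 200)
  }
})

test_that("reported CI widths reproduce the published round-half-up values", {
  expect_equal(ci_width_points(c(0.98, 0.97, 0.95, 0.99, 0.93)),
               c(8L, 10L, 13L, 6L, 15L))
  expect_equal(ci_width_points(0.94), 14L)
  expect_equal(ci_width_points(1), 0L)
  # non-increasing in reliability across the range used in practice
  widths <- ci_width_points(seq(0.5, 0.999, by = 0.001))
  expect_true(all(diff(widths) <= 0))
})

test_that("closed intervals overlap when touching", {
  expect_true(intervals_overlap(c(90, 110), c(105, 120)))
  expect_false(intervals_overlap(c(90, 100), c(100.5, 110)))
  expect_true(intervals_overlap(c(90, 100), c(100, 110)))
  expect_error(intervals_overlap(c(110, 90), c(100, 120)), "exceeds")
})

test_that("criteria separate nominal boundaries and CI category runs", {
  b <- two_composite_battery()
  lookup <- build_reliability_lookup(
    NULL, b, overrides = list(full = list(overall = 0.98),
                              screen = list(overall = 0.98)))
  nom <- criterion_spec("NomIQ")
  expect_false(evaluate_criterion(84, 85, nom))
  expect_true(evaluate_criterion(85, 115, nom))

  # 112 vs 121: different nominal categories, but the CI category runs
  # ({average, above_average} and {above_average}) intersect
  expect_false(evaluate_criterion(112, 121, nom))
  expect_true(evaluate_criterion(112, 121, criterion_spec("NomCI"), lookup,
                                 "full", "screen", band = "5-13"))
  # and the raw CIs themselves ([107.6, 115.9] vs [116.5, 124.7]) do not
  expect_false(evaluate_criterion(112, 121, criterion_spec("CI_overall"),
                                  lookup, "full", "screen", band = "5-13"))
})

test_that("equal IQs are comparable under all six criteria", {
  b <- two_composite_battery()
  res <- normed_cohort(b, n = 4000, seed = 31)
  iq <- res$cohort$iq_full
  band <- b$age_bands$label[age_band_index(res$cohort$age, b)]
  for (kind in c("NomIQ", "CI_overall", "CI_age", "NomCI", "CI_rtt",
                 "CI_ageIQ")) {
    flag <- evaluate_criterion(iq, iq, criterion_spec(kind), res$lookup,
                               "full", "full", band)
    expect_true(all(flag, na.rm = TRUE), info = kind)
    expect_gt(sum(!is.na(flag)), 0)
  }
})

test_that("rates aggregate exactly and self-pairs are fully comparable", {
  b <- two_composite_battery()
  res <- normed_cohort(b, n = 4000, seed = 33)
  self <- compare_composites(res$cohort, b, c("full", "full"), res$lookup,
                             criteria = c("NomIQ", "CI_overall"))
  for (gp in c("overall", "iq", "age")) {
    tab <- comparability_rates(self, "CI_overall", gp)
    expect_true(all(tab$rate[tab$n > 0] == 100))
  }

  pair <- compare_composites(res$cohort, b, c("full", "screen"), res$lookup)
  overall <- comparability_rates(pair, "NomIQ", "overall")
  for (gp in c("iq", "age")) {
    tab <- comparability_rates(pair, "NomIQ", gp)
    expect_equal(sum(tab$rate * tab$n, na.rm = TRUE) / sum(tab$n),
                 overall$rate)  # aggregation identity
    expect_equal(sum(tab$n), overall$n)  # no silent subject loss
  }
})

test_that("NomCI comparability dominates NomIQ on simulated cohorts", {
  b <- two_composite_battery()
  for (seed in c(41, 42, 43)) {
    res <- normed_cohort(b, n = 2000, seed = seed)
    pair <- compare_composites(res$cohort, b, c("full", "screen"), res$lookup,
                               criteria = c("NomIQ", "NomCI"))
    expect_gte(comparability_rates(pair, "NomCI", "overall")$rate,
               comparability_rates(pair, "NomIQ", "overall")$rate)
    # subject-level containment: every NomIQ-comparable pair is NomCI-comparable
    expect_true(all(pair$NomCI[pair$NomIQ]))
  }
})

test_that("comparability under a CI criterion is non-decreasing in CI width", {
  b <- two_composite_battery()
  res <- normed_cohort(b, n = 4000, seed = 51)
  rates <- vapply(c(0.98, 0.95, 0.9, 0.8, 0.7), function(r) {
    lk <- build_reliability_lookup(
      res$cohort, b, overrides = list(full = list(overall = r),
                                      screen = list(overall = r)))
    pair <- compare_composites(res$cohort, b, c("full", "screen"), lk,
                               criteria = "CI_overall")
    comparability_rates(pair, "CI_overall", "overall")$rate
  }, numeric(1))
  # reliabilities fall from .98 to .70, so widths grow and overlap can only
  # be preserved or created
  expect_true(all(diff(rates) >= 0))
})

test_that("the CI-overlap rule agrees with an independent closed-form oracle", {
  # with equal reliabilities r for both scores, the two true-score CIs
  # overlap iff r * |iq_a - iq_b| <= 2 * z * 15 * sqrt(r (1 - r)); computing
  # the rate from that inequality is independent of the interval machinery
  set.seed(91)
  n <- 200000
  r <- 0.95
  z1 <- rnorm(n)
  z2 <- 0.95 * z1 + sqrt(1 - 0.95^2) * rnorm(n)
  iq_a <- round(100 + 15 * z1)
  iq_b <- round(100 + 15 * z2)
  oracle <- mean(r * abs(iq_a - iq_b) <=
                   2 * qnorm(0.975) * 15 * sqrt(r * (1 - r)))
  pkg <- mean(intervals_overlap(true_score_ci(iq_a, r),
                                true_score_ci(iq_b, r)))
  expect_lt(abs(100 * pkg - 100 * oracle), 0.5)
})

test_that("difference summaries and group-level statistics behave at the anchors", {
  same <- pair_table(rep(c(95L, 105L), 50), rep(c(95L, 105L), 50))
  s <- abs_difference_summary(same)
  expect_equal(s$mean[s$quantity == "abs"], 0)
  expect_equal(s$max[s$quantity == "abs"], 0)

  gl <- group_level_comparison(same, 0.95, 0.95)
  expect_true(is.na(gl$t))  # zero difference variance: t undefined
  expect_true(is.na(gl$d))
  expect_equal(gl$mean_diff, 0)
  expect_equal(gl$r, 1)

  shifted <- pair_table(c(100L, 104L, 108L, 112L, 99L, 105L),
                        c(98L, 103L, 105L, 110L, 98L, 101L))
  gl2 <- group_level_comparison(shifted, 0.95, 0.95)
  expect_equal(sign(gl2$d), sign(gl2$mean_diff))
  expect_equal(gl2$d, dunlap_d(gl2$t, gl2$r, gl2$n))
})

test_that("paired effect size matches the published conversion", {
  expect_equal(round(dunlap_d(3.73, 0.93, 2109), 3), 0.030)
})

test_that("extremity ratio follows the composite aggregation algebra", {
  expect_equal(extremity_ratio(1, 0.5), 1)
  expect_equal(extremity_ratio(5, 1), 1)
  expect_equal(round(extremity_ratio(4, 0.5), 3), 1.265)
  expect_gt(extremity_ratio(10, 0.3), extremity_ratio(4, 0.3))
  expect_error(extremity_ratio(3, -0.6), "positive")
})
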