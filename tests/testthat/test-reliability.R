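test_that("alpha behaves at the classical anchor points", {
  set.seed(1)
  x <- rnorm(1000)
  expect_equal(cronbach_alpha(cbind(x, x)), 1)

  set.seed(2)
  noise <- matrix(rnorm(2e5), ncol = 2)
  expect_lt(abs(cronbach_alpha(noise)), 0.03)

  # two parallel components with population correlation .5 step up to 2/3
  set.seed(3)
  g <- rnorm(1e5)
  par2 <- cbind(sqrt(.5) * g + sqrt(.5) * rnorm(1e5),
                sqrt(.5) * g + sqrt(.5) * rnorm(1e5))
  expect_lt(abs(cronbach_alpha(par2) - 2 * .5 / 1.5), 0.01)

  expect_error(cronbach_alpha(matrix(1:10, ncol = 1)), "2 components")
  expect_error(cronbach_alpha(cbind(c(1, 1, 1), c(2, 2, 2))), "zero variance")
})

test_that("alpha is invariant under column shifts and a common rescale", {
  # the variance-based alpha weighs components by their variances, so it is
  # location-free per column and scale-free only under a shared rescale
  set.seed(4)
  m <- matrix(rnorm(300), ncol = 3)
  shifted <- sweep(m, 2, c(100, -3, 7), "+")
  expect_lt(abs(cronbach_alpha(m) - cronbach_alpha(shifted)), 1e-10)
  expect_lt(abs(cronbach_alpha(m) - cronbach_alpha(m * 7)), 1e-10)
})

test_that("composite reliability reduces to Spearman-Brown for parallel components", {
  for (k in 1:20) {
    r <- 0.8
    V <- matrix(r, k, k)
    diag(V) <- 1
    expect_lt(abs(composite_reliability(rep(r, k), V) -
                    k * r / (1 + (k - 1) * r)), 1e-12)
  }
})

test_that("composite reliability matches hand arithmetic and validates input", {
  expect_equal(composite_reliability(0.8, matrix(2)), 0.8)  # identity at k=1
  V <- matrix(0.8, 2, 2); diag(V) <- 1
  expect_equal(composite_reliability(c(0.9, 0.9), V), 1 - 0.2 / 3.6)
  expect_error(composite_reliability(c(.9, .9), matrix(c(1, -1.2, -1.2, 1), 2)),
               "non-positive")
  expect_error(composite_reliability(c(.9, .9, .9), V), "do not match")
  expect_error(composite_reliability(c(.9, 1.1), V), "\\(0,1\\]")
})

test_that("cohort alpha matches the composite formula under essential tau-equivalence", {
  # with r_j = lambda_j^2 all non-common variance is error, which is the
  # condition under which alpha equals the component-based composite
  # reliability; with specific variance present alpha is only a lower bound
  lam <- 0.8
  b <- one_composite_battery(k = 4, loading = lam, reliability = lam^2)
  co <- generate_cohort(sim_config(100000, 17, b))
  V <- matrix(lam^2, 4, 4)
  diag(V) <- 1
  r_c <- composite_reliability(rep(lam^2, 4), V)
  a <- cronbach_alpha(co[paste0("s", 1:4)])
  expect_lt(abs(a - r_c), 0.01)

  b2 <- one_composite_battery(k = 4, loading = 0.7, reliability = 0.85)
  co2 <- generate_cohort(sim_config(50000, 18, b2))
  V2 <- matrix(0.49, 4, 4)
  diag(V2) <- 1
  expect_lt(cronbach_alpha(co2[paste0("s", 1:4)]),
            composite_reliability(rep(0.85, 4), V2))
})

test_that("group-specific alphas reflect range restriction and flag small cells", {
  b <- one_composite_battery(k = 4)
  res <- normed_cohort(b, n = 20000, seed = 11)
  gr <- groupwise_reliability(res$cohort, "comp", b)
  # conditioning cells on the composite's own IQ restricts the very sum the
  # components form: every large cell sits strictly below the overall alpha
  big <- gr$age_iq[gr$age_iq$n >= 500 & !is.na(gr$age_iq$alpha), ]
  expect_gt(nrow(big), 0)
  expect_true(all(big$alpha < gr$overall))

  tiny <- normed_cohort(b, n = 120, seed = 12)
  gr2 <- groupwise_reliability(tiny$cohort, "comp", b, min_cell = 200L)
  expect_true(all(is.na(gr2$age_iq$alpha)))  # unavailable, not a number
  expect_true(all(gr2$age_iq$n < 200))
})

test_that("a score ceiling lowers top-IQ-cell alpha below the mid cell", {
  b <- one_composite_battery(k = 4)
  res <- normed_cohort(b, n = 30000, seed = 12, score_ceiling = 13)
  gr <- groupwise_reliability(res$cohort, "comp", b)
  cells <- gr$age_iq
  top <- cells$alpha[cells$iq_group == "above_average"]
  mid <- cells$alpha[cells$iq_group == "average"]
  expect_gte(min(cells$n[cells$iq_group %in% c("average", "above_average")]),
             2000)
  expect_lt(top, mid)
})

test_that("disattenuation matches the textbook formula and caps at one", {
  expect_equal(round(disattenuate(0.93, 0.95, 0.93), 2), 0.99)
  expect_equal(disattenuate(0, 0.9, 0.8), 0)
  expect_equal(disattenuate(0.5, 1, 1), 0.5)
  expect_warning(out <- disattenuate(0.95, 0.9, 0.9), "capped")
  expect_equal(out, 1)
  expect_error(disattenuate(0.5, 0, 0.9), "\\(0,1\\]")
})

test_that("the reliability lookup serves every slice and honors overrides", {
  b <- two_composite_battery()
  res <- normed_cohort(b, n = 3000, seed = 21)
  lk <- res$lookup
  expect_true(lookup_reliability(lk, "full", "overall") > 0)
  expect_equal(lookup_reliability(lk, "full", "retest"), 0.90)
  expect_true(is.na(lookup_reliability(lk, "full", "age", band = "nope")))

  lk2 <- build_reliability_lookup(res$cohort, b,
                                  overrides = list(full = list(overall = 0.97)))
  expect_equal(lookup_reliability(lk2, "full", "overall"), 0.97)
  expect_error(lookup_reliability(lk, "ghost", "overall"), "no reliability")
})
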