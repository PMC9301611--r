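test_that("norm table reproduces hand-computed cell statistics and rejects degenerate cells", {
  b <- one_composite_battery(k = 2, bands = list(c(5, 21)))
  cohort <- data.frame(age = c(10, 12), s1 = c(30, 40), s2 = c(30, 40))
  norms <- build_norm_table(cohort, b)
  expect_equal(norms$mean, 70)
  expect_equal(norms$sd, sd(c(60, 80)))  # 14.142 with the n-1 denominator
  expect_equal(norms$n, 2L)

  # identical cohort and config give the identical table
  expect_identical(norms, build_norm_table(cohort, b))

  flat <- data.frame(age = c(10, 12), s1 = c(35, 35), s2 = c(35, 35))
  expect_error(build_norm_table(flat, b), "zero variance")
  expect_error(build_norm_table(cohort[1, ], b), "fewer than 2")
})

test_that("composite IQ is the normed, rounded, clipped sum of member scores", {
  b <- one_composite_battery(k = 2, clip_range = c(55, 145))
  cohort <- data.frame(age = rep(10, 50), s1 = 1:50, s2 = 1:50)
  norms <- build_norm_table(cohort, b)
  mu <- norms$mean
  sig <- norms$sd
  score_at <- function(total)
    compute_composite_iq(c(s1 = total / 2, s2 = total / 2), "comp", norms,
                         age = 10, battery = b)
  expect_equal(score_at(mu), 100L)
  expect_equal(score_at(mu + sig), 115L)
  expect_equal(score_at(mu + 4 * sig), 145L)   # ceiling clip
  expect_error(
    compute_composite_iq(c(s1 = 10), "comp", norms, 10, b), "missing member")
  expect_error(
    compute_composite_iq(c(s1 = 10, s2 = NA), "comp", norms, 10, b),
    "missing member")
})

test_that("vectorized composite IQ agrees with the scalar path", {
  b <- one_composite_battery(k = 3)
  res <- normed_cohort(b, n = 300, seed = 3)
  co <- res$cohort
  for (i in c(1, 57, 300)) {
    scores <- unlist(co[i, paste0("s", 1:3)])
    expect_equal(co$iq_comp[i],
                 compute_composite_iq(scores, "comp", res$norms, co$age[i], b))
  }
})

test_that("nominal categories follow the conventional boundaries", {
  expect_equal(as.character(nominal_category(69)), "lower_extreme")
  expect_equal(as.character(nominal_category(70)), "below_average")
  expect_equal(as.character(nominal_category(115)), "average")
  expect_equal(as.character(nominal_category(116)), "above_average")
  expect_equal(as.character(nominal_category(130)), "above_average")
  expect_equal(as.character(nominal_category(131)), "upper_extreme")
})

test_that("category and group assignments partition the IQ line", {
  iqs <- 40:160
  expect_false(anyNA(nominal_category(iqs)))
  expect_false(anyNA(assign_iq_group(iqs, "three")))
  expect_false(anyNA(assign_iq_group(iqs, "six")))
  # each label is a contiguous block and all labels occur
  expect_equal(nlevels(droplevels(nominal_category(iqs))), 5L)
  expect_equal(nlevels(droplevels(assign_iq_group(iqs, "six"))), 6L)
  expect_equal(as.character(assign_iq_group(84, "three")), "below_average")
  expect_equal(as.character(assign_iq_group(85, "three")), "average")
  expect_equal(as.character(assign_iq_group(130, "six")), ">=130")
  expect_equal(as.character(assign_iq_group(129, "six")), "115-129")
})

test_that("intervals map to contiguous runs of nominal categories", {
  expect_equal(as.character(interval_to_categories(c(112, 120))),
               c("average", "above_average"))
  expect_equal(as.character(interval_to_categories(c(100, 100))), "average")
  expect_equal(as.character(interval_to_categories(c(60, 90))),
               c("lower_extreme", "below_average", "average"))
  expect_error(interval_to_categories(c(120, 112)))
})

test_that("content overlap matches the shared-ability counting rule", {
  b <- reference_batteries()
  expect_equal(content_overlap(b$ids2, "ebiq", "fsiq"), 100L)
  expect_equal(content_overlap(b$ids2, "fsiq", "abiq"), 44L)
  expect_equal(content_overlap(b$ids2, "abiq", "ebiq"), 38L)  # 37.5 rounds up
  expect_equal(content_overlap(b$sb5, "fsiq", "abiq"), 50L)
  expect_equal(content_overlap(b$rias, "fsiq", "abiq"), 100L)
  # symmetric, and identical composites fully overlap
  expect_equal(content_overlap(b$ids2, "abiq", "fsiq"),
               content_overlap(b$ids2, "fsiq", "abiq"))
  expect_equal(content_overlap(b$ids2, "ebiq", "ebiq"), 100L)
})

test_that("GPA averages reported grades and keeps missing as missing", {
  g <- data.frame(a = c(5, 4.5, NA), b = c(5, NA, NA), c = c(6, NA, NA),
                  d = c(4, NA, NA))
  expect_equal(gpa(g), c(5, 4.5, NA))
  expect_equal(gpa(data.frame(a = 4.5, b = 5.5)), 5)
  expect_error(gpa(data.frame(a = 7)), "\\[1, 6\\]")
})
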