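# Fixtures are built in code: small batteries and simulated cohorts.

# k subtests tapping one ability, a single composite over all of them
one_composite_battery <- function(k = 4, loading = 0.7, reliability = 0.85,
                                  clip_range = c(40, 160),
                                  bands = list(c(5, 21)), name = "test") {
  battery_config(
    name,
    subtests = lapply(seq_len(k), function(j)
      subtest_spec(paste0("s", j), "Gf", loading, reliability)),
    composites = list(composite_spec("comp", paste0("s", seq_len(k)),
                                     clip_range = clip_range)),
    age_bands = bands)
}

# two-ability battery with a full composite and a two-subtest screen,
# retest coefficients set so all six criteria are evaluable
two_composite_battery <- function(loading = 0.7, reliability = 0.85) {
  battery_config(
    "twoc",
    subtests = list(
      subtest_spec("f1", "Gf", loading, reliability),
      subtest_spec("f2", "Gf", loading, reliability),
      subtest_spec("c1", "Gc", loading, reliability),
      subtest_spec("c2", "Gc", loading, reliability)),
    composites = list(
      composite_spec("full", c("f1", "f2", "c1", "c2"),
                     clip_range = c(40, 160), retest = 0.90),
      composite_spec("screen", c("f1", "c1"),
                     clip_range = c(40, 160), retest = 0.85)),
    age_bands = list(c(5, 13), c(13, 21)))
}

# cohort with composite IQ columns and a reliability lookup, ready for
# criterion evaluation
normed_cohort <- function(battery, n = 4000, seed = 101, ...) {
  cohort <- generate_cohort(sim_config(n, seed, battery, ...))
  norms <- build_norm_table(cohort, battery)
  cohort <- add_composite_iqs(cohort, battery, norms)
  list(cohort = cohort, norms = norms,
       lookup = build_reliability_lookup(cohort, battery))
}

# minimal pair table for the difference/statistics operations
pair_table <- function(iq_a, iq_b) {
  out <- data.frame(id = seq_along(iq_a), iq_a = iq_a, iq_b = iq_b,
                    diff = iq_a - iq_b, abs_diff = abs(iq_a - iq_b))
  class(out) <- c("pair_comparison", "data.frame")
  out
}

# integer IQ pairs from a bivariate normal with correlation rho
sim_iq_pair <- function(n, rho, seed) {
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  pair_table(as.integer(round(100 + 15 * z1)),
             as.integer(round(100 + 15 * z2)))
}
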