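#' Build the predictor table for modelling absolute IQ differences
#'
#' Assembles, per subject, the demographic predictors (age, sex, AD(H)D,
#' native-language dummies with monolingual as reference, education) and the
#' IQ-level dummies (below-average `iq_a < 85`, above-average `iq_a > 115`,
#' average as reference, judged on the pair's reference composite), divides
#' all of them by two SDs ([two_sd_standardize()]), and then forms the
#' age-by-IQ-level interaction columns from the standardized mains.
#'
#' @param pair a [compare_composites()] table (rows aligned with `cohort`).
#' @param cohort the cohort the pair was computed from.
#' @return data frame with outcome `abs_diff` and standardized predictors.
#' @export
difference_model_data <- function(pair, cohort) {
  stopifnot(nrow(pair) == nrow(cohort))
  grp <- assign_iq_group(pair$iq_a, "three")
  d <- data.frame(
    abs_diff = pair$abs_diff,
    age = cohort$age,
    sex = cohort$sex,
    adhd = cohort$adhd,
    bilingual = as.integer(cohort$language == "bilingual"),
    other_language = as.integer(cohort$language == "other"),
    education = cohort$education,
    below_iq = as.integer(grp == "below_average"),
    above_iq = as.integer(grp == "above_average"))
  # drop constant predictors (e.g. nobody bilingual in a small cohort)
  keep <- vapply(d[-1], function(x) stats::sd(x, na.rm = TRUE) > 0, TRUE)
  d <- d[c("abs_diff", names(keep)[keep])]
  d <- two_sd_standardize(d, columns = setdiff(names(d), "abs_diff"))
  if (all(c("age", "below_iq") %in% names(d)))
    d$age_x_below_iq <- d$age * d$below_iq
  if (all(c("age", "above_iq") %in% names(d)))
    d$age_x_above_iq <- d$age * d$above_iq
  d
}

#' Run the full comparability analysis
#'
#' Orchestrates the whole pipeline on one battery: cohort acquisition
#' (simulation via [generate_cohort()] or a table passed in), norming,
#' composite IQs, reliability lookup, and per composite pair the
#' individual-level comparison under all requested criteria with rate
#' breakdowns, the difference-moment summary, group-level statistics, the
#' external-validity regressions with median split and 50%-CI-overlap
#' comparison (when grades are present), and the gamma GLM of absolute
#' differences with likelihood-ratio test. Deterministic given `seed`; all
#' randomness flows through named per-stage substreams.
#'
#' @param battery a [battery_config()].
#' @param cohort a cohort table, or `NULL` to simulate.
#' @param n_subjects cohort size when simulating (default 2000).
#' @param pairs list of `c(reference, other)` composite-name pairs; default
#'   all ordered pairs by decreasing subtest count.
#' @param criteria criterion kinds; default all six.
#' @param reliability_overrides passed to [build_reliability_lookup()].
#' @param grade_validity generating validity for simulated grades; `NULL`
#'   skips grade simulation.
#' @param grade_fraction fraction of subjects with grades (default 0.25).
#' @param min_cell minimum cell size for group-specific alphas.
#' @param outdir optional directory; when given, every table is written as
#'   CSV together with a provenance file.
#' @param seed root seed (default 1).
#' @return list with `cohort`, `norms`, `lookup`, and per-pair results
#'   (`comparison`, `rates`, `differences`, `group_level`, `glm`, `lrt`,
#'   `validity` when grades exist).
#' @export
run_full_analysis <- function(battery, cohort = NULL, n_subjects = 2000L,
                              pairs = NULL,
                              criteria = c("NomIQ", "CI_overall", "CI_age",
                                           "NomCI", "CI_rtt", "CI_ageIQ"),
                              reliability_overrides = list(),
                              grade_validity = 0.5, grade_fraction = 0.25,
                              min_cell = 30L, outdir = NULL, seed = 1L) {
  if (is.null(cohort)) {
    cohort <- generate_cohort(sim_config(n_subjects, seed, battery))
    if (!is.null(grade_validity))
      cohort <- generate_grades(cohort, grade_validity, seed,
                                fraction = grade_fraction)
  }
  if (is.null(pairs)) {
    sizes <- vapply(battery$composites, function(cmp) length(cmp$members), 0L)
    nm <- names(sort(sizes, decreasing = TRUE))
    pairs <- list()
    if (length(nm) >= 2L)
      for (i in seq_len(length(nm) - 1L))
        for (j in seq(i + 1L, length(nm)))
          pairs[[length(pairs) + 1L]] <- c(nm[i], nm[j])
  }
  stopifnot(length(pairs) >= 1L, length(criteria) >= 1L)

  norms <- build_norm_table(cohort, battery)
  cohort <- add_composite_iqs(cohort, battery, norms)
  lookup <- build_reliability_lookup(cohort, battery, min_cell = min_cell,
                                     overrides = reliability_overrides)

  grade_cols <- grep("^grade_", names(cohort), value = TRUE)
  results <- list()
  for (pr in pairs) {
    key <- paste(pr, collapse = "_vs_")
    cmp_a <- get_composite(battery, pr[1])
    cmp_b <- get_composite(battery, pr[2])
    comparison <- compare_composites(cohort, battery, pr, lookup, criteria)

    rates <- do.call(rbind, lapply(criteria, function(cr) {
      do.call(rbind, lapply(c("overall", "iq", "age"), function(gp) {
        tab <- comparability_rates(comparison, cr, gp)
        cbind(criterion = cr, grouping = gp, tab)
      }))
    }))

    res <- list(
      comparison = comparison,
      rates = rates,
      differences = abs_difference_summary(comparison),
      group_level = group_level_comparison(
        comparison,
        r_a = lookup$entries[[pr[1]]]$overall,
        r_b = lookup$entries[[pr[2]]]$overall))

    if (stats::sd(comparison$abs_diff) > 0) {
      model_data <- difference_model_data(comparison, cohort)
      full <- fit_gamma_glm(abs_diff ~ ., model_data)
      null <- fit_gamma_glm(abs_diff ~ 1, model_data)
      res$glm <- full
      res$lrt <- likelihood_ratio_test(full, null)
    }

    if (length(grade_cols)) {
      g <- gpa(cohort[grade_cols])
      split <- median_split(comparison)
      fit_if <- function(rows, iq) {
        keep <- rows[!is.na(g[rows])]
        if (length(keep) >= 10 && stats::sd(g[keep]) > 0)
          fit_grade_regression(g[keep], iq[keep]) else NULL
      }
      validity <- list(
        all_a = fit_if(seq_len(nrow(cohort)), comparison$iq_a),
        all_b = fit_if(seq_len(nrow(cohort)), comparison$iq_b),
        small_a = fit_if(split$small, comparison$iq_a),
        small_b = fit_if(split$small, comparison$iq_b),
        large_a = fit_if(split$large, comparison$iq_a),
        large_b = fit_if(split$large, comparison$iq_b),
        split_n = split$n)
      both <- function(x, y) !is.null(x) && !is.null(y)
      if (both(validity$all_a, validity$all_b))
        validity$beta_overlap_all <- beta_ci_overlap_fraction(
          validity$all_a$ci, validity$all_b$ci)
      if (both(validity$large_a, validity$large_b))
        validity$beta_overlap_large <- beta_ci_overlap_fraction(
          validity$large_a$ci, validity$large_b$ci)
      res$validity <- validity
    }
    results[[key]] <- res
  }

  out <- list(battery = battery$name, cohort = cohort, norms = norms,
              lookup = lookup, pairs = results, seed = seed)
  if (!is.null(outdir)) write_analysis_tables(out, outdir)
  invisible(out)
}

write_analysis_tables <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(outdir, paste0(name, ".csv")),
                     row.names = FALSE, na = "")
  wr(as.data.frame(result$norms), "norm_table")
  for (key in names(result$pairs)) {
    res <- result$pairs[[key]]
    wr(res$rates, paste0(key, "_rates"))
    wr(res$differences, paste0(key, "_differences"))
    gl <- res$group_level
    wr(data.frame(stat = names(gl), value = unlist(gl)),
       paste0(key, "_group_level"))
    if (!is.null(res$glm))
      wr(data.frame(term = names(res$glm$coefficients),
                  estimate = res$glm$coefficients, se = res$glm$se,
                  p = res$glm$p,
                  lrt_stat = res$lrt$statistic, lrt_df = res$lrt$df,
                  lrt_p = res$lrt$p),
       paste0(key, "_glm"))
  }
  yaml::write_yaml(list(seed = result$seed, battery = result$battery,
                        n = nrow(result$cohort),
                        package_version = as.character(
                          utils::packageVersion("scorecomp"))),
                   file.path(outdir, "provenance.yml"))
  invisible(outdir)
}
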