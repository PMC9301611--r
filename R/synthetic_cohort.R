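#' Configuration for the synthetic standardization cohort
#'
#' The generator draws subtest scores from a one-general-factor model: for
#' each subject a latent ability `g ~ N(0,1)`, then for subtest j
#' `x_j = lambda_j(g) * g + sqrt(psi_j) * s_j + sqrt(theta_j) * e_j`
#' with specific variance `psi_j = r_j - lambda_j(g)^2`, error variance
#' `theta_j = 1 - r_j`, and `s_j`, `e_j` independent standard normals. With
#' `slodr_slope = 0` every subtest has unit variance and reliability `r_j`
#' by construction. A positive `slodr_slope` attenuates loadings linearly
#' above the mean ability only (`lambda_j(g) = lambda_j * (1 - delta *
#' max(0, g))`, floored at 0), emulating diminishing general-factor
#' saturation at high ability.
#'
#' Scores are affine-mapped to the scaled-score metric (mean 10, SD 3),
#' rounded to integers, and optionally floored/ceilinged.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @param battery a [battery_config()]; its subtests supply the loadings
#'   `lambda_j` and reliabilities `r_j`, its age bands the age range.
#' @param slodr_slope attenuation slope `delta >= 0`; default 0 (off).
#' @param score_floor,score_ceiling optional integer bounds on scaled scores
#'   (e.g. 1 and 19); `NULL` disables truncation.
#' @param prevalence named list of covariate parameters: `sex` (probability
#'   of female), `adhd`, `education` (Bernoulli prevalences), `language`
#'   (probabilities for monolingual/bilingual/other, summing to 1),
#'   `participation_cor` (correlation of the participation rating with `g`).
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects, seed, battery,
                       slodr_slope = 0,
                       score_floor = NULL, score_ceiling = NULL,
                       prevalence = list()) {
  stopifnot(n_subjects >= 1, slodr_slope >= 0)
  defaults <- list(sex = 0.5, adhd = 0.05, education = 0.30,
                   language = c(monolingual = 0.80, bilingual = 0.12,
                                other = 0.08),
                   participation_cor = 0.3)
  prevalence <- utils::modifyList(defaults, prevalence)
  probs <- unlist(prevalence[c("sex", "adhd", "education")])
  if (any(probs < 0 | probs > 1)) stopf("prevalences must lie in [0,1]")
  if (abs(sum(prevalence$language) - 1) > 1e-8)
    stopf("language category probabilities must sum to 1")
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 battery = battery, slodr_slope = slodr_slope,
                 score_floor = score_floor, score_ceiling = score_ceiling,
                 prevalence = prevalence),
            class = "sim_config")
}

#' Generate a synthetic standardization-like cohort
#'
#' Draws ages uniformly over the battery's age range, latent abilities and
#' subtest scaled scores from the one-factor model described in
#' [sim_config()], and demographic covariates from the configured
#' prevalences. Latent quantities (`g` and the unrounded true score
#' `true_<subtest>` of every subtest, i.e. the score free of measurement
#' error) are retained for oracle tests and flagged via the
#' `"latent_columns"` attribute; [write_cohort()] omits them by default.
#'
#' @param config a [sim_config()].
#' @return a data frame of class `"cohort_table"`: one row per subject with
#'   `id`, `age`, covariates, one column per subtest, and latent columns.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  battery <- config$battery
  n <- config$n_subjects
  set.seed(stage_seed(config$seed, "cohort"))

  bands <- battery$age_bands
  age <- stats::runif(n, min(bands$lower), max(bands$upper))
  g <- stats::rnorm(n)

  prev <- config$prevalence
  cohort <- data.frame(
    id = sprintf("S%05d", seq_len(n)),
    age = age,
    sex = stats::rbinom(n, 1L, prev$sex),
    adhd = stats::rbinom(n, 1L, prev$adhd),
    language = sample(names(prev$language), n, replace = TRUE,
                      prob = prev$language),
    education = stats::rbinom(n, 1L, prev$education),
    g = g,
    stringsAsFactors = FALSE
  )
  # participation rating on the scaled metric, weakly tied to ability
  pc <- prev$participation_cor
  cohort$participation <- as.integer(round_half_up(
    10 + 3 * (pc * g + sqrt(1 - pc^2) * stats::rnorm(n))))

  delta <- config$slodr_slope
  clamped <- 0L
  for (st in battery$subtests) {
    lam <- st$loading * (1 - delta * pmax(0, g))
    lam <- pmax(lam, 0)
    psi <- st$reliability - lam^2
    if (any(psi < 0)) {
      clamped <- clamped + sum(psi < 0)
      psi <- pmax(psi, 0)
    }
    theta <- 1 - st$reliability
    s <- stats::rnorm(n)
    e <- stats::rnorm(n)
    true <- lam * g + sqrt(psi) * s        # error-free part, kept as oracle
    x <- true + sqrt(theta) * e
    scaled <- round_half_up(10 + 3 * x)
    if (!is.null(config$score_floor)) scaled <- pmax(scaled, config$score_floor)
    if (!is.null(config$score_ceiling)) scaled <- pmin(scaled, config$score_ceiling)
    cohort[[st$name]] <- as.integer(scaled)
    cohort[[paste0("true_", st$name)]] <- 10 + 3 * true
  }
  if (clamped > 0)
    warnf("specific variance clamped to 0 for %d subject-subtest draws (SLODR slope %.2f)",
          clamped, delta)

  attr(cohort, "latent_columns") <-
    c("g", paste0("true_", names(battery$subtests)))
  attr(cohort, "battery") <- battery$name
  attr(cohort, "seed") <- config$seed
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

#' Attach school grades to a cohort
#'
#' Grades live on the Swiss 1-6 ladder in half-point steps, 6 best. Each
#' grade is `clip(round_to_half(4.5 + 0.8 * (gamma * g + sqrt(1 - gamma^2)
#' * eps)), 1, 6)` with independent standard normal `eps` per grade column,
#' so `gamma` is the generating validity (latent correlation between grades
#' and ability before rounding/clipping). Grades are generated for a random
#' subsample of subjects, emulating the partial return of grade
#' questionnaires.
#'
#' @param cohort a cohort from [generate_cohort()] (must retain latent `g`).
#' @param validity generating validity `gamma` in `[0, 1)`.
#' @param seed integer seed for the grade draws.
#' @param fraction fraction of subjects with grades (default 1).
#' @param subjects grade column names (default German, mathematics and two
#'   further subjects).
#' @return the cohort with `grade_*` columns appended (`NA` outside the
#'   graded subsample).
#' @export
generate_grades <- function(cohort, validity, seed, fraction = 1,
                            subjects = c("german", "math", "social", "science")) {
  stopifnot(validity >= 0, validity < 1, fraction > 0, fraction <= 1)
  if (!"g" %in% names(cohort))
    stopf("cohort lacks the latent ability column 'g'")
  set.seed(stage_seed(seed, "grades"))
  n <- nrow(cohort)
  graded <- sort(sample.int(n, size = max(1L, round(fraction * n))))
  for (subj in subjects) {
    eps <- stats::rnorm(length(graded))
    raw <- 4.5 + 0.8 * (validity * cohort$g[graded] +
                          sqrt(1 - validity^2) * eps)
    grade <- clip(round_half_up(raw * 2) / 2, 1, 6)
    col <- rep(NA_real_, n)
    col[graded] <- grade
    cohort[[paste0("grade_", subj)]] <- col
  }
  attr(cohort, "grade_validity") <- validity
  cohort
}
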