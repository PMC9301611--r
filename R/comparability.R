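z_value <- function(level) stats::qnorm((1 + level) / 2)

#' Estimated true score
#'
#' The regression-to-the-mean-adjusted score `100 + r * (X - 100)` on the IQ
#' metric: the best linear prediction of the true score given the observed
#' score and the score's reliability.
#'
#' @param iq observed IQ (vectorized).
#' @param r reliability in `(0, 1]`.
#' @return estimated true score(s), unrounded.
#' @export
estimated_true_score <- function(iq, r) {
  if (any(r <= 0 | r > 1)) stopf("reliability must be in (0,1]")
  100 + r * (iq - 100)
}

#' True-score confidence interval via the standard error of estimate
#'
#' The interval is centred on the estimated true score and uses the standard
#' error of estimate `SE_E = 15 * sqrt(r * (1 - r))` — the SD of observed
#' scores around the estimated true score — not the standard error of
#' measurement. Bounds are left unrounded; only reported widths are rounded
#' (see [ci_width_points()]).
#'
#' @param iq observed IQ (vectorized).
#' @param r reliability in `(0, 1]` (scalar or per-subject).
#' @param level confidence level in `(0, 1)`; default 0.95.
#' @return for scalar input a named numeric `c(lower, upper)`; otherwise a
#'   two-column matrix.
#' @export
true_score_ci <- function(iq, r, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (any(r <= 0 | r > 1)) stopf("reliability must be in (0,1]")
  t_hat <- estimated_true_score(iq, r)
  half <- z_value(level) * 15 * sqrt(r * (1 - r))
  if (length(iq) == 1L && length(r) == 1L)
    c(lower = t_hat - half, upper = t_hat + half)
  else
    cbind(lower = t_hat - half, upper = t_hat + half)
}

#' Width of the confidence interval in IQ points
#'
#' `2 * z * 15 * sqrt(r * (1 - r))` rounded half-up to an integer — the
#' "width of the 95% CI" a manual would print next to a reliability
#' coefficient.
#'
#' @param r reliability in `(0, 1]` (vectorized).
#' @param level confidence level; default 0.95.
#' @return integer width(s).
#' @export
ci_width_points <- function(r, level = 0.95) {
  if (any(r <= 0 | r > 1)) stopf("reliability must be in (0,1]")
  as.integer(round_half_up(2 * z_value(level) * 15 * sqrt(r * (1 - r))))
}

#' Do two closed intervals overlap?
#'
#' Intervals are inclusive: touching endpoints count as overlap.
#'
#' @param a,b numeric `c(lower, upper)` or two-column matrices (vectorized
#'   row-wise).
#' @return logical.
#' @export
intervals_overlap <- function(a, b) {
  a <- if (is.null(dim(a))) matrix(a, ncol = 2) else as.matrix(a)
  b <- if (is.null(dim(b))) matrix(b, ncol = 2) else as.matrix(b)
  if (any(a[, 1] > a[, 2]) || any(b[, 1] > b[, 2]))
    stopf("interval lower bound exceeds upper bound")
  out <- a[, 1] <= b[, 2] & b[, 1] <= a[, 2]
  unname(out)
}

#' Specify a comparability criterion
#'
#' Six rules decide whether two composite IQs are exchangeable for one
#' subject: `NomIQ` (identical nominal categories), `NomCI` (the nominal
#' category runs of the two overall-reliability CIs intersect), and four
#' CI-overlap rules differing only in which reliability coefficient builds
#' the intervals — `CI_overall` (overall internal consistency), `CI_age`
#' (age-band-specific), `CI_ageIQ` (age-band by IQ-group-specific, indexed
#' by each composite's own IQ), `CI_rtt` (test-retest).
#'
#' @param kind one of `"NomIQ"`, `"CI_overall"`, `"CI_age"`, `"NomCI"`,
#'   `"CI_rtt"`, `"CI_ageIQ"`.
#' @param level confidence level for the CI-based rules; default 0.95.
#' @return an object of class `"criterion_spec"`.
#' @export
criterion_spec <- function(kind = c("NomIQ", "CI_overall", "CI_age", "NomCI",
                                    "CI_rtt", "CI_ageIQ"),
                           level = 0.95) {
  kind <- match.arg(kind)
  structure(list(kind = kind, level = level), class = "criterion_spec")
}

# per-subject reliability vector for one composite under a CI criterion
criterion_reliability <- function(kind, lookup, composite, band, own_iq) {
  entry <- lookup$entries[[composite]]
  if (is.null(entry)) stopf("no reliability entry for composite '%s'", composite)
  n <- length(band)
  switch(kind,
    CI_overall = ,
    NomCI = rep(entry$overall, n),
    CI_rtt = rep(entry$retest %||% NA_real_, n),
    CI_age = {
      idx <- match(band, entry$age$band)
      entry$age$alpha[idx]
    },
    CI_ageIQ = {
      grp <- as.character(assign_iq_group(own_iq, "three"))
      key <- paste(band, grp)
      idx <- match(key, paste(entry$age_iq$band, entry$age_iq$iq_group))
      entry$age_iq$alpha[idx]
    },
    stopf("criterion '%s' does not use a reliability slice", kind))
}

# index range of nominal categories covered by CI bounds (vectorized)
category_range <- function(lower, upper) {
  cbind(first = as.integer(nominal_category(round_half_up(lower))),
        last = as.integer(nominal_category(round_half_up(upper))))
}

#' Evaluate one comparability criterion for paired IQs
#'
#' Vectorized over subjects. Subjects for whom a required reliability cell
#' is unavailable get `NA` (they are excluded from rates with a logged
#' count, never silently dropped).
#'
#' @param iq_a,iq_b integer IQ vectors for the two composites.
#' @param criterion a [criterion_spec()].
#' @param lookup a [build_reliability_lookup()] object (not needed for
#'   `NomIQ`).
#' @param composite_a,composite_b composite names in the lookup.
#' @param band age-band label per subject (needed for `CI_age`/`CI_ageIQ`).
#' @return logical vector of comparability flags.
#' @export
evaluate_criterion <- function(iq_a, iq_b, criterion, lookup = NULL,
                               composite_a = NULL, composite_b = NULL,
                               band = NULL) {
  stopifnot(inherits(criterion, "criterion_spec"),
            length(iq_a) == length(iq_b))
  kind <- criterion$kind
  if (kind == "NomIQ")
    return(as.integer(nominal_category(iq_a)) ==
             as.integer(nominal_category(iq_b)))

  band <- band %||% rep(NA_character_, length(iq_a))
  r_a <- criterion_reliability(kind, lookup, composite_a, band, iq_a)
  r_b <- criterion_reliability(kind, lookup, composite_b, band, iq_b)
  # a non-positive cell alpha (possible under severe range restriction) is
  # unusable for CI construction: treat the cell as unavailable
  r_a[!is.na(r_a) & (r_a <= 0 | r_a > 1)] <- NA_real_
  r_b[!is.na(r_b) & (r_b <= 0 | r_b > 1)] <- NA_real_
  ok <- !is.na(r_a) & !is.na(r_b)
  out <- rep(NA, length(iq_a))
  if (!any(ok)) return(out)

  half_a <- z_value(criterion$level) * 15 * sqrt(r_a[ok] * (1 - r_a[ok]))
  half_b <- z_value(criterion$level) * 15 * sqrt(r_b[ok] * (1 - r_b[ok]))
  ta <- estimated_true_score(iq_a[ok], r_a[ok])
  tb <- estimated_true_score(iq_b[ok], r_b[ok])
  if (kind == "NomCI") {
    ra_rng <- category_range(ta - half_a, ta + half_a)
    rb_rng <- category_range(tb - half_b, tb + half_b)
    out[ok] <- ra_rng[, "first"] <= rb_rng[, "last"] &
      rb_rng[, "first"] <= ra_rng[, "last"]
  } else {
    out[ok] <- intervals_overlap(cbind(ta - half_a, ta + half_a),
                                 cbind(tb - half_b, tb + half_b))
  }
  out
}

#' Compare two composites subject by subject
#'
#' Builds the pairwise comparison table: per subject the two IQs, the signed
#' and absolute difference, and one comparability flag column per requested
#' criterion.
#'
#' @param cohort cohort with `iq_<composite>` columns and `age`.
#' @param battery a [battery_config()].
#' @param pair character vector `c(a, b)` of composite names; the first is
#'   the reference composite used for IQ-group breakdowns (conventionally
#'   the one with more subtests).
#' @param lookup a [build_reliability_lookup()] object.
#' @param criteria list of [criterion_spec()]s, or character vector of
#'   criterion kinds; default all six.
#' @return a data frame of class `"pair_comparison"` with attributes `pair`
#'   and `excluded` (per-criterion count of subjects lacking a reliability
#'   cell).
#' @export
compare_composites <- function(cohort, battery, pair, lookup,
                               criteria = c("NomIQ", "CI_overall", "CI_age",
                                            "NomCI", "CI_rtt", "CI_ageIQ")) {
  stopifnot(length(pair) == 2L)
  if (is.character(criteria)) criteria <- lapply(criteria, criterion_spec)
  cols <- paste0("iq_", pair)
  missing <- setdiff(cols, names(cohort))
  if (length(missing))
    stopf("cohort lacks IQ columns: %s (run add_composite_iqs())",
          paste(missing, collapse = ", "))
  iq_a <- cohort[[cols[1]]]
  iq_b <- cohort[[cols[2]]]
  band <- battery$age_bands$label[age_band_index(cohort$age, battery)]
  out <- data.frame(id = cohort$id %||% seq_len(nrow(cohort)),
                    age = cohort$age, band = band,
                    iq_a = iq_a, iq_b = iq_b,
                    diff = iq_a - iq_b, abs_diff = abs(iq_a - iq_b),
                    stringsAsFactors = FALSE)
  excluded <- integer(0)
  for (cr in criteria) {
    flag <- evaluate_criterion(iq_a, iq_b, cr, lookup, pair[1], pair[2], band)
    out[[cr$kind]] <- flag
    excluded[cr$kind] <- sum(is.na(flag))
  }
  if (any(excluded > 0))
    message(sprintf("excluded subjects (unavailable reliability cells): %s",
                    paste(sprintf("%s=%d", names(excluded[excluded > 0]),
                                  excluded[excluded > 0]), collapse = ", ")))
  attr(out, "pair") <- pair
  attr(out, "excluded") <- excluded
  attr(out, "criteria") <- vapply(criteria, `[[`, "", "kind")
  class(out) <- c("pair_comparison", "data.frame")
  out
}

#' Comparability rates, overall and by group
#'
#' Percentage of subjects whose two IQs are comparable under a criterion,
#' overall and broken down by 6-level IQ group (on the reference composite,
#' the first of the pair) or by age band. Subjects with an `NA` flag
#' (unavailable reliability cell) are excluded from both numerator and
#' denominator; empty cells report `NA` with `n = 0`.
#'
#' @param pair a [compare_composites()] table.
#' @param criterion criterion kind (column name in `pair`).
#' @param grouping `"overall"`, `"iq"` (6-group scheme) or `"age"`.
#' @return data frame with `group`, `n`, `comparable`, `rate` (percent).
#' @export
comparability_rates <- function(pair, criterion,
                                grouping = c("overall", "iq", "age")) {
  grouping <- match.arg(grouping)
  if (!criterion %in% names(pair))
    stopf("criterion '%s' not present in the comparison table", criterion)
  flag <- pair[[criterion]]
  grp <- switch(grouping,
                overall = factor(rep("overall", nrow(pair))),
                iq = assign_iq_group(pair$iq_a, "six"),
                age = factor(pair$band, levels = unique(pair$band)))
  keep <- !is.na(flag)
  tab <- lapply(levels(grp), function(g) {
    sel <- keep & grp == g
    n <- sum(sel)
    data.frame(group = g, n = n, comparable = sum(flag[sel]),
               rate = if (n > 0) 100 * mean(flag[sel]) else NA_real_)
  })
  do.call(rbind, tab)
}

#' Moments of the intraindividual IQ differences
#'
#' Mean, median, range, skewness and excess kurtosis of the absolute and the
#' signed per-subject difference between the two composite IQs.
#'
#' @param pair a [compare_composites()] table (or any data frame with
#'   `diff` and `abs_diff` columns).
#' @return data frame with one row per quantity (`abs`, `signed`).
#' @export
abs_difference_summary <- function(pair) {
  stopifnot(nrow(pair) >= 1L)
  one <- function(x, label) data.frame(
    quantity = label, mean = mean(x), median = stats::median(x),
    min = min(x), max = max(x),
    skewness = moment_skewness(x), kurtosis = moment_kurtosis(x))
  rbind(one(pair$abs_diff, "abs"), one(pair$diff, "signed"))
}

#' Group-level agreement of two composites
#'
#' Paired t test on the signed differences, the paired-samples effect size
#' `d = t * sqrt(2 * (1 - r) / n)` (which accounts for the correlation
#' between the paired scores), the Pearson correlation, and the
#' disattenuated correlation given both composites' reliabilities.
#'
#' @param pair a [compare_composites()] table.
#' @param r_a,r_b reliabilities of the two composites for disattenuation.
#' @return list with `t`, `df`, `p`, `d`, `r`, `r_corr`, `mean_diff`, `n`.
#'   With zero difference variance, `t`, `p` and `d` are `NA` (undefined).
#' @export
group_level_comparison <- function(pair, r_a, r_b) {
  n <- nrow(pair)
  if (n < 3L) stopf("need at least 3 subjects")
  r <- stats::cor(pair$iq_a, pair$iq_b)
  r_corr <- disattenuate(r, r_a, r_b)
  if (stats::sd(pair$diff) == 0) {
    return(list(t = NA_real_, df = n - 1L, p = NA_real_, d = NA_real_,
                r = r, r_corr = r_corr, mean_diff = mean(pair$diff), n = n))
  }
  tt <- stats::t.test(pair$iq_a, pair$iq_b, paired = TRUE)
  t_stat <- unname(tt$statistic)
  list(t = t_stat, df = unname(tt$parameter), p = tt$p.value,
       d = dunlap_d(t_stat, r, n),
       r = r, r_corr = r_corr, mean_diff = mean(pair$diff), n = n)
}

#' Paired-samples effect size from the t statistic
#'
#' `d = t * sqrt(2 * (1 - r) / n)`: converts a paired t statistic into a
#' between-conditions standardized mean difference without letting the
#' pairing correlation inflate the effect.
#'
#' @param t paired t statistic.
#' @param r correlation between the paired scores.
#' @param n number of pairs.
#' @return Cohen's d for paired samples.
#' @export
dunlap_d <- function(t, r, n) t * sqrt(2 * (1 - r) / n)

#' Extremity ratio of a composite relative to its components
#'
#' For a fixed profile (every standardized component score equal), the
#' standardized composite score exceeds the mean standardized component
#' score by the factor `sqrt(k / (1 + (k - 1) * mean_rho))`: aggregation
#' cancels component-specific variance, so the composite sits further into
#' the tail than the average of its parts. Equals 1 for a single component
#' or perfectly correlated components.
#'
#' @param k number of components (>= 1).
#' @param mean_rho mean component intercorrelation in `(-1/(k-1), 1]`.
#' @return the ratio (>= 1 for `mean_rho <= 1`).
#' @export
extremity_ratio <- function(k, mean_rho) {
  stopifnot(k >= 1)
  denom <- 1 + (k - 1) * mean_rho
  if (denom <= 0) stopf("1 + (k-1)*mean_rho must be positive")
  sqrt(k / denom)
}
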