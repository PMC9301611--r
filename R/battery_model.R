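#' Declare a subtest of an intelligence battery
#'
#' A subtest is the smallest scored unit of a battery. Scores are assumed to
#' be age-normed scaled scores with mean 10 and SD 3. The general-factor
#' loading and the reliability describe the subtest's behaviour in the
#' standardization population and drive both the synthetic cohort generator
#' and the reliability algebra.
#'
#' @param name subtest identifier (column name in cohort tables).
#' @param ability Cattell-Horn-Carroll broad-ability code the subtest taps
#'   (e.g. `"Gf"`, `"Gc"`, `"Gsm"`, `"Gv"`, `"Glr"`, `"Gs"`, `"Gq"`).
#'   Compared by string equality; any label is accepted.
#' @param loading general-factor loading in `[0, 1]`.
#' @param reliability internal consistency in `(0, 1]`. Must satisfy
#'   `loading^2 <= reliability`: common variance cannot exceed true-score
#'   variance.
#' @param retest optional test-retest coefficient in `(0, 1]`.
#' @return an object of class `"subtest_spec"`.
#' @export
subtest_spec <- function(name, ability, loading, reliability, retest = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(ability), length(ability) == 1L)
  if (loading < 0 || loading > 1) stopf("loading for '%s' must be in [0,1]", name)
  if (reliability <= 0 || reliability > 1)
    stopf("reliability for '%s' must be in (0,1]", name)
  if (loading^2 > reliability + 1e-12)
    stopf("subtest '%s': loading^2 (%.3f) exceeds reliability (%.3f)",
          name, loading^2, reliability)
  if (!is.null(retest) && (retest <= 0 || retest > 1))
    stopf("retest for '%s' must be in (0,1]", name)
  structure(list(name = name, ability = ability, loading = loading,
                 reliability = reliability, retest = retest),
            class = "subtest_spec")
}

#' Declare a composite (general intelligence composite, GIC)
#'
#' A composite is a unit-weighted sum of member subtest scaled scores, normed
#' to the IQ metric (mean 100, SD 15) within age bands and clipped to a
#' battery-specific floor/ceiling.
#'
#' @param name composite identifier.
#' @param members character vector of member subtest names (k >= 1).
#' @param clip_range inclusive IQ bounds for floor/ceiling; default `c(55, 145)`.
#' @param retest optional composite test-retest coefficient in `(0, 1]`.
#' @return an object of class `"composite_spec"`.
#' @export
composite_spec <- function(name, members, clip_range = c(55, 145), retest = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(members) < 1L) stopf("composite '%s' has no members", name)
  stopifnot(length(clip_range) == 2L)
  if (clip_range[1] >= clip_range[2])
    stopf("composite '%s': clip_range lower must be < upper", name)
  if (!is.null(retest) && (retest <= 0 || retest > 1))
    stopf("retest for '%s' must be in (0,1]", name)
  structure(list(name = name, members = as.character(members),
                 clip_range = as.numeric(clip_range), retest = retest),
            class = "composite_spec")
}

#' Declare a test battery
#'
#' Bundles subtests, composites and the age bands used for norming.
#' Age bands are half-open `[lower, upper)` intervals in years, except the
#' last band which includes its upper bound; they must be ordered,
#' non-overlapping and exhaustive over the battery's age range.
#'
#' @param name battery identifier.
#' @param subtests list of [subtest_spec()] objects.
#' @param composites list of [composite_spec()] objects; all members must
#'   resolve to declared subtests.
#' @param age_bands list of length-2 numeric vectors `c(lower, upper)`.
#' @return an object of class `"battery_config"`.
#' @export
battery_config <- function(name, subtests, composites, age_bands) {
  stopifnot(is.list(subtests), is.list(composites), is.list(age_bands))
  sub_names <- vapply(subtests, `[[`, "", "name")
  if (anyDuplicated(sub_names)) stopf("duplicate subtest names")
  for (cmp in composites) {
    missing <- setdiff(cmp$members, sub_names)
    if (length(missing))
      stopf("composite '%s' references unknown subtests: %s",
            cmp$name, paste(missing, collapse = ", "))
  }
  bands <- do.call(rbind, lapply(age_bands, function(b) {
    stopifnot(length(b) == 2L, b[1] < b[2])
    data.frame(lower = b[1], upper = b[2])
  }))
  bands <- bands[order(bands$lower), , drop = FALSE]
  if (nrow(bands) > 1L && any(abs(bands$upper[-nrow(bands)] - bands$lower[-1]) > 1e-9))
    stopf("age bands must be contiguous (no gaps or overlaps)")
  bands$label <- paste0(bands$lower, "-", bands$upper)
  structure(list(name = name,
                 subtests = stats::setNames(subtests, sub_names),
                 composites = stats::setNames(
                   composites, vapply(composites, `[[`, "", "name")),
                 age_bands = bands),
            class = "battery_config")
}

#' @export
print.battery_config <- function(x, ...) {
  cat(sprintf("<battery_config> %s: %d subtests, %d composites, %d age bands\n",
              x$name, length(x$subtests), length(x$composites),
              nrow(x$age_bands)))
  for (cmp in x$composites)
    cat(sprintf("  %s (k=%d): %s\n", cmp$name, length(cmp$members),
                paste(cmp$members, collapse = ", ")))
  invisible(x)
}

get_composite <- function(battery, composite) {
  if (inherits(composite, "composite_spec")) return(composite)
  cmp <- battery$composites[[composite]]
  if (is.null(cmp)) stopf("unknown composite '%s' in battery '%s'",
                          composite, battery$name)
  cmp
}

#' Index of the age band containing each age
#'
#' @param age numeric vector of ages in years.
#' @param battery a [battery_config()].
#' @return integer vector of band indices (`NA` for out-of-range ages).
#' @export
age_band_index <- function(age, battery) {
  bands <- battery$age_bands
  idx <- findInterval(age, c(bands$lower, bands$upper[nrow(bands)]),
                      rightmost.closed = TRUE)
  idx[idx < 1L | idx > nrow(bands)] <- NA_integer_
  idx
}

composite_sum <- function(cohort, composite) {
  missing <- setdiff(composite$members, names(cohort))
  if (length(missing))
    stopf("cohort lacks subtest columns: %s", paste(missing, collapse = ", "))
  rowSums(as.matrix(cohort[composite$members]))
}

#' Build a norm table from a reference cohort
#'
#' For every (composite, age band) cell, stores the mean and SD (n-1
#' denominator) of the unit-weighted sum of member scaled scores in the
#' reference cohort. These norms map raw composite sums onto the IQ metric.
#'
#' @param cohort a cohort data frame with an `age` column and one column per
#'   subtest scaled score.
#' @param battery a [battery_config()].
#' @return a data frame of class `"norm_table"` with columns `composite`,
#'   `band`, `mean`, `sd`, `n`.
#' @export
build_norm_table <- function(cohort, battery) {
  stopifnot("age" %in% names(cohort))
  idx <- age_band_index(cohort$age, battery)
  if (anyNA(idx)) stopf("%d subjects fall outside the battery age range",
                        sum(is.na(idx)))
  rows <- list()
  for (cmp in battery$composites) {
    s <- composite_sum(cohort, cmp)
    for (b in seq_len(nrow(battery$age_bands))) {
      cell <- s[idx == b & !is.na(s)]
      lbl <- battery$age_bands$label[b]
      if (length(cell) < 2L)
        stopf("norming cell (%s, %s) has fewer than 2 complete subjects",
              cmp$name, lbl)
      sdv <- stats::sd(cell)
      if (sdv <= 0)
        stopf("norming cell (%s, %s) has zero variance", cmp$name, lbl)
      rows[[length(rows) + 1L]] <- data.frame(
        composite = cmp$name, band = lbl, mean = mean(cell), sd = sdv,
        n = length(cell))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("norm_table", "data.frame")
  out
}

norm_cell <- function(norms, composite_name, band_label) {
  row <- norms[norms$composite == composite_name & norms$band == band_label, ]
  if (nrow(row) != 1L)
    stopf("norm table has no cell for (%s, %s)", composite_name, band_label)
  row
}

#' Composite IQ from subtest scaled scores
#'
#' The unit-weighted sum of member scaled scores is standardized against the
#' norm-table cell for the subject's age band, placed on the IQ metric
#' (mean 100, SD 15), rounded half-up to an integer, and clipped to the
#' composite's floor/ceiling range.
#'
#' @param scores named numeric vector of subtest scaled scores (must contain
#'   every member; missing members are an error, no imputation is done).
#' @param composite a [composite_spec()] or composite name.
#' @param norms a norm table from [build_norm_table()].
#' @param age age in years (must fall in some band).
#' @param battery the [battery_config()] owning the composite.
#' @return integer IQ.
#' @export
compute_composite_iq <- function(scores, composite, norms, age, battery) {
  cmp <- get_composite(battery, composite)
  missing <- setdiff(cmp$members, names(scores))
  if (length(missing) || anyNA(scores[cmp$members]))
    stopf("missing member score(s) for composite '%s'", cmp$name)
  b <- age_band_index(age, battery)
  if (is.na(b)) stopf("age %.2f outside battery age range", age)
  cell <- norm_cell(norms, cmp$name, battery$age_bands$label[b])
  s <- sum(scores[cmp$members])
  iq <- round_half_up(100 + 15 * (s - cell$mean) / cell$sd)
  as.integer(clip(iq, cmp$clip_range[1], cmp$clip_range[2]))
}

#' Add composite IQ columns to a cohort
#'
#' Vectorized convenience wrapper around the same arithmetic as
#' [compute_composite_iq()]: adds one `iq_<composite>` integer column per
#' requested composite.
#'
#' @param cohort cohort data frame.
#' @param battery a [battery_config()].
#' @param norms a norm table from [build_norm_table()].
#' @param composites character vector of composite names (default: all).
#' @return the cohort with `iq_*` columns appended.
#' @export
add_composite_iqs <- function(cohort, battery, norms,
                              composites = names(battery$composites)) {
  idx <- age_band_index(cohort$age, battery)
  labels <- battery$age_bands$label[idx]
  for (nm in composites) {
    cmp <- get_composite(battery, nm)
    s <- composite_sum(cohort, cmp)
    mu <- sig <- numeric(length(s))
    for (b in unique(labels)) {
      cell <- norm_cell(norms, cmp$name, b)
      sel <- labels == b
      mu[sel] <- cell$mean
      sig[sel] <- cell$sd
    }
    iq <- round_half_up(100 + 15 * (s - mu) / sig)
    cohort[[paste0("iq_", nm)]] <-
      as.integer(clip(iq, cmp$clip_range[1], cmp$clip_range[2]))
  }
  cohort
}

# nominal category boundaries on the integer IQ line
.nominal_levels <- c("lower_extreme", "below_average", "average",
                     "above_average", "upper_extreme")
.nominal_upper <- c(69, 84, 115, 130, Inf)

#' Nominal IQ category
#'
#' The conventional qualitative labels: `<70` lower extreme, `70-84` below
#' average, `85-115` average, `116-130` above average, `>130` upper extreme.
#'
#' @param iq integer IQ vector.
#' @return ordered factor over the five categories.
#' @export
nominal_category <- function(iq) {
  i <- findInterval(iq, c(-Inf, .nominal_upper) + 0.5)
  factor(.nominal_levels[i], levels = .nominal_levels, ordered = TRUE)
}

#' Nominal categories intersected by an IQ interval
#'
#' Bounds are rounded half-up to integers first (categories are defined on
#' the integer IQ line); the result is the contiguous run of categories the
#' rounded interval touches. For example an interval of 112 to 120 spans
#' average to above average.
#'
#' @param interval numeric `c(lower, upper)` with `lower <= upper`.
#' @return ordered factor of the categories covered.
#' @export
interval_to_categories <- function(interval) {
  stopifnot(length(interval) == 2L, interval[1] <= interval[2])
  lo <- round_half_up(interval[1])
  hi <- round_half_up(interval[2])
  i <- as.integer(nominal_category(lo))
  j <- as.integer(nominal_category(hi))
  factor(.nominal_levels[i:j], levels = .nominal_levels, ordered = TRUE)
}

#' Assign IQ group labels
#'
#' Two partitions of the IQ line used for group breakdowns: a 3-group scheme
#' (`<85` below average, `85-115` average, `>115` above average) and a
#' 6-group scheme (`<70`, `70-84`, `85-99`, `100-114`, `115-129`, `>=130`).
#'
#' @param iq integer IQ vector.
#' @param scheme `"three"` or `"six"`.
#' @return factor of group labels.
#' @export
assign_iq_group <- function(iq, scheme = c("three", "six")) {
  scheme <- match.arg(scheme)
  if (scheme == "three") {
    lev <- c("below_average", "average", "above_average")
    i <- findInterval(iq, c(-Inf, 84, 115) + 0.5)
    factor(lev[i], levels = lev)
  } else {
    lev <- c("<70", "70-84", "85-99", "100-114", "115-129", ">=130")
    i <- findInterval(iq, c(-Inf, 69, 84, 99, 114, 129) + 0.5)
    factor(lev[i], levels = lev)
  }
}

#' Content overlap between two composites (percent)
#'
#' The number of subtests, in either composite, tapping a broad ability that
#' both composites tap, divided by the total number of subtests over both
#' composites, times 100, rounded half-up to an integer. Identical ability
#' profiles give 100.
#'
#' @param battery a [battery_config()].
#' @param a,b composite names or [composite_spec()] objects.
#' @return integer percent in `[0, 100]`.
#' @export
content_overlap <- function(battery, a, b) {
  a <- get_composite(battery, a)
  b <- get_composite(battery, b)
  ability <- function(cmp)
    vapply(battery$subtests[cmp$members], `[[`, "", "ability")
  ab_a <- ability(a)
  ab_b <- ability(b)
  shared <- intersect(unique(ab_a), unique(ab_b))
  pct <- 100 * (sum(ab_a %in% shared) + sum(ab_b %in% shared)) /
    (length(ab_a) + length(ab_b))
  as.integer(round_half_up(pct))
}

#' Grade point average
#'
#' Arithmetic mean of all reported (non-missing) grades per subject, on the
#' 1 (lowest) to 6 (highest) grade scale. Subjects with no grades get `NA`,
#' never zero.
#'
#' @param grades data frame or matrix of grade columns (one row per subject),
#'   values in `[1, 6]` or `NA`.
#' @return numeric vector of per-subject means.
#' @export
gpa <- function(grades) {
  g <- as.matrix(grades)
  if (any(g < 1 | g > 6, na.rm = TRUE))
    stopf("grades must lie in [1, 6]")
  out <- rowMeans(g, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}
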