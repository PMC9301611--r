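#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(var_j) / var_total)` with sample variances
#' (n-1 denominator). Scale-free: invariant under affine rescaling of any
#' component column.
#'
#' @param score_matrix numeric matrix or data frame, subjects x components
#'   (k >= 2 columns, >= 3 rows).
#' @return the alpha coefficient.
#' @export
cronbach_alpha <- function(score_matrix) {
  m <- as.matrix(score_matrix)
  if (ncol(m) < 2L) stopf("alpha needs at least 2 components")
  if (nrow(m) < 3L) stopf("alpha needs at least 3 subjects")
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) stopf("total score has zero variance")
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Composite reliability from component reliabilities and covariances
#'
#' The classical formula for the reliability of a unit-weighted sum of
#' components with known reliabilities:
#' `r_C = 1 - sum(sigma2_j * (1 - r_j)) / sigma2_C`, where `sigma2_C` is the
#' sum of all entries of the component covariance matrix. For k parallel
#' standardized components (equal `r`, equal intercorrelation `rho = r`)
#' this reduces to the Spearman-Brown stepped-up value `k*r / (1 + (k-1)*r)`.
#'
#' @param component_reliabilities numeric vector `r_j` in `(0, 1]`.
#' @param component_covariances symmetric covariance matrix of the
#'   components (positive diagonal), same order and length.
#' @return the composite reliability coefficient.
#' @export
composite_reliability <- function(component_reliabilities,
                                  component_covariances) {
  r <- component_reliabilities
  v <- as.matrix(component_covariances)
  if (length(r) != nrow(v) || nrow(v) != ncol(v))
    stopf("reliability vector and covariance matrix sizes do not match")
  if (any(r <= 0 | r > 1)) stopf("component reliabilities must be in (0,1]")
  if (any(diag(v) <= 0)) stopf("component variances must be positive")
  if (max(abs(v - t(v))) > 1e-8) stopf("covariance matrix must be symmetric")
  sigma2_c <- sum(v)
  if (sigma2_c <= 0) stopf("composite variance is non-positive")
  1 - sum(diag(v) * (1 - r)) / sigma2_c
}

#' Correct a correlation for unreliability of both measures
#'
#' Disattenuation: `r / sqrt(r_a * r_b)`. Values exceeding 1 in magnitude
#' (possible with sample coefficients) are capped at +/-1 with a warning.
#'
#' @param r observed Pearson correlation in `[-1, 1]`.
#' @param r_a,r_b reliabilities of the two measures, in `(0, 1]`.
#' @return the disattenuated correlation.
#' @export
disattenuate <- function(r, r_a, r_b) {
  if (r_a <= 0 || r_b <= 0 || r_a > 1 || r_b > 1)
    stopf("reliabilities must be in (0,1]")
  if (abs(r) > 1) stopf("correlation must be in [-1,1]")
  out <- r / sqrt(r_a * r_b)
  if (abs(out) > 1) {
    warnf("disattenuated correlation %.3f capped at %d", out, sign(out))
    out <- sign(out)
  }
  out
}

#' Age- and IQ-group-specific alphas for a composite
#'
#' Splits the cohort into (age band x 3-level IQ group) cells — the IQ group
#' is taken from the composite's own observed IQ column — and computes
#' Cronbach's alpha over the member subtests within each cell, plus
#' age-band-only alphas and the overall alpha. Cells with fewer than
#' `min_cell` subjects are reported as unavailable (`NA`) rather than as
#' unstable estimates; a cell whose alpha computation fails (e.g. zero
#' variance) is likewise `NA` without aborting other cells.
#'
#' @param cohort cohort with subtest columns and an `iq_<composite>` column
#'   (see [add_composite_iqs()]).
#' @param composite composite name or [composite_spec()].
#' @param battery a [battery_config()].
#' @param min_cell minimum subjects per cell (default 30).
#' @return list with `overall` (alpha), `age` (data frame band/alpha/n) and
#'   `age_iq` (data frame band/iq_group/alpha/n).
#' @export
groupwise_reliability <- function(cohort, composite, battery, min_cell = 30L) {
  cmp <- get_composite(battery, composite)
  iq_col <- paste0("iq_", cmp$name)
  if (!iq_col %in% names(cohort))
    stopf("cohort lacks column '%s'; run add_composite_iqs() first", iq_col)
  m <- as.matrix(cohort[cmp$members])
  band <- battery$age_bands$label[age_band_index(cohort$age, battery)]
  group <- assign_iq_group(cohort[[iq_col]], "three")

  cell_alpha <- function(sel) {
    if (sum(sel) < max(min_cell, 3L)) return(c(NA_real_, sum(sel)))
    a <- tryCatch(cronbach_alpha(m[sel, , drop = FALSE]),
                  error = function(e) NA_real_)
    c(a, sum(sel))
  }

  age_rows <- lapply(battery$age_bands$label, function(b) {
    res <- cell_alpha(band == b)
    data.frame(band = b, alpha = res[1], n = res[2])
  })
  age_iq_rows <- list()
  for (b in battery$age_bands$label) {
    for (gme in levels(group)) {
      res <- cell_alpha(band == b & group == gme)
      age_iq_rows[[length(age_iq_rows) + 1L]] <-
        data.frame(band = b, iq_group = gme, alpha = res[1], n = res[2])
    }
  }
  list(overall = cronbach_alpha(m),
       age = do.call(rbind, age_rows),
       age_iq = do.call(rbind, age_iq_rows))
}

#' Assemble a reliability lookup for comparability criteria
#'
#' A reliability lookup holds, per composite, every coefficient the six
#' comparability criteria can request: the overall internal consistency,
#' age-band-specific coefficients, (age band x 3-level IQ group)
#' coefficients, and the test-retest coefficient. Coefficients may be
#' estimated from a cohort (Cronbach's alpha via
#' [groupwise_reliability()]) or supplied externally (e.g. hand-entered
#' manual values) through `overrides`; retest coefficients always come from
#' the composite specs since a single-session cohort cannot estimate them.
#'
#' @param cohort cohort with subtest and `iq_*` columns, or `NULL` if every
#'   coefficient is supplied via `overrides`.
#' @param battery a [battery_config()].
#' @param composites composite names (default all).
#' @param min_cell minimum cell size for group-specific alphas.
#' @param overrides optional named list, per composite, of lists with any of
#'   `overall`, `retest`, `age` (data frame band/alpha), `age_iq` (data
#'   frame band/iq_group/alpha) replacing the estimated values.
#' @return an object of class `"reliability_lookup"`.
#' @export
build_reliability_lookup <- function(cohort, battery,
                                     composites = names(battery$composites),
                                     min_cell = 30L, overrides = list()) {
  entries <- list()
  for (nm in composites) {
    cmp <- get_composite(battery, nm)
    est <- if (!is.null(cohort))
      groupwise_reliability(cohort, cmp, battery, min_cell)
    else
      list(overall = NA_real_,
           age = data.frame(band = battery$age_bands$label, alpha = NA_real_,
                            n = 0L),
           age_iq = expand.grid(band = battery$age_bands$label,
                                iq_group = levels(assign_iq_group(100, "three")),
                                stringsAsFactors = FALSE))
    if (is.null(est$age_iq$alpha)) est$age_iq$alpha <- NA_real_
    ov <- overrides[[nm]] %||% list()
    entry <- list(overall = ov$overall %||% est$overall,
                  retest = ov$retest %||% cmp$retest,
                  age = ov$age %||% est$age,
                  age_iq = ov$age_iq %||% est$age_iq)
    entries[[nm]] <- entry
  }
  structure(list(entries = entries, min_cell = min_cell,
                 battery = battery$name),
            class = "reliability_lookup")
}

#' Fetch a reliability coefficient from a lookup
#'
#' @param lookup a [build_reliability_lookup()] object.
#' @param composite composite name.
#' @param slice one of `"overall"`, `"retest"`, `"age"`, `"age_iq"`.
#' @param band age-band label (for `"age"` and `"age_iq"`).
#' @param iq_group 3-level IQ group label (for `"age_iq"`).
#' @return the coefficient, or `NA` if the cell is unavailable.
#' @export
lookup_reliability <- function(lookup, composite,
                               slice = c("overall", "retest", "age", "age_iq"),
                               band = NULL, iq_group = NULL) {
  slice <- match.arg(slice)
  entry <- lookup$entries[[composite]]
  if (is.null(entry)) stopf("no reliability entry for composite '%s'", composite)
  switch(slice,
    overall = entry$overall,
    retest = entry$retest %||% NA_real_,
    age = {
      row <- entry$age[entry$age$band == band, ]
      if (nrow(row) != 1L) NA_real_ else row$alpha
    },
    age_iq = {
      row <- entry$age_iq[entry$age_iq$band == band &
                            entry$age_iq$iq_group == iq_group, ]
      if (nrow(row) != 1L) NA_real_ else row$alpha
    })
}
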