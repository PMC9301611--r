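# Cohort and configuration readers/writers. Dialect is fixed: comma
# separator, UTF-8, period decimal mark, empty string = missing.

#' Write a battery configuration to YAML
#'
#' @param battery a [battery_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_battery_config <- function(battery, path) {
  cfg <- list(
    name = battery$name,
    subtests = lapply(unname(battery$subtests), function(s)
      Filter(Negate(is.null), s[c("name", "ability", "loading",
                                  "reliability", "retest")])),
    composites = lapply(unname(battery$composites), function(cmp)
      Filter(Negate(is.null), list(name = cmp$name, members = cmp$members,
                                   clip_range = cmp$clip_range,
                                   retest = cmp$retest))),
    age_bands = lapply(seq_len(nrow(battery$age_bands)), function(i)
      c(battery$age_bands$lower[i], battery$age_bands$upper[i])))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a battery configuration from YAML
#'
#' @param path YAML file written by [write_battery_config()] or by hand,
#'   with `name`, `subtests`, `composites` and `age_bands` keys.
#' @return a validated [battery_config()].
#' @export
read_battery_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("name", "subtests", "composites", "age_bands"))
    if (is.null(cfg[[key]])) stopf("battery config lacks key '%s'", key)
  subtests <- lapply(cfg$subtests, function(s)
    subtest_spec(s$name, s$ability, s$loading, s$reliability, s$retest))
  composites <- lapply(cfg$composites, function(cmp)
    composite_spec(cmp$name, unlist(cmp$members),
                   clip_range = unlist(cmp$clip_range %||% c(55, 145)),
                   retest = cmp$retest))
  battery_config(cfg$name, subtests, composites,
                 lapply(cfg$age_bands, unlist))
}

#' Write a cohort table to delimited text
#'
#' Comma-separated, UTF-8, missing values as empty strings. Latent columns
#' (the generating ability and the error-free subtest scores) are dropped
#' by default since a real standardization export would not contain them; a
#' YAML provenance sidecar (`<path>.provenance.yml`) records the seed and
#' battery so a run can be reproduced.
#'
#' @param cohort a cohort data frame.
#' @param path output file.
#' @param drop_latent drop latent columns (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, drop_latent = TRUE) {
  out <- as.data.frame(cohort)
  if (drop_latent) {
    latent <- intersect(attr(cohort, "latent_columns") %||% character(),
                        names(out))
    out <- out[setdiff(names(out), latent)]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  prov <- Filter(Negate(is.null),
                 list(seed = attr(cohort, "seed"),
                      battery = attr(cohort, "battery"),
                      n = nrow(cohort)))
  if (length(prov))
    yaml::write_yaml(prov, paste0(path, ".provenance.yml"))
  invisible(path)
}

#' Read a cohort table from delimited text
#'
#' Validates the schema against the battery: every subtest column must be
#' present and numeric; grades, if present, must lie on the 1-6 scale.
#' Errors name the offending column and row. Missing values (empty cells)
#' are preserved as `NA`.
#'
#' @param path CSV file with a header row, one row per subject.
#' @param battery a [battery_config()] naming the expected subtest columns.
#' @return a data frame of class `"cohort_table"`.
#' @export
read_cohort <- function(path, battery) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing <- setdiff(names(battery$subtests), names(raw))
  if (length(missing))
    stopf("cohort file lacks subtest column(s): %s",
          paste(missing, collapse = ", "))
  if (!"age" %in% names(raw)) stopf("cohort file lacks an 'age' column")
  for (col in names(battery$subtests)) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stopf("column '%s' is not numeric (first bad row: %d)",
            col, if (length(bad)) bad[1] else NA_integer_)
    }
  }
  for (col in grep("^grade_", names(raw), value = TRUE)) {
    bad <- which(!is.na(raw[[col]]) & (raw[[col]] < 1 | raw[[col]] > 6))
    if (length(bad))
      stopf("grade column '%s' outside [1,6] at row %d", col, bad[1])
  }
  message(sprintf("read %d subjects from %s", nrow(raw), path))
  class(raw) <- c("cohort_table", "data.frame")
  raw
}
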