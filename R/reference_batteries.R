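#' Reference battery configurations
#'
#' Ships declarative descriptions of three widely used intelligence test
#' batteries as they matter for composite comparability: an extended
#' battery with 14 subtests (two per profile ability) offering an extended
#' IQ (`ebiq`, all 14), a full-scale IQ (`fsiq`, one subtest per ability)
#' and a two-subtest screening IQ (`abiq`, the fluid-reasoning and verbal
#' subtests); a ten-subtest battery with verbal/nonverbal subtests for five
#' broad abilities (`fsiq` all ten, `abiq` the two routing subtests); and a
#' four-subtest battery with two verbal (Gc) and two nonverbal (Gf)
#' subtests (`fsiq` all four, `abiq` one of each).
#'
#' Composite test-retest coefficients and the published overall internal
#' consistencies (see [published_reliabilities()]) are taken from the
#' publicly printed manual summaries; subtest general-factor loadings and
#' reliabilities are synthetic stand-ins for simulation only (the item-level
#' norm data are proprietary). The visuospatial short-term-memory subtests
#' are mapped to Gsm alongside the auditory ones — an assumption, since
#' published ability profiles list the memory domains jointly; content
#' overlap between the shipped composites does not depend on it.
#'
#' @return named list of three [battery_config()] objects: `ids2`, `sb5`,
#'   `rias`.
#' @export
reference_batteries <- function() {
  st <- function(name, ability, loading = 0.70)
    subtest_spec(name, ability, loading = loading, reliability = 0.85)

  ids2 <- battery_config(
    name = "ids2",
    subtests = list(
      st("vp1", "Gv"), st("vp2", "Gv"),
      st("ps1", "Gs", 0.60), st("ps2", "Gs", 0.60),
      st("asm1", "Gsm"), st("asm2", "Gsm"),
      st("vsm1", "Gsm"), st("vsm2", "Gsm"),
      st("ltm1", "Glr"), st("ltm2", "Glr"),
      st("ar1", "Gf", 0.75), st("ar2", "Gf", 0.75),
      st("vr1", "Gc", 0.75), st("vr2", "Gc", 0.75)),
    composites = list(
      composite_spec("ebiq", c("vp1", "vp2", "ps1", "ps2", "asm1", "asm2",
                               "vsm1", "vsm2", "ltm1", "ltm2", "ar1", "ar2",
                               "vr1", "vr2"),
                     clip_range = c(55, 145), retest = 0.85),
      composite_spec("fsiq", c("vp1", "ps1", "asm1", "vsm1", "ltm1", "ar1",
                               "vr1"),
                     clip_range = c(55, 145), retest = 0.89),
      composite_spec("abiq", c("ar1", "vr1"),
                     clip_range = c(55, 145), retest = 0.86)),
    age_bands = list(c(5, 7), c(7, 9), c(9, 13), c(13, 16), c(16, 21)))

  sb5 <- battery_config(
    name = "sb5",
    subtests = list(
      st("fr_nv", "Gf", 0.75), st("fr_v", "Gf", 0.75),
      st("kn_nv", "Gc", 0.75), st("kn_v", "Gc", 0.75),
      st("qr_nv", "Gq"), st("qr_v", "Gq"),
      st("vs_nv", "Gv"), st("vs_v", "Gv"),
      st("wm_nv", "Gsm"), st("wm_v", "Gsm")),
    composites = list(
      composite_spec("fsiq", c("fr_nv", "fr_v", "kn_nv", "kn_v", "qr_nv",
                               "qr_v", "vs_nv", "vs_v", "wm_nv", "wm_v"),
                     clip_range = c(55, 145), retest = 0.94),
      composite_spec("abiq", c("fr_nv", "kn_v"),
                     clip_range = c(55, 145), retest = 0.86)),
    age_bands = list(c(4, 7), c(7, 9), c(9, 13), c(13, 16), c(16, 21),
                     c(21, 30), c(30, 60), c(60, 84)))

  rias <- battery_config(
    name = "rias",
    subtests = list(
      st("guess_what", "Gc", 0.75), st("verbal_reasoning", "Gc", 0.75),
      st("odd_item_out", "Gf", 0.75), st("whats_missing", "Gf", 0.70)),
    composites = list(
      composite_spec("fsiq", c("guess_what", "verbal_reasoning",
                               "odd_item_out", "whats_missing"),
                     clip_range = c(45, 160), retest = 0.88),
      composite_spec("abiq", c("guess_what", "odd_item_out"),
                     clip_range = c(40, 160), retest = 0.87)),
    age_bands = list(c(3, 5), c(5, 7), c(7, 9), c(9, 13), c(13, 16),
                     c(16, 21), c(21, 60), c(60, 100)))

  list(ids2 = ids2, sb5 = sb5, rias = rias)
}

#' Published overall reliabilities for the reference composites
#'
#' Overall internal consistencies as printed in the batteries' manual
#' summaries, shaped as the `overrides` argument of
#' [build_reliability_lookup()] for reproduction runs that should use
#' published rather than cohort-estimated coefficients.
#'
#' @return named list (battery) of named lists (composite) with `overall`
#'   coefficients.
#' @export
published_reliabilities <- function() {
  list(
    ids2 = list(ebiq = list(overall = 0.98),
                fsiq = list(overall = 0.97),
                abiq = list(overall = 0.95)),
    sb5 = list(fsiq = list(overall = 0.99),
               abiq = list(overall = 0.97)),
    rias = list(fsiq = list(overall = 0.95),
                abiq = list(overall = 0.93)))
}

#' Composite pairs conventionally compared within each reference battery
#'
#' Each pair is ordered with the larger composite first (it serves as the
#' reference for IQ-group breakdowns).
#'
#' @return named list (battery) of character-pair lists.
#' @export
reference_pairs <- function() {
  list(ids2 = list(c("ebiq", "fsiq"), c("fsiq", "abiq"), c("ebiq", "abiq")),
       sb5 = list(c("fsiq", "abiq")),
       rias = list(c("fsiq", "abiq")))
}
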