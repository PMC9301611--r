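# Internal helpers shared across modules.

#' Round half away from zero ("half-up" on the positive line)
#'
#' Base `round()` rounds half to even; reported IQ points, CI widths and
#' percent overlaps in this package round .5 upward instead, matching how
#' practitioners report integer scores.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
#' @noRd
round_half_up <- function(x) {
  trunc(abs(x) + 0.5) * sign(x)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-stage seed derived from a root seed, so adding a
# pipeline stage never perturbs another stage's draws
stage_seed <- function(root, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root) * 131 + h) %% 2147483587L) + 1L
}

# sample skewness and excess kurtosis (moment estimators)
moment_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((x - m)^3) / s2^1.5
}

moment_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((x - m)^4) / s2^2 - 3
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
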