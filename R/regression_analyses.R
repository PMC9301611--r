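#' Standardized simple regression of grades on an IQ composite
#'
#' Both variables are z-scored, so the slope is the standardized beta and
#' equals the Pearson correlation; `R^2 = beta^2`. The beta's confidence
#' interval uses the t distribution with n-2 degrees of freedom on the
#' slope's standard error.
#'
#' @param grades numeric outcome vector (missing values dropped pairwise).
#' @param iq numeric predictor vector, same length.
#' @param level confidence level; default 0.95.
#' @return list of class `"grade_regression"` with `beta`, `ci`, `r2`, `n`,
#'   `p`.
#' @export
fit_grade_regression <- function(grades, iq, level = 0.95) {
  keep <- !is.na(grades) & !is.na(iq)
  y <- grades[keep]
  x <- iq[keep]
  n <- length(y)
  if (n < 10L) stopf("need at least 10 complete observations")
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    stopf("constant outcome or predictor")
  zy <- (y - mean(y)) / stats::sd(y)
  zx <- (x - mean(x)) / stats::sd(x)
  fit <- stats::lm(zy ~ zx)
  beta <- unname(stats::coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2]
  p <- summary(fit)$coefficients[2, 4]
  tcrit <- stats::qt((1 + level) / 2, df = n - 2)
  structure(list(beta = beta, ci = c(lower = beta - tcrit * se,
                                     upper = beta + tcrit * se),
                 r2 = beta^2, n = n, p = p),
            class = "grade_regression")
}

#' Proportion overlap of two confidence intervals
#'
#' The length of the intersection divided by the mean half-width (average
#' arm length) of the two intervals, floored at 0 and capped at 2. Two
#' estimates are flagged as significantly different when the overlap is at
#' most 0.5 — the 50%-overlap convention for comparing independent effect
#' sizes by eye.
#'
#' @param ci_a,ci_b numeric `c(lower, upper)`.
#' @return list with `fraction` and logical `different`.
#' @export
beta_ci_overlap_fraction <- function(ci_a, ci_b) {
  stopifnot(length(ci_a) == 2L, length(ci_b) == 2L,
            ci_a[1] <= ci_a[2], ci_b[1] <= ci_b[2])
  half_a <- (ci_a[2] - ci_a[1]) / 2
  half_b <- (ci_b[2] - ci_b[1]) / 2
  if (half_a == 0 && half_b == 0) stopf("both intervals have zero width")
  inter <- max(0, min(ci_a[2], ci_b[2]) - max(ci_a[1], ci_b[1]))
  frac <- min(2, inter / mean(c(half_a, half_b)))
  list(fraction = unname(frac), different = unname(frac <= 0.5))
}

#' Split subjects at the median absolute IQ difference
#'
#' `small` holds subjects strictly below the median of `|D|`, `large` those
#' at or above it; the two sets partition the sample. If every value ties at
#' the median, `small` is empty and `large` holds everyone.
#'
#' @param pair a [compare_composites()] table.
#' @return list with integer index vectors `small` and `large` and the
#'   `median` used.
#' @export
median_split <- function(pair) {
  med <- stats::median(pair$abs_diff)
  small <- which(pair$abs_diff < med)
  large <- which(pair$abs_diff >= med)
  list(small = small, large = large, median = med,
       n = c(small = length(small), large = length(large)))
}

#' Standardize predictors by twice their standard deviation
#'
#' Every listed predictor — continuous and binary alike — is divided by two
#' sample SDs, which puts coefficients of continuous predictors on the same
#' footing as those of balanced binary indicators (a 50/50 indicator has
#' SD 0.5, so its divisor is 1). Columns are not centred. Interaction
#' columns should be built after standardizing the mains. The returned
#' frame carries a `"two_sd_standardized"` attribute; standardizing twice
#' is refused because the operation is not idempotent.
#'
#' @param design data frame of predictors.
#' @param columns character vector of columns to scale (default: all
#'   numeric columns).
#' @return the design with scaled columns and a provenance attribute.
#' @export
two_sd_standardize <- function(design, columns = NULL) {
  if (isTRUE(attr(design, "two_sd_standardized")))
    stopf("design is already 2SD-standardized (non-idempotent operation)")
  if (is.null(columns))
    columns <- names(design)[vapply(design, is.numeric, TRUE)]
  for (col in columns) {
    s <- stats::sd(design[[col]], na.rm = TRUE)
    if (is.na(s) || s == 0) stopf("predictor '%s' has zero SD", col)
    design[[col]] <- design[[col]] / (2 * s)
  }
  attr(design, "two_sd_standardized") <- TRUE
  design
}

#' Gamma generalized linear model with log link
#'
#' Models strictly positive, right-skewed outcomes (absolute IQ
#' differences) as gamma-distributed with `log(E[y]) = X beta`. The mean
#' model is fitted by iteratively reweighted least squares; the shape
#' parameter by maximum likelihood given the fitted means, and the reported
#' log-likelihood is evaluated at that ML shape so that nested fits can be
#' compared with [likelihood_ratio_test()]. Exact zeros in the outcome are
#' replaced by 0.5 IQ points — the smallest half-unit of the integer IQ
#' scale — with the count recorded (set `zero_rule = "error"` to forbid
#' them instead).
#'
#' @param formula model formula for the mean.
#' @param data data frame holding outcome and (typically
#'   [two_sd_standardize()]d) predictors.
#' @param zero_rule `"half_point"` (default) or `"error"`.
#' @param maxit IRLS iteration cap; non-convergence is an error.
#' @return object of class `"gamma_glm_fit"`: `coefficients`, `se`, `p`
#'   (Wald), `shape`, `loglik`, `deviance`, `n`, `n_zero_adjusted`, and the
#'   underlying `glm` object.
#' @export
fit_gamma_glm <- function(formula, data, zero_rule = c("half_point", "error"),
                          maxit = 100L) {
  zero_rule <- match.arg(zero_rule)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  n_zero <- sum(y == 0)
  if (n_zero > 0) {
    if (zero_rule == "error")
      stopf("%d zero outcome values and zero_rule = 'error'", n_zero)
    y[y == 0] <- 0.5
  }
  if (any(y < 0)) stopf("outcome must be non-negative")
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X))
    stopf("design is rank deficient (collinear or duplicated columns)")
  dat <- data.frame(.y = y, X[, colnames(X) != "(Intercept)", drop = FALSE],
                    check.names = FALSE)
  fit <- stats::glm(.y ~ ., data = dat, family = stats::Gamma(link = "log"),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = maxit))
  if (!fit$converged) stopf("gamma GLM did not converge in %d iterations", maxit)
  shape <- MASS::gamma.shape(fit)$alpha
  mu <- stats::fitted(fit)
  ll <- sum(stats::dgamma(y, shape = shape, rate = shape / mu, log = TRUE))
  sm <- summary(fit, dispersion = 1 / shape)
  structure(list(coefficients = stats::coef(fit),
                 se = sm$coefficients[, 2],
                 p = sm$coefficients[, 4],
                 shape = shape, loglik = ll,
                 deviance = stats::deviance(fit),
                 n = length(y), n_zero_adjusted = n_zero,
                 formula = formula, glm = fit),
            class = "gamma_glm_fit")
}

#' @export
print.gamma_glm_fit <- function(x, ...) {
  cat(sprintf("<gamma_glm_fit> n=%d, shape=%.3f, logLik=%.3f\n",
              x$n, x$shape, x$loglik))
  print(round(cbind(estimate = x$coefficients, se = x$se, p = x$p), 4))
  invisible(x)
}

#' Likelihood ratio test for nested gamma GLMs
#'
#' `LRT = 2 * (logLik_full - logLik_null)` compared to a chi-square with
#' degrees of freedom equal to the difference in mean-model parameter
#' counts (the shape is a nuisance parameter present in both fits). The
#' null model's terms must be a subset of the full model's and both must be
#' fitted to the same outcome.
#'
#' @param full,null [fit_gamma_glm()] objects.
#' @return list with `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, null) {
  stopifnot(inherits(full, "gamma_glm_fit"), inherits(null, "gamma_glm_fit"))
  if (full$n != null$n)
    stopf("models were fitted to different numbers of observations")
  if (!all(names(null$coefficients) %in% names(full$coefficients)))
    stopf("null model is not nested in the full model")
  df <- length(full$coefficients) - length(null$coefficients)
  if (df < 0) stopf("null model has more parameters than the full model")
  stat <- max(0, 2 * (full$loglik - null$loglik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}
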