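---
title: "Methods: individual-level comparability of intelligence composites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-level comparability of intelligence composites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scorecomp)
```

## The problem

An intelligence battery usually offers several general intelligence
composites (GICs): a full battery sum, an extended sum, and a short
screening form of two subtests. All are normed to the same IQ metric (mean
100, SD 15) and advertised as measuring the same construct, and at the
group level they correlate in the .76-.95 range. Group-level agreement,
however, says little about the individual test taker: two composites that
correlate .95 still produce a mean absolute intraindividual difference of
about 3.8 IQ points, and at .76 about 8.3 points, with tails far beyond
that. `scorecomp` implements the individual-level analysis of this problem:
when are two IQs from the same battery *exchangeable for one person*, under
which reliability assumptions, and what predicts large discrepancies.

## Score model and norming

Subtest scores are age-normed scaled scores (mean 10, SD 3). A composite is
the unit-weighted sum of its member scaled scores, standardized within an
age band against a reference cohort (`build_norm_table()`), mapped to the
IQ metric, rounded half-up to an integer — practitioners see integer IQs —
and clipped to a battery-specific floor/ceiling (default 55-145,
configurable per composite because published score ranges differ between
batteries). All downstream machinery (categories, differences, CIs)
consumes these integer IQs; CI *bounds*, in contrast, stay unrounded, and
only reported widths are rounded (half-up). This combination reproduces all
published overall-consistency CI widths we use as anchors; the
half-up rule matters (e.g. a content overlap of 37.5% is reported as 38).

## True-score confidence intervals

Classical test theory decomposes an observed score as $X = T + E$ with
reliability $r = \mathrm{var}(T)/\mathrm{var}(X)$. The package's intervals
are centred on the *estimated true score*

$$\hat T = 100 + r\,(X - 100),$$

and use the *standard error of estimate*

$$SE_E = 15\sqrt{r(1-r)},$$

the SD of observed scores around $\hat T$, so a level-$\alpha$ interval is
$\hat T \pm z_{\alpha}\,SE_E$. Internally $z_{.95} = 1.959964$
(`qnorm(.975)`); the rounded-width pipeline yields the same integer widths
as 1.96 for every anchor coefficient. Under bivariate normality of
$(T, X)$ the conditional distribution $T \mid X$ is exactly
$N(\hat T, SE_E^2)$, so the interval has exact coverage — a property the
test suite verifies by simulation (95% ± 1% at n = 100 000), using the
reliability of the *observed integer* scores (the generating reliability
plus the 1/12-per-subtest discretization variance in the error term);
ignoring discretization shifts coverage to about 94.2%, which illustrates
how sensitive coverage is to the coefficient used.

Note that the width $2 z \cdot 15\sqrt{r(1-r)}$ is *not* monotone over all
of $(0,1)$ — it peaks at $r = .5$. Over the range that occurs in practice
($r \ge .5$) it decreases in $r$, which is what the tests assert.

## The six comparability criteria

Two IQs are deemed comparable for a subject when their intervals overlap
(closed intervals; touching counts):

* **NomIQ** — the nominal categories are identical (<70 lower extreme,
  70-84 below average, 85-115 average, 116-130 above average, >130 upper
  extreme).
* **CI_overall** — 95% CIs built from each composite's overall internal
  consistency overlap.
* **CI_age** — as above with age-band-specific coefficients.
* **CI_ageIQ** — age-band × IQ-group-specific coefficients (3-level
  scheme: <85, 85-115, >115).
* **CI_rtt** — test-retest coefficients, which include transient error that
  internal consistency misses.
* **NomCI** — the runs of nominal categories touched by the two overall
  CIs intersect (e.g. an interval of 112-120 spans average to above
  average). By construction NomCI can only be more lenient than NomIQ,
  which the suite verifies on every simulated cohort.

Each composite uses its own coefficient; for **CI_ageIQ** the cell is
indexed by the composite's *own* observed IQ — the only score available
when that composite is interpreted. Subjects whose required cell is
unavailable are excluded from that criterion only, with counts logged —
never silently dropped, and every rate table carries its cell n so that
input n = analyzed n + excluded n is checkable.

A caution discovered in validation and worth stating: estimating
IQ-group-specific alphas from cells that are themselves defined by the
composite's own IQ induces severe range restriction (conditioning on the
components' sum), driving cell alphas toward zero or below. Cell
coefficients of that provenance are statistically honest but practically
useless for CI construction; non-positive cells are treated as
unavailable. Published age×IQ coefficients from test manuals (supplied via
`overrides` in `build_reliability_lookup()`) do not have this problem and
are the intended input for reproduction runs.

## Reliability algebra

`cronbach_alpha()` is the raw variance-based alpha
$\frac{k}{k-1}(1 - \sum_j \sigma^2_j / \sigma^2_{total})$; it is
location-free per column and scale-free under a common rescale, but *not*
under rescaling a single column (only standardized alpha is).
`composite_reliability()` implements the component-based formula
$r_C = 1 - \sum_j \sigma^2_j (1 - r_j) / \sigma^2_C$, which reduces to
Spearman-Brown $k r / (1 + (k-1) r)$ for parallel components (asserted to
1e-12 for k = 1..20). The two agree only under essential tau-equivalence
(component reliability = squared loading): alpha credits *common* variance
only, whereas the component formula also counts subtest-specific variance
as true variance. With the default generator settings (loading .7,
reliability .85) alpha for a 7-subtest composite is about .87 while the
generating true-score reliability is about .96 — both are "the"
reliability under different definitions of error, and the coverage
simulations show it is the latter that calibrates the CIs.
`disattenuate()` divides a correlation by $\sqrt{r_a r_b}$, capping at
±1 with a warning.

## Difference statistics and models

Per pair of composites the package reports moments of signed and absolute
differences, a paired t test, and the paired-samples effect size
$d = t\sqrt{2(1-r)/n}$, which removes the pairing correlation from the
denominator. For bivariate-normal IQs with correlation $\rho$ the mean
absolute difference has the folded-normal closed form
$15\sqrt{2(1-\rho)}\sqrt{2/\pi}$, used as an independent oracle in the
acceptance suite. The extremity ratio
$\sqrt{k / (1 + (k-1)\bar\rho)}$ quantifies how much further into the tail
a $k$-part composite sits than the average of its parts.

Absolute differences are strictly positive, continuous and right-skewed,
so predictors of incomparability are modelled with a gamma GLM with log
link. The mean model is fitted by IRLS (`stats::glm`); the shape by
maximum likelihood (`MASS::gamma.shape`), and the log-likelihood is
re-evaluated at the ML shape so that the likelihood-ratio test
$2(\ell_{full} - \ell_{null}) \sim \chi^2_{df}$ is a proper profile-ML
comparison. Exact zero differences (which occur: difference ranges start
at 0) are replaced by 0.5 IQ points — the smallest half-unit of the
integer IQ scale — with the count recorded on the fit. All predictors,
binary ones included, are divided by two sample SDs before fitting, making
continuous and binary coefficients comparable in size; interaction columns
are formed after standardizing the mains. Per-predictor significance uses
Wald tests; overall significance the LRT.

For external validity, grades are regressed on each composite after
z-scoring both sides, so the slope is the standardized beta (= Pearson r,
$R^2 = \beta^2$) with a t-based CI. Two betas count as significantly
different when their 95% CIs overlap by at most 50% of the average arm
length (the proportion-overlap convention; the average-arm denominator is
one of two published variants and is the one implemented). The median
split on $|D|$ assigns ties upward (below-median vs at-or-above), so the
two subsamples always partition the sample.

## The synthetic cohort generator

Real standardization samples are proprietary, so the generator emulates
their statistical structure: one general factor $g \sim N(0,1)$; subtest
$j$ scores $x_j = \lambda_j g + \sqrt{\psi_j}\,s_j + \sqrt{\theta_j}\,e_j$
with $\psi_j = r_j - \lambda_j^2$ and $\theta_j = 1 - r_j$, mapped to the
scaled metric and rounded to integers. Optional features: linear loading
attenuation above the mean ability (`slodr_slope`, default 0) emulating
diminishing general-factor saturation at high ability, and score
floors/ceilings. Ages are uniform within the battery range with no age
trend in latent ability (scores are norm-referenced within band anyway).
Covariate prevalences default to sex .5, AD(H)D .05,
monolingual/bilingual/other .80/.12/.08, university education .30 —
plausible round numbers for a European standardization cohort, chosen once
and documented as stand-ins. Grades use the Swiss 1-6 half-point ladder
via $\mathrm{clip}(\mathrm{round}_{0.5}(4.5 + 0.8(\gamma g +
\sqrt{1-\gamma^2}\,\varepsilon)), 1, 6)$; anchor 4.5 and spread 0.8 keep
simulated grades off the bounds and are deliberately arbitrary. Latent
columns (`g`, per-subtest error-free scores) are retained and flagged for
oracle tests; `write_cohort()` drops them by default.

What the generator does *not* emulate: correlated broad-ability factors
beyond the single general factor, age trends in raw ability, item-level
response processes, retest sessions, and the demographic structure of any
real norm sample. Passing tests therefore show that the *pipeline* is
correct under a known model, not that any real battery behaves this way.

## Numerical choices and problem sizes

Rounding is half-up throughout where integers are reported; CI bounds stay
unrounded. Degenerate inputs fail loudly: zero-variance norm cells,
missing member scores (no imputation), non-positive composite variance,
rank-deficient GLM designs, grades outside 1-6. The retest coefficients
.89 and .86 produce widths of 19 and 20 under the package's rounding rule;
published tables sometimes print one point more, consistent with widths
computed from unrounded manual coefficients — the package computes, it
does not reconcile.

Simulation sizes in the test suite were chosen for stable verification at
desk scale: n = 100 000 for coverage, correlation and folded-normal
checks; n = 5 000 for GLM coefficient recovery; 2 000 replicates of n =
400 (df = 3) for LRT type-I calibration; cohorts of 2 000-30 000 for the
criterion and restriction properties. The reference battery configurations
ship with published composite retest/consistency coefficients; their
subtest loadings and reliabilities are synthetic stand-ins, so simulated
comparability rates are illustrative, not reproductions of any published
rate.
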