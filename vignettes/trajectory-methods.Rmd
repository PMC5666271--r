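---
title: "Methods: estimating and comparing allometric growth trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and comparing allometric growth trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontotraj)
```

This vignette documents the statistical model behind `ontotraj`, the
assumptions it rests on, the numerical choices made where the literature is
silent, and what the synthetic-data validation does and does not establish
about real measurement series.

## The growth model

Postnatal skull growth is treated as log-linear: a measurement $y_k$ of
specimen $j$ follows the standard allometric (power-law) equation, in base-10
logarithms

$$\log_{10} y_{jk} = a_k + b_k \log_{10} s_j + \varepsilon_{jk},$$

where $s_j$ is the specimen's overall size, $b_k$ the allometric exponent of
variable $k$ (1 = isometry), and $\varepsilon_{jk}$ lognormal measurement
noise. Ages are not required: size serves as the developmental time proxy,
which presumes a single growth phase with no secondary growth spurt and
shared trajectories for the sexes. Series should span a wide size range —
smallest specimens at most half the size of the largest — or exponents are
poorly identified.

## Multivariate allometry

For one series, the analysis takes the complete-case specimens over the
analysis variable set, and computes the covariance matrix (denominator
$n-1$) of the $\log_{10}$ data. The multivariate allometry vector is the
unit-norm eigenvector of the largest eigenvalue; under pure isometry every
element is $1/\sqrt{p}$ ($0.267$ at $p = 14$). Eigenvectors are defined up
to sign, so the full-sample vector is oriented to a positive element sum
(all-positive loadings are expected of a size axis), and every leave-one-out
vector is aligned to the full-sample vector by positive dot product —
without this, arbitrary sign flips between jackknife rounds would destroy
the pseudovalues. A numerically tied pair of leading eigenvalues (no
identifiable size axis) is an error, as is any series with fewer than three
complete specimens.

Uncertainty uses first-order Tukey pseudovalues,
$\tilde\theta_i = n\hat\theta - (n-1)\hat\theta^{(-i)}$. Per coefficient,
their mean is the jackknife estimate, `mean - full-sample estimate` the
(signed) bias, and the confidence interval is
$\bar{\tilde\theta} \pm t_{n'-1,(1+\gamma)/2}\, s/\sqrt{n'}$ at level
$\gamma$ (default 0.95). The Student-t multiplier is the standard jackknife
interval; since the underlying report of "mean and standard deviation" does
not pin the multiplier, a plain $\pm 2s/\sqrt{n'}$ variant is available
(`ci_multiplier = "2sd"`) for sensitivity analysis.

Extreme pseudovalues can inflate the intervals, so everything is computed
twice: untrimmed, and with the $m = 1$ largest and smallest pseudovalues of
each coefficient removed (per-column order statistics, i.e. element-wise,
not per-specimen). In `mode = "auto"` the trimmed result is reported when
its mean SD across coefficients is lower; exact ties fall through to mean
absolute bias and then to untrimmed. Two consequences are worth knowing: on
clean unimodal pseudovalue distributions trimming almost always lowers the
SD slightly, so auto mode reports `T` for most well-behaved series; and the
SD criterion deliberately takes precedence over bias when the two disagree.

A variable is classified `+`/`=`/`-` by whether its interval lies entirely
above, contains, or lies entirely below $1/\sqrt{p}$. A $10^{-9}$ tolerance
guards these comparisons so that the zero-width intervals produced by
noise-free data are not misclassified by floating-point rounding. When a
series lacks variables (e.g. no dentary measurements), $p$ — and hence the
isometric value — is the number of variables actually analyzed for that
series, and sign strings show `?` at the missing positions. Jackknife
intervals from very small series are not meaningful: below 10 specimens the
package warns, below 5 it refuses.

## Added change

For each wild–domestic pair, per variable, the divergence is the gap between
the two confidence intervals: `max(0, low_b - high_a, low_a - high_b)` —
zero when they intersect, symmetric, and a pseudo-metric on intervals. Two
forms can also disagree in allometric *sign* while their intervals overlap
(only one containing $1/\sqrt p$); this is flagged separately
(`sign_disagreement`) and contributes nothing to the sums. The pair's
*added change* is the sum of gaps over its common variable set; summaries
also accumulate per-variable sums across pairs. Variables missing for a pair
are excluded from both marginals rather than imputed. Each form's interval
enters with its own independently selected U/T mode. The metric is
descriptive: no significance test is attached to it.

## Bivariate allometry

Overall size is the geometric mean (GM) of the measurement set — isometric
by construction, since its log is the average of the logs. Within a pair
both forms use the identical proxy set (the pair's common variables), so
sizes are comparable across forms; the dependent variable is not excluded
from its own GM, following standard practice. Normality of the GM is checked
per series with Shapiro–Wilk as an advisory gate: the analysis proceeds with
a warning, because departures mostly reflect the sampling design of the
series, not a defect of the regression.

Lines are fitted by standardized major axis (SMA), the symmetric estimator
appropriate when both axes carry error: slope $\hat b = \mathrm{sign}(r)\,
s_y/s_x$, intercept through the centroid, slope CI from the F distribution
of the correlation. Deviation from isometry tests $H_0\!: b = 1$ through the
correlation $r_{rf}$ between residual scores $y - x$ and axis scores
$y + x$, with $F = r_{rf}^2 (n-2)/(1-r_{rf}^2)$ on $(1, n-2)$ df; data lying
exactly on the hypothesized line give $r_{rf} = 0$ and $p = 1$. Trends are
called at the Bonferroni level $\alpha/p$ per series — $0.05/14 = 0.0036$
for complete series, $0.05/10 = 0.005$ for a 10-variable one.

## Comparing trajectories and classifying heterochrony

Wild and domestic trajectories for a variable are compared by a gated
sequence at the same corrected level:

1. **Common slope.** Likelihood-ratio statistic
   $\min_b \sum_i n_i \log\!\big(1/(1 - r_i(b)^2)\big)$, where $r_i(b)$ is
   the residual-vs-axis correlation of group $i$ at slope $b$, referred to
   $\chi^2_1$. The common slope is found by bracketed minimization between
   (and slightly beyond) the two group slopes at tolerance $10^{-10}$; its
   sampling variance comes from the numerical curvature of the profile.
2. **Common elevation**, only if slopes are shared: Wald test of equal
   $a_i = \bar y_i - b\bar x_i$, with variance including the residual terms
   and $(\bar x_1 - \bar x_2)^2\,\mathrm{var}(\hat b)$.
3. **Shift**, only if slopes and elevations are shared: Wald test of equal
   mean axis scores $y + bx$ — displacement of one form along the shared
   trajectory.

Treating the wild form as the ancestral condition, the first significant
difference yields the heterochrony label: larger domestic slope →
*acceleration*, smaller → *deceleration*; higher domestic intercept →
*pre-displacement*, lower → *post-displacement*; domestic extension along
the axis → *hypermorphosis*, truncation → *hypomorphosis*; otherwise *no
change*. The first three are peramorphic (extended development), the second
three paedomorphic. The intercept polarity (higher domestic intercept =
earlier onset) is a convention, not a theorem — elevation differences can
equally signal neomorphy — so it is configurable
(`intercept_polarity = "higher_dom_post"`) and recorded with the result.
Per-pair tallies report both countings of "heterochronic events": variables
with a non-null label, and individual significant tests.

Calibration, measured by the test suite and the acceptance script: type-I
error of the isometry F-test and the common-slope LR test is within
[0.03, 0.08] at nominal 0.05 with $n = 80$ per group, and the elevation
Wald test holds its size under equal intercepts.

## The synthetic-data generator

`synthetic_spec()`/`generate_series()` implement exactly the growth model
above: latent size log-uniform over `size_range` (default 1–4, honouring the
two-fold minimum; a warning fires below it), default exponents following the
conserved mammalian pattern (splanchnocranial variables positive,
neurocranial negative, range 0.70–1.25), intercepts at plausible juvenile
proportions in mm, and independent lognormal noise (default SD 0.02 log10
units, roughly a 5% coefficient of variation typical of interspecimen
scatter around cranial growth lines). An optional shared "size-error" term
produces correlated noise for robustness probing; it is off by default.
One master seed drives everything; per-series seeds are fixed offsets.

`generate_pair()` plants each heterochrony scenario: rate scenarios offset
the target exponent by ±0.4, displacement scenarios the target intercept by
±0.2 at σ = 0.05 and n = 80; shift scenarios put both forms on one line but
give the domestic form a size range of 1–10 (hypermorphosis) or 1–2
(hypomorphosis) against the wild 1–4. Two constructional caveats are
deliberate:

* Every variable enters the shared GM, so an effect planted on one variable
  leaks a small opposite effect into the others' regressions. The ground
  truth therefore constrains only the target variable, except in shift
  scenarios where the planted label applies to all.
* The shift scenarios default to σ = 0.01. At higher noise the narrower
  size range changes the signal-to-noise ratio of one group, and error
  attenuation then *genuinely* moves its population SMA slope — the slope
  gate fires on a real difference, and a pure "shared slope and intercept,
  shifted axis" configuration is unattainable. At σ = 0.01 the distortion is
  far below test resolution.

`make_study_fixture()` assembles a full study: by default 13 pairs × 14
variables × 60 specimens per series, with pair $k$'s domestic exponents
offset on four variables (two up, two down, keeping the GM nearly neutral)
by a planted divergence falling linearly from 0.48 to 0. The added-change
ranking of such a study recovers the planted order essentially perfectly.

### What the validation does and does not show

The simulations establish internal correctness — oracle-equality of the
jackknife, nominal CI coverage (92–95% pooled at n = 100, σ = 0.02),
calibrated tests, recovery of planted scenarios at their design effect
sizes. Real growth series differ in ways the generator does not emulate:
measurement error correlated across variables (a shared size-error term can
probe this), non-uniform age/size sampling, biphasic growth, sexual
dimorphism, and genuinely correlated residual structure among skull modules.
Passing tests therefore certify the estimators and tests, not that any
particular biological dataset satisfies their assumptions.

## Problem sizes and defaults

| Quantity | Default | Why |
|---|---|---|
| CI level | 0.95 | conventional |
| Trim depth m | 1 | smallest trim that damps single extreme pseudovalues |
| α (family-wise) | 0.05, Bonferroni ÷ p per series | one test per variable on the same specimens |
| Size range | 1–4 (log-uniform) | ≥2× range, evenly covered in log size |
| Noise SD | 0.02 log10 | ≈5% CV, typical cranial measurement scatter |
| Study fixture | 13 pairs × 14 vars × 60 specimens | study-shaped but desk-scale |
| Coverage / calibration runs | 500 / 1000 replicates | binomial error ≈ 1% on a 5% rate |

Degenerate inputs are handled explicitly: non-positive measurements are
validation errors (logs undefined); zero-variance variables abort SMA fits;
exactly collinear (noise-free) data give point intervals, sign `=`, trend
`=`, and p = 1 in all comparison tests; tied leading eigenvalues abort the
multivariate stage with a clear message.

## Known limitations

* Added change inherits the arbitrariness of CI width: it grows with
  confidence level and shrinks with n; comparisons are only meaningful at a
  fixed level and comparable sample sizes.
* The U/T auto-selection rule (SD first, bias second) nearly always selects
  T on clean data; it matters only for series with aberrant pseudovalues.
* The heterochrony classifier is a decision tree over sequential tests, so
  its per-variable error rate compounds the gates' levels; with Bonferroni
  correction the compounded null error stays below about $3\alpha/p$.
* Size-as-time: none of the labels distinguish true temporal heterochrony
  from pure allometric repatterning; with size as the proxy, that
  distinction is unidentifiable by design.
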