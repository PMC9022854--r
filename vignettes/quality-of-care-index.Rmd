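---
title: "Constructing a quality of care index from burden-of-disease ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing a quality of care index from burden-of-disease ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcindex)
```

## The problem and the model

Direct measurement of cancer-care quality — screening coverage, stage at
diagnosis, treatment adequacy — is unavailable for most of the world. What
is available, for every country-year-sex stratum, is the set of six burden
measures that descriptive epidemiology produces: incidence, mortality,
prevalence, years of life lost (YLL), years lived with disability (YLD),
and disability-adjusted life years (DALY), as age-standardized rates per
100,000. The premise of the index built here is that care quality leaves a
recoverable signature in the *relationships* among these measures even when
each one alone mostly reflects underlying disease burden.

Four scale-free ratios carry that signature:

* **MIR** (deaths/incidence): at a given incidence, more deaths mean worse
  care. For colorectal cancer globally in 2019 this is about 0.51.
* **prevalence/incidence**: effective treatment keeps patients alive, so at
  a given incidence a *higher* prevalence indicates better management. Under
  steady-state assumptions this ratio approximates the mean duration of
  prevalent disease in years.
* **DALY/prevalence**: healthy life lost per prevalent case; higher = worse.
* **YLL/YLD**: deaths versus disability — a health system that postpones
  death shifts burden from YLL to YLD; higher = worse.

Using ratios rather than raw rates removes the common burden scale:
multiplying all six measures of a stratum by any positive constant changes
none of them (a property the test suite asserts).

The four ratios are redundant — they are driven by the same latent quality —
so they are combined by principal component analysis. With `Z` the matrix of
z-scored ratios, the index direction is the unit-norm leading eigenvector
`v` of `cor(Z)`, i.e. the linear combination of the ratios with maximal
variance. Raw scores `s = orientation * Z v` are rescaled affinely to

```
QCI = 100 * (s - min s) / (max s - min s),
```

with the extremes taken over the fitting frame, so the worst stratum in the
frame scores exactly 0 and the best exactly 100.

**Orientation.** Eigenvectors are defined up to sign, but the index has a
required polarity: higher = better care. Of the four ratios, MIR has the
least ambiguous direction (higher is always worse), so the sign is chosen to
make the oriented MIR loading non-positive. If the MIR loading is exactly
zero the rule falls through YLL/YLD, then DALY/prevalence (both
"higher = worse"), and finally makes the prevalence/incidence loading
non-negative. In practice the first rule always decides; the rest make the
procedure total.

**Gender disparity ratio.** `GDR = QCI_female / QCI_male` per location-year;
1 is parity, values above 1 favor females. It is computed on full-precision
scores and rounded to one decimal only for reporting — dividing
already-rounded scores would inject spurious disparity of up to about 0.002.
GDR is left undefined (omitted and logged, not 0 or infinity) when the male
score is 0 or either sex is missing.

## Tunable parameters and defaults

* `standardize = TRUE` (correlation-matrix PCA). The four ratios live on
  very different scales — MIR is below 1 while YLL/YLD commonly exceeds 10 —
  so covariance-mode PCA would be dominated by whichever ratio has the
  widest numeric range. Covariance mode remains available for sensitivity
  analysis.
* `log_transform = FALSE`. A natural-log transform tames the heavy right
  tail of YLL/YLD and makes the PCA less sensitive to extreme strata; it is
  off by default because the plain-scale index is the primary definition.
  The flag is stored in the model so scoring always matches fitting.
* `fit_scope` (pipeline): `pooled` (default) fits one model on all
  location-year-sex strata at the age-standardized level, putting female and
  male scores on one scale — a prerequisite for a meaningful GDR. `per_sex`
  and `per_age` refit and rescale within each group, which makes scores
  comparable only within the group.
* Zero-denominator policy (`compute_ratios`): strata with zero incidence,
  prevalence, or YLD are excluded and logged with a reason, mirroring the
  manual inspection for zero estimates that precedes index construction on
  real extracts. An epsilon-imputation mode exists behind a flag but is off
  by default: silently imputing denominators distorts the loadings with no
  visible trace in the output.
* SDI quintiles: `rank` mode places the 20/40/60/80th percentile boundaries
  over locations in a reference year (default: the latest year present, so
  a location keeps one quintile across years); `fixed_cutpoints` mode takes
  published boundaries for replication against external tables. Ties are
  broken by stable (sdi, location) ordering so assignment is row-order
  independent.
* Age standardization: direct standardization, `sum(weight * rate)` over
  5-year bins (0–4 … 95+ by default). The reference weights are an explicit
  config input, defaulting to equal weights per bin, because published
  extracts rarely restate the standard population they used; analyses of
  real extracts should supply the matching standard.

## Numerical choices

The leading eigenvector comes from a dense symmetric eigendecomposition of
the 4×4 correlation (or covariance) matrix; the test suite verifies it
against an independent SVD-based decomposition of the data matrix to 1e-8.
If the two leading eigenvalues tie (degenerate correlation structure), the
eigenvector with the larger |MIR| loading is taken so the fit is
deterministic. Fitting requires at least 3 strata and four non-constant
ratio columns; a zero-variance column raises an error naming the column
rather than producing a silent 0/0. Scoring a stratum outside the fitting
frame can legitimately fall outside 0–100; such scores are flagged in an
`out_of_range` column and are clamped only on request, never silently.
The published rescaling formula is typographically garbled in its source
(the division sign and percentage factor are missing); the implementation
follows the stated 0–100 range, i.e. `100 * (s - min) / (max - min)`.

No randomness is used anywhere in the index itself; model quantities are
invariant to row order.

## What the synthetic generator emulates

`synthetic_config()` defines a latent-quality world: each location draws a
quality `q ~ Beta(2, 2)`, an SDI value follows `0.1 + 0.8q` plus truncated
Gaussian noise (sd 0.05), and every measure is generated per 5-year age bin:

* age-specific incidence follows a logistic curve in age (midpoint 60 years,
  width 12, peak 150 per 100,000) — rare in the young, plateauing in old
  age, the qualitative shape of colorectal-cancer incidence;
* `deaths = incidence * (0.1 + 0.8(1 - q))`: the MIR link spans 0.1 (best)
  to 0.9 (worst), bracketing observed cancer MIRs;
* `prevalence = incidence * duration(q)`, duration rising from 2 to 10 years
  with quality — the steady-state prevalence identity;
* `yld = prevalence * 0.2` (disability weight), `yll = deaths * residual
  life expectancy` (linear, 85 years at age 0 down to 2 at the top bin),
  and `daly = yll + yld` exactly — the defining identity, preserved by
  construction because noise is applied to YLL and YLD before summing;
* multiplicative log-normal noise (sd 0.1 on the log scale) per measure and
  age bin, because rates are positive and estimation error in burden data
  is heavier on the multiplicative scale;
* one RNG substream per purpose derived from the master seed, so adding a
  measure or toggling a knob does not shift the other draws; a fixed seed
  gives bit-identical tables.

By default noise is drawn once per location-year-age-measure and shared by
both sexes (`shared_sex_noise = TRUE`). With the default `sex_effect = 1`
this makes female and male measures identical, so the GDR null — parity —
holds exactly and any disparity observed downstream is attributable to a
configured sex effect rather than to independent measurement noise. Setting
`shared_sex_noise = FALSE` gives the harder regime where GDR scatters
around 1.

Because all four ratios are monotone in `q`, the fitted index should recover
the latent ranking: the test suite requires Spearman correlation of at least
0.9 between QCI and `q` on the default conditions (100 locations, one year,
noise sd 0.1) and at least 0.99 noise-free; observed values are about 0.997
and 1.0.

**What passing these tests does not show.** The generator produces a
one-factor world: all four ratios are driven by a single latent quality, so
the first component carries ~95% of the variance and recovery is easy. Real
extracts mix care quality with registry quality, cause-of-death coding,
screening-induced incidence shifts, and cohort effects; the first component
there will carry less variance, and nothing in these tests validates the
*interpretation* of the component as care quality on real data. The
generator also makes no attempt to match real colorectal-cancer magnitudes —
it targets structure (directions, identities, scale-freeness), not burden
realism.

## Problem sizes and reproducibility

Unit and property tests run on tables of 5–200 strata and generators of
10–30 locations with a reduced age span (bins up to 30+); the recovery and
disparity checks use the generator's default study conditions of 100–120
locations over the full 0–95+ age span. The acceptance script re-runs the
default-condition pipeline from scratch under a caller-supplied seed and
reports its quantities as JSON; every stage is deterministic given the seed,
and `cmd_simulate`/`cmd_run` write settings manifests from which a run can
be reproduced bit-identically.

## Known limitations

* The fitting frame determines comparability: scores from different fits
  (e.g. per-sex) are not on a common scale, and out-of-frame scores can
  leave 0–100. The pipeline defaults to one pooled fit for this reason.
* Whether a published index of this kind was fit on both-sexes, sex-specific,
  or pooled strata — and with correlation or covariance PCA, or log
  transforms — is generally not stated; these are exposed as configuration
  rather than asserted, and replications of published score tables should
  treat the defaults as one reasonable choice among several.
* Regional or global scores can be formed either by aggregating country
  scores (`summarize_by`, optionally population-weighted) or by fitting on
  region-level rates; the two do not coincide and neither is asserted as
  canonical.
* Only the first component is retained; no factor rotation, no uncertainty
  propagation from the underlying draws, and no mixed-effects validation
  against external coverage indices (which requires covariate data outside
  this package's scope).
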