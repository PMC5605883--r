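---
title: "Methods: cause-of-death estimation, correction, and burden at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cause-of-death estimation, correction, and burden at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codburden)
```

`codburden` implements a complete cause-of-death estimation chain on
synthetic, verifiable data. This vignette is the package's account of the
science: the models at each stage, the assumptions they make, the
parameters that matter, the numerical choices, and what passing the test
suite does and does not demonstrate about real data.

## The synthetic world

Every downstream stage is tested against a generated truth, so the
generator is first-class code, not a fixture. The latent truth is a cube of
death rates over locations, calendar years, the 23 standard age groups
(three neonatal/post-neonatal groups under age 1, ages 1-4, eighteen 5-year
groups, and an open-ended 95+ group; all intervals closed-open), two sexes,
and most-detailed causes arranged in a mutually exclusive, collectively
exhaustive 3-level hierarchy with three Level 1 groups: CMNN
(communicable, maternal, neonatal, nutritional), NCDs, and injuries.

On the log scale a cell's rate is

```
log m(l, t, a, s, c) = alpha_g(c) + beta_g(c) * SDI(l, t)
                       + f_g(age) + gamma * male + u(l, c)
```

an epidemiological transition that is log-linear in the Socio-demographic
Index. Defaults (all overridable in `sim_config()`): CMNN slope -3 per unit
SDI, injuries -1.5, NCDs -0.7, so development shifts the cause composition
from infections toward chronic disease; age offsets load CMNN causes on
infancy, rise NCD rates steeply with age, and peak injuries in young
adults; the male offset is +0.15; `u(l, c)` is location-by-cause noise with
SD 0.3 — real between-location heterogeneity, not measurement error. SDI
trajectories start uniformly on (0.15, 0.85) and rise by 0.007 per year,
the pace of a slow development trend. Populations are about 60,000 persons
per location-age-sex cell, declining with age, which puts cause-level death
counts in the tens to hundreds — the regime of national registration data
for a mid-sized country.

Observation is a chain of defects applied to Poisson counts at the true
rates: binomial thinning by registration completeness (VR locations draw
completeness from 0.7-1.0, VA locations 0.4-0.8, `none` locations produce
no records); multinomial misclassification in VA strata (default matrix:
0.64 on the diagonal — the published chance-corrected concordance for
physician-certified VA — with the remainder uniform; the matrix form itself
is a modelling choice, as no published matrix exists); garbage coding with
probability logistic in the age-group index (maximum 0.35, midpoint at
group 14, roughly age 60, steepness 3), reflecting the strong rise of
ill-defined certification with age; and recording of a fraction of deaths
at the Level 2 parent cause (5% for VR, 30% for VA) to emulate limited
cause-list detail. Poisson counting, binomial thinning, and multinomial
reallocation form the simplest generative model consistent with count
data. A fixed seed makes the whole world bit-identical; the observation
stage takes its own seed so the observation process can be replicated over
a fixed truth in Monte-Carlo tests.

What the generator does *not* emulate: ICD revision changes and bridge
coding, aggregate-age records needing age-sex splitting, demographic change
(populations are time-invariant), migration, and fatal discontinuities
(war, disaster, epidemic). Passing tests therefore demonstrate the
correctness and calibration of the estimation machinery under a clean
generative model, not robustness to every defect of real registries.

## Data-quality star rating

Percent well certified for a location-period is

```
W = 100 * C * (1 - G) * D
```

completeness times the fraction of deaths not on *major* garbage codes
(codes whose redistribution spans Levels 1-2 of the hierarchy, such as
heart failure or sepsis) times the fraction assigned to detailed (Level
3-4) causes. VA data are multiplied by 0.64; subnational VA additionally by
0.10, since a subnational study need not resemble the national picture. `W`
is binned into 0-5 stars with left-closed boundaries: 85, 65, 35, 10, with
1 star for anything positive below 10 and 0 stars only for exactly 0.

Two definitional gaps are resolved as follows. The detailed-cause fraction
`D` excludes garbage from the numerator only, so its denominator is all
recorded deaths; this makes `(1 - G)` and `D` penalise major garbage and
missing detail separately. The full-period (1980-2016) value aggregates
per-year values by a deaths-weighted mean (equal weights when counts are
unavailable); published tables print the full-period value directly, so
nothing downstream depends on this choice. Reporting intervals are the six
5-year intervals from 1980 plus the 7-year terminal interval 2000-16, with
years assigned by calendar membership; intervals with no usable data score
zero.

The packaged country table (`table1_quality()`) prints percent well
certified to one decimal. A printed value within printing precision
(±0.05) of a bin boundary is genuinely ambiguous — a country printing 0.0
can hold a tiny positive value worth 1 star, and one printing 65.0 can sit
just below the 4-star boundary. `star_rating_printed()` resolves such rows
with the printed star rating when (and only when) it is consistent with
some pre-rounding value in the window; unambiguous rows always use the
binning rule.

## Source exclusion, redistribution, completeness correction

VR location-years below 50% completeness are excluded (selection bias),
as is any location-year with more than half its deaths on major garbage
codes; VR between 50% and 70% complete is retained but flagged
non-representative, which downstream models treat as a doubled observation
variance (the inflation factor is configuration). Location-years with no
completeness estimate follow VA rules — no completeness exclusion — and are
logged.

Garbage deaths are redistributed within each location-year-age-sex stratum
by one of three methods. *Proportional*: split across the target causes in
proportion to the deaths already observed on them in the same stratum; when
every target is zero there, the split is uniform — this conserves mass
without borrowing from neighbouring strata (the borrowing schemes used at
full scale are deliberately out of scope). *Fixed*: stated proportions,
which must sum to 1 within 1e-9; this method also covers fractional
reassignment of multi-cause records, whose per-cause fractions are the
fixed proportions. *Regression*: one log-linear model per target cause of
the target's within-stratum share on age, sex, and an optional covariate,
fit across all strata, predicted and normalised per stratum — a documented
simplification of the family of fitted models used at full scale.
Redistribution conserves stratum totals to 1e-9 and leaves no mass on
garbage codes; redistribution uncertainty is not propagated, a known
limitation of the approach this package mirrors.

Completeness correction multiplies each stratum's cause *fractions* by the
all-cause envelope, so corrected deaths sum to the envelope exactly and the
result is invariant to rescaling the stratum's counts. A zero envelope over
positive recorded deaths is an error naming the cell, never an imputation.

## Ensemble estimation

The candidate pool crosses every non-empty covariate subset with two
response spaces — log death rate and logit cause fraction (floored and
ceilinged at 1e-6 before the transform) — optionally with a location random
intercept (spatial pooling is *only* a random intercept; there is no
space-time residual smoothing here). A fitted candidate survives screening
only if each covariate coefficient matches its declared expected sign and
is significant two-sided at alpha = 0.05 (a configurable default; for mixed
models the Wald z-test is used).

Predictive validity is scored by cross-validation: location-years are
randomly partitioned into folds; each surviving model is scored on RMSE of
held-out log rates (levels) and RMSE of held-out year-on-year first
differences of log rates within location (trends). Models are ranked on
each, the combined rank is the mean, and ensemble weights are

```
w_m = exp(-rank_m / T) / sum_k exp(-rank_k / T)
```

Draws sample a model by weight, then coefficients from their fitted
sampling distribution, then location effects from their conditional
distribution (unseen locations draw from the marginal), then a residual
term. The residual term represents *rate heterogeneity the covariates do
not explain*, not measurement error: with count data at realistic
population sizes the Poisson contribution to the residual is small, so the
estimated residual SD is dominated by real variation in rates, and
including it is what makes the draw intervals cover the latent truth. Rows
flagged non-representative draw residual noise inflated by sqrt(2).

The temperature `T` is the method's calibration knob. The packaged
recovery experiment (`codem_recovery_experiment()`) generates five causes
over 200 location-years from a known pool member — location intercepts
(SD 0.2), cell-level heterogeneity (SD 0.2), Poisson observation at
population 1e6 — fits the full pool, and rescales the cause draws to the
true envelope. At `T = 1`, poorly ranked pool members (wrong covariate,
residual SD up to 3x the truth's) retain 10-15% weight and push the
coverage of the corrected 95% draw intervals above 0.97; at the default
`T = 0.5` (adjacent ranks differ by a factor `exp(-2)`) coverage sits in
the 0.93-0.97 band across replicate experiments, and the test suite asserts
this at seed 1 along with the requirement that the ensemble's RMSE not
exceed the pool-median single-model RMSE.

Nine-causes-style rare-count series use an intercept-only negative binomial
with a log-exposure offset. Equidispersed series make the NB likelihood
flat in the dispersion; the fit then falls back to Poisson and reports
dispersion 0. An all-zero series returns zero-rate draws with a warning
rather than an error, since an observed zero count is informative, not
invalid.

## Envelope rescaling and uncertainty

Cause-specific draws are made consistent with all-cause mortality by
multiplying every cause in a location-year-age-sex cell, draw by draw, by
`envelope / sum(causes)`. Draw pairing is positional — draw i of every
quantity belongs to draw i — which is the only coherent way to propagate
the correlation the draws encode. The rescale is exact to 1e-9,
scale-equivariant, and rank-preserving within a cell-draw. A cell where
every cause model predicts zero under a positive envelope raises an error;
how to fill such cells is a modelling decision no algorithm should take
silently. The miscoding-aware variant of the rescale for
dementia/parkinsonism (which restricts the correction to a set of plausibly
miscoded recipient causes) is replaced by the generic proportional rescale
and left as a future extension.

Point estimates are draw means; 95% uncertainty intervals are the 2.5th and
97.5th percentiles computed with linear interpolation between order
statistics (R's quantile type 7, stated so an oracle can match it
bit-for-bit). A change between two periods is significant when at least 95%
of positionally matched draws moved the same way — the boundary is
inclusive: exactly 950 of 1000 increasing draws is an increase.

## Burden

YLLs multiply deaths by standard life expectancy at the age of death. The
packaged life table is a synthetic stand-in anchored at 86.6 years at
birth and strictly decreasing (`86.6 * exp(-0.031 * age)`, about 4.3
remaining years in the 95+ group); the packaged standard population is a
synthetic young-population weight set normalised to 1. Both are swappable
two-column files (`read_life_table()`, `read_standard_population()`) so
reference tables can be dropped in; because the true standard-population
weights are not published in a main text, everything depending on them is
property-tested (linearity, exchange of aggregation and standardisation),
never value-matched. Age-standardised rates are `sum_a w(a) m(a)` on the
scale of the input rates (use rates per 100,000 for standardised rates per
100,000). The annualised rate of change is `100 * log(v2/v1) / years` per
draw — the natural annualisation, as no closed form is published — with
draws at a zero or negative ratio dropped and counted per cell.

## SDI and expected burden

SDI is the geometric mean of three indices rescaled to [0, 1]: log income
per capita (income spans orders of magnitude, so rescaling is on the log
scale), mean educational attainment, and total fertility inverted (higher
fertility, lower index). Rescaling anchors are configuration with
documented defaults (income 250-60,000; education 0-17 years; fertility
1-8 births); degenerate anchors (min = max) are an error. Quintile
membership is fixed at a reference year's distribution — cut-points are
type-7 quintiles, ties fall to the lower bin — and is invariant to
monotone transforms of SDI.

The expected death rate as a function of SDI is a Gaussian process in
log-rate space: squared-exponential kernel plus a noise nugget, with a
*fitted linear mean* in SDI (universal kriging). The linear mean matters:
with a constant mean the posterior reverts to the data mean outside the
observed SDI range and misses a transition-like trend at the grid edges.
Hyperparameters maximise the marginal likelihood by L-BFGS-B from three
fixed starting points with box bounds (length-scale in [0.02, 10]), so the
fit is deterministic given the data; the mean function's prediction
variance is added to the posterior band. Non-positive rates are floored at
1e-12 before the log; a jitter of 1e-10 stabilises the Cholesky
factorisation. Expected values use each location-year's point SDI, not an
integral over its SDI path — the simpler reading, documented here.
Observed/expected ratios aggregate observed and expected over age *before*
dividing, use the same standard tables as the burden stage (so O/E
differences are attributable to rates alone), are scale-free, and return a
missing value where the expected aggregate is zero.

A note on verifying the GP band: the fraction of grid points at which the
posterior 95% band covers the generating line is a bimodal statistic —
usually 1.0, occasionally far lower when the fitted mean happens to sit two
standard errors off over a stretch, which is ordinary sampling variation of
a pointwise band. The test suite therefore averages this fraction over ten
replicate datasets rather than asserting it on one.

## Problem sizes and interfaces

The packaged experiments are sized for a desk: the default world is 20
locations by 10 years by 12 causes (about 110,000 truth cells), the
recovery experiment is 1,000 cause-cells by 1,000 draws, and the envelope-
conservation check runs 20 locations by 5 years by 23 ages by 2 sexes by 8
causes by 100 draws. Records, garbage maps, draw cubes, life tables, and
standard populations all read and write as headered delimited text; the
package's functions are its interface, with the acceptance script as the
reproducible entry point for the headline numbers.

## Known limitations

Redistribution uncertainty is not propagated into the draws. The ensemble
has no space-time residual smoothing and no covariate-selection machinery
beyond subset enumeration. The VA misclassification matrix is a stylised
single-parameter form. The standard life table and population are labelled
synthetic stand-ins. Cells where all cause models predict zero under a
positive envelope are errors by design. None of the packaged defaults have
been calibrated against real registry data; they define a plausible,
internally consistent world in which the machinery can be proven correct.
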