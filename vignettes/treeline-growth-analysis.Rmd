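---
title: "Modelling climate-growth relationships and growth trends at alpine treeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling climate-growth relationships and growth trends at alpine treeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrogrowth)
```

## The scientific problem

Tree growth at upper treeline is limited primarily by temperature, which
makes ring-width series from treeline trees a sensitive archive of climate
effects on growth. Two questions drive the analyses this package
implements:

1. **Short term** — which monthly mean temperatures of the current and
   previous year control year-to-year variation in ring width, and how much
   do individual trees differ in those responses ("among-tree
   variability")?
2. **Long term** — have growth rates trended upward as temperatures rose
   over the last ~150 years, and does the trend change with elevation
   (a proxy for the long-term mean temperature a tree experiences)?

Both questions are answered with linear mixed-effects models (LMMs) on
detrended ring-width indices (RWI), with tree-level random effects carrying
the among-tree variability and a first-order autoregressive (AR(1))
residual process absorbing the serial correlation that remains within each
tree's series.

## Detrending

Raw ring widths confound climate signal with the tree's intrinsic
age/size trend, so each analysis starts from indices rather than widths.

**Spline detrending (short-term analyses).** Each series is divided by a
smoothing-spline fit whose amplitude response is 50% at a 32-year
wavelength. The spline is the discrete second-difference-penalty smoother:
minimize $\sum_t (w_t - g_t)^2 + \lambda \sum_t (\Delta^2 g_t)^2$, whose
frequency response is $1/(1 + 16\lambda \sin^4(\pi f))$; solving for a
response of $1/2$ at period $p$ gives $\lambda = 1/(16 \sin^4(\pi/p))$.
This removes variability slower than ~32 years (including the age trend)
and keeps the interannual signal the climate models need. Constant and
linear series pass through unchanged, so a constant series yields indices
identically 1. Indices are ratios (width / fitted curve), which keeps them
dimensionless with mean ~1.

**Regional curve standardization (long-term analyses).** Spline detrending
would also remove any true multi-decadal growth trend, so the trend model
uses RCS instead: all series are aligned by *cambial age* (ring number
counted from the pith) and averaged into one regional curve per
species-and-site population; each width is divided by the curve value at
its ring's cambial age. Because the divisor depends only on age, calendar-
time trends survive. The regional curve is the raw age-aligned mean by
default; optional spline smoothing of the curve is available but off by
default, recorded in the `smoothing` field, because the raw mean is
unbiased and our sample depths make it stable.

RCS needs the cambial age, hence the number of rings missing between the
innermost measured ring and the pith. For cores that missed the pith the
offset is estimated geometrically from the innermost ring arc: a chord of
length $L$ with arc height $h$ lies on a circle of radius
$r = (L^2 + 4h^2)/(8h)$, and the missing-ring count is $r$ divided by the
mean of the first five measurable widths, rounded. Cores with **more than
10** estimated missing rings are excluded (a core with exactly 10 is
kept); the strict inequality matters at the boundary and is tested.

Zero widths (locally absent rings) are floored at 0.005 mm — half the
0.01 mm measurement resolution — before division so that the log transform
used by the trend model stays finite. Series are detrended over their full
length and truncated to 1850+ afterwards, matching the climate-data period
without distorting the spline fit near the cut.

## The mixed-model core

Both analyses share one likelihood machine. For tree $j$ in year $t$:

$$y_{jt} = x_{jt}'\beta + z_{jt}' b_j + \epsilon_{jt}, \qquad
  b_j \sim N(0, G), \qquad
  \mathrm{cor}(\epsilon_{js}, \epsilon_{jt}) = \phi^{|s - t|}$$

with $G$ diagonal. The marginal likelihood is evaluated by whitening each
tree's residual vector with the AR(1) innovations transform (which handles
missing years exactly, since the correlation is $\phi^{\Delta\text{yr}}$
across a gap of $\Delta$ years) and applying the Woodbury identity for the
low-rank random-effect part, so each evaluation is linear in the number of
observations. The fixed effects are profiled out by generalized least
squares and the residual variance analytically, leaving a small
optimization over $(\operatorname{atanh}\phi, \log\gamma_k)$ where
$\gamma_k$ are variance ratios; this transformed-scale parametrization
keeps the optimizer unconstrained. ML and REML are both available; REML is
used for final fits, ML for likelihood-based model comparison.

Design choices worth stating:

* **Diagonal $G$ only.** The climate-growth models can carry up to 11
  random slopes; an unstructured covariance of that size is not
  identifiable at realistic sample sizes, and the reported quantities are
  random-effect SDs. A correlated-random-effects extension was therefore
  left out deliberately.
* **Wald t-tests** with denominator degrees of freedom
  $n_{obs} - n_{trees} - p$ (the within-group convention). These p-values
  are approximate, as always in LMMs; the package reports them with the
  conventional significance levels.
* **Standard errors of variance parameters** ($\phi$, random-effect SDs,
  $\sigma$) come from the numerical Hessian of the profile likelihood on
  the transformed scale, delta-mapped back. They power the
  parameter-recovery checks.
* **BIC uses $n = n_{obs}$** (total observations, not trees). Any single
  convention is debatable in mixed models; this one is comparable across
  models fitted to identical data, which is the only use made of it.
* **Convergence** is declared at a relative tolerance of 1e-10 in the
  optimizer; "false convergence" reports at a variance boundary are
  re-checked by restarting, and a fit whose objective cannot be improved
  beyond 1e-6 is accepted as converged. Singular random effects
  ($\gamma < 10^{-7}$) are reported as SD 0.
* The likelihood path is verified against a brute-force stacked
  multivariate-normal density on small instances (to 1e-8) and
  cross-checked against `nlme::lme` on a shared dataset in the test suite;
  neither is part of the implementation.

## Short-term analysis: exhaustive BIC selection

The candidate predictors are the 15 standardized monthly mean temperatures
from previous August through current October — months of the year of ring
formation and of the preceding year, which physiology links to reserve
building, snow cover and the growing season. Seasonal means are
deliberately not formed; months enter individually. Standardization (per
column, over the response years of the fit) makes a coefficient of 0.1
read as "a 10% change in RWI per +1 SD of that month's temperature".

All $2^{15} = 32{,}768$ subsets are fitted by ML with a tree-level random
intercept and AR(1) residuals, and ranked by BIC; ties break toward fewer
parameters, then the lexicographically smaller subset. Fits are
warm-started from the parent subset's variance estimates, which speeds the
enumeration up without affecting the argmin (checked by brute force at 6
candidates against cold starts). The winning fixed structure is then
extended with diagonal random slopes for every selected month and refitted
by REML — fixed effects describe the population-mean temperature response,
random-effect SDs the among-tree variability around it. The
selection-stage random structure is intercept-only on purpose: slopes are
added only after selection, keeping the enumeration tractable and the
criterion comparable.

## Long-term analysis: trend with elevation interaction

The trend model is

$$\log(\mathrm{RWI}^{RCS}_{jt}) = \beta_0 + (\beta_1 + b_{1j})\,t +
  (\beta_2 + b_{2j})\,\mathrm{elev}_j + (\beta_3 + b_{3j})\,t\,
  \mathrm{elev}_j + b_{0j} + \epsilon_{jt}$$

with $t$ the calendar year, elevation in m a.s.l., diagonal random effects
and AR(1) residuals, fitted by REML from 1850 on. The log response makes
the trend multiplicative in the index. Internally the model is fitted on
centred year and elevation — the raw year x elevation interaction makes
the design catastrophically ill-conditioned — and the coefficients are
transformed back to the uncentred scale afterwards, with delta-method
standard errors; the interaction coefficient and all predictions are
invariant to the centring. On the uncentred scale the coefficients have
the familiar large-intercept/small-slope pattern
($\beta_1 \sim -0.1$, $\beta_3 \sim 10^{-5}$), so the log-scale growth
trend at elevation $e$ is $\beta_1 + \beta_3 e$: a positive interaction on
a negative time slope means steeper growth increases at higher elevation,
with a sign change at $e = -\beta_1/\beta_3$.

Before settling on the base model, all subsets of the additional tree
covariates (height, DBH, crown length, aspect, slope) are screened by ML
and AIC with the base terms always included. The screening fits use a
random intercept only; the winner is refit with the full random-slope
structure. AIC (not BIC) is used here since the screen is about
explanatory power, not parsimony of a final reported model.

Predictions are reported at the 0th, 20th, 40th, 60th, 80th and 100th
percentiles of the elevation *range* (six evenly spaced elevations between
the lowest and highest sampled tree), back-transformed with
$\exp(\cdot)$, either from fixed effects alone or adding each tree's
predicted random effects (BLUPs).

## Stand structure

Canopy-height tables (trees taller than the 2.5 m detection threshold)
are split into three elevation classes at the 25th and 75th percentile of
elevation, with boundary values assigned to the lower class so the split
is deterministic. Tree ages for these un-cored trees come from a
site-specific OLS regression of age on height, fitted on the cored sample
(ages from pith-dated base cores plus pith offset). "Ingrowth time" is
operationalized as the estimated tree age at the survey year (default
2015, configurable — the field campaigns that motivate the default ran
2014-2015): the years elapsed since establishment. Predicted ages are
floored at 1 year. Distribution shapes (reverse-J vs unimodal) are
described by histogram counts and sample skewness rather than a
classifier, since the field labels are qualitative. Densities are counts
per hectare, per class and overall.

## The synthetic-data generator

Every pipeline stage is exercised on synthetic data with recorded ground
truth. The generator is the package's single generative bridge between
the two model scales: growth is **multiplicative**,

$$w_{jt} = \mathrm{RC}(\text{age}_{jt}) \cdot \exp\!\big(\textstyle\sum_i
  (\beta_i + b_{ij}) T^*_{it} + \beta_1 t + \beta_2 e_j + \beta_3 t e_j +
  b_{0j} + \epsilon_{jt}\big)$$

with $\mathrm{RC}(a) = a_0 e^{-a/\tau} + c$ the declining cambial-age
curve, $T^*$ the standardized monthly temperatures, and $\epsilon$ AR(1).
For small effects $\exp(\eta) \approx 1 + \eta$, so the spline-index
equation (index $\approx 1 +$ effects) and the log-RCS trend equation are
both limits of the same process. Widths are rounded to the 0.01 mm
measurement resolution *last*, so rounding noise is part of the recovery
error budget; a configurable fraction of cores has inner rings truncated
to exercise the pith-offset path.

The default (`"larch_like"`) parameters describe a temperature-limited
larch population: July coefficient 0.25 per +1 SD with positive
previous-fall and negative spring/late-summer effects; among-tree SDs
largest for the previous-fall months and smallest for July; random
intercept SD 0.1; $\phi = 0.5$, $\sigma = 0.15$; trend coefficients
$\beta_1 = -0.140$, $\beta_2 = -0.123$, $\beta_3 = 6\times10^{-5}$ over
elevations 2,250-2,540 m; monthly normals for ~2,400 m in the central
Alps with warming that starts in 1950, strongest in June
(0.035 °C yr$^{-1}$, i.e. about +2 °C by 2008) and nearly flat in
September; monthly noise SD 1.2 °C. The age-height line for stands is
age $= 10 + 8 \times$ height, with exponential (reverse-J) age
distributions by default.

What the generator deliberately does **not** emulate: precipitation and
snow (the real mechanisms behind spring effects), disturbance and
mortality, competition, size-dependent sampling bias, and measurement
error beyond rounding. Passing recovery tests therefore demonstrates that
the estimation machinery is correct and well-calibrated under the stated
generative model — not that real series satisfy that model.

## Problem sizes and numerical checks in the test suite

The shipped tests run the full chain at sizes chosen to make the
statistical checks sharp while keeping the suite quick: likelihood-oracle
agreement on 200 random small instances (tolerance 1e-8);
parameter recovery on 20 replicates of 60 trees x 100 years;
exact-subset BIC recovery on 20 replicates of a reduced 2^8 candidate set
(the spec of the full analysis is 2^15, whose enumeration is verified
directly) at 40 trees x 80 years; trend recovery on 20 replicates of 90
trees x 150 years at the coefficient magnitudes above; the spline's
empirical 50% response measured on 640-year sinusoids; and the pith
geometry against an independent three-point circle fit on 1,000 random
chord/height pairs. `scripts/acceptance.R` re-runs the same computations
from scratch at these sizes and writes the resulting numbers as JSON.

## Known limitations

* p-values are Wald-type with a heuristic df; no Kenward-Roger or
  parametric-bootstrap correction.
* Random-effect covariance is diagonal; correlations among slopes are not
  estimated.
* RCS is known to damp trend slopes somewhat when the age structure is
  uneven; the trend tests simulate the trend equation directly, and the
  full-pipeline checks assert sign recovery rather than unbiasedness.
* The crossdating check is a screening correlation against the
  leave-one-out mean chronology, not a full COFECHA replication (no
  autoregressive prewhitening or segment-shift testing).
* Only temperature is modelled; precipitation, snow and CO$_2$ are outside
  the scope of both the models and the generator.
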