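# dendrogrowth

Dendroecological analysis of climate–growth relationships and long-term
growth trends for temperature-limited trees at alpine treeline.

Ring-width series from treeline trees record how monthly temperatures
drive year-to-year growth and whether growth rates have risen with recent
warming. This package implements the full analysis chain for such studies,
for dendroecologists and quantitative ecologists who want the individual
tree — not just the population chronology — as the unit of analysis:

* **I/O and QC** — Tucson/RWL decadal ring-width files (0.01 mm and
  0.001 mm dialects), tree metadata tables, and a moving-window
  crossdating check against the leave-one-out mean chronology.
* **Detrending** — 32-year smoothing-spline indices
  (`RWI^sp`, high-frequency, for climate models) and regional curve
  standardization (`RWI^RCS`, trend-preserving), with geometric
  pith-offset estimation (`r = (L² + 4h²) / (8h)` from the innermost ring
  arc) and the strict ">10 missing rings" exclusion rule.
* **Mixed models** — the core model, written from the marginal likelihood:

      RWI_jt = β₀ + Σᵢ βᵢ T*ᵢₜ + Σᵢ b_ij T*ᵢₜ + b₀ⱼ + ε_jt,
      ε_jt = φ ε_j,t−1 + η_jt,   b ~ N(0, diag), η Gaussian

  with tree-level random intercepts/slopes (diagonal covariance), AR(1)
  within-tree residuals that decay correctly across missing years
  (`φ^Δyr`), ML/REML estimation, Wald tests, information criteria, and
  diagnostics (VIF, normality, heteroscedasticity, whitened-residual
  autocorrelation).
* **Exhaustive selection** — all 2¹⁵ = 32,768 subsets of the 15 lagged
  monthly temperature predictors (previous August–December, current
  January–October; standardized, so a coefficient of 0.1 means +10% RWI
  per +1 SD), ranked by BIC under ML, then a REML refit with random
  slopes for the selected months.
* **Growth trends** — `log(RWI^RCS) = β₀ + (β₁+b₁)t + (β₂+b₂)elev +
  (β₃+b₃)t·elev + b₀ + ε` with AR(1), AIC screening of extra tree
  covariates, and back-transformed predictions at six elevation
  percentiles.
* **Stand structure** — elevation classes at the 25th/75th percentiles,
  age–height regression, height→age conversion, ingrowth-time
  distributions and stand densities from canopy-height tree tables.
* **Synthetic data** — seeded generators (climate with a post-1950
  warming break, tree populations with known β/φ/σ and declining
  age curves, stand tables) so the whole chain is testable against
  recorded ground truth.

## Worked example

Simulate a larch-like treeline population, detrend, and run the
short-term climate–growth analysis (a reduced 6-month candidate set keeps
the example quick; the full analysis uses all 15 months):

```r
library(dendrogrowth)

truth   <- sim_truth("larch_like", population = list(n_trees = 40L),
                     trend = list(beta1 = 0, beta2 = 0, beta3 = 0,
                                  beta0 = 0, re_sd = c(0, 0, 0, 0)))
climate <- simulate_climate(truth, 1850:2008, seed = 42)
pop     <- simulate_population(truth, climate, seed = 42)

rwi_sp <- lapply(pop$series, spline_detrend)
rwi_sp <- Filter(Negate(is.null), lapply(rwi_sp, truncate_rwi, start = 1851))
design <- build_lag_design(climate)

sel <- exhaustive_select(design, rwi_table(rwi_sp),
                         candidates = c("prevSep", "prevOct", "curFeb",
                                        "curApr", "curJun", "curJul"))
final <- finalize_with_random_slopes(sel)
summary(final)
```

```
         term estimate      se      t        p signif  re_sd
1 (Intercept)   0.9964 0.00371 268.23 0.00e+00    *** 0.0000
2     prevSep   0.0834 0.01092   7.64 2.52e-14    *** 0.0660
3     prevOct   0.0881 0.00989   8.91 6.74e-19    *** 0.0591
4      curFeb  -0.1292 0.00701 -18.42 1.66e-73    *** 0.0395
5      curApr  -0.1293 0.00779 -16.60 2.31e-60    *** 0.0446
6      curJun   0.1142 0.00542  21.06 1.29e-94    *** 0.0276
7      curJul   0.1927 0.00426  45.26 0.00e+00    *** 0.0159
```

Read: July temperature has the strongest effect — +1 SD of July mean
temperature raises the ring-width index by ~19% — with the *smallest*
among-tree SD (0.016, in the `re_sd` column): summer warmth synchronizes
all trees. The previous-fall effects (reserve building) are positive with
the largest among-tree variability; late-winter/spring effects are
negative. The generating values (0.25 for July, ±0.11–0.15 elsewhere) are
attenuated a little by the spline detrending, and the random-intercept SD
is 0 because a per-tree level offset is exactly what detrending removes.

Long-term trend on RCS indices from the same generator (full preset,
60 trees):

```r
truth2 <- sim_truth("larch_like", population = list(n_trees = 60L))
pop2   <- simulate_population(truth2,
                              simulate_climate(truth2, 1850:2008, seed = 43),
                              seed = 43)
# pith-hit cores get offset 0; truncated cores here take the generator's
# recorded true offsets (field data would use estimate_pith_offset())
series <- pop2$series
for (j in seq_along(series)) {
  if (series[[j]]$pith_hit) series[[j]] <- set_pith_offset(series[[j]])
  else series[[j]]$pith_offset_rings <- pop2$truth_record$true_pith_offset[j]
}
series <- apply_pith_exclusion(series)
rc      <- build_regional_curve(series)
rwi_rcs <- lapply(series, rcs_detrend, rc = rc)
rwi_rcs <- Filter(Negate(is.null), lapply(rwi_rcs, truncate_rwi, 1850))
tf <- fit_trend(rwi_table(rwi_rcs), pop2$meta)
tf$beta
```

```
                  term  estimate       se     t         p
1               beta_0  2.91e+02 7.30e+00  39.9 1.54e-318
2        beta_1 (year) -1.42e-01 3.75e-03 -38.0 1.75e-290
3        beta_2 (elev) -1.26e-01 3.08e-03 -40.9  0.00e+00
4 beta_3 (year x elev)  6.15e-05 1.58e-06  39.0 3.08e-304
```

The generating coefficients were β₁ = −0.140, β₂ = −0.123,
β₃ = 6×10⁻⁵: the log-scale growth trend at elevation *e* is
β₁ + β₃·e, positive and steepest near the top of the 2,250–2,540 m
gradient. `predict_trend(tf)` returns back-transformed index predictions
at the six elevation percentiles (at a fixed year they decrease with
elevation — the β₂ effect — while their slopes over time increase with
elevation).

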