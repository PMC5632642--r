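test_that("a constant series detrends to indices of exactly 1", {
  s <- ring_series("C01", rep(1.5, 100), 1900)
  r <- spline_detrend(s)
  expect_lt(max(abs(r$indices - 1)), 1e-6)
  expect_identical(r$method, "spline")
})

test_that("a linear ramp is removed by the spline", {
  w <- round(seq(0.5, 2.5, length.out = 200), 2)
  s <- ring_series("R01", w, 1800)
  r <- spline_detrend(s)
  expect_gt(mean(r$indices), 0.99)
  expect_lt(mean(r$indices), 1.01)
  expect_lt(abs(cor(r$indices, seq_along(w))), 0.2)
})

test_that("high-frequency variability survives detrending", {
  t <- 1:200
  ramp <- seq(1.0, 2.0, length.out = 200)
  w <- round(ramp + 0.2 * sin(2 * pi * t / 8), 2)
  s <- ring_series("S01", w, 1800)
  r <- spline_detrend(s)
  # expected index-scale sinusoid, allowing for the ramp in the denominator
  s_t <- 0.2 * sin(2 * pi * t / 8) / ramp
  slope <- coef(lm(I(r$indices - mean(r$indices)) ~ 0 + s_t))[[1]]
  expect_gt(slope^2, 0.8)  # >= 80% of the sinusoid's variance retained
})

test_that("detrending is invariant to a positive scale factor", {
  set.seed(21)
  w <- round(pmax(rnorm(150, 1.5, 0.3), 0.01), 2)
  s1 <- ring_series("SC1", w, 1850)
  s2 <- ring_series("SC2", w * 3, 1850)
  expect_lt(max(abs(spline_detrend(s1)$indices - spline_detrend(s2)$indices)),
            1e-9)
})

test_that("the spline's empirical frequency response is 50% at the wavelength", {
  for (wl in c(20, 32, 64)) {
    t <- 1:640
    y <- 1.5 + 0.3 * sin(2 * pi * t / wl)
    g <- dendrogrowth:::caps_spline(y, wl)
    mid <- 120:520  # away from boundaries
    cf <- coef(lm(g[mid] ~ sin(2 * pi * mid / wl) + cos(2 * pi * mid / wl)))
    resp <- sqrt(sum(cf[2:3]^2)) / 0.3
    expect_gt(resp, 0.45)
    expect_lt(resp, 0.55)
  }
})

test_that("degenerate inputs to spline_detrend error", {
  expect_error(spline_detrend(ring_series("Z", rep(0, 50), 1900)), "all-zero")
  expect_error(spline_detrend(ring_series("S", c(1, 1, 1), 1900)), "short")
})

test_that("pith offsets match the geometric closed form and circle-fit oracle", {
  p1 <- estimate_pith_offset(10, 5, 1.0)
  expect_equal(p1$estimated_radius_to_pith, 5.0)
  expect_identical(p1$missing_rings, 5L)
  p2 <- estimate_pith_offset(8, 1, 0.5)
  expect_equal(p2$estimated_radius_to_pith, 8.5)
  expect_identical(p2$missing_rings, 17L)
  set.seed(4)
  for (i in 1:200) {
    L <- runif(1, 0.5, 30)
    h <- runif(1, 0.05, L)
    est <- estimate_pith_offset(L, h, runif(1, 0.1, 2))
    expect_lt(abs(est$estimated_radius_to_pith - circle_fit_radius(L, h)),
              1e-9)
    expect_gte(est$estimated_radius_to_pith, h / 2)
  }
  expect_error(estimate_pith_offset(0, 1, 1), "positive")
  expect_error(estimate_pith_offset(1, -1, 1), "positive")
})

test_that("pith-hit series get offset 0 and others need an estimate", {
  hit <- ring_series("H1", rep(1, 20), 1950, pith_hit = TRUE)
  expect_identical(set_pith_offset(hit)$pith_offset_rings, 0L)
  miss <- ring_series("M1", rep(1, 20), 1950)
  expect_error(set_pith_offset(miss), "pith_estimate")
  est <- estimate_pith_offset(6, 2, 0.8)
  expect_identical(set_pith_offset(miss, est)$pith_offset_rings,
                   est$missing_rings)
})

test_that("the missing-ring exclusion boundary is strict at 10", {
  mk <- function(id, off) {
    s <- ring_series(id, rep(1, 30), 1950)
    s$pith_offset_rings <- as.integer(off)
    s
  }
  kept <- apply_pith_exclusion(list(mk("A", 10), mk("B", 11), mk("C", 0)))
  expect_setequal(vapply(kept, `[[`, "", "series_id"), c("A", "C"))
  expect_identical(attr(kept, "n_excluded"), 1L)
  empty <- apply_pith_exclusion(list())
  expect_length(empty, 0L)
})

test_that("the regional curve averages constants exactly", {
  mk <- function(id, w) {
    s <- ring_series(id, rep(w, 40), 1950, pith_hit = TRUE)
    set_pith_offset(s)
  }
  rc <- build_regional_curve(list(mk("A", 1.0), mk("B", 3.0)))
  expect_equal(rc$mean_width, rep(2.0, 40))
  expect_equal(rc$n_at_age, rep(2L, 40))
  one <- mk("A", 1.25)
  rc1 <- build_regional_curve(list(one))
  expect_equal(rc1$mean_width, one$widths)
})

test_that("the regional curve recovers a known age trend from noisy series", {
  set.seed(31)
  true_curve <- function(age) 2 * exp(-age / 50) + 0.3
  series <- lapply(1:80, function(j) {
    n <- sample(60:120, 1)
    w <- round(pmax(true_curve(1:n) * exp(rnorm(n, 0, 0.08)), 0.01), 2)
    s <- ring_series(sprintf("RC%02d", j), w, 1900 - n, pith_hit = TRUE)
    set_pith_offset(s)
  })
  rc <- build_regional_curve(series)
  deep <- rc$n_at_age >= 25
  rel_err <- abs(rc$mean_width[deep] - true_curve(rc$cambial_age[deep])) /
    true_curve(rc$cambial_age[deep])
  expect_lt(max(rel_err), 0.05)
  expect_lt(mean(rel_err), 0.02)
})

test_that("RCS of the regional curve itself gives indices 1 (and 2 for x2)", {
  s <- ring_series("RCS1", round(2 * exp(-(1:60) / 50) + 0.3, 2), 1940,
                   pith_hit = TRUE)
  s <- set_pith_offset(s)
  rc <- build_regional_curve(list(s))
  expect_equal(rcs_detrend(s, rc)$indices, rep(1, 60))
  s2 <- s
  s2$widths <- s$widths * 2
  expect_equal(rcs_detrend(s2, rc)$indices, rep(2, 60))
})

test_that("RCS indices are invariant to a common scale on curve and series", {
  set.seed(8)
  s <- ring_series("SCL", round(pmax(2 * exp(-(1:50) / 40) + rnorm(50, 0, 0.1),
                                     0.01), 2), 1950, pith_hit = TRUE)
  s <- set_pith_offset(s)
  rc <- build_regional_curve(list(s))
  # multiply the curve by c and the series by c: indices unchanged
  rc2 <- rc
  rc2$mean_width <- rc$mean_width * 3
  s_mul <- s
  s_mul$widths <- s$widths * 3
  expect_equal(rcs_detrend(s, rc)$indices, rcs_detrend(s_mul, rc2)$indices,
               tolerance = 1e-12)
})

test_that("RCS extends the curve by holding the last value and floors zeros", {
  s <- ring_series("EXT", rep(1, 10), 1990, pith_hit = TRUE)
  s <- set_pith_offset(s)
  rc <- build_regional_curve(list(ring_series("SHORT", rep(2, 5), 1990,
                                              pith_hit = TRUE) |>
                                    set_pith_offset()))
  r <- rcs_detrend(s, rc)
  expect_equal(r$indices, rep(0.5, 10))
  expect_true(attr(r, "rc_extended"))
  # a zero-width (locally absent) ring is floored, keeping log(index) finite
  ones <- set_pith_offset(ring_series("ONES", rep(1, 5), 2000,
                                      pith_hit = TRUE))
  z <- set_pith_offset(ring_series("ZERO", c(1, 0, 1, 1, 1), 2000,
                                   pith_hit = TRUE))
  rz <- rcs_detrend(z, build_regional_curve(list(ones)))
  expect_true(all(rz$indices > 0))
  expect_equal(rz$indices[2], 0.005)
  # a genuinely zero regional-curve value is an error
  expect_error(rcs_detrend(ones, build_regional_curve(list(z))),
               "zero at a needed")
})

test_that("truncation keeps post-1850 years and rwi_table flattens", {
  s <- ring_series("T1", rep(1.5, 100), 1800)
  r <- truncate_rwi(spline_detrend(s), 1850)
  expect_identical(r$first_year, 1850L)
  expect_length(r$indices, 50L)
  tab <- rwi_table(list(r))
  expect_equal(nrow(tab), 50L)
  expect_equal(unique(tab$method), "spline")
  expect_null(truncate_rwi(spline_detrend(ring_series("T2", rep(1, 20), 1700)),
                           1850))
})
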