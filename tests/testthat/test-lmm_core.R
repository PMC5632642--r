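test_that("the marginal likelihood matches the brute-force MVN oracle", {
  set.seed(55)
  for (i in 1:30) {
    inst <- random_small_instance()
    spec <- lmm_spec("y", inst$fixed,
                     random = if (length(inst$random_slopes))
                       inst$random_slopes else "intercept",
                     ar1 = TRUE)
    ours <- marginal_loglik(spec, inst$data, inst$params, method = "ML")
    oracle <- brute_force_loglik(inst$data, inst$fixed, inst$random_slopes,
                                 inst$params, method = "ML")
    expect_lt(abs(ours - oracle), 1e-8)
  }
})

test_that("with phi = 0 and no random effects the likelihood is the OLS one", {
  set.seed(60)
  d <- expand.grid(tree_id = paste0("t", 1:4), year = 2001:2010,
                   stringsAsFactors = FALSE)
  d$x1 <- rnorm(nrow(d))
  d$y <- 1 + 0.5 * d$x1 + rnorm(nrow(d), 0, 0.3)
  spec <- lmm_spec("y", "x1", random = "none", ar1 = FALSE)
  beta <- c(1, 0.5); sigma <- 0.3
  ll <- marginal_loglik(spec, d, list(beta = beta, phi = 0, sigma = sigma))
  r <- d$y - beta[1] - beta[2] * d$x1
  expect_equal(ll, sum(dnorm(r, 0, sigma, log = TRUE)), tolerance = 1e-10)
})

test_that("REML minus ML at the GLS solution equals the standard adjustment", {
  set.seed(61)
  inst <- random_small_instance()
  spec <- lmm_spec("y", inst$fixed,
                   random = if (length(inst$random_slopes))
                     inst$random_slopes else "intercept",
                   ar1 = TRUE)
  reml <- marginal_loglik(spec, inst$data, inst$params, method = "REML")
  oracle <- brute_force_loglik(inst$data, inst$fixed, inst$random_slopes,
                               inst$params, method = "REML")
  expect_lt(abs(reml - oracle), 1e-8)
})

test_that("the likelihood is invariant to tree order and a common year shift", {
  set.seed(62)
  inst <- random_small_instance()
  spec <- lmm_spec("y", inst$fixed,
                   random = if (length(inst$random_slopes))
                     inst$random_slopes else "intercept",
                   ar1 = TRUE)
  ll <- marginal_loglik(spec, inst$data, inst$params)
  shuf <- inst$data[sample(nrow(inst$data)), ]
  expect_equal(marginal_loglik(spec, shuf, inst$params), ll,
               tolerance = 1e-10)
  shifted <- inst$data
  shifted$year <- shifted$year + 137L
  expect_equal(marginal_loglik(spec, shifted, inst$params), ll,
               tolerance = 1e-10)
})

test_that("invalid parameters are rejected", {
  d <- expand.grid(tree_id = paste0("t", 1:2), year = 2001:2005,
                   stringsAsFactors = FALSE)
  d$x1 <- rnorm(nrow(d)); d$y <- rnorm(nrow(d))
  spec <- lmm_spec("y", "x1", ar1 = TRUE)
  expect_error(marginal_loglik(spec, d, list(beta = c(0, 0), re_sd = 0.1,
                                             phi = 1.2, sigma = 1)),
               "phi")
  expect_error(marginal_loglik(spec, d, list(beta = c(0, 0), re_sd = -0.1,
                                             phi = 0, sigma = 1)),
               ">= 0")
})

test_that("fit_lmm reduces to OLS without variance structure", {
  set.seed(63)
  d <- expand.grid(tree_id = paste0("t", 1:6), year = 1991:2010,
                   stringsAsFactors = FALSE)
  d$x1 <- rnorm(nrow(d)); d$x2 <- rnorm(nrow(d))
  d$y <- 0.3 - 0.2 * d$x1 + 0.5 * d$x2 + rnorm(nrow(d), 0, 0.2)
  f <- fit_lmm(lmm_spec("y", c("x1", "x2"), random = "none", ar1 = FALSE), d)
  ols <- coef(lm(y ~ x1 + x2, data = d))
  expect_equal(f$beta$estimate, unname(ols), tolerance = 1e-8)
})

test_that("parameters of an AR(1) random-intercept model are recovered", {
  des <- make_design()
  ds <- make_growth_dataset(60, 1929:2008, c(curJul = 0.2),
                            re_sd_intercept = 0.1, phi = 0.6, sigma = 0.15,
                            seed = 11, design = des)
  spec <- lmm_spec("rwi", "curJul", random = "intercept", ar1 = TRUE)
  f <- fit_lmm(spec, ds$data, method = "REML")
  expect_true(f$converged)
  b <- f$beta[f$beta$term == "curJul", ]
  expect_lt(abs(b$estimate - 0.2) / b$se, 3)
  expect_false(is.null(f$var_se))
  expect_lt(abs(f$phi - 0.6) / f$var_se[["phi"]], 3)
  expect_lt(abs(f$sigma - 0.15) / f$var_se[["sigma"]], 3)
  expect_lt(abs(f$re_sd[["(Intercept)"]] - 0.1) / f$var_se[["(Intercept)"]], 3)
})

test_that("refits from dispersed starts reach the same likelihood", {
  des <- make_design()
  ds <- make_growth_dataset(20, 1959:2008, c(curJun = 0.15), seed = 13,
                            design = des)
  spec <- lmm_spec("rwi", "curJun", random = "intercept", ar1 = TRUE)
  lls <- vapply(1:5, function(k) {
    start <- list(phi = c(-0.5, 0, 0.3, 0.7, 0.9)[k],
                  gamma = c(1e-4, 0.01, 0.1, 1, 10)[k])
    fit_lmm(spec, ds$data, method = "ML", start = start, se = FALSE)$loglik
  }, numeric(1))
  expect_lt(diff(range(lls)), 1e-4)
})

test_that("ML likelihood is monotone in nested fixed structures", {
  des <- make_design()
  ds <- make_growth_dataset(15, 1969:2008, c(curJul = 0.2), seed = 17,
                            design = des)
  small <- fit_lmm(lmm_spec("rwi", "curJul"), ds$data, method = "ML",
                   se = FALSE)
  big <- fit_lmm(lmm_spec("rwi", c("curJul", "curJan", "prevSep")), ds$data,
                 method = "ML", se = FALSE)
  expect_gte(big$loglik, small$loglik - 1e-6)
})

test_that("phi is estimated near zero for serially independent data", {
  des <- make_design()
  hits <- vapply(1:10, function(s) {
    ds <- make_growth_dataset(60, 1929:2008, c(curJul = 0.2), phi = 0,
                              sigma = 0.15, seed = 100 + s, design = des)
    f <- fit_lmm(lmm_spec("rwi", "curJul"), ds$data, method = "ML",
                 se = FALSE)
    abs(f$phi) < 0.1
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("information criteria follow their definitions", {
  ic <- information_criteria(loglik = -100, k = 5, n_obs = 100)
  expect_equal(ic[["AIC"]], 210)
  expect_equal(ic[["BIC"]], 200 + 5 * log(100), tolerance = 1e-10)
  expect_equal(ic[["BIC"]], 223.0259, tolerance = 1e-4)
  expect_error(information_criteria(loglik = -100, k = 0, n_obs = 100),
               ">= 1")
})

test_that("BIC prefers the smaller model when the extra term is null", {
  des <- make_design()
  wins <- vapply(1:100, function(s) {
    ds <- make_growth_dataset(8, 1984:2008, c(curJul = 0.2),
                              re_sd_intercept = 0.05, phi = 0.3,
                              sigma = 0.15, seed = 3000 + s, design = des)
    f1 <- fit_lmm(lmm_spec("rwi", "curJul"), ds$data, method = "ML",
                  se = FALSE)
    f2 <- fit_lmm(lmm_spec("rwi", c("curJul", "curMar")), ds$data,
                  method = "ML", se = FALSE)
    information_criteria(f1)[["BIC"]] < information_criteria(f2)[["BIC"]]
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("diagnostics behave on well- and mis-specified models", {
  des <- make_design()
  ds <- make_growth_dataset(30, 1949:2008, c(curJul = 0.2, curJun = 0.15),
                            phi = 0.5, seed = 19, design = des)
  f <- fit_lmm(lmm_spec("rwi", c("curJul", "curJun")), ds$data)
  dg <- diagnostics(f)
  expect_gt(dg$resid_lag1, -0.1)
  expect_lt(dg$resid_lag1, 0.1)
  expect_false(dg$collinearity_flag)

  # near-duplicated predictor -> huge VIF
  d2 <- ds$data
  d2$curJul2 <- d2$curJul + rnorm(nrow(d2), 0, 1e-4)
  f2 <- fit_lmm(lmm_spec("rwi", c("curJul", "curJul2")), d2, se = FALSE)
  dg2 <- diagnostics(f2)
  expect_true(dg2$collinearity_flag)

  # heavy-tailed noise -> normality flag
  set.seed(77)
  d3 <- ds$data
  d3$rwi <- 1 + 0.2 * d3$curJul + 0.1 * stats::rt(nrow(d3), df = 2)
  f3 <- fit_lmm(lmm_spec("rwi", "curJul"), d3, se = FALSE)
  expect_true(diagnostics(f3)$normality_flag)
})

test_that("the fit agrees with nlme::lme on a shared dataset", {
  des <- make_design()
  ds <- make_growth_dataset(20, 1959:2008, c(curJul = 0.2), phi = 0.6,
                            seed = 23, design = des)
  f <- fit_lmm(lmm_spec("rwi", "curJul"), ds$data, method = "REML")
  g <- nlme::lme(rwi ~ curJul, random = ~ 1 | tree_id, data = ds$data,
                 correlation = nlme::corAR1(form = ~ year | tree_id),
                 method = "REML")
  expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-4)
  expect_equal(f$beta$estimate, unname(nlme::fixef(g)), tolerance = 1e-4)
  expect_equal(f$phi,
               as.numeric(coef(g$modelStruct$corStruct,
                               unconstrained = FALSE)),
               tolerance = 1e-3)
  expect_equal(f$sigma, g$sigma, tolerance = 1e-4)
})

test_that("rank-deficient designs and tiny groups are rejected", {
  d <- expand.grid(tree_id = paste0("t", 1:5), year = 2001:2012,
                   stringsAsFactors = FALSE)
  d$x1 <- rnorm(nrow(d))
  d$x2 <- d$x1  # exact duplicate
  d$y <- rnorm(nrow(d))
  expect_error(fit_lmm(lmm_spec("y", c("x1", "x2")), d), "rank deficient")
  d1 <- d[d$tree_id == "t1", ]
  expect_error(fit_lmm(lmm_spec("y", "x1"), d1), ">= 2 trees")
})
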