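# Shared dataset builders for model-level tests.

# Climate -> lagged design over the requested response years.
make_design <- function(years = 1925:2008, seed = 5) {
  truth <- sim_truth("larch_like")
  build_lag_design(simulate_climate(truth, years, seed = seed))
}

# Long dataset of trees x years with the 15 standardized monthly columns and
# a simulated index response; returns both the modelling frame and the
# rwi-table view used by the selection functions.
make_growth_dataset <- function(n_trees, years, beta_named,
                                re_sd_intercept = 0.1, slope_sd = NULL,
                                phi = 0.5, sigma = 0.15, seed = 1,
                                design = NULL) {
  if (is.null(design)) design <- make_design(c(min(years) - 5, max(years))[1]:max(years))
  base <- expand.grid(tree_id = sprintf("t%03d", seq_len(n_trees)),
                      year = years, stringsAsFactors = FALSE)
  di <- match(base$year, design$response_years)
  stopifnot(!anyNA(di))
  dat <- cbind(base, as.data.frame(design$X[di, , drop = FALSE],
                                   row.names = NULL))
  cols <- colnames(design$X)
  beta <- setNames(numeric(15), cols)
  beta[names(beta_named)] <- beta_named
  if (is.null(slope_sd)) {
    random <- "intercept"
    re_sd <- re_sd_intercept
  } else {
    random <- names(slope_sd)
    re_sd <- c(re_sd_intercept, unname(slope_sd))
  }
  dat <- simulate_lmm_response(dat, cols, random = random,
                               beta = c(1, beta), re_sd = re_sd,
                               phi = phi, sigma = sigma,
                               response = "rwi", seed = seed)
  rwi_df <- data.frame(series_id = dat$tree_id, tree_id = dat$tree_id,
                       year = dat$year, index = dat$rwi, method = "spline")
  list(data = dat, rwi = rwi_df, design = design, beta = beta)
}

# Direct simulation of the long-term trend equation: log RCS index as a
# linear function of year, elevation and their interaction with tree-level
# random effects and AR(1) noise.
make_trend_dataset <- function(n_trees = 90, years = 1859:2008,
                               elev_range = c(2250, 2540),
                               beta = c(NA, -0.13, -0.12, 6e-5),
                               re_sd = c(0.08, 1e-4, 2e-5, 3e-8),
                               phi = 0.6, sigma = 0.18, seed = 1) {
  set.seed(seed)
  elev <- runif(n_trees, elev_range[1], elev_range[2])
  rows <- do.call(rbind, lapply(seq_len(n_trees), function(j) {
    data.frame(tree_id = sprintf("t%03d", j), year = years,
               elevation = elev[j])
  }))
  rows$t_e <- rows$year * rows$elevation
  if (is.na(beta[1])) {
    beta[1] <- -(beta[2] * mean(years) + beta[3] * mean(elev) +
                   beta[4] * mean(years) * mean(elev))
  }
  rows <- simulate_lmm_response(rows, c("year", "elevation", "t_e"),
                                random = c("year", "elevation", "t_e"),
                                beta = beta, re_sd = re_sd, phi = phi,
                                sigma = sigma, response = "log_rwi",
                                seed = seed + 1000L)
  list(rwi = data.frame(tree_id = rows$tree_id, year = rows$year,
                        index = exp(rows$log_rwi)),
       meta = unique(rows[c("tree_id", "elevation")]),
       beta = beta)
}
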