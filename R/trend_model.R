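# Long-term growth-trend model: log RCS index as a function of calendar
# year, elevation and their interaction, with tree-level random slopes and
# AR(1) residuals.

# Build the modelling frame: log index, centered year/elevation and their
# interaction, plus any extra (centered) tree covariates.
.trend_frame <- function(rwi_rcs, meta, start_year = 1850,
                         covariates = character()) {
  if (!is.data.frame(rwi_rcs)) rwi_rcs <- rwi_table(rwi_rcs)
  need <- c("tree_id", "year", "index")
  if (!all(need %in% names(rwi_rcs))) {
    stop("rwi table needs columns tree_id, year, index", call. = FALSE)
  }
  rwi_rcs <- rwi_rcs[rwi_rcs$year >= start_year, , drop = FALSE]
  mi <- match(rwi_rcs$tree_id, meta$tree_id)
  if (anyNA(mi)) stop("trees missing from metadata: ",
                      paste(unique(rwi_rcs$tree_id[is.na(mi)]), collapse = ", "),
                      call. = FALSE)
  d <- data.frame(tree_id = rwi_rcs$tree_id, year = rwi_rcs$year,
                  log_rwi = log(rwi_rcs$index),
                  elevation = meta$elevation[mi])
  for (cv in covariates) d[[cv]] <- meta[[cv]][mi]
  n0 <- nrow(d)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < n0) {
    message(sprintf("%d rows dropped for missing covariate values", n0 - nrow(d)))
  }
  t_bar <- mean(d$year)
  e_bar <- mean(d$elevation)
  d$t_c <- d$year - t_bar
  d$elev_c <- d$elevation - e_bar
  d$t_elev_c <- d$t_c * d$elev_c
  for (cv in covariates) d[[cv]] <- d[[cv]] - mean(d[[cv]])
  structure(d, t_bar = t_bar, e_bar = e_bar)
}

#' Fit the long-term growth-trend model
#'
#' Fits, by REML, the mixed model
#' \deqn{\log(\mathrm{RWI}^{RCS}_t) = \beta_0 + (\beta_1 + b_1) t +
#'   (\beta_2 + b_2)\,\mathrm{elev} + (\beta_3 + b_3)\, t \cdot \mathrm{elev}
#'   + b_0 + \epsilon_t}
#' with diagonal tree-level random effects \eqn{b_0..b_3}, AR(1) residual
#' correlation, `t` the calendar year and `elev` the tree's elevation in m.
#' Internally the model is fitted on centred `t` and `elev` for numerical
#' conditioning; the reported coefficients are transformed back to the
#' uncentred scale (year and m a.s.l.), where the interaction coefficient and
#' all predictions are invariant to the centring.
#'
#' @param rwi_rcs RCS-detrended indices (list of `rwi_series` or a
#'   [rwi_table()] data frame with positive `index` values).
#' @param meta Tree metadata with `tree_id` and `elevation` (m a.s.l.).
#' @param start_year Trend analysis start (default 1850).
#' @param covariates Optional extra tree covariates to include as fixed
#'   effects (used by [screen_covariates()]).
#' @param random `"slopes"` (default: random `b_0..b_3`) or `"intercept"`.
#' @param method `"REML"` (default) or `"ML"`.
#' @param se Compute variance-parameter standard errors.
#' @return An object of class `trend_fit` (extending `lmm_fit`) whose
#'   `beta` table reports `beta_0..beta_3` on the uncentred year/elevation
#'   scale; random-effect SDs refer to the centred predictors.
#' @export
fit_trend <- function(rwi_rcs, meta, start_year = 1850,
                      covariates = character(),
                      random = c("slopes", "intercept"),
                      method = c("REML", "ML"), se = TRUE) {
  random <- match.arg(random)
  method <- match.arg(method)
  d <- .trend_frame(rwi_rcs, meta, start_year, covariates)
  if (length(unique(d$tree_id)) < 3L) stop("need >= 3 trees", call. = FALSE)
  base_terms <- c("t_c", "elev_c", "t_elev_c")
  spec <- lmm_spec("log_rwi", c(base_terms, covariates),
                   random = if (random == "slopes") base_terms else "intercept",
                   ar1 = TRUE)
  fit <- fit_lmm(spec, d, method = method, se = se)

  t_bar <- attr(d, "t_bar"); e_bar <- attr(d, "e_bar")
  # uncentred beta = T %*% centred beta (extras map one-to-one)
  cn <- fit$beta$term
  p <- length(cn)
  Tm <- diag(p)
  dimnames(Tm) <- list(cn, cn)
  Tm["(Intercept)", c("t_c", "elev_c", "t_elev_c")] <-
    c(-t_bar, -e_bar, t_bar * e_bar)
  Tm["t_c", "t_elev_c"] <- -e_bar
  Tm["elev_c", "t_elev_c"] <- -t_bar
  b_u <- as.numeric(Tm %*% fit$beta$estimate)
  V_u <- Tm %*% fit$vcov_beta %*% t(Tm)
  se_u <- sqrt(diag(V_u))
  tv <- b_u / se_u
  pv <- 2 * pt(-abs(tv), df = max(fit$df_resid, 1L))
  lab <- cn
  lab[match(c("(Intercept)", "t_c", "elev_c", "t_elev_c"), cn)] <-
    c("beta_0", "beta_1 (year)", "beta_2 (elev)", "beta_3 (year x elev)")
  fit$beta_centered <- fit$beta
  fit$beta <- data.frame(term = lab, estimate = b_u, se = se_u, t = tv,
                         p = pv, row.names = NULL)
  fit$vcov_beta <- V_u
  fit$centers <- c(t_bar = t_bar, e_bar = e_bar)
  fit$elev_range <- range(d$elevation)
  fit$year_range <- range(d$year)
  fit$frame <- d
  class(fit) <- c("trend_fit", "lmm_fit")
  fit
}

#' AIC screening of tree covariates for the trend model
#'
#' Compares, by ML and AIC, all subsets of the candidate tree covariates
#' added to the base trend terms (year, elevation, year x elevation — always
#' included). Candidate fits use a tree-level random intercept with AR(1)
#' residuals; the winning fixed structure is meant to be refit with the full
#' random-slope structure via [fit_trend()].
#'
#' @param rwi_rcs,meta,start_year As in [fit_trend()].
#' @param candidates Tree covariate names to screen (must be columns of
#'   `meta`); defaults to height, dbh, crown_length, aspect, slope where
#'   present.
#' @return A list with `table` (one row per subset with AIC, sorted),
#'   `best_covariates` (character, possibly empty), and `base_wins`
#'   (logical).
#' @export
screen_covariates <- function(rwi_rcs, meta, start_year = 1850,
                              candidates = intersect(
                                c("height", "dbh", "crown_length", "aspect",
                                  "slope"), names(meta))) {
  m <- length(candidates)
  if (m == 0L) {
    return(list(table = data.frame(covariates = "(none)", k = NA, loglik = NA,
                                   AIC = NA),
                best_covariates = character(), base_wins = TRUE))
  }
  masks <- 0:(2^m - 1L)
  rows <- lapply(masks, function(mk) {
    cv <- candidates[bitwAnd(bitwShiftR(mk, 0:(m - 1L)), 1L) == 1L]
    fit <- fit_trend(rwi_rcs, meta, start_year, covariates = cv,
                     random = "intercept", method = "ML", se = FALSE)
    ic <- information_criteria(fit)
    data.frame(covariates = if (length(cv)) paste(cv, collapse = "+") else "(none)",
               n_cov = length(cv), k = fit$n_params, loglik = fit$loglik,
               AIC = ic[["AIC"]], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AIC, tab$k), ]
  rownames(tab) <- NULL
  best <- tab$covariates[1L]
  best_cov <- if (best == "(none)") character() else strsplit(best, "\\+")[[1]]
  list(table = tab, best_covariates = best_cov,
       base_wins = length(best_cov) == 0L)
}

#' Predict ring-width indices from a trend fit
#'
#' Back-transformed (exponentiated) predictions of the RCS index over time.
#' In `"fixed_only"` mode predictions are made at six elevation levels — the
#' 0th, 20th, 40th, 60th, 80th and 100th percentiles of the elevation range
#' of the fitted trees. In `"per_tree"` mode each tree's predicted random
#' effects are added and predictions are made at the tree's own elevation
#' over its fitted years.
#'
#' @param fit A converged `trend_fit`.
#' @param mode `"fixed_only"` (default) or `"per_tree"`.
#' @param years Calendar years to predict (default: the fitted range).
#' @param allow_extrapolate Permit years outside the fitted range.
#' @return A data frame: `elev_percentile`, `elevation`, `year`, `rwi_pred`
#'   for `"fixed_only"`; `tree_id`, `elevation`, `year`, `rwi_pred` for
#'   `"per_tree"`.
#' @export
predict_trend <- function(fit, mode = c("fixed_only", "per_tree"),
                          years = NULL, allow_extrapolate = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "trend_fit"))
  if (is.null(years)) years <- fit$year_range[1]:fit$year_range[2]
  if (!allow_extrapolate &&
      (min(years) < fit$year_range[1] || max(years) > fit$year_range[2])) {
    stop("years outside the fitted range; set allow_extrapolate = TRUE",
         call. = FALSE)
  }
  b <- setNames(fit$beta$estimate, fit$beta$term)
  b0 <- b[["beta_0"]]; b1 <- b[["beta_1 (year)"]]
  b2 <- b[["beta_2 (elev)"]]; b3 <- b[["beta_3 (year x elev)"]]
  if (mode == "fixed_only") {
    pct <- seq(0, 100, by = 20)
    levels <- fit$elev_range[1] + pct / 100 * diff(fit$elev_range)
    out <- expand.grid(year = years, elevation = levels)
    out$elev_percentile <- rep(pct, each = length(years))
    out$rwi_pred <- exp(b0 + b1 * out$year + b2 * out$elevation +
                          b3 * out$year * out$elevation)
    return(out[, c("elev_percentile", "elevation", "year", "rwi_pred")])
  }
  # per-tree: fixed part at the tree's elevation plus its predicted random
  # effects (on the centred basis used in the fit)
  B <- ranef_lmm(fit)
  d <- fit$frame
  trees <- rownames(B)
  rows <- lapply(trees, function(tr) {
    sel <- d$tree_id == tr
    e <- d$elevation[sel][1L]
    yrs <- intersect(years, d$year[sel])
    if (!length(yrs)) return(NULL)
    tc <- yrs - fit$centers[["t_bar"]]
    ec <- e - fit$centers[["e_bar"]]
    eta <- b0 + b1 * yrs + b2 * e + b3 * yrs * e
    re <- B[tr, "(Intercept)"]
    if ("t_c" %in% colnames(B)) re <- re + B[tr, "t_c"] * tc
    if ("elev_c" %in% colnames(B)) re <- re + B[tr, "elev_c"] * ec
    if ("t_elev_c" %in% colnames(B)) re <- re + B[tr, "t_elev_c"] * tc * ec
    data.frame(tree_id = tr, elevation = e, year = yrs,
               rwi_pred = exp(eta + re), row.names = NULL)
  })
  do.call(rbind, rows)
}
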