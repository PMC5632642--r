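# Synthetic study generator: monthly climate with a post-1950 warming break,
# tree populations whose ring widths follow a declining cambial-age curve
# modulated by monthly temperature effects (with tree-level random slopes),
# an elevation-dependent long-term trend and AR(1) residuals, and stand
# tables coupled to age through a linear age-height relationship. All
# generating parameters are recorded so recovery can be tested end to end.

#' Ground-truth parameter set for a synthetic study
#'
#' Returns the full generative parameter list. The `"larch_like"` preset
#' mimics a temperature-limited larch population near the alpine treeline:
#' positive previous-fall and mid-summer temperature effects with the
#' largest coefficient (0.25 per +1 SD) in current July, negative late
#' winter/spring and late-summer effects, a tree-level random intercept and
#' slopes concentrated on the previous-fall months, moderate AR(1) residual
#' correlation, monthly warming that accelerates after 1950 (strongest in
#' June, weakest in September), and a long-term log-scale trend interacting
#' with elevation (positive at the top of the 2,250-2,540 m range).
#'
#' @param preset `"larch_like"` or `"null"` (all effects zero; pure
#'   age-curve growth).
#' @param ... Named overrides of any element (nested lists are replaced
#'   wholesale).
#' @return A list of class `sim_truth` with elements `climate`,
#'   `population`, `growth`, `trend`, `stand`.
#' @export
sim_truth <- function(preset = c("larch_like", "null"), ...) {
  preset <- match.arg(preset)
  betas <- setNames(numeric(15), lag_design_columns())
  re_sd <- betas
  if (preset == "larch_like") {
    betas[c("prevAug", "prevSep", "prevOct")] <- c(0.07, 0.12, 0.12)
    betas[c("curFeb", "curApr")] <- c(-0.11, -0.12)
    betas[c("curJun", "curJul")] <- c(0.15, 0.25)
    betas["curAug"] <- -0.08
    re_sd[c("prevAug", "prevSep", "prevOct")] <- 0.08
    re_sd[c("curFeb", "curApr")] <- 0.05
    re_sd[c("curJun", "curJul")] <- c(0.04, 0.02)
    re_sd["curAug"] <- 0.06
  }
  truth <- list(
    climate = list(
      # monthly normals (degC) at ~2,400 m in the central Alps
      seasonal_mean = c(-8, -8, -6, -3, 1.5, 5, 7.5, 7, 4.5, 1, -4, -7),
      warming_start = 1950,
      # warming slope per month (degC / yr after the break); June strongest,
      # September nearly flat
      warming_slope = c(0.030, 0.028, 0.030, 0.025, 0.025, 0.035, 0.030,
                        0.030, 0.008, 0.020, 0.020, 0.025),
      noise_sd = 1.2),
    population = list(
      n_trees = 90L,
      elev_range = c(2250, 2540),
      establishment_range = c(1750, 1950),
      p_no_pith = 0.3,
      max_truncated_rings = 8L),
    growth = list(
      rc = list(a = 1.2, tau = 60, c = 0.25),   # width(age) = a exp(-age/tau) + c, mm
      beta = if (preset == "larch_like") betas else 0 * betas,
      re_sd = if (preset == "larch_like") re_sd else 0 * re_sd,
      re_sd_intercept = if (preset == "larch_like") 0.10 else 0,
      phi = if (preset == "larch_like") 0.5 else 0,
      sigma = if (preset == "larch_like") 0.15 else 0),
    trend = list(
      beta1 = if (preset == "larch_like") -0.140 else 0,
      beta2 = if (preset == "larch_like") -0.123 else 0,
      beta3 = if (preset == "larch_like") 6e-5 else 0,
      beta0 = NULL,   # NULL: chosen so the mean log index is 0
      re_sd = c(0, 0, 0, 0)),  # SDs of b_0..b_3 (off by default; model-level sims set them)
    stand = list(
      age_height_b0 = 10,   # age = b0 + b1 * height
      age_height_b1 = 8,
      height_noise_sd = 1.5,
      mean_age = 80,
      detection_threshold = 2.5)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% names(truth) && is.list(dots[[nm]])) {
      truth[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      truth[[nm]] <- dots[[nm]]
    }
  }
  structure(truth, class = "sim_truth", preset = preset)
}

# Stationary AR(1) noise with unit-lag correlation phi and marginal sd sigma.
.sim_ar1 <- function(n, phi, sigma) {
  if (sigma == 0) return(numeric(n))
  e <- numeric(n)
  e[1L] <- rnorm(1L, 0, sigma)
  if (n > 1L) {
    innov <- rnorm(n - 1L, 0, sigma * sqrt(1 - phi^2))
    for (t in 2:n) e[t] <- phi * e[t - 1L] + innov[t - 1L]
  }
  e
}

#' Simulate a monthly temperature series with a warming break
#'
#' `T(y, m) = seasonal_mean(m) + warming_slope(m) * max(0, y - start) +
#' N(0, noise_sd)`, seeded and reproducible.
#'
#' @param truth A [sim_truth()].
#' @param years Calendar years (>= 30 of them).
#' @param seed RNG seed.
#' @param site Site label.
#' @return A [monthly_climate()].
#' @export
simulate_climate <- function(truth, years = 1850:2008, seed = 1,
                             site = "synthetic") {
  if (length(years) < 30L) stop("need >= 30 years of climate", call. = FALSE)
  cl <- truth$climate
  with_seed(seed, {
    warm <- outer(pmax(years - cl$warming_start, 0), cl$warming_slope)
    temp <- matrix(rep(cl$seasonal_mean, each = length(years)),
                   ncol = 12L) + warm +
      matrix(rnorm(length(years) * 12L, 0, cl$noise_sd), ncol = 12L)
    monthly_climate(site, years, temp)
  })
}

#' Simulate a tree population with known growth parameters
#'
#' Generates ring-width series for `n_trees` trees: each tree establishes in
#' a uniform random year, its expected width follows the declining regional
#' curve `a exp(-age/tau) + c`, and the log width is modulated by the
#' standardized monthly temperature effects (fixed plus tree-level random
#' slopes), the elevation-dependent long-term trend, a tree-level random
#' intercept, and AR(1) residual noise. Widths are rounded to the 0.01 mm
#' measurement resolution last. A fraction of cores miss the pith: their
#' innermost rings are truncated and the true offset recorded, exercising
#' the pith-estimation path.
#'
#' Growth is generated multiplicatively (log-additive), so for small effects
#' the spline index scale (index ~ 1 + effect) and the log RCS trend scale
#' are consistent limits of the same generative model.
#'
#' @param truth A [sim_truth()].
#' @param climate A [monthly_climate()] covering the simulation years.
#' @param seed RNG seed.
#' @return A list with `series` (list of [ring_series()]; truncated cores
#'   have `pith_hit = FALSE`), `meta` (tree metadata data frame), and
#'   `truth_record` (the generating parameters plus per-tree random effects
#'   and true pith offsets).
#' @export
simulate_population <- function(truth, climate, seed = 1) {
  pop <- truth$population
  gr <- truth$growth
  rc_fun <- function(age) gr$rc$a * exp(-age / gr$rc$tau) + gr$rc$c
  if (any(rc_fun(1:500) <= 0)) {
    stop("regional-curve parameters yield nonpositive expected widths",
         call. = FALSE)
  }
  last_year <- max(climate$years)
  design <- build_lag_design(climate)
  beta <- gr$beta[colnames(design$X)]
  re_sd <- gr$re_sd[colnames(design$X)]
  tr <- truth$trend
  with_seed(seed, {
    n <- pop$n_trees
    elev <- runif(n, pop$elev_range[1], pop$elev_range[2])
    est_max <- min(pop$establishment_range[2], last_year - 20L)
    est <- floor(runif(n, pop$establishment_range[1], est_max + 1))
    # trend intercept: centre the mean log index at 0 over the sample
    t_mid <- mean(c(max(min(est), 1850), last_year))
    e_mid <- mean(pop$elev_range)
    beta0 <- tr$beta0 %||%
      -(tr$beta1 * t_mid + tr$beta2 * e_mid + tr$beta3 * t_mid * e_mid)
    b0 <- rnorm(n, 0, gr$re_sd_intercept)
    b_slopes <- matrix(rnorm(n * 15L, 0, rep(re_sd, each = n)), nrow = n,
                       dimnames = list(NULL, names(re_sd)))
    trend_b <- cbind(
      rnorm(n, 0, tr$re_sd[1]), rnorm(n, 0, tr$re_sd[2]),
      rnorm(n, 0, tr$re_sd[3]), rnorm(n, 0, tr$re_sd[4]))
    no_pith <- runif(n) < pop$p_no_pith
    trunc_k <- ifelse(no_pith,
                      sample(seq_len(pop$max_truncated_rings), n, replace = TRUE),
                      0L)
    series <- vector("list", n)
    meta_rows <- vector("list", n)
    for (j in seq_len(n)) {
      yrs <- est[j]:last_year
      ages <- seq_along(yrs)
      eta <- rep(beta0 + b0[j] + trend_b[j, 1L], length(yrs)) +
        (tr$beta1 + trend_b[j, 2L]) * yrs +
        (tr$beta2 + trend_b[j, 3L]) * elev[j] +
        (tr$beta3 + trend_b[j, 4L]) * yrs * elev[j]
      di <- match(yrs, design$response_years)
      has_cl <- !is.na(di)
      if (any(has_cl)) {
        eff <- design$X[di[has_cl], , drop = FALSE] %*% (beta + b_slopes[j, ])
        eta[has_cl] <- eta[has_cl] + as.numeric(eff)
      }
      eta <- eta + .sim_ar1(length(yrs), gr$phi, gr$sigma)
      w <- round(rc_fun(ages) * exp(eta), 2)
      k <- trunc_k[j]
      first_yr <- est[j]
      if (k > 0L) {
        if (k >= length(w) - 5L) k <- 0L else {
          w <- w[-(seq_len(k))]
          first_yr <- est[j] + k
        }
      }
      id <- sprintf("SYN%03d", j)
      series[[j]] <- ring_series(id, w, first_yr, tree_id = id,
                                 site = climate$site, species = "synthetic",
                                 pith_hit = k == 0L,
                                 pith_offset_rings = if (k == 0L) 0L else NA_integer_)
      height <- max(1, (last_year - est[j] - truth$stand$age_height_b0) /
                      truth$stand$age_height_b1 + rnorm(1, 0, 1))
      meta_rows[[j]] <- data.frame(
        tree_id = id, site = climate$site, species = "synthetic",
        elevation = elev[j],
        dbh = max(2 * sum(w) / 10, 1),
        height = height,
        crown_length = 0.6 * height,
        aspect = runif(1, 0, 360), slope = runif(1, 0, 40),
        multi_stem = FALSE)
      trunc_k[j] <- k
    }
    names(series) <- vapply(series, `[[`, character(1), "series_id")
    list(series = series,
         meta = do.call(rbind, meta_rows),
         truth_record = list(truth = truth, seed = seed, beta0 = beta0,
                             establishment = est, elevation = elev,
                             b0 = b0, b_slopes = b_slopes,
                             trend_random = trend_b,
                             true_pith_offset = trunc_k))
  })
}

#' Simulate a stand table of detected trees
#'
#' Draws tree ages (negative-J exponential by default), converts them to
#' heights through the inverse of the age-height line plus noise, applies
#' the 2.5 m detection threshold, and places trees uniformly over the
#' elevation range.
#'
#' @param truth A [sim_truth()].
#' @param n_trees Number of trees before the detection threshold.
#' @param ages Optional explicit ages (years); default exponential with mean
#'   `truth$stand$mean_age`.
#' @param elevations Optional explicit elevations (m).
#' @param seed RNG seed.
#' @return A data frame (`id`, `elevation`, `height`) of detected trees;
#'   the dropped count is in attribute `n_below_threshold`. Empty output
#'   warns.
#' @export
simulate_stand <- function(truth, n_trees = 1000, ages = NULL,
                           elevations = NULL, seed = 1) {
  st <- truth$stand
  with_seed(seed, {
    if (is.null(ages)) ages <- 1 + stats::rexp(n_trees, 1 / st$mean_age)
    n <- length(ages)
    if (is.null(elevations)) {
      elevations <- runif(n, truth$population$elev_range[1],
                          truth$population$elev_range[2])
    }
    h <- (ages - st$age_height_b0) / st$age_height_b1 +
      rnorm(n, 0, st$height_noise_sd)
    keep <- h > st$detection_threshold
    if (!any(keep)) warning("all simulated trees below the detection threshold")
    structure(data.frame(id = sprintf("T%05d", seq_len(n))[keep],
                         elevation = elevations[keep], height = h[keep],
                         row.names = NULL),
              n_below_threshold = sum(!keep))
  })
}

#' Simulate a mixed-model response on an existing data frame
#'
#' Adds a simulated response `y = X beta + Z b + e` to a long data frame,
#' with tree-level random effects `b ~ N(0, diag(re_sd^2))` and AR(1)
#' residuals. This is the direct generative counterpart of [fit_lmm()] and
#' is used for parameter-recovery experiments at the model level (both the
#' climate-growth and the trend-model equations).
#'
#' @param data Long data frame with `tree_id`, `year`, and all columns in
#'   `fixed`.
#' @param fixed Fixed-effect column names (intercept implicit).
#' @param random `"intercept"`, or fixed columns carrying random slopes (the
#'   random intercept is always included).
#' @param beta Fixed-effect coefficients, intercept first
#'   (length `1 + length(fixed)`).
#' @param re_sd Random-effect SDs, intercept first.
#' @param phi,sigma AR(1) parameter and residual SD.
#' @param response Name of the response column to create.
#' @param seed RNG seed.
#' @return `data` with the response column added; the per-tree random
#'   effects are in attribute `random_effects`.
#' @export
simulate_lmm_response <- function(data, fixed, random = "intercept",
                                  beta, re_sd, phi = 0, sigma = 0.15,
                                  response = "y", seed = 1) {
  spec <- lmm_spec(response, fixed, random = random, ar1 = TRUE)
  rnd_cols <- c("(Intercept)", spec$random_slopes)
  if (length(re_sd) != length(rnd_cols)) {
    stop(sprintf("`re_sd` must have length %d", length(rnd_cols)), call. = FALSE)
  }
  if (length(beta) != 1L + length(spec$fixed)) {
    stop(sprintf("`beta` must have length %d", 1L + length(spec$fixed)),
         call. = FALSE)
  }
  ord <- order(data$tree_id, data$year)
  data <- data[ord, , drop = FALSE]
  X <- cbind(1, as.matrix(data[spec$fixed]))
  Z <- X[, c(1L, match(spec$random_slopes, spec$fixed) + 1L), drop = FALSE]
  g <- factor(data$tree_id, levels = unique(data$tree_id))
  with_seed(seed, {
    B <- matrix(rnorm(nlevels(g) * length(re_sd), 0,
                      rep(re_sd, each = nlevels(g))),
                nrow = nlevels(g),
                dimnames = list(levels(g), rnd_cols))
    e <- unlist(lapply(split(seq_len(nrow(data)), g), function(idx) {
      .sim_ar1(length(idx), phi, sigma)
    }), use.names = FALSE)
    data[[response]] <- as.numeric(X %*% beta) +
      rowSums(Z * B[as.integer(g), , drop = FALSE]) + e
    structure(data, random_effects = B)
  })
}
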