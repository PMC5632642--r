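#' Specify a mixed model for ring-width indices
#'
#' Describes a linear mixed-effects model with tree-level random effects and
#' optional AR(1) within-tree residual correlation:
#' \deqn{y_{jt} = x_{jt}' \beta + z_{jt}' b_j + \epsilon_{jt},\qquad
#'       b_j \sim N(0, G),\quad
#'       \mathrm{cor}(\epsilon_{js}, \epsilon_{jt}) = \phi^{|s-t|}}
#' with `G` diagonal. The intercept is always a fixed effect; the random
#' structure always includes a tree-level intercept unless `random = "none"`.
#'
#' @param response Name of the response column (e.g. `"rwi"` for spline
#'   indices or `"log_rwi"` for log RCS indices).
#' @param fixed Character vector of fixed-effect column names (the intercept
#'   is implicit).
#' @param random Either `"intercept"` (tree-level random intercept only, the
#'   default), `"none"` (no random effects), or a character vector of fixed
#'   columns that carry tree-level random slopes in addition to the random
#'   intercept.
#' @param ar1 Logical; include the AR(1) residual correlation.
#' @return An object of class `lmm_spec`.
#' @export
lmm_spec <- function(response, fixed, random = "intercept", ar1 = TRUE) {
  fixed <- unique(as.character(fixed))
  if (identical(random, "none")) {
    rnd <- character()
    has_re <- FALSE
  } else if (identical(random, "intercept") || length(random) == 0L) {
    rnd <- character()
    has_re <- TRUE
  } else {
    rnd <- unique(as.character(random))
    if (!all(rnd %in% fixed)) {
      stop("random slopes must be a subset of the fixed effects", call. = FALSE)
    }
    has_re <- TRUE
  }
  structure(list(response = response, fixed = fixed, random_slopes = rnd,
                 has_random = has_re, ar1 = isTRUE(ar1)),
            class = "lmm_spec")
}

#' @export
print.lmm_spec <- function(x, ...) {
  cat(sprintf("<lmm_spec> %s ~ 1%s\n", x$response,
              if (length(x$fixed)) paste0(" + ", paste(x$fixed, collapse = " + ")) else ""))
  cat(sprintf("  random: %s | AR(1): %s\n",
              if (!x$has_random) "none"
              else if (length(x$random_slopes)) paste("intercept +", paste(x$random_slopes, collapse = ", "))
              else "intercept",
              x$ar1))
  invisible(x)
}

# ---- internal data preparation -------------------------------------------

# Order observations by tree and year; build response, design and random-
# effect matrices plus the year-gap structure needed by the AR(1) whitening.
.lmm_prep <- function(data, spec, group = "tree_id", year = "year") {
  need <- c(group, year, spec$response, spec$fixed)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data misses columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  keep <- stats::complete.cases(data[need])
  data <- data[keep, , drop = FALSE]
  ord <- order(data[[group]], data[[year]])
  data <- data[ord, , drop = FALSE]
  g <- as.integer(factor(data[[group]], levels = unique(data[[group]])))
  yr <- as.numeric(data[[year]])
  n <- nrow(data)
  first <- !duplicated(g)
  d <- c(NA_real_, diff(yr))
  d[first] <- NA_real_
  if (any(d <= 0, na.rm = TRUE)) {
    stop("years must be strictly increasing within each tree", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(data[spec$fixed]))
  q <- if (spec$has_random) 1L + length(spec$random_slopes) else 0L
  Z <- if (q > 0L) X[, c("(Intercept)", spec$random_slopes), drop = FALSE] else NULL
  list(y = as.numeric(data[[spec$response]]), X = X, Z = Z,
       g = g, first = first, d = d, n = n, p = ncol(X), q = q,
       G = max(g), groups = split(seq_len(n), g),
       year = yr, group_labels = unique(data[[group]]))
}

# AR(1) innovation whitening: returns scale factors so that
# v* = (v - a * lag(v)) / s has iid unit-variance structure under C(phi).
.whiten_factors <- function(prep, phi) {
  a <- phi^prep$d
  a[prep$first] <- 0
  s <- sqrt(1 - phi^(2 * prep$d))
  s[prep$first] <- 1
  list(a = a, s = s, logdetC = sum(log(s[!prep$first]^2)))
}

.whiten_mat <- function(M, w, first) {
  n <- nrow(M)
  lag <- rbind(0, M[-n, , drop = FALSE])
  lag[first, ] <- 0
  (M - lag * w$a) / w$s
}

.whiten_vec <- function(v, w, first) {
  n <- length(v)
  lag <- c(0, v[-n])
  lag[first] <- 0
  (v - lag * w$a) / w$s
}

# Core GLS/likelihood quantities for given variance parameters.
# Returns beta-profiled pieces; sigma2/beta can be supplied to evaluate the
# likelihood at fixed values instead of the profiled ones.
.ll_core <- function(prep, phi, gamma, method = "ML",
                     sigma2 = NULL, beta = NULL) {
  w <- .whiten_factors(prep, phi)
  ys <- .whiten_vec(prep$y, w, prep$first)
  Xs <- .whiten_mat(prep$X, w, prep$first)
  logdetW <- w$logdetC
  XtWX <- crossprod(Xs)
  XtWy <- crossprod(Xs, ys)
  ytWy <- sum(ys^2)

  q <- prep$q
  if (q > 0L) {
    active <- which(gamma > 1e-12)
    if (length(active)) {
      Zs <- .whiten_mat(prep$Z[, active, drop = FALSE], w, prep$first)
      ga <- gamma[active]
      if (length(active) == 1L) {
        z <- Zs[, 1L]
        A <- rowsum(z^2, prep$g)[, 1L]
        U <- rowsum(Xs * z, prep$g)
        v <- rowsum(ys * z, prep$g)[, 1L]
        k <- 1 / ga + A
        XtWX <- XtWX - crossprod(U / sqrt(k))
        XtWy <- XtWy - crossprod(U, v / k)
        ytWy <- ytWy - sum(v^2 / k)
        logdetW <- logdetW + sum(log1p(ga * A))
      } else {
        qa <- length(active)
        for (idx in prep$groups) {
          Zi <- Zs[idx, , drop = FALSE]
          A <- crossprod(Zi)
          K <- A + diag(1 / ga, qa)
          R <- chol(K)
          B <- crossprod(Xs[idx, , drop = FALSE], Zi)   # p x qa
          ci <- crossprod(Zi, ys[idx])[, 1L]            # qa
          M <- backsolve(R, forwardsolve(t(R), t(B)))   # qa x p, = K^-1 B'
          XtWX <- XtWX - B %*% M
          sK <- backsolve(R, forwardsolve(t(R), ci))
          XtWy <- XtWy - B %*% sK
          ytWy <- ytWy - sum(ci * sK)
          logdetW <- logdetW + sum(log(ga)) + 2 * sum(log(diag(R)))
        }
      }
    }
  }

  n <- prep$n; p <- prep$p
  beta_hat <- tryCatch(solve(XtWX, XtWy)[, 1L], error = function(e) NULL)
  if (is.null(beta_hat)) return(list(ll = -Inf, singular = TRUE))
  if (is.null(beta)) {
    beta_use <- beta_hat
    rss <- max(ytWy - sum(beta_hat * XtWy), 1e-12)
  } else {
    beta_use <- beta
    rss <- max(ytWy - 2 * sum(beta * XtWy) + sum(beta * (XtWX %*% beta)),
               1e-12)
  }
  if (method == "ML") {
    s2 <- if (is.null(sigma2)) rss / n else sigma2
    ll <- -0.5 * (n * log(2 * pi * s2) + logdetW + rss / s2)
  } else {
    s2 <- if (is.null(sigma2)) rss / (n - p) else sigma2
    ldXtWX <- as.numeric(determinant(XtWX, logarithm = TRUE)$modulus)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2) + logdetW + ldXtWX + rss / s2)
  }
  list(ll = ll, beta = beta_use, beta_gls = beta_hat, sigma2 = s2,
       XtWX = XtWX, logdetW = logdetW, rss = rss, singular = FALSE)
}

#' Marginal log-likelihood of a mixed model at given parameters
#'
#' Evaluates the Gaussian log-likelihood of the model described by `spec` at
#' explicit parameter values, with per-tree covariance
#' `V_j = Z_j G Z_j' + sigma^2 C_j(phi)` where `C_j` has entries
#' `phi^|year_s - year_t|` and `G = diag(re_sd^2)`. For `method = "REML"`
#' the fixed effects are profiled out (`beta` is ignored) and the standard
#' restricted-likelihood adjustment is applied.
#'
#' @param spec An [lmm_spec()].
#' @param data Long data frame with columns `tree_id`, `year`, the response,
#'   and the fixed-effect columns.
#' @param params List with elements `beta` (length 1 + number of fixed
#'   effects, intercept first), `re_sd` (length = number of random effects,
#'   intercept first; omit when `random = "none"`), `phi` (in (-1, 1); omit
#'   or 0 when `ar1 = FALSE`), and `sigma` (> 0).
#' @param method `"ML"` or `"REML"`.
#' @return The log-likelihood (a scalar).
#' @export
marginal_loglik <- function(spec, data, params, method = c("ML", "REML")) {
  method <- match.arg(method)
  prep <- .lmm_prep(data, spec)
  phi <- params$phi %||% 0
  if (spec$ar1 && abs(phi) >= 1) stop("|phi| must be < 1", call. = FALSE)
  sigma <- params$sigma
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  re_sd <- params$re_sd %||% numeric(0)
  if (length(re_sd) != prep$q) {
    stop(sprintf("`re_sd` must have length %d for this spec", prep$q),
         call. = FALSE)
  }
  if (any(re_sd < 0)) stop("random-effect SDs must be >= 0", call. = FALSE)
  gamma <- (re_sd / sigma)^2
  if (method == "ML") {
    beta <- params$beta
    if (length(beta) != prep$p) {
      stop(sprintf("`beta` must have length %d (intercept first)", prep$p),
           call. = FALSE)
    }
    out <- .ll_core(prep, phi, gamma, "ML", sigma2 = sigma^2, beta = beta)
  } else {
    out <- .ll_core(prep, phi, gamma, "REML", sigma2 = sigma^2)
  }
  out$ll
}

# ---- fitting --------------------------------------------------------------

# Minimal fit used both by fit_lmm() and by the exhaustive-selection loop.
# theta layout: [atanh(phi) if ar1][log(gamma_1..q)]
.fit_core <- function(prep, ar1, method, theta_start = NULL,
                      rel_tol = 1e-10) {
  q <- prep$q
  n_theta <- as.integer(ar1) + q
  unpack <- function(theta) {
    i <- 0L
    phi <- 0
    if (ar1) { phi <- tanh(theta[1L]); i <- 1L }
    gamma <- if (q > 0L) exp(pmin(pmax(theta[i + seq_len(q)], -30), 15)) else numeric(0)
    list(phi = phi, gamma = gamma)
  }
  if (n_theta == 0L) {
    core <- .ll_core(prep, 0, numeric(0), method)
    return(list(theta = numeric(0), phi = 0, gamma = numeric(0),
                core = core, converged = TRUE, unpack = unpack))
  }
  if (is.null(theta_start)) {
    theta_start <- numeric(n_theta)
    if (ar1) {
      # start phi at the lag-1 autocorrelation of OLS residuals
      ols <- .ll_core(prep, 0, rep(0, q), "ML")
      r <- prep$y - prep$X %*% ols$beta_gls
      lag_ok <- !prep$first
      rho <- suppressWarnings(cor(r[lag_ok], r[which(lag_ok) - 1L]))
      if (!is.finite(rho)) rho <- 0
      theta_start[1L] <- atanh(max(min(rho * 0.9, 0.9), -0.9))
    }
    if (q > 0L) theta_start[as.integer(ar1) + seq_len(q)] <- log(0.1)
  }
  nll <- function(theta) {
    pr <- unpack(theta)
    ll <- .ll_core(prep, pr$phi, pr$gamma, method)$ll
    if (!is.finite(ll)) 1e10 else -ll
  }
  ctrl <- list(rel.tol = rel_tol, iter.max = 500, eval.max = 1500)
  opt <- nlminb(theta_start, nll, control = ctrl)
  converged <- opt$convergence == 0
  if (!converged) {
    # "false convergence" is common when a variance parameter sits on its
    # boundary; restart from the current point and accept a stationary
    # objective as converged
    opt2 <- nlminb(opt$par, nll, control = ctrl)
    improve <- opt$objective - opt2$objective
    if (opt2$objective <= opt$objective) opt <- opt2
    converged <- opt$convergence == 0 || improve < 1e-6
  }
  pr <- unpack(opt$par)
  core <- .ll_core(prep, pr$phi, pr$gamma, method)
  list(theta = opt$par, phi = pr$phi, gamma = pr$gamma, core = core,
       converged = converged && !core$singular, unpack = unpack)
}

#' Fit a linear mixed-effects model with AR(1) residuals
#'
#' Estimates the model described by `spec` by maximum likelihood or
#' restricted maximum likelihood from the marginal likelihood. Variance
#' parameters are optimized on a transformed scale (`atanh` for the AR(1)
#' parameter, log for relative variances) with the fixed effects profiled
#' out by generalized least squares at each evaluation and the residual
#' variance profiled analytically. Standard errors of the fixed effects come
#' from the inverse GLS information; p-values are Wald t-tests with
#' denominator degrees of freedom `n_obs - n_groups - p` (within-group
#' convention). Standard errors of the variance parameters are obtained from
#' the numerical Hessian of the profile likelihood on the transformed scale.
#'
#' @param spec An [lmm_spec()].
#' @param data Long data frame with `tree_id`, `year`, the response, and all
#'   fixed-effect columns. Rows with missing values are dropped.
#' @param method `"REML"` (default) or `"ML"`.
#' @param start Optional list with elements `phi` and/or `gamma` (relative
#'   variances, length = number of random effects) used as optimizer start.
#' @param se Compute standard errors for the variance parameters (numerical
#'   Hessian); disable for speed inside model-selection loops.
#' @return An object of class `lmm_fit`; see [summary.lmm_fit()]. Key fields:
#'   `beta` (coefficient table), `re_sd` (random-effect SDs, with SEs when
#'   available), `phi`, `sigma`, `loglik`, `method`, `n_obs`, `n_groups`,
#'   `converged`.
#' @export
fit_lmm <- function(spec, data, method = c("REML", "ML"), start = NULL,
                    se = TRUE) {
  method <- match.arg(method)
  prep <- .lmm_prep(data, spec)
  if (prep$G < 2L) stop("need >= 2 trees", call. = FALSE)
  n_var <- prep$q + as.integer(spec$ar1) + 1L
  if (prep$n <= prep$p + n_var) stop("more parameters than observations",
                                     call. = FALSE)
  # rank check on the fixed design
  qr_X <- qr(prep$X)
  if (qr_X$rank < prep$p) {
    bad <- colnames(prep$X)[qr_X$pivot[(qr_X$rank + 1L):prep$p]]
    stop("fixed-effect design is rank deficient; inestimable terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  theta_start <- NULL
  if (!is.null(start)) {
    theta_start <- numeric(as.integer(spec$ar1) + prep$q)
    i <- 0L
    if (spec$ar1) { theta_start[1L] <- atanh(start$phi %||% 0); i <- 1L }
    if (prep$q > 0L) {
      g0 <- start$gamma %||% rep(0.1, prep$q)
      theta_start[i + seq_len(prep$q)] <- log(pmax(g0, 1e-8))
    }
  }
  fit <- .fit_core(prep, spec$ar1, method, theta_start)
  if (!fit$converged) {
    warning("optimizer did not report convergence; inspect the fit")
  }
  core <- fit$core
  sigma2 <- core$sigma2
  vcov_beta <- solve(core$XtWX) * sigma2
  se_beta <- sqrt(diag(vcov_beta))
  df <- prep$n - prep$G - prep$p
  tval <- core$beta / se_beta
  pval <- 2 * pt(-abs(tval), df = max(df, 1L))
  beta_tab <- data.frame(term = colnames(prep$X), estimate = as.numeric(core$beta),
                         se = se_beta, t = as.numeric(tval),
                         p = as.numeric(pval), row.names = NULL)
  re_names <- if (prep$q > 0L) colnames(prep$Z) else character()
  re_sd <- sqrt(fit$gamma * sigma2)
  names(re_sd) <- re_names
  singular_re <- re_names[fit$gamma < 1e-7]
  re_sd[fit$gamma < 1e-7] <- 0

  # SEs for (phi, re_sd, sigma) from the profile-likelihood Hessian
  var_se <- NULL
  if (se) var_se <- .variance_ses(prep, spec, method, fit)

  structure(
    list(spec = spec, method = method,
         beta = beta_tab, vcov_beta = vcov_beta,
         re_sd = re_sd, phi = if (spec$ar1) fit$phi else NA_real_,
         sigma = sqrt(sigma2), loglik = core$ll,
         n_obs = prep$n, n_groups = prep$G, df_resid = df,
         n_params = prep$p + n_var,
         converged = fit$converged,
         singular_re = singular_re,
         var_se = var_se,
         theta = fit$theta,
         prep = prep),
    class = "lmm_fit")
}

# Numerical SEs for variance parameters via the (beta-profiled, sigma-free)
# likelihood Hessian on (atanh phi, log gamma, log sigma), delta-mapped to
# (phi, re_sd, sigma).
.variance_ses <- function(prep, spec, method, fit) {
  q <- prep$q
  ar1 <- spec$ar1
  ls_hat <- 0.5 * log(fit$core$sigma2)
  th0 <- c(fit$theta, ls_hat)
  nll_ext <- function(th) {
    m <- length(th)
    pr <- fit$unpack(th[-m])
    s2 <- exp(2 * th[m])
    out <- .ll_core(prep, pr$phi, pr$gamma, method, sigma2 = s2)
    if (!is.finite(out$ll)) 1e10 else -out$ll
  }
  H <- tryCatch(optimHess(th0, nll_ext), error = function(e) NULL)
  if (is.null(H)) return(NULL)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) return(NULL)
  # transforms: phi = tanh(t1); re_sd_k = exp(ls + 0.5 lg_k); sigma = exp(ls)
  m <- length(th0)
  J <- matrix(0, nrow = as.integer(ar1) + q + 1L, ncol = m)
  r <- 0L; i <- 0L
  out_names <- character()
  if (ar1) {
    r <- r + 1L; i <- 1L
    J[r, 1L] <- 1 - fit$phi^2
    out_names <- "phi"
  }
  if (q > 0L) {
    sig <- sqrt(fit$core$sigma2)
    for (k in seq_len(q)) {
      r <- r + 1L
      sd_k <- sqrt(fit$gamma[k]) * sig
      J[r, i + k] <- 0.5 * sd_k
      J[r, m] <- sd_k
      out_names <- c(out_names, colnames(prep$Z)[k])
    }
  }
  r <- r + 1L
  J[r, m] <- sqrt(fit$core$sigma2)
  out_names <- c(out_names, "sigma")
  ses <- sqrt(pmax(diag(J %*% V %*% t(J)), 0))
  setNames(ses, out_names)
}

#' @export
logLik.lmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s (%s), %d obs / %d trees, logLik %.2f%s\n",
              x$spec$response, x$method, x$n_obs, x$n_groups, x$loglik,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(x$beta, digits = 4)
  if (length(x$re_sd)) {
    cat("random-effect SDs: ",
        paste(sprintf("%s=%.4g", names(x$re_sd), x$re_sd), collapse = ", "),
        "\n")
  }
  if (!is.na(x$phi)) cat(sprintf("phi = %.3f, ", x$phi))
  cat(sprintf("sigma = %.4g\n", x$sigma))
  invisible(x)
}

#' Summarize a mixed-model fit
#'
#' @param object An `lmm_fit`.
#' @param ... Unused.
#' @return A data frame mirroring the usual reporting layout: one row per
#'   fixed effect with estimate, SE, p-value and significance stars, plus the
#'   matching random-effect SD (in brackets in printed figures) where one
#'   exists.
#' @export
summary.lmm_fit <- function(object, ...) {
  stars <- function(p) ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  tab <- object$beta
  tab$signif <- stars(tab$p)
  tab$re_sd <- object$re_sd[match(tab$term, names(object$re_sd))]
  tab
}

#' Information criteria of a mixed-model fit
#'
#' `AIC = -2 loglik + 2 k` and `BIC = -2 loglik + k log(n_obs)`, with `k`
#' the number of fixed effects plus variance parameters (random-effect SDs,
#' the AR(1) parameter when present, and the residual SD). `n` is the total
#' number of observations.
#'
#' @param fit An `lmm_fit`, or `NULL` if `loglik`, `k`, `n_obs` are given
#'   directly.
#' @param loglik,k,n_obs Explicit values (used when `fit` is `NULL`).
#' @return Named numeric vector `c(AIC = ..., BIC = ...)`.
#' @export
information_criteria <- function(fit = NULL, loglik = NULL, k = NULL,
                                 n_obs = NULL) {
  if (!is.null(fit)) {
    loglik <- fit$loglik; k <- fit$n_params; n_obs <- fit$n_obs
  }
  if (is.null(k) || k < 1L) stop("parameter count k must be >= 1", call. = FALSE)
  c(AIC = -2 * loglik + 2 * k, BIC = -2 * loglik + k * log(n_obs))
}

# ---- BLUPs, fitted values, diagnostics ------------------------------------

#' Predicted tree-level random effects (BLUPs)
#'
#' @param fit An `lmm_fit` with random effects.
#' @return Matrix with one row per tree and one column per random effect.
#' @export
ranef_lmm <- function(fit) {
  prep <- fit$prep
  if (prep$q == 0L) stop("model has no random effects", call. = FALSE)
  gamma <- (fit$re_sd / fit$sigma)^2
  phi <- if (is.na(fit$phi)) 0 else fit$phi
  w <- .whiten_factors(prep, phi)
  r <- prep$y - as.numeric(prep$X %*% fit$beta$estimate)
  rs <- .whiten_vec(r, w, prep$first)
  Zs <- .whiten_mat(prep$Z, w, prep$first)
  B <- matrix(0, prep$G, prep$q, dimnames = list(prep$group_labels,
                                                 colnames(prep$Z)))
  active <- gamma > 1e-12
  if (!any(active)) return(B)
  for (i in seq_len(prep$G)) {
    idx <- prep$groups[[i]]
    Zi <- Zs[idx, active, drop = FALSE]
    K <- crossprod(Zi) + diag(1 / gamma[active], sum(active))
    B[i, active] <- solve(K, crossprod(Zi, rs[idx]))[, 1L]
  }
  B
}

#' Fitted values of a mixed-model fit
#'
#' @param object An `lmm_fit`.
#' @param level `"population"` (fixed effects only) or `"tree"` (adds each
#'   tree's predicted random effects).
#' @param ... Unused.
#' @return Numeric vector aligned with the rows used in the fit (sorted by
#'   tree and year).
#' @export
fitted.lmm_fit <- function(object, level = c("population", "tree"), ...) {
  level <- match.arg(level)
  prep <- object$prep
  fv <- as.numeric(prep$X %*% object$beta$estimate)
  if (level == "tree" && prep$q > 0L) {
    B <- ranef_lmm(object)
    fv <- fv + rowSums(prep$Z * B[prep$g, , drop = FALSE])
  }
  fv
}

#' Model diagnostics for a mixed-model fit
#'
#' Computes the checks used to validate climate-growth and trend models:
#' variance inflation factors of the fixed-effect columns (collinearity),
#' the Shapiro-Wilk statistic of the normalized (whitened) residuals
#' (normality), the slope of `|residual|` on fitted values
#' (heteroscedasticity, Breusch-Pagan flavour), and the lag-1 autocorrelation
#' of the whitened residuals, which should be near 0 once the AR(1)
#' structure has absorbed the serial correlation.
#'
#' @param fit A converged `lmm_fit`.
#' @param shapiro_max Maximum sample size passed to [shapiro.test()]; larger
#'   residual vectors are subsampled deterministically.
#' @return A list of class `lmm_diagnostics`.
#' @export
diagnostics <- function(fit, shapiro_max = 4999L) {
  prep <- fit$prep
  # VIF from the correlation matrix of the non-intercept columns
  Xc <- prep$X[, -1L, drop = FALSE]
  vif <- setNames(rep(NA_real_, ncol(Xc)), colnames(Xc))
  if (ncol(Xc) >= 2L) {
    R <- cor(Xc)
    inv <- tryCatch(solve(R), error = function(e) NULL)
    vif[] <- if (is.null(inv)) Inf else diag(inv)
  } else if (ncol(Xc) == 1L) vif[] <- 1

  # normalized residuals: AR(1)-whitened marginal residuals minus the RE part
  phi <- if (is.na(fit$phi)) 0 else fit$phi
  r <- prep$y - fitted.lmm_fit(fit, level = if (prep$q > 0L) "tree" else "population")
  w <- .whiten_factors(prep, phi)
  rn <- .whiten_vec(r, w, prep$first) / fit$sigma

  sw <- {
    x <- rn
    if (length(x) > shapiro_max) x <- x[seq(1L, length(x), length.out = shapiro_max)]
    shapiro.test(x)
  }
  fv <- fitted.lmm_fit(fit, level = "population")
  bp <- lm(abs(rn) ~ fv)
  bp_slope <- coef(bp)[2L]
  bp_p <- summary(bp)$coefficients[2L, 4L]
  lag_ok <- !prep$first
  lag1 <- suppressWarnings(cor(rn[lag_ok], rn[which(lag_ok) - 1L]))

  structure(list(vif = vif,
                 shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
                 bp_slope = unname(bp_slope), bp_p = unname(bp_p),
                 resid_lag1 = lag1,
                 normality_flag = sw$p.value < 0.05,
                 collinearity_flag = any(!is.finite(vif)) || any(vif > 10, na.rm = TRUE),
                 heteroscedasticity_flag = bp_p < 0.05),
            class = "lmm_diagnostics")
}

#' @export
print.lmm_diagnostics <- function(x, ...) {
  cat("<lmm_diagnostics>\n")
  cat(sprintf("  max VIF: %.2f%s\n", suppressWarnings(max(x$vif)),
              if (x$collinearity_flag) " [FLAG]" else ""))
  cat(sprintf("  Shapiro-Wilk W = %.4f (p = %.3g)%s\n", x$shapiro_w,
              x$shapiro_p, if (x$normality_flag) " [FLAG]" else ""))
  cat(sprintf("  |resid| ~ fitted slope = %.4f (p = %.3g)%s\n", x$bp_slope,
              x$bp_p, if (x$heteroscedasticity_flag) " [FLAG]" else ""))
  cat(sprintf("  whitened-residual lag-1 autocorrelation = %.3f\n",
              x$resid_lag1))
  invisible(x)
}
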