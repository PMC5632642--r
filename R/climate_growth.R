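#' Join detrended indices with the lagged climate design
#'
#' Builds the long modelling table for the climate-growth analysis: one row
#' per tree and year, holding the spline ring-width index and the 15
#' standardized monthly temperature columns for that year.
#'
#' @param rwi Either a list of `rwi_series` (spline method) or the long data
#'   frame from [rwi_table()].
#' @param design A [build_lag_design()] result.
#' @return A data frame with columns `tree_id`, `year`, `rwi`, and the 15
#'   design columns; years outside the design's response years are dropped.
#' @export
assemble_growth_data <- function(rwi, design) {
  stopifnot(inherits(design, "lag_design"))
  if (!is.data.frame(rwi)) rwi <- rwi_table(rwi)
  keep <- rwi$year %in% design$response_years
  rwi <- rwi[keep, , drop = FALSE]
  ri <- match(rwi$year, design$response_years)
  out <- data.frame(tree_id = rwi$tree_id, year = rwi$year, rwi = rwi$index)
  cbind(out, as.data.frame(design$X[ri, , drop = FALSE], row.names = NULL))
}

.popcount <- function(x) {
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

#' Exhaustive information-criterion selection over monthly predictors
#'
#' Fits every subset of the candidate monthly-temperature columns (2^m
#' models; 32,768 for the full 15-month set) as a mixed model with tree-level
#' random intercept and AR(1) residuals by maximum likelihood, and ranks the
#' subsets by BIC (or AIC). Enumeration proceeds in order of subset size so
#' that each fit can be warm-started from a parent model's variance
#' estimates, which speeds up the optimizer without affecting the ranking.
#' Ties on the criterion are broken by smaller model size, then by subset
#' bitmask.
#'
#' @param design A [build_lag_design()] result.
#' @param rwi Spline ring-width indices (list of `rwi_series` or
#'   [rwi_table()] output).
#' @param candidates Candidate column names; default all 15 lagged months.
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @param method Estimation method for the candidate fits (`"ML"`).
#' @param ar1 Keep the AR(1) parameter in every candidate fit.
#' @param enumerate_only If `TRUE`, return the enumerated subset table
#'   without fitting any model (criterion columns are `NA`).
#' @param warm_start Reuse parent-subset variance estimates as optimizer
#'   starts.
#' @param progress Print a progress line every 1000 fits.
#' @return An object of class `selection_table`: a list with `table` (one
#'   row per subset: `mask`, `terms`, `k`, `loglik`, criterion, delta,
#'   `converged`, sorted by the criterion) and `best_spec` (an [lmm_spec()]
#'   for the winning subset; `NULL` when `enumerate_only`).
#' @export
exhaustive_select <- function(design, rwi, candidates = lag_design_columns(),
                              criterion = c("BIC", "AIC"), method = "ML",
                              ar1 = TRUE, enumerate_only = FALSE,
                              warm_start = TRUE, progress = FALSE) {
  criterion <- match.arg(criterion)
  m <- length(candidates)
  if (m > 20L) stop("too many candidates to enumerate", call. = FALSE)
  masks <- 0:(2^m - 1L)
  sizes <- .popcount(masks)
  bits_of <- function(mk) {
    if (m == 0L) return(integer())
    which(bitwAnd(bitwShiftR(mk, 0:(m - 1L)), 1L) == 1L)
  }
  term_list <- lapply(masks, function(mk) candidates[bits_of(mk)])
  terms_str <- vapply(term_list, function(tt) paste(tt, collapse = "+"), character(1))
  # k = fixed effects (1 + |subset|) + random-intercept SD + phi + sigma
  k_all <- 1L + sizes + 1L + as.integer(ar1) + 1L

  tab <- data.frame(mask = masks, terms = terms_str, k = k_all,
                    loglik = NA_real_, crit = NA_real_, delta = NA_real_,
                    converged = NA, stringsAsFactors = FALSE)
  names(tab)[names(tab) == "crit"] <- criterion
  if (enumerate_only) {
    return(structure(list(table = tab, best_spec = NULL,
                          criterion = criterion, n_models = length(masks)),
                     class = "selection_table"))
  }

  dat <- assemble_growth_data(rwi, design)
  full_spec <- lmm_spec("rwi", candidates, random = "intercept", ar1 = ar1)
  prep_full <- .lmm_prep(dat, full_spec)
  cand_cols <- match(candidates, colnames(prep_full$X))

  theta_store <- vector("list", length(masks))
  ord_fit <- order(sizes, masks)
  crit_vals <- rep(NA_real_, length(masks))
  ll_vals <- rep(NA_real_, length(masks))
  conv <- rep(NA, length(masks))
  done <- 0L
  for (j in ord_fit) {
    mk <- masks[j]
    idx <- cand_cols[bits_of(mk)]
    prep <- prep_full
    prep$X <- prep_full$X[, c(1L, idx), drop = FALSE]
    prep$p <- ncol(prep$X)
    start <- NULL
    if (warm_start && mk > 0L) {
      start <- theta_store[[bitwAnd(mk, mk - 1L) + 1L]]
    }
    fit <- .fit_core(prep, ar1, method, theta_start = start, rel_tol = 1e-9)
    theta_store[[j]] <- fit$theta
    ll_vals[j] <- fit$core$ll
    conv[j] <- fit$converged
    crit_vals[j] <- information_criteria(loglik = fit$core$ll, k = k_all[j],
                                         n_obs = prep$n)[[criterion]]
    done <- done + 1L
    if (progress && done %% 1000L == 0L) {
      message(sprintf("fitted %d / %d candidate models", done, length(masks)))
    }
  }
  tab$loglik <- ll_vals
  tab[[criterion]] <- crit_vals
  tab$converged <- conv

  ok <- which(tab$converged)
  if (length(ok) == 0L) stop("no candidate model converged", call. = FALSE)
  if (any(!tab$converged)) {
    warning(sprintf("%d candidate fits did not converge and were excluded from the argmin",
                    sum(!tab$converged)))
  }
  best_val <- min(tab[[criterion]][ok])
  tab$delta <- tab[[criterion]] - best_val
  # tie-break: smallest criterion, then fewer parameters, then bitmask
  ord <- order(!tab$converged, tab[[criterion]], tab$k, tab$mask)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  best <- tab[1L, ]
  best_terms <- term_list[[match(best$mask, masks)]]
  best_spec <- lmm_spec("rwi", best_terms, random = "intercept", ar1 = ar1)
  structure(list(table = tab, best_spec = best_spec, criterion = criterion,
                 n_models = length(masks), data = dat),
            class = "selection_table")
}

#' @export
print.selection_table <- function(x, ...) {
  cat(sprintf("<selection_table> %d candidate models ranked by %s\n",
              x$n_models, x$criterion))
  if (!is.null(x$best_spec)) {
    cat("best subset: ",
        if (length(x$best_spec$fixed)) paste(x$best_spec$fixed, collapse = ", ")
        else "(intercept only)", "\n")
    print(head(x$table, 5))
  }
  invisible(x)
}

#' REML refit of the selected model with tree-level random slopes
#'
#' Extends the BIC-selected fixed-effect structure with tree-level random
#' slopes (diagonal covariance) for every selected month, keeps the random
#' intercept and the AR(1) parameter, and refits by REML. This is the final
#' climate-growth model whose fixed effects are interpreted as the
#' proportional RWI change per +1 SD of that month's temperature, and whose
#' random-effect SDs quantify among-tree variability in those responses.
#'
#' @param selection A `selection_table` from [exhaustive_select()], or an
#'   [lmm_spec()] for the chosen fixed effects.
#' @param design A [build_lag_design()] result (needed when `selection` is a
#'   spec or `data` is missing).
#' @param rwi Spline ring-width indices, as in [exhaustive_select()].
#' @param data Optional pre-assembled data (from [assemble_growth_data()]).
#' @return An `lmm_fit` (REML) with random slopes; see [summary.lmm_fit()]
#'   for the reporting table.
#' @export
finalize_with_random_slopes <- function(selection, design = NULL, rwi = NULL,
                                        data = NULL) {
  if (inherits(selection, "selection_table")) {
    spec <- selection$best_spec
    if (is.null(data)) data <- selection$data
  } else {
    spec <- selection
  }
  if (is.null(data)) data <- assemble_growth_data(rwi, design)
  final_spec <- lmm_spec(spec$response, spec$fixed,
                         random = if (length(spec$fixed)) spec$fixed else "intercept",
                         ar1 = spec$ar1)
  fit_lmm(final_spec, data, method = "REML")
}
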