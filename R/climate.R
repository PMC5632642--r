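#' Construct a monthly temperature grid for one site
#'
#' @param site Site label.
#' @param years Consecutive calendar years (integer vector).
#' @param temp Numeric matrix, `length(years)` rows by 12 columns (Jan-Dec),
#'   of monthly mean temperatures in degrees Celsius.
#' @return An object of class `monthly_climate`.
#' @export
monthly_climate <- function(site, years, temp) {
  years <- as.integer(years)
  temp <- as.matrix(temp)
  if (length(years) < 2L || any(diff(years) != 1L)) {
    stop("`years` must be consecutive calendar years", call. = FALSE)
  }
  if (nrow(temp) != length(years) || ncol(temp) != 12L) {
    stop("`temp` must be a length(years) x 12 matrix", call. = FALSE)
  }
  dimnames(temp) <- list(years, month.abb)
  structure(list(site = site, years = years, temp = temp),
            class = "monthly_climate")
}

#' @export
print.monthly_climate <- function(x, ...) {
  cat(sprintf("<monthly_climate> %s, %d-%d, annual mean %.2f degC\n",
              x$site, min(x$years), max(x$years),
              mean(x$temp, na.rm = TRUE)))
  invisible(x)
}

#' Read a monthly climate CSV
#'
#' Expects long format with columns `site`, `year`, `month` (1-12), `temp_c`.
#'
#' @param path CSV file path.
#' @param site Optional site to filter on (required if the file holds
#'   several).
#' @return A [monthly_climate()] object.
#' @export
read_climate_csv <- function(path, site = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "year", "month", "temp_c")
  if (!all(need %in% names(d))) {
    stop("climate CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(site)) {
    site <- unique(d$site)
    if (length(site) > 1L) stop("several sites in file; pass `site`",
                                call. = FALSE)
  }
  d <- d[d$site == site, ]
  yrs <- sort(unique(d$year))
  temp <- matrix(NA_real_, length(yrs), 12L)
  temp[cbind(match(d$year, yrs), d$month)] <- d$temp_c
  monthly_climate(site, yrs, temp)
}

#' Write a monthly climate grid to CSV (long format)
#'
#' @param climate A [monthly_climate()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_climate_csv <- function(climate, path) {
  d <- data.frame(site = climate$site,
                  year = rep(climate$years, times = 12L),
                  month = rep(1:12, each = length(climate$years)),
                  temp_c = as.vector(climate$temp))
  d <- d[order(d$year, d$month), ]
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

# The 15 lagged monthly predictors: previous-year August..December, then
# current-year January..October.
lag_design_columns <- function() {
  c(paste0("prev", month.abb[8:12]), paste0("cur", month.abb[1:10]))
}

#' Build the lagged, standardized monthly-temperature design matrix
#'
#' For each response year `t` the row holds monthly mean temperatures of the
#' previous August-December and the current January-October (15 columns).
#' Each column is centred and scaled over the response years so that model
#' coefficients are per +1 SD of that month's temperature.
#'
#' @param climate A [monthly_climate()].
#' @param year_range Optional `c(first, last)` response years; defaults to
#'   the largest usable range (first climate year + 1 through the last).
#' @return An object of class `lag_design` with fields `response_years`,
#'   `X` (standardized matrix with the 15 named columns), and
#'   `standardization` (per-column mean and sd).
#' @export
build_lag_design <- function(climate, year_range = NULL) {
  stopifnot(inherits(climate, "monthly_climate"))
  usable <- (min(climate$years) + 1L):max(climate$years)
  if (!is.null(year_range)) {
    usable <- intersect(usable, year_range[1]:year_range[2])
    if (length(usable) == 0L) stop("no usable response years", call. = FALSE)
    if (year_range[1] <= min(climate$years)) {
      stop("climate must cover the year before the first response year",
           call. = FALSE)
    }
  }
  cols <- lag_design_columns()
  X <- matrix(NA_real_, length(usable), 15L, dimnames = list(usable, cols))
  ri <- match(usable, climate$years)
  for (k in 1:5) X[, k] <- climate$temp[cbind(ri - 1L, 7L + k)]     # prev Aug..Dec
  for (k in 1:10) X[, 5L + k] <- climate$temp[cbind(ri, k)]          # cur Jan..Oct
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)
    stop("missing monthly temperatures for: ",
         paste(unique(sprintf("%s %s", rownames(X)[bad[, 1]],
                              cols[bad[, 2]])), collapse = ", "),
         call. = FALSE)
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  if (any(sdv == 0)) {
    stop("zero-variance temperature column(s): ",
         paste(cols[sdv == 0], collapse = ", "), call. = FALSE)
  }
  X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  structure(list(response_years = usable, X = X,
                 standardization = data.frame(column = cols, mean = mu,
                                              sd = sdv, row.names = NULL)),
            class = "lag_design")
}

#' @export
print.lag_design <- function(x, ...) {
  cat(sprintf("<lag_design> %d response years (%d-%d), 15 standardized monthly columns\n",
              length(x$response_years), min(x$response_years),
              max(x$response_years)))
  invisible(x)
}

#' Smoothed monthly temperature anomalies
#'
#' Computes anomalies of one month's mean temperature relative to a reference
#' period (default 1971-2000) and fits a locally weighted (tricube, local
#' linear) regression with a pointwise 95% confidence band.
#'
#' @param climate A [monthly_climate()].
#' @param month Month number 1-12.
#' @param ref_period `c(first, last)` reference years.
#' @param span loess span (fraction of points in each local fit).
#' @return A data frame of class `anomaly_series` with columns `year`,
#'   `anomaly`, `smooth`, `lower`, `upper`, and attributes `month` and
#'   `ref_period`.
#' @export
anomaly_smooth <- function(climate, month, ref_period = c(1971, 2000),
                           span = 0.4) {
  stopifnot(inherits(climate, "monthly_climate"))
  if (!month %in% 1:12) stop("`month` must be in 1..12", call. = FALSE)
  ref <- ref_period[1]:ref_period[2]
  if (!all(ref %in% climate$years)) {
    stop("reference period not fully covered by the climate data",
         call. = FALSE)
  }
  x <- climate$temp[, month]
  if (anyNA(x[match(ref, climate$years)])) {
    stop("reference period has missing values", call. = FALSE)
  }
  anom <- x - mean(x[match(ref, climate$years)])
  d <- data.frame(year = climate$years, anomaly = anom)
  lo <- loess(anomaly ~ year, data = d, span = span, degree = 1,
              family = "gaussian")
  pr <- predict(lo, se = TRUE)
  d$smooth <- as.numeric(pr$fit)
  d$lower <- d$smooth - 1.96 * pr$se.fit
  d$upper <- d$smooth + 1.96 * pr$se.fit
  structure(d, class = c("anomaly_series", "data.frame"),
            month = month, ref_period = ref_period)
}
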