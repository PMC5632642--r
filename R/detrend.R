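#' Smoothing spline with a 50% frequency-response wavelength
#'
#' Fits the discrete smoothing spline used for dendrochronological detrending:
#' the minimizer of `sum((y - g)^2) + lambda * sum(diff(g, differences = 2)^2)`.
#' The penalty weight is chosen so that the spline's amplitude response equals
#' `f` (default 0.5) at the design wavelength, the standard criterion for
#' "n-year splines" in tree-ring work. Constants and straight lines pass
#' through unchanged.
#'
#' @param y Numeric vector (annual values).
#' @param wavelength Period in years at which the amplitude response is `f`.
#' @param f Amplitude response at `wavelength` (default 0.5).
#' @return The fitted smooth values, same length as `y`.
#' @keywords internal
caps_spline <- function(y, wavelength, f = 0.5) {
  n <- length(y)
  if (n < 3L) return(y)
  # response(freq) = 1 / (1 + lambda * 16 sin^4(pi / period))
  lambda <- ((1 - f) / f) / (16 * sin(pi / wavelength)^4)
  D <- diff(diag(n), differences = 2)
  g <- solve(diag(n) + lambda * crossprod(D), y)
  as.numeric(g)
}

#' Spline-detrend a ring-width series
#'
#' Divides the raw widths by a smoothing-spline fit whose frequency response
#' is 50% at `wavelength` years, yielding dimensionless ring-width indices
#' centred on 1 that retain interannual (high-frequency) variability. The
#' fitted curve is floored at a small positive constant before division.
#'
#' @param series A [ring_series()].
#' @param wavelength Spline wavelength in years (default 32).
#' @param floor Minimum fitted value used in the division (mm).
#' @return An object of class `rwi_series` with fields `series_id`,
#'   `tree_id`, `first_year`, `indices`, `method = "spline"`, and
#'   `spline_wavelength`.
#' @export
spline_detrend <- function(series, wavelength = 32, floor = 0.005) {
  stopifnot(inherits(series, "ring_series"))
  stopifnot_scalar(wavelength, "wavelength", positive = TRUE)
  if (length(series$widths) < 5L) {
    stop("series too short to detrend (< 5 rings)", call. = FALSE)
  }
  if (all(series$widths == 0)) {
    stop("cannot detrend an all-zero series", call. = FALSE)
  }
  fit <- pmax(caps_spline(series$widths, wavelength), floor)
  structure(
    list(series_id = series$series_id, tree_id = series$tree_id,
         first_year = series$first_year,
         indices = series$widths / fit,
         method = "spline", spline_wavelength = wavelength),
    class = "rwi_series")
}

#' @export
print.rwi_series <- function(x, ...) {
  cat(sprintf("<rwi_series> %s, %s method, years %d-%d, mean index %.3f\n",
              x$series_id, x$method, x$first_year,
              x$first_year + length(x$indices) - 1L, mean(x$indices)))
  invisible(x)
}

#' Restrict a detrended series to years at or after a start year
#'
#' Detrending is done on the full series; analyses then truncate to the
#' climate-data period (1850 onward by default).
#'
#' @param rwi An `rwi_series`.
#' @param start First calendar year to keep.
#' @return The truncated `rwi_series`, or `NULL` if nothing remains.
#' @export
truncate_rwi <- function(rwi, start = 1850) {
  yrs <- rwi$first_year + seq_along(rwi$indices) - 1L
  keep <- yrs >= start
  if (!any(keep)) return(NULL)
  rwi$indices <- rwi$indices[keep]
  if (!is.null(rwi$cambial_ages)) rwi$cambial_ages <- rwi$cambial_ages[keep]
  rwi$first_year <- as.integer(yrs[keep][1L])
  rwi
}

#' Geometric pith-offset estimate from ring curvature
#'
#' Estimates the distance from the innermost measured ring to the pith from
#' the curvature of the innermost ring arc: for a chord of length `L` (mm)
#' with arc height `h` (mm), the circle through the arc has radius
#' `r = (L^2 + 4 h^2) / (8 h)`. The number of missing rings is `r` divided by
#' the mean of the first five measurable ring widths, rounded to the nearest
#' integer.
#'
#' @param chord_length Chord length `L` across the innermost ring arc (mm).
#' @param arc_height Arc height `h` of that chord (mm).
#' @param mean_first5_width Mean of the first five measurable ring widths (mm).
#' @return An object of class `pith_estimate` with fields `chord_length`,
#'   `arc_height`, `mean_first5_width`, `estimated_radius_to_pith`, and
#'   `missing_rings`.
#' @export
estimate_pith_offset <- function(chord_length, arc_height, mean_first5_width) {
  stopifnot_scalar(chord_length, "chord_length", positive = TRUE)
  stopifnot_scalar(arc_height, "arc_height", positive = TRUE)
  stopifnot_scalar(mean_first5_width, "mean_first5_width", positive = TRUE)
  r <- (chord_length^2 + 4 * arc_height^2) / (8 * arc_height)
  structure(
    list(chord_length = chord_length, arc_height = arc_height,
         mean_first5_width = mean_first5_width,
         estimated_radius_to_pith = r,
         missing_rings = as.integer(round(r / mean_first5_width))),
    class = "pith_estimate")
}

#' @export
print.pith_estimate <- function(x, ...) {
  cat(sprintf("<pith_estimate> radius to pith %.2f mm -> %d missing rings\n",
              x$estimated_radius_to_pith, x$missing_rings))
  invisible(x)
}

#' Attach a pith offset to a ring-width series
#'
#' Pith-hit cores get offset 0 by definition; others take the
#' [estimate_pith_offset()] result.
#'
#' @param series A [ring_series()].
#' @param estimate A `pith_estimate`, ignored when `series$pith_hit`.
#' @return The series with `pith_offset_rings` set.
#' @export
set_pith_offset <- function(series, estimate = NULL) {
  if (series$pith_hit) {
    series$pith_offset_rings <- 0L
  } else {
    if (is.null(estimate)) {
      stop("non-pith-hit series needs a pith_estimate", call. = FALSE)
    }
    series$pith_offset_rings <- estimate$missing_rings
  }
  series
}

#' Exclude series with too uncertain pith offsets
#'
#' Series whose estimated number of missing rings exceeds `max_missing`
#' (strictly) are dropped; a series with exactly `max_missing` missing rings
#' is kept.
#'
#' @param series List of [ring_series()] with `pith_offset_rings` set.
#' @param max_missing Exclusion threshold (default 10).
#' @return The kept series, with attributes `n_kept` and `n_excluded`.
#' @export
apply_pith_exclusion <- function(series, max_missing = 10) {
  if (length(series) == 0L) {
    return(structure(list(), n_kept = 0L, n_excluded = 0L))
  }
  offs <- vapply(series, function(s) {
    if (is.na(s$pith_offset_rings)) {
      stop(sprintf("series %s has no pith offset; run set_pith_offset() first",
                   s$series_id), call. = FALSE)
    }
    s$pith_offset_rings
  }, integer(1))
  keep <- offs <= max_missing
  structure(series[keep], n_kept = sum(keep), n_excluded = sum(!keep))
}

#' Build a regional curve (mean width at cambial age)
#'
#' Aligns all series by cambial age (ring `i` of a series with pith offset
#' `o` has cambial age `o + i`) and averages ring widths at each age. The
#' mean curve can optionally be smoothed with the same wavelength-
#' parametrized spline used for detrending.
#'
#' @param series List of [ring_series()] with `pith_offset_rings` set.
#' @param smoothing `"none"` (raw age-aligned mean, the default) or
#'   `"spline"`.
#' @param wavelength Spline wavelength if `smoothing = "spline"`.
#' @return An object of class `regional_curve` with fields `cambial_age`,
#'   `mean_width`, `n_at_age`, and `smoothing`.
#' @export
build_regional_curve <- function(series, smoothing = c("none", "spline"),
                                 wavelength = 32) {
  smoothing <- match.arg(smoothing)
  if (length(series) == 0L) stop("need >= 1 series", call. = FALSE)
  ages <- unlist(lapply(series, function(s) {
    o <- s$pith_offset_rings
    if (is.na(o)) stop(sprintf("series %s has no pith offset", s$series_id),
                       call. = FALSE)
    o + seq_along(s$widths)
  }))
  w <- unlist(lapply(series, `[[`, "widths"))
  age_grid <- seq_len(max(ages))
  sums <- tabulate(ages, nbins = max(ages))
  mean_w <- rep(NA_real_, max(ages))
  agg <- rowsum(w, ages)
  mean_w[as.integer(rownames(agg))] <- agg[, 1L] / sums[as.integer(rownames(agg))]
  present <- sums > 0L
  cambial_age <- age_grid[present]
  mean_width <- mean_w[present]
  n_at_age <- sums[present]
  label <- "none"
  if (smoothing == "spline" && length(mean_width) >= 3L) {
    mean_width <- pmax(caps_spline(mean_width, wavelength), 0)
    label <- sprintf("spline(%g yr)", wavelength)
  }
  structure(
    list(cambial_age = cambial_age, mean_width = mean_width,
         n_at_age = n_at_age, smoothing = label),
    class = "regional_curve")
}

#' @export
print.regional_curve <- function(x, ...) {
  cat(sprintf("<regional_curve> ages %d-%d, max depth %d series, smoothing: %s\n",
              min(x$cambial_age), max(x$cambial_age), max(x$n_at_age),
              x$smoothing))
  invisible(x)
}

#' @export
as.data.frame.regional_curve <- function(x, ...) {
  data.frame(age = x$cambial_age, mean_width = x$mean_width, n = x$n_at_age)
}

#' Regional curve standardization of a ring-width series
#'
#' Divides each ring width by the regional-curve value at that ring's cambial
#' age. Indices from RCS preserve low-frequency (multi-decadal) variability,
#' which spline detrending removes, and are the basis of the long-term trend
#' model (on the log scale). Zero widths are floored at half the measurement
#' resolution (0.005 mm) so that `log` of the index stays finite. Where the
#' series is older than the curve, the curve is extended by holding its last
#' value (recorded in the `rc_extended` attribute).
#'
#' @param series A [ring_series()] with `pith_offset_rings` set.
#' @param rc A [build_regional_curve()] result.
#' @param width_floor Floor applied to zero widths before division (mm).
#' @return An `rwi_series` with `method = "rcs"` and `cambial_ages`.
#' @export
rcs_detrend <- function(series, rc, width_floor = 0.005) {
  stopifnot(inherits(series, "ring_series"), inherits(rc, "regional_curve"))
  o <- series$pith_offset_rings
  if (is.na(o)) stop("series has no pith offset", call. = FALSE)
  ages <- o + seq_along(series$widths)
  rc_full <- rep(NA_real_, max(ages, rc$cambial_age))
  rc_full[rc$cambial_age] <- rc$mean_width
  # interior gaps: linear interpolation; beyond last age: hold last value
  known <- which(!is.na(rc_full))
  rc_full <- approx(known, rc_full[known], xout = seq_along(rc_full),
                    rule = 2)$y
  vals <- rc_full[ages]
  if (any(vals <= 0)) {
    stop("regional curve is zero at a needed cambial age", call. = FALSE)
  }
  extended <- any(ages > max(rc$cambial_age))
  structure(
    list(series_id = series$series_id, tree_id = series$tree_id,
         first_year = series$first_year,
         indices = pmax(series$widths, width_floor) / vals,
         method = "rcs", cambial_ages = ages),
    class = "rwi_series",
    rc_extended = extended)
}

#' Flatten detrended series to a long table
#'
#' @param rwi_list List of `rwi_series`.
#' @return A data frame with columns `series_id`, `tree_id`, `year`, `index`,
#'   `method`, suitable for CSV export and for the modelling functions.
#' @export
rwi_table <- function(rwi_list) {
  rwi_list <- rwi_list[!vapply(rwi_list, is.null, logical(1))]
  do.call(rbind, lapply(rwi_list, function(s) {
    data.frame(series_id = s$series_id, tree_id = s$tree_id,
               year = s$first_year + seq_along(s$indices) - 1L,
               index = s$indices, method = s$method, row.names = NULL)
  }))
}
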