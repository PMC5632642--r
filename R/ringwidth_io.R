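#' Construct a dated ring-width series
#'
#' A `ring_series` holds one dated raw ring-width measurement series (one
#' core), in millimetres at 0.01 mm resolution, together with the metadata
#' needed downstream: which tree and site it belongs to, whether the core hit
#' the pith, and (once estimated) how many innermost rings are missing.
#'
#' @param series_id Unique series (core) identifier, at most 8 characters for
#'   RWL export.
#' @param widths Numeric vector of ring widths in mm, one per year, ordered
#'   from the innermost measured ring outward. All values must be >= 0 and
#'   representable as integer hundredths of a millimetre.
#' @param first_year Calendar year of the first (innermost) ring.
#' @param tree_id,site,species Identifiers carried through to the models.
#' @param coring_height Either `"base"` (root-collar core, used for age
#'   estimation) or `"breast_height"` (used for growth analyses).
#' @param pith_hit Logical; `TRUE` if the core contains the pith, in which
#'   case the pith offset is 0 by definition.
#' @param pith_offset_rings Nonnegative integer count of estimated missing
#'   innermost rings; `NA` until estimated (see [estimate_pith_offset()]).
#'
#' @return An object of class `ring_series`.
#' @seealso [read_rwl()], [write_rwl()], [spline_detrend()]
#' @export
ring_series <- function(series_id, widths, first_year,
                        tree_id = series_id, site = "site", species = "species",
                        coring_height = c("breast_height", "base"),
                        pith_hit = FALSE, pith_offset_rings = NA_integer_) {
  coring_height <- match.arg(coring_height)
  widths <- as.numeric(widths)
  if (length(widths) == 0L) stop("`widths` must be nonempty", call. = FALSE)
  if (anyNA(widths) || any(!is.finite(widths))) {
    stop("`widths` must be finite", call. = FALSE)
  }
  if (any(widths < 0)) stop("ring widths must be >= 0", call. = FALSE)
  hundredths <- widths * 100
  if (max(abs(hundredths - round(hundredths))) > 1e-6) {
    stop("ring widths must be representable at 0.01 mm resolution", call. = FALSE)
  }
  if (!is.na(pith_offset_rings) && pith_offset_rings < 0) {
    stop("`pith_offset_rings` must be nonnegative", call. = FALSE)
  }
  structure(
    list(series_id = as.character(series_id),
         tree_id = as.character(tree_id),
         site = as.character(site),
         species = as.character(species),
         first_year = as.integer(first_year),
         widths = round(hundredths) / 100,
         coring_height = coring_height,
         pith_hit = isTRUE(pith_hit),
         pith_offset_rings = as.integer(pith_offset_rings)),
    class = "ring_series"
  )
}

#' @export
print.ring_series <- function(x, ...) {
  cat(sprintf("<ring_series> %s (%s, %s, %s core)\n", x$series_id, x$site,
              x$species, x$coring_height))
  cat(sprintf("  years %d-%d (%d rings), mean width %.2f mm\n",
              x$first_year, x$first_year + length(x$widths) - 1L,
              length(x$widths), mean(x$widths)))
  if (!is.na(x$pith_offset_rings)) {
    cat(sprintf("  pith offset: %d missing rings\n", x$pith_offset_rings))
  } else if (x$pith_hit) {
    cat("  pith hit\n")
  }
  invisible(x)
}

years.ring_series <- function(x) x$first_year + seq_along(x$widths) - 1L

#' Read a Tucson/RWL decadal ring-width file
#'
#' Parses the decadal-row Tucson format. Two dialects are auto-detected from
#' the end-of-series marker: widths in 0.01 mm terminated by `999` (the
#' default written by [write_rwl()]) and widths in 0.001 mm terminated by
#' `-9999`.
#'
#' @param path Path to an RWL text file.
#' @return A named list of [ring_series()] objects (empty, with a warning,
#'   for an empty file).
#' @export
read_rwl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty RWL file: ", path)
    return(structure(list(), names = character()))
  }
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  # dialect: -9999 marker => 0.001 mm, otherwise 0.01 mm with 999 marker
  flat <- unlist(toks)
  divisor <- if (any(flat == "-9999")) 1000 else 100
  marker <- if (divisor == 1000) -9999L else 999L

  out <- list()
  cur_id <- NULL
  cur_first <- NULL
  cur_vals <- integer()
  next_year <- NULL
  closed <- character()

  finish <- function() {
    if (is.null(cur_id)) return(invisible())
    if (cur_id %in% names(out)) {
      stop("duplicate series code in RWL file: ", cur_id, call. = FALSE)
    }
    out[[cur_id]] <<- ring_series(cur_id, cur_vals / divisor, cur_first)
    closed <<- c(closed, cur_id)
  }

  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) < 3L) {
      stop(sprintf("malformed decade row at line %d of %s", i, path), call. = FALSE)
    }
    id <- tk[[1]]
    year <- suppressWarnings(as.integer(tk[[2]]))
    vals <- suppressWarnings(as.integer(tk[-(1:2)]))
    if (is.na(year) || anyNA(vals)) {
      stop(sprintf("malformed decade row at line %d of %s", i, path), call. = FALSE)
    }
    if (is.null(cur_id) || id != cur_id) {
      finish()
      if (id %in% closed) {
        stop("duplicate series code in RWL file: ", id, call. = FALSE)
      }
      cur_id <- id
      cur_first <- year
      cur_vals <- integer()
      next_year <- year
    } else if (year != next_year) {
      stop(sprintf("malformed decade row at line %d of %s: expected year %d, found %d",
                   i, path, next_year, year), call. = FALSE)
    }
    hit_marker <- match(marker, vals)
    if (!is.na(hit_marker)) {
      cur_vals <- c(cur_vals, vals[seq_len(hit_marker - 1L)])
      finish()
      cur_id <- NULL
    } else {
      cur_vals <- c(cur_vals, vals)
      next_year <- year + length(vals)
    }
  }
  finish()
  out
}

#' Write ring-width series to a Tucson/RWL decadal file
#'
#' Writes the 0.01 mm dialect with `999` end-of-series marker by default, or
#' the 0.001 mm dialect with `-9999`. Rows are split at decade boundaries so
#' that each line covers years up to the next year ending in 9.
#'
#' @param series A list of [ring_series()] objects, or a single one.
#' @param path Output file path.
#' @param dialect `"hundredths"` (0.01 mm, marker 999) or `"thousandths"`
#'   (0.001 mm, marker -9999).
#' @return `path`, invisibly.
#' @export
write_rwl <- function(series, path, dialect = c("hundredths", "thousandths")) {
  dialect <- match.arg(dialect)
  if (inherits(series, "ring_series")) series <- list(series)
  mult <- if (dialect == "hundredths") 100 else 1000
  marker <- if (dialect == "hundredths") 999L else -9999L
  # marker value must be unreachable as a width
  max_units <- if (dialect == "hundredths") 998L else 99999L
  con <- file(path, "w")
  on.exit(close(con))
  for (s in series) {
    vals <- as.integer(round(s$widths * mult))
    if (any(vals > max_units)) {
      stop(sprintf("series %s has widths exceeding the %s dialect maximum",
                   s$series_id, dialect), call. = FALSE)
    }
    yrs <- years.ring_series(s)
    vals <- c(vals, marker)
    yrs <- c(yrs, max(yrs) + 1L)
    row_of <- yrs %/% 10L
    for (d in unique(row_of)) {
      sel <- row_of == d
      writeLines(sprintf("%-8s%4d%s", s$series_id, min(yrs[sel]),
                         paste0(sprintf("%6d", vals[sel]), collapse = "")), con)
    }
  }
  invisible(path)
}

#' Read a tree metadata table
#'
#' Reads a CSV with one row per tree and at least the columns `tree_id`,
#' `site`, `species`, `elevation`; the optional columns `dbh`, `height`,
#' `crown_length`, `aspect`, `slope`, `multi_stem` are kept when present.
#'
#' @param path CSV file path.
#' @return A data frame, one row per `tree_id`.
#' @export
read_tree_meta <- function(path) {
  meta <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("tree_id", "site", "species", "elevation")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata file misses columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$tree_id)) {
    stop("metadata must contain one record per tree_id", call. = FALSE)
  }
  if (any(!is.finite(meta$elevation))) {
    stop("elevation must be finite for all trees", call. = FALSE)
  }
  if ("dbh" %in% names(meta) && any(meta$dbh <= 0, na.rm = TRUE)) {
    stop("dbh must be positive where present", call. = FALSE)
  }
  meta
}

#' Simplified quantitative crossdating quality control
#'
#' Correlates each high-pass-filtered (spline-detrended) series against the
#' leave-one-out mean index chronology of all other series, overall and in
#' sliding windows. Windows whose correlation falls below `threshold` are
#' flagged. This is a light-weight screening check in the spirit of COFECHA's
#' moving correlations, not a replication of its full filtering chain.
#'
#' @param series List of [ring_series()] objects (>= 2 with pairwise overlap).
#' @param window_length,window_offset Sliding-window length and step in years.
#' @param threshold Flagging threshold for window correlations (default 0.32,
#'   the conventional 99% significance level for 50-year segments).
#' @param wavelength Spline wavelength (years) for the high-pass detrending.
#' @param transform Only `"detrended_correlation"` is implemented.
#' @return A list of `crossdate_report` objects, one per series with
#'   sufficient overlap; each has `series_id`, `overall_r`, a `windows` data
#'   frame (`start`, `end`, `r`) and `flags` (window start years with
#'   `r < threshold`). Series with insufficient overlap are skipped with a
#'   warning. Use [crossdate_table()] for a flat CSV-ready summary.
#' @export
crossdate_qc <- function(series, window_length = 50, window_offset = 25,
                         threshold = 0.32, wavelength = 32,
                         transform = "detrended_correlation") {
  transform <- match.arg(transform, "detrended_correlation")
  if (length(series) < 2L) stop("crossdating requires >= 2 series", call. = FALSE)
  rwi <- lapply(series, spline_detrend, wavelength = wavelength)
  yr_min <- min(vapply(rwi, function(s) s$first_year, integer(1)))
  yr_max <- max(vapply(rwi, function(s) s$first_year + length(s$indices) - 1L,
                       numeric(1)))
  all_years <- yr_min:yr_max
  mat <- vapply(rwi, function(s) {
    v <- rep(NA_real_, length(all_years))
    v[match(s$first_year + seq_along(s$indices) - 1L, all_years)] <- s$indices
    v
  }, numeric(length(all_years)))

  reports <- list()
  for (j in seq_len(ncol(mat))) {
    others <- mat[, -j, drop = FALSE]
    master <- rowMeans(others, na.rm = TRUE)
    master[!rowSums(!is.na(others))] <- NA
    ok <- !is.na(mat[, j]) & !is.na(master)
    if (sum(ok) < window_length) {
      warning(sprintf("series %s skipped: overlap with master (%d yr) < window length",
                      series[[j]]$series_id, sum(ok)))
      next
    }
    x <- mat[ok, j]
    m <- master[ok]
    yrs <- all_years[ok]
    overall_r <- cor(x, m)
    starts <- seq(1L, length(x) - window_length + 1L, by = window_offset)
    if (tail(starts, 1L) + window_length - 1L < length(x)) {
      starts <- c(starts, length(x) - window_length + 1L)  # cover the tail
    }
    win <- data.frame(
      start = yrs[starts],
      end = yrs[starts + window_length - 1L],
      r = vapply(starts, function(s0) {
        idx <- s0:(s0 + window_length - 1L)
        cor(x[idx], m[idx])
      }, numeric(1))
    )
    reports[[series[[j]]$series_id]] <- structure(
      list(series_id = series[[j]]$series_id,
           overall_r = overall_r,
           windows = win,
           flags = win$start[win$r < threshold],
           threshold = threshold),
      class = "crossdate_report")
  }
  reports
}

#' @export
print.crossdate_report <- function(x, ...) {
  cat(sprintf("<crossdate_report> %s: overall r = %.3f, %d/%d windows flagged (r < %.2f)\n",
              x$series_id, x$overall_r, length(x$flags), nrow(x$windows),
              x$threshold))
  invisible(x)
}

#' Flatten crossdating reports to a data frame
#'
#' @param reports Output of [crossdate_qc()].
#' @return A data frame with one row per series and window, ready for CSV
#'   export: `series_id`, `overall_r`, `window_start`, `window_end`,
#'   `window_r`, `flagged`.
#' @export
crossdate_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(series_id = r$series_id, overall_r = r$overall_r,
               window_start = r$windows$start, window_end = r$windows$end,
               window_r = r$windows$r,
               flagged = r$windows$r < r$threshold,
               row.names = NULL)
  }))
}
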